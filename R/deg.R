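#' Log2 fold change between age groups
#'
#' `log2((mean_aged + pseudocount) / (mean_young + pseudocount))`;
#' positive values mean upregulation with age.
#'
#' @param mean_young,mean_aged Group mean expression (RPKM); vectorized.
#' @param pseudocount Stabilizer added to both means.
#' @export
#' @examples
#' log2_fold_change(4, 1)   # -2: downregulated 4-fold with age
log2_fold_change <- function(mean_young, mean_aged, pseudocount = 0) {
  check_number(pseudocount, "pseudocount", min = 0)
  if (any(mean_young < 0) || any(mean_aged < 0)) {
    stop_cochle("means must be non-negative", "config_error")
  }
  if (pseudocount == 0 && any(mean_young == 0 & mean_aged == 0)) {
    stop_cochle("log2 fold change undefined: both means zero with zero pseudocount",
                "undefined_value")
  }
  log2((mean_aged + pseudocount) / (mean_young + pseudocount))
}

#' One-way fixed-effects ANOVA for a two-group comparison
#'
#' For two groups the F statistic equals the square of the pooled-variance
#' t statistic, with p from the F distribution on (1, n-2) degrees of
#' freedom. Degenerate inputs: identical groups with zero within-group
#' variance give p = 1; distinct means with zero within-group variance
#' give p = 0.
#'
#' @param young_reps,aged_reps Numeric replicate vectors (>= 2 each).
#' @return A list with `f`, `p_value`, `df`.
#' @export
#' @examples
#' two_group_anova(c(1, 2, 3), c(3, 4, 5))  # F = 6, p ~ 0.070
two_group_anova <- function(young_reps, aged_reps) {
  n1 <- length(young_reps); n2 <- length(aged_reps)
  if (n1 < 2 || n2 < 2) {
    stop_cochle("need >= 2 replicates per group", "config_error")
  }
  m1 <- mean(young_reps); m2 <- mean(aged_reps)
  ssw <- sum((young_reps - m1)^2) + sum((aged_reps - m2)^2)
  gm <- (n1 * m1 + n2 * m2) / (n1 + n2)
  ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  df2 <- n1 + n2 - 2
  if (ssw == 0) {
    f <- if (ssb == 0) 0 else Inf
    p <- if (ssb == 0) 1 else 0
  } else {
    f <- (ssb / 1) / (ssw / df2)
    p <- pf(f, 1, df2, lower.tail = FALSE)
  }
  list(f = f, p_value = p, df = c(1, df2))
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false-discovery-rate adjustment (monotone in rank, clipped to
#' 1; tied p values receive identical adjusted values).
#'
#' @param p_values Numeric vector in \[0, 1\]; `NA` is an error.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_fdr <- function(p_values) {
  if (anyNA(p_values)) stop_cochle("NA p values", "config_error")
  check_prob(p_values, "p_values")
  p.adjust(p_values, method = "BH")
}

#' Classify differentially expressed genes for one cell type
#'
#' Implements the study's DEG rule. Genes expressed above background
#' (mean replicate RPKM > `background_rpkm`) in at least one age are
#' tested: a one-way ANOVA on `log2(RPKM + pseudocount)` per gene, BH-FDR
#' over tested genes only, then
#' `up` if `log2fc >= log2fc_min` and `fdr <= fdr_max`,
#' `down` if `log2fc <= -log2fc_min` and `fdr <= fdr_max`, else `ns`;
#' genes below background in both ages are `not_expressed`.
#'
#' @param rpkm RPKM tibble (`gene_symbol` + sample columns named
#'   `<celltype>_<age>_rep<k>`).
#' @param cell_type Which cell type to test.
#' @param ages Character of length 2: `c(young_label, aged_label)`.
#' @param thresholds A [deg_thresholds()] bundle.
#' @param pseudocount Added inside the log2 for both the test and the
#'   fold change.
#' @return A `deg_table` tibble with columns `gene_symbol`, `mean_young`,
#'   `mean_aged`, `log2fc`, `p_value`, `fdr`, `status`; the summary
#'   triple is available via [glance.deg_table()].
#' @export
classify_deg <- function(rpkm, cell_type, ages = c("young", "aged"),
                         thresholds = deg_thresholds(),
                         pseudocount = 0.01) {
  stopifnot(length(ages) == 2)
  check_number(pseudocount, "pseudocount", min = 0, strict_min = TRUE)
  info <- parse_sample_names(names(rpkm)[-1])
  young_cols <- info$sample[info$cell_type == cell_type &
                              info$age == ages[1]]
  aged_cols <- info$sample[info$cell_type == cell_type &
                             info$age == ages[2]]
  if (!length(young_cols) || !length(aged_cols)) {
    stop_cochle(sprintf("cell type '%s' lacks samples at one of the ages",
                        cell_type), "config_error")
  }
  young <- as.matrix(rpkm[young_cols])
  aged <- as.matrix(rpkm[aged_cols])
  mean_young <- rowMeans(young)
  mean_aged <- rowMeans(aged)
  expressed <- mean_young > thresholds$background_rpkm |
    mean_aged > thresholds$background_rpkm

  # vectorized two-group pooled-variance F on log2(RPKM + pseudocount)
  ly <- log2(young + pseudocount); la <- log2(aged + pseudocount)
  n1 <- ncol(ly); n2 <- ncol(la)
  m1 <- rowMeans(ly); m2 <- rowMeans(la)
  ssw <- rowSums((ly - m1)^2) + rowSums((la - m2)^2)
  gm <- (n1 * m1 + n2 * m2) / (n1 + n2)
  ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  df2 <- n1 + n2 - 2
  f <- ifelse(ssw == 0, ifelse(ssb == 0, 0, Inf), ssb / (ssw / df2))
  p <- ifelse(ssw == 0, ifelse(ssb == 0, 1, 0),
              pf(ssb / (ssw / df2), 1, df2, lower.tail = FALSE))

  out <- tibble(
    gene_symbol = rpkm$gene_symbol,
    mean_young = mean_young, mean_aged = mean_aged,
    log2fc = log2((mean_aged + pseudocount) /
                    (mean_young + pseudocount)),
    p_value = ifelse(expressed, p, NA_real_),
    fdr = NA_real_,
    status = "not_expressed"
  )
  # FDR family: genes expressed in >= 1 age for this cell type
  out$fdr[expressed] <- bh_fdr(out$p_value[expressed])
  sig <- expressed & !is.na(out$fdr) & out$fdr <= thresholds$fdr_max
  out$status[expressed] <- "ns"
  out$status[sig & out$log2fc >= thresholds$log2fc_min] <- "up"
  out$status[sig & out$log2fc <= -thresholds$log2fc_min] <- "down"
  out$status <- factor(out$status,
                       levels = c("up", "down", "ns", "not_expressed"))
  structure(out, cell_type = cell_type, ages = ages,
            thresholds = thresholds,
            class = c("deg_table", class(out)))
}

#' Summary triple of a DEG table
#'
#' @param x A `deg_table` from [classify_deg()].
#' @param ... Unused.
#' @return One-row tibble with `n_tested`, `n_deg`, `n_up`, `n_down`
#'   (`n_deg = n_up + n_down` always).
#' @method glance deg_table
#' @export
glance.deg_table <- function(x, ...) {
  tibble(cell_type = attr(x, "cell_type") %||% NA_character_,
         n_tested = sum(x$status != "not_expressed"),
         n_deg = sum(x$status %in% c("up", "down")),
         n_up = sum(x$status == "up"),
         n_down = sum(x$status == "down"))
}

#' @importFrom rlang %||%
NULL

#' Write a DEG table as TSV
#'
#' @param deg A `deg_table`.
#' @param path Output path.
#' @export
write_deg_table <- function(deg, path) {
  readr::write_tsv(as_tibble(deg), path)
  invisible(path)
}
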