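#' Read or write a gene expression matrix (TSV)
#'
#' Expression tables are tab-separated with a header row: first column
#' `gene_symbol`, remaining columns one sample each, named
#' `<celltype>_<age>_rep<k>` (e.g. `IHC_aged_rep2`). Values are RPKM or
#' raw counts; duplicate gene symbols and non-numeric cells are format
#' errors, not silently coerced.
#'
#' @param path File path.
#' @return A tibble with `gene_symbol` plus one numeric column per sample.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) {
    stop_cochle(sprintf("no such file: %s", path), "format_error")
  }
  raw <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t",
                      colClasses = "character", check.names = FALSE),
    error = function(e) stop_cochle(
      sprintf("cannot parse %s as TSV: %s", path, conditionMessage(e)),
      "format_error"))
  if (nrow(raw) == 0 || ncol(raw) < 2) {
    stop_cochle("expression TSV is empty or has no sample columns",
                "format_error")
  }
  names(raw)[1] <- "gene_symbol"
  dup <- raw$gene_symbol[duplicated(raw$gene_symbol)]
  if (length(dup)) {
    stop_cochle(sprintf("duplicate gene symbol(s): %s",
                        paste(unique(dup), collapse = ", ")),
                "format_error")
  }
  for (j in 2:ncol(raw)) {
    vals <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(vals) & !is.na(raw[[j]]) & raw[[j]] != "NA")
    if (length(bad)) {
      stop_cochle(sprintf(
        "non-numeric value '%s' at row %d, column '%s'",
        raw[[j]][bad[1]], bad[1], names(raw)[j]), "format_error")
    }
    raw[[j]] <- vals
  }
  if (any(vapply(raw[-1], function(x) any(x < 0, na.rm = TRUE),
                 logical(1)))) {
    stop_cochle("expression values must be non-negative", "format_error")
  }
  as_tibble(raw)
}

#' @rdname read_expression_matrix
#' @param matrix A tibble as returned by [read_expression_matrix()].
#' @export
write_expression_matrix <- function(matrix, path) {
  stopifnot(is.data.frame(matrix), names(matrix)[1] == "gene_symbol")
  readr::write_tsv(matrix, path)
  invisible(path)
}

#' Parse sample descriptors from column names
#'
#' Sample columns follow `<celltype>_<age>_rep<k>`.
#'
#' @param x Character vector of sample names.
#' @return A tibble with columns `sample`, `cell_type`, `age`,
#'   `replicate`.
#' @export
parse_sample_names <- function(x) {
  m <- regmatches(x, regexec("^(.+)_(.+)_rep([0-9]+)$", x))
  bad <- x[vapply(m, length, integer(1)) != 4]
  if (length(bad)) {
    stop_cochle(sprintf(
      "sample name(s) not of form <celltype>_<age>_rep<k>: %s",
      paste(bad, collapse = ", ")), "format_error")
  }
  tibble(sample = x,
         cell_type = vapply(m, `[`, character(1), 2),
         age = vapply(m, `[`, character(1), 3),
         replicate = as.integer(vapply(m, `[`, character(1), 4)))
}

#' Convert raw counts to RPKM
#'
#' RPKM (reads per kilobase of transcript per million mapped reads):
#' \eqn{count \cdot 10^9 / (length_{bp} \cdot library)}.
#'
#' @param counts A counts tibble (`gene_symbol` + sample columns).
#' @param gene_lengths A data frame with `gene_symbol` and `length_bp`,
#'   covering every gene in `counts`.
#' @param library_sizes Named numeric vector (or data frame with `sample`,
#'   `reads`) of mapped reads per sample; defaults to the per-sample
#'   column sums of `counts`.
#' @return A tibble of the same shape with RPKM values.
#' @export
#' @examples
#' counts <- tibble::tibble(gene_symbol = "Slc26a5", OHC_young_rep1 = 10)
#' lens <- tibble::tibble(gene_symbol = "Slc26a5", length_bp = 1000)
#' compute_rpkm(counts, lens, c(OHC_young_rep1 = 1e6))  # 10 RPKM
compute_rpkm <- function(counts, gene_lengths, library_sizes = NULL) {
  stopifnot(names(counts)[1] == "gene_symbol")
  samples <- names(counts)[-1]
  if (is.data.frame(library_sizes)) {
    library_sizes <- setNames(library_sizes$reads, library_sizes$sample)
  }
  if (is.null(library_sizes)) {
    library_sizes <- vapply(counts[samples], sum, numeric(1))
  }
  if (!all(samples %in% names(library_sizes))) {
    stop_cochle("library_sizes missing for some samples", "config_error")
  }
  if (any(library_sizes[samples] <= 0)) {
    stop_cochle("library sizes must be positive", "config_error")
  }
  len <- gene_lengths$length_bp[match(counts$gene_symbol,
                                      gene_lengths$gene_symbol)]
  if (anyNA(len)) {
    miss <- counts$gene_symbol[is.na(len)]
    stop_cochle(sprintf("missing gene length(s): %s%s",
                        paste(utils::head(miss, 5), collapse = ", "),
                        if (length(miss) > 5) ", ..." else ""),
                "config_error")
  }
  out <- counts
  for (s in samples) {
    out[[s]] <- counts[[s]] * 1e9 / (len * library_sizes[[s]])
  }
  out
}

#' DEG thresholds
#'
#' The classification thresholds of the differential-expression rule:
#' a gene must be expressed above `background_rpkm` (mean replicate RPKM,
#' strict `>`), show `|log2FC| >= log2fc_min` between the ages, and reach
#' `fdr <= fdr_max` (both inclusive).
#'
#' @param background_rpkm Background expression cutoff (RPKM).
#' @param log2fc_min Minimum absolute log2 fold change.
#' @param fdr_max Maximum BH-adjusted p value.
#' @export
deg_thresholds <- function(background_rpkm = 0.1, log2fc_min = 1,
                           fdr_max = 0.10) {
  check_number(background_rpkm, "background_rpkm", min = 0,
               strict_min = TRUE)
  check_number(log2fc_min, "log2fc_min", min = 0, strict_min = TRUE)
  check_number(fdr_max, "fdr_max", min = 0, strict_min = TRUE)
  structure(list(background_rpkm = background_rpkm,
                 log2fc_min = log2fc_min, fdr_max = fdr_max),
            class = "deg_thresholds")
}

#' Genes expressed above background in one (cell type, age) group
#'
#' A gene counts as expressed in a group when its mean replicate RPKM
#' exceeds the background cutoff (strict `>`; with `rule = "any"`, a
#' single replicate above background suffices instead).
#'
#' @param rpkm RPKM tibble (`gene_symbol` + sample columns).
#' @param cell_type,age Group selector, matched against the parsed sample
#'   descriptors.
#' @param thresholds A [deg_thresholds()] bundle.
#' @param rule `"mean"` (default) or `"any"`.
#' @return A tibble with `gene_symbol` and `mean_rpkm` for expressed
#'   genes; the number expressed is `nrow()` of the result.
#' @export
filter_expressed <- function(rpkm, cell_type, age,
                             thresholds = deg_thresholds(),
                             rule = c("mean", "any")) {
  rule <- match.arg(rule)
  info <- parse_sample_names(names(rpkm)[-1])
  cols <- info$sample[info$cell_type == cell_type & info$age == age]
  if (!length(cols)) {
    stop_cochle(sprintf("no samples for group (%s, %s)", cell_type, age),
                "config_error")
  }
  vals <- as.matrix(rpkm[cols])
  mean_rpkm <- rowMeans(vals)
  keep <- if (rule == "mean") {
    mean_rpkm > thresholds$background_rpkm
  } else {
    apply(vals > thresholds$background_rpkm, 1, any)
  }
  tibble(gene_symbol = rpkm$gene_symbol[keep],
         mean_rpkm = mean_rpkm[keep])
}
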