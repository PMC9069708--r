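#' Design of a synthetic two-age expression study
#'
#' Describes a replicate RNA-seq study of isolated cochlear cell
#' populations at two ages, with a planted aging signature: a chosen
#' fraction of genes is shifted up or down by a fixed log2 fold change in
#' the aged samples of every cell type. Baseline gene abundances are
#' lognormal across genes; replicate counts are negative binomial;
#' RPKM is then derived from the counts, the drawn gene lengths and the
#' realized library sizes, so the whole RPKM pipeline is exercised.
#'
#' @param n_genes Number of genes.
#' @param n_replicates Replicates per (cell type, age) group.
#' @param cell_types Cell-type labels.
#' @param ages Two age labels, young first.
#' @param frac_up,frac_down Fractions of genes planted up/down in aged
#'   samples (`frac_up + frac_down <= 1`).
#' @param effect_log2fc Planted absolute log2 fold change (>= 1 for the
#'   effect to be detectable under the DEG rule).
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param mean_log_expression,sd_log_expression Mean and SD of the
#'   natural-log gene abundance distribution.
#' @param library_size Mapped reads per sample.
#' @param gene_length_range Transcript length interval (bp).
#' @param seed RNG seed.
#' @return A validated `study_design` list.
#' @export
study_design <- function(n_genes = 2000, n_replicates = 3,
                         cell_types = c("IHC", "OHC", "SVC"),
                         ages = c("young", "aged"),
                         frac_up = 0.05, frac_down = 0.05,
                         effect_log2fc = 2, nb_dispersion = 0.05,
                         mean_log_expression = 1, sd_log_expression = 2,
                         library_size = 2e7,
                         gene_length_range = c(500, 10000), seed = 1) {
  check_number(n_genes, "n_genes", min = 1)
  check_number(n_replicates, "n_replicates", min = 2)
  if (length(ages) != 2 || anyDuplicated(ages)) {
    stop_cochle("`ages` must be two distinct labels", "config_error")
  }
  if (!length(cell_types)) stop_cochle("need >= 1 cell type",
                                       "config_error")
  check_prob(frac_up, "frac_up"); check_prob(frac_down, "frac_down")
  if (frac_up + frac_down > 1) {
    stop_cochle("frac_up + frac_down must not exceed 1", "config_error")
  }
  check_number(effect_log2fc, "effect_log2fc", min = 0)
  check_number(nb_dispersion, "nb_dispersion", min = 0)
  check_number(sd_log_expression, "sd_log_expression", min = 0)
  check_number(mean_log_expression, "mean_log_expression")
  check_number(library_size, "library_size", min = 1)
  check_number(gene_length_range, "gene_length_range", min = 1, len = 2)
  structure(list(n_genes = as.integer(n_genes),
                 n_replicates = as.integer(n_replicates),
                 cell_types = cell_types, ages = ages,
                 frac_up = frac_up, frac_down = frac_down,
                 effect_log2fc = effect_log2fc,
                 nb_dispersion = nb_dispersion,
                 mean_log_expression = mean_log_expression,
                 sd_log_expression = sd_log_expression,
                 library_size = library_size,
                 gene_length_range = gene_length_range,
                 seed = seed),
            class = "study_design")
}

#' Simulate a replicate expression study with planted truth
#'
#' Generates counts and RPKM for every (cell type, age) group of the
#' design. Exactly `round(frac_up * n_genes)` genes carry
#' `+effect_log2fc` and `round(frac_down * n_genes)` carry
#' `-effect_log2fc` in the aged samples (the same planted sets in every
#' cell type, emulating a shared aging signature); truth labels are
#' attached. Identical seeds give identical output.
#'
#' @param design A [study_design()].
#' @return An `expression_study` list: `counts` and `rpkm` tibbles
#'   (`gene_symbol` + `<celltype>_<age>_rep<k>` columns), `gene_lengths`,
#'   `library_sizes`, `truth` (tibble `gene_symbol`, `planted` in
#'   up/down/null) and the `design`.
#' @export
simulate_expression_study <- function(design = study_design()) {
  stopifnot(inherits(design, "study_design"))
  with_seed(design$seed, {
    ng <- design$n_genes
    genes <- sprintf("gene%0*d", nchar(ng), seq_len(ng))
    lengths_bp <- round(runif(ng, design$gene_length_range[1],
                              design$gene_length_range[2]))
    abund <- rlnorm(ng, design$mean_log_expression,
                    design$sd_log_expression)

    n_up <- round(design$frac_up * ng)
    n_down <- round(design$frac_down * ng)
    planted_idx <- sample.int(ng, n_up + n_down)
    planted <- rep("null", ng)
    planted[planted_idx[seq_len(n_up)]] <- "up"
    planted[planted_idx[n_up + seq_len(n_down)]] <- "down"
    fc <- rep(1, ng)
    fc[planted == "up"] <- 2^design$effect_log2fc
    fc[planted == "down"] <- 2^(-design$effect_log2fc)

    samples <- tidyr::expand_grid(cell_type = design$cell_types,
                                  age = design$ages,
                                  replicate = seq_len(design$n_replicates))
    samples$sample <- sprintf("%s_%s_rep%d", samples$cell_type,
                              samples$age, samples$replicate)
    counts <- matrix(0, ng, nrow(samples),
                     dimnames = list(NULL, samples$sample))
    size <- if (design$nb_dispersion > 0) 1 / design$nb_dispersion else Inf
    for (j in seq_len(nrow(samples))) {
      rel <- if (samples$age[j] == design$ages[2]) abund * fc else abund
      mu <- rel / sum(rel) * design$library_size
      counts[, j] <- if (is.finite(size)) {
        rnbinom(ng, mu = mu, size = size)
      } else {
        stats::rpois(ng, mu)
      }
    }
    counts_tbl <- dplyr::bind_cols(tibble(gene_symbol = genes),
                                   as_tibble(counts))
    gene_lengths <- tibble(gene_symbol = genes, length_bp = lengths_bp)
    library_sizes <- tibble(sample = samples$sample,
                            reads = colSums(counts))
    rpkm <- compute_rpkm(counts_tbl, gene_lengths,
                         setNames(library_sizes$reads,
                                  library_sizes$sample))
    structure(list(counts = counts_tbl, rpkm = rpkm,
                   gene_lengths = gene_lengths,
                   library_sizes = library_sizes,
                   truth = tibble(gene_symbol = genes, planted = planted),
                   design = design),
              class = "expression_study")
  })
}

#' Write the tables of a synthetic expression study to a directory
#'
#' Counts and RPKM as TSV, library sizes and gene lengths as TSV, and the
#' planted-truth labels as a JSON sidecar.
#'
#' @param study An `expression_study`.
#' @param dir Output directory (created if missing).
#' @export
write_expression_study <- function(study, dir) {
  stopifnot(inherits(study, "expression_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(study$counts, file.path(dir, "counts.tsv"))
  write_expression_matrix(study$rpkm, file.path(dir, "rpkm.tsv"))
  readr::write_tsv(study$gene_lengths, file.path(dir, "gene_lengths.tsv"))
  readr::write_tsv(study$library_sizes,
                   file.path(dir, "library_sizes.tsv"))
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
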