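#' Top genes changed in the same direction in two cell types
#'
#' Genes carrying the requested status (`up` or `down`) in *both* DEG
#' tables, ranked by the smaller of the two absolute log2 fold changes
#' (descending; a gene must change strongly in both cell types to rank
#' high), ties broken lexicographically by gene symbol. At most `n` genes
#' are returned; no padding when fewer qualify.
#'
#' @param deg_a,deg_b `deg_table`s from [classify_deg()] (same
#'   thresholds).
#' @param direction `"up"` or `"down"`.
#' @param n Maximum list length.
#' @return A tibble `gene_symbol`, `log2fc_a`, `log2fc_b`, `rank_metric`.
#' @export
rank_top_common <- function(deg_a, deg_b, direction = c("up", "down"),
                            n = 200) {
  direction <- match.arg(direction)
  check_number(n, "n", min = 1)
  common <- inner_join(
    select(as_tibble(deg_a), "gene_symbol", status_a = "status",
           log2fc_a = "log2fc"),
    select(as_tibble(deg_b), "gene_symbol", status_b = "status",
           log2fc_b = "log2fc"),
    by = "gene_symbol")
  common <- filter(common, .data$status_a == direction,
                   .data$status_b == direction)
  common <- mutate(common,
                   rank_metric = pmin(abs(.data$log2fc_a),
                                      abs(.data$log2fc_b)))
  common <- arrange(common, desc(.data$rank_metric), .data$gene_symbol)
  utils::head(select(common, "gene_symbol", "log2fc_a", "log2fc_b",
                     "rank_metric"), n)
}

#' Members of a gene list showing the same trend in a reference table
#'
#' Keeps the genes whose status in the reference DEG table equals
#' `direction`, preserving the input order (used to count, e.g., how many
#' of the top hair-cell aging genes change the same way in stria
#' vascularis cells).
#'
#' @param gene_list Character vector (or tibble with `gene_symbol`).
#' @param reference_deg A `deg_table`.
#' @param direction `"up"` or `"down"`.
#' @return Character vector, a subset of `gene_list` in order.
#' @export
concordant_subset <- function(gene_list, reference_deg,
                              direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (is.data.frame(gene_list)) gene_list <- gene_list$gene_symbol
  ref <- as_tibble(reference_deg)
  hits <- ref$gene_symbol[ref$status == direction]
  gene_list[gene_list %in% hits]
}

#' Top genes changed in one cell type only
#'
#' Genes with status `direction` in `deg_this` whose status in
#' `deg_other` is `ns` or `not_expressed` (absent genes count as
#' `not_expressed`), ranked by absolute log2 fold change descending,
#' ties broken lexicographically.
#'
#' @param deg_this,deg_other `deg_table`s.
#' @inheritParams rank_top_common
#' @return A tibble `gene_symbol`, `log2fc`.
#' @export
exclusive_top <- function(deg_this, deg_other,
                          direction = c("up", "down"), n = 50) {
  direction <- match.arg(direction)
  check_number(n, "n", min = 1)
  this <- filter(as_tibble(deg_this), .data$status == direction)
  other <- as_tibble(deg_other)
  changed_other <- other$gene_symbol[other$status %in% c("up", "down")]
  this <- filter(this, !.data$gene_symbol %in% changed_other)
  this <- arrange(this, desc(abs(.data$log2fc)), .data$gene_symbol)
  utils::head(select(this, "gene_symbol", "log2fc"), n)
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability of seeing at least the observed overlap between
#' a hit list and an annotation category, drawing without replacement
#' from the gene universe: `P(X >= overlap)` with
#' `X ~ Hypergeom(|category|, |universe| - |category|, |hits|)`.
#'
#' @param hits,category,universe Character vectors of gene symbols;
#'   `hits` and `category` must be subsets of `universe`.
#' @return A list with `p_value`, `overlap`, `n_hits`, `n_category`,
#'   `n_universe`.
#' @export
#' @examples
#' hypergeom_enrichment(letters[1:4], letters[1:5], letters[1:10])
hypergeom_enrichment <- function(hits, category, universe) {
  universe <- unique(universe)
  hits <- unique(hits); category <- unique(category)
  if (!length(universe)) stop_cochle("empty universe", "config_error")
  if (!all(hits %in% universe) || !all(category %in% universe)) {
    stop_cochle("hits and category must be subsets of the universe",
                "config_error")
  }
  overlap <- length(intersect(hits, category))
  if (length(category) == length(universe) && overlap < length(hits)) {
    stop_cochle("inconsistent sets: category spans the universe but misses hits",
                "config_error")
  }
  p <- phyper(overlap - 1, length(category),
              length(universe) - length(category), length(hits),
              lower.tail = FALSE)
  list(p_value = p, overlap = overlap, n_hits = length(hits),
       n_category = length(category), n_universe = length(universe))
}

#' Over-representation across an annotation table
#'
#' Runs [hypergeom_enrichment()] for every category of a two-column
#' gene-to-category annotation and BH-adjusts across categories.
#'
#' @param hits Character vector of gene symbols.
#' @param annotations Data frame with columns `gene_symbol`, `category`
#'   (or a path to such a TSV).
#' @param universe Gene universe; defaults to all annotated genes plus
#'   the hits.
#' @return Tibble: `category`, `overlap`, `n_category`, `p_value`, `fdr`,
#'   sorted by p.
#' @export
enrich_categories <- function(hits, annotations, universe = NULL) {
  if (is.character(annotations) && length(annotations) == 1) {
    annotations <- readr::read_tsv(annotations, show_col_types = FALSE)
  }
  stopifnot(all(c("gene_symbol", "category") %in% names(annotations)))
  if (is.null(universe)) {
    universe <- union(annotations$gene_symbol, hits)
  }
  hits <- intersect(hits, universe)
  ann <- filter(annotations, .data$gene_symbol %in% universe)
  res <- ann |>
    group_by(.data$category) |>
    summarise(res = list(hypergeom_enrichment(hits,
                                              unique(.data$gene_symbol),
                                              universe))) |>
    ungroup()
  out <- mutate(res,
                overlap = purrr::map_int(.data$res,
                                         ~ as.integer(.x$overlap)),
                n_category = purrr::map_int(.data$res,
                                            ~ as.integer(.x$n_category)),
                p_value = purrr::map_dbl(.data$res, "p_value"))
  out <- select(out, -"res")
  out$fdr <- bh_fdr(out$p_value)
  arrange(out, .data$p_value)
}
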