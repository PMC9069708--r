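#' Hair-cell survival percentage along the cochlea
#'
#' Surviving cells at an aged time point as a percentage of the baseline
#' count at the corresponding location, per cell type:
#' `100 * aged / baseline`. Counts are taken from fixed-length areas
#' (400 um by convention) at measured distances from the apex.
#'
#' @param aged,baseline Data frames with columns `location_um`,
#'   `cell_type`, `count` (and optionally `age`). Every aged row must
#'   have a matching baseline row; zero baseline counts yield `NA`
#'   percentages, reported not dropped.
#' @return Tibble `location_um`, `cell_type`, `baseline_count`,
#'   `aged_count`, `percent`.
#' @export
#' @examples
#' survival_percentage(
#'   tibble::tibble(location_um = 800, cell_type = "OHC", count = 60),
#'   tibble::tibble(location_um = 800, cell_type = "OHC", count = 100))
survival_percentage <- function(aged, baseline) {
  need <- c("location_um", "cell_type", "count")
  stopifnot(all(need %in% names(aged)), all(need %in% names(baseline)))
  if (any(aged$count < 0) || any(baseline$count < 0)) {
    stop_cochle("counts must be non-negative", "config_error")
  }
  joined <- left_join(
    select(as_tibble(aged), "location_um", "cell_type",
           aged_count = "count"),
    select(as_tibble(baseline), "location_um", "cell_type",
           baseline_count = "count"),
    by = c("location_um", "cell_type"))
  if (anyNA(joined$baseline_count)) {
    miss <- filter(joined, is.na(.data$baseline_count))
    stop_cochle(sprintf(
      "no baseline counts for %d aged location/cell-type combination(s), e.g. %s %s",
      nrow(miss), miss$cell_type[1], format(miss$location_um[1])),
      "config_error")
  }
  mutate(joined,
         percent = ifelse(.data$baseline_count == 0, NA_real_,
                          100 * .data$aged_count /
                            .data$baseline_count)) |>
    select("location_um", "cell_type", "baseline_count", "aged_count",
           "percent")
}

#' Two-group comparison by Student's t-test
#'
#' Two-sided pooled-variance (classical Student) t-test with group means
#' and SDs; Welch's unequal-variance variant behind `welch = TRUE`.
#'
#' @param group_a,group_b Numeric vectors (>= 2 values each).
#' @param welch Use the Welch test instead of pooled variance.
#' @return One-row tibble: `mean_a`, `sd_a`, `mean_b`, `sd_b`, `t`,
#'   `df`, `p_value`.
#' @export
#' @examples
#' group_compare(c(1, 2, 3), c(3, 4, 5))  # t = -2.449, p ~ 0.0705
group_compare <- function(group_a, group_b, welch = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop_cochle("need >= 2 values per group", "config_error")
  }
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    same <- mean(group_a) == mean(group_b)
    return(tibble(mean_a = mean(group_a), sd_a = 0,
                  mean_b = mean(group_b), sd_b = 0,
                  t = if (same) 0 else sign(mean(group_a) -
                                              mean(group_b)) * Inf,
                  df = length(group_a) + length(group_b) - 2,
                  p_value = if (same) 1 else 0))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = !welch)
  tibble(mean_a = mean(group_a), sd_a = sd(group_a),
         mean_b = mean(group_b), sd_b = sd(group_b),
         t = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value)
}

#' Holm-Sidak step-down multiple-comparison correction
#'
#' Sort the p values ascending; the k-th smallest is adjusted to
#' \eqn{\max_{j \le k} [1 - (1 - p_{(j)})^{m-j+1}]}, clipped to 1, and
#' the adjusted values are mapped back to the input order. Uniformly more
#' powerful than Holm-Bonferroni under independence.
#'
#' @param p_values Numeric vector in \[0, 1\]; `NA` is an error.
#' @return Adjusted p values, same order as the input.
#' @export
#' @examples
#' holm_sidak(c(0.01, 0.04))  # c(0.0199, 0.04)
holm_sidak <- function(p_values) {
  if (anyNA(p_values)) stop_cochle("NA p values", "config_error")
  check_prob(p_values, "p_values")
  m <- length(p_values)
  ord <- order(p_values)
  ps <- p_values[ord]
  adj <- pmin(1, cummax(1 - (1 - ps)^(m - seq_len(m) + 1)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Fluorescence integrated-density fold change per target
#'
#' Integrated density of a fluorescent signal is mean gray value times
#' signal area; the reported fold change is
#' `log2(mean aged ID / mean baseline ID)` per (target, cell type), with
#' the per-cell integrated densities averaged within each age first.
#'
#' @param aged,baseline Data frames with columns `target`, `cell_type`,
#'   `mean_gray`, `area` (or a precomputed `integrated_density`).
#' @return Tibble `target`, `cell_type`, `mean_id_baseline`,
#'   `mean_id_aged`, `log2fc`.
#' @export
integrated_density_foldchange <- function(aged, baseline) {
  prep <- function(df, label) {
    df <- as_tibble(df)
    if (!"integrated_density" %in% names(df)) {
      stopifnot(all(c("mean_gray", "area") %in% names(df)))
      df <- mutate(df,
                   integrated_density = .data$mean_gray * .data$area)
    }
    stopifnot(all(c("target", "cell_type") %in% names(df)))
    df |>
      group_by(.data$target, .data$cell_type) |>
      summarise("{label}" := mean(.data$integrated_density),
                .groups = "drop")
  }
  joined <- inner_join(prep(baseline, "mean_id_baseline"),
                       prep(aged, "mean_id_aged"),
                       by = c("target", "cell_type"))
  if (!nrow(joined)) {
    stop_cochle("no matching (target, cell_type) pairs", "config_error")
  }
  if (any(joined$mean_id_baseline == 0)) {
    stop_cochle("baseline integrated density is zero for some target",
                "undefined_value")
  }
  mutate(joined,
         log2fc = log2(.data$mean_id_aged / .data$mean_id_baseline))
}
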