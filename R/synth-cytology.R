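#' Simulate a cochleogram count table
#'
#' Baseline (young) counts are taken as given per location and cell
#' type; aged counts are drawn binomially from the baseline with the
#' stated survival probabilities, emulating independent cell loss.
#'
#' @param baseline Data frame with columns `location_um`, `cell_type`,
#'   `count` (non-negative integers).
#' @param survival_prob Either a single probability, or a data frame
#'   with `location_um`, `cell_type`, `prob` matched against `baseline`.
#' @param aged_label,baseline_label Age labels attached to the output.
#' @param seed RNG seed.
#' @return Tibble `location_um`, `cell_type`, `age`, `count`: the
#'   baseline rows unchanged plus the drawn aged rows.
#' @export
#' @examples
#' base <- tibble::tibble(location_um = c(800, 2000),
#'                        cell_type = "OHC", count = c(200, 180))
#' simulate_cochleogram(base, survival_prob = 0.6, seed = 1)
simulate_cochleogram <- function(baseline, survival_prob,
                                 aged_label = "aged",
                                 baseline_label = "young", seed = NULL) {
  need <- c("location_um", "cell_type", "count")
  stopifnot(all(need %in% names(baseline)))
  if (any(baseline$count < 0) ||
      any(baseline$count != round(baseline$count))) {
    stop_cochle("baseline counts must be non-negative integers",
                "config_error")
  }
  base <- as_tibble(baseline)
  if (is.data.frame(survival_prob)) {
    stopifnot(all(c("location_um", "cell_type", "prob") %in%
                    names(survival_prob)))
    base <- left_join(base, survival_prob,
                      by = c("location_um", "cell_type"))
    if (anyNA(base$prob)) {
      stop_cochle("survival_prob missing for some location/cell type",
                  "config_error")
    }
  } else {
    base$prob <- survival_prob
  }
  check_prob(base$prob, "survival_prob")
  aged_counts <- with_seed(seed,
                           rbinom(nrow(base), base$count, base$prob))
  bind_rows(
    mutate(select(base, -"prob"), age = baseline_label),
    mutate(select(base, -"prob", -"count"), age = aged_label,
           count = aged_counts)
  ) |>
    select("location_um", "cell_type", "age", "count")
}

#' Simulate a fluorescence quantification table
#'
#' Per-cell mean gray values are lognormal around a target-specific
#' baseline, scaled in the aged group by the planted fold change of that
#' target; signal areas are lognormal and age-independent. Recovering the
#' planted log2 fold changes with [integrated_density_foldchange()]
#' closes the loop.
#'
#' @param targets Character vector of target (gene/protein) labels.
#' @param log2fc Planted log2 fold change per target (recycled).
#' @param n_cells Cells measured per target and age.
#' @param cell_type Cell-type label attached to all rows.
#' @param baseline_gray Median baseline mean-gray value (a.u.).
#' @param sdlog_gray Lognormal sdlog of per-cell gray values.
#' @param mean_area Median signal area (px^2).
#' @param sdlog_area Lognormal sdlog of areas.
#' @param ages Two labels, young first.
#' @param seed RNG seed.
#' @return Tibble `target`, `cell_type`, `age`, `cell`, `mean_gray`,
#'   `area`, `integrated_density`.
#' @export
simulate_fluorescence <- function(targets, log2fc, n_cells = 20,
                                  cell_type = "OHC",
                                  baseline_gray = 100, sdlog_gray = 0.3,
                                  mean_area = 50, sdlog_area = 0.2,
                                  ages = c("young", "aged"),
                                  seed = NULL) {
  stopifnot(length(ages) == 2)
  check_number(n_cells, "n_cells", min = 1)
  log2fc <- rep_len(log2fc, length(targets))
  with_seed(seed, {
    grid <- tidyr::expand_grid(target = targets, age = ages,
                               cell = seq_len(n_cells))
    fc <- setNames(log2fc, targets)
    scale <- ifelse(grid$age == ages[2], 2^fc[grid$target], 1)
    grid$mean_gray <- rlnorm(nrow(grid), log(baseline_gray * scale),
                             sdlog_gray)
    grid$area <- rlnorm(nrow(grid), log(mean_area), sdlog_area)
    mutate(grid, cell_type = cell_type,
           integrated_density = .data$mean_gray * .data$area) |>
      select("target", "cell_type", "age", "cell", "mean_gray", "area",
             "integrated_density")
  })
}
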