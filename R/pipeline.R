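#' Pipeline configuration
#'
#' Assembles and validates the configuration of a full synthetic-study
#' run: the RNG seed, DEG thresholds, expression-study design, dual-sine
#' protocol and cell parameters, fiber and cytology settings, and stage
#' toggles. Unknown keys are rejected up front so typos fail before any
#' stage runs.
#'
#' @param seed Integer seed governing every stage's RNG stream.
#' @param thresholds A [deg_thresholds()] bundle.
#' @param design A [study_design()]; its own seed is derived from `seed`.
#' @param protocol,circuit,boltzmann Electrophysiology settings (see
#'   [two_sine_protocol()], [circuit_params()], [boltzmann_params()]).
#' @param noise_rms_pA Current noise for the simulated recording, pA.
#' @param fiber List: `kf`, `true_kc`, `lf_amp`, `noise_rms`.
#' @param cochleogram List: `baseline` count table, `survival_prob`.
#' @param fluorescence List: `targets`, `log2fc`, `n_cells`.
#' @param stages Character subset of
#'   `c("expression", "nlc", "stiffness", "cytology")`.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(
    seed = 1,
    thresholds = deg_thresholds(),
    design = study_design(seed = seed),
    protocol = two_sine_protocol(),
    circuit = circuit_params(),
    boltzmann = boltzmann_params(),
    noise_rms_pA = 5,
    fiber = list(kf = 5, true_kc = 4, lf_amp = 50, noise_rms = 1),
    cochleogram = list(
      baseline = tibble(
        location_um = rep(c(800, 1600, 2400, 3200, 4000, 4800),
                          each = 2),
        cell_type = rep(c("IHC", "OHC"), times = 6),
        count = rep(c(50, 150), times = 6)),
      survival_prob = 0.8),
    fluorescence = list(targets = c("Slc26a5", "Kcnq4", "Cbx3"),
                        log2fc = c(-1.5, -1, 0.5), n_cells = 20),
    stages = c("expression", "nlc", "stiffness", "cytology")) {
  check_number(seed, "seed")
  stopifnot(inherits(thresholds, "deg_thresholds"),
            inherits(design, "study_design"),
            inherits(protocol, "two_sine_protocol"),
            inherits(circuit, "circuit_params"),
            inherits(boltzmann, "boltzmann_params"))
  check_number(noise_rms_pA, "noise_rms_pA", min = 0)
  known <- c("expression", "nlc", "stiffness", "cytology")
  if (!all(stages %in% known)) {
    stop_cochle(sprintf("unknown stage(s): %s",
                        paste(setdiff(stages, known), collapse = ", ")),
                "config_error")
  }
  cfg <- list(seed = as.integer(seed), thresholds = thresholds,
              design = design, protocol = protocol, circuit = circuit,
              boltzmann = boltzmann, noise_rms_pA = noise_rms_pA,
              fiber = fiber, cochleogram = cochleogram,
              fluorescence = fluorescence, stages = stages)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; nested sections
#' (`thresholds`, `design`, `protocol`, `circuit`, `boltzmann`) override
#' individual defaults. Unknown keys anywhere are rejected.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  top_known <- c("seed", "thresholds", "design", "protocol", "circuit",
                 "boltzmann", "noise_rms_pA", "fiber", "cochleogram",
                 "fluorescence", "stages")
  extra <- setdiff(names(raw), top_known)
  if (length(extra)) {
    stop_cochle(sprintf("unknown config key(s): %s",
                        paste(extra, collapse = ", ")), "config_error")
  }
  build <- function(ctor, vals, extra_args = list()) {
    if (is.null(vals)) vals <- list()
    ok <- names(formals(ctor))
    bad <- setdiff(names(vals), ok)
    if (length(bad)) {
      stop_cochle(sprintf("unknown config key(s): %s",
                          paste(bad, collapse = ", ")), "config_error")
    }
    do.call(ctor, c(vals, extra_args[setdiff(names(extra_args),
                                             names(vals))]))
  }
  seed <- raw$seed %||% 1
  args <- list(
    seed = seed,
    thresholds = build(deg_thresholds, raw$thresholds),
    design = build(study_design, raw$design, list(seed = seed)),
    protocol = build(two_sine_protocol, raw$protocol),
    circuit = build(circuit_params, raw$circuit),
    boltzmann = build(boltzmann_params, raw$boltzmann))
  for (k in c("noise_rms_pA", "fiber", "cochleogram", "fluorescence",
              "stages")) {
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  }
  if (!is.null(args$cochleogram$baseline)) {
    args$cochleogram$baseline <- as_tibble(args$cochleogram$baseline)
  }
  do.call(pipeline_config, args)
}

config_hash <- function(config) {
  rlang::hash(unclass(lapply(unclass(config), unclass)))
}

#' Run the full synthetic-study pipeline
#'
#' Executes the enabled stages in dependency order — simulate an
#' expression study, filter/classify/summarize DEGs and gene lists;
#' simulate a dual-sine recording, estimate the capacitance-voltage
#' series and fit the Boltzmann model; simulate fiber traces and recover
#' axial stiffness; simulate cochleogram and fluorescence tables and
#' quantify them — writing stage artifacts under `outdir` and a
#' machine-readable JSON report. A failed stage is recorded in the
#' report; later independent stages still run. Identical config and seed
#' give identical reports.
#'
#' @param config A `pipeline_config`.
#' @param outdir Output directory for artifacts and `report.json`.
#' @return The report, invisibly (a nested list).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(
    package_version = as.character(utils::packageVersion("cochleaging")),
    config_hash = config_hash(config),
    seed = config$seed,
    stages = list())

  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return()
    res <- tryCatch(fun(), error = function(e) {
      list(failed = TRUE, error = conditionMessage(e))
    })
    report$stages[[name]] <<- res
  }

  run_stage("expression", function() {
    study <- simulate_expression_study(config$design)
    write_expression_study(study, file.path(outdir, "expression"))
    ages <- config$design$ages
    deg_tables <- lapply(
      setNames(config$design$cell_types, config$design$cell_types),
      function(ct) classify_deg(study$rpkm, ct, ages, config$thresholds))
    per_ct <- lapply(config$design$cell_types, function(ct) {
      deg <- deg_tables[[ct]]
      write_deg_table(deg, file.path(outdir, "expression",
                                     paste0("deg_", ct, ".tsv")))
      expressed <- lapply(setNames(ages, ages), function(a) {
        nrow(filter_expressed(study$rpkm, ct, a, config$thresholds))
      })
      truth <- study$truth
      called_up <- deg$gene_symbol[deg$status == "up"]
      called_down <- deg$gene_symbol[deg$status == "down"]
      planted_up <- truth$gene_symbol[truth$planted == "up"]
      planted_down <- truth$gene_symbol[truth$planted == "down"]
      n_planted <- length(planted_up) + length(planted_down)
      tp <- length(intersect(called_up, planted_up)) +
        length(intersect(called_down, planted_down))
      n_called <- length(called_up) + length(called_down)
      g <- glance(deg)
      list(expressed = expressed,
           n_tested = g$n_tested, n_deg = g$n_deg, n_up = g$n_up,
           n_down = g$n_down,
           sensitivity = if (n_planted) tp / n_planted else NA,
           false_discovery = if (n_called) 1 - tp / n_called else NA)
    })
    names(per_ct) <- config$design$cell_types
    cts <- config$design$cell_types
    lists <- list()
    if (length(cts) >= 2) {
      for (dir in c("up", "down")) {
        common <- rank_top_common(deg_tables[[cts[1]]],
                                  deg_tables[[cts[2]]], dir, n = 200)
        readr::write_tsv(common, file.path(
          outdir, "expression", paste0("top_common_", dir, ".tsv")))
        lists[[paste0("n_common_", dir)]] <- nrow(common)
        if (length(cts) >= 3) {
          lists[[paste0("n_concordant_", dir)]] <-
            length(concordant_subset(common$gene_symbol,
                                     deg_tables[[cts[3]]], dir))
        }
      }
    }
    c(list(cell_types = per_ct), lists)
  })

  run_stage("nlc", function() {
    rec <- simulate_voltage_clamp(config$circuit, config$boltzmann,
                                  config$protocol,
                                  noise_rms_pA = config$noise_rms_pA,
                                  seed = config$seed)
    write_vc_recording(rec, file.path(outdir, "recording.csv"))
    pts <- cm_voltage_series(rec)
    readr::write_csv(pts, file.path(outdir, "cm_points.csv"))
    fit <- fit_boltzmann(pts)
    est <- glance(fit)
    truth <- c(config$boltzmann[c("qmax", "alpha", "vpk")],
               clin = config$circuit$clin)
    list(fit = as.list(est),
         recovery_error_pct = list(
           qmax = 100 * (fit$qmax - truth$qmax) / truth$qmax,
           alpha = 100 * (fit$alpha - truth$alpha) / truth$alpha,
           vpk = 100 * (fit$vpk - truth$vpk) / truth$vpk,
           clin = 100 * (fit$clin - truth$clin) / truth$clin))
  })

  run_stage("stiffness", function() {
    fb <- config$fiber
    tr <- simulate_fiber_traces(fb$kf, fb$true_kc, fb$lf_amp,
                                noise_rms = fb$noise_rms %||% 0,
                                seed = config$seed)
    readr::write_csv(as_tibble(tr), file.path(outdir, "fiber.csv"))
    res <- fiber_stiffness(tr)
    readr::write_csv(res, file.path(outdir, "stiffness.csv"))
    list(kc = res$kc, true_kc = fb$true_kc,
         error_pct = 100 * (res$kc - fb$true_kc) / fb$true_kc)
  })

  run_stage("cytology", function() {
    cg <- config$cochleogram
    counts <- simulate_cochleogram(cg$baseline, cg$survival_prob,
                                   seed = config$seed)
    readr::write_csv(counts, file.path(outdir, "cochleogram.csv"))
    surv <- survival_percentage(filter(counts, .data$age == "aged"),
                                filter(counts, .data$age == "young"))
    readr::write_tsv(surv, file.path(outdir, "survival.tsv"))
    fl <- config$fluorescence
    quant <- simulate_fluorescence(fl$targets, fl$log2fc,
                                   n_cells = fl$n_cells %||% 20,
                                   seed = config$seed)
    readr::write_csv(quant, file.path(outdir, "fluorescence.csv"))
    fcs <- integrated_density_foldchange(
      filter(quant, .data$age == "aged"),
      filter(quant, .data$age == "young"))
    readr::write_tsv(fcs, file.path(outdir, "fluorescence_fc.tsv"))
    by_ct <- surv |>
      group_by(.data$cell_type) |>
      summarise(percent = mean(.data$percent, na.rm = TRUE))
    list(mean_survival_percent = mean(surv$percent, na.rm = TRUE),
         survival_percent_by_cell_type =
           setNames(as.list(by_ct$percent), by_ct$cell_type),
         fold_changes = setNames(as.list(fcs$log2fc), fcs$target))
  })

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}
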