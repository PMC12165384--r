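#' Shipped mouse-study scenarios
#'
#' Two mouse-scale treatment scenarios mirroring the locoregional CAR
#' T-cell imaging studies the model is calibrated against: a single
#' intratumoral dose of 1e7 CAR T cells into a large (0.8 cm diameter)
#' aggressive flank tumor (`"zhao"`), and a single intracavitary
#' (intrapleural) dose of 1e7 cells against a small (0.3 cm) orthotopic
#' tumor (`"skovgard"`).  Tumor and CAR T-cell parameters are the
#' synthetic reconstructions of [cart_preset()]; geometry values are
#' config-driven, not hard-coded elsewhere.
#'
#' @param name `"zhao"` or `"skovgard"`.
#' @return A [scenario()].
#' @export
mouse_scenario <- function(name = c("zhao", "skovgard")) {
  name <- match.arg(name)
  switch(name,
    zhao = scenario(
      tumor = tumor_params(a = 0.45, D_T = 1e-4, u_star = 2.39e6),
      cart = cart_preset("zhao"), mode = "intratumoral", dose = 1e7,
      treat_diameter = 0.8, r_inj = 0.1, horizon = 55),
    skovgard = scenario(
      tumor = tumor_params(a = 0.25, D_T = 1e-4, u_star = 2.39e6),
      cart = cart_preset("skovgard"), mode = "intracavitary", dose = 1e7,
      treat_diameter = 0.3, horizon = 8))
}

# mouse runs use a finer grid and step than the human-scale default
.MOUSE_DR <- 0.005
.MOUSE_DT <- 0.002

.preset_table <- function() {
  p <- list()
  for (ty in c("typeI", "typeII", "typeIII", "typeIV"))
    p[[paste0("fig2_", ty)]] <- list(
      experiment = "single-run", tumor = ty, mode = "none", dose = 0,
      treat_diameter = 2, horizon = 200,
      description = sprintf("untreated 200-day growth of %s from 2 cm; VDT/TTP report", ty))
  p$fig3_typeIII_1e9_it <- list(
    experiment = "single-run", tumor = "typeIII", mode = "intratumoral",
    dose = 1e9, treat_diameter = 2, horizon = 56,
    description = "intratumoral 1e9 vs type III: eradication ~day 30")
  p$fig3_typeI_1e9_it <- list(
    experiment = "single-run", tumor = "typeI", mode = "intratumoral",
    dose = 1e9, treat_diameter = 2, horizon = 56,
    description = "intratumoral 1e9 vs type I: eradication, slowest of the four types")
  p$fig3_typeII_2e8_it <- list(
    experiment = "single-run", tumor = "typeII", mode = "intratumoral",
    dose = 2e8, treat_diameter = 2, horizon = 56,
    description = "intratumoral 2e8 vs type II: stable at 8 weeks, later escape")
  p$fig3_typeIV_2e8_it <- list(
    experiment = "single-run", tumor = "typeIV", mode = "intratumoral",
    dose = 2e8, treat_diameter = 2, horizon = 56,
    description = "intratumoral 2e8 vs type IV: uncontrolled growth")
  p$fig4_typeI_1e9_ic <- list(
    experiment = "single-run", tumor = "typeI", mode = "intracavitary",
    dose = 1e9, treat_diameter = 2, horizon = 56,
    description = "intracavitary 1e9 vs type I: disease control without eradication")
  p$fig4_typeIII_1e9_ic <- list(
    experiment = "single-run", tumor = "typeIII", mode = "intracavitary",
    dose = 1e9, treat_diameter = 2, horizon = 56,
    description = "intracavitary 1e9 vs type III: holds size steady")
  p$fig4_typeIV_2e8_ic <- list(
    experiment = "single-run", tumor = "typeIV", mode = "intracavitary",
    dose = 2e8, treat_diameter = 2, horizon = 56,
    description = "intracavitary 2e8 vs type IV: minimal impact")
  for (ty in c("typeI", "typeII", "typeIII", "typeIV"))
    for (md in c(it = "intratumoral", ic = "intracavitary")) {
      tag <- if (md == "intratumoral") "it" else "ic"
      p[[paste0("fig6_", ty, "_", tag)]] <- list(
        experiment = "outcome-map", tumor = ty, mode = md,
        doses = 10^seq(7, 9, length.out = 5),
        exhausted_fractions = seq(0, 1, by = 0.25),
        treat_diameter = 2, eval_time = 56,
        description = sprintf("RECIST outcome map, %s %s delivery", ty, md))
    }
  p$fig7_typeII_choi <- list(
    experiment = "single-run", tumor = "typeII", mode = "intratumoral",
    dose = 2e8, treat_diameter = 2, horizon = 56,
    description = "type II, 2e8 intratumoral: Choi PR vs RECIST SD example")
  for (par in c("D_C", "d", "s", "l", "j", "k", "q", "m"))
    p[[paste0("fig8_", par)]] <- list(
      experiment = "sensitivity", param = par,
      description = sprintf("nadir/peak sensitivity to %s (type II, 5e8 intratumoral)", par))
  p$figE_mindose_typeIII <- list(
    experiment = "min-dose", tumor = "typeIII", mode = "intratumoral",
    treat_diameter = 2, horizon = 56,
    description = "minimum intratumoral dose eradicating type III at 2 cm")
  p$zhao_fit <- list(
    experiment = "calibration", mouse = "zhao",
    description = "mouse intratumoral injection scenario (eradication ~day 15)")
  p$skovgard_fit <- list(
    experiment = "calibration", mouse = "skovgard",
    description = "mouse intrapleural scenario (eradication by day 4, ~6x CAR T expansion)")
  p$mms <- list(
    experiment = "mms",
    description = "manufactured-solution convergence orders (temporal & spatial)")
  p
}

#' List shipped run presets
#'
#' @return Data frame with preset `name` and one-line `description`.
#' @export
list_presets <- function() {
  p <- .preset_table()
  data.frame(name = names(p),
             description = vapply(p, `[[`, "", "description"),
             row.names = NULL)
}

.validate_config <- function(cfg) {
  if (is.null(cfg$experiment))
    stop("config field 'experiment' is missing")
  ok <- c("single-run", "outcome-map", "sensitivity", "min-dose",
          "calibration", "mms")
  if (!cfg$experiment %in% ok)
    stop(sprintf("config field 'experiment' must be one of: %s",
                 paste(ok, collapse = ", ")))
  # [[ ]] indexing: $ would partial-match e.g. `doses` for `dose`
  if (!is.null(cfg[["dose"]]) && cfg[["dose"]] < 0)
    stop("config field 'dose' must be nonnegative")
  if (!is.null(cfg[["doses"]]) && any(cfg[["doses"]] < 0))
    stop("config field 'doses' must be nonnegative")
  ef <- cfg[["exhausted_fraction"]]
  if (!is.null(ef) && (ef < 0 || ef > 1))
    stop("config field 'exhausted_fraction' must lie in [0, 1]")
  if (!is.null(cfg[["horizon"]]) && cfg[["horizon"]] < 0)
    stop("config field 'horizon' must be nonnegative")
  invisible(cfg)
}

#' Run a configured experiment
#'
#' Executes one experiment described by a preset name, a YAML/JSON config
#' file, or a config list, and writes its artifacts (trajectory CSVs,
#' outcome CSV/JSON, and a JSON manifest) into `out_dir`.  Runs are
#' deterministic given the same config and seed; on error, partial
#' outputs are removed.
#'
#' @param config Preset name (see [list_presets()]), path to a YAML/JSON
#'   config, or a config list.
#' @param out_dir Output directory.
#' @param seed RNG seed recorded in the manifest (the PDE runs themselves
#'   are deterministic).
#' @param dr Grid spacing override (cm); mouse-scale runs default finer.
#' @return Invisible named vector of files written.
#' @export
run <- function(config, out_dir = "cartloco_out", seed = 1, dr = 0.015) {
  cfg <- config
  if (is.character(cfg) && length(cfg) == 1) {
    if (cfg %in% names(.preset_table())) {
      nm <- cfg
      cfg <- .preset_table()[[cfg]]
      cfg$name <- nm
    } else if (file.exists(cfg)) {
      cfg <- if (grepl("\\.json$", cfg)) jsonlite::read_json(cfg, simplifyVector = TRUE)
             else yaml::read_yaml(cfg)
    } else stop(sprintf("unknown preset or missing config file: '%s'", cfg))
  }
  .validate_config(cfg)
  name <- if (!is.null(cfg$name)) cfg$name else cfg$experiment
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  on_fail <- function(e) {
    unlink(files)
    stop(e)
  }
  set.seed(seed)
  tryCatch({
    if (cfg$experiment == "single-run") {
      sc <- scenario(cfg$tumor, cart_preset("default"),
                     mode = if (is.null(cfg[["mode"]])) "none" else cfg[["mode"]],
                     dose = if (is.null(cfg[["dose"]])) 0 else cfg[["dose"]],
                     exhausted_fraction = if (is.null(cfg[["exhausted_fraction"]])) 0
                                          else cfg[["exhausted_fraction"]],
                     treat_diameter = cfg$treat_diameter,
                     horizon = cfg$horizon)
      tr <- run_scenario(sc, dr = dr)
      files <- export_trajectory(tr, out_dir, prefix = name, seed = seed)
      summary <- if (sc$mode == "none") {
        vt <- vdt_ttp(tr)
        list(vdt_days = if (is.na(vt$vdt)) NULL else vt$vdt,
             ttp_days = if (is.na(vt$ttp)) NULL else vt$ttp)
      } else {
        as.list(outcome_record(tr, eval_time = min(56, sc$horizon)))
      }
      fr <- file.path(out_dir, paste0(name, "_outcome.json"))
      jsonlite::write_json(summary, fr, auto_unbox = TRUE, digits = NA,
                           null = "null")
      files <- c(files, outcome = fr)
    } else if (cfg$experiment == "outcome-map") {
      m <- outcome_map(cfg$tumor, cfg$mode, doses = cfg$doses,
                       exhausted_fractions = cfg$exhausted_fractions,
                       treat_diameter = cfg$treat_diameter,
                       eval_time = cfg$eval_time, dr = dr)
      fm <- file.path(out_dir, paste0(name, "_map.csv"))
      write_outcome_map(m, fm)
      files <- c(files, map = fm)
    } else if (cfg$experiment == "sensitivity") {
      vals <- if (!is.null(cfg$values)) cfg$values
              else .default_sweep_values(cfg$param)
      sw <- sensitivity_sweep(cfg$param, vals, dr = dr)
      fs <- file.path(out_dir, paste0(name, "_sweep.csv"))
      write.csv(sw, fs, row.names = FALSE)
      files <- c(files, sweep = fs)
    } else if (cfg$experiment == "min-dose") {
      md <- min_effective_dose(cfg$tumor, cfg$mode,
                               treat_diameter = cfg$treat_diameter,
                               horizon = cfg$horizon, dr = dr)
      fd <- file.path(out_dir, paste0(name, "_mindose.json"))
      jsonlite::write_json(md, fd, auto_unbox = TRUE, digits = NA,
                           null = "null")
      files <- c(files, mindose = fd)
    } else if (cfg$experiment == "calibration") {
      sc <- mouse_scenario(cfg$mouse)
      tr <- run_scenario(sc, dr = .MOUSE_DR,
                         control = solver_config(dt = .MOUSE_DT,
                                                 record_every = 0.25,
                                                 stop_tumor_below = 1))
      files <- export_trajectory(tr, out_dir, prefix = name, seed = seed)
      s <- tr$series
      summary <- list(
        eradication_day = if (tr$stop_reason == "eradication")
          max(s$t) else NULL,
        peak_cart = max(s$effector + s$exhausted),
        cart_expansion_fold = max(s$effector + s$exhausted) / sc$dose)
      fr <- file.path(out_dir, paste0(name, "_summary.json"))
      jsonlite::write_json(summary, fr, auto_unbox = TRUE, digits = NA,
                           null = "null")
      files <- c(files, summary = fr)
    } else if (cfg$experiment == "mms") {
      tc <- mms_convergence(what = "temporal")
      sc_ <- mms_convergence(what = "spatial")
      out <- list(
        temporal_order_u = tc$u[[1]]$order,
        temporal_order_v = tc$v[[1]]$order,
        spatial_order_u = sc_$u[[1]]$order,
        spatial_order_v = sc_$v[[1]]$order)
      fm <- file.path(out_dir, paste0(name, "_orders.json"))
      jsonlite::write_json(out, fm, auto_unbox = TRUE, digits = NA)
      files <- c(files, orders = fm)
    }
    mf <- file.path(out_dir, paste0(name, "_run_config.json"))
    jsonlite::write_json(c(cfg, list(seed = seed, dr = dr,
                                     package_version = as.character(
                                       utils::packageVersion("cartloco")))),
                         mf, auto_unbox = TRUE, digits = NA, null = "null")
    files <- c(files, config = mf)
  }, error = on_fail)
  invisible(files)
}

# one-order-of-magnitude default grids centered on the preset value
.default_sweep_values <- function(param) {
  base <- cart_preset("default")
  if (!param %in% names(base)) stop(sprintf("unknown parameter '%s'", param))
  base[[param]] * 10^seq(-0.5, 0.5, length.out = 5)
}
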