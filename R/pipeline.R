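# Pipeline: orchestrated end-to-end runs (simulate or load -> detachment ->
# stretched-exponential fits -> universal curve -> report), configured from
# a validated list or YAML file, with provenance (seed + config hash) on
# every output row.

.known_config_keys <- list(
  top = c("cell", "protocol", "simulate", "inputs", "analysis", "seed",
          "condition"),
  cell = c("diameter_um", "cell_density", "medium_density"),
  protocol = c("loading_rate", "f_max", "f_start", "step_duration",
               "t_start", "hold_duration", "rotor_radius", "rpm_ceiling"),
  simulate = c("n_trials", "lambda_range", "lambdas", "k0", "f_beta",
               "n_cells", "frame_rate", "p_miss", "background_fraction"),
  analysis = c("gravity_interval", "window", "smoothing_window",
               "jitter_tol", "bin_width", "n_floor", "af_cap",
               "monolayer_max_drop")
)

#' Assemble and validate a run configuration
#'
#' A run is configured by nested lists: `cell` (arguments of
#' [cell_params()]), `protocol` (arguments of [design_ramp()]), either
#' `simulate` (trial generation via [simulate_trial()]) or `inputs`
#' (CSV count-trace paths), and `analysis` options. Unknown keys are
#' rejected rather than ignored, so typos cannot silently change a run.
#'
#' @param config A nested list, or a path to a YAML file holding one.
#' @return A validated list of class `run_config` with defaults filled in.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path",
                             call. = FALSE)
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad))
      stop(sprintf("unknown config key(s) in %s: %s", where,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  check_keys(config, .known_config_keys$top, "top level")
  for (blk in c("cell", "protocol", "simulate", "analysis"))
    if (!is.null(config[[blk]]))
      check_keys(config[[blk]], .known_config_keys[[blk]], blk)
  if (is.null(config$simulate) && is.null(config$inputs))
    stop("config needs either a `simulate` block or `inputs` paths",
         call. = FALSE)
  config$seed <- config$seed %||% 1L
  config$condition <- config$condition %||% "default"
  config$analysis <- modifyList(
    list(gravity_interval = 120, window = 2, smoothing_window = 5,
         jitter_tol = 0.05, bin_width = 20, n_floor = 5, af_cap = 0.999,
         monolayer_max_drop = 0.2),
    config$analysis %||% list())
  config$protocol <- modifyList(
    list(loading_rate = 4, f_max = 480, f_start = 0, step_duration = 0.25,
         t_start = config$analysis$gravity_interval, hold_duration = 420),
    config$protocol %||% list())
  if (!is.null(config$simulate))
    config$simulate <- modifyList(
      list(n_trials = 5, lambda_range = c(0.2, 5), k0 = 1e-5, f_beta = 10,
           n_cells = 1000, frame_rate = 4, p_miss = 0.02,
           background_fraction = 0),
      config$simulate)
  structure(config, class = "run_config")
}

# stable short hash of the config for provenance
config_hash <- function(config) {
  substr(rlang::hash(unclass(config)), 1, 12)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: obtain count traces (simulated per trial,
#' or read from CSV), compute adhesion frequency and detachment curve per
#' trial, fit the stretched exponential, then — given at least 5 usable
#' trials — fit the universal curve. Per-trial failures are recorded and
#' the run continues; the run fails only if no trial succeeds.
#'
#' @param config A [run_config()] (or list / YAML path coercible to one).
#' @return An object of class `run_report`: list with `trials` (data.frame:
#'   condition, seed, config hash, AF, g/tau/beta/rmse, QC flags),
#'   `universal` (a [fit_universal_curve()] result or `NULL` with a flag
#'   when under-determined), `curves` (list of detachment curves),
#'   `config`, `flags`.
#' @export
run_pipeline <- function(config) {
  config <- run_config(config)
  hash <- config_hash(config)
  cellp <- do.call(cell_params, config$cell %||% list())
  prot <- do.call(design_ramp, c(config$protocol, list(cell = cellp)))
  an <- config$analysis
  flags <- character(0)

  traces <- list()
  labels <- character(0)
  seeds <- integer(0)
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    lambdas <- sim$lambdas %||%
      seq(sim$lambda_range[1], sim$lambda_range[2],
          length.out = sim$n_trials)
    for (i in seq_along(lambdas)) {
      s <- as.integer((config$seed * 10000 + i) %% 2147483647)
      m <- bond_model(lam = lambdas[i], k0 = sim$k0, f_beta = sim$f_beta)
      tr <- simulate_trial(m, prot, cellp, n_cells = sim$n_cells,
                           frame_rate = sim$frame_rate, p_miss = sim$p_miss,
                           gravity_interval = an$gravity_interval,
                           background_fraction = sim$background_fraction,
                           seed = s)
      traces[[i]] <- tr$count_trace
      labels[i] <- sprintf("sim_lambda_%.3g", lambdas[i])
      seeds[i] <- s
    }
  } else {
    for (i in seq_along(config$inputs)) {
      traces[[i]] <- read_count_trace(config$inputs[[i]])
      labels[i] <- basename(config$inputs[[i]])
      seeds[i] <- NA_integer_
    }
  }

  rows <- list()
  curves <- list()
  for (i in seq_along(traces)) {
    res <- tryCatch({
      tr <- traces[[i]]
      af <- adhesion_frequency(tr, t_flip = 0,
                               t_centrifuge = an$gravity_interval,
                               window = an$window)
      cv <- build_detachment_curve(tr, "centrifuge_start",
                                   t_origin = an$gravity_interval,
                                   smoothing_window = an$smoothing_window,
                                   window = an$window,
                                   jitter_tol = an$jitter_tol)
      fit <- fit_stretched_exponential(cv)
      qc <- monolayer_qc(tr, an$monolayer_max_drop)
      trial_flags <- c(attr(cv, "flags"), fit$flags,
                       if (isFALSE(qc$ok)) "monolayer QC: coverage drop")
      curves[[length(curves) + 1]] <- cv
      data.frame(trial = labels[i], condition = config$condition,
                 seed = seeds[i], config_hash = hash,
                 adhesion_frequency = af$adhesion_frequency,
                 n_initial = af$n_initial, g = fit$g, tau = fit$tau,
                 beta = fit$beta, fit_rmse = fit$rmse,
                 converged = fit$converged,
                 flags = paste(trial_flags, collapse = "; "))
    }, error = function(e) {
      data.frame(trial = labels[i], condition = config$condition,
                 seed = seeds[i], config_hash = hash,
                 adhesion_frequency = NA_real_, n_initial = NA_real_,
                 g = NA_real_, tau = NA_real_, beta = NA_real_,
                 fit_rmse = NA_real_, converged = FALSE,
                 flags = paste("trial failed:", conditionMessage(e)))
    })
    rows[[i]] <- res
  }
  trials <- do.call(rbind, rows)
  if (all(!trials$converged))
    stop("no trial produced a usable fit: run-level failure", call. = FALSE)

  usable <- trials[trials$converged & is.finite(trials$tau), ]
  universal <- NULL
  if (nrow(usable) >= 5 && diff(range(usable$adhesion_frequency)) > 1e-6) {
    universal <- fit_universal_curve(usable, af_cap = an$af_cap)
  } else {
    flags <- c(flags, sprintf(
      "universal curve under-determined: %d usable trial(s), need >= 5 spanning an AF range",
      nrow(usable)))
  }
  structure(list(trials = trials, universal = universal, curves = curves,
                 config = config, config_hash = hash, flags = flags,
                 version = as.character(utils::packageVersion("cellavidity"))),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d trials (%d converged), condition '%s', config %s\n",
              nrow(x$trials), sum(x$trials$converged),
              x$config$condition, x$config_hash))
  if (!is.null(x$universal)) print(x$universal)
  for (f in x$flags) cat("  flag:", f, "\n")
  invisible(x)
}

#' Serialize a run report to JSON + CSV
#'
#' Writes `report.json` (fits, flags, config, version), `trials.csv` and
#' per-curve CSVs under `dir`.
#'
#' @param report A [run_pipeline()] report.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  uni <- if (is.null(report$universal)) NULL
         else unclass(report$universal)
  jsonlite::write_json(
    list(universal = uni, flags = report$flags,
         config_hash = report$config_hash, version = report$version,
         config = unclass(report$config)),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  for (i in seq_along(report$curves)) {
    write.csv(as.data.frame(report$curves[[i]]),
              file.path(dir, sprintf("curve_%03d.csv", i)),
              row.names = FALSE)
  }
  invisible(dir)
}

#' Summarize runs by condition
#'
#' Per-condition mean and SD of adhesion frequency and population lifetime
#' over the (converged) trials of one or more reports.
#'
#' @param reports A single `run_report` or a list of them.
#' @param by Grouping column of the trial tables (default `"condition"`).
#' @return A data.frame: one row per group with `n_trials`, `mean_af`,
#'   `sd_af`, `mean_tau`, `sd_tau`.
#' @export
summarize_conditions <- function(reports, by = "condition") {
  if (inherits(reports, "run_report")) reports <- list(reports)
  if (!length(reports)) stop("no reports to summarize", call. = FALSE)
  trials <- do.call(rbind, lapply(reports, function(r) r$trials))
  trials <- trials[trials$converged & is.finite(trials$tau), ]
  if (!nrow(trials)) stop("no converged trials to summarize", call. = FALSE)
  if (!by %in% names(trials))
    stop(sprintf("grouping column '%s' not present", by), call. = FALSE)
  groups <- split(trials, trials[[by]])
  out <- do.call(rbind, lapply(names(groups), function(g) {
    tg <- groups[[g]]
    data.frame(group = g, n_trials = nrow(tg),
               mean_af = mean(tg$adhesion_frequency),
               sd_af = sd(tg$adhesion_frequency),
               mean_tau = mean(tg$tau), sd_tau = sd(tg$tau))
  }))
  names(out)[1] <- by
  out
}
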