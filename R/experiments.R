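# Fig-5 amplitude pairs used as the default sweep, ordered by increasing
# coupling strength. The final pair uses Ki = 2.85 (the sweep panel), while
# the unstable demo uses Ki = 2.80 (the parameter-table value); both are
# legitimate and kept distinct on purpose.
default_sweep_pairs <- function() {
  matrix(c(0.30, 0.25,
           0.40, 0.35,
           0.50, 0.45,
           0.70, 0.63,
           0.90, 0.86,
           1.00, 0.92,
           2.00, 1.85,
           3.00, 2.85),
         ncol = 2L, byrow = TRUE,
         dimnames = list(NULL, c("Ke", "Ki")))
}

config_fields <- function() {
  c("mode", "Ke", "sigma_e", "Ki", "sigma_i",
    "grid_n", "domain_a", "domain_b", "q",
    "tau", "gamma", "dt", "t", "epochs", "seed",
    "init_low", "init_high", "coupling", "log_stride", "sweep_pairs")
}

#' Experiment configuration
#'
#' Builds a fully validated, flat configuration for the experiment drivers.
#' `mode = "stable_demo"` defaults to the stable parameter set (Ke = 0.90,
#' sigma_e = 0.1, Ki = 0.86, sigma_i = 1.0; tau = 1, dt = 0.015, t = 25,
#' gamma = 0.002, 7000 epochs on a 40 x 40 unit-square lattice);
#' `"unstable_demo"` differs only in Ke = 3.0, Ki = 2.80. `"sweep"` adds the
#' eight default `(Ke, Ki)` pairs. Any field can be overridden through
#' `...`; validation problems are reported collectively, field by field.
#'
#' @param mode One of `"stable_demo"`, `"unstable_demo"`, `"sweep"`,
#'   `"custom"`.
#' @param ... Field overrides: `Ke`, `sigma_e`, `Ki`, `sigma_i`, `grid_n`,
#'   `domain_a`, `domain_b`, `q`, `tau`, `gamma`, `dt`, `t`, `epochs`,
#'   `seed`, `init_low`, `init_high`, `coupling`, `log_stride`,
#'   `sweep_pairs`.
#' @return An object of class `nfsom_config` (a named list).
#' @export
experiment_config <- function(mode = c("stable_demo", "unstable_demo",
                                       "sweep", "custom"), ...) {
  mode <- match.arg(mode)
  cfg <- list(
    mode = mode,
    Ke = 0.90, sigma_e = 0.1, Ki = 0.86, sigma_i = 1.0,
    grid_n = 40L, domain_a = 0, domain_b = 1, q = 2L,
    tau = 1.0, gamma = 0.002, dt = 0.015, t = 25.0, epochs = 7000L,
    seed = 10L, init_low = 0, init_high = 0.01, coupling = "network",
    log_stride = 1L, sweep_pairs = NULL
  )
  if (mode == "unstable_demo") {
    cfg$Ke <- 3.0
    cfg$Ki <- 2.80
  }
  if (mode == "sweep") cfg$sweep_pairs <- default_sweep_pairs()

  overrides <- list(...)
  unknown <- setdiff(names(overrides), config_fields())
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  cfg$mode <- mode
  validate_config(cfg)
  class(cfg) <- "nfsom_config"
  cfg
}

validate_config <- function(cfg) {
  errors <- character(0)
  num1 <- function(field, positive = FALSE) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      errors <<- c(errors, sprintf("`%s` must be a single finite number", field))
      FALSE
    } else if (positive && v <= 0) {
      errors <<- c(errors, sprintf("`%s` must be strictly positive (got %g)", field, v))
      FALSE
    } else TRUE
  }
  for (f in c("Ke", "sigma_e", "Ki", "sigma_i", "tau", "gamma", "dt", "t"))
    num1(f, positive = TRUE)
  for (f in c("domain_a", "domain_b", "init_low", "init_high", "seed"))
    num1(f)
  if (num1("grid_n") && (cfg$grid_n < 1 || cfg$grid_n != round(cfg$grid_n)))
    errors <- c(errors, "`grid_n` must be a positive integer")
  if (num1("epochs") && (cfg$epochs < 0 || cfg$epochs != round(cfg$epochs)))
    errors <- c(errors, "`epochs` must be a non-negative integer")
  if (num1("log_stride") && cfg$log_stride < 1)
    errors <- c(errors, "`log_stride` must be >= 1")
  if (is.numeric(cfg$q) && !cfg$q %in% c(1, 2))
    errors <- c(errors, "`q` must be 1 or 2")
  if (!is.character(cfg$coupling) ||
      !cfg$coupling %in% c("network", "integral"))
    errors <- c(errors, "`coupling` must be \"network\" or \"integral\"")
  if (is.numeric(cfg$domain_a) && is.numeric(cfg$domain_b) &&
      cfg$domain_b <= cfg$domain_a)
    errors <- c(errors, "`domain_b` must be > `domain_a`")
  if (is.numeric(cfg$dt) && is.numeric(cfg$t) && cfg$dt >= cfg$t)
    errors <- c(errors, "`dt` must be smaller than `t`")
  if (identical(cfg$mode, "sweep") &&
      (is.null(cfg$sweep_pairs) || nrow(cfg$sweep_pairs) == 0L))
    errors <- c(errors, "`sweep_pairs` must be non-empty in sweep mode")
  if (!is.null(cfg$sweep_pairs) &&
      (!is.matrix(cfg$sweep_pairs) || ncol(cfg$sweep_pairs) != 2L ||
       any(cfg$sweep_pairs <= 0)))
    errors <- c(errors, "`sweep_pairs` must be a matrix of positive (Ke, Ki) pairs")
  if (length(errors))
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  invisible(cfg)
}

#' @export
print.nfsom_config <- function(x, ...) {
  cat(sprintf("<nfsom_config> mode = %s\n", x$mode))
  cat(sprintf("  kernel: Ke = %g, sigma_e = %g, Ki = %g, sigma_i = %g\n",
              x$Ke, x$sigma_e, x$Ki, x$sigma_i))
  cat(sprintf("  grid: %d x %d on [%g, %g]^%d\n",
              x$grid_n, x$grid_n, x$domain_a, x$domain_b, x$q))
  cat(sprintf("  dynamics: tau = %g, dt = %g, t = %g, gamma = %g, epochs = %d, seed = %d\n",
              x$tau, x$dt, x$t, x$gamma, x$epochs, x$seed))
  if (!is.null(x$sweep_pairs))
    cat(sprintf("  sweep over %d (Ke, Ki) pairs\n", nrow(x$sweep_pairs)))
  invisible(x)
}

# Turn a config into the model objects the core functions take.
config_objects <- function(config) {
  grid <- spatial_grid(config$grid_n, config$domain_a, config$domain_b,
                       config$q)
  spec <- kernel_spec(config$Ke, config$sigma_e, config$Ki, config$sigma_i)
  params <- model_params(tau = config$tau, gamma = config$gamma,
                         dt = config$dt, t_epoch = config$t,
                         epochs = config$epochs,
                         init_low = config$init_low,
                         init_high = config$init_high,
                         coupling = config$coupling)
  list(grid = grid, spec = spec, params = params)
}

apply_profile <- function(config, profile) {
  if (profile == "ci") {
    config$grid_n <- 16L
    config$epochs <- 1500L
    config$t <- 5.0
  } else if (profile == "full") {
    config$grid_n <- 40L
    config$epochs <- 7000L
    config$t <- 25.0
  }
  config
}

log_line <- function(con, ..., level = "INFO") {
  msg <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 level, paste0(...))
  if (!is.null(con)) writeLines(msg, con)
  invisible(msg)
}

#' Run one end-to-end experiment
#'
#' Executes the full pipeline for a configuration: stability report first
#' (so an unstable configuration is flagged before a long training run),
#' then training, then map-quality metrics. With `out_dir` set, writes
#' `trace.csv`, `report.json`, `snapshot.json` and a timestamped `run.log`.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional output directory (created if missing).
#' @param profile `"as_is"` runs the config unchanged; `"ci"` shrinks it to
#'   the desk-scale profile (16 x 16 grid, 1500 epochs, t = 5); `"full"`
#'   forces the full-scale profile (40 x 40, 7000 epochs, t = 25).
#' @return A list with `config`, `stability` (report), `fit`, `metrics`
#'   (`NULL` after a blowup) and `status` (`"ok"` or `"blowup"`).
#' @export
run_experiment <- function(config, out_dir = NULL,
                           profile = c("as_is", "ci", "full")) {
  stopifnot(inherits(config, "nfsom_config"))
  profile <- match.arg(profile)
  config <- apply_profile(config, profile)
  validate_config(config)
  obj <- config_objects(config)

  logcon <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    logcon <- file(file.path(out_dir, "run.log"), open = "wt")
    on.exit(close(logcon), add = TRUE)
  }
  log_line(logcon, sprintf("mode=%s grid=%dx%d epochs=%d seed=%d",
                           config$mode, config$grid_n, config$grid_n,
                           config$epochs, config$seed))

  report <- stability_report(obj$spec, obj$grid)
  log_line(logcon, sprintf("stability verdict: %s (closed LHS %.4f)",
                           report$verdict, report$lhs_closed),
           level = if (report$verdict == "stable") "INFO" else "WARN")

  fit <- train_som(obj$params, obj$spec, obj$grid, seed = config$seed,
                   log_stride = config$log_stride)
  metrics <- NULL
  status <- "ok"
  if (fit$blowup) {
    status <- "blowup"
    log_line(logcon, sprintf("numeric blowup at epoch %d", fit$blowup_epoch),
             level = "ERROR")
  } else {
    mq <- map_quality(fit$codebook, obj$grid)
    final_d <- if (nrow(fit$trace)) fit$trace$distortion[nrow(fit$trace)] else NA_real_
    metrics <- list(distortion = final_d, slope_ref = mq$slope_ref,
                    slope_fit = mq$slope_fit, P = mq$P)
    log_line(logcon, sprintf("final distortion %.5f, P = %.4f", final_d, mq$P))
  }

  if (!is.null(out_dir)) {
    write_trace(fit$trace, file.path(out_dir, "trace.csv"))
    jsonlite::write_json(
      list(stability = list(lhs_closed = report$lhs_closed,
                            lhs_quadrature = report$lhs_quadrature,
                            wbar_l = report$wbar_l,
                            cond10_inf = report$cond10_inf,
                            verdict = report$verdict),
           metrics = metrics, status = status),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, null = "null", na = "null")
    snap <- snapshot_record(fit$codebook,
                            field = numeric(obj$grid$k),
                            epoch = config$epochs, config = config)
    write_snapshot(snap, file.path(out_dir, "snapshot.json"))
  }

  list(config = config, stability = report, fit = fit,
       metrics = metrics, status = status)
}

#' Sweep the lateral amplitudes
#'
#' Trains one map per `(Ke, Ki)` pair (all with the configured seed, all
#' other parameters shared) and tabulates, per pair, the closed-form
#' stability condition value, the distortion averaged over the last 10
#' epochs, and the topographic performance index. Pairs whose run diverges
#' are recorded with `status = "blowup"` and the sweep continues.
#'
#' @param config An [experiment_config()] with `sweep_pairs` set (the
#'   `"sweep"` mode provides the eight default pairs).
#' @param out_dir Optional output directory for `sweep.csv`.
#' @param profile See [run_experiment()].
#' @return A data frame with columns `Ke`, `Ki`, `lhs_closed`,
#'   `distortion_last10`, `P`, `status`.
#' @export
run_sweep <- function(config, out_dir = NULL,
                      profile = c("as_is", "ci", "full")) {
  stopifnot(inherits(config, "nfsom_config"))
  profile <- match.arg(profile)
  config <- apply_profile(config, profile)
  pairs <- config$sweep_pairs
  if (is.null(pairs) || nrow(pairs) == 0L)
    stop("`sweep_pairs` is empty; use mode = \"sweep\" or set pairs explicitly")

  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    cfg_i <- config
    cfg_i$Ke <- pairs[i, 1L]
    cfg_i$Ki <- pairs[i, 2L]
    obj <- config_objects(cfg_i)
    lhs <- condition_lhs_closed(obj$spec, cfg_i$domain_a, cfg_i$domain_b,
                                q = cfg_i$q)
    row <- data.frame(Ke = cfg_i$Ke, Ki = cfg_i$Ki, lhs_closed = lhs,
                      distortion_last10 = NA_real_, P = NA_real_,
                      status = "ok", stringsAsFactors = FALSE)
    fit <- tryCatch(
      train_som(obj$params, obj$spec, obj$grid, seed = cfg_i$seed,
                log_stride = cfg_i$log_stride),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      row$status <- "error"
    } else if (fit$blowup) {
      row$status <- "blowup"
    } else {
      tail_d <- utils::tail(fit$trace$distortion[!is.na(fit$trace$distortion)], 10L)
      row$distortion_last10 <- mean(tail_d)
      row$P <- map_quality(fit$codebook, obj$grid)$P
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(out_dir, "sweep.csv"), row.names = FALSE)
  }
  out
}
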