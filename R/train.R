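#' Deterministic stimulus and initialization stream
#'
#' One seed determines both the codebook initialization and the entire
#' stimulus sequence: the generator (R's Mersenne-Twister via `set.seed`)
#' first draws the `k x m` initial codebook i.i.d. U(`init_low`,
#' `init_high`), then the `epochs x m` stimulus matrix i.i.d. U(0, 1), in
#' that documented order. Identical seeds therefore reproduce runs bitwise
#' across machines.
#'
#' @param seed Integer PRNG seed.
#' @param epochs Number of stimuli to draw.
#' @param k Number of lattice nodes (codebook rows).
#' @param m Input dimension.
#' @param init_low,init_high Codebook initialization bounds.
#' @return A list with `init` (`k x m`), `stimuli` (`epochs x m`) and `seed`.
#' @export
seed_stream <- function(seed, epochs, k, m = 2L,
                        init_low = 0, init_high = 0.01) {
  stopifnot(length(seed) == 1L, is.finite(seed), epochs >= 0, k >= 1, m >= 1)
  set.seed(as.integer(seed))
  init <- matrix(stats::runif(k * m, init_low, init_high), k, m)
  stimuli <- matrix(stats::runif(epochs * m), nrow = epochs, ncol = m)
  list(init = init, stimuli = stimuli, seed = as.integer(seed))
}

# Epochs at which the trace logs distortion: 1, every `stride`, the last
# `tail` epochs, and the final epoch.
logged_epochs <- function(epochs, stride, tail) {
  if (epochs == 0L) return(integer(0))
  sort(unique(c(1L, seq.int(stride, epochs, by = stride),
                seq.int(max(1L, epochs - tail + 1L), epochs), epochs)))
}

#' Train a neural-field self-organizing map
#'
#' Runs the online learning loop: at each epoch one stimulus is presented,
#' the coupled field/learning dynamics are integrated over the epoch
#' horizon, and the field is reset to zero. The codebook is initialized
#' i.i.d. U(`init_low`, `init_high`) and stimuli are drawn uniformly on
#' `[0, 1]^m`, both from `seed` via [seed_stream()] (a custom `stimuli`
#' matrix may be supplied instead, e.g. for degenerate test streams).
#'
#' The trace logs, at epoch 1, every `log_stride` epochs and over the final
#' `log_tail` epochs: the distortion of the current codebook against all
#' stimuli seen so far, the mean absolute weight change of the epoch, and
#' the maximum of the field at the end of the epoch. At every logged epoch
#' the codebook is checked to lie in `[0, 1]` (it must, for any trajectory
#' initialized there).
#'
#' If the field diverges the run stops early: the returned fit has
#' `blowup = TRUE`, the failing epoch, and the trace up to that point.
#'
#' @param params A [model_params()].
#' @param spec A [kernel_spec()].
#' @param grid A [spatial_grid()].
#' @param seed Integer seed for [seed_stream()].
#' @param m Input dimension (2 in the experiments).
#' @param log_stride Logging stride in epochs.
#' @param log_tail Number of final epochs always logged (the sweep
#'   experiments average distortion over the last 10 epochs).
#' @param stimuli Optional `epochs x m` stimulus matrix overriding the
#'   seeded stream (the seeded codebook initialization is still used).
#' @param engine Integration engine, see [run_epoch()].
#' @return An object of class `nfsom_fit`: list with the final `codebook`,
#'   the `trace` data frame (`epoch`, `distortion`, `mean_weight_change`,
#'   `field_max`), `stimuli`, `seed`, `blowup` flag (+ `blowup_epoch`),
#'   and the `params`, `spec`, `grid` used.
#' @export
train_som <- function(params, spec, grid, seed, m = 2L,
                      log_stride = 1L, log_tail = 10L,
                      stimuli = NULL, engine = c("auto", "cpp", "r")) {
  stopifnot(inherits(params, "nfsom_params"),
            inherits(spec, "nfsom_kernel_spec"),
            inherits(grid, "nfsom_grid"))
  engine <- match.arg(engine)
  stream <- seed_stream(seed, params$epochs, grid$k, m,
                        params$init_low, params$init_high)
  codebook <- stream$init
  if (is.null(stimuli)) {
    stimuli <- stream$stimuli
  } else {
    stimuli <- as.matrix(stimuli)
    if (nrow(stimuli) != params$epochs || ncol(stimuli) != m)
      stop("`stimuli` must be an epochs x m matrix")
  }

  kernels <- som_kernels(spec, grid)
  state <- field_state(grid)
  log_at <- logged_epochs(params$epochs, as.integer(log_stride),
                          as.integer(log_tail))
  trace <- data.frame(epoch = log_at,
                      distortion = rep(NA_real_, length(log_at)),
                      mean_weight_change = rep(NA_real_, length(log_at)),
                      field_max = rep(NA_real_, length(log_at)))
  blowup <- FALSE
  blowup_epoch <- NA_integer_
  li <- 1L

  for (e in seq_len(params$epochs)) {
    res <- tryCatch(
      run_epoch(state, codebook, stimuli[e, ], kernels, params, grid, engine),
      nfsom_blowup = function(err) err
    )
    if (inherits(res, "nfsom_blowup")) {
      blowup <- TRUE
      blowup_epoch <- e
      trace <- trace[trace$epoch < e, , drop = FALSE]
      break
    }
    state <- res$state
    codebook <- res$codebook
    if (li <= length(log_at) && e == log_at[li]) {
      if (min(codebook) < -1e-12 || max(codebook) > 1 + 1e-12)
        stop("codebook left [0, 1] at epoch ", e,
             ": the update rule's bounding property was violated")
      trace$distortion[li] <- distortion(stimuli[seq_len(e), , drop = FALSE],
                                         codebook)
      trace$mean_weight_change[li] <- res$diagnostics$mean_weight_change
      trace$field_max[li] <- res$diagnostics$field_max
      li <- li + 1L
    }
  }

  structure(
    list(codebook = codebook, trace = trace, stimuli = stimuli,
         seed = stream$seed, blowup = blowup, blowup_epoch = blowup_epoch,
         params = params, spec = spec, grid = grid),
    class = "nfsom_fit"
  )
}

#' @export
print.nfsom_fit <- function(x, ...) {
  cat(sprintf("<nfsom_fit> %d epochs on a %d-node grid (seed %d)\n",
              x$params$epochs, x$grid$k, x$seed))
  if (x$blowup) {
    cat(sprintf("  numeric blowup at epoch %d\n", x$blowup_epoch))
  } else if (nrow(x$trace)) {
    last <- x$trace[nrow(x$trace), ]
    cat(sprintf("  final distortion %.5f (epoch %d)\n",
                last$distortion, last$epoch))
  }
  invisible(x)
}
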