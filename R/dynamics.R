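#' Rectification activation
#'
#' `rect(x) = max(x, 0)`, the activation used for both the lateral coupling
#' and the learning gate. Lipschitz with constant 1.
#'
#' @param x Numeric.
#' @return `pmax(x, 0)`.
#' @export
rect <- function(x) pmax(x, 0)

# Structured error for diverging trajectories; callers in the experiment
# drivers catch this class so unstable regimes fail loudly but cleanly.
blowup_error <- function(where, epoch = NA_integer_, step = NA_integer_) {
  stop(errorCondition(
    sprintf("numeric blowup in %s (epoch %s, step %s): field exceeded 1e6 or became non-finite",
            where, epoch, step),
    epoch = epoch, step = step,
    class = c("nfsom_blowup", "nfsom_error", "error")
  ))
}

BLOWUP_LIMIT <- 1e6

#' Integration and learning parameters
#'
#' Collects the time constants of the coupled field/learning dynamics and the
#' activation functions. Defaults are the values used throughout the
#' numerical experiments: `tau = 1`, `gamma = 0.002`, Euler step
#' `dt = 0.015`, per-epoch horizon `t_epoch = 25` and 7000 epochs. `dt` and
#' `t_epoch` share one time unit, so each epoch integrates
#' `floor(t_epoch / dt)` Euler steps (1666 at the defaults).
#'
#' The activations `f_l` (lateral), `f_e` (learning gate) and `f_s` (input
#' drive) may be replaced by any Lipschitz functions; the defaults
#' `f_l = f_e = rect` and `f_s(x) = 1 - |x|_1 / m` give the self-organizing
#' map instantiation. The compiled integration engine supports the default
#' activations; custom ones fall back to the R engine.
#'
#' The `coupling` convention fixes how the lateral interaction term is
#' discretized. `"network"` (the default, matching the reference
#' simulations) treats the lattice as a network of `k` neurons and uses raw
#' node sums, \eqn{\sum_{r'} w(|r - r'|) g(r')}: competition is strong, the
#' field forms a selective activity bump, and topographic maps unfold.
#' `"integral"` weights the sums by the cell measure, i.e. discretizes the
#' continuous-domain integral exactly as the stability theory states it;
#' this is the convention under which the equilibrium and Lyapunov analyses
#' apply verbatim. The two differ by the constant factor
#' \eqn{((b-a)/n)^q} in the coupling strength.
#'
#' @param tau Field decay time constant (> 0).
#' @param gamma Learning rate (> 0).
#' @param dt Forward-Euler step (> 0, < `t_epoch`).
#' @param t_epoch Integration horizon of one epoch.
#' @param epochs Number of training epochs (one stimulus each).
#' @param init_low,init_high Bounds of the uniform codebook initialization.
#' @param coupling Lateral-coupling discretization: `"network"` (raw node
#'   sums) or `"integral"` (cell-measure quadrature).
#' @param f_l,f_e Scalar activation functions applied elementwise.
#' @param f_s Drive function applied to the codebook-stimulus deviation
#'   vector at one node; `NULL` selects the default `1 - |x|_1 / m`.
#' @return An object of class `nfsom_params`.
#' @export
model_params <- function(tau = 1.0, gamma = 0.002, dt = 0.015,
                         t_epoch = 25.0, epochs = 7000,
                         init_low = 0, init_high = 0.01,
                         coupling = c("network", "integral"),
                         f_l = rect, f_e = rect, f_s = NULL) {
  coupling <- match.arg(coupling)
  for (nm in c("tau", "gamma", "dt", "t_epoch")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("`", nm, "` must be a single strictly positive number")
  }
  if (dt >= t_epoch) stop("`dt` must be smaller than `t_epoch`")
  if (!is.numeric(epochs) || epochs < 0 || epochs != round(epochs))
    stop("`epochs` must be a non-negative integer")
  if (init_high < init_low) stop("`init_high` must be >= `init_low`")
  default_act <- identical(f_l, rect) && identical(f_e, rect) && is.null(f_s)
  structure(
    list(tau = tau, gamma = gamma, dt = dt, t_epoch = t_epoch,
         epochs = as.integer(epochs), init_low = init_low,
         init_high = init_high, coupling = coupling,
         f_l = f_l, f_e = f_e, f_s = f_s,
         default_activations = default_act),
    class = "nfsom_params"
  )
}

# Scale factor converting the integral-convention convolution
# (cell_measure * sum) to the convention requested by `params`.
coupling_scale <- function(params, grid) {
  if (identical(params$coupling, "network")) 1 / grid$cell_measure else 1
}

#' Field state at rest
#'
#' The membrane potential `u` on the lattice (zero at rest, the baseline it
#' is reset to at every epoch boundary) together with the within-epoch time.
#'
#' @param grid A [spatial_grid()].
#' @return An object of class `nfsom_field_state` with elements `u` and `t`.
#' @export
field_state <- function(grid) {
  stopifnot(inherits(grid, "nfsom_grid"))
  u <- if (grid$q == 1L) numeric(grid$n) else matrix(0, grid$n, grid$n)
  structure(list(u = u, t = 0), class = "nfsom_field_state")
}

#' Initialize a codebook
#'
#' Draws the feed-forward weight matrix (one m-vector per lattice node)
#' i.i.d. from U(`low`, `high`); the experiments use U(0, 0.01). Uses the
#' current RNG state, so seed upstream for reproducibility.
#'
#' @param grid A [spatial_grid()].
#' @param m Input dimension.
#' @param low,high Uniform bounds.
#' @return A `k x m` numeric matrix.
#' @export
init_codebook <- function(grid, m = 2L, low = 0, high = 0.01) {
  stopifnot(inherits(grid, "nfsom_grid"), m >= 1)
  matrix(stats::runif(grid$k * m, low, high), grid$k, m)
}

#' Feed-forward input drive
#'
#' Computes the per-node drive \eqn{I(r) = 1 - |w_f(r) - s(p)|_1 / m}: large
#' where the codebook already resembles the stimulus, and in `[0, 1]`
#' whenever codebook and stimulus are.
#'
#' @param codebook `k x m` codebook matrix.
#' @param stim Stimulus vector of length `m` (already mapped through `s`;
#'   the identity in the experiments).
#' @param f_s Optional replacement drive function applied to each row of
#'   `codebook - stim`.
#' @return Numeric vector of length `k`.
#' @export
input_drive <- function(codebook, stim, f_s = NULL) {
  if (!is.matrix(codebook)) stop("`codebook` must be a k x m matrix")
  m <- ncol(codebook)
  if (length(stim) != m)
    stop("stimulus has length ", length(stim),
         " but the codebook has m = ", m, " columns")
  dev <- codebook - rep(stim, each = nrow(codebook))
  if (is.null(f_s)) {
    1 - rowSums(abs(dev)) / m
  } else {
    apply(dev, 1L, f_s)
  }
}

#' One forward-Euler step of the field equation
#'
#' Advances \eqn{\tau \dot u = -u + \int_\Omega w_l(|r - r'|) f_l(u(r'))\,dr'
#' + I} by one explicit Euler step of size `dt`. Reference (R) integration
#' path; [run_epoch()] uses a compiled equivalent for full epochs.
#'
#' @param state A [field_state()].
#' @param I Input drive, a length-`k` vector or grid-shaped array.
#' @param kernel_table Lateral kernel table from [kernel_on_grid()].
#' @param params A [model_params()].
#' @param grid The [spatial_grid()].
#' @return The updated `nfsom_field_state`.
#' @export
field_step <- function(state, I, kernel_table, params, grid) {
  stopifnot(inherits(state, "nfsom_field_state"), inherits(params, "nfsom_params"))
  u <- state$u
  if (is.null(dim(u)) != is.null(dim(I))) {
    if (grid$q == 2L && is.null(dim(I))) I <- matrix(I, grid$n, grid$n)
  }
  lat <- coupling_scale(params, grid) *
    lateral_convolve(params$f_l(u), kernel_table, grid)
  u <- u + (params$dt / params$tau) * (-u + lat + I)
  if (any(!is.finite(u)) || max(abs(u)) > BLOWUP_LIMIT)
    blowup_error("field_step")
  state$u <- u
  state$t <- state$t + params$dt
  state
}

#' One forward-Euler step of the learning rule
#'
#' Advances the Oja-like rule \eqn{\dot w_f = \gamma (s(p) - w_f)
#' \int_\Omega w_e(|r - r'|) f_e(u(r'))\,dr'} by one Euler step. The
#' excitatory integral gates learning: nodes outside the activity bump (where
#' `f_e(u)` vanishes) keep their weights. Entries stay in `[0, 1]` as long as
#' `dt * gamma * E <= 1`.
#'
#' @param codebook `k x m` codebook matrix.
#' @param state The current [field_state()] (after the field update).
#' @param stim Stimulus vector of length `m`.
#' @param excit_kernel_table Excitatory kernel table from [kernel_on_grid()].
#' @param params A [model_params()].
#' @param grid The [spatial_grid()].
#' @return The updated codebook matrix.
#' @export
weights_step <- function(codebook, state, stim, excit_kernel_table, params, grid) {
  stopifnot(inherits(state, "nfsom_field_state"), inherits(params, "nfsom_params"))
  E <- coupling_scale(params, grid) *
    as.vector(lateral_convolve(params$f_e(state$u), excit_kernel_table, grid))
  target <- rep(stim, each = nrow(codebook))
  codebook + (params$dt * params$gamma) * (target - codebook) * E
}

#' Precompute kernels for the training loop
#'
#' Bundles the lateral and excitatory kernel tables together with the
#' one-dimensional Gaussian factors that the compiled engine uses: because
#' the squared Euclidean distance separates across axes, convolution with
#' each Gaussian is two small matrix products, algebraically identical to
#' the zero-padded convolution of [lateral_convolve()].
#'
#' @param spec A [kernel_spec()].
#' @param grid A [spatial_grid()].
#' @return A list of class `nfsom_kernels` with `spec`, `lateral`,
#'   `excitatory` tables and (for `q = 2`) factors `Ge`, `Gi`.
#' @export
som_kernels <- function(spec, grid) {
  stopifnot(inherits(spec, "nfsom_kernel_spec"), inherits(grid, "nfsom_grid"))
  out <- list(
    spec = spec,
    lateral = kernel_on_grid(spec, grid, "lateral"),
    excitatory = kernel_on_grid(spec, grid, "excitatory")
  )
  if (grid$q == 2L) {
    D2 <- outer(grid$nodes1, grid$nodes1, "-")^2
    out$Ge <- sqrt(spec$Ke) * grid$h * exp(-D2 / (2 * spec$sigma_e^2))
    out$Gi <- sqrt(spec$Ki) * grid$h * exp(-D2 / (2 * spec$sigma_i^2))
  }
  class(out) <- "nfsom_kernels"
  out
}

#' Integrate one training epoch
#'
#' Runs `floor(t_epoch / dt)` paired Euler steps: at each step the input
#' drive is recomputed from the evolving codebook, the field is advanced
#' first (from the previous codebook's drive), then the learning rule is
#' advanced using the freshly updated field. Afterwards the field activity
#' is reset to its zero baseline.
#'
#' @param state A [field_state()].
#' @param codebook `k x m` codebook matrix.
#' @param stim Stimulus vector of length `m`.
#' @param kernels A [som_kernels()] bundle.
#' @param params A [model_params()].
#' @param grid The [spatial_grid()].
#' @param engine `"auto"` (compiled when available), `"cpp"` or `"r"`.
#' @return A list with the reset `state`, the updated `codebook`, and
#'   `diagnostics` (`u_final`, `field_max`, `mean_weight_change`, `steps`).
#' @export
run_epoch <- function(state, codebook, stim, kernels, params, grid,
                      engine = c("auto", "cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(kernels, "nfsom_kernels"), inherits(params, "nfsom_params"))
  steps <- as.integer(floor(params$t_epoch / params$dt))
  use_cpp <- grid$q == 2L && params$default_activations && !is.null(kernels$Ge)
  if (engine == "cpp" && !use_cpp)
    stop("compiled engine requires q = 2 and the default activations")
  if (engine == "auto") engine <- if (use_cpp) "cpp" else "r"
  w_old <- codebook

  if (engine == "cpp") {
    # the Toeplitz factors carry one factor h each; dividing both by h
    # turns the cell-measure quadrature into the raw network sum
    fs <- if (identical(params$coupling, "network")) 1 / grid$h else 1
    res <- run_epoch_cpp(state$u, codebook, as.numeric(stim),
                         kernels$Ge * fs, kernels$Gi * fs,
                         params$dt, params$tau, params$gamma, steps,
                         BLOWUP_LIMIT)
    if (!res$ok) blowup_error("run_epoch", step = res$step)
    u_final <- res$u
    codebook <- res$W
  } else {
    for (s in seq_len(steps)) {
      I <- input_drive(codebook, stim, params$f_s)
      state <- field_step(state, I, kernels$lateral, params, grid)
      codebook <- weights_step(codebook, state, stim, kernels$excitatory,
                               params, grid)
    }
    u_final <- state$u
  }

  diagnostics <- list(
    u_final = u_final,
    field_max = max(u_final),
    mean_weight_change = mean(abs(codebook - w_old)),
    steps = steps
  )
  state$u <- if (grid$q == 1L) numeric(grid$n) else matrix(0, grid$n, grid$n)
  state$t <- 0
  list(state = state, codebook = codebook, diagnostics = diagnostics)
}

#' Equilibrium field pattern
#'
#' Solves the fixed-point equation \eqn{u^*(r) = I_0 + \int_\Omega
#' w_l(|r - r'|) f_l(u^*(r'))\,dr'} (with \eqn{I_0 = f_s(0) = 1} for the
#' default drive) by Picard iteration from \eqn{u \equiv I_0}. When the
#' kernel's L2 norm is below `1 / ell_l` the map is a contraction and the
#' iteration converges to the unique equilibrium; otherwise a warning is
#' issued and convergence is not guaranteed.
#'
#' @param kernel_table Lateral kernel table from [kernel_on_grid()].
#' @param grid The [spatial_grid()].
#' @param f_l Lateral activation (default [rect()]).
#' @param I0 Constant drive at equilibrium (default 1).
#' @param tol Sup-norm residual tolerance.
#' @param max_iter Iteration cap; exceeding it raises an error of class
#'   `nfsom_no_convergence` carrying the last residual.
#' @param ell_l Lipschitz constant of `f_l` used for the contraction check.
#' @return The equilibrium field (grid-shaped), with attributes `residual`
#'   and `iterations`.
#' @export
equilibrium_field <- function(kernel_table, grid, f_l = rect, I0 = 1,
                              tol = 1e-11, max_iter = 500L, ell_l = 1) {
  stopifnot(inherits(kernel_table, "nfsom_kernel_table"),
            inherits(grid, "nfsom_grid"))
  wbar <- sqrt(condition_lhs_quadrature(kernel_table$spec, grid))
  if (wbar * ell_l >= 1)
    warning(sprintf(
      "lateral kernel L2 norm (%.3f) * ell_l >= 1: Picard iteration is not a contraction; convergence not guaranteed",
      wbar))
  u <- if (grid$q == 1L) rep(I0, grid$n) else matrix(I0, grid$n, grid$n)
  res <- Inf
  for (it in seq_len(max_iter)) {
    u_new <- I0 + lateral_convolve(f_l(u), kernel_table, grid)
    res <- max(abs(u_new - u))
    u <- u_new
    if (res < tol) {
      attr(u, "residual") <- res
      attr(u, "iterations") <- it
      return(u)
    }
  }
  stop(errorCondition(
    sprintf("equilibrium iteration did not converge in %d steps (last residual %.3e)",
            max_iter, res),
    residual = res, class = c("nfsom_no_convergence", "nfsom_error", "error")
  ))
}

#' Lyapunov functional of the deviation from equilibrium
#'
#' Evaluates \eqn{V = (\tau/2)\,\|\tilde u\|^2 + (\rho / 2\gamma)\,
#' \|\tilde w_f\|^2}, the energy whose exponential decay underlies the
#' stability analysis. Spatial L2 norms are approximated by
#' cell-measure-weighted node sums. Useful as a monitoring quantity along
#' trajectories near the equilibrium `(u*, s(p))`.
#'
#' @param u_dev Field deviation `u - u*` on the grid.
#' @param w_dev Codebook deviation `w_f - s(p)`, a `k x m` matrix (or
#'   anything summable elementwise).
#' @param rho Positive coupling weight between the two energy terms.
#' @param tau,gamma Model time constants.
#' @param grid The [spatial_grid()].
#' @return A single non-negative number.
#' @export
lyapunov_value <- function(u_dev, w_dev, rho, tau, gamma, grid) {
  stopifnot(inherits(grid, "nfsom_grid"), rho > 0)
  cm <- grid$cell_measure
  (tau / 2) * cm * sum(u_dev^2) + (rho / (2 * gamma)) * cm * sum(w_dev^2)
}
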