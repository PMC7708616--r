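test_that("input drive maps codebook-stimulus distance to [0, 1]", {
  expect_equal(input_drive(rbind(c(0.3, 0.6)), c(0.3, 0.6)), 1)
  expect_equal(input_drive(rbind(c(0, 0)), c(1, 1)), 0)
  expect_equal(input_drive(rbind(c(1, 0)), c(0, 0)), 0.5)
  set.seed(3)
  W <- matrix(runif(50 * 2), 50, 2)
  I <- input_drive(W, runif(2))
  expect_true(all(I >= 0 & I <= 1))
  expect_error(input_drive(W, runif(3)), "m = 2")
})

test_that("field step performs explicit Euler with the lateral integral", {
  g <- spatial_grid(6)
  # integral coupling: expectations below are cell-measure quadratures
  params <- model_params(tau = 1, dt = 0.015, t_epoch = 25,
                         coupling = "integral")
  # zero lateral kernel, unit drive: one step moves u from 0 to dt/tau
  kt0 <- kernel_on_grid(balanced_spec(), g, "lateral")
  st <- field_state(g)
  st1 <- field_step(st, matrix(1, 6, 6), kt0, params, g)
  expect_equal(st1$u, matrix(0.015, 6, 6))
  expect_equal(st1$t, 0.015)

  # at the equilibrium pattern with matching constant drive, nothing moves
  spec <- stable_spec()
  kt <- kernel_on_grid(spec, g, "lateral")
  us <- equilibrium_field(kt, g)
  st$u <- matrix(as.vector(us), 6, 6)
  st2 <- field_step(st, matrix(1, 6, 6), kt, params, g)
  expect_lt(max(abs(st2$u - st$u)), 0.015 * 1e-9)
})

test_that("Euler integration error halves with the step (first order)", {
  g <- spatial_grid(6)
  spec <- stable_spec()
  kt <- kernel_on_grid(spec, g, "lateral")
  set.seed(11)
  u0 <- matrix(runif(36, -0.2, 0.8), 6, 6)
  I <- matrix(runif(36), 6, 6)
  integrate_to <- function(dt, Tend) {
    p <- model_params(tau = 1, dt = dt, t_epoch = 25, coupling = "integral")
    st <- field_state(g); st$u <- u0
    for (i in seq_len(round(Tend / dt))) st <- field_step(st, I, kt, p, g)
    st$u
  }
  ref <- integrate_to(0.3 / 256, 0.3)
  e1 <- max(abs(integrate_to(0.03, 0.3) - ref))
  e2 <- max(abs(integrate_to(0.015, 0.3) - ref))
  expect_equal(e1 / e2, 2, tolerance = 0.2)
})

test_that("learning is gated by rectified field activity and contracts toward the stimulus", {
  g <- spatial_grid(6)
  spec <- stable_spec()
  exc <- kernel_on_grid(spec, g, "excitatory")
  params <- model_params(gamma = 0.5, dt = 0.015, t_epoch = 25,
                         coupling = "integral")
  stim <- c(0.4, 0.9)
  st <- field_state(g)

  # codebook already at the stimulus: zero drive
  W0 <- matrix(stim, g$k, 2, byrow = TRUE)
  expect_equal(weights_step(W0, st, stim, exc, params, g), W0)

  # non-positive field: rect gates all learning off
  st$u <- matrix(-0.5, 6, 6)
  set.seed(5)
  W <- matrix(runif(g$k * 2), g$k, 2)
  expect_equal(weights_step(W, st, stim, exc, params, g), W)

  # positive activity shrinks the 1-norm gap at every gated node
  st$u <- matrix(runif(36, 0.1, 1), 6, 6)
  E <- as.vector(lateral_convolve(rect(st$u), exc, g))
  W1 <- weights_step(W, st, stim, exc, params, g)
  gap0 <- rowSums(abs(W - matrix(stim, g$k, 2, byrow = TRUE)))
  gap1 <- rowSums(abs(W1 - matrix(stim, g$k, 2, byrow = TRUE)))
  expect_true(all(gap1[E > 0] < gap0[E > 0]))
  # per-component contraction factor (1 - dt*gamma*E)
  expect_equal(gap1, gap0 * (1 - params$dt * params$gamma * E),
               tolerance = 1e-12)
})

test_that("an epoch runs floor(t_epoch/dt) paired steps and resets the field", {
  g <- spatial_grid(8)
  spec <- stable_spec()
  kn <- som_kernels(spec, g)
  params <- model_params(dt = 0.015, t_epoch = 25.0, epochs = 1)
  set.seed(2)
  W <- init_codebook(g, 2)
  res <- run_epoch(field_state(g), W, c(0.2, 0.8), kn, params, g)
  expect_equal(res$diagnostics$steps, 1666L)
  expect_equal(res$state$u, matrix(0, 8, 8))  # reset to baseline
  expect_equal(res$state$t, 0)
  expect_gt(max(res$diagnostics$u_final), 0)

  # frozen learning: gamma = 0 leaves the codebook untouched
  p0 <- model_params(gamma = 1e-300, dt = 0.05, t_epoch = 1)
  p0$gamma <- 0  # constructor demands > 0; freeze explicitly
  res0 <- run_epoch(field_state(g), W, c(0.2, 0.8), kn, p0, g)
  expect_equal(res0$codebook, W)
})

test_that("compiled and reference engines integrate identically", {
  g <- spatial_grid(8)
  spec <- stable_spec()
  kn <- som_kernels(spec, g)
  set.seed(9)
  W <- matrix(runif(g$k * 2), g$k, 2)
  stim <- c(0.7, 0.1)
  for (coupling in c("network", "integral")) {
    params <- model_params(gamma = 0.05, dt = 0.015, t_epoch = 0.5,
                           coupling = coupling)
    r_cpp <- run_epoch(field_state(g), W, stim, kn, params, g, engine = "cpp")
    r_r <- run_epoch(field_state(g), W, stim, kn, params, g, engine = "r")
    expect_equal(r_cpp$diagnostics$u_final, r_r$diagnostics$u_final,
                 tolerance = 1e-12)
    expect_equal(r_cpp$codebook, r_r$codebook, tolerance = 1e-12)
  }
})

test_that("training is deterministic in the seed and respects epochs = 0", {
  g <- spatial_grid(6)
  spec <- stable_spec()
  params <- model_params(epochs = 5, t_epoch = 1.5)
  f1 <- train_som(params, spec, g, seed = 433, log_stride = 1)
  f2 <- train_som(params, spec, g, seed = 433, log_stride = 1)
  expect_identical(f1$codebook, f2$codebook)
  expect_identical(f1$trace, f2$trace)

  p0 <- model_params(epochs = 0, t_epoch = 1.5)
  f0 <- train_som(p0, spec, g, seed = 74)
  expect_equal(f0$codebook, seed_stream(74, 0, g$k, 2, 0, 0.01)$init)
  expect_equal(nrow(f0$trace), 0L)
})

test_that("codebook entries stay inside [0, 1] along trajectories", {
  g <- spatial_grid(8)
  for (spec in list(stable_spec(), unstable_spec())) {
    fit <- train_som(model_params(epochs = 40, t_epoch = 5), spec, g,
                     seed = 721, log_stride = 4)
    expect_false(fit$blowup)
    expect_true(min(fit$codebook) >= 0 && max(fit$codebook) <= 1)
  }
})

test_that("runaway excitation raises a structured blowup error", {
  g <- spatial_grid(8)
  spec <- kernel_spec(Ke = 80, sigma_e = 0.4, Ki = 0.01, sigma_i = 1.0)
  kn <- som_kernels(spec, g)
  params <- model_params(dt = 0.05, t_epoch = 20)
  W <- matrix(0.5, g$k, 2)
  expect_error(
    run_epoch(field_state(g), W, c(0.5, 0.5), kn, params, g),
    class = "nfsom_blowup"
  )
  # train_som converts it into a flagged partial fit
  p <- model_params(dt = 0.05, t_epoch = 20, epochs = 3)
  fit <- train_som(p, spec, g, seed = 10)
  expect_true(fit$blowup)
  expect_equal(fit$blowup_epoch, 1L)
})

test_that("equilibrium solver matches a semismooth Newton oracle", {
  # zero lateral kernel: the equilibrium is exactly the constant drive
  g <- spatial_grid(6)
  kt0 <- kernel_on_grid(balanced_spec(), g, "lateral")
  u0 <- equilibrium_field(kt0, g)
  expect_equal(as.vector(u0), rep(1, 36))
  expect_equal(attr(u0, "iterations"), 1L)

  g16 <- spatial_grid(16)
  spec <- stable_spec()
  kt <- kernel_on_grid(spec, g16, "lateral")
  us <- equilibrium_field(kt, g16)
  expect_lt(attr(us, "residual"), 1e-10)

  # independent oracle: semismooth Newton on the dense discretized system
  k <- g16$k
  D <- as.matrix(stats::dist(g16$nodes))
  C <- matrix(lateral_weight(as.vector(D), spec), k, k) * g16$cell_measure
  u <- rep(1, k)
  for (it in 1:50) {
    Fv <- u - 1 - C %*% pmax(u, 0)
    if (max(abs(Fv)) < 1e-12) break
    J <- diag(k) - C %*% diag(as.numeric(u > 0))
    u <- u - solve(J, Fv)
  }
  expect_lt(max(abs(Fv)), 1e-12)
  expect_equal(as.vector(us), as.vector(u), tolerance = 1e-9)

  # non-convergence surfaces as a structured error
  expect_error(
    suppressWarnings(equilibrium_field(kernel_on_grid(unstable_spec(), g16,
                                                      "lateral"),
                                       g16, max_iter = 3L)),
    class = "nfsom_no_convergence"
  )
})

test_that("the Lyapunov functional weighs field and codebook deviations", {
  g <- spatial_grid(10)  # unit square, cell sums to 1
  zero_w <- matrix(0, g$k, 2)
  expect_equal(lyapunov_value(matrix(0, 10, 10), zero_w, rho = 1,
                              tau = 1, gamma = 0.002, g), 0)
  expect_equal(lyapunov_value(matrix(1, 10, 10), zero_w, rho = 1,
                              tau = 2, gamma = 0.002, g), 1)
  # rho / (2 gamma) scaling of the codebook term
  # rho/(2 gamma) = 2 times the squared norm cell*k*m = 2
  expect_equal(lyapunov_value(matrix(0, 10, 10), zero_w + 1, rho = 0.4,
                              tau = 1, gamma = 0.1, g), 4)
})
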