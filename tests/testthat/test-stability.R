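test_that("rational erf approximation stays within its stated error", {
  expect_identical(erf_rational(0), 0)
  expect_equal(erf_rational(50), 1, tolerance = 1e-9)
  expect_equal(erf_rational(-1.3), -erf_rational(1.3))
  x <- seq(0, 10, by = 1e-3)
  ref <- if (requireNamespace("pracma", quietly = TRUE)) {
    pracma::erf(x)
  } else {
    2 * pnorm(x * sqrt(2)) - 1
  }
  expect_lt(max(abs(erf_rational(x) - ref)), 5e-4)
})

test_that("xi equals the squared Gaussian double integral", {
  expect_equal(xi_ab(0.4, 0.4, sigma = 0.7), 0)
  # frozen value checked against dense quadrature of the double integral
  expect_equal(xi_ab(0, 1, 1 / sqrt(2)), 0.74223, tolerance = 1e-4)

  dbl_integral <- function(a, b, sigma) {
    inner <- Vectorize(function(x)
      stats::integrate(function(y) exp(-(x - y)^2 / (2 * sigma^2)),
                       a, b, rel.tol = 1e-11)$value)
    stats::integrate(inner, a, b, rel.tol = 1e-10)$value
  }
  set.seed(14)
  for (i in 1:20) {
    a <- runif(1, -2, 1)
    b <- a + runif(1, 0.2, 2)
    sigma <- runif(1, 0.05, 1.5)
    expect_equal(sqrt(xi_ab(a, b, sigma)), dbl_integral(a, b, sigma),
                 tolerance = 1e-4)
  }
  expect_error(xi_ab(0, 1, sigma = -1), "positive")
})

test_that("closed-form condition value behaves as a quadratic form in the gains", {
  spec <- stable_spec()
  # balanced kernels cancel exactly
  expect_lt(abs(condition_lhs_closed(balanced_spec())), 1e-12)
  # scaling (Ke, Ki) by lambda scales the LHS by lambda^2
  lam <- 1.7
  scaled <- kernel_spec(spec$Ke * lam, spec$sigma_e, spec$Ki * lam, spec$sigma_i)
  expect_equal(condition_lhs_closed(scaled),
               lam^2 * condition_lhs_closed(spec), tolerance = 1e-12)
  # translation invariance of the domain
  expect_equal(condition_lhs_closed(spec, a = 0, b = 1),
               condition_lhs_closed(spec, a = -3.2, b = -2.2),
               tolerance = 1e-12)
  # Gram-matrix structure: LHS = Ke^2 xi_e + Ki^2 xi_i - 2 Ke Ki xi_x
  xe <- xi_ab(0, 1, spec$sigma_e / sqrt(2))
  xi_i <- xi_ab(0, 1, spec$sigma_i / sqrt(2))
  xx <- xi_ab(0, 1, spec$sigma_e * spec$sigma_i /
                sqrt(spec$sigma_e^2 + spec$sigma_i^2))
  expect_equal(condition_lhs_closed(spec),
               spec$Ke^2 * xe + spec$Ki^2 * xi_i - 2 * spec$Ke * spec$Ki * xx)
})

test_that("grid quadrature of the condition matches pairwise sums and the closed form", {
  spec <- stable_spec()
  expect_equal(condition_lhs_quadrature(balanced_spec(), spatial_grid(12)), 0)

  # single-node grid: (b - a)^(2q) * w_l(0)^2
  expect_equal(condition_lhs_quadrature(spec, spatial_grid(1, 0, 2)),
               2^4 * lateral_weight(0, spec)^2)
  expect_equal(condition_lhs_quadrature(spec, spatial_grid(1, 0, 3, q = 1)),
               3^2 * lateral_weight(0, spec)^2)

  # displacement-counted sum equals the naive all-pairs double sum
  g6 <- spatial_grid(6)
  D <- as.matrix(stats::dist(g6$nodes))
  naive <- sum(lateral_weight(as.vector(D), spec)^2) * g6$cell_measure^2
  expect_equal(condition_lhs_quadrature(spec, g6), naive, tolerance = 1e-13)

  # refinement approaches the closed form; 2% already at 64 x 64
  for (sp in list(spec, unstable_spec())) {
    closed <- condition_lhs_closed(sp)
    q64 <- condition_lhs_quadrature(sp, spatial_grid(64))
    expect_lt(abs(q64 - closed) / closed, 0.02)
    errs <- vapply(c(10L, 20L, 40L), function(n)
      abs(condition_lhs_quadrature(sp, spatial_grid(n)) - closed), numeric(1))
    expect_true(all(diff(errs) < 0))
  }
  expect_gte(condition_lhs_quadrature(kernel_spec(2, 0.3, 1, 0.2),
                                      spatial_grid(9)), 0)
})

test_that("kernel L2 norm handles both parameterized and generic kernels", {
  g <- spatial_grid(8)
  spec <- stable_spec()
  expect_equal(lateral_l2_norm(spec, g),
               sqrt(condition_lhs_quadrature(spec, g)))
  # the same kernel supplied as a generic two-argument function
  wfun <- function(r, rp) lateral_weight(sqrt(sum((r - rp)^2)), spec)
  expect_equal(lateral_l2_norm(wfun, g), lateral_l2_norm(spec, g),
               tolerance = 1e-12)
  # constant kernel c on a 1-D unit domain has norm |c|
  g1 <- spatial_grid(20, q = 1)
  expect_equal(lateral_l2_norm(function(r, rp) -0.8, g1), 0.8)
  expect_equal(lateral_l2_norm(function(r, rp) 0, g1), 0)
})

test_that("sufficient-excitation condition reads the equilibrium correctly", {
  g <- spatial_grid(10)
  exc <- kernel_on_grid(stable_spec(), g, "excitatory")
  pos <- check_condition10(matrix(1, 10, 10), exc, g)
  expect_true(pos$ok)
  expect_gt(pos$inf_value, 0)
  neg <- check_condition10(matrix(-2, 10, 10), exc, g)
  expect_false(neg$ok)
  expect_equal(neg$inf_value, 0)
})

test_that("stability reports give the expected verdicts", {
  g <- spatial_grid(16)
  rep_stable <- stability_report(stable_spec(), g)
  expect_equal(rep_stable$verdict, "stable")
  expect_true(rep_stable$cond9_ok && rep_stable$cond10_ok)
  expect_equal(rep_stable$wbar_l, sqrt(rep_stable$lhs_quadrature))
  expect_lt(rep_stable$equilibrium_residual, 1e-10)

  rep_unstable <- stability_report(unstable_spec(), g)
  expect_gt(rep_unstable$lhs_closed, 1)
  expect_false(rep_unstable$cond9_ok)
  expect_true(rep_unstable$verdict %in% c("not_guaranteed", "undetermined"))

  rep_balanced <- stability_report(balanced_spec(), g)
  expect_equal(rep_balanced$lhs_closed, 0)
  expect_equal(rep_balanced$verdict, "stable")
})
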