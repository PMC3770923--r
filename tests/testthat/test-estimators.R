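test_that("TI quadrature is exact for constant and linear integrands", {
  cst <- make_lambda_series("constant", coef = 5)
  lin <- make_lambda_series("linear", coef = c(0, 2))
  for (scheme in c("linear", "quadratic", "pow34")) {
    expect_equal(ti_integrate(cst$series, scheme)$dg, 5, tolerance = 1e-12)
    expect_equal(ti_integrate(lin$series, scheme)$dg, 1, tolerance = 1e-12)
  }
})

test_that("the pow34 scheme integrates the singular reference within 2%", {
  ls <- make_lambda_series("pow34", coef = 1)
  ti <- ti_integrate(ls$series, "pow34")
  expect_equal(ti$dg, 4, tolerance = 0.02)
  ## linear/quadratic endpoint fits are visibly worse on this integrand
  expect_gt(abs(ti_integrate(ls$series, "linear")$dg - 4), abs(ti$dg - 4))
  ## scheme spread contributes to the reported error
  expect_gt(ti$error, 0)
})

test_that("TI input validation and error propagation behave", {
  expect_error(ti_integrate(data.frame(lambda = 0.5, dudl = 1)), "at least 2")
  expect_error(lambda_series(c(0, 0.5), c(1, 1)), "in \\(0, 1\\)")
  expect_error(lambda_series(c(0.5, 0.4), c(1, 1)), "increasing")
  ## standard errors propagate to a positive uncertainty
  ls <- make_lambda_series("constant", coef = 5, noise = 0.2, seed = 3)
  expect_gt(ti_integrate(ls$series)$error, 0)
})

test_that("Jarzynski direct averaging matches closed forms", {
  ctx <- thermo_context(300)
  b <- ctx$beta_kj
  ## degenerate distribution
  expect_equal(ji_direct(rep(7.5, 40), ctx), 7.5, tolerance = 1e-12)
  ## two-value closed form
  W <- c(0, 50)
  expect_equal(ji_direct(W, ctx), -log((1 + exp(-b * 50)) / 2) / b,
               tolerance = 1e-12)
  ## log-sum-exp contract survives enormous exponents
  expect_true(is.finite(ji_direct(c(2e4, 4e4), ctx)))
  expect_error(ji_direct(numeric(0)), "empty")
})

test_that("the cumulant estimator equals its algebraic definition", {
  ctx <- thermo_context(300)
  set.seed(9)
  w <- rnorm(25, 12, 4)
  expect_equal(ji_cumulant(w, ctx), mean(w) - ctx$beta_kj / 2 * var(w),
               tolerance = 1e-12)
  expect_equal(ji_cumulant(rep(3, 5), ctx), 3)
  expect_error(ji_cumulant(1, ctx), "at least 2")
})

test_that("both estimators agree with the Gaussian closed form", {
  ctx <- thermo_context(300)
  g <- make_work_ensemble("gaussian", list(mean = 20, sd = 5), n = 2e4,
                          seed = 12, context = ctx)
  truth <- 20 - ctx$beta_kj * 25 / 2
  expect_equal(g$truth_dg, truth, tolerance = 1e-12)
  se_cum <- sqrt(25 / 2e4) * 3  # generous scale for both estimators
  expect_lt(abs(ji_direct(g$work, ctx) - truth), 3 * se_cum)
  expect_lt(abs(ji_cumulant(g$work, ctx) - truth), 3 * se_cum)
})

test_that("Jensen's bound holds on arbitrary work samples", {
  ctx <- thermo_context(300)
  set.seed(31)
  for (i in 1:25) {
    w <- switch(1 + i %% 3,
                rnorm(50, 10, 8),
                rexp(50, 0.05),
                5 + rgamma(50, 2, scale = 10))
    expect_lte(ji_direct(w, ctx), mean(w) + 1e-9)
  }
})

test_that("finite-sample bias has the documented signs on short-tailed work", {
  ## dissipative shifted-gamma regime: direct averaging overestimates, the
  ## cumulant expansion underestimates the exact free energy
  ctx <- thermo_context(300)
  sg <- make_work_ensemble("shifted-gamma", n = 150, seed = 8, context = ctx)
  expect_gt(ji_direct(sg$work, ctx), sg$truth_dg)
  expect_lt(ji_cumulant(sg$work, ctx), sg$truth_dg)
})

test_that("PMF reconstruction matches ground truth on toy potentials", {
  ctx <- thermo_context(300)
  ## flat potential: the true profile is identically zero
  wp <- steered_toy_simulate("flat", k_g = 400, v = 0.1, n_traj = 120,
                             n_steps = 1000, dt = 0.001, context = ctx,
                             seed = 3)
  pm <- pmf_from_work(wp, "cumulant", ctx)
  se <- apply(wp$W, 1, sd) / sqrt(wp$n)
  expect_true(all(abs(pm$G) <= 4 * pmax(se, 0.05)))
  ## harmonic well pulled quasi-statically: G(xi) = k/2 (xi - x0)^2
  wh <- steered_toy_simulate("harmonic", list(k0 = 50, x0 = 1), k_g = 450,
                             v = 0.05, n_traj = 120, n_steps = 2000,
                             dt = 5e-4, context = ctx, seed = 4,
                             x_start = 1, record_every = 100)
  ph <- pmf_from_work(wh, "cumulant", ctx)
  ref <- 0.5 * 50 * (wh$xi - 1)^2
  expect_lt(max(abs(ph$G - ref)), 0.05)
  ## a single trajectory cannot feed the cumulant estimator
  one <- work_profile_set(wp$xi, wp$W[, 1, drop = FALSE])
  expect_error(pmf_from_work(one, "cumulant", ctx), "at least 2")
})

test_that("the toy simulator is reproducible, dissipative, and guarded", {
  a <- steered_toy_simulate("flat", n_traj = 10, n_steps = 300, seed = 5)
  b <- steered_toy_simulate("flat", n_traj = 10, n_steps = 300, seed = 5)
  expect_identical(a$W, b$W)
  expect_true(all(abs(a$W[1, ]) < 1e-12))
  ## finite-speed pulling dissipates on average
  fast <- steered_toy_simulate("flat", v = 1, n_traj = 150, n_steps = 500,
                               seed = 6)
  expect_gt(mean(fast$W[nrow(fast$W), ]), 0)
  ## quasi-static limit: mean work compatible with zero
  slow <- steered_toy_simulate("flat", v = 0.01, n_traj = 150, n_steps = 500,
                               seed = 6)
  wfin <- slow$W[nrow(slow$W), ]
  expect_lt(abs(mean(wfin)), 3 * sd(wfin) / sqrt(length(wfin)) + 1e-3)
  expect_error(steered_toy_simulate("flat", k_g = 1000, dt = 0.001),
               "unstable dt")
})

test_that("work and lambda tables round-trip through TSV", {
  d <- tempfile(); dir.create(d)
  wp <- steered_toy_simulate("flat", n_traj = 5, n_steps = 200, seed = 2)
  p <- file.path(d, "work.tsv")
  write_work_table(wp, p)
  wp2 <- read_work_table(p)
  expect_equal(wp2$W, unname(wp$W), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(wp2$xi, wp$xi)
  ls <- make_lambda_series("pow34", path = file.path(d, "lam.tsv"))
  ls2 <- read_lambda_table(file.path(d, "lam.tsv"))
  expect_equal(ls2$dudl, ls$series$dudl)
})
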