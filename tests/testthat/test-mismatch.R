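test_that("expected mismatch at tau = 0 is the geometric equilibrium", {
  for (theta in c(0.3, 1, 4)) {
    e <- mismatch_expected_sudden(0:12, 0, theta)
    expect_equal(e, theta^(0:12) / (theta + 1)^(1:13), tolerance = 1e-12)
  }
})

test_that("sudden-expansion closed form matches numerical integration", {
  # independent route: integrate Pois(j; x) against the piecewise
  # exponential coalescence-time density
  f_num <- function(j, tau, theta0, theta1) {
    recent <- stats::integrate(function(x) {
      stats::dpois(j, x) * (1 / theta1) * exp(-x / theta1)
    }, 0, tau, rel.tol = 1e-10)$value
    older <- stats::integrate(function(y) {
      stats::dpois(j, y + tau) * (1 / theta0) * exp(-y / theta0)
    }, 0, Inf, rel.tol = 1e-10)$value
    recent + exp(-tau / theta1) * older
  }
  for (prm in list(c(2, 0.5, 5), c(0.7, 1.5, 20))) {
    tau <- prm[1]; th0 <- prm[2]; th1 <- prm[3]
    got <- mismatch_expected_sudden(0:8, tau, th0, th1)
    want <- vapply(0:8, f_num, numeric(1), tau = tau, theta0 = th0,
                   theta1 = th1)
    expect_equal(got, want, tolerance = 1e-8)
  }
  # pure-growth limit: theta1 = Inf means no coalescence before tau
  got <- mismatch_expected_sudden(0:8, 1.5, 0.8, Inf)
  want <- vapply(0:8, function(j) {
    stats::integrate(function(y) {
      stats::dpois(j, y + 1.5) * (1 / 0.8) * exp(-y / 0.8)
    }, 0, Inf, rel.tol = 1e-10)$value
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("spatial-expansion closed form matches numerical integration", {
  tau <- 1.8; theta <- 2; M <- 3; theta0 <- 0.4
  lam <- (1 + M) / theta
  want <- vapply(0:10, function(j) {
    recent <- stats::integrate(function(x) {
      stats::dpois(j, x) * (1 / theta) * exp(-lam * x)
    }, 0, tau, rel.tol = 1e-10)$value
    p_nc <- 1 - (1 - exp(-lam * tau)) / (1 + M)
    older <- stats::integrate(function(y) {
      stats::dpois(j, y + tau) * (1 / theta0) * exp(-y / theta0)
    }, 0, Inf, rel.tol = 1e-10)$value
    recent + p_nc * older
  }, numeric(1))
  got <- mismatch_expected_spatial(0:10, tau, theta, M, theta0)
  expect_equal(got, want, tolerance = 1e-8)
  # distributions integrate to 1 over all classes
  expect_equal(sum(mismatch_expected_spatial(0:400, 1.2, 1.5, 2, 0.3)), 1,
               tolerance = 1e-6)
  expect_equal(sum(mismatch_expected_sudden(0:400, 2, 1.2, 30)), 1,
               tolerance = 1e-6)
})

test_that("raggedness matches its hand-computed definition", {
  x <- c(4, 2, 0, 0)  # frequencies 4/6, 2/6, 0, 0
  f <- x / 6
  expect_equal(raggedness(x), sum(diff(c(f, 0))^2))
  # perfectly flat distribution is smoother than a spiky one
  expect_lt(raggedness(rep(1, 10)), raggedness(c(5, 0, 5, 0, 5)))
})

test_that("fit_expansion output is reproducible and internally consistent", {
  d <- generate_study_like(seed = 6)
  aus <- subset_alignment(d$alignment,
                          which(d$alignment$meta$population == "Australia"))
  obs <- mismatch_observed(aus)
  f1 <- fit_expansion(obs, n_sequences(aus), model = "spatial",
                      n_boot = 10, seed = 9)
  f2 <- fit_expansion(obs, n_sequences(aus), model = "spatial",
                      n_boot = 10, seed = 9)
  expect_equal(f1$tau, f2$tau)
  expect_equal(f1$p_ssd, f2$p_ssd)
  expect_gte(f1$tau, 0); expect_gte(f1$theta, 0); expect_gte(f1$M, 0)
  expect_true(f1$p_ssd >= 0 && f1$p_ssd <= 1)
  expect_true(f1$p_raggedness >= 0 && f1$p_raggedness <= 1)
  expect_equal(sum(f1$observed), choose(n_sequences(aus), 2))
  expect_error(fit_expansion(obs, 4, model = "sudden"), "n")
})

test_that("sudden-model fit recovers tau with small bias on simulated data", {
  set.seed(31)
  tau_true <- 3; theta_true <- 1
  taus <- replicate(100, {
    obs <- barcodemog:::sim_mismatch_sudden(50, tau_true, theta_true)
    barcodemog:::fit_mismatch_ls(obs, "sudden")$tau
  })
  bias <- mean(taus) - tau_true
  expect_lt(abs(bias), 0.2 * tau_true)
})

test_that("expansion time conversion is linear in tau and hits 67 ka", {
  expect_equal(expansion_time(0, 1.77e-8, 456)$t_years, 0)
  et <- expansion_time(1.081, 1.77e-8, 456, 1)
  expect_equal(et$t_years, 1.081 / (2 * 1.77e-8 * 456), tolerance = 1e-12)
  expect_equal(et$t_years, 67000, tolerance = 0.01)
  et2 <- expansion_time(2 * 1.081, 1.77e-8, 456, 1)
  expect_equal(et2$t_years, 2 * et$t_years)
  # two generations per year halves the per-generation rate, so years
  # since expansion are unchanged while generations double
  et3 <- expansion_time(1.081, 1.77e-8, 456, 2)
  expect_equal(et3$t_generations, 2 * et$t_generations)
  expect_equal(et3$t_years, et$t_years)
  expect_error(expansion_time(1, 0, 456), "positive|> 0|mu")
})
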