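# Small reference tables shared across the ABC tests (built once per run).
ref_small <- NULL
make_ref_small <- function() {
  if (is.null(ref_small)) {
    ref_small <<- build_reference(list(scenario_recent(), scenario_ancient()),
                                  n_sims = 600, sample_sizes = c(6, 6, 6),
                                  L = 200, seed = 17)
  }
  ref_small
}

test_that("summary statistics have fixed order and impute NA as zero", {
  d <- simulate_dataset(
    make_scenario("custom", N1 = 1e3, N2 = 1e3, N3 = 1e3, t1 = 5e3,
                  t2 = 2e3),
    hky_model(kappa = 2, L = 100, rate = 1e-6), 4, 4, 4, seed = 2)
  s <- summary_stats(d$alignment)
  expect_true(all(is.finite(s)))
  expect_true(all(c("pop1_K", "pop1_S", "pop1_tajD", "pop1_tajD_na",
                    "pop1_privS", "pop1xpop2_fst",
                    "pop2xpop3_sharedK") %in% names(s)))
  # identical sequences: D undefined -> imputed 0 with indicator 1
  aln0 <- labeled_alignment(
    stats::setNames(rep("ACGTACGT", 6), paste0("s", 1:6)),
    make_meta(paste0("s", 1:6), population = rep(c("p1", "p2"), each = 3)))
  s0 <- summary_stats(aln0)
  expect_equal(unname(s0["p1_tajD"]), 0)
  expect_equal(unname(s0["p1_tajD_na"]), 1)
  expect_equal(unname(s0["p1xp2_fst"]), 0)
})

test_that("reference tables are reproducible under the master seed", {
  r1 <- build_reference(list(scenario_recent()), n_sims = 10,
                        sample_sizes = c(4, 4, 4), L = 100, seed = 5)
  r2 <- build_reference(list(scenario_recent()), n_sims = 10,
                        sample_sizes = c(4, 4, 4), L = 100, seed = 5)
  expect_identical(r1$stats, r2$stats)
  expect_identical(r1$params, r2$params)
  expect_equal(nrow(r1$stats), 10)
})

test_that("degenerate point-mass priors fix parameters but not summaries", {
  pt <- lapply(test_priors(c(3e4, 3e4), c(8e3, 8e3)), function(p) p)
  pt <- lapply(pt, function(p) prior_unif((p$min + p$max) / 2,
                                          (p$min + p$max) / 2))
  sc <- abc_scenario("point", pt)
  r <- build_reference(list(sc), n_sims = 8, sample_sizes = c(4, 4, 4),
                       L = 150, seed = 6)
  expect_true(all(apply(r$params, 2, function(x) length(unique(x)) == 1)))
  expect_gt(stats::sd(r$stats[, "pop1_S"]), 0)
})

test_that("direct scenario choice: an exact row match wins at k = 1", {
  ref <- make_ref_small()
  obs <- ref$stats[37, ]
  p <- scenario_posterior_direct(ref, obs, k = 1)
  expect_equal(unname(p[as.character(ref$scenario[37])]), 1)
  expect_equal(sum(p), 1)
  expect_error(scenario_posterior_direct(ref, obs, k = 0), "k")
})

test_that("scenario posteriors are invariant to affine rescaling of summaries", {
  ref <- make_ref_small()
  obs <- ref$stats[10, ] * 0.9
  p0 <- scenario_posterior_direct(ref, obs, k = 50)
  scale <- stats::runif(ncol(ref$stats), 0.5, 10)
  shift <- stats::rnorm(ncol(ref$stats))
  ref2 <- ref
  ref2$stats <- sweep(sweep(ref$stats, 2, scale, "*"), 2, shift, "+")
  ref2$norm <- apply(ref2$stats, 2, stats::mad)
  ref2$norm[ref2$norm < 1e-8] <- 1
  obs2 <- obs * scale + shift
  p1 <- scenario_posterior_direct(ref2, obs2, k = 50)
  expect_equal(p0, p1)
})

test_that("indistinguishable scenarios split the posterior evenly", {
  same1 <- abc_scenario("s1", test_priors(c(2e4, 6e4), c(3e3, 1.5e4)))
  same2 <- abc_scenario("s2", test_priors(c(2e4, 6e4), c(3e3, 1.5e4)))
  ref <- build_reference(list(same1, same2), n_sims = 500,
                         sample_sizes = c(5, 5, 5), L = 150, seed = 23)
  set.seed(31)
  dr <- barcodemog:::draw_scenario_params(same1)
  obs <- summary_stats(barcodemog:::simulate_from_params(dr$par,
                                                         c(5, 5, 5), 150))
  p <- scenario_posterior_direct(ref, obs, k = 200)
  expect_equal(unname(p["s1"]), 0.5, tolerance = 0.3)  # binomial error at k=200
  pl <- scenario_posterior_logistic(ref, obs, closest_fraction = 0.5)
  expect_equal(unname(pl["s1"]), 0.5, tolerance = 0.35)
})

test_that("logistic and direct approaches agree on well-separated scenarios", {
  ref <- make_ref_small()
  # representative mid-prior parameter sets, so the observations sit in
  # the core of their scenario's summary cloud rather than near the
  # boundary where the methods legitimately differ
  mid <- c(N1 = 1e4, N2 = 1e4, N3 = 1e4, N2b = 100, N3b = 100,
           t_db = 500, mu = 2e-7, kappa = 4, gamma_shape = 1.1)
  cases <- list(recent = c(mid, t1 = 4e4, t2 = 9e3),
                ancient = c(mid, t1 = 7e5, t2 = 2e5))
  set.seed(41)
  for (nm in names(cases)) {
    obs <- summary_stats(barcodemog:::simulate_from_params(cases[[nm]],
                                                           c(6, 6, 6), 200))
    pd <- scenario_posterior_direct(ref, obs, k = 30)
    pl <- scenario_posterior_logistic(ref, obs, closest_fraction = 0.1)
    expect_equal(sum(pl), 1, tolerance = 1e-8)
    expect_lt(max(abs(pd - pl[names(pd)])), 0.15)
    expect_equal(names(which.max(pd)), nm)
  }
})

test_that("rejection sampling with closest_fraction 1 returns the prior", {
  ref <- build_reference(list(scenario_recent()), n_sims = 400,
                         sample_sizes = c(4, 4, 4), L = 150, seed = 29)
  set.seed(43)
  dr <- barcodemog:::draw_scenario_params(scenario_recent())
  obs <- summary_stats(barcodemog:::simulate_from_params(dr$par,
                                                         c(4, 4, 4), 150))
  post <- estimate_parameters(ref, obs, "recent", closest_fraction = 1,
                              adjust = FALSE)
  # retained draws with uniform-ish weights reproduce the uniform t2 prior
  ks <- suppressWarnings(stats::ks.test(post$samples$t2,
                                        "punif", 3e3, 1.5e4))
  expect_gt(ks$p.value, 0.01)
  expect_error(estimate_parameters(ref, obs, "nope"), "not present")
  small <- build_reference(list(scenario_recent()), n_sims = 20,
                           sample_sizes = c(4, 4, 4), L = 150, seed = 30)
  expect_error(estimate_parameters(small, obs, "recent"), "enlarge")
})

test_that("prior pre-evaluation flags only far-outside observations", {
  ref <- make_ref_small()
  med <- apply(ref$stats, 2, stats::median)
  pe <- prior_preevaluation(ref, med)
  expect_false(any(pe$flagged))
  # continuous statistics sit mid-cloud at the median; heavily discrete
  # ones (e.g. shared-haplotype counts, mostly zero) legitimately do not
  mpd_rows <- grepl("_mpd$", pe$statistic)
  expect_true(all(pe$quantile[mpd_rows] > 0.2 & pe$quantile[mpd_rows] < 0.8))
  far <- med + 1000
  pe2 <- prior_preevaluation(ref, far)
  expect_true(any(pe2$flagged))
})

test_that("posterior model checking flags extreme observations", {
  ref <- make_ref_small()
  set.seed(47)
  dr <- barcodemog:::draw_scenario_params(scenario_recent())
  obs <- summary_stats(barcodemog:::simulate_from_params(dr$par,
                                                         c(6, 6, 6), 200))
  post <- estimate_parameters(ref, obs, "recent", closest_fraction = 0.3)
  mc <- model_check(post, obs, c(6, 6, 6), 200, n_rep = 30, seed = 7)
  expect_true(all(mc$p_value >= 0 & mc$p_value <= 1))
  # a wildly inflated observation is flagged
  obs_bad <- obs + 500
  mc2 <- model_check(post, obs_bad, c(6, 6, 6), 200, n_rep = 30, seed = 7)
  expect_gt(sum(mc2$flagged), sum(mc$flagged))
})
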