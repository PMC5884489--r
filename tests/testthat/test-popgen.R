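test_that("diversity on degenerate and two-haplotype samples", {
  toy <- worked_toy()
  d0 <- diversity(toy$identical4)
  expect_equal(d0$h, 0)
  expect_equal(d0$pi, 0)
  expect_equal(d0$S, 0)
  # two distinct haplotypes, n = 2 -> h = 1
  aln2 <- labeled_alignment(c(x = "AAAA", y = "AATT"), make_meta(c("x", "y")))
  expect_equal(diversity(aln2)$h, 1)
  expect_error(diversity(subset_alignment(aln2, "x")), "at least 2")
})

test_that("diversity matches hand computation on the two-haplotype fixture", {
  toy <- worked_toy()$two_haps
  d <- diversity(toy)
  # counts 2+2 over n=4: h = 4/3 * (1 - 2*(1/2)^2) = 2/3
  expect_equal(d$h, 2 / 3)
  expect_equal(d$S, 3)
  # 4 of 6 pairs differ at 3 of 20 sites
  expect_equal(d$mean_pairwise_diff, 4 * 3 / 6)
  expect_equal(d$pi, (4 * 3 / 20) / 6)
})

test_that("Tajima's D equals the textbook formula on a toy sample", {
  seqs <- c(s1 = "AAAAAAAAAA", s2 = "AAAAAAAAAT", s3 = "AAAAAAAATT",
            s4 = "AAAAATAAAA", s5 = "AAAAATAAAA")
  aln <- labeled_alignment(seqs, make_meta(names(seqs)))
  # independent arithmetic: count S and mean pairwise diff by direct
  # enumeration, then apply Tajima's constants computed from scratch
  mat <- do.call(rbind, strsplit(seqs, ""))
  S_hand <- sum(apply(mat, 2, function(cc) length(unique(cc)) > 1))
  pairs <- utils::combn(5, 2)
  k_hand <- mean(apply(pairs, 2, function(p) sum(mat[p[1], ] != mat[p[2], ])))
  n <- 5
  a1 <- sum(1 / 1:4); a2 <- sum(1 / (1:4)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  D_hand <- (k_hand - S_hand / a1) /
    sqrt(e1 * S_hand + e2 * S_hand * (S_hand - 1))
  td <- tajimas_d(aln, n_sim = 200, seed = 1)
  expect_equal(td$D, D_hand, tolerance = 1e-12)
  expect_gte(td$P, 0); expect_lte(td$P, 1)
})

test_that("Tajima's D is NA (not 0) when there is no variation", {
  aln <- labeled_alignment(stats::setNames(rep("ACGTACGT", 5),
                                           paste0("s", 1:5)),
                           make_meta(paste0("s", 1:5)))
  td <- tajimas_d(aln, n_sim = 10)
  expect_true(is.na(td$D))
  expect_true(is.na(td$P))
  expect_error(tajimas_d(subset_alignment(aln, 1:3)), "n >= 4")
})

test_that("neutral constant-size simulations centre Tajima's D near zero", {
  set.seed(42)
  sims <- barcodemog:::sim_neutral_stats(12, theta = 3, nrep = 600)
  D <- barcodemog:::tajima_d_stat_vec(12, sims$S, sims$mpd)
  expect_gt(mean(D, na.rm = TRUE), -0.3)
  expect_lt(mean(D, na.rm = TRUE), 0.3)
})

test_that("Fu's S-prime equals brute-force enumeration over permutation cycles", {
  # |s(n,k)| is the number of n-permutations with k cycles, so the Ewens
  # probability P(K >= k) can be recomputed by exhaustive enumeration
  count_cycles <- function(perm) {
    seen <- rep(FALSE, length(perm)); k <- 0
    for (i in seq_along(perm)) {
      if (!seen[i]) {
        k <- k + 1; j <- i
        while (!seen[j]) { seen[j] <- TRUE; j <- perm[j] }
      }
    }
    k
  }
  perms <- function(n) {
    if (n == 1) return(matrix(1, 1, 1))
    p <- perms(n - 1)
    do.call(rbind, lapply(seq_len(n), function(pos) {
      cbind(p[, seq_len(pos - 1), drop = FALSE], n,
            p[, seq(pos, n - 1)[seq_len(n - pos)], drop = FALSE])
    }))
  }
  for (n in c(4, 6)) {
    for (theta in c(0.6, 2.5)) {
      allp <- perms(n)
      cyc <- apply(allp, 1, count_cycles)
      wt <- theta^cyc / prod(theta + 0:(n - 1))
      for (kobs in 2:(n - 1)) {
        expect_equal(barcodemog:::fu_s_prime(n, kobs, theta),
                     sum(wt[cyc >= kobs]), tolerance = 1e-10)
      }
    }
  }
})

test_that("Fu's Fs is strongly negative when haplotypes exceed theta's prediction", {
  # a star of singletons: every sequence one private step from a core, so
  # the haplotype count is far above the Ewens expectation at the small
  # observed mean pairwise difference
  base <- rep("A", 12)
  seqs <- vapply(0:5, function(i) {
    s <- base
    if (i > 0) s[i] <- "T"
    paste(s, collapse = "")
  }, character(1))
  names(seqs) <- paste0("s", 0:5)
  aln <- labeled_alignment(seqs, make_meta(names(seqs)))
  ff <- fus_fs(aln, n_sim = 100, seed = 3)
  expect_lt(ff$Fs, -2)
  aln0 <- labeled_alignment(stats::setNames(rep("AAAA", 3), c("a", "b", "c")),
                            make_meta(c("a", "b", "c")))
  expect_true(is.na(fus_fs(aln0, n_sim = 10)$Fs))
})

test_that("Grant & Bowen quadrants and the boundary tie rule", {
  expect_equal(grant_bowen_class(0.6, 0.003), "large-h/small-pi")
  expect_equal(grant_bowen_class(0.85, 0.006), "large-h/large-pi")
  expect_equal(grant_bowen_class(0.2, 0.001), "small-h/small-pi")
  expect_equal(grant_bowen_class(0.3, 0.02), "small-h/large-pi")
  # boundary values go to the small side
  expect_equal(grant_bowen_class(0.5, 0.005), "small-h/small-pi")
})

test_that("observed mismatch distribution sums to n(n-1)/2", {
  toy <- worked_toy()
  m0 <- mismatch_observed(toy$identical4)
  expect_equal(unname(m0), 6)
  expect_equal(names(m0), "0")
  m <- mismatch_observed(toy$two_haps)
  expect_equal(m, c(`0` = 2, `1` = 0, `2` = 0, `3` = 4))
  aln <- random_alignment(7, 40, seed = 21)
  expect_equal(sum(mismatch_observed(aln)), choose(7, 2))
})

test_that("population_summary mirrors the per-sample diversity table", {
  d <- generate_study_like(seed = 2)
  ps <- population_summary(d$alignment, n_sim = 50, seed = 4)
  expect_true(all(c("sample", "n", "S", "K", "h", "pi_pct", "tajima_D",
                    "fu_Fs", "grant_bowen") %in% names(ps)))
  expect_true(all(ps$h >= 0 & ps$h <= 1))
  expect_setequal(ps$sample,
                  c("ArabiaSAsia", "Australia", "Eurasia", "SEAsia"))
})
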