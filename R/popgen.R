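#' Molecular diversity indexes for a population sample
#'
#' Computes the standard barcode diversity summaries: number of sequences
#' `n`, segregating sites `S` (sites with at least two distinct called
#' states), haplotype (gene) diversity `h = n/(n-1) (1 - sum p_i^2)`,
#' nucleotide diversity `pi` (mean pairwise uncorrected p-distance, per
#' site), mean number of pairwise differences (absolute counts, pairwise
#' deletion) and the Grant & Bowen quadrant of (h, pi).
#'
#' @param aln A [labeled_alignment] with at least two sequences.
#' @return List of class `diversity_summary`.
#' @export
diversity <- function(aln) {
  n <- n_sequences(aln)
  if (n < 2L) stop("diversity requires at least 2 sequences")
  enc <- encode_alignment(aln$seq)
  S <- sum(polymorphic_flags(enc))
  hs <- collapse_haplotypes(aln)
  p <- hs$count / n
  h <- n / (n - 1) * (1 - sum(p^2))
  pd <- pairwise_diff_stats(enc)
  structure(list(n = n, S = S, h = h, pi = pd$mean_prop,
                 mean_pairwise_diff = pd$mean_count,
                 var_pairwise_diff = pd$var_count,
                 n_haplotypes = length(hs$count),
                 grant_bowen = grant_bowen_class(h, pd$mean_prop)),
            class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf(
    "<diversity> n=%d  S=%d  K=%d  h=%.4f  pi=%.4f%%  mean diffs=%.3f  [%s]\n",
    x$n, x$S, x$n_haplotypes, x$h, 100 * x$pi, x$mean_pairwise_diff,
    x$grant_bowen))
  invisible(x)
}

# Pairwise difference statistics under pairwise deletion.
# Returns mean/var of absolute counts and mean proportion (per comparable site).
pairwise_diff_stats <- function(enc) {
  n <- nrow(enc)
  counts <- numeric(n * (n - 1) / 2)
  props <- numeric(length(counts))
  k <- 0L
  for (i in seq_len(n - 1L)) {
    xi <- enc[i, ]
    for (j in (i + 1L):n) {
      xj <- enc[j, ]
      ok <- !is.na(xi) & !is.na(xj)
      k <- k + 1L
      d <- sum(xi[ok] != xj[ok])
      counts[k] <- d
      props[k] <- if (any(ok)) d / sum(ok) else NA_real_
    }
  }
  list(mean_count = mean(counts),
       var_count = if (length(counts) > 1) stats::var(counts) else 0,
       mean_prop = mean(props, na.rm = TRUE),
       counts = counts)
}

#' Grant & Bowen four-quadrant classification of (h, pi)
#'
#' Classifies a sample by haplotype diversity versus nucleotide diversity
#' with the conventional thresholds h = 0.5 and pi = 0.5%. Large h with
#' small pi is the bottleneck-then-growth signature; large h with large pi
#' suggests a large stable population. Boundary values are assigned to the
#' "small" side.
#'
#' @param h Haplotype diversity in `[0, 1]`.
#' @param pi Nucleotide diversity as a proportion (0.005 = 0.5%).
#' @return One of `"large-h/small-pi"`, `"large-h/large-pi"`,
#'   `"small-h/small-pi"`, `"small-h/large-pi"`.
#' @export
grant_bowen_class <- function(h, pi) {
  stopifnot(is.finite(h), is.finite(pi), h >= 0, h <= 1, pi >= 0)
  paste0(if (h > 0.5) "large-h" else "small-h", "/",
         if (pi > 0.005) "large-pi" else "small-pi")
}

tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

tajima_d_stat <- function(n, S, mean_pairwise_diff) {
  if (S < 1L) return(NA_real_)
  cst <- tajima_constants(n)
  (mean_pairwise_diff - S / cst$a1) /
    sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
}

#' Tajima's D with a coalescent-simulated P-value
#'
#' The statistic follows Tajima (1989): the difference between the mean
#' pairwise difference and `S/a1`, scaled by its estimated standard
#' deviation. The P-value is obtained as the fraction of statistics at or
#' below the observed one among neutral constant-size coalescent
#' simulations conditioned on the sample size and Watterson's estimate
#' `theta = S/a1` (the behaviour of standard population-genetic software).
#'
#' @param aln A [labeled_alignment] with `n >= 4`.
#' @param n_sim Number of neutral simulations for the P-value (default 1000).
#' @param seed Optional RNG seed.
#' @return List with `D`, `P`, `n`, `S`, `theta_W`. When `S = 0` both `D`
#'   and `P` are `NA`.
#' @export
tajimas_d <- function(aln, n_sim = 1000, seed = NULL) {
  n <- n_sequences(aln)
  if (n < 4L) stop("Tajima's D requires n >= 4")
  enc <- encode_alignment(aln$seq)
  div <- diversity(aln)
  if (div$S < 1L) {
    return(list(D = NA_real_, P = NA_real_, n = n, S = 0L, theta_W = 0))
  }
  D <- tajima_d_stat(n, div$S, div$mean_pairwise_diff)
  theta <- div$S / tajima_constants(n)$a1
  set_seed_if(seed)
  sims <- sim_neutral_stats(n, theta, n_sim)
  Dsim <- tajima_d_stat_vec(n, sims$S, sims$mpd)
  P <- mean(Dsim[!is.na(Dsim)] <= D)
  list(D = D, P = P, n = n, S = div$S, theta_W = theta)
}

tajima_d_stat_vec <- function(n, S, mpd) {
  cst <- tajima_constants(n)
  out <- (mpd - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
  out[S < 1] <- NA_real_
  out
}

#' Fu's Fs with a coalescent-simulated P-value
#'
#' `Fs = ln(S' / (1 - S'))` where `S'` is the probability, under the Ewens
#' sampling distribution with `theta` set to the mean pairwise difference,
#' of observing at least as many haplotypes as seen. `S'` is computed from
#' unsigned Stirling numbers of the first kind in log space. The P-value is
#' the fraction of simulated `Fs` values at or below the observed one among
#' neutral constant-size coalescent simulations (significance for Fs is
#' conventionally judged at alpha = 0.02; the threshold is reported by the
#' caller, not hard-coded here).
#'
#' @param aln A [labeled_alignment] with `n >= 2`.
#' @param n_sim Simulations for the P-value (default 1000).
#' @param seed Optional RNG seed.
#' @return List with `Fs`, `P`, `S_prime`, `n`, `k_obs`, `theta_pi`. `NA`
#'   statistics when the mean pairwise difference is zero.
#' @export
fus_fs <- function(aln, n_sim = 1000, seed = NULL) {
  n <- n_sequences(aln)
  if (n < 2L) stop("Fu's Fs requires n >= 2")
  div <- diversity(aln)
  theta <- div$mean_pairwise_diff
  k_obs <- div$n_haplotypes
  if (theta <= 0) {
    return(list(Fs = NA_real_, P = NA_real_, S_prime = NA_real_,
                n = n, k_obs = k_obs, theta_pi = 0))
  }
  Sp <- fu_s_prime(n, k_obs, theta)
  Fs <- log(Sp) - log1p(-Sp)
  set_seed_if(seed)
  sims <- sim_neutral_stats(n, theta, n_sim)
  Fsim <- vapply(seq_len(n_sim), function(i) {
    th <- sims$mpd[i]
    if (th <= 0) return(NA_real_)
    sp <- fu_s_prime(n, sims$K[i], th)
    log(sp) - log1p(-sp)
  }, numeric(1))
  P <- mean(Fsim[!is.na(Fsim)] <= Fs)
  list(Fs = Fs, P = P, S_prime = Sp, n = n, k_obs = k_obs, theta_pi = theta)
}

# log unsigned Stirling numbers of the first kind, row n (k = 1..n)
log_stirling1 <- function(n) {
  lg <- -Inf * numeric(n); lg[1] <- 0  # row 1: |s(1,1)| = 1
  if (n == 1L) return(lg)
  for (m in 1:(n - 1)) {
    new <- -Inf * numeric(n)
    for (k in 1:(m + 1)) {
      terms <- c(if (k <= m) log(m) + lg[k] else -Inf,
                 if (k >= 2) lg[k - 1] else -Inf)
      new[k] <- logsumexp(terms)
    }
    lg <- new
  }
  lg
}

# P(K >= k_obs) under the Ewens sampling formula with parameter theta:
# sum_{k >= k_obs} |s(n,k)| theta^k / theta^{(n)}  (rising factorial).
fu_s_prime <- function(n, k_obs, theta) {
  lg <- log_stirling1(n)
  lrise <- sum(log(theta + 0:(n - 1)))
  lp <- lg + (1:n) * log(theta) - lrise
  sp <- sum(exp(lp[k_obs:n]))
  min(max(sp, .Machine$double.xmin), 1 - 1e-15)
}

#' Observed mismatch distribution
#'
#' Counts of pairwise absolute nucleotide differences (pairwise deletion)
#' by difference class `0, 1, ..., max`. The counts sum to `n(n-1)/2`.
#'
#' @param aln A [labeled_alignment] with `n >= 2`.
#' @return Integer vector named by difference class.
#' @export
mismatch_observed <- function(aln) {
  if (n_sequences(aln) < 2L) stop("mismatch distribution requires n >= 2")
  enc <- encode_alignment(aln$seq)
  counts <- pairwise_diff_stats(enc)$counts
  tab <- tabulate(counts + 1L, nbins = max(counts) + 1L)
  names(tab) <- 0:max(counts)
  tab
}

# ---- neutral constant-size coalescent simulation -----------------------
# Simulates the Kingman coalescent with infinite-sites mutation at rate
# theta/2 per lineage per unit of 2N generations, and returns per-replicate
# segregating sites S, mean pairwise difference mpd, and haplotype count K.
# Used for the null distributions of Tajima's D and Fu's Fs.
sim_neutral_stats <- function(n, theta, nrep) {
  S <- integer(nrep); mpd <- numeric(nrep); K <- integer(nrep)
  npairs <- n * (n - 1) / 2
  for (r in seq_len(nrep)) {
    tr <- sim_kingman_tree(n)
    nmut <- stats::rpois(1, theta / 2 * tr$total_len)
    S[r] <- nmut
    if (nmut == 0L) { mpd[r] <- 0; K[r] <- 1L; next }
    e <- sample.int(length(tr$len), nmut, replace = TRUE,
                    prob = tr$len / tr$total_len)
    sz <- tr$size[e]
    mpd[r] <- sum(sz * (n - sz)) / npairs
    # haplotype of a tip = set of mutated edges above it
    memb <- tr$tips[e]
    sig <- character(n)
    for (m in seq_along(e)) {
      tips <- memb[[m]]
      sig[tips] <- paste0(sig[tips], ",", m)
    }
    K[r] <- length(unique(sig))
  }
  list(S = S, mpd = mpd, K = K)
}

# Kingman coalescent topology + branch lengths (units of 2N generations).
# Returns per-edge length, descendant tip count and descendant tip sets.
sim_kingman_tree <- function(n) {
  tipsets <- lapply(seq_len(n), identity)
  lens <- numeric(n)
  edge_len <- numeric(0); edge_size <- integer(0); edge_tips <- list()
  k <- n
  while (k > 1L) {
    dt <- stats::rexp(1, rate = k * (k - 1) / 2)
    lens <- lens + dt
    pair <- sample.int(k, 2L)
    i <- min(pair); j <- max(pair)
    edge_len <- c(edge_len, lens[i], lens[j])
    edge_size <- c(edge_size, length(tipsets[[i]]), length(tipsets[[j]]))
    edge_tips <- c(edge_tips, tipsets[i], tipsets[j])
    tipsets[[i]] <- c(tipsets[[i]], tipsets[[j]])
    tipsets[[j]] <- NULL
    lens[i] <- 0
    lens <- lens[-j]
    k <- k - 1L
  }
  list(len = edge_len, size = edge_size, tips = edge_tips,
       total_len = sum(edge_len))
}

#' Per-population summary table
#'
#' Convenience wrapper producing one row of the classical molecular-diversity
#' table for each population sample: n, S, K, h, pi (%), mean pairwise
#' differences, Tajima's D (+P), Fu's Fs (+P) and the Grant & Bowen class.
#'
#' @param aln A [labeled_alignment].
#' @param by Metadata column defining the samples (default `"population"`).
#' @param n_sim Simulations per neutrality test.
#' @param seed Optional master seed (per-population seeds derived from it).
#' @return Data frame with one row per population.
#' @export
population_summary <- function(aln, by = "population", n_sim = 1000,
                               seed = NULL) {
  labs <- aln$meta[[by]]
  out <- NULL
  for (i in seq_along(sort(unique(labs)))) {
    lab <- sort(unique(labs))[i]
    sub <- subset_alignment(aln, which(labs == lab))
    if (n_sequences(sub) < 4L) next
    dv <- diversity(sub)
    sd_i <- if (is.null(seed)) NULL else derive_seed(seed, i)
    td <- tajimas_d(sub, n_sim = n_sim, seed = sd_i)
    ff <- fus_fs(sub, n_sim = n_sim,
                 seed = if (is.null(sd_i)) NULL else sd_i + 1L)
    out <- rbind(out, data.frame(
      sample = lab, n = dv$n, S = dv$S, K = dv$n_haplotypes,
      h = dv$h, pi_pct = 100 * dv$pi,
      mean_pairwise_diff = dv$mean_pairwise_diff,
      tajima_D = td$D, tajima_P = td$P,
      fu_Fs = ff$Fs, fu_P = ff$P,
      grant_bowen = dv$grant_bowen))
  }
  rownames(out) <- NULL
  out
}
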