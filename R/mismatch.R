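# Mismatch-distribution expansion models.
#
# Time is measured in mutational units: tau = 2 u t, where u is the
# per-sequence per-generation mutation rate and t is in generations. theta
# values are scaled population sizes (2 N u for haploid N). Expected
# distributions are probabilities over difference classes j = 0, 1, ...

# Equilibrium (stationary) mismatch: geometric with mean theta.
mismatch_equilibrium <- function(j, theta) {
  if (theta == 0) return(as.numeric(j == 0))
  exp(j * log(theta) - (j + 1) * log(theta + 1))
}

#' Expected mismatch distribution under the sudden-expansion model
#'
#' A population at stationarity with scaled size `theta0` grows
#' instantaneously to `theta1` at `tau` mutational-time units before the
#' present. The distribution of pairwise differences is the Poisson mixture
#' over the piecewise-exponential coalescence time; at `tau = 0` it reduces
#' to the geometric equilibrium `theta0^j / (theta0+1)^(j+1)`, and with
#' `theta1 = Inf` (pure growth, the default in fitting) to the classical
#' Poisson-geometric convolution of Rogers & Harpending.
#'
#' @param j Integer vector of difference classes.
#' @param tau Expansion age in mutational units (`>= 0`).
#' @param theta0 Pre-expansion scaled size.
#' @param theta1 Post-expansion scaled size (default `Inf`).
#' @return Numeric vector of probabilities, same length as `j`.
#' @export
mismatch_expected_sudden <- function(j, tau, theta0, theta1 = Inf) {
  jmax <- max(j)
  geo0 <- mismatch_equilibrium(0:jmax, theta0)
  # convolution term: sum_i dpois(j - i, tau) * geo0[i]
  conv <- vapply(0:jmax, function(jj) {
    sum(stats::dpois(jj - 0:jj, tau) * geo0[1:(jj + 1)])
  }, numeric(1))
  if (is.infinite(theta1)) {
    out <- conv
  } else {
    lam <- (theta1 + 1) / theta1
    partA <- mismatch_equilibrium(0:jmax, theta1) *
      stats::pgamma(tau * lam, shape = 0:jmax + 1)
    out <- partA + exp(-tau / theta1) * conv
  }
  out[j + 1]
}

#' Expected mismatch distribution under the spatial-expansion model
#'
#' Infinite-island founder model: two lineages sampled in one deme either
#' coalesce (rate `1/theta` per mutational unit) or separate by migration
#' (rate `M/theta`, `M = 2Nm` scaled migrants) during the expansion phase of
#' age `tau`; lineages that fail to coalesce meet again only in the single
#' ancestral deme of scaled size `theta0`, entered at `tau`. Mismatch shape
#' is governed mainly by `tau` and `M`, as in the spatial expansion fitted
#' by standard software.
#'
#' @param j Integer vector of difference classes.
#' @param tau Expansion age in mutational units.
#' @param theta Scaled deme size after the expansion.
#' @param M Scaled number of migrants exchanged per deme (`2Nm`).
#' @param theta0 Scaled size of the single ancestral deme (default 0.1).
#' @return Numeric vector of probabilities.
#' @export
mismatch_expected_spatial <- function(j, tau, theta, M, theta0 = 0.1) {
  jmax <- max(j)
  lam <- (1 + M) / theta
  # coalescence during the expansion phase
  partA <- (1 / theta) * (1 / (1 + lam))^(0:jmax + 1) *
    stats::pgamma((1 + lam) * tau, shape = 0:jmax + 1)
  # survival to the ancestral deme, then Poisson(tau) * geometric(theta0)
  p_nc <- 1 - (1 - exp(-lam * tau)) / (1 + M)
  geo0 <- mismatch_equilibrium(0:jmax, theta0)
  conv <- vapply(0:jmax, function(jj) {
    sum(stats::dpois(jj - 0:jj, tau) * geo0[1:(jj + 1)])
  }, numeric(1))
  (partA + p_nc * conv)[j + 1]
}

#' Harpending's raggedness index
#'
#' Sum of squared differences between successive relative frequencies of the
#' mismatch distribution (a trailing zero class is appended so the final
#' drop-off contributes). Smooth, low-raggedness distributions are the
#' expansion signature.
#'
#' @param x Mismatch counts or frequencies over classes `0..max`.
#' @return Raggedness index.
#' @export
raggedness <- function(x) {
  f <- x / sum(x)
  sum(diff(c(f, 0))^2)
}

ssd_stat <- function(obs_freq, expected) sum((obs_freq - expected)^2)

fit_mismatch_ls <- function(obs, model, theta1 = Inf, theta0_anc = 0.1,
                            starts = NULL) {
  j <- seq_along(obs) - 1L
  f <- obs / sum(obs)
  mean_d <- sum(j * f)
  # soft box bounds keep the search off degenerate ridges (theta -> 0,
  # M -> Inf reproduce near-identical expectations); ranges are generous
  # relative to any barcode dataset
  lo <- log(c(1e-4, 1e-4, 1e-4))
  hi <- log(c(50, 100, 1e4))
  objective <- function(lp) {
    pen <- sum(pmax(0, lp - hi[seq_along(lp)])^2) +
      sum(pmax(0, lo[seq_along(lp)] - lp)^2)
    lp <- pmin(pmax(lp, lo[seq_along(lp)]), hi[seq_along(lp)])
    if (model == "sudden") {
      e <- mismatch_expected_sudden(j, exp(lp[1]), exp(lp[2]), theta1)
    } else {
      e <- mismatch_expected_spatial(j, exp(lp[1]), exp(lp[2]), exp(lp[3]),
                                     theta0_anc)
    }
    if (any(!is.finite(e))) return(1e6)
    ssd_stat(f, e) + pen
  }
  if (is.null(starts)) {
    taus <- unique(pmax(c(0.5, mean_d, 2 * mean_d + 0.5), 0.05))
    thetas <- unique(pmax(c(0.1, 1, mean_d / 2 + 0.1), 0.01))
    Ms <- c(0.5, 5, 50)
    starts <- if (model == "sudden") {
      expand.grid(tau = taus, theta = thetas)
    } else {
      expand.grid(tau = taus, theta = thetas, M = Ms)
    }
  }
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- stats::optim(log(as.numeric(starts[s, ])), objective,
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-10, maxit = 2000))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  np <- length(best$par)
  par <- exp(pmin(pmax(best$par, lo[seq_len(np)]), hi[seq_len(np)]))
  list(tau = par[1], theta = par[2],
       M = if (model == "spatial") par[3] else NA_real_,
       ssd = best$value, converged = best$convergence == 0)
}

#' Fit an expansion model to a mismatch distribution
#'
#' Least-squares fit of the sudden- or spatial-expansion expected mismatch
#' to the observed distribution (sum of squared deviations, SSD, over
#' difference-class frequencies), with goodness-of-fit P-values by
#' parametric bootstrap: `n_boot` datasets are simulated by coalescent
#' under the fitted parameters (the spatial model by the exact
#' infinite-island structured coalescent), refitted, and the observed SSD and
#' raggedness are ranked among the simulated ones (`P = Pr(sim >= obs)`,
#' so large P means the model fits).
#'
#' @param obs Observed mismatch counts (vector over classes `0..max`, e.g.
#'   from [mismatch_observed()]).
#' @param n Sample size the distribution came from (needed for bootstrap).
#' @param model `"spatial"` (default) or `"sudden"`.
#' @param n_boot Parametric-bootstrap replicates (default 100).
#' @param seed Optional RNG seed.
#' @param theta1 Post-expansion size for the sudden model (default `Inf`).
#' @param theta0_anc Ancestral deme size for the spatial model (default 0.1).
#' @return A `mismatch_fit`: list with `tau`, `theta`, `M`, `ssd`, `p_ssd`,
#'   `raggedness`, `p_raggedness`, `model`, `observed`, `expected`,
#'   `converged`.
#' @export
fit_expansion <- function(obs, n, model = c("spatial", "sudden"),
                          n_boot = 100, seed = NULL, theta1 = Inf,
                          theta0_anc = 0.1) {
  model <- match.arg(model)
  stopifnot(sum(obs) == n * (n - 1) / 2)
  set_seed_if(seed)
  fit <- fit_mismatch_ls(obs, model, theta1, theta0_anc)
  j <- seq_along(obs) - 1L
  expected <- if (model == "sudden") {
    mismatch_expected_sudden(j, fit$tau, fit$theta, theta1)
  } else {
    mismatch_expected_spatial(j, fit$tau, fit$theta, fit$M, theta0_anc)
  }
  rag_obs <- raggedness(obs)
  ssd_sim <- rag_sim <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    sim <- if (model == "sudden") {
      sim_mismatch_sudden(n, fit$tau, fit$theta, theta1)
    } else {
      sim_mismatch_spatial(n, fit$tau, fit$theta, fit$M, theta0_anc)
    }
    # warm-started refit: the fitted parameters plus two dispersed starts
    mean_sim <- sum((seq_along(sim) - 1L) * sim) / sum(sim)
    warm <- if (model == "sudden") {
      rbind(c(fit$tau, fit$theta),
            c(max(mean_sim, 0.1), max(mean_sim / 2, 0.1)))
    } else {
      rbind(c(fit$tau, fit$theta, max(fit$M, 1e-3)),
            c(max(mean_sim, 0.1), max(mean_sim / 2, 0.1), 1))
    }
    refit <- fit_mismatch_ls(sim, model, theta1, theta0_anc, starts = warm)
    ssd_sim[b] <- refit$ssd
    rag_sim[b] <- raggedness(sim)
  }
  structure(list(tau = fit$tau, theta = fit$theta, M = fit$M,
                 ssd = fit$ssd,
                 p_ssd = mean(ssd_sim >= fit$ssd, na.rm = TRUE),
                 raggedness = rag_obs,
                 p_raggedness = mean(rag_sim >= rag_obs, na.rm = TRUE),
                 model = model, observed = obs, expected = expected,
                 n = n, converged = fit$converged),
            class = "mismatch_fit")
}

#' @export
print.mismatch_fit <- function(x, ...) {
  cat(sprintf("<mismatch_fit> model=%s  tau=%.3f  theta=%.3f%s\n",
              x$model, x$tau, x$theta,
              if (!is.na(x$M)) sprintf("  M=%.2f", x$M) else ""))
  cat(sprintf("  SSD=%.5f (P=%.3f)  raggedness=%.4f (P=%.3f)\n",
              x$ssd, x$p_ssd, x$raggedness, x$p_raggedness))
  invisible(x)
}

# ---- mutational-time coalescent simulators for the bootstrap -----------

# Sudden expansion: no coalescence more recent than tau when theta1 = Inf
# (otherwise rate pairs/theta1), then standard coalescence at rate
# pairs/theta0 in the ancestral population. Mutations: Poisson(len/2) per
# lineage per mutational unit; infinite sites.
sim_mismatch_sudden <- function(n, tau, theta0, theta1 = Inf) {
  merge_events <- sim_piecewise_pair_times(n, tau, theta1, theta0)
  mismatch_from_tree(n, merge_events)
}

sim_piecewise_pair_times <- function(n, tau, theta_recent, theta_anc) {
  # returns list of (time, i, j) coalescences among lineages 1..n
  active <- seq_len(n)
  t <- 0
  events <- list()
  k <- n
  while (k > 1L) {
    rate_recent <- if (is.infinite(theta_recent)) 0 else
      k * (k - 1) / 2 / theta_recent
    if (t < tau) {
      if (rate_recent > 0) {
        dt <- stats::rexp(1, rate_recent)
        if (t + dt < tau) {
          t <- t + dt
        } else {
          t <- tau
          next
        }
      } else {
        t <- tau
        next
      }
    } else {
      t <- t + stats::rexp(1, k * (k - 1) / 2 / theta_anc)
    }
    pair <- sample.int(k, 2L)
    events[[length(events) + 1L]] <- c(t, active[min(pair)], active[max(pair)])
    active <- c(active[-pair], active[min(pair)])  # merged keeps first label
    active <- sort(unique(active))
    k <- k - 1L
  }
  events
}

# Spatial expansion, infinite-island limit: n lineages start in one deme;
# within-deme pairs coalesce at rate 1/theta, each lineage migrates at
# rate M/(2*theta) to a fresh, unoccupied deme (and can never rejoin an
# occupied one). Once every deme holds a single lineage nothing further
# can happen before tau, so the simulation jumps there; at tau all
# surviving lineages drop into the ancestral deme (theta0). Event count
# is O(n), so the simulation stays fast for any (theta, M).
sim_mismatch_spatial <- function(n, tau, theta, M, theta0 = 0.1) {
  deme <- rep(1L, n)
  next_deme <- 2L
  labels <- seq_len(n)
  t <- 0
  events <- list()
  while (length(labels) > 1L) {
    k <- length(labels)
    if (t < tau) {
      kk <- table(deme)
      movable <- sum(kk[kk >= 2])   # migration of a singleton changes nothing
      rate_coal <- sum(kk * (kk - 1) / 2) / theta
      rate_mig <- movable * M / (2 * theta)
      total <- rate_coal + rate_mig
      if (total == 0) { t <- tau; deme <- rep(0L, k); next }
      dt <- stats::rexp(1, total)
      if (t + dt >= tau) { t <- tau; deme <- rep(0L, k); next }
      t <- t + dt
      if (stats::runif(1) < rate_coal / total) {
        demes_with_pairs <- as.integer(names(kk))[kk >= 2]
        w <- kk[kk >= 2] * (kk[kk >= 2] - 1) / 2
        d <- demes_with_pairs[sample.int(length(demes_with_pairs), 1,
                                         prob = w)]
        in_d <- which(deme == d)
        pair <- in_d[sample.int(length(in_d), 2L)]
        events[[length(events) + 1L]] <-
          c(t, labels[min(pair)], labels[max(pair)])
        keep <- setdiff(seq_len(k), max(pair))
        labels <- labels[keep]; deme <- deme[keep]
      } else {
        crowded <- which(deme %in% as.integer(names(kk))[kk >= 2])
        m <- crowded[sample.int(length(crowded), 1L)]
        deme[m] <- next_deme
        next_deme <- next_deme + 1L
      }
    } else {
      t <- t + stats::rexp(1, k * (k - 1) / 2 / theta0)
      pair <- sample.int(k, 2L)
      events[[length(events) + 1L]] <-
        c(t, labels[min(pair)], labels[max(pair)])
      keep <- setdiff(seq_len(k), max(pair))
      labels <- labels[keep]; deme <- deme[keep]
    }
  }
  mismatch_from_tree(n, events)
}

# Build pairwise differences from coalescence events: each pair's
# differences ~ Poisson(2 * T_coal * 1/2) = Poisson(T_coal) in mutational
# units. T_coal obtained by union-find over the event sequence.
mismatch_from_tree <- function(n, events) {
  tcoal <- matrix(NA_real_, n, n)
  comp <- as.list(seq_len(n))
  of <- seq_len(n)
  for (ev in events) {
    t <- ev[1]; a <- of[ev[2]]; b <- of[ev[3]]
    for (x in comp[[a]]) for (y in comp[[b]]) {
      tcoal[x, y] <- tcoal[y, x] <- t
    }
    comp[[a]] <- c(comp[[a]], comp[[b]])
    of[of == b] <- a
  }
  times <- tcoal[upper.tri(tcoal)]
  diffs <- stats::rpois(length(times), times)
  tab <- tabulate(diffs + 1L, nbins = max(diffs) + 1L)
  names(tab) <- 0:max(diffs)
  tab
}

#' Convert tau into time since expansion
#'
#' `t = tau / (2 u)` with `u` the per-sequence per-generation mutation rate,
#' assembled explicitly as `u = mu_site_year * L / generations_per_year` so
#' the unit bookkeeping (per-site per-year rate, sequence length,
#' generations per year) is visible. With the mid-Aegean COI rate
#' 1.77e-8 substitutions/site/year, L = 456 and one generation per year,
#' `tau = 1.081` gives about 67 thousand years.
#'
#' @param tau Moment estimator of the expansion age, mutational units.
#' @param mu_site_year Mutation rate, substitutions/site/year.
#' @param L Sequence length in sites.
#' @param generations_per_year Generations per year (default 1).
#' @return List with `tau`, `t_generations`, `t_years`, `mu_site_year`,
#'   `L`, `generations_per_year`.
#' @export
expansion_time <- function(tau, mu_site_year, L, generations_per_year = 1) {
  stopifnot(tau >= 0, mu_site_year > 0, L > 0, generations_per_year > 0)
  u <- mu_site_year * L / generations_per_year
  t_gen <- tau / (2 * u)
  list(tau = tau, t_generations = t_gen,
       t_years = t_gen / generations_per_year,
       mu_site_year = mu_site_year, L = L,
       generations_per_year = generations_per_year)
}
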