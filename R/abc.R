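# DIYABC-style summary statistics and ABC machinery.

# Logical flag per column: at least two distinct called states.
polymorphic_flags <- function(enc) {
  if (ncol(enc) == 0L) return(logical(0))
  if (!anyNA(enc)) {
    ref <- enc[rep(1L, nrow(enc)), , drop = FALSE]
    return(colSums(enc != ref) > 0L)
  }
  apply(enc, 2, function(col) {
    u <- unique(col[!is.na(col)])
    length(u) >= 2L
  })
}

polymorphic_columns <- function(enc) which(polymorphic_flags(enc))

#' Summary-statistic vector for a multi-population alignment
#'
#' One- and two-sample statistics in a fixed order: per population, the
#' haplotype count, segregating sites, mean and variance of pairwise
#' differences, Tajima's D and private segregating sites; per population
#' pair, the mean between-population pairwise difference, Hudson-style
#' F_ST (`1 - mean within-pair diversity / between diversity`) and the
#' number of shared haplotypes. Undefined statistics (e.g. Tajima's D with
#' `S = 0`) are imputed as 0 with a companion `*_na` indicator, so vectors
#' are always finite and of fixed length.
#'
#' @param aln A [labeled_alignment] whose metadata `population` column
#'   defines the samples.
#' @param populations Optional population ordering (default sorted unique).
#' @return Named numeric vector.
#' @export
summary_stats <- function(aln, populations = NULL) {
  pops <- populations %||% sort(unique(aln$meta$population))
  enc <- encode_alignment(aln$seq)
  # restrict to segregating columns once for speed
  sub <- enc[, polymorphic_columns(enc), drop = FALSE]
  n_all <- nrow(enc)
  if (!anyNA(sub)) {
    # pairwise differences via per-state indicator cross-products
    same <- matrix(0, n_all, n_all)
    for (st in 1:4) {
      I <- (sub == st) * 1
      same <- same + tcrossprod(I)
    }
    dmat <- ncol(sub) - same
    diag(dmat) <- 0
  } else {
    dmat <- matrix(0, n_all, n_all)
    for (s in seq_len(ncol(sub))) {
      x <- sub[, s]
      dm <- outer(x, x, "!=")
      dm[is.na(dm)] <- 0
      dmat <- dmat + dm
    }
  }
  hapkey <- apply(sub, 1, paste, collapse = "")
  out <- c()
  seg_by_pop <- list()
  within_pi <- c()
  for (p in pops) {
    idx <- which(aln$meta$population == p)
    np <- length(idx)
    cols_var <- polymorphic_flags(sub[idx, , drop = FALSE])
    S <- sum(cols_var)
    seg_by_pop[[p]] <- cols_var
    K <- length(unique(hapkey[idx]))
    pd <- dmat[idx, idx][upper.tri(diag(np))]
    mpd <- mean(pd); vpd <- if (length(pd) > 1) stats::var(pd) else 0
    within_pi[p] <- mpd
    D <- if (np >= 4 && S >= 1) tajima_d_stat(np, S, mpd) else NA_real_
    out <- c(out, stats::setNames(
      c(K, S, mpd, vpd, ifelse(is.na(D), 0, D), as.numeric(is.na(D))),
      paste0(p, "_", c("K", "S", "mpd", "vpd", "tajD", "tajD_na"))))
  }
  # private segregating sites per population
  for (p in pops) {
    others <- Reduce(`|`, seg_by_pop[setdiff(pops, p)], rep(FALSE, ncol(sub)))
    out <- c(out, stats::setNames(sum(seg_by_pop[[p]] & !others),
                                  paste0(p, "_privS")))
  }
  if (length(pops) > 1) {
    for (i in seq_len(length(pops) - 1L)) {
      for (j in (i + 1L):length(pops)) {
        ii <- which(aln$meta$population == pops[i])
        jj <- which(aln$meta$population == pops[j])
        between <- mean(dmat[ii, jj])
        fst <- if (between > 0) {
          1 - mean(c(within_pi[pops[i]], within_pi[pops[j]])) / between
        } else 0
        shared <- length(intersect(unique(hapkey[ii]), unique(hapkey[jj])))
        out <- c(out, stats::setNames(
          c(between, fst, shared),
          paste0(pops[i], "x", pops[j], "_", c("between", "fst", "sharedK"))))
      }
    }
  }
  out
}

#' Uniform / log-uniform prior specification
#'
#' @param min,max Bounds (finite, `min <= max`; equal bounds fix the value).
#' @param log Draw uniformly on the log scale.
#' @return A `prior` list.
#' @export
prior_unif <- function(min, max, log = FALSE) {
  stopifnot(is.finite(min), is.finite(max), min <= max, !log || min > 0)
  structure(list(min = min, max = max, log = log), class = "prior")
}

draw_prior <- function(pr) {
  if (pr$min == pr$max) return(pr$min)
  if (pr$log) exp(stats::runif(1, log(pr$min), log(pr$max)))
  else stats::runif(1, pr$min, pr$max)
}

#' Define an ABC scenario: a named set of parameter priors
#'
#' Priors are needed for `N1,N2,N3,N2b,N3b,t1,t2,t_db` plus the mutation
#' model (`mu` substitutions/site/generation, `kappa`, `gamma_shape`).
#' Draws violating the scenario geometry (`t1 > t2 > t_db`, founder sizes
#' below extant sizes) are rejected and redrawn, with the rejection count
#' recorded on the reference table.
#'
#' @param name Scenario label.
#' @param priors Named list of [prior_unif()] objects.
#' @return An `abc_scenario` list.
#' @export
abc_scenario <- function(name, priors) {
  needed <- c("N1", "N2", "N3", "N2b", "N3b", "t1", "t2", "t_db",
              "mu", "kappa", "gamma_shape")
  missing <- setdiff(needed, names(priors))
  if (length(missing)) stop("missing priors: ", paste(missing, collapse = ", "))
  structure(list(name = name, priors = priors), class = "abc_scenario")
}

draw_scenario_params <- function(scn, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    par <- vapply(scn$priors, draw_prior, numeric(1))
    par["N2b"] <- min(par["N2b"], par["N2"])
    par["N3b"] <- min(par["N3b"], par["N3"])
    ok <- par["t1"] > par["t2"] && par["t2"] > par["t_db"] &&
      all(par[c("N1", "N2", "N3", "N2b", "N3b")] >= 1)
    if (ok) return(list(par = par, rejected = i - 1L))
  }
  stop("could not draw valid parameters for scenario ", scn$name)
}

simulate_from_params <- function(par, n_sizes, L) {
  scn <- make_scenario("custom",
                       N1 = par[["N1"]], N2 = par[["N2"]], N3 = par[["N3"]],
                       N2b = par[["N2b"]], N3b = par[["N3b"]],
                       t1 = par[["t1"]], t2 = par[["t2"]],
                       t_db = par[["t_db"]])
  model <- hky_model(kappa = par[["kappa"]], gamma_shape = par[["gamma_shape"]],
                     L = L, rate = par[["mu"]])
  gen <- simulate_genealogy(scn, n_sizes[1], n_sizes[2],
                            if (length(n_sizes) > 2) n_sizes[3] else 0L)
  evolve_sequences(gen, model)
}

#' Build an ABC reference table
#'
#' Draws a scenario from the scenario prior, parameters from its priors,
#' simulates a dataset through the coalescent + HKY engine, and stores the
#' summary-statistic vector. Per-row seeds are derived from the master seed
#' by a counter, so the table is reproducible and could be generated in
#' chunks. Per-statistic median absolute deviations (floored at a small
#' constant) are computed once and stored as the normalisation.
#'
#' @param scenarios List of `abc_scenario` objects.
#' @param n_sims Number of rows.
#' @param sample_sizes Integer vector `c(n1, n2, n3)`.
#' @param L Sequence length in sites.
#' @param seed Master seed.
#' @param scenario_prior Probabilities per scenario (default equal).
#' @return An `abc_reftable`: list with `scenario` (factor), `params`
#'   (data frame), `stats` (matrix), `norm` (MAD vector), `n_rejected`,
#'   `sample_sizes`, `L`.
#' @export
build_reference <- function(scenarios, n_sims, sample_sizes, L, seed = 1,
                            scenario_prior = NULL) {
  stopifnot(n_sims >= 1)
  nsc <- length(scenarios)
  scenario_prior <- scenario_prior %||% rep(1 / nsc, nsc)
  stopifnot(abs(sum(scenario_prior) - 1) < 1e-8)
  scn_names <- vapply(scenarios, `[[`, character(1), "name")
  scn_col <- character(n_sims)
  stats_list <- vector("list", n_sims)
  params_list <- vector("list", n_sims)
  n_rejected <- 0L
  for (i in seq_len(n_sims)) {
    set.seed(derive_seed(seed, i))
    s <- sample.int(nsc, 1, prob = scenario_prior)
    dr <- draw_scenario_params(scenarios[[s]])
    n_rejected <- n_rejected + dr$rejected
    aln <- simulate_from_params(dr$par, sample_sizes, L)
    scn_col[i] <- scn_names[s]
    params_list[[i]] <- dr$par
    stats_list[[i]] <- summary_stats(aln)
  }
  stats_mat <- do.call(rbind, stats_list)
  norm <- apply(stats_mat, 2, stats::mad)
  norm[norm < 1e-8] <- 1
  bounds <- lapply(scenarios, function(sc) {
    do.call(rbind, lapply(sc$priors, function(pr) c(pr$min, pr$max)))
  })
  names(bounds) <- scn_names
  structure(list(scenario = factor(scn_col, levels = scn_names),
                 params = as.data.frame(do.call(rbind, params_list)),
                 stats = stats_mat, norm = norm, n_rejected = n_rejected,
                 bounds = bounds,
                 sample_sizes = sample_sizes, L = L, seed = seed),
            class = "abc_reftable")
}

#' @export
print.abc_reftable <- function(x, ...) {
  cat(sprintf("<abc_reftable> %d rows, %d statistics, scenarios: %s\n",
              nrow(x$stats), ncol(x$stats),
              paste(sprintf("%s (%d)", levels(x$scenario),
                            table(x$scenario)), collapse = ", ")))
  invisible(x)
}

ref_distances <- function(ref, obs) {
  obs <- obs[colnames(ref$stats)]
  z <- sweep(sweep(ref$stats, 2, obs), 2, ref$norm, "/")
  sqrt(rowSums(z^2))
}

#' Scenario posterior probabilities, direct (rejection) approach
#'
#' Posterior probability of each scenario is its frequency among the `k`
#' reference rows closest to the observed summaries (Euclidean distance on
#' MAD-normalised statistics).
#'
#' @param ref An `abc_reftable`.
#' @param obs Observed summary vector (from [summary_stats()]).
#' @param k Number of nearest rows (default 500, capped at the table size).
#' @return Named probability vector summing to 1.
#' @export
scenario_posterior_direct <- function(ref, obs, k = 500) {
  if (k < 1) stop("k must be >= 1")
  k <- min(k, nrow(ref$stats))
  d <- ref_distances(ref, obs)
  nearest <- order(d)[seq_len(k)]
  tab <- table(ref$scenario[nearest])
  as.numeric(tab / k) |> stats::setNames(names(tab))
}

#' Scenario posterior probabilities, logistic-regression approach
#'
#' Polychotomous logistic regression of the scenario indicator on the
#' (summary - observed) differences over the closest fraction of reference
#' rows, evaluated at zero difference. Falls back to the direct estimate
#' with a warning if the regression is degenerate (e.g. only one scenario
#' retained, or separation).
#'
#' @param ref An `abc_reftable`.
#' @param obs Observed summary vector.
#' @param closest_fraction Fraction of rows retained (default 0.01).
#' @return Named probability vector over all scenarios, summing to 1.
#' @export
scenario_posterior_logistic <- function(ref, obs, closest_fraction = 0.01) {
  stopifnot(closest_fraction > 0, closest_fraction <= 1)
  n_keep <- max(ceiling(closest_fraction * nrow(ref$stats)), 20L)
  n_keep <- min(n_keep, nrow(ref$stats))
  d <- ref_distances(ref, obs)
  keep <- order(d)[seq_len(n_keep)]
  y <- droplevels(ref$scenario[keep])
  lv <- levels(ref$scenario)
  if (nlevels(y) < 2L) {
    warning("only one scenario among retained rows; falling back to direct")
    return(scenario_posterior_direct(ref, obs, k = n_keep))
  }
  X <- sweep(ref$stats[keep, , drop = FALSE], 2, obs[colnames(ref$stats)])
  X <- sweep(X, 2, ref$norm, "/")
  # drop constant columns to keep the design full rank
  keep_col <- apply(X, 2, function(z) stats::sd(z) > 1e-10)
  X <- X[, keep_col, drop = FALSE]
  dat <- data.frame(y = y, X)
  fit <- tryCatch(
    nnet::multinom(y ~ ., data = dat, trace = FALSE, maxit = 500),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("logistic regression failed; falling back to direct")
    return(scenario_posterior_direct(ref, obs, k = n_keep))
  }
  nd <- as.data.frame(matrix(0, 1, ncol(X)))
  names(nd) <- colnames(X)
  p <- predict(fit, newdata = nd, type = "probs")
  if (is.null(dim(p))) p <- stats::setNames(c(1 - p, p), levels(y))
  out <- stats::setNames(numeric(length(lv)), lv)
  out[names(p)] <- pmin(pmax(as.numeric(p), 0), 1)
  out / sum(out)
}

#' Local-linear ABC parameter estimation
#'
#' Retains the closest fraction of the chosen scenario's rows, then applies
#' the Beaumont local-linear regression adjustment on log-transformed
#' parameters: each retained draw is corrected by the fitted linear trend
#' of the (normalised) summary differences, with Epanechnikov weights on
#' distance. Reports mean, median and 2.5/97.5% quantiles per parameter.
#'
#' @param ref An `abc_reftable`.
#' @param obs Observed summary vector.
#' @param scenario Scenario name present in `ref`.
#' @param closest_fraction Fraction of that scenario's rows kept (default 0.01).
#' @param min_retained Error below this many retained rows (default 50).
#' @param adjust Apply the local-linear regression correction (default
#'   `TRUE`); `FALSE` gives plain rejection sampling, so with
#'   `closest_fraction = 1` the posterior equals the prior.
#' @return An `abc_posterior`: list with `samples` (adjusted draws, data
#'   frame), `weights`, `summary` (data frame mean/median/q2.5/q97.5),
#'   `scenario`.
#' @export
estimate_parameters <- function(ref, obs, scenario, closest_fraction = 0.01,
                                min_retained = 50L, adjust = TRUE) {
  rows <- which(ref$scenario == scenario)
  if (!length(rows)) stop("scenario not present in reference table: ", scenario)
  n_keep <- max(ceiling(closest_fraction * length(rows)), min_retained)
  if (length(rows) < min_retained) {
    stop("only ", length(rows), " rows for scenario ", scenario,
         "; enlarge the reference table")
  }
  n_keep <- min(n_keep, length(rows))
  d <- ref_distances(ref, obs)[rows]
  keep <- rows[order(d)[seq_len(n_keep)]]
  dk <- sort(d)[seq_len(n_keep)]
  dmax <- max(dk) * (1 + 1e-9)
  w <- 1 - (dk / dmax)^2  # Epanechnikov
  X <- sweep(ref$stats[keep, , drop = FALSE], 2, obs[colnames(ref$stats)])
  X <- sweep(X, 2, ref$norm, "/")
  keep_col <- apply(X, 2, function(z) stats::sd(z) > 1e-10)
  X <- X[, keep_col, drop = FALSE]
  pars <- ref$params[keep, , drop = FALSE]
  bounds <- ref$bounds[[scenario]]
  adj <- pars
  if (adjust) for (pn in names(pars)) {
    y <- pars[[pn]]
    if (stats::sd(y) < 1e-12) { adj[[pn]] <- y; next }
    # transform to an unbounded scale before the regression: logit within
    # the prior bounds when known (DIYABC convention), else log when
    # positive, else identity
    bd <- if (!is.null(bounds) && pn %in% rownames(bounds)) {
      bounds[pn, ]
    } else NULL
    tr <- param_transform(y, bd)
    fit <- stats::lm.wfit(cbind(1, X), tr$z, w)
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0  # dropped collinear columns contribute nothing
    resid <- tr$z - cbind(1, X) %*% beta
    # residuals understate the conditional spread by the regression's
    # degrees of freedom; inflate by the usual finite-sample factor
    # (effective sample size from the weights)
    n_eff <- sum(w)^2 / sum(w^2)
    k_par <- sum(!is.na(fit$coefficients))
    infl <- sqrt(n_eff / max(n_eff - k_par, 1))
    z_adj <- beta[1] + resid * infl
    adj[[pn]] <- tr$back(z_adj)
  }
  qs <- t(vapply(adj, function(v) {
    c(mean = weighted_mean(v, w),
      median = weighted_quantile(v, w, 0.5),
      q2.5 = weighted_quantile(v, w, 0.025),
      q97.5 = weighted_quantile(v, w, 0.975))
  }, numeric(4)))
  structure(list(samples = adj, weights = w,
                 summary = data.frame(parameter = names(pars), qs,
                                      row.names = NULL),
                 scenario = scenario),
            class = "abc_posterior")
}

# Transform a parameter vector to an unbounded scale and return the
# inverse. Bounded (finite prior interval) -> logit; positive -> log.
param_transform <- function(y, bounds = NULL) {
  if (!is.null(bounds) && diff(bounds) > 0 && all(is.finite(bounds))) {
    a <- bounds[1]; b <- bounds[2]
    eps <- 1e-6 * (b - a)
    yc <- pmin(pmax(y, a + eps), b - eps)
    list(z = log((yc - a) / (b - yc)),
         back = function(z) a + (b - a) * stats::plogis(z))
  } else if (all(y > 0)) {
    list(z = log(y), back = function(z) exp(z))
  } else {
    list(z = y, back = function(z) z)
  }
}

weighted_mean <- function(x, w) sum(x * w) / sum(w)

# Weighted quantile with the midpoint (type-7-like) interpolation rule;
# a step-function quantile truncates interval endpoints noticeably when
# the retained sample is modest.
weighted_quantile <- function(x, w, p) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  pos <- cumsum(w) - w / 2
  if (p <= pos[1]) return(x[1])
  if (p >= pos[length(pos)]) return(x[length(x)])
  stats::approx(pos, x, xout = p, ties = "ordered")$y
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat(sprintf("<abc_posterior> scenario %s, %d retained draws\n",
              x$scenario, nrow(x$samples)))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Confidence in scenario choice: type I / type II error rates
#'
#' Simulates pseudo-observed datasets (pods) under each scenario from its
#' priors, classifies each with the direct approach against `ref`, and
#' reports: type I error (fraction of target-scenario pods not assigned to
#' the target), type II error (fraction of other-scenario pods assigned to
#' the target) and the overall posterior predictive (misclassification)
#' error over all pods.
#'
#' @param ref An `abc_reftable`.
#' @param scenarios The `abc_scenario` list used to build `ref`.
#' @param target Name of the scenario whose choice is evaluated.
#' @param n_pods Pods per scenario.
#' @param k Nearest-neighbour count for classification.
#' @param seed Master seed.
#' @return List with `type_I`, `type_II`, `predictive_error`,
#'   `assignments` (data frame of true/assigned).
#' @export
scenario_confidence <- function(ref, scenarios, target, n_pods = 100,
                                k = 500, seed = 1) {
  stopifnot(n_pods >= 1)
  scn_names <- vapply(scenarios, `[[`, character(1), "name")
  stopifnot(target %in% scn_names)
  truth <- character(0); assigned <- character(0)
  ctr <- 0L
  for (s in seq_along(scenarios)) {
    for (p in seq_len(n_pods)) {
      ctr <- ctr + 1L
      set.seed(derive_seed(seed + 104729L, ctr))
      dr <- draw_scenario_params(scenarios[[s]])
      aln <- simulate_from_params(dr$par, ref$sample_sizes, ref$L)
      post <- scenario_posterior_direct(ref, summary_stats(aln), k)
      truth <- c(truth, scn_names[s])
      assigned <- c(assigned, names(post)[which.max(post)])
    }
  }
  is_target <- truth == target
  list(type_I = mean(assigned[is_target] != target),
       type_II = mean(assigned[!is_target] == target),
       predictive_error = mean(assigned != truth),
       assignments = data.frame(true = truth, assigned = assigned))
}

#' Pre-evaluation of prior combinations
#'
#' Checks that the observed summaries lie inside the cloud of simulated
#' summaries: for each statistic, the quantile of the observed value among
#' the reference simulations; values outside `[0.5%, 99.5%]` are flagged.
#'
#' @param ref An `abc_reftable`.
#' @param obs Observed summary vector.
#' @return Data frame with `statistic`, `quantile`, `flagged`.
#' @export
prior_preevaluation <- function(ref, obs) {
  obs <- obs[colnames(ref$stats)]
  q <- vapply(seq_along(obs), function(j) {
    mean(ref$stats[, j] <= obs[j])
  }, numeric(1))
  data.frame(statistic = colnames(ref$stats), quantile = q,
             flagged = q < 0.005 | q > 0.995, row.names = NULL)
}

#' Posterior predictive model checking
#'
#' Simulates `n_rep` datasets from parameter draws of the posterior and
#' compares each summary statistic with its observed value: the p-value is
#' the fraction of simulated values at or below the observed one, flagged
#' two-sided at 0.025.
#'
#' @param posterior An `abc_posterior` from [estimate_parameters()].
#' @param obs Observed summary vector.
#' @param sample_sizes,L Simulation dimensions (as used for `obs`).
#' @param n_rep Number of posterior predictive replicates (default 100).
#' @param seed Master seed.
#' @return Data frame with `statistic`, `p_value`, `flagged`.
#' @export
model_check <- function(posterior, obs, sample_sizes, L, n_rep = 100,
                        seed = 1) {
  stopifnot(nrow(posterior$samples) >= 1)
  sims <- matrix(NA_real_, n_rep, length(obs),
                 dimnames = list(NULL, names(obs)))
  w <- posterior$weights / sum(posterior$weights)
  for (r in seq_len(n_rep)) {
    set.seed(derive_seed(seed + 7907L, r))
    i <- sample.int(nrow(posterior$samples), 1, prob = w)
    par <- unlist(posterior$samples[i, ])
    par["t_db"] <- min(par[["t_db"]], 0.99 * par[["t2"]])
    if (par[["t1"]] <= par[["t2"]]) par["t1"] <- par[["t2"]] * 1.01
    aln <- simulate_from_params(par, sample_sizes, L)
    sims[r, ] <- summary_stats(aln)[names(obs)]
  }
  p <- vapply(seq_along(obs), function(j) mean(sims[, j] <= obs[j]),
              numeric(1))
  data.frame(statistic = names(obs), p_value = p,
             flagged = pmin(p, 1 - p) < 0.025, row.names = NULL)
}
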