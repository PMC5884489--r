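# Three-population coalescent with founder bottlenecks.
#
# Geometry (backward in time, generations): Pop2 and Pop3 each derive from
# Pop1. Pop3 merges into Pop1 at t2, Pop2 at t1, with t1 > t2. For the
# t_db generations immediately after each colonisation (forward time),
# i.e. the backward interval [t_split - t_db, t_split), the daughter
# population has reduced founder size (N3b resp. N2b). All N are haploid
# effective numbers (maternal mtDNA); no migration between demes.

#' Define a demographic scenario
#'
#' Validates a three-population split scenario with founder bottlenecks.
#' Named scenarios constrain the split times to the epochs they represent
#' (at one generation per year): `"2-CG"` places the Pop3 split in the Late
#' Pleistocene (11.7--129 ka) and the Pop2 split since the mid-Pleistocene
#' transition (<= 774 ka); `"1-CG"` requires older splits (t2 >= 129 ka,
#' t1 >= 774 ka). `"custom"` only enforces the geometric invariants.
#'
#' @param name `"1-CG"`, `"2-CG"` or `"custom"`.
#' @param N1,N2,N3 Haploid effective sizes of the extant populations.
#' @param N2b,N3b Founder sizes (`<=` the corresponding extant size).
#' @param t1 Pop2 split time, generations (`> t2`).
#' @param t2 Pop3 split time, generations.
#' @param t_db Bottleneck duration, generations (`< min(t1, t2)`).
#' @return A validated `demographic_scenario` list.
#' @export
make_scenario <- function(name = c("custom", "1-CG", "2-CG"),
                          N1, N2, N3, N2b = N2, N3b = N3,
                          t1, t2, t_db = 0) {
  name <- match.arg(name)
  sizes <- c(N1 = N1, N2 = N2, N3 = N3, N2b = N2b, N3b = N3b)
  if (any(sizes < 1)) stop("all population sizes must be >= 1")
  if (!(t1 > t2 && t2 > 0)) stop("split ordering violated: need t1 > t2 > 0")
  if (t_db < 0 || t_db >= min(t1, t2)) {
    stop("bottleneck duration must satisfy 0 <= t_db < min(t1, t2)")
  }
  if (N2b > N2 || N3b > N3) stop("founder sizes must not exceed N2 / N3")
  if (name == "2-CG" && !(t2 >= 11700 && t2 <= 129000 && t1 <= 774000)) {
    stop("2-CG requires t2 in the Late Pleistocene (11700-129000) ",
         "and t1 <= 774000 generations")
  }
  if (name == "1-CG" && !(t2 >= 129000 && t1 >= 774000)) {
    stop("1-CG requires t2 >= 129000 and t1 >= 774000 generations")
  }
  structure(list(name = name, N1 = N1, N2 = N2, N3 = N3, N2b = N2b,
                 N3b = N3b, t1 = t1, t2 = t2, t_db = t_db),
            class = "demographic_scenario")
}

#' @export
print.demographic_scenario <- function(x, ...) {
  cat(sprintf("<scenario %s> N1=%g N2=%g N3=%g N2b=%g N3b=%g\n",
              x$name, x$N1, x$N2, x$N3, x$N2b, x$N3b))
  cat(sprintf("  t1=%g  t2=%g  t_db=%g generations\n", x$t1, x$t2, x$t_db))
  invisible(x)
}

# Deme size at backward time t under the scenario.
deme_size_at <- function(scn, deme, t) {
  switch(deme,
         `1` = scn$N1,
         `2` = if (t >= scn$t1 - scn$t_db) scn$N2b else scn$N2,
         `3` = if (t >= scn$t2 - scn$t_db) scn$N3b else scn$N3)
}

#' Simulate a genealogy under a demographic scenario
#'
#' Backward-time structured coalescent: within each deme, every lineage
#' pair coalesces at rate `1/N_d(t)` per generation; at `t2` all Pop3
#' lineages move to Pop1, at `t1` all Pop2 lineages do. Founder sizes apply
#' over the `t_db` generations preceding each merge (backward). Sample
#' sizes of 0 are allowed, so a single-deme simulation is `n2 = n3 = 0`.
#'
#' @param scn A `demographic_scenario` from [make_scenario()].
#' @param n1,n2,n3 Sample sizes per population.
#' @param seed Optional RNG seed.
#' @return A `genealogy`: list with `edge` (2-column parent/child matrix,
#'   tips `1..n`, root last), `edge_length` (generations), `n_tip`,
#'   `tip_label`, `tip_pop`, `node_time` and `tmrca`.
#' @export
simulate_genealogy <- function(scn, n1, n2, n3 = 0L, seed = NULL) {
  stopifnot(n1 >= 0, n2 >= 0, n3 >= 0, n1 + n2 + n3 >= 2)
  set_seed_if(seed)
  n <- n1 + n2 + n3
  deme <- rep(c(1L, 2L, 3L), c(n1, n2, n3))
  tip_pop <- paste0("pop", deme)
  node <- seq_len(n)           # current node id per lineage
  node_time <- numeric(2 * n - 1)
  edges <- matrix(0L, 2 * (n - 1), 2)
  edge_len <- numeric(2 * (n - 1))
  next_node <- n + 1L
  e <- 0L
  t <- 0
  boundaries <- sort(unique(c(scn$t2 - scn$t_db, scn$t2,
                              scn$t1 - scn$t_db, scn$t1, Inf)))
  while (length(node) > 1L) {
    # apply merges
    if (t >= scn$t2) deme[deme == 3L] <- 1L
    if (t >= scn$t1) deme[deme == 2L] <- 1L
    kk <- tabulate(deme, nbins = 3L)
    rates <- numeric(3)
    for (d in 1:3) {
      if (kk[d] >= 2) {
        rates[d] <- kk[d] * (kk[d] - 1) / 2 / deme_size_at(scn, d, t)
      }
    }
    total <- sum(rates)
    nxt <- boundaries[boundaries > t][1]
    if (total == 0) { t <- nxt; next }
    dt <- stats::rexp(1, total)
    if (t + dt >= nxt) { t <- nxt; next }
    t <- t + dt
    d <- sample.int(3L, 1, prob = rates)
    in_d <- which(deme == d)
    pair <- in_d[sample.int(length(in_d), 2L)]
    parent <- next_node; next_node <- next_node + 1L
    node_time[parent] <- t
    for (ch in node[pair]) {
      e <- e + 1L
      edges[e, ] <- c(parent, ch)
      edge_len[e] <- t - node_time[ch]
    }
    node <- c(node[-pair], parent)
    deme <- c(deme[-pair], d)
  }
  structure(list(edge = edges, edge_length = edge_len, n_tip = n,
                 tip_label = paste0(tip_pop, "_", stats::ave(
                   seq_len(n), tip_pop, FUN = seq_along)),
                 tip_pop = tip_pop, node_time = node_time, tmrca = t),
            class = "genealogy")
}

#' Convert a genealogy to an ape phylo tree
#' @param gen A `genealogy`.
#' @return An object of class `phylo`.
#' @export
as_phylo <- function(gen) {
  tr <- list(edge = gen$edge[, c(1, 2)], edge.length = gen$edge_length,
             tip.label = gen$tip_label, Nnode = gen$n_tip - 1L)
  # ape expects internal nodes numbered n+1..2n-1 with root = n+1
  n <- gen$n_tip
  relab <- seq_len(2 * n - 1)
  internal <- (n + 1):(2 * n - 1)
  relab[internal] <- n + rank(-gen$node_time[internal])
  tr$edge <- matrix(relab[tr$edge], ncol = 2)
  storage.mode(tr$edge) <- "integer"
  class(tr) <- "phylo"
  tr
}

#' HKY+Gamma mutation model
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param base_freqs Equilibrium base frequencies (A, C, G, T), summing to 1.
#' @param gamma_shape Shape of the gamma distribution of site rates
#'   (mean 1); `Inf` means uniform rates.
#' @param L Sequence length in sites.
#' @param rate Mutation rate, substitutions per site per generation.
#' @return A `mutation_model` list including the normalised rate matrix `Q`.
#' @export
hky_model <- function(kappa = 2, base_freqs = rep(0.25, 4),
                      gamma_shape = Inf, L, rate) {
  stopifnot(kappa > 0, length(base_freqs) == 4, all(base_freqs > 0),
            abs(sum(base_freqs) - 1) < 1e-8, gamma_shape > 0,
            L >= 1, rate >= 0)
  Q <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T")))
  transitions <- rbind(c(1, 3), c(3, 1), c(2, 4), c(4, 2))  # A<->G, C<->T
  for (a in 1:4) for (b in 1:4) {
    if (a == b) next
    ts <- any(transitions[, 1] == a & transitions[, 2] == b)
    Q[a, b] <- base_freqs[b] * if (ts) kappa else 1
  }
  diag(Q) <- -rowSums(Q)
  scale <- -sum(base_freqs * diag(Q))  # expected substitutions per unit time
  Q <- Q / scale
  structure(list(kind = "HKY", kappa = kappa, base_freqs = base_freqs,
                 gamma_shape = gamma_shape, L = L, rate = rate, Q = Q),
            class = "mutation_model")
}

# Real eigendecomposition of the reversible Q via symmetrisation.
hky_eigen <- function(model) {
  pi_sqrt <- sqrt(model$base_freqs)
  B <- diag(pi_sqrt) %*% model$Q %*% diag(1 / pi_sqrt)
  es <- eigen((B + t(B)) / 2, symmetric = TRUE)
  V <- diag(1 / pi_sqrt) %*% es$vectors        # right eigenvectors of Q
  Vinv <- t(es$vectors) %*% diag(pi_sqrt)
  list(values = es$values, V = V, Vinv = Vinv, tVinv = t(Vinv))
}

# Transition-probability propagation of parent states along one branch for
# all sites at once, with per-site rate multipliers.
propagate_branch <- function(parent_states, t_branch, model, eg, site_rates) {
  L <- length(parent_states)
  child <- parent_states
  Ex <- exp(outer(eg$values, model$rate * t_branch * site_rates))  # 4 x L
  u <- stats::runif(L)
  for (a in 1:4) {
    sel <- which(parent_states == a)
    if (!length(sel)) next
    # stay probability P_aa(t r_s) = sum_i V[a,i] Vinv[i,a] Ex[i,s]
    w <- eg$V[a, ] * eg$Vinv[, a]
    p_stay <- colSums(w * Ex[, sel, drop = FALSE])
    hit <- sel[u[sel] > p_stay]
    if (!length(hit)) next
    # full transition vector only for the (few) sites that do change:
    # P[b, s] = sum_i V[a,i] Ex[i,s] Vinv[i,b], row a excluded
    P <- eg$tVinv %*% (eg$V[a, ] * Ex[, hit, drop = FALSE])
    P[P < 0] <- 0
    P[a, ] <- 0
    c1 <- P[1, ]; c2 <- c1 + P[2, ]; c3 <- c2 + P[3, ]
    uu <- stats::runif(length(hit)) * (c3 + P[4, ])
    child[hit] <- 1L + (uu > c1) + (uu > c2) + (uu > c3)
  }
  child
}

#' Evolve sequences along a genealogy under HKY+Gamma
#'
#' Draws the root sequence from the equilibrium base frequencies (unless
#' given), assigns each site an independent gamma rate multiplier (mean 1),
#' and propagates states down every branch with exact HKY transition
#' probabilities (matrix exponential via eigendecomposition).
#'
#' @param gen A `genealogy` from [simulate_genealogy()].
#' @param model A `mutation_model` from [hky_model()].
#' @param seed Optional RNG seed.
#' @param root_seq Optional integer vector (1--4) of root states.
#' @return A [labeled_alignment]; species is `"sim"`, population is the
#'   tip's deme label.
#' @export
evolve_sequences <- function(gen, model, seed = NULL, root_seq = NULL) {
  set_seed_if(seed)
  L <- model$L
  site_rates <- if (is.finite(model$gamma_shape)) {
    stats::rgamma(L, shape = model$gamma_shape, rate = model$gamma_shape)
  } else rep(1, L)
  eg <- hky_eigen(model)
  n <- gen$n_tip
  states <- matrix(NA_integer_, 2 * n - 1, L)
  root <- 2 * n - 1L
  states[root, ] <- if (is.null(root_seq)) {
    sample.int(4, L, replace = TRUE, prob = model$base_freqs)
  } else root_seq
  # edges were recorded child-after-parent going back in time: process in
  # reverse chronological order of the parent (root first)
  ord <- order(-gen$node_time[gen$edge[, 1]])
  for (e in ord) {
    p <- gen$edge[e, 1]; ch <- gen$edge[e, 2]
    if (gen$edge_length[e] == 0 || model$rate == 0) {
      states[ch, ] <- states[p, ]
    } else {
      states[ch, ] <- propagate_branch(states[p, ], gen$edge_length[e],
                                       model, eg, site_rates)
    }
  }
  seq_mat <- decode_states(states[seq_len(n), , drop = FALSE])
  rownames(seq_mat) <- gen$tip_label
  meta <- data.frame(id = gen$tip_label, species = "sim",
                     population = gen$tip_pop, locality = "")
  structure(list(seq = seq_mat, meta = meta), class = "labeled_alignment")
}

#' Simulate a dataset under a scenario
#'
#' Genealogy plus sequence evolution in one call; the result round-trips
#' through the rest of the package (collapsing, distances, summaries).
#'
#' @param scn A `demographic_scenario`.
#' @param model A `mutation_model`.
#' @param n1,n2,n3 Sample sizes.
#' @param seed Optional RNG seed (controls both stages).
#' @return List with `alignment` ([labeled_alignment]), `genealogy`,
#'   `scenario`, `model`, `seed`.
#' @export
simulate_dataset <- function(scn, model, n1, n2, n3 = 0L, seed = NULL) {
  set_seed_if(seed)
  gen <- simulate_genealogy(scn, n1, n2, n3)
  aln <- evolve_sequences(gen, model)
  list(alignment = aln, genealogy = gen, scenario = scn, model = model,
       seed = seed)
}

# Single-population size-change genealogy (recent size N_recent back to
# t_change, ancestral N_anc before). Used for star-like expansion samples.
sim_single_pop_genealogy <- function(n, N_recent, N_anc, t_change,
                                     seed = NULL) {
  scn <- structure(list(name = "custom", N1 = N_recent, N2 = 1, N3 = 1,
                        N2b = 1, N3b = 1, t1 = Inf, t2 = Inf, t_db = 0),
                   class = "demographic_scenario")
  set_seed_if(seed)
  # piecewise-constant single deme: run manually
  node <- seq_len(n)
  node_time <- numeric(2 * n - 1)
  edges <- matrix(0L, 2 * (n - 1), 2)
  edge_len <- numeric(2 * (n - 1))
  next_node <- n + 1L; e <- 0L; t <- 0
  while (length(node) > 1L) {
    k <- length(node)
    Nt <- if (t >= t_change) N_anc else N_recent
    dt <- stats::rexp(1, k * (k - 1) / 2 / Nt)
    if (t < t_change && t + dt >= t_change) { t <- t_change; next }
    t <- t + dt
    pair <- sample.int(k, 2L)
    parent <- next_node; next_node <- next_node + 1L
    node_time[parent] <- t
    for (ch in node[pair]) {
      e <- e + 1L
      edges[e, ] <- c(parent, ch)
      edge_len[e] <- t - node_time[ch]
    }
    node <- c(node[-pair], parent)
  }
  structure(list(edge = edges, edge_length = edge_len, n_tip = n,
                 tip_label = paste0("pop1_", seq_len(n)),
                 tip_pop = rep("pop1", n), node_time = node_time, tmrca = t),
            class = "genealogy")
}
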