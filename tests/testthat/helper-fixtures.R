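# Shared fixture builders; everything is generated in code.

make_meta <- function(ids, species = "A", population = "P1") {
  data.frame(id = ids, species = species, population = population,
             locality = "", stringsAsFactors = FALSE)
}

random_alignment <- function(n, L, seed, species = "A", population = "P1") {
  set.seed(seed)
  mat <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
  rownames(mat) <- sprintf("s%02d", seq_len(n))
  labeled_alignment(mat, make_meta(rownames(mat), species, population))
}

write_fixture_files <- function(aln, dir = tempfile("aln")) {
  dir.create(dir)
  fasta <- file.path(dir, "seqs.fasta")
  meta <- file.path(dir, "meta.tsv")
  write_alignment(aln, fasta, meta)
  list(fasta = fasta, meta = meta, dir = dir)
}

# Small, fast prior sets for ABC tests: three-population scenario with a
# high mutation rate so short sequences carry signal.
test_priors <- function(t1_range, t2_range) {
  list(N1 = prior_unif(1e3, 1e5, log = TRUE),
       N2 = prior_unif(1e3, 1e5, log = TRUE),
       N3 = prior_unif(1e3, 1e5, log = TRUE),
       N2b = prior_unif(10, 1e3, log = TRUE),
       N3b = prior_unif(10, 1e3, log = TRUE),
       t_db = prior_unif(100, 2000, log = TRUE),
       mu = prior_unif(2e-7, 2e-7),
       kappa = prior_unif(4, 4),
       gamma_shape = prior_unif(1.1, 1.1),
       t1 = prior_unif(t1_range[1], t1_range[2]),
       t2 = prior_unif(t2_range[1], t2_range[2]))
}

scenario_recent <- function() {
  abc_scenario("recent", test_priors(c(2e4, 6e4), c(3e3, 1.5e4)))
}

scenario_ancient <- function() {
  abc_scenario("ancient", test_priors(c(4e5, 1e6), c(1e5, 3e5)))
}

# Brute-force minimal Steiner spanning cost over the reduced state space:
# candidate extra nodes are all site-wise combinations of observed states;
# tries adding up to `max_extra` of them and returns the minimal MST cost.
brute_force_steiner_cost <- function(seq_mat, max_extra = 2) {
  states <- apply(seq_mat, 2, unique, simplify = FALSE)
  cands <- as.matrix(expand.grid(states, stringsAsFactors = FALSE))
  existing <- apply(seq_mat, 1, paste, collapse = "")
  cands <- cands[!apply(cands, 1, paste, collapse = "") %in% existing, ,
                 drop = FALSE]
  best <- barcodemog:::mst_cost(barcodemog:::hamming_rows(seq_mat))
  if (nrow(cands) == 0 || max_extra == 0) return(best)
  for (k in seq_len(min(max_extra, nrow(cands)))) {
    combs <- utils::combn(nrow(cands), k)
    for (ci in seq_len(ncol(combs))) {
      aug <- rbind(seq_mat, cands[combs[, ci], , drop = FALSE])
      cost <- barcodemog:::mst_cost(barcodemog:::hamming_rows(aug))
      if (cost < best) best <- cost
    }
  }
  best
}
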