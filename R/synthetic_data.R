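# Study-like synthetic datasets with known truth.
#
# The default template emulates the structure of a typical two-species
# barcode phylogeography data set: one species with three geographically
# structured populations (a Southeast-Asian-like source, an Arabian/South
# Asian-like daughter and an Australian-like daughter founded through a
# bottleneck in the Late Pleistocene), one widespread species with a
# star-like, recently expanded haplotype cloud, and a deep outgroup
# species at > 6% divergence. Intra-species divergences stay below ~2%,
# inter-species divergences above ~6%, alignment length 456 bp.

#' Template for a study-like synthetic dataset
#'
#' @param L Alignment length in sites (456 or 648 are the usual windows).
#' @param n_structured Sample sizes of the structured species' three
#'   populations (source, old daughter, bottlenecked daughter).
#' @param n_star Sample size of the star-like species.
#' @param n_outgroup Outgroup sample size.
#' @param scenario `demographic_scenario` for the structured species
#'   (default: recent-colonisation geometry with a strong founder
#'   bottleneck into the third population).
#' @param mu_site_year Mutation rate, substitutions/site/year (default the
#'   mid-Aegean COI rate 1.77e-8; one generation per year).
#' @param kappa,gamma_shape HKY+Gamma parameters (defaults 4 and 1.1,
#'   typical for mitochondrial barcodes).
#' @param t_species Species split depth in generations (default 2.3e6,
#'   giving inter-species p-distances of roughly 6-8%).
#' @param star_expansion Parameters of the star species' single-deme
#'   expansion: list with `N_recent`, `N_anc`, `t_change`.
#' @return A `study_template` list.
#' @export
study_template <- function(L = 456,
                           n_structured = c(20, 20, 15),
                           n_star = 39,
                           n_outgroup = 2,
                           scenario = make_scenario(
                             "2-CG", N1 = 3e5, N2 = 1e5, N3 = 1e6,
                             N2b = 500, N3b = 150,
                             t1 = 143000, t2 = 65000, t_db = 5000),
                           mu_site_year = 1.77e-8,
                           kappa = 4, gamma_shape = 1.1,
                           t_species = 2.3e6,
                           star_expansion = list(N_recent = 3e5,
                                                 N_anc = 2e3,
                                                 t_change = 196000)) {
  stopifnot(L >= 100, all(n_structured >= 2), n_star >= 2, n_outgroup >= 1)
  structure(list(L = L, n_structured = n_structured, n_star = n_star,
                 n_outgroup = n_outgroup, scenario = scenario,
                 mu_site_year = mu_site_year, kappa = kappa,
                 gamma_shape = gamma_shape, t_species = t_species,
                 star_expansion = star_expansion),
            class = "study_template")
}

#' Generate a study-like dataset with known truth
#'
#' Simulates the structured species through the three-population scenario,
#' the star-like species through a single-deme recent expansion, and the
#' outgroup from a common ancestral sequence at the species-split depth,
#' then assembles everything into one labelled alignment. The returned
#' `truth` record carries every generating parameter and seed so recovery
#' tests are self-describing.
#'
#' @param template A [study_template()].
#' @param seed RNG seed (the dataset is byte-identical under a fixed seed).
#' @return List with `alignment` (a [labeled_alignment]) and `truth`.
#' @export
generate_study_like <- function(template = study_template(), seed = 1) {
  tp <- template
  mu_gen <- tp$mu_site_year  # 1 generation per year
  model <- hky_model(kappa = tp$kappa, gamma_shape = tp$gamma_shape,
                     L = tp$L, rate = mu_gen)
  set.seed(derive_seed(seed, 1))
  ancestor <- sample.int(4, tp$L, replace = TRUE, prob = model$base_freqs)
  eg <- hky_eigen(model)
  site_rates <- if (is.finite(tp$gamma_shape)) {
    stats::rgamma(tp$L, tp$gamma_shape, tp$gamma_shape)
  } else rep(1, tp$L)
  species_root <- function(depth) {
    propagate_branch(ancestor, depth, model, eg, site_rates)
  }
  # structured species
  set.seed(derive_seed(seed, 2))
  root_a <- species_root(tp$t_species)
  gen_a <- simulate_genealogy(tp$scenario, tp$n_structured[1],
                              tp$n_structured[2], tp$n_structured[3])
  aln_a <- evolve_sequences(gen_a, model, root_seq = root_a)
  pop_map <- c(pop1 = "SEAsia", pop2 = "ArabiaSAsia", pop3 = "Australia")
  meta_a <- data.frame(
    id = paste0("str_", aln_a$meta$id),
    species = "species_structured",
    population = unname(pop_map[aln_a$meta$population]),
    locality = "")
  rownames(aln_a$seq) <- meta_a$id
  # star-like species
  set.seed(derive_seed(seed, 3))
  root_b <- species_root(tp$t_species)
  gen_b <- sim_single_pop_genealogy(tp$n_star,
                                    tp$star_expansion$N_recent,
                                    tp$star_expansion$N_anc,
                                    tp$star_expansion$t_change)
  aln_b <- evolve_sequences(gen_b, model, root_seq = root_b)
  meta_b <- data.frame(id = paste0("star_", seq_len(tp$n_star)),
                       species = "species_star", population = "Eurasia",
                       locality = "")
  rownames(aln_b$seq) <- meta_b$id
  # outgroup: deeper split
  set.seed(derive_seed(seed, 4))
  root_c <- species_root(2.2 * tp$t_species)
  if (tp$n_outgroup > 1) {
    gen_c <- sim_single_pop_genealogy(tp$n_outgroup, 5e4, 5e4, 1)
    aln_c_seq <- evolve_sequences(gen_c, model, root_seq = root_c)$seq
  } else {
    aln_c_seq <- decode_states(matrix(root_c, nrow = 1))
  }
  meta_c <- data.frame(id = paste0("out_", seq_len(tp$n_outgroup)),
                       species = "species_outgroup", population = "Outgroup",
                       locality = "")
  rownames(aln_c_seq) <- meta_c$id
  seq_all <- rbind(aln_a$seq, aln_b$seq, aln_c_seq)
  meta_all <- rbind(meta_a, meta_b, meta_c)
  aln <- structure(list(seq = seq_all, meta = meta_all),
                   class = "labeled_alignment")
  truth <- list(seed = seed, L = tp$L,
                scenario = unclass(tp$scenario),
                mu_site_year = tp$mu_site_year, kappa = tp$kappa,
                gamma_shape = tp$gamma_shape, t_species = tp$t_species,
                star_expansion = tp$star_expansion,
                n = c(structured = sum(tp$n_structured), star = tp$n_star,
                      outgroup = tp$n_outgroup))
  list(alignment = validate_labeled_alignment(aln), truth = truth)
}

#' Write a synthetic dataset to FASTA + TSV + truth JSON
#'
#' @param dataset Result of [generate_study_like()].
#' @param prefix Output path prefix; writes `<prefix>.fasta`,
#'   `<prefix>_metadata.tsv`, `<prefix>_truth.json`.
#' @return `dataset`, invisibly.
#' @export
write_study_like <- function(dataset, prefix) {
  write_alignment(dataset$alignment, paste0(prefix, ".fasta"),
                  paste0(prefix, "_metadata.tsv"))
  jsonlite::write_json(dataset$truth, paste0(prefix, "_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dataset)
}

#' Tiny hand-verifiable fixtures
#'
#' Deterministic toy alignments (at most 8 sequences x 30 sites) whose
#' diversity indexes, mismatch classes, Hamming distances and
#' median-joining networks can be verified by hand:
#' * `identical4`: four identical sequences (h = 0, pi = 0, S = 0);
#' * `two_haps`: two haplotypes, 3 differences, counts 2 + 2 (mismatch
#'   classes 0: 2 pairs, 3: 4 pairs);
#' * `triangle`: three haplotypes pairwise 2 apart whose quasi-median
#'   exists (the MJ network adds exactly one median vector);
#' * `two_species`: two tight clusters separated by ~30% divergence (a
#'   clean barcoding gap).
#'
#' @return Named list of [labeled_alignment] objects, with an attribute
#'   `expected` holding the hand-computed values.
#' @export
worked_toy <- function() {
  meta <- function(ids, sp = "A", pop = "P1") {
    data.frame(id = ids, species = sp, population = pop, locality = "")
  }
  base <- "AAAAAAAAAAAAAAAAAAAA"
  identical4 <- labeled_alignment(
    stats::setNames(rep(base, 4), paste0("s", 1:4)), meta(paste0("s", 1:4)))
  two <- c(rep("AAAAAAAAAAAAAAAAAAAA", 2), rep("TTTAAAAAAAAAAAAAAAAA", 2))
  two_haps <- labeled_alignment(stats::setNames(two, paste0("s", 1:4)),
                                meta(paste0("s", 1:4)))
  # each haplotype one step from the (unsampled) all-A median vector
  tri <- c(h1 = "TAAAAAAAAAAA",
           h2 = "ATAAAAAAAAAA",
           h3 = "AATAAAAAAAAA")
  triangle <- labeled_alignment(tri, meta(names(tri)))
  sp2 <- c(a1 = "AAAAAAAAAAAAAAAAAAAA", a2 = "AAAAAAAAAAAAAAAAAAAT",
           b1 = "TTTTTTAAAAAAAAAAAAAA", b2 = "TTTTTTAAAAAAAAAAAAAT")
  two_species <- labeled_alignment(
    sp2, data.frame(id = names(sp2), species = rep(c("A", "B"), each = 2),
                    population = rep(c("P1", "P2"), each = 2),
                    locality = ""))
  out <- list(identical4 = identical4, two_haps = two_haps,
              triangle = triangle, two_species = two_species)
  attr(out, "expected") <- list(
    identical4 = list(h = 0, pi = 0, S = 0),
    two_haps = list(h = 2 / 3, mismatch = c(`0` = 2, `3` = 4)),
    triangle = list(n_median = 1, total_cost = 3),
    two_species = list(max_intra = 0.05, min_inter = 0.30))
  out
}
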