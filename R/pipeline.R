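#' Run the full barcode-phylogeography pipeline
#'
#' Orchestrates every stage from one configuration: read (or synthesise)
#' the alignment, collapse haplotypes, compute distances and the barcoding
#' gap, build the median-joining network, produce per-population diversity
#' and neutrality summaries, fit mismatch expansions with time conversion,
#' and (optionally) run a desk-scale ABC analysis. All stage artifacts are
#' written under `config$outdir` in standard formats, plus a combined
#' `report.json` and `report.md`. A stage failure stops with a message
#' naming the stage; outputs of earlier stages are preserved on disk.
#'
#' @param config A list, or path to a YAML/JSON file, with elements:
#'   `fasta`/`metadata` (input paths) or `synthetic = TRUE` (use the
#'   default [study_template()]), `outdir`, `seed`, and optional stage
#'   blocks `trim` (list: `min_keep`), `distances` (list: `deletion`,
#'   `bin_width`, `n_boot`), `network` (list: `epsilon`), `popgen` (list:
#'   `n_sim`, `mismatch_model`, `n_boot`, `mu_site_year`,
#'   `generations_per_year`), `abc` (list: `enabled`, `n_sims`, `k`,
#'   `closest_fraction`, `n_pods`).
#' @return The report as a list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)  # YAML parser also accepts JSON
  }
  cfg <- config
  stopifnot(!is.null(cfg$outdir), !is.null(cfg$seed))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  report <- list(seed = seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  aln <- stage("input", {
    if (isTRUE(cfg$synthetic)) {
      ds <- generate_study_like(seed = seed)
      write_study_like(ds, file.path(cfg$outdir, "synthetic"))
      ds$alignment
    } else {
      read_alignment(cfg$fasta, cfg$metadata)
    }
  })
  if (!is.null(cfg$trim$min_keep)) {
    aln <- stage("trim", trim_to_common_length(aln, cfg$trim$min_keep))
  }
  report$input <- list(n_sequences = n_sequences(aln), n_sites = n_sites(aln),
                       species = as.list(table(aln$meta$species)))

  hs <- stage("collapse", collapse_haplotypes(aln))
  write_haplotype_table(hs, file.path(cfg$outdir, "haplotypes.tsv"))
  report$haplotypes <- list(n_haplotypes = n_haplotypes(hs))

  dist_cfg <- cfg$distances %||% list()
  gap <- stage("distances", {
    dm <- distance_matrix(aln, deletion = dist_cfg$deletion %||% "pairwise")
    write_distance_csv(dm, file.path(cfg$outdir, "distances.csv"))
    div <- group_divergence(aln, "species",
                            n_boot = dist_cfg$n_boot %||% 1000,
                            seed = derive_seed(seed, 11))
    utils::write.table(div, file.path(cfg$outdir, "group_divergence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    g <- barcoding_gap(dm, aln$meta$species,
                       bin_width = dist_cfg$bin_width %||% 0.005)
    jsonlite::write_json(
      list(max_intra = g$max_intra, min_inter = g$min_inter,
           gap_exists = g$gap_exists, threshold = g$threshold),
      file.path(cfg$outdir, "gap_report.json"), auto_unbox = TRUE,
      digits = NA)
    utils::write.table(g$histogram,
                       file.path(cfg$outdir, "gap_histogram.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    g
  })
  report$barcoding_gap <- list(max_intra = gap$max_intra,
                               min_inter = gap$min_inter,
                               gap_exists = gap$gap_exists,
                               threshold = gap$threshold)

  net <- stage("network", {
    nt <- build_mj(hs, epsilon = cfg$network$epsilon %||% 0L)
    write_network_gml(nt, file.path(cfg$outdir, "network.gml"))
    write_network_edges(nt, file.path(cfg$outdir, "network_edges.tsv"))
    nt
  })
  sp_of_hap <- vapply(hs$members, function(ids) {
    hs$meta$species[match(ids[1], hs$meta$id)]
  }, character(1))
  sep <- stage("network", group_separation(net, sp_of_hap))
  utils::write.table(sep, file.path(cfg$outdir, "group_separation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$network <- list(
    n_nodes = nrow(net$nodes), n_edges = nrow(net$edges),
    n_median_vectors = sum(net$nodes$kind == "median-vector"),
    separation = sep)

  pg_cfg <- cfg$popgen %||% list()
  popsum <- stage("popgen", population_summary(
    aln, n_sim = pg_cfg$n_sim %||% 1000, seed = derive_seed(seed, 21)))
  utils::write.csv(popsum, file.path(cfg$outdir, "population_summary.csv"),
                   row.names = FALSE)
  report$populations <- popsum

  mm <- stage("mismatch", {
    out <- NULL
    pops <- sort(unique(aln$meta$population))
    i <- 0L
    for (p in pops) {
      i <- i + 1L
      sub <- subset_alignment(aln, which(aln$meta$population == p))
      if (n_sequences(sub) < 10L) next
      obs <- mismatch_observed(sub)
      fit <- fit_expansion(obs, n_sequences(sub),
                           model = pg_cfg$mismatch_model %||% "spatial",
                           n_boot = pg_cfg$n_boot %||% 100,
                           seed = derive_seed(seed, 30 + i))
      et <- expansion_time(
        fit$tau,
        mu_site_year = pg_cfg$mu_site_year %||% 1.77e-8,
        L = n_sites(sub),
        generations_per_year = pg_cfg$generations_per_year %||% 1)
      utils::write.table(
        data.frame(class = seq_along(obs) - 1L, observed = obs,
                   expected = fit$expected * sum(obs)),
        file.path(cfg$outdir, paste0("mismatch_", p, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      out <- rbind(out, data.frame(
        sample = p, n = n_sequences(sub), tau = fit$tau, theta = fit$theta,
        M = fit$M, ssd = fit$ssd, p_ssd = fit$p_ssd,
        raggedness = fit$raggedness, p_raggedness = fit$p_raggedness,
        t_years = et$t_years))
    }
    out
  })
  if (!is.null(mm)) {
    utils::write.csv(mm, file.path(cfg$outdir, "expansion_times.csv"),
                     row.names = FALSE)
  }
  report$mismatch <- mm

  abc_cfg <- cfg$abc %||% list()
  if (isTRUE(abc_cfg$enabled)) {
    report$abc <- stage("abc", {
      run_abc_stage(aln, abc_cfg, seed, cfg$outdir)
    })
  }

  jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null")
  write_report_md(report, file.path(cfg$outdir, "report.md"))
  invisible(report)
}

# Desk-scale ABC over the default scenario pair, applied to the structured
# species' three populations.
run_abc_stage <- function(aln, abc_cfg, seed, outdir) {
  target_sp <- abc_cfg$species %||% names(which.max(table(aln$meta$species)))
  sub <- subset_alignment(aln, which(aln$meta$species == target_sp))
  pops <- sort(unique(sub$meta$population))
  if (length(pops) != 3L) {
    stop("ABC stage expects a species with exactly 3 populations, got ",
         length(pops))
  }
  # observed populations in (source, daughter-1, daughter-2) order so they
  # line up with simulated pop1..pop3
  pop_order <- abc_cfg$pop_order %||%
    (if (all(c("SEAsia", "ArabiaSAsia", "Australia") %in% pops)) {
      c("SEAsia", "ArabiaSAsia", "Australia")
    } else pops)
  sizes <- as.integer(table(factor(sub$meta$population,
                                   levels = pop_order)))
  scenarios <- default_scenarios(abc_cfg)
  ref <- build_reference(scenarios, n_sims = abc_cfg$n_sims %||% 2000,
                         sample_sizes = sizes, L = n_sites(sub),
                         seed = derive_seed(seed, 41))
  obs <- summary_stats(sub, populations = pop_order)
  names(obs) <- colnames(ref$stats)  # positional: pop_order -> pop1..pop3
  k <- abc_cfg$k %||% max(50L, round(0.02 * nrow(ref$stats)))
  direct <- scenario_posterior_direct(ref, obs, k = k)
  logistic <- scenario_posterior_logistic(
    ref, obs, closest_fraction = abc_cfg$closest_fraction %||% 0.05)
  chosen <- names(direct)[which.max(direct)]
  post <- estimate_parameters(
    ref, obs, chosen, closest_fraction = abc_cfg$closest_fraction %||% 0.05)
  utils::write.csv(cbind(scenario = as.character(ref$scenario), ref$params,
                         ref$stats),
                   file.path(outdir, "abc_reference.csv"), row.names = FALSE)
  utils::write.csv(post$summary, file.path(outdir, "abc_posterior.csv"),
                   row.names = FALSE)
  preeval <- prior_preevaluation(ref, obs)
  utils::write.csv(preeval, file.path(outdir, "abc_preevaluation.csv"),
                   row.names = FALSE)
  list(scenario_posterior_direct = as.list(direct),
       scenario_posterior_logistic = as.list(logistic),
       chosen_scenario = chosen,
       posterior = post$summary,
       n_flagged_preevaluation = sum(preeval$flagged))
}

# Two default scenario prior sets: recent-colonisation (2-CG-like, Late
# Pleistocene split into pop3) versus ancient-divergence (1-CG-like).
default_scenarios <- function(abc_cfg = list()) {
  base <- list(
    N1 = prior_unif(1e4, 1e6, log = TRUE),
    N2 = prior_unif(1e4, 1e6, log = TRUE),
    N3 = prior_unif(1e3, 5e5, log = TRUE),
    N2b = prior_unif(10, 1e4, log = TRUE),
    N3b = prior_unif(10, 1e4, log = TRUE),
    t_db = prior_unif(100, 10000, log = TRUE),
    mu = prior_unif(1e-8, 3e-8, log = TRUE),
    kappa = prior_unif(4, 4),
    gamma_shape = prior_unif(1.1, 1.1))
  recent <- abc_scenario("recent", c(base, list(
    t1 = prior_unif(129000, 774000), t2 = prior_unif(11700, 129000))))
  ancient <- abc_scenario("ancient", c(base, list(
    t1 = prior_unif(774000, 2500000), t2 = prior_unif(129000, 774000))))
  list(recent, ancient)
}

write_report_md <- function(report, path) {
  ln <- c("# Barcode phylogeography report", "",
          sprintf("- master seed: %d", report$seed),
          sprintf("- sequences: %d x %d sites", report$input$n_sequences,
                  report$input$n_sites),
          sprintf("- haplotypes: %d", report$haplotypes$n_haplotypes),
          sprintf("- barcoding gap: %s (max intra %.4f, min inter %.4f)",
                  ifelse(report$barcoding_gap$gap_exists, "yes", "no"),
                  report$barcoding_gap$max_intra,
                  report$barcoding_gap$min_inter),
          sprintf("- network: %d nodes (%d median vectors), %d edges",
                  report$network$n_nodes, report$network$n_median_vectors,
                  report$network$n_edges),
          "", "## Population summaries", "")
  if (!is.null(report$populations)) {
    ln <- c(ln, utils::capture.output(print(report$populations, digits = 4)))
  }
  if (!is.null(report$mismatch)) {
    ln <- c(ln, "", "## Mismatch / expansion fits", "",
            utils::capture.output(print(report$mismatch, digits = 4)))
  }
  if (!is.null(report$abc)) {
    ln <- c(ln, "", "## ABC", "",
            sprintf("- chosen scenario: %s", report$abc$chosen_scenario),
            sprintf("- direct posterior: %s",
                    paste(sprintf("%s=%.3f",
                                  names(report$abc$scenario_posterior_direct),
                                  unlist(report$abc$scenario_posterior_direct)),
                          collapse = ", ")))
  }
  writeLines(ln, path)
}
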