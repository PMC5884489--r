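#' Uncorrected p-distance between two sequences
#'
#' Proportion of differing sites among comparable sites. Sites where either
#' sequence carries `N` or a gap are excluded (pairwise deletion), matching
#' the usual default for barcode p-distances.
#'
#' @param a,b Equal-length sequence strings or character vectors.
#' @return List with `distance` (proportion) and `comparable_sites` (integer).
#' @export
p_distance <- function(a, b) {
  if (length(a) == 1L) a <- strsplit(toupper(a), "")[[1]]
  if (length(b) == 1L) b <- strsplit(toupper(b), "")[[1]]
  if (length(a) != length(b)) stop("sequences must have equal length")
  xa <- match(a, c("A", "C", "G", "T"))
  xb <- match(b, c("A", "C", "G", "T"))
  ok <- !is.na(xa) & !is.na(xb)
  n_comp <- sum(ok)
  if (n_comp == 0L) stop("no comparable sites; distance undefined")
  list(distance = sum(xa[ok] != xb[ok]) / n_comp, comparable_sites = n_comp)
}

#' All-pairs uncorrected p-distances for an alignment
#'
#' @param aln A [labeled_alignment] (or a `haplotype_set`).
#' @param deletion `"pairwise"` (default; sites with N/gap in either member of
#'   a pair are skipped for that pair) or `"complete"` (columns containing any
#'   N/gap are removed once for all pairs).
#' @return A `pdist` object: list with `ids`, `values` (symmetric proportion
#'   matrix, zero diagonal) and `comparable_sites` (symmetric integer matrix).
#' @export
distance_matrix <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  enc <- encode_alignment(aln$seq)
  if (deletion == "complete") {
    keep <- !apply(is.na(enc), 2, any)
    if (!any(keep)) stop("complete deletion removed every site")
    enc <- enc[, keep, drop = FALSE]
  }
  n <- nrow(enc)
  ids <- rownames(enc)
  vals <- matrix(0, n, n, dimnames = list(ids, ids))
  comp <- matrix(ncol(enc), n, n, dimnames = list(ids, ids))
  for (i in seq_len(max(n - 1L, 0L))) {
    xi <- enc[i, ]
    for (j in (i + 1L):n) {
      xj <- enc[j, ]
      ok <- !is.na(xi) & !is.na(xj)
      nc <- sum(ok)
      comp[i, j] <- comp[j, i] <- nc
      if (nc == 0L) {
        vals[i, j] <- vals[j, i] <- NA_real_
      } else {
        d <- sum(xi[ok] != xj[ok]) / nc
        vals[i, j] <- vals[j, i] <- d
      }
    }
  }
  structure(list(ids = ids, values = vals, comparable_sites = comp),
            class = "pdist")
}

#' @export
print.pdist <- function(x, ...) {
  cat(sprintf("<pdist> %d x %d uncorrected p-distances (mean %.4f)\n",
              length(x$ids), length(x$ids),
              mean(x$values[upper.tri(x$values)], na.rm = TRUE)))
  invisible(x)
}

#' Mean between-group divergences with bootstrap standard errors
#'
#' Mean uncorrected p-distance over all between-group sequence pairs, for
#' every pair of groups, with standard errors from resampling alignment
#' columns with replacement (the site-bootstrap convention of standard
#' distance software).
#'
#' @param aln A [labeled_alignment].
#' @param groups Character vector of group labels, one per sequence (defaults
#'   to the species column of the metadata), or the name of a metadata column.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Optional RNG seed.
#' @param deletion Missing-data handling as in [distance_matrix()].
#' @return Data frame with `group1`, `group2`, `mean_distance`, `bootstrap_SE`.
#' @export
group_divergence <- function(aln, groups = "species", n_boot = 1000,
                             seed = NULL, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  if (length(groups) == 1L && groups %in% names(aln$meta)) {
    groups <- aln$meta[[groups]]
  }
  stopifnot(length(groups) == n_sequences(aln))
  if (any(table(groups) < 1L)) stop("every group needs at least one member")
  set_seed_if(seed)
  enc <- encode_alignment(aln$seq)
  if (deletion == "complete") {
    keep <- !apply(is.na(enc), 2, any)
    enc <- enc[, keep, drop = FALSE]
  }
  L <- ncol(enc)
  glev <- sort(unique(groups))
  out <- NULL
  W <- matrix(0, L, n_boot)
  for (b in seq_len(n_boot)) {
    tb <- tabulate(sample.int(L, L, replace = TRUE), nbins = L)
    W[, b] <- tb
  }
  for (i in seq_along(glev)) {
    for (j in seq_along(glev)) {
      if (j <= i) next
      ii <- which(groups == glev[i]); jj <- which(groups == glev[j])
      pairs <- expand.grid(a = ii, b = jj)
      # per-pair site mismatch (M) and validity (V) indicators
      M <- matrix(0, nrow(pairs), L); V <- matrix(0, nrow(pairs), L)
      for (p in seq_len(nrow(pairs))) {
        xa <- enc[pairs$a[p], ]; xb <- enc[pairs$b[p], ]
        ok <- !is.na(xa) & !is.na(xb)
        V[p, ] <- ok
        M[p, ok] <- xa[ok] != xb[ok]
      }
      dist_obs <- mean(rowSums(M) / rowSums(V))
      MW <- M %*% W; VW <- V %*% W
      boot_means <- colMeans(MW / VW)
      out <- rbind(out, data.frame(
        group1 = glev[i], group2 = glev[j],
        mean_distance = dist_obs,
        bootstrap_SE = stats::sd(boot_means)))
    }
  }
  rownames(out) <- NULL
  out
}

#' Barcoding-gap analysis
#'
#' Partitions all pairwise distances into intra- and inter-specific sets,
#' reports the largest intraspecific and smallest interspecific distance,
#' whether an empty interval (barcoding gap) separates them, a midpoint
#' threshold when it does, and a binned histogram of both sets.
#'
#' @param dm A `pdist` from [distance_matrix()].
#' @param species Character vector of species labels aligned with `dm$ids`.
#' @param bin_width Histogram bin width as a proportion (default 0.005 = 0.5%).
#' @return A `gap_report`: list with `intra`, `inter` (data frames of pairs
#'   and distances), `max_intra`, `min_inter`, `gap_exists`, `threshold`
#'   (NA when no gap) and `histogram` (bin mid, intra count, inter count).
#' @export
barcoding_gap <- function(dm, species, bin_width = 0.005) {
  stopifnot(length(species) == length(dm$ids))
  if (length(unique(species)) < 2L) {
    warning("fewer than 2 species: interspecific set is empty")
  }
  singletons <- names(which(table(species) == 1L))
  if (length(singletons)) {
    warning("species with a single member contribute no intraspecific pairs: ",
            paste(singletons, collapse = ", "))
  }
  n <- length(dm$ids)
  rows <- NULL
  idx <- which(upper.tri(dm$values), arr.ind = TRUE)
  rows <- data.frame(id1 = dm$ids[idx[, 1]], id2 = dm$ids[idx[, 2]],
                     distance = dm$values[idx],
                     intra = species[idx[, 1]] == species[idx[, 2]])
  rows <- rows[!is.na(rows$distance), ]
  intra <- rows[rows$intra, c("id1", "id2", "distance")]
  inter <- rows[!rows$intra, c("id1", "id2", "distance")]
  max_intra <- if (nrow(intra)) max(intra$distance) else NA_real_
  min_inter <- if (nrow(inter)) min(inter$distance) else NA_real_
  gap_exists <- is.finite(max_intra) && is.finite(min_inter) &&
    min_inter > max_intra
  threshold <- if (isTRUE(gap_exists)) (max_intra + min_inter) / 2 else NA_real_
  top <- max(rows$distance, 0) + bin_width
  breaks <- seq(0, ceiling(top / bin_width) * bin_width, by = bin_width)
  hist_df <- data.frame(
    bin_low = breaks[-length(breaks)],
    bin_high = breaks[-1],
    intra = graphics::hist(intra$distance, breaks = breaks, plot = FALSE)$counts,
    inter = if (nrow(inter)) graphics::hist(inter$distance, breaks = breaks,
                                            plot = FALSE)$counts else 0L)
  structure(list(intra = intra, inter = inter, max_intra = max_intra,
                 min_inter = min_inter, gap_exists = gap_exists,
                 threshold = threshold, histogram = hist_df,
                 bin_width = bin_width),
            class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  cat("<gap_report>\n")
  cat(sprintf("  max intraspecific: %s\n",
              ifelse(is.na(x$max_intra), "NA", sprintf("%.4f", x$max_intra))))
  cat(sprintf("  min interspecific: %s\n",
              ifelse(is.na(x$min_inter), "NA", sprintf("%.4f", x$min_inter))))
  cat(sprintf("  barcoding gap: %s\n", ifelse(x$gap_exists, "yes", "no")))
  if (isTRUE(x$gap_exists)) {
    cat(sprintf("  threshold (midpoint): %.4f\n", x$threshold))
  }
  invisible(x)
}

#' Write a square distance matrix to CSV
#' @param dm A `pdist`.
#' @param path Output CSV path.
#' @return `dm`, invisibly.
#' @export
write_distance_csv <- function(dm, path) {
  utils::write.csv(as.data.frame(dm$values), path)
  invisible(dm)
}
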