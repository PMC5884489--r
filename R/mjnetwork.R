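#' Hamming distance matrix between haplotypes
#'
#' Counts of differing sites for every pair of haplotypes, with sites
#' carrying `N` or a gap in either member of a pair skipped (pairwise
#' deletion). Consistent with [p_distance()] times comparable sites.
#'
#' @param hs A `haplotype_set` (or any object with a `$seq` character matrix).
#' @return Symmetric integer matrix.
#' @export
hamming_matrix <- function(hs) {
  enc <- encode_alignment(hs$seq)
  n <- nrow(enc)
  d <- matrix(0L, n, n, dimnames = list(rownames(enc), rownames(enc)))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(enc[i, ]) & !is.na(enc[j, ])
      d[i, j] <- d[j, i] <- sum(enc[i, ok] != enc[j, ok])
    }
  }
  d
}

hamming_rows <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0L, n, n)
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- sum(mat[i, ] != mat[j, ])
    }
  }
  d
}

# Prim MST total weight over a full distance matrix.
mst_cost <- function(d) {
  n <- nrow(d)
  if (n < 2L) return(0)
  intree <- c(TRUE, rep(FALSE, n - 1))
  key <- d[1, ]
  total <- 0
  for (step in seq_len(n - 1L)) {
    v <- which(!intree)[which.min(key[!intree])]
    total <- total + key[v]
    intree[v] <- TRUE
    key <- pmin(key, d[v, ])
  }
  total
}

# Minimum-spanning network: union of all minimum spanning trees within
# tolerance epsilon. Edge (i,j) is kept iff d_ij <= w*(i,j) + epsilon where
# w* is the minimax connection weight (max edge on the MST path).
msn_edges <- function(d, epsilon = 0L) {
  n <- nrow(d)
  if (n < 2L) return(data.frame(from = integer(0), to = integer(0),
                                weight = integer(0)))
  # Prim MST with parent tracking
  parent <- rep(NA_integer_, n)
  intree <- c(TRUE, rep(FALSE, n - 1))
  key <- d[1, ]; from <- rep(1L, n)
  edges <- NULL
  for (step in seq_len(n - 1L)) {
    cand <- which(!intree)
    v <- cand[which.min(key[cand])]
    intree[v] <- TRUE
    edges <- rbind(edges, c(from[v], v, key[v]))
    upd <- !intree & d[v, ] < key
    key[upd] <- d[v, upd]; from[upd] <- v
  }
  # minimax weights via BFS over the MST per source (n small)
  adj <- vector("list", n)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]; w <- edges[e, 3]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  wstar <- matrix(0, n, n)
  for (s in seq_len(n)) {
    seen <- rep(FALSE, n); seen[s] <- TRUE
    queue <- list(c(s, 0))
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      v <- cur[1]; wmax <- cur[2]
      for (r in seq_len(NROW(adj[[v]]))) {
        nb <- adj[[v]][r, 1]; w <- adj[[v]][r, 2]
        if (!seen[nb]) {
          seen[nb] <- TRUE
          wstar[s, nb] <- max(wmax, w)
          queue <- c(queue, list(c(nb, max(wmax, w))))
        }
      }
    }
  }
  keep <- which(upper.tri(d) & d <= wstar + epsilon & d >= 1, arr.ind = TRUE)
  data.frame(from = keep[, 1], to = keep[, 2], weight = d[keep])
}

# Per-site majority consensus of three sequences; a site where all three
# states differ is resolved to the state of the first sequence (the triple
# is always passed ordered by node id, so the rule is deterministic).
quasi_median <- function(s1, s2, s3) {
  out <- s1
  agree23 <- s2 == s3
  out[agree23] <- s2[agree23]
  out
}

#' Build a median-joining haplotype network
#'
#' Implements the median-joining construction: (i) the minimum-spanning
#' network (union of all minimum spanning trees within tolerance `epsilon`)
#' over the current node set; (ii) iterative rounds that add every
#' quasi-median (per-site consensus) vector of a triple with at least one
#' linked pair that individually reduces the total spanning cost (Steiner
#' criterion),
#' followed by pruning of median vectors whose removal leaves the spanning
#' cost unchanged; candidates are processed in sorted order so the result
#' is deterministic. Character weights are uniform.
#'
#' @param hs A `haplotype_set` (sequences must be fully called; `N`/gap
#'   sites are tolerated in distances but not in median inference).
#' @param epsilon Non-negative integer tolerance of the minimum-spanning
#'   network (default 0, the usual default settings).
#' @param max_median Safety cap on added median vectors (default 64).
#' @return A `haplo_network`: list with `nodes` (data frame: `node_id`,
#'   `kind` = sampled/median-vector, `count`), `seq` (node sequence matrix),
#'   `edges` (`from`, `to`, `weight` in substitutions), `populations`
#'   (composition per sampled node), `epsilon`.
#' @export
build_mj <- function(hs, epsilon = 0L, max_median = 64L) {
  seqs <- hs$seq
  node_ids <- rownames(seqs)
  kind <- rep("sampled", nrow(seqs))
  n_mv <- 0L
  # Iteratively drop the median vector whose removal leaves the lowest
  # spanning cost, as long as that cost does not exceed the current one.
  # Evaluating all candidates before removing avoids discarding a needed
  # median while a useless one still inflates the reference cost.
  prune <- function(seqs, node_ids, kind) {
    repeat {
      cost <- mst_cost(hamming_rows(seqs))
      mvs <- which(kind == "median-vector")
      if (!length(mvs)) break
      without <- vapply(mvs, function(v) {
        mst_cost(hamming_rows(seqs[-v, , drop = FALSE]))
      }, numeric(1))
      if (min(without) > cost) break
      removable <- mvs[which.min(without)]
      seqs <- seqs[-removable, , drop = FALSE]
      node_ids <- node_ids[-removable]
      kind <- kind[-removable]
    }
    list(seqs = seqs, node_ids = node_ids, kind = kind)
  }
  repeat {
    d <- hamming_rows(seqs)
    cur_cost <- mst_cost(d)
    ed <- msn_edges(d, epsilon)
    # candidate medians: quasi-medians of triples in which at least one
    # pair is linked in the current network (edge u - v plus any third
    # node w)
    existing <- apply(seqs, 1, paste, collapse = "")
    cand <- list()
    for (e in seq_len(nrow(ed))) {
      u <- ed$from[e]; v <- ed$to[e]
      for (w in seq_len(nrow(seqs))) {
        if (w == u || w == v) next
        trip <- sort(c(u, v, w))  # ordered by node index
        m <- quasi_median(seqs[trip[1], ], seqs[trip[2], ], seqs[trip[3], ])
        key <- paste(m, collapse = "")
        if (key %in% existing || key %in% names(cand)) next
        if (mst_cost(hamming_rows(rbind(seqs, m))) < cur_cost) {
          cand[[key]] <- m
        }
      }
    }
    if (length(cand) == 0L || n_mv >= max_median) break
    for (key in sort(names(cand))) {  # sorted for determinism
      if (n_mv >= max_median) break
      n_mv <- n_mv + 1L
      mv_id <- sprintf("mv%02d", n_mv)
      seqs <- rbind(seqs, cand[[key]])
      rownames(seqs)[nrow(seqs)] <- mv_id
      node_ids <- c(node_ids, mv_id)
      kind <- c(kind, "median-vector")
    }
    pr <- prune(seqs, node_ids, kind)
    seqs <- pr$seqs; node_ids <- pr$node_ids; kind <- pr$kind
    # terminate if the round changed nothing (pruning undid every addition)
    if (setequal(apply(seqs, 1, paste, collapse = ""), existing) &&
        mst_cost(hamming_rows(seqs)) >= cur_cost) break
  }
  pr <- prune(seqs, node_ids, kind)
  seqs <- pr$seqs; node_ids <- pr$node_ids; kind <- pr$kind
  d <- hamming_rows(seqs)
  ed <- msn_edges(d, epsilon)
  edges <- data.frame(from = node_ids[ed$from], to = node_ids[ed$to],
                      weight = as.integer(ed$weight))
  counts <- ifelse(kind == "sampled", hs$count[node_ids], 0L)
  counts[is.na(counts)] <- 0L
  nodes <- data.frame(node_id = node_ids, kind = kind,
                      count = as.integer(counts))
  pops <- haplotype_groups(hs, "population")
  structure(list(nodes = nodes, seq = seqs, edges = edges,
                 populations = pops, epsilon = epsilon),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat(sprintf("<haplo_network> %d nodes (%d sampled, %d median), %d edges\n",
              nrow(x$nodes), sum(x$nodes$kind == "sampled"),
              sum(x$nodes$kind == "median-vector"), nrow(x$edges)))
  invisible(x)
}

haplo_network_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  igraph::E(g)$weight <- net$edges$weight
  g
}

#' Minimum substitution separation between labelled groups
#'
#' Shortest weighted path in the network between any two sampled nodes of
#' different groups (e.g. species), for every group pair. Disconnected
#' pairs yield `Inf` with a warning.
#'
#' @param net A `haplo_network` from [build_mj()].
#' @param labels Named character vector: group label per sampled node id.
#' @return Data frame with `group1`, `group2`, `min_path_weight`.
#' @export
group_separation <- function(net, labels) {
  sampled <- net$nodes$node_id[net$nodes$kind == "sampled"]
  labels <- labels[sampled]
  glev <- sort(unique(labels))
  if (length(glev) < 2L) {
    return(data.frame(group1 = character(0), group2 = character(0),
                      min_path_weight = numeric(0)))
  }
  g <- haplo_network_igraph(net)
  dmat <- igraph::distances(g, v = sampled, to = sampled)
  out <- NULL
  for (i in seq_len(length(glev) - 1L)) {
    for (j in (i + 1L):length(glev)) {
      sub <- dmat[labels == glev[i], labels == glev[j], drop = FALSE]
      w <- min(sub)
      if (!is.finite(w)) warning("groups ", glev[i], " and ", glev[j],
                                 " are disconnected in the network")
      out <- rbind(out, data.frame(group1 = glev[i], group2 = glev[j],
                                   min_path_weight = w))
    }
  }
  out
}

#' Export a haplotype network
#'
#' `write_network_gml()` writes GML with node kind and count attributes
#' (via igraph); `write_network_edges()` writes the edge list as TSV.
#'
#' @param net A `haplo_network`.
#' @param path Output path.
#' @return `net`, invisibly.
#' @export
write_network_gml <- function(net, path) {
  g <- haplo_network_igraph(net)
  igraph::write_graph(g, path, format = "gml")
  invisible(net)
}

#' @rdname write_network_gml
#' @export
write_network_edges <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(net)
}
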