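hapset_from_matrix <- function(mat) {
  rownames(mat) <- sprintf("H%03d", seq_len(nrow(mat)))
  aln <- labeled_alignment(mat, make_meta(rownames(mat)))
  collapse_haplotypes(aln)
}

test_that("hamming distances agree with p_distance times comparable sites", {
  aln <- random_alignment(6, 25, seed = 41)
  aln$seq[2, 5] <- "N"
  hs <- collapse_haplotypes(aln)
  hm <- hamming_matrix(hs)
  for (i in 1:5) for (j in (i + 1):6) {
    pd <- p_distance(paste(hs$seq[i, ], collapse = ""),
                     paste(hs$seq[j, ], collapse = ""))
    expect_equal(hm[i, j], round(pd$distance * pd$comparable_sites))
  }
  expect_true(all(diag(hm) == 0))
})

test_that("trivial networks: one node, one weighted edge", {
  one <- hapset_from_matrix(matrix(c("A", "C", "G"), 1))
  net1 <- build_mj(one)
  expect_equal(nrow(net1$nodes), 1)
  expect_equal(nrow(net1$edges), 0)
  two <- hapset_from_matrix(rbind(c("A", "A", "A", "A"),
                                  c("T", "T", "T", "A")))
  net2 <- build_mj(two)
  expect_equal(nrow(net2$edges), 1)
  expect_equal(net2$edges$weight, 3)
})

test_that("the equidistant triangle gains exactly one median vector", {
  toy <- worked_toy()$triangle
  net <- build_mj(collapse_haplotypes(toy))
  expect_equal(sum(net$nodes$kind == "median-vector"), 1)
  expect_equal(nrow(net$edges), 3)
  expect_true(all(net$edges$weight == 1))
  # the median is the all-A consensus
  mv <- net$seq[net$nodes$kind == "median-vector", ]
  expect_true(all(mv == "A"))
})

test_that("tree-like data with sampled intermediates yields the plain MST", {
  # a path H1 - H2 - H3 - H4, one step apart, every intermediate sampled
  mat <- rbind(rep("A", 8),
               c("T", rep("A", 7)),
               c("T", "T", rep("A", 6)),
               c("T", "T", "T", rep("A", 5)))
  net <- build_mj(hapset_from_matrix(mat))
  expect_equal(sum(net$nodes$kind == "median-vector"), 0)
  expect_equal(nrow(net$edges), 3)
  expect_true(all(net$edges$weight == 1))
})

test_that("network spanning cost equals brute-force Steiner search on small cases", {
  checked <- 0
  for (s in 1:15) {
    set.seed(s)
    nh <- sample(3:5, 1); L <- sample(6:10, 1)
    mat <- matrix(sample(c("A", "T"), nh * L, TRUE, prob = c(0.7, 0.3)),
                  nh, L)
    if (any(duplicated(apply(mat, 1, paste, collapse = "")))) next
    hs <- hapset_from_matrix(mat)
    net <- build_mj(hs)
    our_cost <- barcodemog:::mst_cost(barcodemog:::hamming_rows(net$seq))
    bf_cost <- brute_force_steiner_cost(mat, max_extra = 2)
    expect_equal(our_cost, bf_cost)
    # cost never increases through median addition
    expect_lte(our_cost,
               barcodemog:::mst_cost(barcodemog:::hamming_rows(hs$seq)))
    checked <- checked + 1
  }
  expect_gte(checked, 10)
})

test_that("networks are deterministic and connected", {
  d <- generate_study_like(seed = 8)
  hs <- collapse_haplotypes(d$alignment)
  n1 <- build_mj(hs)
  n2 <- build_mj(hs)
  expect_identical(n1$edges, n2$edges)
  g <- igraph::graph_from_data_frame(n1$edges, directed = FALSE,
                                     vertices = n1$nodes)
  expect_true(igraph::is_connected(g))
  # sampled node sequences match the input haplotypes
  sampled <- n1$nodes$node_id[n1$nodes$kind == "sampled"]
  expect_equal(n1$seq[sampled, ], hs$seq[sampled, ])
})

test_that("group separation reports shortest between-group path weights", {
  # two 2-node clusters joined by one weight-5 edge
  mat <- rbind(rep("A", 10),
               c("T", rep("A", 9)),
               c(rep("T", 6), rep("A", 4)),
               c(rep("T", 7), rep("A", 3)))
  hs <- hapset_from_matrix(mat)
  net <- build_mj(hs)
  labels <- stats::setNames(c("X", "X", "Y", "Y"), rownames(hs$seq))
  sep <- group_separation(net, labels)
  expect_equal(nrow(sep), 1)
  expect_equal(sep$min_path_weight, 5)
  # single group: empty table
  sep1 <- group_separation(net, stats::setNames(rep("X", 4),
                                                rownames(hs$seq)))
  expect_equal(nrow(sep1), 0)
})

test_that("species in a study-like network separate by many substitutions", {
  d <- generate_study_like(seed = 9)
  hs <- collapse_haplotypes(d$alignment)
  net <- build_mj(hs)
  sp <- vapply(hs$members, function(ids) {
    hs$meta$species[match(ids[1], hs$meta$id)]
  }, character(1))
  sep <- group_separation(net, sp)
  expect_true(all(sep$min_path_weight >= 20))
  # within the structured species haplogroups sit a few steps apart
  intra <- net$edges$weight[net$edges$weight < 20]
  expect_gt(length(intra), 0)
})

test_that("GML and edge-list exports are readable", {
  net <- build_mj(collapse_haplotypes(worked_toy()$triangle))
  gml <- tempfile(fileext = ".gml")
  tsv <- tempfile(fileext = ".tsv")
  write_network_gml(net, gml)
  write_network_edges(net, tsv)
  g <- igraph::read_graph(gml, format = "gml")
  expect_equal(igraph::gorder(g), 4)
  expect_equal(nrow(utils::read.delim(tsv)), 3)
})
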