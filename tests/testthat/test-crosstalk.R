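toy_stats <- function(genes, log2fc, r_gs = rep(0.5, length(genes))) {
  data.frame(gene_id = genes, de_p = 0.01, de_q = 0.01, log2fc = log2fc,
             r_gs = r_gs, r_p = 0.01, stringsAsFactors = FALSE)
}

toy_graph <- function(edges_from, edges_to, genes, log2fc, ppi_min = 0) {
  ppi <- make_ppi(edges_from, edges_to, rep(0.9, length(edges_from)))
  g <- merge_networks(ppi, stats = toy_stats(genes, log2fc), ppi_min = ppi_min)
  node_costs(g)
}

test_that("merging copies causal direction/sign onto shared PPI edges", {
  ppi <- make_ppi(c("A", "B"), c("B", "C"), c(0.8, 0.3))
  causal <- structure(list(
    nodes = c("A", "B", "D"),
    edges = data.frame(from = c("A", "D"), to = c("B", "B"),
                       strength = 1, sign = c("+", "-"), belief = c(0.9, 0.6),
                       stringsAsFactors = FALSE),
    score = 0, adjacency = NULL), class = "CausalNetwork")
  g <- merge_networks(ppi, causal = causal,
                      stats = toy_stats(c("A", "B", "C", "D"), c(1, 2, 0.5, 1)),
                      ppi_min = 0.4)
  ed <- igraph::as_data_frame(g, "edges")
  shared <- ed[(ed$from == "A" & ed$to == "B") | (ed$from == "B" & ed$to == "A"), ]
  expect_equal(nrow(shared), 1L)
  expect_equal(shared$sign, "+")
  expect_equal(shared$ppi_score, 0.8)      # PPI score kept for shared edges
  expect_false(shared$causal_only)
  # B-C fell below ppi_min
  expect_false(any((ed$from == "B" & ed$to == "C") | (ed$from == "C" & ed$to == "B")))
  # causal-only edge D->B added with ppi_score = belief, flagged
  co <- ed[(ed$from == "D" & ed$to == "B") | (ed$from == "B" & ed$to == "D"), ]
  expect_equal(nrow(co), 1L)
  expect_true(co$causal_only)
  expect_equal(co$ppi_score, 0.6)
})

test_that("merging requires overlap between graph and expression genes", {
  ppi <- make_ppi("A", "B", 0.9)
  expect_error(merge_networks(ppi, stats = toy_stats("Z", 1)), "no overlap")
})

test_that("node costs follow the -log min-max relevance map", {
  g <- toy_graph(c("A", "B", "C"), c("B", "C", "D"),
                 c("A", "B", "C"), c(0, 1, 2))  # D missing from expression
  v <- igraph::as_data_frame(g, "vertices")
  costs <- setNames(v$cost, v$name)
  expect_equal(unname(costs["C"]), 0)                       # max |fc| -> cost 0
  expect_equal(unname(costs["D"]), -log(1e-6))              # missing -> floor
  expect_true(costs["A"] > costs["B"] && costs["B"] > costs["C"])
  expect_true(v$missing_expr[v$name == "D"])
})

test_that("equal fold changes give all-zero costs with a warning", {
  ppi <- make_ppi(c("A", "B"), c("B", "C"), c(0.9, 0.9))
  g <- merge_networks(ppi, stats = toy_stats(c("A", "B", "C"), c(1, 1, 1)))
  expect_warning(g <- node_costs(g), "all fold changes equal")
  expect_equal(igraph::V(g)$cost, rep(0, 3))
})

test_that("adjacent seeds with costly alternatives take the direct path", {
  g <- toy_graph(c("A", "A", "C"), c("B", "C", "B"),
                 c("A", "B", "C"), c(2, 2, 0.1))
  p <- shortest_crosstalk_path(g, "A", "B")
  expect_equal(p[[1]]$nodes, c("A", "B"))
})

test_that("the diamond fixture picks the cheap interior exactly", {
  # A-B-D and A-C-D with costs A=1, B=5, C=1, D=1 -> A,C,D with cost 3
  ppi <- make_ppi(c("A", "B", "A", "C"), c("B", "D", "C", "D"), rep(0.9, 4))
  g <- merge_networks(ppi, stats = toy_stats(c("A", "B", "C", "D"), c(1, 5, 1, 1)))
  igraph::V(g)$cost <- c(A = 1, B = 5, C = 1, D = 1)[igraph::V(g)$name]
  p <- shortest_crosstalk_path(g, "A", "D")
  expect_equal(p[[1]]$nodes, c("A", "C", "D"))
  expect_equal(p[[1]]$total_cost, 3)
  expect_equal(p[[1]]$n_hops, 2L)
})

test_that("disconnected pairs return an empty result with status", {
  ppi <- make_ppi(c("A", "C"), c("B", "D"), c(0.9, 0.9))
  g <- node_costs(merge_networks(ppi, stats = toy_stats(c("A", "B", "C", "D"),
                                                        c(1, 2, 1, 2))))
  res <- shortest_crosstalk_path(g, "A", "D")
  expect_length(res, 0)
  expect_equal(attr(res, "status"), "disconnected")
  expect_error(shortest_crosstalk_path(g, "A", "ZZ"), "absent")
})

test_that("ties break by fewer hops then lexicographic sequence", {
  # two equal-cost routes A-B-D and A-C-D plus an equal-cost longer one
  ppi <- make_ppi(c("A", "B", "A", "C", "A"), c("B", "D", "C", "D", "D"),
                  rep(0.9, 5))
  g <- merge_networks(ppi, stats = toy_stats(c("A", "B", "C", "D"), c(1, 1, 1, 1)))
  suppressWarnings(g <- node_costs(g))   # all costs zero: everything ties
  p <- shortest_crosstalk_path(g, "A", "D")
  expect_equal(p[[1]]$nodes, c("A", "D"))  # fewest hops wins at equal cost
  # remove the direct edge: now 2-hop ties resolved lexicographically (B < C)
  ppi2 <- make_ppi(c("A", "B", "A", "C"), c("B", "D", "C", "D"), rep(0.9, 4))
  g2 <- merge_networks(ppi2, stats = toy_stats(c("A", "B", "C", "D"), c(1, 1, 1, 1)))
  suppressWarnings(g2 <- node_costs(g2))
  p2 <- shortest_crosstalk_path(g2, "A", "D")
  expect_equal(p2[[1]]$nodes, c("A", "B", "D"))
})

test_that("with equal node costs the optimum is a minimum-hop path", {
  set.seed(101)
  a <- sample(1:12, 30, TRUE)
  b <- sample(1:12, 30, TRUE)
  ok <- a != b
  ppi <- make_ppi(sprintf("N%02d", a[ok]), sprintf("N%02d", b[ok]),
                  rep(0.9, sum(ok)))
  genes <- sort(unique(c(ppi$protein1, ppi$protein2)))
  g <- merge_networks(ppi, stats = toy_stats(genes, rep(1, length(genes))))
  suppressWarnings(g <- node_costs(g))
  nm <- igraph::V(g)$name
  ig_dist <- igraph::distances(g, v = nm[1], to = nm[length(nm)])[1, 1]
  if (is.finite(ig_dist)) {
    p <- shortest_crosstalk_path(g, nm[1], nm[length(nm)])
    expect_equal(p[[1]]$n_hops, as.integer(ig_dist))
  }
})

test_that("random small graphs agree exactly with exhaustive enumeration", {
  for (s in 1:20) {
    set.seed(200 + s)
    nv <- sample(5:10, 1)
    nodes <- sprintf("N%02d", seq_len(nv))
    ne <- sample(nv:(2 * nv), 1)
    from <- sample(nodes, ne, TRUE); to <- sample(nodes, ne, TRUE)
    keep <- from != to
    from <- from[keep]; to <- to[keep]
    if (!length(from)) next
    cost <- setNames(round(runif(nv, 0, 3), 2), nodes)
    ppi <- make_ppi(from, to, rep(0.9, length(from)))
    g <- merge_networks(ppi, stats = toy_stats(nodes, rep(1, nv)))
    nm <- igraph::V(g)$name
    igraph::V(g)$cost <- cost[nm]
    s_t <- sample(nm, 2)
    oracle <- oracle_min_cost_path(ppi$protein1, ppi$protein2, nm, cost,
                                   s_t[1], s_t[2])
    res <- shortest_crosstalk_path(g, s_t[1], s_t[2])
    if (is.null(oracle)) {
      expect_length(res, 0)
    } else {
      expect_equal(res[[1]]$total_cost, oracle$cost, tolerance = 1e-12)
      expect_equal(res[[1]]$nodes, oracle$path)
    }
  }
})

test_that("removing a non-path edge leaves the optimum unchanged", {
  ppi <- make_ppi(c("A", "B", "A", "C", "B"), c("B", "D", "C", "D", "C"),
                  rep(0.9, 5))
  g <- merge_networks(ppi, stats = toy_stats(c("A", "B", "C", "D"),
                                             c(3, 2, 0.5, 3)))
  g <- node_costs(g)
  p <- shortest_crosstalk_path(g, "A", "D")[[1]]
  on_path <- paste(p$nodes[-length(p$nodes)], p$nodes[-1])
  ed <- igraph::as_data_frame(g, "edges")
  off <- which(!(paste(ed$from, ed$to) %in% on_path |
                 paste(ed$to, ed$from) %in% on_path))[1]
  g2 <- igraph::delete_edges(g, off)
  class(g2) <- class(g)
  p2 <- shortest_crosstalk_path(g2, "A", "D")[[1]]
  expect_equal(p2$total_cost, p$total_cost)
  expect_equal(p2$nodes, p$nodes)
})

test_that("k-shortest paths are loopless, ordered and distinct", {
  ppi <- make_ppi(c("A", "B", "A", "C", "A"), c("B", "D", "C", "D", "D"),
                  rep(0.9, 5))
  g <- merge_networks(ppi, stats = toy_stats(c("A", "B", "C", "D"),
                                             c(1, 0.6, 2, 1)))
  g <- node_costs(g)
  ps <- shortest_crosstalk_path(g, "A", "D", k = 3)
  expect_equal(length(ps), 3L)
  costs <- vapply(ps, `[[`, numeric(1), "total_cost")
  expect_true(all(diff(costs) >= -1e-12))
  keys <- vapply(ps, function(p) paste(p$nodes, collapse = ">"), character(1))
  expect_equal(anyDuplicated(keys), 0L)
  for (p in ps) expect_equal(anyDuplicated(p$nodes), 0L)
})

test_that("respecting causal direction blocks reverse-only traversal", {
  ppi <- make_ppi(c("A", "B"), c("B", "C"), c(0.9, 0.9))
  causal <- structure(list(
    nodes = c("A", "B", "C"),
    edges = data.frame(from = c("A", "B"), to = c("B", "C"),
                       strength = 1, sign = "+", belief = c(0.9, 0.8),
                       stringsAsFactors = FALSE),
    score = 0, adjacency = NULL), class = "CausalNetwork")
  g <- merge_networks(ppi, causal = causal,
                      stats = toy_stats(c("A", "B", "C"), c(1, 2, 3)))
  g <- node_costs(g)
  fwd <- shortest_crosstalk_path(g, "A", "C", respect_direction = TRUE)
  expect_equal(fwd[[1]]$nodes, c("A", "B", "C"))
  expect_equal(fwd[[1]]$path_belief, NA_real_)  # no causal net passed
  fwd2 <- shortest_crosstalk_path(g, "A", "C", respect_direction = TRUE,
                                  causal = causal)
  expect_equal(fwd2[[1]]$path_belief, 0.72)
  rev <- shortest_crosstalk_path(g, "C", "A", respect_direction = TRUE)
  expect_length(rev, 0)
})
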