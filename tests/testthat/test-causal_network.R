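test_that("a strong linear chain's skeleton is recovered", {
  f1 <- vapply(1:5, function(s) {
    sim <- simulate_linear_gaussian_dag(p = 3, n = 500, edge_prob = 1,
                                        coef_range = c(0.9, 0.9), seed = s)
    # keep only the chain part: regenerate as explicit chain
    set.seed(s)
    x <- rnorm(500); y <- 0.9 * x + rnorm(500); z <- 0.9 * y + rnorm(500)
    m <- rbind(A = x, B = y, C = z)
    colnames(m) <- sprintf("s%03d", 1:500)
    net <- suppressWarnings(learn_structure(m, restarts = 3, seed = s))
    skeleton_f1(data.frame(from = c("A", "B"), to = c("B", "C")), net)$f1
  }, numeric(1))
  expect_gte(median(f1), 1)
})

test_that("independent data yields almost no edges", {
  spurious <- vapply(1:7, function(s) {
    sim <- simulate_linear_gaussian_dag(p = 10, n = 500, edge_prob = 0, seed = s)
    net <- suppressWarnings(learn_structure(sim$expr, restarts = 3, seed = s))
    nrow(net$edges)
  }, numeric(1))
  expect_lte(median(spurious), 1)
})

test_that("learned graphs are acyclic with consistent local-model strengths", {
  sim <- simulate_linear_gaussian_dag(p = 8, n = 300, edge_prob = 0.3,
                                      random_signs = TRUE, seed = 13)
  net <- suppressWarnings(learn_structure(sim$expr, restarts = 5, seed = 13))
  g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                     vertices = data.frame(name = net$nodes))
  expect_true(igraph::is_dag(g))
  expect_true(all(is.finite(net$edges$strength)))
})

test_that("structure learning validates its inputs", {
  m <- matrix(rnorm(20), 2, 10, dimnames = list(c("A", "B"), sprintf("s%d", 1:10)))
  expect_error(learn_structure(m), ">= 3 nodes")
  m3 <- rbind(m, C = rnorm(10))
  m3[1, 1] <- NA
  expect_error(suppressWarnings(learn_structure(m3)), "non-finite")
  expect_error(learn_structure(rbind(m, C = rnorm(10)), genes = c("A", "ZZ")),
               "absent")
})

test_that("a deterministic relationship always recovers the adjacency", {
  set.seed(77)
  x <- rnorm(300); y <- 2 * x
  m <- rbind(X = x, Y = y, Z = rnorm(300))
  colnames(m) <- sprintf("s%03d", 1:300)
  net <- suppressWarnings(learn_structure(m, restarts = 3, seed = 7))
  net <- suppressWarnings(bootstrap_beliefs(m, net, B = 20, seed = 7))
  bm <- net$belief_matrix
  i <- match("X", net$nodes); j <- match("Y", net$nodes)
  expect_equal(bm[i, j] + bm[j, i], 1.0)
})

test_that("belief pruning and determinism hold", {
  cfg <- sim_config(n_per_stratum = rep(20L, 5), n_genes = 30,
                    n_trend_genes = 6, seed = 19)
  co <- simulate_cohort(cfg)
  genes <- rownames(co$expr)[1:6]
  net <- suppressWarnings(learn_structure(co$expr, genes = genes,
                                          restarts = 3, seed = 3))
  b1 <- suppressWarnings(bootstrap_beliefs(co$expr, net, B = 20, seed = 5))
  b2 <- suppressWarnings(bootstrap_beliefs(co$expr, net, B = 20, seed = 5))
  expect_identical(b1$edges, b2$edges)
  if (nrow(b1$edges)) expect_true(all(b1$edges$belief >= 0.3))
  expect_error(bootstrap_beliefs(co$expr, net, B = 10), ">= 20")
})

test_that("edge signs follow the partial-correlation oracle", {
  set.seed(91)
  n <- 500
  x1 <- rnorm(n); x2 <- rnorm(n)
  y_pos <- 0.8 * x1 + rnorm(n, 0, 0.6)
  y_neg <- -0.8 * x1 + rnorm(n, 0, 0.6)
  y_two <- x1 - x2 + rnorm(n, 0, 0.4)
  m <- rbind(X1 = x1, X2 = x2, YP = y_pos, YN = y_neg, YT = y_two)
  colnames(m) <- sprintf("s%03d", seq_len(n))
  # impose the known structure, then let sign_edges recover coefficients
  A <- matrix(FALSE, 5, 5, dimnames = list(rownames(m), rownames(m)))
  A["X1", "YP"] <- A["X1", "YN"] <- A["X1", "YT"] <- A["X2", "YT"] <- TRUE
  X <- scale(t(m))
  net <- xdeath:::network_from_adjacency(A, rownames(m), X, 0)
  net <- sign_edges(m, net)
  key <- paste(net$edges$from, net$edges$to)
  expect_equal(net$edges$sign[key == "X1 YP"], "+")
  expect_equal(net$edges$sign[key == "X1 YN"], "-")
  expect_equal(net$edges$sign[key == "X1 YT"], "+")
  expect_equal(net$edges$sign[key == "X2 YT"], "-")
  # oracle: sign of partial correlation via explicit covariance inversion
  S <- cov(t(m))
  P <- solve(S)
  expect_equal(net$edges$sign[key == "X1 YT"],
               if (-P["X1", "YT"] >= 0) "+" else "-")
})

test_that("path belief is the product of edge beliefs", {
  net <- structure(list(
    nodes = c("A", "B", "C"),
    edges = data.frame(from = c("A", "B"), to = c("B", "C"),
                       strength = 1, sign = "+", belief = c(0.9, 0.8),
                       stringsAsFactors = FALSE),
    score = 0, adjacency = NULL), class = "CausalNetwork")
  expect_equal(path_belief(net, c("A", "B", "C")), 0.72)
  expect_equal(path_belief(net, c("B", "C")), 0.8)
  expect_identical(path_belief(net, "A"), 1.0)
  expect_error(path_belief(net, c("A", "C")), "no edge A -> C")
  # monotone non-increasing in path length
  expect_lte(path_belief(net, c("A", "B", "C")), path_belief(net, c("A", "B")))
})
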