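ranked_fixture <- function(scores, genes = sprintf("g%02d", seq_along(scores))) {
  out <- data.frame(gene_id = genes, score = scores, stringsAsFactors = FALSE)
  class(out) <- c("RankedList", "data.frame")
  out
}

test_that("single hit at the top with unit weight gives ES 1", {
  rl <- ranked_fixture(c(5, 4, 3, 2, 1))
  es <- enrichment_score(rl, "g01", weight_exp = 0)
  expect_equal(es$es, 1)
})

test_that("the hand-enumerated running sum is reproduced exactly", {
  rl <- ranked_fixture(c(9, 7, 5, 3, 1))
  es <- enrichment_score(rl, c("g01", "g03"), weight_exp = 0)
  expect_equal(es$running, c(1/2, 1/6, 2/3, 1/3, 0), tolerance = 1e-15)
  expect_equal(es$es, 2/3, tolerance = 1e-15)
})

test_that("degenerate gene sets are skipped with a warning", {
  rl <- ranked_fixture(c(3, 2, 1))
  expect_warning(es <- enrichment_score(rl, c("nope")), "empty intersection")
  expect_true(is.na(es$es))
  expect_warning(es2 <- enrichment_score(rl, rl$gene_id), "whole universe")
  expect_true(is.na(es2$es))
})

test_that("with weight 0 the ES depends only on hit positions", {
  set.seed(41)
  sc <- sort(rnorm(30), decreasing = TRUE)
  rl1 <- ranked_fixture(sc)
  rl2 <- ranked_fixture(rank(sc))  # monotone transform, same order
  set <- rl1$gene_id[c(2, 9, 20)]
  expect_equal(enrichment_score(rl1, set, 0)$es,
               enrichment_score(rl2, set, 0)$es, tolerance = 1e-15)
})

test_that("random sets have mean ES near zero", {
  set.seed(43)
  rl <- ranked_fixture(sort(rnorm(60), decreasing = TRUE))
  es <- vapply(1:1000, function(i) {
    enrichment_score(rl, sample(rl$gene_id, 6), weight_exp = 1)$es
  }, numeric(1))
  expect_lt(abs(mean(es)), 3 * sd(es) / sqrt(length(es)) + 0.02)
})

test_that("rank_genes orders by signal-to-noise with lexicographic ties", {
  set.seed(47)
  codes <- rep(0:4, each = 5)
  ann <- make_annotation(sprintf("s%02d", seq_along(codes)),
                         ifelse(codes == 0, "normal", "tumor"),
                         ifelse(codes == 0, NA, codes + 5))
  x <- matrix(rnorm(125), 5, 25,
              dimnames = list(c("B", "A", "E", "C", "D"), ann$sample_id))
  x["B", codes == 4] <- x["B", codes == 4] + 5  # clearly up in GS>=9
  rl <- rank_genes(x, ann, "GS>=9")
  expect_equal(rl$gene_id[1], "B")
  expect_gt(rl$score[1], 0)
  # constant matrix: all scores equal -> lexicographic order
  xc <- matrix(1, 3, 25, dimnames = list(c("Z", "Y", "X"), ann$sample_id))
  rlc <- rank_genes(xc, ann, "GS>=9")
  expect_equal(rlc$gene_id, c("X", "Y", "Z"))
})

test_that("rank_genes validates stratum size", {
  codes <- c(0, 0, 0, 1, 1, 4, 4)
  ann <- make_annotation(sprintf("s%d", 1:7),
                         ifelse(codes == 0, "normal", "tumor"),
                         ifelse(codes == 0, NA, codes + 5))
  x <- matrix(rnorm(21), 3, 7,
              dimnames = list(c("A", "B", "C"), ann$sample_id))
  expect_error(rank_genes(x, ann, "GS6"), ">= 3 samples")
  expect_error(rank_genes(x, ann, "GS7"), "absent")
})

test_that("permutation p-values match exhaustive enumeration on a tiny case", {
  rl <- ranked_fixture(c(3, 2.5, 2, 1.5, 1, 0.5))
  set <- c("g01", "g03")
  es_obs <- enrichment_score(rl, set, 1)$es
  combs <- combn(rl$gene_id, 2)
  null_es <- apply(combs, 2, function(s) enrichment_score(rl, s, 1)$es)
  same <- null_es[sign(null_es) == sign(es_obs)]
  p_exact <- sum(abs(same) >= abs(es_obs)) / length(same)
  res <- normalize_and_test(rl, list(PW = set), n_perm = 2000, seed = 99)
  # binomial 99% CI around the exact enumeration value
  half <- 2.576 * sqrt(p_exact * (1 - p_exact) / 2000)
  expect_lt(abs(res$nominal_p - p_exact), half + 1e-9)
  expect_equal(sign(res$NES), sign(res$ES))
})

test_that("normalize_and_test is deterministic given its seed", {
  rl <- ranked_fixture(sort(rnorm(40), decreasing = TRUE))
  sets <- list(A = rl$gene_id[c(1, 5, 9)], B = rl$gene_id[c(30, 35, 40)])
  r1 <- normalize_and_test(rl, sets, n_perm = 200, seed = 7)
  r2 <- normalize_and_test(rl, sets, n_perm = 200, seed = 7)
  expect_identical(r1, r2)
  expect_error(normalize_and_test(rl, sets, n_perm = 50), "n_perm")
})

test_that("progression correlation handles perfect, reversed and flat trajectories", {
  res <- data.frame(
    pathway_id = rep(c("P1", "P2", "P3"), each = 4),
    mode = "apoptosis",
    stratum = rep(c("GS6", "GS7", "GS8", "GS>=9"), 3),
    NES = c(0.5, 1.0, 1.5, 2.0,  2.0, 1.5, 1.0, 0.5,  1, 1, 1, 1),
    rank = c(3, 2, 2, 1,  1, 1, 2, 3,  2, 3, 1, 2),
    stringsAsFactors = FALSE
  )
  pc <- progression_correlation(res)
  expect_equal(pc$progression_r[pc$pathway_id == "P1"], 1, tolerance = 1e-12)
  expect_equal(pc$progression_r[pc$pathway_id == "P2"], -1, tolerance = 1e-12)
  expect_true(pc$flagged[pc$pathway_id == "P3"])
})

test_that("pathways of planted trend genes out-correlate decoys end to end", {
  cfg <- sim_config(n_per_stratum = rep(25L, 5), n_genes = 100,
                    n_trend_genes = 15, seed = 53)
  co <- simulate_cohort(cfg)
  nets <- simulate_networks(cfg, co)
  enr <- run_enrichment(co$expr, co$annotation, nets$pathway_db,
                        n_perm = 200, seed = 53)
  pc <- progression_correlation(enr)
  prog <- pc$mode %in% c("apoptosis", "autophagy")
  expect_gt(median(abs(pc$progression_r[prog]), na.rm = TRUE),
            median(abs(pc$progression_r[!prog]), na.rm = TRUE))
})
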