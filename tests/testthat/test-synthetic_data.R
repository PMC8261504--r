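test_that("simulation is bit-identical under a fixed seed", {
  cfg <- sim_config(n_per_stratum = rep(10L, 5), n_genes = 40, n_trend_genes = 8,
                    seed = 5)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$expr, b$expr)
  expect_identical(a$truth$trend_genes, b$truth$trend_genes)
  na <- simulate_networks(cfg, a)
  nb <- simulate_networks(cfg, b)
  expect_identical(na$ppi, nb$ppi)
  expect_identical(na$meth, nb$meth)
})

test_that("trend calibration puts realized Spearman |r| near the target", {
  rs <- unlist(lapply(1:8, function(s) {
    cfg <- sim_config(n_per_stratum = rep(60L, 5), n_genes = 60,
                      n_trend_genes = 12, trend_strength = 0.7, seed = s)
    co <- simulate_cohort(cfg)
    codes <- co$annotation$stratum_code
    vapply(co$truth$trend_genes$gene, function(g) {
      abs(cor(rank(co$expr[g, ]), rank(codes)))
    }, numeric(1))
  }))
  expect_lt(abs(mean(rs) - 0.7), 0.1)
})

test_that("realized trend strength is monotone in the target", {
  means <- vapply(c(0.3, 0.5, 0.8), function(ts) {
    mean(unlist(lapply(1:5, function(s) {
      cfg <- sim_config(n_per_stratum = rep(40L, 5), n_genes = 40,
                        n_trend_genes = 8, trend_strength = ts, seed = s)
      co <- simulate_cohort(cfg)
      codes <- co$annotation$stratum_code
      vapply(co$truth$trend_genes$gene, function(g) {
        abs(cor(rank(co$expr[g, ]), rank(codes)))
      }, numeric(1))
    })))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("null genes show no trend and a nominal false-positive rate", {
  stats <- lapply(1:10, function(s) {
    cfg <- sim_config(n_per_stratum = rep(30L, 5), n_genes = 60,
                      n_trend_genes = 4, seed = s)
    co <- simulate_cohort(cfg)
    nulls <- setdiff(rownames(co$expr),
                     c(co$truth$trend_genes$gene,
                       unique(c(co$truth$chain_edges$from, co$truth$chain_edges$to))))
    gc <- grade_correlation(co$expr[nulls, ], co$annotation)
    list(absr = abs(gc$r_gs), sig = gc$r_p < 0.05)
  })
  expect_lt(mean(unlist(lapply(stats, `[[`, "absr"))), 0.15)
  frac_sig <- mean(unlist(lapply(stats, `[[`, "sig")))
  expect_lt(abs(frac_sig - 0.05), 0.04)
})

test_that("PPI always contains the chain with high confidence", {
  cfg <- sim_config(n_per_stratum = rep(10L, 5), n_genes = 50,
                    n_trend_genes = 8, seed = 3)
  co <- simulate_cohort(cfg)
  nets <- simulate_networks(cfg, co)
  ce <- co$truth$chain_edges
  key <- paste(nets$ppi$protein1, nets$ppi$protein2)
  for (k in seq_len(nrow(ce))) {
    i <- match(paste(pmin(ce$from[k], ce$to[k]), pmax(ce$from[k], ce$to[k])), key)
    expect_false(is.na(i))
    expect_gte(nets$ppi$score[i], 0.7)
  }
})

test_that("zero decoy probability leaves exactly the chain edges", {
  cfg <- sim_config(n_per_stratum = rep(10L, 5), n_genes = 30,
                    n_trend_genes = 5, decoy_edge_prob = 0, seed = 2)
  co <- simulate_cohort(cfg)
  nets <- simulate_networks(cfg, co)
  expect_equal(nrow(nets$ppi), nrow(co$truth$chain_edges))
})

test_that("methylation is anti-correlated with expression for the planted subset", {
  cfg <- sim_config(n_per_stratum = rep(60L, 5), n_genes = 80,
                    n_trend_genes = 12, seed = 4)
  co <- simulate_cohort(cfg)
  nets <- simulate_networks(cfg, co)
  rs <- vapply(nets$anti_correlated_genes, function(g) {
    cor(rank(nets$meth[g, ]), rank(co$expr[g, ]))
  }, numeric(1))
  expect_gte(mean(rs < -0.5), 0.9)
})

test_that("infeasible trend strength is rejected", {
  expect_error(sim_config(trend_strength = 1), "trend_strength")
  expect_error(sim_config(trend_strength = 0), "trend_strength")
  expect_error(sim_config(block_rho = 1), "block_rho")
  expect_error(sim_config(chain = list(genes = c("G0001", "NOPE"),
                                       signs = 1, coefs = 0.9)),
               "universe")
})

test_that("simulate_to_dir emits files the readers accept, consistently", {
  cfg <- sim_config(n_per_stratum = rep(8L, 5), n_genes = 30,
                    n_trend_genes = 5, seed = 6)
  d <- file.path(tempdir(), "simdir_test")
  sim <- simulate_to_dir(cfg, d)
  m <- read_expression(file.path(d, "expression.tsv"))
  expect_equal(dim(m), dim(sim$cohort$expr))
  expect_equal(m, sim$cohort$expr, tolerance = 1e-10)
  ann <- read_annotation(file.path(d, "annotation.tsv"))
  expect_equal(ann$stratum_code, sim$cohort$annotation$stratum_code)
  db <- read_gene_sets(file.path(d, "pathways.gmt"), file.path(d, "mode_map.tsv"))
  expect_equal(length(db$sets), length(sim$networks$pathway_db$sets))
  ppi <- read_ppi(file.path(d, "ppi.tsv"))
  expect_equal(nrow(ppi), nrow(sim$networks$ppi))
})
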