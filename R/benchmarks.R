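# Self-contained recovery benchmarks with planted ground truth. These are
# the package's reference validation scenarios: they are exercised by the
# test suite and recomputed by the acceptance script.

#' Simulate data from a random linear-Gaussian DAG
#'
#' Draws a random DAG (uniform topological order, each order-respecting edge
#' present with probability `edge_prob`), assigns edge coefficients uniform
#' in `coef_range` (random sign if `random_signs`), and generates samples by
#' ancestral sampling with unit-variance residuals.
#'
#' @param p Number of nodes (default 10).
#' @param n Number of samples (default 500).
#' @param edge_prob Probability of each order-respecting edge (default 0.2;
#'   0 gives independent data, the null benchmark).
#' @param coef_range Range of |edge coefficient| (default 0.6-0.9).
#' @param random_signs Randomize coefficient signs (default FALSE).
#' @param seed RNG seed.
#' @return list with `expr` (genes x samples matrix, node names `N01`...)
#'   and `edges` (data.frame `from`, `to`, `coef`).
#' @export
simulate_linear_gaussian_dag <- function(p = 10L, n = 500L, edge_prob = 0.2,
                                         coef_range = c(0.6, 0.9),
                                         random_signs = FALSE, seed = 1L) {
  with_seed(seed, {
    nodes <- sprintf("N%02d", seq_len(p))
    ord <- sample.int(p)
    A <- matrix(0, p, p, dimnames = list(nodes, nodes))
    for (k in seq_len(p)[-1]) {
      anc <- ord[seq_len(k - 1)]
      pick <- anc[stats::runif(k - 1) < edge_prob]
      if (length(pick)) {
        cf <- stats::runif(length(pick), coef_range[[1]], coef_range[[2]])
        if (random_signs) cf <- cf * sample(c(-1, 1), length(pick), replace = TRUE)
        A[pick, ord[[k]]] <- cf
      }
    }
    X <- matrix(0, n, p, dimnames = list(NULL, nodes))
    for (k in seq_len(p)) {
      j <- ord[[k]]
      parents <- which(A[, j] != 0)
      mu <- if (length(parents)) X[, parents, drop = FALSE] %*% A[parents, j] else 0
      X[, j] <- mu + stats::rnorm(n)
    }
    idx <- which(A != 0, arr.ind = TRUE)
    edges <- data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
                        coef = A[idx], stringsAsFactors = FALSE)
    list(expr = t(X), edges = edges)
  })
}

#' Skeleton F1 of a learned network against true edges
#'
#' Compares undirected adjacencies (the skeleton): F1 = 2PR/(P+R) with
#' precision P and recall R over unordered node pairs. An empty learned
#' network against a nonempty truth scores 0.
#'
#' @param true_edges data.frame with `from`, `to`.
#' @param network A `CausalNetwork` (or data.frame with `from`, `to`).
#' @return list with `f1`, `precision`, `recall`, `n_learned`, `n_true`.
#' @export
skeleton_f1 <- function(true_edges, network) {
  le <- if (inherits(network, "CausalNetwork")) network$edges else network
  tk <- unique(paste(pmin(true_edges$from, true_edges$to),
                     pmax(true_edges$from, true_edges$to)))
  lk <- unique(paste(pmin(le$from, le$to), pmax(le$from, le$to)))
  tp <- length(intersect(tk, lk))
  prec <- if (length(lk)) tp / length(lk) else 0
  rec <- if (length(tk)) tp / length(tk) else 1
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(f1 = f1, precision = prec, recall = rec,
       n_learned = length(lk), n_true = length(tk))
}

#' Reference configuration for the planted co-target benchmark
#'
#' The end-to-end recovery scenario: a four-gene all-positive regulatory
#' chain (coefficients 0.9) between two upregulated seeds, chain source at
#' trend strength 0.75, background trend genes at 70% of that strength (the
#' seeds are the cohort's strongest progression genes, the situation the
#' ranking is meant to detect), 60 samples per stratum, 200 genes, 30%
#' negative-direction background trend genes.
#'
#' @param seed RNG seed for the scenario.
#' @return A [sim_config()] object.
#' @export
cotarget_benchmark_config <- function(seed = 1L) {
  sim_config(trend_strength = 0.75, background_trend_frac = 0.7,
             frac_negative = 0.3, seed = seed)
}

#' Run the planted co-target recovery benchmark
#'
#' Simulates the reference scenario, writes it to disk in the pipeline's
#' input formats, runs the full pipeline (the two planted seeds plus a
#' random subset of background trend genes form the druggable-target list),
#' and reports whether the planted pair and chain were recovered.
#'
#' @param seed Scenario and pipeline seed.
#' @param out_dir Working directory for pipeline outputs (default: a
#'   session temporary directory).
#' @param n_perm Enrichment permutations (default 100; the enrichment stage
#'   is part of the run but not of the recovery metric).
#' @param enrich Run the enrichment stage (default TRUE).
#' @return list with `pair_rank`, `n_pairs`, `chain_recovered` (logical:
#'   optimal path equals the planted chain), `optimal_path`, `path_cost`,
#'   `pairs` (the ranked table) and the run `manifest`.
#' @export
cotarget_benchmark <- function(seed = 1L, out_dir = NULL, n_perm = 100L,
                               enrich = TRUE) {
  if (is.null(out_dir)) {
    out_dir <- file.path(tempdir(), paste0("xdeath_bench_", seed))
  }
  config <- cotarget_benchmark_config(seed)
  sim <- simulate_to_dir(config, file.path(out_dir, "sim"))
  truth <- sim$cohort$truth
  up_background <- with_seed(derive_seed(seed, 9L), {
    bg <- truth$trend_genes$gene[truth$trend_genes$direction > 0]
    bg <- setdiff(bg, truth$pair)
    sample(bg, min(6L, length(bg)))
  })
  druggable_path <- file.path(out_dir, "druggable.txt")
  writeLines(c(truth$pair, up_background), druggable_path)
  cfg <- run_config(list(
    inputs = list(expr = file.path(out_dir, "sim", "expression.tsv"),
                  annotation = file.path(out_dir, "sim", "annotation.tsv"),
                  gmt = file.path(out_dir, "sim", "pathways.gmt"),
                  mode_map = file.path(out_dir, "sim", "mode_map.tsv"),
                  ppi = file.path(out_dir, "sim", "ppi.tsv"),
                  druggable = druggable_path),
    out_dir = file.path(out_dir, "run"),
    seed = seed,
    seeds = as.character(truth$pair),
    hallmark = list(r_min = 0.3),
    enrich = list(enabled = enrich, n_perm = n_perm),
    bn = list(bootstrap_B = 25L, restarts = 3L, max_genes = 15L)
  ))
  manifest <- run_pipeline(cfg)
  res <- manifest$results
  pr <- res$pairs
  tp <- sort(truth$pair)
  hit <- which(pr$gene_a == tp[[1]] & pr$gene_b == tp[[2]])
  chain_nodes <- c(truth$chain_edges$from[[1]], truth$chain_edges$to)
  opt <- if (length(res$paths)) res$paths[[1]]$nodes else character(0)
  list(
    pair_rank = if (length(hit)) pr$rank[[hit]] else NA_integer_,
    n_pairs = nrow(pr),
    chain_recovered = identical(opt, chain_nodes) ||
      identical(opt, rev(chain_nodes)),
    optimal_path = opt,
    path_cost = if (length(res$paths)) res$paths[[1]]$total_cost else NA_real_,
    pairs = pr,
    manifest = manifest
  )
}
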