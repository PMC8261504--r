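# Independent oracles used to check the package's implementations.
# Deliberately written in a different style from the implementation
# (explicit loops, direct formulas) so agreement is informative.

# Brute-force weighted-KS running sum: walk the list position by position.
oracle_es <- function(scores, is_hit, weight_exp) {
  n <- length(scores)
  n_hit <- sum(is_hit)
  stopifnot(n_hit > 0, n_hit < n)
  denom_hit <- 0
  for (i in seq_len(n)) if (is_hit[i]) denom_hit <- denom_hit + abs(scores[i])^weight_exp
  run <- numeric(n)
  acc <- 0
  for (i in seq_len(n)) {
    if (is_hit[i]) {
      acc <- acc + abs(scores[i])^weight_exp / denom_hit
    } else {
      acc <- acc - 1 / (n - n_hit)
    }
    run[i] <- acc
  }
  # earliest position whose |deviation| reaches the maximum (ties within
  # float noise resolve to the earliest position, as in the implementation)
  peak <- 0
  for (i in seq_len(n)) if (abs(run[i]) > peak) peak <- abs(run[i])
  best <- NA_real_
  for (i in seq_len(n)) {
    if (abs(run[i]) >= peak - 1e-12) { best <- run[i]; break }
  }
  list(es = best, running = run)
}

# Exhaustive node-weighted shortest path by enumerating all simple paths.
oracle_min_cost_path <- function(edge_from, edge_to, nodes, cost, s, t) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = edge_from, to = edge_to), directed = FALSE,
    vertices = data.frame(name = nodes))
  ps <- igraph::all_simple_paths(g, from = s, to = t)
  if (!length(ps)) return(NULL)
  best_cost <- Inf; best_path <- NULL
  for (p in ps) {
    nm <- igraph::V(g)$name[as.integer(p)]
    cst <- sum(cost[nm])
    if (cst < best_cost - 1e-12 ||
        (abs(cst - best_cost) <= 1e-12 &&
         (length(nm) < length(best_path) ||
          (length(nm) == length(best_path) &&
           paste(nm, collapse = "\r") < paste(best_path, collapse = "\r"))))) {
      best_cost <- cst; best_path <- nm
    }
  }
  list(cost = best_cost, path = best_path)
}

# Spearman via the classical rank formulas: 1 - 6*sum(d^2)/(n(n^2-1)) when
# rank vectors are permutations (no ties); with ties, the explicit
# sum-of-products formula on midranks.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  if (!any(duplicated(rx)) && !any(duplicated(ry))) {
    d <- rx - ry
    return(1 - 6 * sum(d^2) / (n * (n^2 - 1)))
  }
  num <- n * sum(rx * ry) - sum(rx) * sum(ry)
  den <- sqrt(n * sum(rx^2) - sum(rx)^2) * sqrt(n * sum(ry^2) - sum(ry)^2)
  num / den
}

# Random grade-stratified annotation + iid Gaussian matrix for null tests.
null_cohort <- function(n_genes, n_per_stratum, seed) {
  set.seed(seed)
  codes <- rep(0:4, times = n_per_stratum)
  ids <- sprintf("S%03d", seq_along(codes))
  ann <- make_annotation(ids, ifelse(codes == 0, "normal", "tumor"),
                         ifelse(codes == 0, NA, codes + 5))
  m <- matrix(rnorm(n_genes * length(codes)), nrow = n_genes,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)), ids))
  list(expr = m, annotation = ann)
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
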