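# Seeded Spearman co-expression network construction around target genes.

#' Build a seeded Spearman co-expression network
#'
#' Computes Spearman correlation (p by the t-approximation) between each
#' seed gene and every other gene, keeping pairs with `|r| > r_min` and
#' `p < p_max`. In `neighborhood_clique` scope, pairs among the retained
#' neighborhood members are additionally tested, which is the input form
#' the Bayesian-network stage expects.
#'
#' @inheritParams differential_expression
#' @param seeds Character vector of seed gene ids (must be in the matrix).
#' @param r_min Minimum |Spearman r| (default 0.5).
#' @param p_max Maximum p-value (default 0.05).
#' @param scope `"seed_edges_only"` (default) or `"neighborhood_clique"`.
#' @return A `CoexpressionNetwork`: list with `seeds`, `edges`
#'   (data.frame `gene_a`, `gene_b`, `r`, `p`; `gene_a < gene_b`),
#'   `neighborhoods` (named list per seed) and `skipped` (constant genes).
#' @export
build_coexpression <- function(expr, seeds, r_min = 0.5, p_max = 0.05,
                               scope = c("seed_edges_only", "neighborhood_clique")) {
  scope <- match.arg(scope)
  assert_expr_matrix(expr)
  seeds <- toupper(seeds)
  absent <- setdiff(seeds, rownames(expr))
  if (length(absent)) {
    xd_validation_error("seed gene(s) absent from matrix: ",
                        paste(absent, collapse = ", "))
  }
  if (ncol(expr) < 10) xd_validation_error("co-expression needs >= 10 samples")
  n <- ncol(expr)
  sds <- apply(expr, 1, stats::sd)
  skipped <- rownames(expr)[sds == 0]
  ok <- rownames(expr)[sds > 0]
  rk <- t(apply(expr[ok, , drop = FALSE], 1, rank))
  rk <- rk - rowMeans(rk)
  rss <- sqrt(rowSums(rk^2))

  pair_cor <- function(a, bs) {
    # Spearman r of gene a against each gene in bs, via centered ranks
    r <- as.numeric(rk[bs, , drop = FALSE] %*% rk[a, ]) / (rss[bs] * rss[a])
    r
  }
  edges <- list()
  neighborhoods <- list()
  for (s in seeds) {
    if (!s %in% ok) { neighborhoods[[s]] <- character(0); next }
    others <- setdiff(ok, s)
    r <- pair_cor(s, others)
    p <- cor_t_pvalue(r, n)
    keep <- abs(r) > r_min & p < p_max
    neighborhoods[[s]] <- others[keep]
    if (any(keep)) {
      edges[[s]] <- data.frame(gene_a = pmin(s, others[keep]),
                               gene_b = pmax(s, others[keep]),
                               r = r[keep], p = p[keep],
                               stringsAsFactors = FALSE)
    }
  }
  if (scope == "neighborhood_clique") {
    members <- setdiff(unique(unlist(neighborhoods)), seeds)
    if (length(members) > 1) {
      cmb <- utils::combn(sort(members), 2)
      ra <- vapply(seq_len(ncol(cmb)), function(i) {
        as.numeric(rk[cmb[1, i], ] %*% rk[cmb[2, i], ]) /
          (rss[cmb[1, i]] * rss[cmb[2, i]])
      }, numeric(1))
      pa <- cor_t_pvalue(ra, n)
      keep <- abs(ra) > r_min & pa < p_max
      if (any(keep)) {
        edges[["clique"]] <- data.frame(gene_a = cmb[1, keep], gene_b = cmb[2, keep],
                                        r = ra[keep], p = pa[keep],
                                        stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) {
    e <- do.call(rbind, edges)
    e <- e[!duplicated(paste(e$gene_a, e$gene_b)), , drop = FALSE]
    e <- e[order(e$gene_a, e$gene_b), , drop = FALSE]
    rownames(e) <- NULL
    e
  } else {
    data.frame(gene_a = character(0), gene_b = character(0),
               r = numeric(0), p = numeric(0), stringsAsFactors = FALSE)
  }
  structure(list(seeds = seeds, edges = edges, neighborhoods = neighborhoods,
                 skipped = skipped, r_min = r_min, p_max = p_max),
            class = "CoexpressionNetwork")
}

#' @export
print.CoexpressionNetwork <- function(x, ...) {
  cat("CoexpressionNetwork:", length(x$seeds), "seed(s),",
      nrow(x$edges), "edges (|r| >", x$r_min, ", p <", x$p_max, ")\n")
  invisible(x)
}
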