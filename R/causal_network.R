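# Signed directed gene-regulation network with bootstrap edge beliefs.
#
# Structure learning is greedy hill-climbing over DAGs scored by BIC under a
# linear-Gaussian model on z-scored expression, with seeded random restarts.
# Edge beliefs are nonparametric bootstrap recovery fractions; edge signs
# come from the partial correlation of parent and child given the child's
# other parents.

# ---- scoring ---------------------------------------------------------------

# Solve on a covariance submatrix; a tiny ridge handles the exactly
# collinear case (e.g. duplicated signals) deterministically.
solve_cov <- function(A, b) {
  tryCatch(solve(A, b), error = function(e) {
    solve(A + diag(1e-9, nrow(A)), b)
  })
}

# Local BIC (to be maximized) of child given parents, from the covariance of
# z-scored data. Constant terms are kept so the total score is comparable
# across structures.
local_bic <- function(S, n, child, parents) {
  sigma2 <- if (length(parents)) {
    S[child, child] - drop(S[child, parents, drop = FALSE] %*%
                             solve_cov(S[parents, parents, drop = FALSE],
                                       S[parents, child, drop = FALSE]))
  } else S[child, child]
  sigma2 <- max(sigma2, 1e-12)
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
  ll - 0.5 * log(n) * (length(parents) + 2)
}

make_score_fn <- function(S, n) {
  cache <- new.env(parent = emptyenv(), hash = TRUE)
  function(child, parents) {
    key <- paste0(child, "|", paste(sort(parents), collapse = ","))
    v <- cache[[key]]
    if (is.null(v)) {
      v <- local_bic(S, n, child, parents)
      cache[[key]] <- v
    }
    v
  }
}

# TRUE if `to` is reachable from `from` in adjacency matrix A (A[i,j]: i->j)
reachable <- function(A, from, to) {
  if (from == to) return(TRUE)
  seen <- logical(nrow(A))
  stack <- from
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (seen[[v]]) next
    seen[[v]] <- TRUE
    nxt <- which(A[v, ])
    if (to %in% nxt) return(TRUE)
    stack <- c(stack, nxt[!seen[nxt]])
  }
  FALSE
}

hill_climb <- function(A0, score, max_parents) {
  A <- A0
  p <- nrow(A)
  loc <- vapply(seq_len(p), function(j) score(j, which(A[, j])), numeric(1))
  repeat {
    best_delta <- 1e-9
    best <- NULL
    for (i in seq_len(p)) for (j in seq_len(p)) {
      if (i == j) next
      if (A[i, j]) {
        # delete i -> j
        d <- score(j, setdiff(which(A[, j]), i)) - loc[[j]]
        if (d > best_delta) { best_delta <- d; best <- c(1L, i, j) }
        # reverse i -> j (must stay acyclic and respect parent cap)
        if (sum(A[, i]) < max_parents) {
          A[i, j] <- FALSE
          cyc <- reachable(A, i, j)
          A[i, j] <- TRUE
          if (!cyc) {
            d <- (score(j, setdiff(which(A[, j]), i)) - loc[[j]]) +
              (score(i, c(which(A[, i]), j)) - loc[[i]])
            if (d > best_delta) { best_delta <- d; best <- c(3L, i, j) }
          }
        }
      } else if (!A[j, i] && sum(A[, j]) < max_parents) {
        # add i -> j: cycle iff j already reaches i
        if (!reachable(A, j, i)) {
          d <- score(j, c(which(A[, j]), i)) - loc[[j]]
          if (d > best_delta) { best_delta <- d; best <- c(2L, i, j) }
        }
      }
    }
    if (is.null(best)) break
    i <- best[[2]]; j <- best[[3]]
    if (best[[1]] == 1L) {
      A[i, j] <- FALSE
    } else if (best[[1]] == 2L) {
      A[i, j] <- TRUE
    } else {
      A[i, j] <- FALSE; A[j, i] <- TRUE
      loc[[i]] <- score(i, which(A[, i]))
    }
    loc[[j]] <- score(j, which(A[, j]))
  }
  list(A = A, score = sum(loc))
}

random_dag <- function(p, max_parents, prob = 0.15) {
  ord <- sample.int(p)
  A <- matrix(FALSE, p, p)
  for (k in 2:p) {
    anc <- ord[seq_len(k - 1)]
    pick <- anc[stats::runif(length(anc)) < prob]
    if (length(pick) > max_parents) pick <- pick[seq_len(max_parents)]
    A[pick, ord[[k]]] <- TRUE
  }
  A
}

fit_structure <- function(X, max_parents, restarts) {
  # X: samples x genes, z-scored columns
  n <- nrow(X); p <- ncol(X)
  S <- crossprod(X) / n
  score <- make_score_fn(S, n)
  best <- hill_climb(matrix(FALSE, p, p), score, max_parents)
  if (restarts > 1) {
    for (r in seq_len(restarts - 1)) {
      fit <- hill_climb(random_dag(p, max_parents), score, max_parents)
      if (fit$score > best$score + 1e-9) best <- fit
    }
  }
  best
}

# ---- public API ------------------------------------------------------------

#' Learn a gene-regulation network structure
#'
#' Greedy hill-climbing over directed acyclic graphs scored by BIC under a
#' linear-Gaussian model on per-gene z-scored expression, with seeded random
#' restarts. Edge strength is the standardized regression coefficient of the
#' parent in the child's local model.
#'
#' @param expr Expression matrix, genes x samples.
#' @param genes Optional subset of genes to restrict to (default: all rows).
#' @param max_parents Maximum number of parents per node (default 3).
#' @param restarts Number of hill-climbing starts (1 empty + restarts-1
#'   random; default 10).
#' @param seed RNG seed; the fit is deterministic given the seed.
#' @return A `CausalNetwork`: list with `nodes`, `edges` (data.frame `from`,
#'   `to`, `strength`, `sign`, `belief`), `score` and the internal adjacency.
#' @export
learn_structure <- function(expr, genes = NULL, max_parents = 3L,
                            restarts = 10L, seed = 1L) {
  if (!is.null(genes)) {
    genes <- toupper(genes)
    absent <- setdiff(genes, rownames(expr))
    if (length(absent)) {
      xd_validation_error("genes absent from matrix: ", paste(absent, collapse = ", "))
    }
    expr <- expr[genes, , drop = FALSE]
  }
  if (nrow(expr) < 3) xd_validation_error("structure learning needs >= 3 nodes")
  if (!all(is.finite(expr))) xd_validation_error("non-finite expression values")
  if (ncol(expr) < 5 * nrow(expr)) {
    warning("fewer than 5x more samples than nodes; structure estimates may be unstable",
            call. = FALSE)
  }
  X <- scale(t(expr))
  if (any(!is.finite(X))) xd_validation_error("constant gene among structure-learning nodes")
  fit <- with_seed(seed, fit_structure(X, max_parents, restarts))
  network_from_adjacency(fit$A, colnames(X), X, fit$score)
}

network_from_adjacency <- function(A, nodes, X, score) {
  n <- nrow(X)
  S <- crossprod(X) / n
  idx <- which(A, arr.ind = TRUE)
  edges <- data.frame(from = character(0), to = character(0),
                      strength = numeric(0), sign = character(0),
                      belief = numeric(0), stringsAsFactors = FALSE)
  if (nrow(idx)) {
    rows <- lapply(unique(idx[, 2]), function(j) {
      parents <- which(A[, j])
      coefs <- solve_cov(S[parents, parents, drop = FALSE], S[parents, j])
      data.frame(from = nodes[parents], to = nodes[[j]],
                 strength = as.numeric(coefs),
                 sign = NA_character_, belief = NA_real_,
                 stringsAsFactors = FALSE)
    })
    edges <- do.call(rbind, rows)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges, score = score, adjacency = A),
            class = "CausalNetwork")
}

#' @export
print.CausalNetwork <- function(x, ...) {
  cat("CausalNetwork:", length(x$nodes), "nodes,", nrow(x$edges),
      "directed edges, BIC score", format(x$score, digits = 6), "\n")
  invisible(x)
}

#' Bootstrap edge beliefs
#'
#' Refits the structure on nonparametric bootstrap resamples of the samples;
#' the belief of an edge is the (direction-sensitive) fraction of resampled
#' fits that contain it. Edges with belief below `belief_min` are pruned.
#'
#' @inheritParams learn_structure
#' @param network A `CausalNetwork` from [learn_structure()].
#' @param B Number of bootstrap resamples (>= 20; default 100).
#' @param belief_min Pruning threshold on belief (default 0.3).
#' @param restarts Hill-climb restarts per bootstrap refit (default 2; the
#'   consensus over resamples compensates for the shallower search).
#' @return The network with `belief` filled in and low-belief edges pruned.
#' @export
bootstrap_beliefs <- function(expr, network, B = 100L, seed = 1L,
                              belief_min = 0.3, restarts = 2L) {
  stopifnot(inherits(network, "CausalNetwork"))
  if (B < 20) xd_validation_error("B must be >= 20")
  expr <- expr[network$nodes, , drop = FALSE]
  X <- scale(t(expr))
  counts <- matrix(0, length(network$nodes), length(network$nodes))
  max_parents <- max(3L, max(colSums(network$adjacency)))
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(nrow(X), replace = TRUE)
      Xb <- scale(X[idx, , drop = FALSE])
      if (any(!is.finite(Xb))) next
      fit <- fit_structure(Xb, max_parents, restarts)
      counts <- counts + fit$A
    }
  })
  beliefs <- counts / B
  if (nrow(network$edges)) {
    ii <- match(network$edges$from, network$nodes)
    jj <- match(network$edges$to, network$nodes)
    network$edges$belief <- beliefs[cbind(ii, jj)]
    keep <- network$edges$belief >= belief_min
    pruned <- network$edges[!keep, , drop = FALSE]
    network$edges <- network$edges[keep, , drop = FALSE]
    rownames(network$edges) <- NULL
    A <- network$adjacency
    if (nrow(pruned)) {
      A[cbind(match(pruned$from, network$nodes),
              match(pruned$to, network$nodes))] <- FALSE
    }
    network$adjacency <- A
  }
  network$belief_matrix <- beliefs
  network
}

#' Sign causal edges
#'
#' Each edge's sign is the sign of the partial correlation of parent and
#' child given the child's other parents (equivalently the sign of the
#' parent's coefficient in the child's local regression). A numerically zero
#' partial correlation falls back to the marginal correlation and is flagged.
#'
#' @inheritParams bootstrap_beliefs
#' @return The network with `sign` (`"+"`/`"-"`) and `sign_flagged` columns.
#' @export
sign_edges <- function(expr, network) {
  stopifnot(inherits(network, "CausalNetwork"))
  if (!nrow(network$edges)) return(network)
  X <- scale(t(expr[network$nodes, , drop = FALSE]))
  S <- crossprod(X) / nrow(X)
  A <- network$adjacency
  sgn <- character(nrow(network$edges))
  flag <- logical(nrow(network$edges))
  for (k in seq_len(nrow(network$edges))) {
    i <- match(network$edges$from[[k]], network$nodes)
    j <- match(network$edges$to[[k]], network$nodes)
    parents <- which(A[, j])
    coefs <- solve_cov(S[parents, parents, drop = FALSE], S[parents, j])
    b <- coefs[[match(i, parents)]]
    if (abs(b) < 1e-10) {
      b <- S[i, j]
      flag[[k]] <- TRUE
    }
    sgn[[k]] <- if (b >= 0) "+" else "-"
  }
  network$edges$sign <- sgn
  network$edges$sign_flagged <- flag
  network
}

#' Belief of a causal path
#'
#' Product of per-edge bootstrap beliefs along an ordered node list (the
#' path-level confidence obtained by multiplying per-edge conditional
#' confidences). An empty or single-node path has belief 1 by convention.
#'
#' @param network A `CausalNetwork` with beliefs.
#' @param path Ordered character vector of node ids.
#' @return A single numeric belief in \[0,1\].
#' @export
path_belief <- function(network, path) {
  stopifnot(inherits(network, "CausalNetwork"))
  if (length(path) < 2) return(1.0)
  key <- paste(network$edges$from, network$edges$to)
  b <- 1.0
  for (k in seq_len(length(path) - 1L)) {
    hit <- match(paste(path[[k]], path[[k + 1L]]), key)
    if (is.na(hit)) {
      xd_validation_error("no edge ", path[[k]], " -> ", path[[k + 1L]],
                          " in the network")
    }
    b <- b * network$edges$belief[[hit]]
  }
  b
}

causal_to_igraph <- function(network) {
  g <- igraph::add_vertices(igraph::make_empty_graph(directed = TRUE),
                            length(network$nodes), name = network$nodes)
  if (nrow(network$edges)) {
    g <- igraph::add_edges(g, rbind(match(network$edges$from, network$nodes),
                                    match(network$edges$to, network$nodes)))
    igraph::E(g)$strength <- network$edges$strength
    igraph::E(g)$sign <- network$edges$sign %||% NA_character_
    igraph::E(g)$belief <- network$edges$belief %||% NA_real_
  }
  g
}
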