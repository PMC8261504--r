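# Merged causal/PPI crosstalk graph and minimum-vertex-weight path search.
#
# Node relevance is the min-max normalized |log2 fold change| mapped to
# (delta, 1]; traversal cost is -log(relevance), so strongly
# progression-linked nodes are cheap to pass through and the minimum-cost
# path is the maximum-relevance crosstalk route (XTALK-style semantics).

#' Merge the PPI, causal and co-expression networks
#'
#' Builds an undirected-by-default igraph whose nodes are the PPI nodes
#' (plus causal-only nodes) annotated with expression statistics. PPI edges
#' below `ppi_min` are dropped. Causal edges carry direction, sign and
#' belief; causal edges absent from the PPI are added with
#' `ppi_score = belief` and flagged `causal_only`. Co-expression r is copied
#' onto edges where the pair was tested and retained.
#'
#' @param ppi A `ppi_network` from [read_ppi()]/[make_ppi()].
#' @param causal Optional `CausalNetwork` (signed, with beliefs).
#' @param coexpr Optional `CoexpressionNetwork`.
#' @param stats Gene statistics from [compute_gene_stats()].
#' @param ppi_min Minimum PPI confidence kept (default 0.4).
#' @return An igraph of class `CrosstalkGraph` with node attributes
#'   `fold_change`, `r_gs` and edge attributes `ppi_score`, `r`, `sign`,
#'   `belief`, `direction` (`"forward"` for causal from->to, `""` otherwise),
#'   `causal_only`.
#' @export
merge_networks <- function(ppi, causal = NULL, coexpr = NULL, stats = NULL,
                           ppi_min = 0.4) {
  stopifnot(inherits(ppi, "ppi_network"))
  keep <- ppi$score >= ppi_min
  edges <- data.frame(from = ppi$protein1[keep], to = ppi$protein2[keep],
                      ppi_score = ppi$score[keep], stringsAsFactors = FALSE)
  edges$direction <- ""
  edges$sign <- NA_character_
  edges$belief <- NA_real_
  edges$causal_only <- FALSE
  ekey <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  if (!is.null(causal) && nrow(causal$edges)) {
    ce <- causal$edges
    ck <- paste(pmin(ce$from, ce$to), pmax(ce$from, ce$to))
    hit <- match(ck, ekey)
    for (k in seq_len(nrow(ce))) {
      if (!is.na(hit[[k]])) {
        i <- hit[[k]]
        edges$direction[[i]] <- if (edges$from[[i]] == ce$from[[k]]) "forward" else "reverse"
        edges$sign[[i]] <- ce$sign[[k]]
        edges$belief[[i]] <- ce$belief[[k]]
      } else {
        edges <- rbind(edges, data.frame(
          from = ce$from[[k]], to = ce$to[[k]],
          ppi_score = ce$belief[[k]] %||% NA_real_,
          direction = "forward", sign = ce$sign[[k]], belief = ce$belief[[k]],
          causal_only = TRUE, stringsAsFactors = FALSE))
        ekey <- c(ekey, ck[[k]])
      }
    }
  }
  nodes <- sort(unique(c(edges$from, edges$to, unique(c(ppi$protein1, ppi$protein2)))))
  if (!is.null(stats)) {
    if (!length(intersect(nodes, stats$gene_id))) {
      xd_validation_error("no overlap between network nodes and expression genes")
    }
  }
  if (!is.null(coexpr) && nrow(coexpr$edges)) {
    ckey <- paste(coexpr$edges$gene_a, coexpr$edges$gene_b)
    hit <- match(paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to)), ckey)
    edges$r <- ifelse(is.na(hit), NA_real_, coexpr$edges$r[hit])
  } else {
    edges$r <- NA_real_
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  if (!is.null(stats)) {
    m <- match(nodes, stats$gene_id)
    igraph::V(g)$fold_change <- stats$log2fc[m]
    igraph::V(g)$r_gs <- stats$r_gs[m]
  } else {
    igraph::V(g)$fold_change <- NA_real_
    igraph::V(g)$r_gs <- NA_real_
  }
  class(g) <- c("CrosstalkGraph", class(g))
  g
}

#' Attach node relevance and traversal costs
#'
#' Relevance is the min-max normalization of |log2 fold change| over graph
#' nodes, rescaled to `(delta, 1]`; cost is `-log(relevance)`, so the
#' maximal-|fold change| node has cost 0. Nodes without expression data get
#' relevance `delta` (maximal cost) and are flagged. If all fold changes are
#' equal, every relevance is 1 (all costs 0) and a warning is raised.
#'
#' @param graph A `CrosstalkGraph` from [merge_networks()].
#' @param delta Relevance floor preventing infinite costs (default 1e-6).
#' @return The graph with node attributes `relevance`, `cost`,
#'   `missing_expr`.
#' @export
node_costs <- function(graph, delta = 1e-6) {
  fc <- abs(igraph::V(graph)$fold_change)
  missing <- is.na(fc)
  rel <- rep(delta, length(fc))
  obs <- fc[!missing]
  if (length(obs)) {
    rng <- range(obs)
    if (diff(rng) == 0) {
      warning("all fold changes equal; all node costs set to 0", call. = FALSE)
      rel[!missing] <- 1
    } else {
      rel[!missing] <- delta + (1 - delta) * (obs - rng[[1]]) / diff(rng)
    }
  }
  igraph::V(graph)$relevance <- rel
  igraph::V(graph)$cost <- -log(rel)
  igraph::V(graph)$missing_expr <- missing
  graph
}

# ---- node-weighted shortest paths ------------------------------------------

# Dijkstra over node costs with fully deterministic tie-breaking:
# (total cost, then fewer hops, then lexicographically earliest node
# sequence). Conceptually each node v is split into v_in -> v_out with arc
# cost cost(v); here the transform is folded into the relaxation. Directed
# (causal) edges are honored when respect_direction = TRUE.
dijkstra_node_weighted <- function(adj, cost, source, target, blocked_nodes = integer(0),
                                   blocked_edges = character(0)) {
  nv <- length(cost)
  dist <- rep(Inf, nv)
  hops <- rep(Inf, nv)
  prev <- rep(NA_integer_, nv)
  done <- logical(nv)
  done[blocked_nodes] <- TRUE
  paths <- vector("list", nv)  # node index sequences, for lexicographic ties
  dist[[source]] <- cost[[source]]
  hops[[source]] <- 0
  paths[[source]] <- source
  repeat {
    u <- NA_integer_; bd <- Inf; bh <- Inf
    for (v in which(!done & is.finite(dist))) {
      if (dist[[v]] < bd - 1e-12 ||
          (abs(dist[[v]] - bd) <= 1e-12 && hops[[v]] < bh)) {
        u <- v; bd <- dist[[v]]; bh <- hops[[v]]
      }
    }
    if (is.na(u)) break
    done[[u]] <- TRUE
    if (u == target) break
    for (v in adj[[u]]) {
      if (done[[v]]) next
      if (paste(u, v) %in% blocked_edges) next
      nd <- dist[[u]] + cost[[v]]
      nh <- hops[[u]] + 1
      np <- c(paths[[u]], v)
      better <- if (nd < dist[[v]] - 1e-12) TRUE
      else if (nd > dist[[v]] + 1e-12) FALSE
      else if (nh != hops[[v]]) nh < hops[[v]]
      else lex_less(np, paths[[v]])
      if (better) {
        dist[[v]] <- nd; hops[[v]] <- nh; prev[[v]] <- u; paths[[v]] <- np
      }
    }
  }
  if (!is.finite(dist[[target]])) return(NULL)
  list(nodes = paths[[target]], cost = dist[[target]])
}

lex_less <- function(a, b) {
  if (is.null(b)) return(TRUE)
  n <- min(length(a), length(b))
  for (k in seq_len(n)) {
    if (a[[k]] != b[[k]]) return(a[[k]] < b[[k]])
  }
  length(a) < length(b)
}

graph_adjacency_list <- function(graph, respect_direction) {
  nv <- igraph::vcount(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  dirn <- if ("direction" %in% igraph::edge_attr_names(graph)) {
    igraph::E(graph)$direction
  } else rep("", nrow(el))
  adj <- vector("list", nv)
  for (k in seq_len(nrow(el))) {
    a <- el[k, 1]; b <- el[k, 2]
    d <- dirn[[k]]
    if (!respect_direction || is.na(d) || d == "") {
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    } else if (d == "forward") {
      adj[[a]] <- c(adj[[a]], b)
    } else {
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  lapply(adj, function(v) sort(unique(v)))
}

#' Minimum-vertex-weight crosstalk path(s)
#'
#' Finds the path between two seed genes whose total sum of member node
#' costs (endpoints included) is minimal, by Dijkstra's algorithm on the
#' node-split transform of the merged graph. Ties are broken by fewer hops,
#' then by lexicographically earliest node sequence, making the result fully
#' deterministic. `k > 1` returns loopless k-shortest paths via Yen's
#' scheme over the same transform.
#'
#' @param graph A `CrosstalkGraph` with costs from [node_costs()].
#' @param source,target Seed gene ids.
#' @param k Number of paths to return (default 1).
#' @param respect_direction Honor causal edge directions (default FALSE;
#'   undirected edges remain traversable both ways when TRUE).
#' @param causal Optional `CausalNetwork`; when given and a returned path is
#'   fully causal, its belief product is reported.
#' @return A list of `CrosstalkPath` lists (`source`, `target`, `nodes`,
#'   `total_cost`, `node_costs`, `n_hops`, `path_belief`, `status`); an
#'   empty list with attribute `status = "disconnected"` when no path
#'   exists.
#' @export
shortest_crosstalk_path <- function(graph, source, target, k = 1L,
                                    respect_direction = FALSE, causal = NULL) {
  names_v <- igraph::V(graph)$name
  source <- toupper(source); target <- toupper(target)
  if (!source %in% names_v) xd_validation_error("source gene absent from graph: ", source)
  if (!target %in% names_v) xd_validation_error("target gene absent from graph: ", target)
  if (!"cost" %in% igraph::vertex_attr_names(graph)) graph <- node_costs(graph)
  cost <- igraph::V(graph)$cost
  adj <- graph_adjacency_list(graph, respect_direction)
  s <- match(source, names_v); t <- match(target, names_v)

  as_path <- function(res) {
    nodes <- names_v[res$nodes]
    pb <- if (!is.null(causal)) tryCatch(path_belief(causal, nodes),
                                         error = function(e) NA_real_) else NA_real_
    structure(list(source = source, target = target, nodes = nodes,
                   total_cost = res$cost, node_costs = cost[res$nodes],
                   n_hops = length(nodes) - 1L, path_belief = pb,
                   status = "ok"), class = "CrosstalkPath")
  }
  first <- dijkstra_node_weighted(adj, cost, s, t)
  if (is.null(first)) {
    out <- list()
    attr(out, "status") <- "disconnected"
    return(out)
  }
  paths <- list(first)
  if (k > 1) {
    candidates <- list()
    while (length(paths) < k) {
      last <- paths[[length(paths)]]$nodes
      for (spur_i in seq_len(length(last) - 1L)) {
        root <- last[seq_len(spur_i)]
        blocked_edges <- character(0)
        for (p in paths) {
          pn <- p$nodes
          if (length(pn) > spur_i && identical(pn[seq_len(spur_i)], root)) {
            blocked_edges <- c(blocked_edges,
                               paste(pn[[spur_i]], pn[[spur_i + 1L]]),
                               paste(pn[[spur_i + 1L]], pn[[spur_i]]))
          }
        }
        blocked_nodes <- root[-length(root)]
        spur <- dijkstra_node_weighted(adj, cost, last[[spur_i]], t,
                                       blocked_nodes = blocked_nodes,
                                       blocked_edges = blocked_edges)
        if (is.null(spur)) next
        total_nodes <- c(root[-length(root)], spur$nodes)
        if (anyDuplicated(total_nodes)) next
        total_cost <- sum(cost[total_nodes])
        key <- paste(total_nodes, collapse = ">")
        if (key %in% vapply(c(paths, candidates),
                            function(p) paste(p$nodes, collapse = ">"),
                            character(1))) next
        candidates[[length(candidates) + 1L]] <- list(nodes = total_nodes,
                                                      cost = total_cost)
      }
      if (!length(candidates)) break
      ord <- order(vapply(candidates, `[[`, numeric(1), "cost"),
                   vapply(candidates, function(p) length(p$nodes), numeric(1)),
                   vapply(candidates, function(p) paste(names_v[p$nodes], collapse = "\r"),
                          character(1)))
      nxt <- candidates[[ord[[1]]]]
      candidates <- candidates[-ord[[1]]]
      paths[[length(paths) + 1L]] <- nxt
    }
  }
  lapply(paths, as_path)
}

#' @export
print.CrosstalkPath <- function(x, ...) {
  cat("CrosstalkPath:", paste(x$nodes, collapse = " - "),
      sprintf("(total cost %.4f, %d hops)\n", x$total_cost, x$n_hops))
  invisible(x)
}
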