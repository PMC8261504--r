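# Enumeration and ranking of candidate co-target gene pairs.

#' Enumerate candidate co-target pairs
#'
#' Unordered pairs of hallmark genes present in the crosstalk graph. With
#' `require_up` (default), both members must be upregulated in tumors
#' (`log2fc > 0`) and positively grade-correlated (`r_gs > 0`), matching the
#' co-target requirement that all target genes be significantly upregulated
#' in tumors. Pairs are capped at `max_pairs` by hallmark rank product.
#'
#' @param hallmarks Ranked hallmark table from [select_hallmarks()].
#' @param graph A `CrosstalkGraph`.
#' @param require_up Require both genes upregulated and positively
#'   correlated (default TRUE).
#' @param max_pairs Optional cap on the number of pairs.
#' @return data.frame with `gene_a`, `gene_b` (`gene_a < gene_b`),
#'   `rank_product`.
#' @export
enumerate_pairs <- function(hallmarks, graph, require_up = TRUE,
                            max_pairs = Inf) {
  if (!nrow(hallmarks)) xd_validation_error("hallmark list is empty")
  h <- hallmarks
  in_graph <- h$gene_id %in% igraph::V(graph)$name
  if (any(!in_graph)) {
    message(sum(!in_graph), " hallmark gene(s) absent from the graph; their pairs excluded")
  }
  h <- h[in_graph, , drop = FALSE]
  if (require_up) h <- h[h$log2fc > 0 & h$r_gs > 0, , drop = FALSE]
  if (nrow(h) < 2) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      rank_product = numeric(0), stringsAsFactors = FALSE))
  }
  cmb <- utils::combn(nrow(h), 2)
  out <- data.frame(
    gene_a = pmin(h$gene_id[cmb[1, ]], h$gene_id[cmb[2, ]]),
    gene_b = pmax(h$gene_id[cmb[1, ]], h$gene_id[cmb[2, ]]),
    rank_product = h$rank[cmb[1, ]] * h$rank[cmb[2, ]],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$rank_product, out$gene_a, out$gene_b), , drop = FALSE]
  if (nrow(out) > max_pairs) out <- out[seq_len(max_pairs), , drop = FALSE]
  rownames(out) <- NULL
  out
}

ranknorm <- function(x) {
  # ascending-rank map to [0,1]; larger value -> closer to 1
  n <- length(x)
  if (n == 1) return(1)
  (rank(x, ties.method = "average") - 1) / (n - 1)
}

#' Score and rank co-target pairs
#'
#' Composite score
#' `w_corr * ranknorm(mean |r_gs|) + w_path * ranknorm(-total_cost) +
#' w_drug * (both druggable)`, where `ranknorm` maps each component to
#' \[0,1\] by ascending rank so the score is invariant to monotone
#' transforms of the raw components. Pairs without a connecting path are
#' dropped (logged). Ties are broken by gene pair lexicographically.
#'
#' @param pairs Candidate pairs from [enumerate_pairs()].
#' @param graph A `CrosstalkGraph` with costs.
#' @param stats Gene statistics table (for `r_gs`).
#' @param weights Numeric triple `(w_corr, w_path, w_drug)`, must sum to 1.
#' @param druggable Character vector of druggable gene ids (user-supplied
#'   target annotations; default empty).
#' @param respect_direction Passed to [shortest_crosstalk_path()].
#' @param causal Optional `CausalNetwork` for path beliefs.
#' @return data.frame of `CoTargetPair` rows: `gene_a`, `gene_b`,
#'   `corr_component`, `path_component`, `path_nodes`, `path_belief`,
#'   `druggable_a`, `druggable_b`, `composite_score`, `rank`.
#' @export
score_pairs <- function(pairs, graph, stats, weights = c(0.4, 0.4, 0.2),
                        druggable = character(0), respect_direction = FALSE,
                        causal = NULL) {
  if (abs(sum(weights) - 1) > 1e-8) {
    xd_validation_error("weights must sum to 1")
  }
  if (!nrow(pairs)) return(empty_pairs_table())
  druggable <- toupper(druggable)
  r_of <- stats::setNames(stats$r_gs, stats$gene_id)
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$gene_a[[i]]; b <- pairs$gene_b[[i]]
    res <- shortest_crosstalk_path(graph, a, b, k = 1,
                                   respect_direction = respect_direction,
                                   causal = causal)
    if (!length(res)) next
    p <- res[[1]]
    rows[[i]] <- data.frame(
      gene_a = a, gene_b = b,
      corr_component = mean(abs(c(r_of[[a]], r_of[[b]]))),
      path_component = p$total_cost,
      path_nodes = paste(p$nodes, collapse = ","),
      path_belief = p$path_belief,
      druggable_a = a %in% druggable,
      druggable_b = b %in% druggable,
      stringsAsFactors = FALSE
    )
  }
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped) message(dropped, " disconnected pair(s) dropped")
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_pairs_table())
  out <- do.call(rbind, rows)
  out$composite_score <- weights[[1]] * ranknorm(out$corr_component) +
    weights[[2]] * ranknorm(-out$path_component) +
    weights[[3]] * as.numeric(out$druggable_a & out$druggable_b)
  ord <- order(-out$composite_score, out$gene_a, out$gene_b)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

empty_pairs_table <- function() {
  data.frame(gene_a = character(0), gene_b = character(0),
             corr_component = numeric(0), path_component = numeric(0),
             path_nodes = character(0), path_belief = numeric(0),
             druggable_a = logical(0), druggable_b = logical(0),
             composite_score = numeric(0), rank = integer(0),
             stringsAsFactors = FALSE)
}
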