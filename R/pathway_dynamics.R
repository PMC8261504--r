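# Per-stratum gene-set enrichment over cell-death modes and correlation of
# enrichment trajectories with grade.

#' Rank genes for one stratum against the normal reference
#'
#' Per-gene signed score is the signal-to-noise ratio (difference of group
#' means over the sum of group standard deviations, each SD floored at
#' 0.2x|group mean| per common enrichment practice, with an absolute floor of
#' 0.2 when the mean is zero). Genes are sorted by decreasing score, ties
#' broken lexicographically by gene id.
#'
#' @inheritParams differential_expression
#' @param stratum Stratum label (one of the tumor strata).
#' @param metric `"s2n"` (default) or `"t"` for a Welch t-statistic.
#' @return data.frame of class `RankedList` with `gene_id`, `score`, in
#'   rank order; the stratum is attached as an attribute.
#' @export
rank_genes <- function(expr, annotation, stratum, metric = c("s2n", "t")) {
  metric <- match.arg(metric)
  assert_expr_matrix(expr)
  annotation <- align_annotation(expr, annotation)
  if (!stratum %in% annotation$stratum) {
    xd_validation_error("stratum absent from annotation: ", stratum)
  }
  grp <- annotation$sample_id[annotation$stratum == stratum]
  ref <- annotation$sample_id[annotation$tissue == "normal"]
  if (length(grp) < 3 || length(ref) < 3) {
    xd_validation_error("stratum and normal reference each need >= 3 samples")
  }
  x1 <- expr[, grp, drop = FALSE]; x0 <- expr[, ref, drop = FALSE]
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  s1 <- apply(x1, 1, stats::sd); s0 <- apply(x0, 1, stats::sd)
  if (metric == "s2n") {
    floor1 <- pmax(0.2 * abs(m1), 0.2 * (abs(m1) == 0))
    floor0 <- pmax(0.2 * abs(m0), 0.2 * (abs(m0) == 0))
    score <- (m1 - m0) / (pmax(s1, floor1) + pmax(s0, floor0))
  } else {
    n1 <- ncol(x1); n0 <- ncol(x0)
    score <- (m1 - m0) / sqrt(s1^2 / n1 + s0^2 / n0)
    score[!is.finite(score)] <- 0
  }
  ord <- order(-score, rownames(expr))
  out <- data.frame(gene_id = rownames(expr)[ord], score = unname(score[ord]),
                    stringsAsFactors = FALSE)
  attr(out, "stratum") <- stratum
  class(out) <- c("RankedList", "data.frame")
  out
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list accumulating `|score|^weight_exp / sum(hit weights)`
#' at set members ("hits") and `-1/(N - |S|)` at non-members. The enrichment
#' score is the signed maximum-magnitude deviation of the running sum.
#'
#' @param ranked A `RankedList` from [rank_genes()].
#' @param gene_set Character vector of gene ids.
#' @param weight_exp Weighting exponent on |score| (0 = classic KS, 1 =
#'   standard weighted form; default 1).
#' @return list with `es` and the `running` sum vector; `es = NA` with a
#'   warning when the set misses the universe entirely or covers it fully.
#' @export
enrichment_score <- function(ranked, gene_set, weight_exp = 1) {
  genes <- ranked$gene_id
  hit <- genes %in% gene_set
  n_hit <- sum(hit)
  if (n_hit == 0) {
    warning("gene set has empty intersection with the ranked universe", call. = FALSE)
    return(list(es = NA_real_, running = NULL))
  }
  if (n_hit == length(genes)) {
    warning("gene set covers the whole universe; ES undefined", call. = FALSE)
    return(list(es = NA_real_, running = NULL))
  }
  w <- abs(ranked$score)^weight_exp
  w[hit] <- w[hit] / sum(w[hit])
  step <- ifelse(hit, w, -1 / (length(genes) - n_hit))
  running <- cumsum(step)
  # signed maximum-magnitude deviation; exact magnitude ties (within float
  # noise) resolve to the earliest position, deterministically
  a <- abs(running)
  es <- running[which(a >= max(a) - 1e-12)[1]]
  list(es = es, running = running)
}

#' Permutation-based NES, nominal p and FDR q
#'
#' Builds a gene-set permutation null (random sets of matched size drawn
#' from the ranked universe). NES divides each ES by the mean |null ES| of
#' matching sign for its size class; nominal p is the fraction of same-sign
#' null ES at least as extreme; FDR q follows the standard positive/negative
#' pooled-NES procedure.
#'
#' @param ranked A `RankedList`.
#' @param sets Named list of gene sets (already coverage-filtered).
#' @param n_perm Number of random sets per size class (>= 100).
#' @param seed RNG seed (the null is reproducible given the seed).
#' @param weight_exp Passed to [enrichment_score()].
#' @return data.frame with `pathway_id`, `ES`, `NES`, `nominal_p`, `fdr_q`,
#'   `flagged`.
#' @export
normalize_and_test <- function(ranked, sets, n_perm = 1000L, seed = 1L,
                               weight_exp = 1) {
  if (n_perm < 100) xd_validation_error("n_perm must be >= 100")
  es_obs <- vapply(sets, function(s) {
    suppressWarnings(enrichment_score(ranked, s, weight_exp)$es)
  }, numeric(1))
  sizes <- vapply(sets, function(s) sum(ranked$gene_id %in% s), integer(1))
  null_by_size <- with_seed(seed, {
    out <- list()
    for (s in sort(unique(sizes[!is.na(es_obs)]))) {
      out[[as.character(s)]] <- vapply(seq_len(n_perm), function(i) {
        rs <- sample(ranked$gene_id, s)
        enrichment_score(ranked, rs, weight_exp)$es
      }, numeric(1))
    }
    out
  })
  res <- data.frame(pathway_id = names(sets), ES = unname(es_obs),
                    NES = NA_real_, nominal_p = NA_real_, fdr_q = NA_real_,
                    flagged = is.na(es_obs), stringsAsFactors = FALSE)
  null_nes <- numeric(0)
  for (i in seq_along(sets)) {
    es <- es_obs[[i]]
    if (is.na(es)) next
    null_es <- null_by_size[[as.character(sizes[[i]])]]
    if (es == 0) { res$NES[i] <- 0; res$nominal_p[i] <- 1; next }
    same <- null_es[sign(null_es) == sign(es)]
    if (!length(same) || mean(abs(same)) == 0) {
      res$flagged[i] <- TRUE
      next
    }
    res$NES[i] <- es / mean(abs(same))
    res$nominal_p[i] <- sum(abs(same) >= abs(es)) / length(same)
  }
  # pooled null NES for the FDR step (each null ES normalized by the
  # same-sign mean of its own size class)
  for (s in names(null_by_size)) {
    ne <- null_by_size[[s]]
    mp <- mean(abs(ne[ne > 0])); mn <- mean(abs(ne[ne < 0]))
    nn <- ifelse(ne > 0, ne / mp, ifelse(ne < 0, ne / mn, 0))
    null_nes <- c(null_nes, nn[is.finite(nn)])
  }
  obs <- res$NES[!is.na(res$NES)]
  for (i in seq_len(nrow(res))) {
    nes <- res$NES[i]
    if (is.na(nes)) next
    if (nes == 0) { res$fdr_q[i] <- 1; next }
    if (nes > 0) {
      num <- mean(null_nes >= nes)
      den <- mean(obs >= nes)
    } else {
      num <- mean(null_nes <= nes)
      den <- mean(obs <= nes)
    }
    res$fdr_q[i] <- min(1, ifelse(den > 0, num / den, 1))
  }
  res
}

#' Per-stratum enrichment across a pathway database
#'
#' Runs [rank_genes()] and [normalize_and_test()] for every tumor stratum
#' present, after filtering pathways by coverage (fraction of set genes
#' present in the expression universe, default minimum 0.5 -- the matching
#' filter applied before enrichment). Within each stratum, pathways are
#' ranked by NES descending.
#'
#' @inheritParams rank_genes
#' @param db A `PathwayDB` from [read_gene_sets()].
#' @param n_perm,seed,weight_exp Passed to [normalize_and_test()].
#' @param min_coverage Minimum fraction of a pathway's genes present in the
#'   matrix (default 0.5).
#' @return Long data.frame: `pathway_id`, `mode`, `stratum`, `ES`, `NES`,
#'   `nominal_p`, `fdr_q`, `rank`.
#' @export
run_enrichment <- function(expr, annotation, db, n_perm = 1000L, seed = 1L,
                           weight_exp = 1, min_coverage = 0.5,
                           metric = "s2n") {
  stopifnot(inherits(db, "PathwayDB"))
  annotation <- align_annotation(expr, annotation)
  universe <- rownames(expr)
  cov <- vapply(db$sets, function(s) mean(s %in% universe), numeric(1))
  keep <- cov >= min_coverage
  if (!any(keep)) xd_validation_error("no pathway passes the coverage filter")
  sets <- db$sets[keep]
  strata <- intersect(stratum_levels()[-1], unique(as.character(annotation$stratum)))
  out <- list()
  for (i in seq_along(strata)) {
    st <- strata[[i]]
    ranked <- rank_genes(expr, annotation, st, metric = metric)
    res <- normalize_and_test(ranked, sets, n_perm = n_perm,
                              seed = derive_seed(seed, i), weight_exp = weight_exp)
    res$mode <- unname(db$modes[res$pathway_id])
    res$stratum <- st
    res$rank <- rank(-res$NES, ties.method = "first", na.last = "keep")
    out[[st]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("pathway_id", "mode", "stratum", "ES", "NES", "nominal_p",
          "fdr_q", "rank", "flagged")]
}

#' Correlate pathway enrichment trajectories with grade
#'
#' Pearson correlation of each pathway's NES trajectory against the ordinal
#' stratum code. Tumor strata only by default (the normals define the
#' ranking reference, so including them would reuse the reference). A
#' rank-trajectory variant (per-stratum NES rank versus grade) is also
#' reported for mode-level summaries.
#'
#' @param results Long enrichment table from [run_enrichment()].
#' @return data.frame per pathway: `pathway_id`, `mode`, `progression_r`,
#'   `progression_p`, `rank_r`, `flagged`.
#' @export
progression_correlation <- function(results) {
  codes <- stats::setNames(0:4, stratum_levels())
  parts <- split(results, results$pathway_id)
  out <- lapply(names(parts), function(pw) {
    d0 <- parts[[pw]]
    d <- d0[!is.na(d0$NES), , drop = FALSE]
    x <- codes[as.character(d$stratum)]
    flagged <- nrow(d) < 3 || stats::sd(d$NES) == 0
    if (flagged) {
      r <- NA_real_; p <- NA_real_; rr <- NA_real_
    } else {
      r <- stats::cor(d$NES, x)
      p <- cor_t_pvalue(r, length(x))
      rr <- if (stats::sd(d$rank) == 0) NA_real_ else stats::cor(d$rank, x)
    }
    data.frame(pathway_id = pw, mode = d0$mode[[1]],
               progression_r = r, progression_p = p, rank_r = rr,
               flagged = flagged, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
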