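# Progression hallmark gene selection: tumor-vs-normal differential
# expression combined with correlation to the ordinal grade stratum.

#' Tumor-versus-normal differential expression
#'
#' Welch two-sample t-test per gene on log2 values (robust to unequal group
#' variances, the standard choice for log-intensity data), with
#' Benjamini-Hochberg adjustment across genes. The log2 fold change is
#' `mean(tumor) - mean(normal)` on the log2 scale. A gene whose two groups
#' have zero pooled variance and equal means gets `de_p = 1` by convention.
#'
#' @param expr Expression matrix, genes x samples (log2 scale).
#' @param annotation Sample annotation from [read_annotation()] /
#'   [make_annotation()].
#' @return data.frame with `gene_id`, `de_p`, `de_q`, `log2fc`.
#' @export
differential_expression <- function(expr, annotation) {
  assert_expr_matrix(expr)
  annotation <- align_annotation(expr, annotation)
  tum <- annotation$sample_id[annotation$tissue == "tumor"]
  nor <- annotation$sample_id[annotation$tissue == "normal"]
  if (length(tum) < 2 || length(nor) < 2) {
    xd_validation_error("each tissue group needs >= 2 samples (tumor: ",
                        length(tum), ", normal: ", length(nor), ")")
  }
  xt <- expr[, tum, drop = FALSE]
  xn <- expr[, nor, drop = FALSE]
  n1 <- length(tum); n0 <- length(nor)
  m1 <- rowMeans(xt); m0 <- rowMeans(xn)
  v1 <- rowSums((xt - m1)^2) / (n1 - 1)
  v0 <- rowSums((xn - m0)^2) / (n0 - 1)
  se2 <- v1 / n1 + v0 / n0
  tt <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * stats::pt(-abs(tt), df = df)
  # zero pooled variance: identical distributions -> p = 1; any mean
  # difference with zero variance is maximal evidence -> p = 0
  degenerate <- !is.finite(p)
  p[degenerate] <- ifelse(abs(m1 - m0)[degenerate] < .Machine$double.eps^0.5, 1, 0)
  data.frame(gene_id = rownames(expr),
             de_p = unname(p),
             de_q = unname(stats::p.adjust(p, method = "BH")),
             log2fc = unname(m1 - m0),
             stringsAsFactors = FALSE)
}

#' Per-gene correlation with the ordinal grade stratum
#'
#' Correlates each gene's expression with the ordinal stratum code over all
#' samples (adjacent normals coded 0). Default Spearman; p-values use the
#' t-approximation for the chosen coefficient. Constant genes are reported
#' as `r = 0`, `p = 1` and flagged.
#'
#' @inheritParams differential_expression
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return data.frame with `gene_id`, `r_gs`, `r_p`, `constant_flag`.
#' @export
grade_correlation <- function(expr, annotation, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  assert_expr_matrix(expr)
  annotation <- align_annotation(expr, annotation)
  codes <- annotation$stratum_code[match(colnames(expr), annotation$sample_id)]
  if (length(unique(codes)) < 3) {
    xd_validation_error("grade correlation needs >= 3 distinct strata")
  }
  n <- ncol(expr)
  y <- if (method == "spearman") rank(codes) else codes
  x <- expr
  flag <- apply(x, 1, function(v) stats::sd(v) == 0)
  if (method == "spearman") x <- t(apply(x, 1, rank))
  xc <- x - rowMeans(x)
  yc <- y - mean(y)
  denom <- sqrt(rowSums(xc^2) * sum(yc^2))
  r <- as.numeric(xc %*% yc) / denom
  r[flag | !is.finite(r)] <- 0
  p <- cor_t_pvalue(r, n)
  p[flag] <- 1
  data.frame(gene_id = rownames(expr), r_gs = r, r_p = p,
             constant_flag = flag | denom == 0, stringsAsFactors = FALSE)
}

#' Combined per-gene statistics table
#'
#' Convenience wrapper joining [differential_expression()] and
#' [grade_correlation()] into a single `GeneStats` table.
#'
#' @inheritParams grade_correlation
#' @return data.frame with `gene_id`, `de_p`, `de_q`, `log2fc`, `r_gs`,
#'   `r_p`, `direction`.
#' @export
compute_gene_stats <- function(expr, annotation, method = "spearman") {
  de <- differential_expression(expr, annotation)
  gc <- grade_correlation(expr, annotation, method)
  out <- merge(de, gc, by = "gene_id", sort = TRUE)
  out$direction <- ifelse(out$r_gs >= 0, "positive", "negative")
  out
}

#' Select progression hallmark genes
#'
#' Filters to genes with tumor-vs-normal `de_p < alpha` and grade
#' correlation `|r_gs| > r_min`, ranks survivors by |r_gs| descending (ties
#' broken by `de_p` ascending, then gene id) and truncates to `top_k`.
#'
#' @param stats Gene statistics from [compute_gene_stats()].
#' @param alpha Differential-expression p-value threshold (default 0.05).
#' @param r_min Minimum |grade correlation| (default 0.5).
#' @param top_k Maximum number of hallmark genes retained (default 400).
#' @return `stats` restricted to hallmarks, with `hallmark = TRUE`,
#'   `rank` 1..k and `direction`, ordered by rank.
#' @export
select_hallmarks <- function(stats, alpha = 0.05, r_min = 0.5, top_k = 400L) {
  need <- c("gene_id", "de_p", "r_gs")
  if (!all(need %in% names(stats))) {
    xd_validation_error("stats must contain columns: ", paste(need, collapse = ", "))
  }
  keep <- stats$de_p < alpha & abs(stats$r_gs) > r_min
  out <- stats[keep, , drop = FALSE]
  ord <- order(-abs(out$r_gs), out$de_p, out$gene_id)
  out <- out[ord, , drop = FALSE]
  if (nrow(out) > top_k) out <- out[seq_len(top_k), , drop = FALSE]
  out$direction <- ifelse(out$r_gs >= 0, "positive", "negative")
  out$hallmark <- TRUE
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

align_annotation <- function(expr, annotation) {
  missing <- setdiff(colnames(expr), annotation$sample_id)
  if (length(missing)) {
    xd_validation_error("samples without annotation: ",
                        paste(utils::head(missing, 3), collapse = ", "))
  }
  annotation[annotation$sample_id %in% colnames(expr), , drop = FALSE]
}
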