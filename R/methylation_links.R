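# Methylation-expression correlation and hyper/hypomethylation calls.

#' Classify per-gene tumor methylation changes
#'
#' Mann-Whitney (Wilcoxon rank-sum) test per gene on promoter beta values
#' between tumors and normals (appropriate for bounded beta values), with
#' Benjamini-Hochberg adjustment. A gene is called hypermethylated when
#' `delta_beta > delta_min` with `q < alpha`, hypomethylated when
#' `delta_beta < -delta_min` with `q < alpha`, else unchanged -- the
#' effect-size gate avoids significance-without-effect calls.
#'
#' @param meth Methylation beta matrix, genes x samples.
#' @param annotation Sample annotation.
#' @param delta_min Minimum |mean beta difference| (default 0.1).
#' @param alpha FDR threshold (default 0.05).
#' @return data.frame with `gene_id`, `delta_beta`, `p`, `q`, `meth_class`.
#' @export
classify_methylation <- function(meth, annotation, delta_min = 0.1, alpha = 0.05) {
  annotation <- annotation[annotation$sample_id %in% colnames(meth), , drop = FALSE]
  tum <- annotation$sample_id[annotation$tissue == "tumor"]
  nor <- annotation$sample_id[annotation$tissue == "normal"]
  if (!length(tum) || !length(nor)) {
    xd_validation_error("both tumor and normal samples are required")
  }
  xt <- meth[, tum, drop = FALSE]; xn <- meth[, nor, drop = FALSE]
  delta <- rowMeans(xt) - rowMeans(xn)
  p <- vapply(seq_len(nrow(meth)), function(i) {
    suppressWarnings(stats::wilcox.test(xt[i, ], xn[i, ], exact = FALSE)$p.value)
  }, numeric(1))
  p[!is.finite(p)] <- 1
  q <- stats::p.adjust(p, method = "BH")
  cls <- ifelse(delta > delta_min & q < alpha, "hypermethylated",
                ifelse(delta < -delta_min & q < alpha, "hypomethylated",
                       "unchanged"))
  data.frame(gene_id = rownames(meth), delta_beta = unname(delta),
             p = unname(p), q = unname(q), meth_class = unname(cls),
             stringsAsFactors = FALSE)
}

#' Correlate promoter methylation with expression
#'
#' Spearman correlation of beta versus expression per gene, over the shared
#' samples. Genes present in only one matrix are skipped (logged); genes
#' with fewer than 10 shared samples are flagged with undefined r.
#'
#' @param meth Methylation beta matrix, genes x samples.
#' @param expr Expression matrix, genes x samples.
#' @return data.frame with `gene_id`, `r_meth_expr`, `r_p`, `n_shared`,
#'   `flagged`.
#' @export
meth_expr_correlation <- function(meth, expr) {
  shared_genes <- intersect(rownames(meth), rownames(expr))
  skipped <- length(union(rownames(meth), rownames(expr))) - length(shared_genes)
  if (skipped) message(skipped, " gene(s) present in only one matrix skipped")
  if (!length(shared_genes)) {
    xd_validation_error("no genes shared between methylation and expression")
  }
  shared_samples <- intersect(colnames(meth), colnames(expr))
  out <- lapply(shared_genes, function(g) {
    n <- length(shared_samples)
    if (n < 10) {
      return(data.frame(gene_id = g, r_meth_expr = NA_real_, r_p = NA_real_,
                        n_shared = n, flagged = TRUE, stringsAsFactors = FALSE))
    }
    ct <- spearman_t(meth[g, shared_samples], expr[g, shared_samples])
    data.frame(gene_id = g, r_meth_expr = ct$r, r_p = ct$p, n_shared = n,
               flagged = ct$flagged, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
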