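# Internal helpers shared across modules.

xd_stop <- function(..., class = "xdeath_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

xd_validation_error <- function(...) xd_stop(..., class = "xdeath_validation_error")
xd_format_error <- function(...) xd_stop(..., class = "xdeath_format_error")
xd_parse_error <- function(...) xd_stop(..., class = "xdeath_parse_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
assert_expr_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    xd_validation_error("expression matrix must be a numeric matrix")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    xd_validation_error("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(x))) xd_validation_error("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(x))) xd_validation_error("duplicate sample ids in expression matrix")
  if (ncol(x) < 2) xd_validation_error("expression matrix needs >= 2 samples")
  if (nrow(x) < 1) xd_validation_error("expression matrix needs >= 1 gene")
  if (!all(is.finite(x))) xd_validation_error("expression matrix contains non-finite values")
  invisible(x)
}

# Ordered stratum labels; codes are 0..4 with adjacent normal as reference 0.
stratum_levels <- function() c("GS<=5/normal", "GS6", "GS7", "GS8", "GS>=9")

# Spearman correlation with the t-approximation p-value used throughout.
# Constant input -> r = 0, p = 1, flagged; mirrors the degenerate-input rule.
spearman_t <- function(x, y) {
  if (length(x) != length(y)) xd_validation_error("length mismatch in correlation")
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = 0, p = 1, flagged = TRUE))
  }
  r <- stats::cor(rank(x), rank(y))
  if (!is.finite(r)) return(list(r = 0, p = 1, flagged = TRUE))
  p <- cor_t_pvalue(r, n)
  list(r = r, p = p, flagged = FALSE)
}

cor_t_pvalue <- function(r, n) {
  r <- pmin(1, pmax(-1, r))
  if (n < 3) return(rep(1, length(r)))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(tt), df = n - 2)
}

# Derive a per-stage RNG seed from the global seed; kept below 2^31.
derive_seed <- function(seed, stage_index) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(stage_index)
}
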