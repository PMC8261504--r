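#' Read a log2 expression matrix
#'
#' Reads a genes-by-samples matrix of log2 expression values from TSV or
#' GCT 1.2. Gene symbols are uppercased to reconcile the expression, pathway
#' and protein-interaction namespaces. Duplicate symbols are collapsed to the
#' highest-variance row (standard signature practice), genes with more than
#' 20% missing values are dropped, and remaining missing values are
#' median-imputed per gene so downstream rank statistics stay well defined.
#'
#' @param path Path to the input file.
#' @param format Either `"tsv"` (header row of sample ids, first column gene
#'   symbols) or `"gct"` (GCT 1.2 with the two-line preamble).
#' @param max_missing Maximum tolerated fraction of missing values per gene
#'   before the gene is dropped (default 0.2).
#' @return A numeric matrix, genes x samples, with uppercase gene rownames.
#' @export
read_expression <- function(path, format = c("tsv", "gct"), max_missing = 0.2) {
  format <- match.arg(format)
  if (!file.exists(path)) xd_validation_error("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "gct") {
    if (length(lines) < 3 || !grepl("^#1\\.2", lines[[1]])) {
      xd_format_error("not a GCT 1.2 file (line 1 must be '#1.2'): ", path)
    }
    dims <- suppressWarnings(as.integer(strsplit(lines[[2]], "\t", fixed = TRUE)[[1]]))
    if (length(dims) < 2 || anyNA(dims[1:2])) {
      xd_format_error("malformed GCT dimension line (line 2): ", path)
    }
    body <- lines[-(1:2)]
    tab <- parse_tsv_matrix(body, path, id_cols = 2L)
    if (nrow(tab$values) != dims[[1]]) {
      xd_format_error("GCT row count ", nrow(tab$values), " does not match declared ", dims[[1]])
    }
  } else {
    tab <- parse_tsv_matrix(lines, path, id_cols = 1L)
  }
  m <- tab$values
  rownames(m) <- toupper(tab$ids)
  if (ncol(m) < 2) xd_validation_error("expression matrix needs >= 2 sample columns")

  # drop genes with too much missingness, then impute the rest per gene
  miss <- rowMeans(is.na(m))
  m <- m[miss <= max_missing, , drop = FALSE]
  if (anyNA(m)) {
    for (i in which(rowSums(is.na(m)) > 0)) {
      v <- m[i, ]
      v[is.na(v)] <- stats::median(v, na.rm = TRUE)
      m[i, ] <- v
    }
  }
  m <- collapse_duplicate_genes(m)
  assert_expr_matrix(m)
  m
}

parse_tsv_matrix <- function(lines, path, id_cols = 1L) {
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 2) xd_format_error("malformed header: no data lines in ", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) <= id_cols) {
    xd_format_error("malformed header at line 1 of ", path, ": no sample columns")
  }
  samples <- header[-seq_len(id_cols)]
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  ids <- character(length(rows))
  values <- matrix(NA_real_, nrow = length(rows), ncol = length(samples))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) != length(header)) {
      xd_format_error("line ", i + 1L, " of ", path, " has ", length(f),
                      " fields, expected ", length(header))
    }
    ids[[i]] <- f[[1]]
    cells <- f[-seq_len(id_cols)]
    cells[cells %in% c("", "NA", "na", "NaN")] <- NA
    num <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(num) & !is.na(cells))
    if (length(bad)) {
      xd_parse_error("non-numeric value '", cells[bad[[1]]], "' at line ", i + 1L,
                     ", column ", bad[[1]] + id_cols, " of ", path)
    }
    values[i, ] <- num
  }
  if (anyDuplicated(samples)) xd_validation_error("duplicate sample ids in ", path)
  colnames(values) <- samples
  list(ids = ids, values = values)
}

collapse_duplicate_genes <- function(m) {
  if (!anyDuplicated(rownames(m))) return(m)
  vars <- apply(m, 1, stats::var)
  keep <- unlist(lapply(split(seq_len(nrow(m)), rownames(m)), function(idx) {
    idx[which.max(vars[idx])]
  }), use.names = FALSE)
  m[sort(keep), , drop = FALSE]
}

#' Read sample annotations with grade strata
#'
#' Reads a TSV with columns `sample_id`, `tissue` (`normal`/`tumor`) and
#' `gleason` (integer 2-10, empty for normals) and derives the ordinal
#' stratum: adjacent normals form the reference stratum, tumors are binned by
#' Gleason score into GS6, GS7, GS8 and GS>=9. Tumors graded below 6 are
#' binned to GS6 with a warning, since no lower tumor bin exists.
#'
#' @param path Path to the annotation TSV.
#' @return A data.frame with columns `sample_id`, `tissue`, `gleason`,
#'   `stratum` (ordered factor) and `stratum_code` (integer 0-4).
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) xd_validation_error("file not found: ", path)
  d <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue", "gleason")
  if (!all(need %in% names(d))) {
    xd_format_error("annotation must have columns: ", paste(need, collapse = ", "))
  }
  make_annotation(d$sample_id, d$tissue, d$gleason)
}

#' Build a sample annotation table from vectors
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param tissue `"normal"` or `"tumor"` per sample.
#' @param gleason Integer Gleason score per tumor sample; `NA` for normals.
#' @return See [read_annotation()].
#' @export
make_annotation <- function(sample_id, tissue, gleason) {
  sample_id <- as.character(sample_id)
  tissue <- as.character(tissue)
  gleason <- suppressWarnings(as.integer(gleason))
  if (anyDuplicated(sample_id)) xd_validation_error("duplicate sample ids in annotation")
  bad <- !tissue %in% c("normal", "tumor")
  if (any(bad)) {
    xd_validation_error("unknown tissue label '", tissue[bad][[1]], "' for sample ",
                        sample_id[bad][[1]])
  }
  if (any(tissue == "tumor" & is.na(gleason))) {
    xd_validation_error("tumor sample with missing gleason: ",
                        sample_id[tissue == "tumor" & is.na(gleason)][[1]])
  }
  code <- integer(length(sample_id))
  for (i in seq_along(sample_id)) {
    if (tissue[[i]] == "normal") {
      code[[i]] <- 0L
    } else {
      g <- gleason[[i]]
      if (g <= 5L) {
        warning("tumor sample ", sample_id[[i]], " has gleason ", g,
                "; binned to GS6", call. = FALSE)
        code[[i]] <- 1L
      } else {
        code[[i]] <- min(g, 9L) - 5L
      }
    }
  }
  data.frame(
    sample_id = sample_id,
    tissue = tissue,
    gleason = gleason,
    stratum = factor(stratum_levels()[code + 1L], levels = stratum_levels()),
    stratum_code = code,
    stringsAsFactors = FALSE
  )
}

#' Read a cell-death pathway database (GMT plus mode map)
#'
#' Parses a standard GMT file (name, description, genes...). Each pathway is
#' tagged with one of up to twelve cell-death modes, taken from a two-column
#' `pathway_id<TAB>mode` map if supplied, or from a `mode=<label>` token in
#' the GMT description field; pathways with neither get mode `"unassigned"`.
#'
#' @param gmt_path Path to the GMT file.
#' @param mode_map_path Optional path to the pathway-to-mode TSV.
#' @return A `PathwayDB`: list with `sets` (named list of uppercase gene
#'   vectors), `modes` (named character), `descriptions` (named character).
#' @export
read_gene_sets <- function(gmt_path, mode_map_path = NULL) {
  if (!file.exists(gmt_path)) xd_validation_error("file not found: ", gmt_path)
  lines <- readLines(gmt_path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sets <- list(); descs <- character(); modes <- character()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) xd_validation_error("pathway '", f[[1]], "' has an empty gene set")
    name <- f[[1]]
    if (name %in% names(sets)) xd_validation_error("duplicate pathway name: ", name)
    genes <- unique(toupper(f[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (!length(genes)) xd_validation_error("pathway '", name, "' has an empty gene set")
    sets[[name]] <- genes
    descs[[name]] <- f[[2]]
    m <- regmatches(f[[2]], regexpr("mode=[^;[:space:]]+", f[[2]]))
    modes[[name]] <- if (length(m)) sub("^mode=", "", m) else "unassigned"
  }
  if (!is.null(mode_map_path)) {
    mm <- utils::read.delim(mode_map_path, header = TRUE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE)
    if (ncol(mm) < 2) xd_format_error("mode map must have two columns")
    hit <- mm[[1]] %in% names(sets)
    modes[mm[[1]][hit]] <- mm[[2]][hit]
  }
  new_pathway_db(sets, modes, descs)
}

new_pathway_db <- function(sets, modes, descriptions = NULL) {
  stopifnot(length(sets) == length(modes))
  structure(list(sets = sets, modes = modes,
                 descriptions = descriptions %||%
                   stats::setNames(rep("", length(sets)), names(sets))),
            class = "PathwayDB")
}

#' @export
print.PathwayDB <- function(x, ...) {
  cat("PathwayDB:", length(x$sets), "pathways,",
      length(unique(x$modes)), "modes,",
      length(unique(unlist(x$sets))), "genes\n")
  invisible(x)
}

#' Read a STRING-style protein-protein interaction edge list
#'
#' Reads a TSV with columns `protein1`, `protein2`, `combined_score`. Scores
#' on the STRING 0-1000 scale are divided by 1000. Pairs are stored
#' canonically (lexicographic order), duplicates keep the maximum score and
#' self-loops are dropped with a warning.
#'
#' @param path Path to the edge-list TSV.
#' @param score_scale `"unit"` for scores already in \[0,1\],
#'   `"string1000"` for STRING combined scores.
#' @return A data.frame of class `ppi_network` with columns `protein1`,
#'   `protein2`, `score`.
#' @export
read_ppi <- function(path, score_scale = c("unit", "string1000")) {
  score_scale <- match.arg(score_scale)
  if (!file.exists(path)) xd_validation_error("file not found: ", path)
  d <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- c("protein1", "protein2", "combined_score")
  if (!all(need %in% names(d))) {
    xd_format_error("PPI file must have columns: ", paste(need, collapse = ", "))
  }
  make_ppi(d$protein1, d$protein2, d$combined_score, score_scale)
}

#' Build a PPI network from vectors
#' @inheritParams read_ppi
#' @param protein1,protein2 Gene symbols for each interaction.
#' @param score Confidence scores.
#' @return See [read_ppi()].
#' @export
make_ppi <- function(protein1, protein2, score, score_scale = c("unit", "string1000")) {
  score_scale <- match.arg(score_scale)
  a <- toupper(as.character(protein1)); b <- toupper(as.character(protein2))
  s <- as.numeric(score)
  if (score_scale == "string1000") s <- s / 1000
  if (any(s < 0 | s > 1)) {
    xd_validation_error("PPI score outside [0,1] after scaling: ", max(s))
  }
  loop <- a == b
  if (any(loop)) {
    warning(sum(loop), " self-loop(s) dropped from PPI", call. = FALSE)
    a <- a[!loop]; b <- b[!loop]; s <- s[!loop]
  }
  p1 <- pmin(a, b); p2 <- pmax(a, b)
  key <- paste(p1, p2, sep = "\r")
  s <- vapply(split(s, key), max, numeric(1))
  parts <- strsplit(names(s), "\r", fixed = TRUE)
  out <- data.frame(
    protein1 = vapply(parts, `[[`, "", 1L),
    protein2 = vapply(parts, `[[`, "", 2L),
    score = unname(s),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$protein1, out$protein2), ]
  rownames(out) <- NULL
  class(out) <- c("ppi_network", "data.frame")
  out
}

#' Read a promoter methylation beta-value matrix
#'
#' @param path Path to a TSV of gene-level promoter beta values
#'   (genes x samples, first column gene symbols).
#' @return A numeric matrix with values in \[0,1\].
#' @export
read_methylation <- function(path) {
  if (!file.exists(path)) xd_validation_error("file not found: ", path)
  tab <- parse_tsv_matrix(readLines(path, warn = FALSE), path, id_cols = 1L)
  m <- tab$values
  rownames(m) <- toupper(tab$ids)
  if (any(m < 0 | m > 1, na.rm = TRUE)) {
    xd_validation_error("methylation beta values must lie in [0,1]")
  }
  m
}

#' Write an expression or generic matrix as TSV
#'
#' Round-trips bit-identically for ids and to full double precision for
#' values through [read_expression()].
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_col Name of the leading identifier column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "gene_id") {
  d <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(d) <- c(id_col, colnames(m))
  utils::write.table(format(d, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a results table as TSV
#'
#' @param d A data.frame (may have zero rows: a header-only file is written).
#' @param path Output path.
#' @export
write_table_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a network as GraphML
#'
#' Accepts an `igraph` object (e.g. a crosstalk graph) or a
#' `CausalNetwork`; node attributes (`weight`, `cost`, `fold_change`) and
#' edge attributes (`r`, `sign`, `belief`, `ppi_score`) present on the object
#' are carried into the file.
#'
#' @param g An `igraph` graph or `CausalNetwork`.
#' @param path Output path.
#' @export
write_network_graphml <- function(g, path) {
  g <- as_igraph_network(g)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML network written by this package
#' @param path Path to the GraphML file.
#' @return An `igraph` graph.
#' @export
read_network_graphml <- function(path) {
  if (!file.exists(path)) xd_validation_error("file not found: ", path)
  igraph::read_graph(path, format = "graphml")
}

#' Export a signed network as SIF
#'
#' Relation labels: `activates` for positive causal edges, `inhibits` for
#' negative ones and `interacts` for unsigned (pure interaction) edges.
#'
#' @inheritParams write_network_graphml
#' @export
write_network_sif <- function(g, path) {
  g <- as_igraph_network(g)
  el <- igraph::as_edgelist(g)
  sgn <- if ("sign" %in% igraph::edge_attr_names(g)) {
    igraph::E(g)$sign
  } else rep(NA_character_, nrow(el))
  rel <- ifelse(is.na(sgn) | sgn == "", "interacts",
                ifelse(sgn %in% c("+", "1", "positive"), "activates", "inhibits"))
  writeLines(paste(el[, 1], rel, el[, 2]), path)
  invisible(path)
}

as_igraph_network <- function(g) {
  if (igraph::is_igraph(g)) return(g)
  if (inherits(g, "CausalNetwork")) return(causal_to_igraph(g))
  if (inherits(g, "ppi_network")) {
    return(igraph::graph_from_data_frame(
      data.frame(from = g$protein1, to = g$protein2, ppi_score = g$score),
      directed = FALSE))
  }
  xd_validation_error("cannot convert object of class ",
                      paste(class(g), collapse = "/"), " to a network")
}
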