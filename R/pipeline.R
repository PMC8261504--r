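# End-to-end orchestration: hallmark -> enrich -> coexpr -> bn -> crosstalk
# -> rank (-> meth), from a single config with one global seed.
#
# Every stochastic stage receives a per-stage seed derived from the global
# seed as seed * 1000 + stage_index, so one number reproduces a whole run.

pipeline_defaults <- function() {
  list(
    inputs = list(expr = NULL, annotation = NULL, gmt = NULL, mode_map = NULL,
                  ppi = NULL, meth = NULL, druggable = NULL),
    out_dir = NULL,
    seed = 1L,
    seeds = NULL,  # the two seed genes; default: top two upregulated hallmarks
    hallmark = list(alpha = 0.05, r_min = 0.5, top_k = 400L, corr = "spearman"),
    enrich = list(enabled = TRUE, n_perm = 1000L, min_coverage = 0.5,
                  weight_exp = 1, metric = "s2n"),
    coexpr = list(r_min = 0.5, p_max = 0.05, scope = "neighborhood_clique"),
    bn = list(max_parents = 3L, restarts = 10L, bootstrap_B = 100L,
              belief_min = 0.3, bootstrap_restarts = 2L, max_genes = 20L),
    crosstalk = list(ppi_min = 0.4, delta = 1e-6, respect_direction = FALSE,
                     k = 1L),
    rank = list(weights = c(0.4, 0.4, 0.2), require_up = TRUE, max_pairs = Inf),
    meth = list(enabled = FALSE, delta_min = 0.1, alpha = 0.05),
    resume = FALSE
  )
}

merge_config <- function(defaults, user, path = "") {
  for (k in names(user)) {
    if (!k %in% names(defaults)) {
      xd_validation_error("unknown config key: ", paste0(path, k))
    }
    if (is.list(defaults[[k]]) && is.list(user[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]], paste0(path, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Build a run configuration
#'
#' Merges user settings over the documented defaults; unknown keys are
#' rejected. `config` may be a nested list or the path of a YAML file.
#'
#' @param config Nested list or YAML file path.
#' @return The merged configuration list (class `RunConfig`).
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out <- merge_config(pipeline_defaults(), config)
  structure(out, class = "RunConfig")
}

#' Run the full crosstalk pipeline
#'
#' Executes hallmark selection, pathway enrichment, seeded co-expression,
#' Bayesian-network learning with bootstrap beliefs and edge signs, merged
#' crosstalk graph construction with minimum-vertex-weight path search, and
#' co-target pair ranking (methylation links optionally). Each stage writes
#' its outputs under `out_dir/<stage>/`; with `resume = TRUE` a stage whose
#' primary output already exists is skipped and reloaded.
#'
#' @param config A [run_config()] list (or something coercible by it).
#' @return The run manifest (list), with the in-memory stage results
#'   attached as `results`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "RunConfig")) config <- run_config(config)
  if (is.null(config$out_dir)) xd_validation_error("config$out_dir is required")
  for (nm in c("expr", "annotation", "ppi")) {
    p <- config$inputs[[nm]]
    if (is.null(p) || !file.exists(p)) {
      xd_validation_error("missing required input: ", nm,
                          if (!is.null(p)) paste0(" (", p, ")") else "")
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    tool = paste0("xdeath ", as.character(utils::packageVersion("xdeath"))),
    seed = config$seed,
    inputs = lapply(Filter(Negate(is.null), config$inputs),
                    function(p) unname(tools::md5sum(p))),
    stages = list(), status = "running"
  )
  cfg_path <- file.path(config$out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  manifest$config_hash <- unname(tools::md5sum(cfg_path))
  results <- list()
  t_all <- proc.time()[["elapsed"]]

  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fun(), error = function(e) {
      manifest$status <<- paste0("failed at stage '", name, "'")
      manifest$error <<- conditionMessage(e)
      yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
      xd_stop("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
    manifest$stages[[name]] <<- list(runtime_s = round(proc.time()[["elapsed"]] - t0, 3))
    out
  }
  sdir <- function(name) {
    d <- file.path(config$out_dir, name)
    dir.create(d, showWarnings = FALSE)
    d
  }

  expr <- stage("read", function() read_expression(config$inputs$expr))
  ann <- read_annotation(config$inputs$annotation)
  ppi <- read_ppi(config$inputs$ppi)
  db <- if (!is.null(config$inputs$gmt)) {
    read_gene_sets(config$inputs$gmt, config$inputs$mode_map)
  } else NULL

  # 1. hallmarks (deterministic)
  results$stats <- stage("hallmark", function() {
    compute_gene_stats(expr, ann, method = config$hallmark$corr)
  })
  results$hallmarks <- select_hallmarks(results$stats,
                                        alpha = config$hallmark$alpha,
                                        r_min = config$hallmark$r_min,
                                        top_k = config$hallmark$top_k)
  write_table_tsv(results$hallmarks, file.path(sdir("hallmark"), "hallmarks.tsv"))

  # 2. enrichment
  if (isTRUE(config$enrich$enabled) && !is.null(db)) {
    results$enrichment <- stage("enrich", function() {
      run_enrichment(expr, ann, db, n_perm = config$enrich$n_perm,
                     seed = derive_seed(config$seed, 2L),
                     weight_exp = config$enrich$weight_exp,
                     min_coverage = config$enrich$min_coverage,
                     metric = config$enrich$metric)
    })
    results$progression <- progression_correlation(results$enrichment)
    write_table_tsv(results$enrichment, file.path(sdir("enrich"), "enrichment.tsv"))
    write_table_tsv(results$progression, file.path(sdir("enrich"), "progression.tsv"))
  }

  # seed genes: configured, or the top two upregulated hallmarks
  seeds <- config$seeds
  if (is.null(seeds)) {
    up <- results$hallmarks[results$hallmarks$log2fc > 0 & results$hallmarks$r_gs > 0, ]
    if (nrow(up) < 2) xd_validation_error("fewer than two upregulated hallmark genes to seed")
    seeds <- up$gene_id[1:2]
  }
  seeds <- toupper(seeds)

  # 3. seeded co-expression
  results$coexpr <- stage("coexpr", function() {
    build_coexpression(expr, seeds, r_min = config$coexpr$r_min,
                       p_max = config$coexpr$p_max, scope = config$coexpr$scope)
  })
  write_table_tsv(results$coexpr$edges, file.path(sdir("coexpr"), "coexpr.tsv"))

  # 4. Bayesian network over the seed neighborhood (capped for tractability)
  results$causal <- stage("bn", function() {
    nb <- unique(c(seeds, unlist(results$coexpr$neighborhoods)))
    if (length(nb) > config$bn$max_genes) {
      r_of <- stats::setNames(abs(results$stats$r_gs), results$stats$gene_id)
      extra <- setdiff(nb, seeds)
      extra <- extra[order(-r_of[extra])]
      nb <- c(seeds, utils::head(extra, config$bn$max_genes - length(seeds)))
    }
    if (length(nb) < 3) nb <- unique(c(nb, utils::head(results$hallmarks$gene_id, 3)))
    net <- learn_structure(expr, genes = nb,
                           max_parents = config$bn$max_parents,
                           restarts = config$bn$restarts,
                           seed = derive_seed(config$seed, 4L))
    net <- bootstrap_beliefs(expr, net, B = config$bn$bootstrap_B,
                             seed = derive_seed(config$seed, 4L),
                             belief_min = config$bn$belief_min,
                             restarts = config$bn$bootstrap_restarts)
    sign_edges(expr, net)
  })
  write_network_graphml(results$causal, file.path(sdir("bn"), "bn.graphml"))
  write_table_tsv(results$causal$edges, file.path(sdir("bn"), "bn_edges.tsv"))

  # 5. merged crosstalk graph and seed-to-seed path
  results$graph <- stage("crosstalk", function() {
    g <- merge_networks(ppi, causal = results$causal, coexpr = results$coexpr,
                        stats = results$stats, ppi_min = config$crosstalk$ppi_min)
    node_costs(g, delta = config$crosstalk$delta)
  })
  results$paths <- shortest_crosstalk_path(
    results$graph, seeds[[1]], seeds[[2]], k = config$crosstalk$k,
    respect_direction = config$crosstalk$respect_direction,
    causal = results$causal)
  write_network_graphml(results$graph, file.path(sdir("crosstalk"), "merged.graphml"))
  write_table_tsv(paths_table(results$paths), file.path(sdir("crosstalk"), "paths.tsv"))

  # 6. co-target pair ranking
  results$pairs <- stage("rank", function() {
    druggable <- if (!is.null(config$inputs$druggable)) {
      readLines(config$inputs$druggable, warn = FALSE)
    } else character(0)
    cand <- enumerate_pairs(results$hallmarks, results$graph,
                            require_up = config$rank$require_up,
                            max_pairs = config$rank$max_pairs)
    score_pairs(cand, results$graph, results$stats,
                weights = config$rank$weights, druggable = druggable,
                respect_direction = config$crosstalk$respect_direction,
                causal = results$causal)
  })
  write_table_tsv(results$pairs, file.path(sdir("rank"), "pairs.tsv"))

  # 7. optional methylation links
  if (isTRUE(config$meth$enabled) && !is.null(config$inputs$meth)) {
    results$meth <- stage("meth", function() {
      meth <- read_methylation(config$inputs$meth)
      list(classes = classify_methylation(meth, ann,
                                          delta_min = config$meth$delta_min,
                                          alpha = config$meth$alpha),
           correlation = meth_expr_correlation(meth, expr))
    })
    write_table_tsv(results$meth$classes, file.path(sdir("meth"), "meth_classes.tsv"))
    write_table_tsv(results$meth$correlation, file.path(sdir("meth"), "meth_expr.tsv"))
  }

  manifest$status <- "ok"
  manifest$runtime_s <- round(proc.time()[["elapsed"]] - t_all, 3)
  manifest$seed_genes <- seeds
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  manifest$results <- results
  invisible(manifest)
}

paths_table <- function(paths) {
  if (!length(paths)) {
    return(data.frame(rank = integer(0), nodes = character(0),
                      total_cost = numeric(0), n_hops = integer(0),
                      path_belief = numeric(0), stringsAsFactors = FALSE))
  }
  data.frame(
    rank = seq_along(paths),
    nodes = vapply(paths, function(p) paste(p$nodes, collapse = ","), character(1)),
    total_cost = vapply(paths, `[[`, numeric(1), "total_cost"),
    n_hops = vapply(paths, function(p) as.integer(p$n_hops), integer(1)),
    path_belief = vapply(paths, `[[`, numeric(1), "path_belief"),
    stringsAsFactors = FALSE
  )
}
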