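#' Configuration for the three-stage pipeline
#'
#' Inputs may be file paths (read with the package loaders) or in-memory
#' objects (`multiPhylo`, `trait_matrix`, `society_metadata`).
#'
#' @param trees tree-sample path or `multiPhylo`.
#' @param matrix trait-matrix path or `trait_matrix`.
#' @param metadata society-metadata path or `society_metadata`.
#' @param outgroup outgroup taxon label (roots trees; coded absent for the
#'   signal screen and missing for ancestral-state reconstruction).
#' @param alias optional named character vector renaming matrix taxa.
#' @param nodes optional named list of taxon sets defining the ancestral
#'   nodes to report; default: all consensus clades.
#' @param n_sims simulations per null in the D screen.
#' @param alpha significance level used throughout.
#' @param radius_km spatial neighbour radius.
#' @param consensus_threshold majority-rule threshold (strict).
#' @param autologistic_method,autologistic_control stage-2 settings.
#' @param weights neighbour-term weighting for stage 2.
#' @param thresholds corpus reporting thresholds
#'   (`inferred` strict, `secure` inclusive).
#' @param bayes run the Bayesian root analysis (stage 3b)? Either `FALSE`,
#'   or a taxon set (the node to interrogate), or `TRUE` for the deepest
#'   consensus clade.
#' @param bayes_control a [bayes_control()] list for stage 3b.
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir output directory for the report bundle.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(trees, matrix, metadata, outgroup,
                            alias = NULL, nodes = NULL,
                            n_sims = 1000, alpha = 0.05, radius_km = 1000,
                            consensus_threshold = 0.5,
                            autologistic_method = "mcmle",
                            autologistic_control = folkphylo::autologistic_control(),
                            weights = "sum",
                            thresholds = c(inferred = 0.5, secure = 0.7),
                            bayes = FALSE,
                            bayes_control = folkphylo::bayes_control(),
                            seed = 1L, out_dir = tempfile("folkphylo_run_")) {
  structure(as.list(environment()), class = "pipeline_config")
}

load_input <- function(x, loader) if (is.character(x)) loader(x) else x

write_tsv <- function(df, dir, name) {
  path <- file.path(dir, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the three-stage comparative pipeline
#'
#' Stage 1 screens every trait for phylogenetic signal with the D
#' statistic on the majority-rules consensus tree (outgroup coded absent).
#' Stage 2 fits the dual-graph autologistic model to exactly the traits
#' flagged significant in stage 1 and classifies the phylogenetic and
#' spatial parameters as +/-/0. Stage 3 reconstructs ancestral states for
#' the vertically dominated traits (phylogenetic sign `+` and spatial sign
#' not `+`, or a larger phylogenetic than spatial estimate) over the whole
#' tree sample, reports the ancestral corpora at the 50%/70% thresholds,
#' and optionally interrogates the deepest node with the Bayesian
#' machinery. Per-trait failures are caught, logged and skipped.
#'
#' @param config a [pipeline_config()] list.
#' @return invisible list with all tables, the consensus, the graphs and
#'   output file paths; the report bundle is written under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  seeds <- sample.int(2^30, 4)
  logf <- file.path(config$out_dir, "run_log.txt")
  logline <- function(...) cat(..., "\n", sep = "", file = logf, append = TRUE)
  cat("", file = logf)
  logline("folkphylo ", as.character(utils::packageVersion("folkphylo")),
          " | R ", paste(R.version$major, R.version$minor, sep = "."))
  logline("timestamp: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  logline("seed: ", config$seed, " | n_sims: ", config$n_sims,
          " | alpha: ", config$alpha, " | radius_km: ", config$radius_km)

  trees <- load_input(config$trees, read_tree_sample)
  m <- load_input(config$matrix, read_trait_matrix)
  meta <- load_input(config$metadata, read_society_metadata)
  if (!is.null(config$alias)) m <- rename_taxa(m, config$alias)
  outgroup <- config$outgroup
  logline("inputs: ", length(trees), " trees, ", nrow(m), " taxa x ",
          ncol(m), " traits, ", nrow(meta), " societies")

  consensus <- majority_consensus(trees, config$consensus_threshold, outgroup)
  write_consensus(consensus, file.path(config$out_dir, "consensus.nwk"))

  # stage 1: D screen, outgroup coded absent (screen cannot take missing)
  m_screen <- set_outgroup_state(m, outgroup, "absent")
  stage1 <- d_screen(consensus, m_screen, n_sims = config$n_sims,
                     alpha = config$alpha, seed = seeds[1])
  stage1$p_fdr <- p.adjust(stage1$p_random, "BH")  # reported, not filtered on
  write_tsv(stage1, config$out_dir, "stage1_d_screen.tsv")
  significant <- stage1$trait[!is.na(stage1$significant) & stage1$significant]
  logline("stage 1: ", length(significant), " of ", ncol(m),
          " traits significant at alpha = ", config$alpha)

  # stage 2: autologistic on the screened set, societies with coordinates
  meta_sp <- meta[!is.na(meta$lat) & !is.na(meta$lon) &
                    meta$society %in% rownames(m), , drop = FALSE]
  dropped <- setdiff(meta$society, meta_sp$society)
  if (length(dropped)) logline("stage 2: dropped (no coordinates): ",
                               paste(dropped, collapse = ", "))
  g_spatial <- build_spatial_graph(meta_sp, config$radius_km)
  g_phylo <- build_phylo_graph(meta_sp)
  gsum <- graph_summary(g_phylo, g_spatial)
  write_graph(g_spatial, file.path(config$out_dir, "graph_spatial.tsv"))
  write_graph(g_phylo, file.path(config$out_dir, "graph_phylo.tsv"))
  logline(sprintf("graphs: mean degree phylo %.2f, spatial %.2f; shared %d, unique %d/%d",
                  gsum$mean_degree_a, gsum$mean_degree_b, gsum$shared,
                  gsum$unique_a, gsum$unique_b))
  ctrl <- config$autologistic_control
  ctrl$weights <- config$weights
  stage2 <- fit_autologistic_all(m, g_phylo, g_spatial, traits = significant,
                                 method = config$autologistic_method,
                                 control = ctrl, seed = seeds[2])
  write_tsv(stage2, config$out_dir, "stage2_autologistic.tsv")
  cont <- sign_contingency(stage2)
  write_tsv(as.data.frame.matrix(cont), config$out_dir, "stage2_sign_contingency.tsv")

  # vertical transmission dominant: lambda classified +, and theta not
  # positive or outweighed by lambda
  ok <- !is.na(stage2$lambda_sign)
  vertical <- stage2$trait[ok & stage2$lambda_sign == "+" &
                             (stage2$theta_sign %in% c("-", "0") |
                                stage2$lambda > stage2$theta)]
  logline("stage 2: ", length(vertical), " of ", length(significant),
          " traits vertically dominated")

  # stage 3: ML ancestral states over the tree sample, outgroup missing
  m_asr <- set_outgroup_state(m, outgroup, "missing")
  nodes <- config$nodes
  stage3_rows <- list()
  for (tr in vertical) {
    res <- tryCatch({
      states <- setNames(unclass(m_asr)[, tr], rownames(m_asr))
      agg <- aggregate_over_sample(trees, states,
                                   if (is.null(nodes)) consensus else nodes,
                                   alpha = config$alpha, outgroup = outgroup)
      agg$trait <- tr
      agg
    }, error = function(e) {
      logline("stage 3: trait ", tr, " failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) stage3_rows[[tr]] <- res
  }
  stage3 <- if (length(stage3_rows)) do.call(rbind, stage3_rows) else
    data.frame(trait = character(0), clade = character(0), combined = numeric(0))
  rownames(stage3) <- NULL
  write_tsv(stage3, config$out_dir, "stage3_asr.tsv")
  corpora <- if (nrow(stage3)) ancestral_corpora(stage3, config$thresholds) else NULL
  if (!is.null(corpora)) write_tsv(corpora, config$out_dir, "stage3_corpora.tsv")

  # stage 3b: Bayesian analysis of the deepest node (optional)
  bayes_tab <- NULL
  if (!isFALSE(config$bayes) && nrow(stage3)) {
    node_taxa <- if (isTRUE(config$bayes)) {
      big <- stage3[which.max(stage3$size), ]
      strsplit(big$members, ";", fixed = TRUE)[[1]]
    } else config$bayes
    root_key <- paste(sort(node_taxa), collapse = ";")
    cand <- unique(stage3$trait[stage3$combined > config$thresholds[["inferred"]] &
                                  vapply(stage3$members, function(mm)
                                    setequal(strsplit(mm, ";", fixed = TRUE)[[1]],
                                             node_taxa), logical(1))])
    if (!length(cand)) logline("stage 3b: no trait inferred at the target node")
    set.seed(seeds[3])
    bayes_rows <- lapply(cand, function(tr) {
      res <- tryCatch({
        states <- setNames(unclass(m_asr)[, tr], rownames(m_asr))
        ft <- fossil_test(trees, states, node_taxa,
                          config = config$bayes_control,
                          seed = sample.int(2^30, 1))
        data.frame(trait = tr, p_present = ft$p_present, p_absent = ft$p_absent,
                   bayes_factor = ft$bayes_factor, label = ft$label,
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        logline("stage 3b: trait ", tr, " failed: ", conditionMessage(e))
        NULL
      })
      res
    })
    bayes_rows <- Filter(Negate(is.null), bayes_rows)
    if (length(bayes_rows)) {
      bayes_tab <- do.call(rbind, bayes_rows)
      write_tsv(bayes_tab, config$out_dir, "stage3_bayes.tsv")
    }
  }

  summary <- list(
    seed = config$seed, n_trees = length(trees), n_traits = ncol(m),
    n_significant = length(significant), n_vertical = length(vertical),
    graph = gsum[c("mean_degree_a", "mean_degree_b", "shared",
                   "unique_a", "unique_b", "n")],
    sign_contingency = as.data.frame(cont),
    corpora = if (!is.null(corpora)) attr(corpora, "corpora") else NULL)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logline("done")
  invisible(list(stage1 = stage1, stage2 = stage2, stage3 = stage3,
                 corpora = corpora, bayes = bayes_tab, consensus = consensus,
                 g_phylo = g_phylo, g_spatial = g_spatial,
                 significant = significant, vertical = vertical,
                 summary = summary, out_dir = config$out_dir))
}
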