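#' Pipeline configuration
#'
#' Collects the file paths and every stage parameter of the analysis;
#' all defaults match the stage documentation. Validation happens here,
#' before any computation.
#'
#' @param mrna_path,mirna_path Expression TSV/CSV paths (features x
#'   samples, first column = feature id).
#' @param trait_path Sample trait CSV (first column = sample id); must
#'   contain `group_column`.
#' @param interaction_path Scored interaction TSV (`mirna`, `gene`,
#'   `score_*`).
#' @param out_dir Output directory (created if missing).
#' @param group_column Binary trait column naming the two sample groups
#'   for the differential-expression filter.
#' @param alpha FDR level of the DE filter.
#' @param beta Fixed soft-thresholding power, or `NULL` to auto-select
#'   per layer via [pick_soft_threshold()].
#' @param candidate_powers,r2_target Soft-threshold scan parameters.
#' @param cut_height Static dendrogram cut height on TOM dissimilarity.
#' @param min_module_size Named pair `c(mRNA =, miRNA =)`; miRNA panels
#'   are much smaller than gene panels, hence the lower default.
#' @param merge_cut Eigengene-dissimilarity merge threshold (0 = off).
#' @param mm_min,gs_min Hub thresholds.
#' @param top_fraction Fraction of best-ranked interactions retained.
#' @param gene_module,mirna_module Module labels to integrate; `NULL`
#'   picks the module with the highest module significance per layer.
#' @param seed Integer seed for any stochastic option.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(mrna_path, mirna_path, trait_path,
                            interaction_path, out_dir,
                            group_column = "group",
                            alpha = 0.05,
                            beta = NULL,
                            candidate_powers = 1:20,
                            r2_target = 0.8,
                            cut_height = 0.995,
                            min_module_size = c(mRNA = 30L, miRNA = 5L),
                            merge_cut = 0.25,
                            mm_min = 0.8,
                            gs_min = 0.2,
                            top_fraction = 0.2,
                            gene_module = NULL,
                            mirna_module = NULL,
                            seed = 1L) {
  bad <- function(field, msg) {
    stop(sprintf("invalid config: `%s` %s", field, msg), call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) bad("alpha", "must lie in (0, 1)")
  if (!is.null(beta) && (length(beta) != 1L || beta < 1)) {
    bad("beta", "must be NULL or a power >= 1")
  }
  if (any(candidate_powers < 1)) bad("candidate_powers", "must be >= 1")
  if (r2_target <= 0 || r2_target > 1) bad("r2_target", "must lie in (0, 1]")
  if (cut_height <= 0 || cut_height > 1) bad("cut_height", "must lie in (0, 1]")
  if (length(min_module_size) != 2L ||
      !all(c("mRNA", "miRNA") %in% names(min_module_size)) ||
      any(min_module_size < 1)) {
    bad("min_module_size", "must be a named pair c(mRNA =, miRNA =), each >= 1")
  }
  if (merge_cut < 0 || merge_cut >= 1) bad("merge_cut", "must lie in [0, 1)")
  if (mm_min <= 0 || mm_min >= 1) bad("mm_min", "must lie in (0, 1)")
  if (gs_min <= 0 || gs_min >= 1) bad("gs_min", "must lie in (0, 1)")
  if (top_fraction <= 0 || top_fraction > 1) {
    bad("top_fraction", "must lie in (0, 1]")
  }
  structure(list(
    mrna_path = mrna_path, mirna_path = mirna_path,
    trait_path = trait_path, interaction_path = interaction_path,
    out_dir = out_dir, group_column = group_column,
    alpha = alpha, beta = beta,
    candidate_powers = as.integer(candidate_powers),
    r2_target = r2_target, cut_height = cut_height,
    min_module_size = stats::setNames(as.integer(min_module_size[c("mRNA", "miRNA")]),
                                      c("mRNA", "miRNA")),
    merge_cut = merge_cut, mm_min = mm_min, gs_min = gs_min,
    top_fraction = top_fraction,
    gene_module = gene_module, mirna_module = mirna_module,
    seed = as.integer(seed)), class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#'
#' The config round-trips losslessly so a run can be reproduced from its
#' manifest.
#'
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @return `write_config`: the path, invisibly. `read_config`: the
#'   re-validated `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  raw <- unclass(config)
  raw$min_module_size <- as.list(raw$min_module_size)  # keep names in JSON
  jsonlite::write_json(raw, path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$min_module_size <- unlist(raw$min_module_size)
  do.call(pipeline_config, raw)
}

analyse_layer <- function(x, layer, traits, config) {
  msg <- function(...) message("[", layer, "] ", ...)
  groups <- traits[[config$group_column]]

  x <- drop_zero_variance(x)
  z <- zscore_normalize(x)
  msg("differential expression: Welch t + BH at FDR alpha = ", config$alpha)
  de <- differential_expression(z, groups, alpha = config$alpha)
  selected <- filter_by_fdr(de, alpha = config$alpha)
  msg(length(selected), " / ", nrow(z), " features pass the FDR filter")
  if (length(selected) < 3L) {
    stop("[", layer, "] differential-expression selection left ",
         length(selected), " feature(s); cannot build a network ",
         "(lower alpha stringency or inspect the inputs)", call. = FALSE)
  }
  zs <- z[selected, , drop = FALSE]

  s <- correlation_matrix(zs)
  if (is.null(config$beta)) {
    sft <- pick_soft_threshold(s, candidate_powers = config$candidate_powers,
                               r2_target = config$r2_target)
    beta <- sft$beta
    msg("soft threshold auto-selected: beta = ", beta,
        " (scale-free R^2 = ",
        round(sft$report$r_squared[sft$report$power == beta], 3), ")")
  } else {
    sft <- NULL
    beta <- config$beta
    msg("soft threshold fixed by config: beta = ", beta)
  }
  a <- adjacency(s, beta)
  tom <- tom_similarity(a)
  dend <- hierarchical_clustering(tom$dissimilarity)
  part <- cut_tree(dend, cut_height = config$cut_height,
                   min_module_size = config$min_module_size[[layer]])
  part <- assign_colors(part, layer = layer)
  if (config$merge_cut > 0 &&
      length(unique(part[!is_grey_label(part)])) > 1L) {
    part <- merge_close_modules(zs, part,
                                me_dissimilarity_cut = config$merge_cut)
  }
  n_mod <- length(unique(part[!is_grey_label(part)]))
  msg(n_mod, " module(s) detected; ", sum(is_grey_label(part)),
      " feature(s) grey")
  if (n_mod == 0L) {
    stop("[", layer, "] no modules survived the cut; adjust cut_height or ",
         "min_module_size", call. = FALSE)
  }

  me <- module_eigengene(zs, part)
  gs <- gene_significance(zs, traits[[config$group_column]])
  ms <- module_significance(gs, part)
  mm <- module_membership(zs, me)
  numeric_traits <- traits[vapply(traits, is.numeric, logical(1))]
  mt <- module_trait_correlation(me, numeric_traits)
  hubs <- identify_hubs(mm, gs, part, mm_min = config$mm_min,
                        gs_min = config$gs_min)
  msg(nrow(hubs), " hub feature(s) called")

  list(layer = layer, de = de, selected = selected, expression = zs,
       soft_threshold = sft, beta = beta, dendrogram = dend,
       partition = part, eigengenes = me, gs = gs, ms = ms, mm = mm,
       module_trait = mt, hubs = hubs)
}

write_layer_outputs <- function(res, config) {
  out <- config$out_dir
  tag <- if (res$layer == "mRNA") "mrna" else "mirna"
  p <- function(name) file.path(out, sprintf("%s_%s.tsv", name, tag))

  de_df <- as.data.frame(res$de)
  names(de_df)[names(de_df) == "feature"] <- "id"
  write_table_with_schema(
    de_df[, c("id", "statistic", "p_value", "adjusted_p", "passes_filter")],
    p("de"), "id, stat (Welch t), p, p_adj (BH), selected")

  write_partition(res$partition, p("partition"))
  write_eigengenes(res$eigengenes, file.path(out, sprintf("eigengenes_%s.csv", tag)))

  gsmm <- data.frame(feature_id = names(res$gs),
                     module_label = unname(res$partition[names(res$gs)]),
                     gene_significance = unname(res$gs),
                     res$mm[names(res$gs), , drop = FALSE],
                     check.names = FALSE, stringsAsFactors = FALSE)
  write_table_with_schema(
    gsmm, p("gs_mm"),
    "feature_id, module_label, gene_significance, MM per module")

  write_table_with_schema(res$ms, p("ms"),
                          "module, MS = mean member GS, n_features, is_grey")

  mt <- res$module_trait
  mt_df <- data.frame(module = rownames(mt$correlation),
                      mt$correlation,
                      stats::setNames(as.data.frame(mt$p_value),
                                      paste0("p_", colnames(mt$p_value))),
                      check.names = FALSE, stringsAsFactors = FALSE)
  write_table_with_schema(
    mt_df, p("module_trait"),
    "module, Pearson cor per trait, two-sided t-test p per trait")

  write_table_with_schema(
    res$hubs, p("hubs"),
    "module, feature, MM in own module, GS")
  invisible(NULL)
}

pick_focus_module <- function(ms, override, layer) {
  real <- ms[!ms$is_grey, , drop = FALSE]
  if (!is.null(override)) {
    if (!override %in% real$module) {
      stop("configured ", layer, " module '", override,
           "' was not detected; available: ",
           paste(real$module, collapse = ", "), call. = FALSE)
    }
    return(override)
  }
  real$module[which.max(real$module_significance)]
}

#' Run the full co-expression integration pipeline
#'
#' Executes, per expression layer: z-score normalization,
#' Welch-t/BH differential-expression filtering, correlation network,
#' soft-threshold selection, TOM, average-linkage module detection with
#' color labels, eigengenes, module-trait statistics, and hub calling;
#' then links the hub miRNAs of the focus miRNA module to the genes of
#' the focus gene module through the ranked interaction table and
#' reports degree and betweenness of the resulting bipartite network.
#' All stage outputs and a JSON run manifest are written to
#' `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return The manifest (list), invisibly; its `files` element maps
#'   every written file to an md5 checksum.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c("mrna_path", "mirna_path", "trait_path", "interaction_path")) {
    if (!file.exists(config[[f]])) {
      stop("input file missing: ", f, " = ", config[[f]], call. = FALSE)
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  traits <- read_trait_table(config$trait_path)
  if (!config$group_column %in% names(traits)) {
    stop("trait table lacks the group column '", config$group_column, "'",
         call. = FALSE)
  }
  mrna <- read_expression(config$mrna_path, layer = "mRNA")
  mirna <- read_expression(config$mirna_path, layer = "miRNA")
  for (m in list(mrna, mirna)) {
    if (!identical(colnames(m), rownames(traits))) {
      stop("expression sample columns do not match the trait table rows",
           call. = FALSE)
    }
  }

  gene_res <- analyse_layer(mrna, "mRNA", traits, config)
  mirna_res <- analyse_layer(mirna, "miRNA", traits, config)
  write_layer_outputs(gene_res, config)
  write_layer_outputs(mirna_res, config)

  gene_module <- pick_focus_module(gene_res$ms, config$gene_module, "gene")
  mirna_module <- pick_focus_module(mirna_res$ms, config$mirna_module, "miRNA")
  message("[integration] linking hub miRNAs of ", mirna_module,
          " to genes of ", gene_module)

  hub_mirnas <- mirna_res$hubs$feature[mirna_res$hubs$module == mirna_module]
  if (length(hub_mirnas) == 0L) {
    stop("focus miRNA module '", mirna_module, "' has no hubs at mm_min = ",
         config$mm_min, ", gs_min = ", config$gs_min, call. = FALSE)
  }
  module_genes <- names(gene_res$partition)[gene_res$partition == gene_module]

  ranked <- rank_interactions(read_interactions(config$interaction_path))
  top <- select_top_interactions(ranked, fraction = config$top_fraction)
  message("[integration] ", nrow(top), " / ", nrow(ranked),
          " interactions retained at the ", config$top_fraction * 100,
          "% rank cutoff")
  net <- build_bipartite_network(hub_mirnas, module_genes, top)
  report <- topology_report(net)

  write_table_with_schema(net$edges,
                          file.path(config$out_dir, "network_edges.tsv"),
                          "mirna, gene (undirected bipartite edge list)")
  if (igraph::vcount(net$graph) > 0) {
    igraph::write_graph(net$graph,
                        file.path(config$out_dir, "network.graphml"),
                        format = "graphml")
  }
  write_table_with_schema(
    report, file.path(config$out_dir, "topology_report.tsv"),
    "node, side, degree, betweenness (normalized)")

  files <- list.files(config$out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    package = "comirnet",
    version = as.character(utils::packageVersion("comirnet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = unclass(config),
    focus_modules = list(gene = gene_module, miRNA = mirna_module),
    files = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(c(manifest,
              list(results = list(mrna = gene_res, mirna = mirna_res,
                                  network = net, report = report))))
}

#' Write a simulated study to disk in the pipeline's input formats
#'
#' @param study Result of [simulate_study()].
#' @param dir Directory to write into (created if missing).
#' @return Named list of the four input paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    mrna_path = file.path(dir, "mrna_expression.tsv"),
    mirna_path = file.path(dir, "mirna_expression.tsv"),
    trait_path = file.path(dir, "traits.csv"),
    interaction_path = file.path(dir, "interactions.tsv"))
  write_expression(study$mrna, paths$mrna_path)
  write_expression(study$mirna, paths$mirna_path)
  write_trait_table(study$traits, paths$trait_path)
  write_interactions(study$interactions, paths$interaction_path)

  gt <- study$ground_truth
  part <- data.frame(
    feature_id = c(names(gt$gene_partition), names(gt$mirna_partition)),
    planted_module = c(unname(gt$gene_partition), unname(gt$mirna_partition)),
    stringsAsFactors = FALSE)
  write_table_with_schema(
    part, file.path(dir, "ground_truth_partition.tsv"),
    "feature_id, planted_module (0 = background)")
  jsonlite::write_json(
    list(trait_module = gt$trait_module,
         planted_regulators = gt$planted_regulators),
    file.path(dir, "ground_truth_regulators.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths
}
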