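#' Simulation design for a two-group modular expression study
#'
#' Describes the synthetic world the generators produce: a normal/tumor
#' two-group sample structure, planted equicorrelated co-expression
#' modules, independent background noise features, a tumor mean shift on
#' designated features, and the noise level of the quantitative trait
#' derived from a module eigengene.
#'
#' @param n_samples Total number of samples.
#' @param group_sizes Integer pair `c(normal, tumor)` summing to
#'   `n_samples`.
#' @param module_sizes Integer vector of planted module sizes (may be
#'   empty for a pure-noise matrix).
#' @param within_module_cor Expected pairwise Pearson correlation inside
#'   each planted module, strictly in (0, 1).
#' @param background_features Number of independent noise features.
#' @param de_effect_size Mean shift (in units of the unit residual
#'   standard deviation) added to tumor samples of differentially
#'   expressed features; 0 disables the shift.
#' @param de_modules Indices of the modules whose features receive the
#'   shift; defaults to all planted modules.
#' @param trait_noise_sd Standard deviation of the Gaussian noise added
#'   when a trait is generated from an eigengene.
#' @param seed Integer seed; the whole design is reproducible from it.
#'
#' @return An object of class `simulation_design` (a validated list).
#' @export
simulation_design <- function(n_samples = 70L,
                              group_sizes = c(normal = 20L, tumor = 50L),
                              module_sizes = c(50L, 50L, 50L, 50L, 50L),
                              within_module_cor = 0.7,
                              background_features = 100L,
                              de_effect_size = 0,
                              de_modules = NULL,
                              trait_noise_sd = 0.5,
                              seed = 1L) {
  fail <- function(field, msg) {
    stop(sprintf("invalid simulation design: `%s` %s", field, msg),
         call. = FALSE)
  }
  if (length(n_samples) != 1L || n_samples < 2 || n_samples != round(n_samples))
    fail("n_samples", "must be a single positive integer >= 2")
  if (length(group_sizes) != 2L || any(group_sizes < 1) ||
      any(group_sizes != round(group_sizes)))
    fail("group_sizes", "must be a pair of positive integers")
  if (sum(group_sizes) != n_samples)
    fail("group_sizes", "must sum to n_samples")
  if (length(module_sizes) > 0 &&
      (any(module_sizes < 1) || any(module_sizes != round(module_sizes))))
    fail("module_sizes", "must be positive integers")
  if (length(within_module_cor) != 1L || !is.finite(within_module_cor) ||
      within_module_cor <= 0 || within_module_cor >= 1)
    fail("within_module_cor", "must lie strictly between 0 and 1")
  if (length(background_features) != 1L || background_features < 0 ||
      background_features != round(background_features))
    fail("background_features", "must be a non-negative integer")
  if (length(de_effect_size) != 1L || !is.finite(de_effect_size) ||
      de_effect_size < 0)
    fail("de_effect_size", "must be a non-negative real")
  if (is.null(de_modules)) de_modules <- seq_along(module_sizes)
  if (length(de_modules) > 0 &&
      !all(de_modules %in% seq_along(module_sizes)))
    fail("de_modules", "must index planted modules")
  if (length(trait_noise_sd) != 1L || !is.finite(trait_noise_sd) ||
      trait_noise_sd < 0)
    fail("trait_noise_sd", "must be a non-negative real")
  if (length(seed) != 1L || !is.finite(seed) || seed != round(seed))
    fail("seed", "must be a single integer")

  structure(
    list(n_samples = as.integer(n_samples),
         group_sizes = stats::setNames(as.integer(group_sizes),
                                       c("normal", "tumor")),
         module_sizes = as.integer(module_sizes),
         within_module_cor = within_module_cor,
         background_features = as.integer(background_features),
         de_effect_size = de_effect_size,
         de_modules = as.integer(de_modules),
         trait_noise_sd = trait_noise_sd,
         seed = as.integer(seed)),
    class = "simulation_design")
}

sample_names_for <- function(design) {
  c(sprintf("normal_%02d", seq_len(design$group_sizes[["normal"]])),
    sprintf("tumor_%02d", seq_len(design$group_sizes[["tumor"]])))
}

#' Sample group labels of a design
#'
#' @param design A [simulation_design()].
#' @return Factor of length `n_samples` with levels `normal`, `tumor`
#'   in the on-disk column order (normals first).
#' @export
group_labels <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  factor(rep(c("normal", "tumor"), design$group_sizes),
         levels = c("normal", "tumor"))
}

#' Generate an expression matrix with planted co-expression modules
#'
#' Each planted module is built from a latent-factor block model: every
#' member equals `sqrt(rho) * factor + sqrt(1 - rho) * noise` with a
#' shared standard-normal per-sample factor, so the expected pairwise
#' correlation inside the module is exactly `rho = within_module_cor`
#' and each feature has unit variance. Background features are
#' independent standard normal. If `de_effect_size > 0`, features of
#' the designated modules get the shift added to their tumor columns.
#'
#' @param design A [simulation_design()].
#' @param layer `"mRNA"` or `"miRNA"`; controls feature id prefixes
#'   (`gene_*` / `mir_*`) and the matrix's `layer` attribute.
#'
#' @return List with elements
#'   * `expression`: numeric features x samples matrix (attribute
#'     `layer` records the data layer),
#'   * `ground_truth`: list with `planted_partition` (named integer
#'     vector, 0 = background) and `de_features` (ids that were shifted).
#' @export
generate_modular_expression <- function(design, layer = c("mRNA", "miRNA")) {
  stopifnot(inherits(design, "simulation_design"))
  layer <- match.arg(layer)
  prefix <- if (layer == "mRNA") "gene" else "mir"
  n <- design$n_samples
  p_mod <- sum(design$module_sizes)
  p <- p_mod + design$background_features
  if (p == 0L) {
    stop("invalid simulation design: `module_sizes`/`background_features` ",
         "describe an empty matrix", call. = FALSE)
  }
  rho <- design$within_module_cor
  ids <- sprintf("%s_%04d", prefix, seq_len(p))

  x <- with_seed(design$seed, {
    out <- matrix(NA_real_, nrow = p, ncol = n)
    row <- 1L
    for (size in design$module_sizes) {
      f <- stats::rnorm(n)
      noise <- matrix(stats::rnorm(size * n), nrow = size)
      out[row:(row + size - 1L), ] <-
        sqrt(rho) * matrix(f, nrow = size, ncol = n, byrow = TRUE) +
        sqrt(1 - rho) * noise
      row <- row + size
    }
    if (design$background_features > 0L) {
      out[row:p, ] <- matrix(stats::rnorm(design$background_features * n),
                             nrow = design$background_features)
    }
    out
  })
  dimnames(x) <- list(ids, sample_names_for(design))

  partition <- rep.int(0L, p)
  if (length(design$module_sizes) > 0) {
    partition[seq_len(p_mod)] <- rep(seq_along(design$module_sizes),
                                     design$module_sizes)
  }
  names(partition) <- ids

  de_features <- character(0)
  if (design$de_effect_size > 0 && length(design$de_modules) > 0) {
    de_features <- ids[partition %in% design$de_modules]
    tumor_cols <- group_labels(design) == "tumor"
    x[de_features, tumor_cols] <- x[de_features, tumor_cols] +
      design$de_effect_size
  }
  attr(x, "layer") <- layer

  list(expression = x,
       ground_truth = list(planted_partition = partition,
                           de_features = de_features))
}

#' Generate a quantitative trait from a module eigengene
#'
#' The trait is the eigengene plus independent Gaussian noise, giving
#' the module-trait association stage a recoverable ground truth: for a
#' unit-variance eigengene the expected trait correlation is
#' `1 / sqrt(1 + trait_noise_sd^2)`.
#'
#' @param eigengene Numeric per-sample vector.
#' @param trait_noise_sd Non-negative noise standard deviation.
#' @param seed Integer seed.
#' @return Numeric trait vector, named like `eigengene`.
#' @export
generate_trait <- function(eigengene, trait_noise_sd, seed) {
  if (!is.numeric(eigengene) || length(eigengene) < 1L) {
    stop("`eigengene` must be a non-empty numeric per-sample vector",
         call. = FALSE)
  }
  if (trait_noise_sd < 0) {
    stop("`trait_noise_sd` must be non-negative", call. = FALSE)
  }
  noise <- with_seed(seed, stats::rnorm(length(eigengene), 0, trait_noise_sd))
  stats::setNames(as.numeric(eigengene) + noise, names(eigengene))
}

#' Generate a multi-source scored miRNA-gene interaction table
#'
#' Emulates aggregated target-prediction output: a random subset of the
#' miRNA x gene grid at the given density, each candidate edge scored
#' uniformly in (0, 1) per simulated source database. Planted edges are
#' always present and re-scored at or above the stated quantile of each
#' source's score distribution, so they survive rank-based selection.
#'
#' @param mirna_ids,gene_ids Character vectors of unique identifiers.
#' @param density Fraction of the full grid retained, in (0, 1].
#' @param planted Optional two-column data frame (`mirna`, `gene`) of
#'   edges that must be present with high scores.
#' @param planted_score_quantile Quantile (of each source's scores)
#'   planted edges are lifted to; default 0.9.
#' @param n_sources Number of simulated score columns.
#' @param seed Integer seed.
#'
#' @return Data frame with columns `mirna`, `gene`,
#'   `score_db1..score_db<K>`, sorted by (`mirna`, `gene`).
#' @export
generate_interaction_table <- function(mirna_ids, gene_ids, density,
                                       planted = NULL,
                                       planted_score_quantile = 0.9,
                                       n_sources = 3L, seed = 1L) {
  stopifnot(length(mirna_ids) > 0, length(gene_ids) > 0,
            !anyDuplicated(mirna_ids), !anyDuplicated(gene_ids))
  if (length(density) != 1L || density <= 0 || density > 1) {
    stop("`density` must lie in (0, 1]", call. = FALSE)
  }
  if (!is.null(planted)) {
    planted <- as.data.frame(planted)
    names(planted)[1:2] <- c("mirna", "gene")
    bad <- !(planted$mirna %in% mirna_ids) | !(planted$gene %in% gene_ids)
    if (any(bad)) {
      stop("planted pairs reference unknown identifiers: ",
           paste(paste(planted$mirna[bad], planted$gene[bad], sep = "->"),
                 collapse = ", "), call. = FALSE)
    }
  }

  grid <- expand.grid(mirna = mirna_ids, gene = gene_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_grid <- nrow(grid)
  n_edges <- ceiling(density * n_grid)

  with_seed(seed, {
    keep <- sort(sample.int(n_grid, n_edges))
    tab <- grid[keep, , drop = FALSE]
    if (!is.null(planted) && nrow(planted) > 0) {
      key <- paste(tab$mirna, tab$gene, sep = "\r")
      pkey <- paste(planted$mirna, planted$gene, sep = "\r")
      missing <- !(pkey %in% key)
      if (any(missing)) {
        tab <- rbind(tab, planted[missing, c("mirna", "gene")])
      }
    }
    m <- nrow(tab)
    scores <- matrix(stats::runif(m * n_sources), nrow = m)
    if (!is.null(planted) && nrow(planted) > 0) {
      pkey <- paste(planted$mirna, planted$gene, sep = "\r")
      idx <- match(pkey, paste(tab$mirna, tab$gene, sep = "\r"))
      for (s in seq_len(n_sources)) {
        # quantile of the background score distribution, so the lifted
        # planted scores stay at or above it after re-scoring
        q <- stats::quantile(scores[-idx, s], planted_score_quantile,
                             names = FALSE)
        scores[idx, s] <- stats::runif(length(idx), q, 1)
      }
    }
    colnames(scores) <- sprintf("score_db%d", seq_len(n_sources))
    tab <- cbind(tab, as.data.frame(scores))
    tab <- tab[order(tab$mirna, tab$gene), , drop = FALSE]
    rownames(tab) <- NULL
    tab
  })
}

#' Simulate a complete paired-layer study
#'
#' Convenience generator assembling everything [run_pipeline()] needs:
#' an mRNA layer and a miRNA layer with planted modules and tumor-shifted
#' features, a sample trait table (binary tumor status plus a
#' quantitative trait generated from a chosen gene module's eigengene),
#' and a scored interaction table enriched for planted hub-miRNA to
#' gene-module edges.
#'
#' @param n_samples,group_sizes,within_module_cor,de_effect_size,trait_noise_sd
#'   Passed to [simulation_design()] for both layers.
#' @param gene_module_sizes,mirna_module_sizes Module sizes per layer.
#' @param gene_background,mirna_background Background feature counts.
#' @param trait_module Gene-module index the quantitative trait derives
#'   from.
#' @param regulator_mirnas How many miRNAs of the first miRNA module act
#'   as planted regulators.
#' @param target_fraction Fraction of the trait module's genes each
#'   planted regulator targets.
#' @param interaction_density Background density of the interaction grid.
#' @param planted_score_quantile Score quantile planted edges are lifted
#'   to.
#' @param seed Master seed; layer/trait/interaction seeds are small
#'   offsets of it.
#'
#' @return List with `mrna`, `mirna` (expression matrices), `traits`
#'   (sample x trait data frame with `group` coded 0/1), `interactions`,
#'   and `ground_truth` (per-layer planted partitions, `trait_module`,
#'   `planted_regulators`).
#' @export
simulate_study <- function(n_samples = 70L,
                           group_sizes = c(normal = 20L, tumor = 50L),
                           gene_module_sizes = c(50L, 50L, 50L),
                           mirna_module_sizes = c(12L, 10L),
                           within_module_cor = 0.7,
                           gene_background = 100L,
                           mirna_background = 20L,
                           de_effect_size = 2,
                           trait_noise_sd = 0.5,
                           trait_module = 1L,
                           regulator_mirnas = 1L,
                           target_fraction = 0.4,
                           interaction_density = 0.05,
                           planted_score_quantile = 0.9,
                           seed = 1L) {
  seed <- as.integer(seed)
  gene_design <- simulation_design(
    n_samples = n_samples, group_sizes = group_sizes,
    module_sizes = gene_module_sizes,
    within_module_cor = within_module_cor,
    background_features = gene_background,
    de_effect_size = de_effect_size,
    trait_noise_sd = trait_noise_sd, seed = seed)
  mirna_design <- simulation_design(
    n_samples = n_samples, group_sizes = group_sizes,
    module_sizes = mirna_module_sizes,
    within_module_cor = within_module_cor,
    background_features = mirna_background,
    de_effect_size = de_effect_size,
    trait_noise_sd = trait_noise_sd, seed = seed + 101L)

  genes <- generate_modular_expression(gene_design, layer = "mRNA")
  mirnas <- generate_modular_expression(mirna_design, layer = "miRNA")

  if (!trait_module %in% seq_along(gene_module_sizes)) {
    stop("`trait_module` must index a planted gene module", call. = FALSE)
  }
  members <- names(genes$ground_truth$planted_partition)[
    genes$ground_truth$planted_partition == trait_module]
  planted_me <- module_eigengene(
    genes$expression[members, , drop = FALSE],
    stats::setNames(rep("turquoise", length(members)), members))
  me_vec <- planted_me$eigengenes[, 1L]
  if (length(me_vec) != n_samples) {
    stop("eigengene length does not match the sample count", call. = FALSE)
  }
  stage <- generate_trait(me_vec, trait_noise_sd, seed = seed + 202L)

  grp <- group_labels(gene_design)
  traits <- data.frame(group = as.integer(grp == "tumor"),
                       stage = as.numeric(stage),
                       row.names = colnames(genes$expression))

  mirna_part <- mirnas$ground_truth$planted_partition
  regulators <- names(mirna_part)[mirna_part == 1L]
  regulators <- regulators[seq_len(min(regulator_mirnas, length(regulators)))]
  n_targets <- ceiling(target_fraction * length(members))
  planted_pairs <- with_seed(seed + 303L, {
    do.call(rbind, lapply(regulators, function(r) {
      data.frame(mirna = r, gene = sample(members, n_targets),
                 stringsAsFactors = FALSE)
    }))
  })

  interactions <- generate_interaction_table(
    mirna_ids = rownames(mirnas$expression),
    gene_ids = rownames(genes$expression),
    density = interaction_density,
    planted = planted_pairs,
    planted_score_quantile = planted_score_quantile,
    seed = seed + 404L)

  list(mrna = genes$expression,
       mirna = mirnas$expression,
       traits = traits,
       interactions = interactions,
       ground_truth = list(
         gene_partition = genes$ground_truth$planted_partition,
         mirna_partition = mirna_part,
         gene_de_features = genes$ground_truth$de_features,
         mirna_de_features = mirnas$ground_truth$de_features,
         trait_module = as.integer(trait_module),
         planted_regulators = planted_pairs))
}
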