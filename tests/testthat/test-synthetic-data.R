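test_that("simulation design validation names the offending field", {
  expect_error(simulation_design(n_samples = 0), "n_samples")
  expect_error(simulation_design(group_sizes = c(10, 10)), "group_sizes")
  expect_error(simulation_design(within_module_cor = 1), "within_module_cor")
  expect_error(simulation_design(within_module_cor = 0), "within_module_cor")
  expect_error(simulation_design(background_features = -1),
               "background_features")
  expect_error(simulation_design(de_effect_size = -0.5), "de_effect_size")
  expect_error(simulation_design(de_modules = 9), "de_modules")
  expect_error(simulation_design(trait_noise_sd = -1), "trait_noise_sd")
})

test_that("planted modules reach the designed within-module correlation", {
  # tight module: expected pairwise correlation 0.99
  d <- simulation_design(n_samples = 50, group_sizes = c(20, 30),
                         module_sizes = 10, within_module_cor = 0.99,
                         background_features = 0, seed = 11)
  sim <- generate_modular_expression(d)
  s <- cor(t(sim$expression))
  expect_gt(mean(s[upper.tri(s)]), 0.9)

  # calibration: mean off-diagonal correlation converges to the design
  # value (checked at n = 2000, absolute tolerance 0.05)
  d2 <- simulation_design(n_samples = 2000, group_sizes = c(1000, 1000),
                          module_sizes = 30, within_module_cor = 0.7,
                          background_features = 0, seed = 12)
  s2 <- cor(t(generate_modular_expression(d2)$expression))
  expect_lt(abs(mean(s2[upper.tri(s2)]) - 0.7), 0.05)
})

test_that("background features are uncorrelated noise", {
  d <- simulation_design(n_samples = 50, group_sizes = c(20, 30),
                         module_sizes = integer(0),
                         background_features = 100, seed = 5)
  sim <- generate_modular_expression(d)
  expect_true(all(sim$ground_truth$planted_partition == 0L))
  s <- cor(t(sim$expression))
  expect_lt(mean(abs(s[upper.tri(s)])), 0.15)
})

test_that("expression generation is deterministic and fully labeled", {
  d <- simulation_design(seed = 3)
  a <- generate_modular_expression(d)
  b <- generate_modular_expression(d)
  expect_identical(a$expression, b$expression)

  part <- a$ground_truth$planted_partition
  expect_identical(sort(names(part)), sort(rownames(a$expression)))
  expect_identical(dim(a$expression),
                   c(sum(d$module_sizes) + d$background_features,
                     d$n_samples))
  expect_false(identical(
    a$expression,
    generate_modular_expression(simulation_design(seed = 4))$expression))
})

test_that("tumor shift lands on designated features only", {
  d <- simulation_design(module_sizes = c(30, 30), de_effect_size = 2,
                         de_modules = 1, background_features = 40,
                         seed = 8)
  sim <- generate_modular_expression(d)
  grp <- group_labels(d)
  diffs <- rowMeans(sim$expression[, grp == "tumor"]) -
    rowMeans(sim$expression[, grp == "normal"])
  shifted <- names(diffs) %in% sim$ground_truth$de_features
  expect_identical(sum(shifted), 30L)
  expect_gt(min(diffs[shifted]), 1)     # 2 sd shift, unit-variance noise
  expect_lt(max(abs(diffs[!shifted])), 1)
})

test_that("trait generation follows the eigengene plus noise model", {
  me <- rnorm(50)
  expect_identical(cor(generate_trait(me, 0, seed = 1), me), 1)
  expect_identical(generate_trait(me, 1, seed = 2),
                   generate_trait(me, 1, seed = 2))
  expect_false(identical(generate_trait(me, 1, seed = 2),
                         generate_trait(me, 1, seed = 3)))
  expect_error(generate_trait(numeric(0), 1, seed = 1), "eigengene")
  expect_error(generate_trait(me, -1, seed = 1), "trait_noise_sd")

  # closed form: cor = 1/sqrt(1 + sigma^2) ~ 0.707 at sigma = 1 for a
  # unit-variance eigengene, Monte-Carlo checked at n = 2000
  set.seed(41)
  me_big <- as.numeric(scale(rnorm(2000)))
  trait <- generate_trait(me_big, 1, seed = 42)
  expect_lt(abs(cor(trait, me_big) - 1 / sqrt(2)), 0.05)
})

test_that("interaction tables honor density, planting, and determinism", {
  full <- generate_interaction_table(paste0("m", 1:3), paste0("g", 1:4),
                                     density = 1.0, seed = 1)
  expect_identical(nrow(full), 12L)
  expect_true(all(c("mirna", "gene", "score_db1", "score_db2",
                    "score_db3") %in% names(full)))

  expect_identical(
    generate_interaction_table(paste0("m", 1:5), paste0("g", 1:20),
                               density = 0.5, seed = 9),
    generate_interaction_table(paste0("m", 1:5), paste0("g", 1:20),
                               density = 0.5, seed = 9))

  expect_error(
    generate_interaction_table(paste0("m", 1:3), paste0("g", 1:4),
                               density = 0.5,
                               planted = data.frame(mirna = "m9",
                                                    gene = "g1"),
                               seed = 1),
    "unknown identifiers")
  expect_error(
    generate_interaction_table("m1", "g1", density = 0), "density")
})

test_that("planted edges score above the stated quantile and survive the 20% cut", {
  mirnas <- sprintf("m%02d", 1:10)
  genes <- sprintf("g%02d", 1:40)
  planted <- data.frame(mirna = "m01", gene = genes[1:8])
  tab <- generate_interaction_table(mirnas, genes, density = 0.3,
                                    planted = planted,
                                    planted_score_quantile = 0.9,
                                    seed = 21)
  key <- paste(tab$mirna, tab$gene)
  idx <- match(paste(planted$mirna, planted$gene), key)
  expect_false(anyNA(idx))
  for (col in grep("^score", names(tab), value = TRUE)) {
    q_bg <- quantile(tab[[col]][-idx], 0.9, names = FALSE)
    expect_true(all(tab[[col]][idx] >= q_bg - 1e-12))
  }

  kept <- select_top_interactions(rank_interactions(tab), fraction = 0.2)
  expect_true(all(paste(planted$mirna, planted$gene) %in%
                    paste(kept$mirna, kept$gene)))
})

test_that("simulate_study assembles a coherent paired-layer world", {
  study <- simulate_study(seed = 2)
  expect_identical(colnames(study$mrna), colnames(study$mirna))
  expect_identical(colnames(study$mrna), rownames(study$traits))
  expect_setequal(unique(study$traits$group), c(0L, 1L))

  gt <- study$ground_truth
  # the quantitative trait tracks the planted gene module's eigengene
  members <- names(gt$gene_partition)[gt$gene_partition == gt$trait_module]
  me <- module_eigengene(
    study$mrna[members, ],
    setNames(rep("turquoise", length(members)), members))
  expect_gt(abs(cor(study$traits$stage, me$eigengenes[, 1])), 0.8)

  # planted regulators reference real features on both sides
  expect_true(all(gt$planted_regulators$mirna %in% rownames(study$mirna)))
  expect_true(all(gt$planted_regulators$gene %in% rownames(study$mrna)))
})
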