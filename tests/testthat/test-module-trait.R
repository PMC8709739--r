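# A small world used across these tests: three planted modules with a
# trait generated from the first module's eigengene.
make_world <- function(seed = 17, noise_sd = 0.5) {
  d <- simulation_design(n_samples = 50, group_sizes = c(25, 25),
                         module_sizes = c(20, 15, 15),
                         within_module_cor = 0.8,
                         background_features = 30, seed = seed)
  sim <- generate_modular_expression(d)
  labels <- planted_labels(sim$ground_truth$planted_partition)
  me <- module_eigengene(sim$expression, labels)
  trait_mod <- colnames(me$eigengenes)[1]  # largest = planted module 1
  trait <- generate_trait(me$eigengenes[, trait_mod], noise_sd,
                          seed = seed + 1)
  list(x = sim$expression, labels = labels, me = me,
       trait = trait, trait_mod = trait_mod,
       truth = sim$ground_truth$planted_partition)
}

test_that("module eigengenes are unit-variance, oriented, rank-1 exact", {
  n <- 30
  x_shared <- matrix(rep(rnorm(n), 5), nrow = 5, byrow = TRUE,
                     dimnames = list(paste0("f", 1:5), NULL))
  labels <- setNames(rep("G-turquoise", 5), rownames(x_shared))
  me <- module_eigengene(x_shared, labels)
  expect_gt(abs(cor(me$eigengenes[, 1], x_shared[1, ])), 0.999)
  expect_equal(unname(me$variance_explained), 1, tolerance = 1e-12)
  expect_equal(sd(me$eigengenes[, 1]), 1, tolerance = 1e-12)

  # orientation: ME correlates non-negatively with the mean member
  # profile, so it is deterministic (and flips with the module)
  w <- make_world()
  for (m in colnames(w$me$eigengenes)) {
    members <- names(w$labels)[w$labels == m]
    xm <- zscore_normalize(w$x[members, ])
    expect_gte(cor(w$me$eigengenes[, m], colMeans(xm)), 0)
  }

  # single-feature module: standardized profile, with a warning
  one <- w$x[1, , drop = FALSE]
  expect_warning(
    me1 <- module_eigengene(one, setNames("G-blue", rownames(one))),
    "single feature")
  expect_equal(abs(cor(me1$eigengenes[, 1], one[1, ])), 1,
               tolerance = 1e-12)
})

test_that("two orthogonal equal sub-signals split the variance evenly", {
  n <- 400
  set.seed(23)
  u <- rnorm(n)
  v <- rnorm(n)
  x <- rbind(matrix(rep(u, 10), 10, byrow = TRUE) +
               0.01 * matrix(rnorm(10 * n), 10),
             matrix(rep(v, 10), 10, byrow = TRUE) +
               0.01 * matrix(rnorm(10 * n), 10))
  rownames(x) <- paste0("f", 1:20)
  me <- module_eigengene(x, setNames(rep("G-red", 20), rownames(x)))
  expect_equal(unname(me$variance_explained), 0.5, tolerance = 0.05)
})

test_that("the eigengene explains at least as much variance as any member", {
  set.seed(29)
  for (i in 1:5) {
    m <- sample(3:10, 1)
    n <- 40
    x <- matrix(rnorm(m * n), m, dimnames = list(paste0("f", 1:m), NULL))
    me <- module_eigengene(x, setNames(rep("G-tan", m), rownames(x)))
    ve_of <- function(v) mean(cor(t(zscore_normalize(x)), v)^2)
    member_ve <- apply(x, 1, ve_of)
    expect_gte(ve_of(me$eigengenes[, 1]), max(member_ve) - 1e-10)
  }
})

test_that("gene significance is absolute correlation with the trait", {
  set.seed(31)
  trait <- rnorm(50)
  x <- rbind(same = trait, flipped = -trait,
             noise = rnorm(50))
  gs <- gene_significance(x, trait)
  expect_equal(unname(gs["same"]), 1, tolerance = 1e-12)
  expect_equal(unname(gs["flipped"]), 1, tolerance = 1e-12)
  expect_lt(gs["noise"], 0.4)
  expect_error(gene_significance(x, rep(1, 50)), "constant")
  expect_error(gene_significance(x, trait[1:10]), "length")
})

test_that("module significance is the exact mean of member GS", {
  gs <- setNames(c(0.2, 0.4, 0.7, 0.1), paste0("f", 1:4))
  part <- setNames(c("G-blue", "G-blue", "G-red", "grey"), paste0("f", 1:4))
  ms <- module_significance(gs, part)
  expect_equal(ms$module_significance[ms$module == "G-blue"], 0.3)
  expect_equal(ms$module_significance[ms$module == "G-red"], 0.7)
  expect_true(ms$is_grey[ms$module == "grey"])

  # removing a member recomputes consistently
  ms2 <- module_significance(gs[-1], part[-1])
  expect_equal(ms2$module_significance[ms2$module == "G-blue"], 0.4)

  # the trait-linked planted module attains the highest MS
  w <- make_world()
  gs_all <- gene_significance(w$x, w$trait)
  ms_all <- module_significance(gs_all, w$labels)
  real <- ms_all[!ms_all$is_grey, ]
  expect_identical(real$module[which.max(real$module_significance)],
                   w$trait_mod)
})

test_that("module membership separates own-module from foreign features", {
  w <- make_world()
  mm <- module_membership(w$x, w$me)

  # a feature equal to its module's ME has MM 1
  x_aug <- rbind(w$x, probe = w$me$eigengenes[, w$trait_mod])
  mm_aug <- module_membership(x_aug, w$me)
  expect_equal(unname(mm_aug["probe", w$trait_mod]), 1, tolerance = 1e-12)

  # background features have small |MM|
  bg <- names(w$truth)[w$truth == 0]
  expect_lt(median(abs(mm[bg, ])), 0.4)

  # members score higher in their own module than in other modules
  for (m in colnames(mm)) {
    members <- names(w$labels)[w$labels == m]
    own <- abs(mm[members, m])
    other <- abs(mm[members, setdiff(colnames(mm), m)])
    expect_gt(median(own), median(other))
  }
})

test_that("module-trait correlation uses the exact t transform", {
  # orthonormal construction with correlation exactly 0.6 at n = 12
  n <- 12
  u <- as.numeric(scale(sin(1:n)))
  v <- residuals(lm(cos(1:n) ~ u))
  v <- as.numeric(scale(v))
  me <- structure(list(
    eigengenes = matrix(u, ncol = 1,
                        dimnames = list(paste0("s", 1:n), "G-turquoise")),
    variance_explained = c("G-turquoise" = 1)),
    class = "module_eigengenes")
  trait <- 0.6 * u + 0.8 * v
  mt <- module_trait_correlation(me, data.frame(t = trait))
  expect_equal(unname(mt$correlation[1, 1]), 0.6, tolerance = 1e-12)
  t_stat <- 0.6 * sqrt(n - 2) / sqrt(1 - 0.36)
  expect_equal(round(t_stat, 3), 2.372)
  expect_equal(unname(mt$p_value[1, 1]), 2 * pt(-t_stat, n - 2),
               tolerance = 1e-12)

  # perfect correlation reports p below machine threshold
  mt1 <- module_trait_correlation(me, data.frame(t = u))
  expect_equal(unname(mt1$correlation[1, 1]), 1, tolerance = 1e-12)
  expect_lt(mt1$p_value[1, 1], 1e-15)

  # constant trait column flagged undefined
  expect_warning(
    mtc <- module_trait_correlation(me, data.frame(t = trait, c = 1)),
    "constant")
  expect_true(is.na(mtc$correlation[1, "c"]))
})

test_that("permuted traits show no module association", {
  w <- make_world()
  set.seed(37)
  cors <- replicate(50, {
    mt <- module_trait_correlation(
      w$me, data.frame(t = sample(w$trait)))
    max(abs(mt$correlation))
  })
  expect_lt(mean(cors), 0.45)   # null |r| stays small at n = 50
})

test_that("eigengene networks mirror the feature correlation operation", {
  w <- make_world()
  en <- eigengene_network(w$me)
  expect_identical(en, correlation_matrix(t(w$me$eigengenes)))
  expect_identical(diag(en),
                   setNames(rep(1, ncol(en)), colnames(en)))

  # modules planted from independent factors are weakly correlated
  off <- en[upper.tri(en)]
  expect_lt(max(abs(off)), 0.4)
})

test_that("hub calling applies both thresholds with deterministic order", {
  mm <- matrix(c(0.9, 0.9, 0.85, 0.3), ncol = 1,
               dimnames = list(paste0("f", 1:4), "G-turquoise"))
  gs <- setNames(c(0.5, 0.1, 0.5, 0.9), paste0("f", 1:4))
  part <- setNames(rep("G-turquoise", 4), paste0("f", 1:4))
  hubs <- identify_hubs(mm, gs, part)
  # f1 qualifies (MM .9, GS .5); f2 fails GS; f4 fails MM
  expect_identical(hubs$feature, c("f1", "f3"))
  expect_error(identify_hubs(mm, gs, part, mm_min = 1.2), "mm_min")

  # a planted near-loading-1 feature in the trait module becomes a hub
  w <- make_world(noise_sd = 0.3)
  members <- names(w$labels)[w$labels == w$trait_mod]
  strong <- 0.95 * w$me$eigengenes[, w$trait_mod] +
    sqrt(1 - 0.95^2) * rnorm(ncol(w$x))
  x_aug <- rbind(w$x, planted_hub = strong)
  labels_aug <- c(w$labels, planted_hub = w$trait_mod)
  me_aug <- module_eigengene(x_aug, labels_aug)
  mm_aug <- module_membership(x_aug, me_aug)
  gs_aug <- gene_significance(x_aug, w$trait)
  hubs_aug <- identify_hubs(mm_aug, gs_aug, labels_aug)
  expect_true("planted_hub" %in%
                hubs_aug$feature[hubs_aug$module == w$trait_mod])
})
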