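test_that("rank-normal transform hits the normal quantiles and handles ties", {
  expect_equal(rank_normal_transform(c(1, 2, 3)),
               qnorm(c(1, 3, 5) / 6), tolerance = 1e-12)
  # median of an odd-length sample maps to 0
  x <- c(10, -3, 2, 7, 100)
  expect_equal(rank_normal_transform(x)[x == 7], 0)
  # average ranks for ties (also the all-identical degenerate case)
  expect_warning(zt <- rank_normal_transform(c(5, 5)), "identical")
  expect_equal(zt, c(0, 0))
  # missing values are preserved and ignored
  z <- rank_normal_transform(c(1, NA, 2, 3))
  expect_true(is.na(z[2]))
  expect_equal(z[-2], qnorm(c(1, 3, 5) / 6))
  # monotone in the input
  set.seed(2)
  x <- rnorm(50)
  expect_identical(order(rank_normal_transform(x)), order(x))
  expect_warning(rank_normal_transform(c(4, 4, 4)), "identical")
})

test_that("rank-normal output is near-normal for skewed continuous input", {
  set.seed(12)
  x <- rexp(200)^2
  z <- rank_normal_transform(x)
  skew <- mean((z - mean(z))^3) / sd(z)^3
  expect_lt(abs(skew), 0.2)
  expect_equal(mean(z), 0, tolerance = 0.05)
})

test_that("variance decomposition matches hand-computed sums of squares", {
  # 2 strains x 2 environments x 2 replicates, known cell means
  cells <- expand.grid(strain = c("s1", "s2"), environment = c("e1", "e2"))
  mu <- c(10, 14, 20, 28) # s1e1 s2e1 s1e2 s2e2
  ph <- do.call(rbind, lapply(seq_len(4), function(i) {
    data.frame(strain = cells$strain[i], environment = cells$environment[i],
               replicate = 1:2, trait = "tr", value = mu[i] + c(-1, 1))
  }))
  dec <- decompose_variance(ph, "tr")
  y <- ph$value
  ss_tot <- sum((y - mean(y))^2)
  # balanced two-way SS by hand
  em <- tapply(y, ph$environment, mean)
  sm <- tapply(y, ph$strain, mean)
  cm <- tapply(y, paste(ph$strain, ph$environment), mean)
  ss_e <- 4 * sum((em - mean(y))^2)
  ss_s <- 4 * sum((sm - mean(y))^2)
  ss_cells <- 2 * sum((cm - mean(y))^2)
  ss_int <- ss_cells - ss_e - ss_s
  expect_equal(dec$ss, c(ss_e, ss_s, ss_int, ss_tot - ss_cells))
  expect_equal(dec$percent,
               100 * c(ss_e, ss_s, ss_int, ss_tot - ss_cells) / ss_tot)
  expect_equal(sum(dec$percent), 100, tolerance = 1e-9)
  # balanced design: order-invariant, so E-first equals a strain-first fit
  an2 <- anova(lm(value ~ strain + environment + strain:environment, data = ph))
  expect_equal(sort(dec$ss), sort(an2[["Sum Sq"]]), tolerance = 1e-9)
})

test_that("variance percents sum to 100 and E-only data gives no S terms", {
  g <- make_cross(n_strains = 30, seed = 21)
  ph <- simulate_phenotypes(g, NULL, env_means = env3,
                            strain_sd = 0, residual_sd = 0.05, seed = 4)
  dec <- decompose_variance(ph, "trait1")
  expect_equal(sum(dec$percent), 100, tolerance = 1e-9)
  expect_lt(dec$percent[dec$term == "S"], 2)
  expect_lt(dec$percent[dec$term == "S*E"], 2)
  expect_gt(dec$percent[dec$term == "E"], 95)

  # degenerate zero-variance table
  ph0 <- ph
  ph0$value <- 3
  dec0 <- decompose_variance(ph0, "trait1")
  expect_true(attr(dec0, "degenerate"))
  expect_equal(sum(dec0$ss), 0)
})

test_that("permutation p-values agree with F tests on strong effects", {
  g <- make_cross(n_strains = 15, seed = 22)
  qt <- qtl_effect(rownames(g$calls)[3], "tr",
                   c(SB14_Sk = 3, M15_Sk = 3, M15 = 3))
  ph <- simulate_phenotypes(g, qt, env_means = env3,
                            strain_sd = 0.1, residual_sd = 0.3, seed = 5)
  gt <- g$calls[3, ]
  dec <- decompose_variance(ph, "tr", unit = "genotype", genotype = gt,
                            n_perm = 99, seed = 6)
  expect_lt(dec$p[dec$term == "Q"], 0.05)
  expect_equal(sum(dec$percent), 100, tolerance = 1e-9)
})

test_that("heritability follows (sigmaP2 - sigmaE2) / sigmaP2", {
  # replicate variance zero -> h2 = 1
  ph <- data.frame(
    strain = rep(c("a", "b", "c", "d"), each = 2), environment = "E1",
    replicate = rep(1:2, 4), trait = "tr",
    value = rep(c(1, 2, 3, 4), each = 2)
  )
  expect_equal(heritability(ph, "tr", "E1")$h2, 1)

  # no strain differences: h2 ~ 0 (median replicate variance ~ population)
  set.seed(9)
  ph0 <- data.frame(
    strain = rep(sprintf("s%03d", 1:150), each = 40), environment = "E1",
    replicate = rep(1:40, 150), trait = "tr", value = rnorm(6000)
  )
  h0 <- heritability(ph0, "tr", "E1")
  expect_lt(abs(h0$h2), 0.1)
})

test_that("heritability recovers the generative value over 50 simulations", {
  # strain_sd^2 = 3 residual_sd^2 -> h2 = 0.75; 10 replicates keep the
  # median-of-replicate-variances close to residual_sd^2
  h <- numeric(50)
  for (i in seq_len(50)) {
    g <- make_cross(n_chr = 1, mpc = 2, n_strains = 100, seed = 100 + i)
    ph <- simulate_phenotypes(g, NULL, env_means = c(E1 = 0),
                              strain_sd = sqrt(3), residual_sd = 1,
                              n_replicates = 10, seed = 200 + i)
    h[i] <- heritability(ph, "trait1", "E1")$h2
  }
  expect_lt(abs(mean(h) - 0.75), 0.05)
})

test_that("transgression counts progeny beyond parental limits", {
  set.seed(13)
  pa <- rnorm(10, 0, 0.2)
  pb <- rnorm(10, 1, 0.2)
  # all progeny between the parental means -> 0%
  expect_equal(
    transgression_fraction(seq(0.1, 0.9, length.out = 9), pa, pb)$percent, 0
  )
  # a clone at high parent + 3 pooled SD is counted at k = 2
  tg <- transgression_fraction(c(mean(pb) + 3 * sd(c(pa - mean(pa), pb - mean(pb)))),
                               pa, pb, k = 2)
  expect_equal(tg$n_transgressive, 1)
  expect_error(transgression_fraction(1, pa, numeric(0)))
})

test_that("two additive QTLs in repulsion generate transgressive segregants", {
  frac <- function(res_sd, seed) {
    g <- make_cross(n_chr = 2, mpc = 2, len = 4e5, n_strains = 150,
                    seed = seed)
    mk <- rownames(g$calls)[c(1, 3)] # one marker per chromosome
    qts <- rbind(qtl_effect(mk[1], "tr", c(E1 = 1)),
                 qtl_effect(mk[2], "tr", c(E1 = -1)))
    ph <- simulate_phenotypes(g, qts, env_means = c(E1 = 0), strain_sd = 0,
                              residual_sd = res_sd, n_replicates = 4,
                              seed = seed + 1)
    means <- tapply(ph$value, ph$strain, mean)
    # parents: all-A carries +1/2 and -1/2 (sum 0), same for all-B
    set.seed(seed + 2)
    pa <- rnorm(10, 0, res_sd / 2)
    pb <- rnorm(10, 0, res_sd / 2)
    transgression_fraction(means, pa, pb)$percent
  }
  noisy <- frac(0.8, 31)
  clean <- frac(0.05, 31)
  expect_gt(clean, 0)
  expect_gt(clean, noisy)
})

test_that("phenotype distance is Euclidean on z-scored condition means", {
  # identical strains are at distance zero
  ph <- expand.grid(strain = c("x", "y", "z"), environment = c("e1", "e2"),
                    replicate = 1, trait = c("t1", "t2"),
                    stringsAsFactors = FALSE)
  ph$value <- ifelse(ph$strain == "z", 5, 1)
  D <- phenotype_distance(ph)
  expect_equal(D["x", "y"], 0)

  # strains one SD apart in each of 4 conditions -> distance sqrt(4)
  a <- sqrt(1.25) # with values (-.5, .5, a, -a), sd = 1 exactly
  ph2 <- expand.grid(strain = c("s1", "s2", "s3", "s4"),
                     environment = "e1", replicate = 1,
                     trait = c("t1", "t2", "t3", "t4"),
                     stringsAsFactors = FALSE)
  ph2$value <- rep(c(-0.5, 0.5, a, -a), 4)
  D2 <- phenotype_distance(ph2)
  expect_equal(D2["s1", "s2"], 2, tolerance = 1e-12)

  # zero-variance conditions are dropped with a warning
  ph3 <- ph2
  ph3$value[ph3$trait == "t4"] <- 1
  expect_warning(D3 <- phenotype_distance(ph3), "zero-variance")
  expect_equal(D3["s1", "s2"], sqrt(3), tolerance = 1e-12)

  # the t80g preset drops the other kinetic traits
  ph4 <- expand.grid(strain = c("p", "q", "r"), environment = "e1",
                     replicate = 1,
                     trait = c("t35g", "t80g", "glycerol"),
                     stringsAsFactors = FALSE)
  set.seed(3); ph4$value <- rnorm(nrow(ph4))
  D4 <- phenotype_distance(ph4, kinetics_preset = "t80g")
  expect_equal(attr(D4, "dim"), c(3L, 3L))
})

test_that("reaction-norm distance obeys the correlation rules", {
  n <- rbind(
    base = c(1, 2, 3),
    affine = 10 + 2.5 * c(1, 2, 3), # positive affine image: distance 0
    mirror = c(3, 2, 1), # correlation -1: distance 2
    flat = c(5, 5, 5),
    flat2 = c(-1, -1, -1)
  )
  D <- reaction_norm_distance(n)
  expect_equal(diag(D), rep(0, 5), ignore_attr = TRUE)
  expect_equal(D, t(D))
  expect_equal(D["base", "affine"], 0, tolerance = 1e-12)
  expect_equal(D["base", "mirror"], 2, tolerance = 1e-12)
  expect_equal(D["flat", "base"], 1)
  expect_equal(D["flat", "flat2"], 0)
  expect_true(all(D >= 0 & D <= 2))
})

test_that("reaction-norm distance is invariant to positive affine transforms", {
  set.seed(14)
  norms <- matrix(rnorm(60), 20, 3)
  rownames(norms) <- paste0("s", 1:20)
  D <- reaction_norm_distance(norms)
  shifted <- norms * rep(runif(20, 0.5, 4), 3) + rep(rnorm(20, 0, 10), 3)
  expect_equal(reaction_norm_distance(shifted), D, tolerance = 1e-10)
})

test_that("medoid clustering recovers planted norm shapes", {
  set.seed(15)
  shapes <- list(c(0, 1, 2), c(2, 1, 0)) # negatively correlated shapes
  norms <- do.call(rbind, lapply(1:2, function(k) {
    t(replicate(25, shapes[[k]] + rnorm(3, 0, 0.08)))
  }))
  rownames(norms) <- paste0("s", 1:50)
  truth <- rep(1:2, each = 25)
  cl <- cluster_reaction_norms(reaction_norm_distance(norms))
  expect_equal(cl$k, 2)
  # perfect recovery up to label switching
  expect_equal(length(unique(paste(cl$clustering, truth))), 2)
  expect_false(cl$degenerate)

  # identical norms: degenerate fallback to one cluster
  flatD <- reaction_norm_distance(matrix(rep(c(1, 2, 3), each = 8), 8, 3,
                                         byrow = FALSE))
  expect_error(cluster_reaction_norms(flatD[1:2, 1:2]))
  same <- matrix(rep(c(1, 2, 3), 8), 8, 3, byrow = TRUE) # all parallel
  cl0 <- cluster_reaction_norms(reaction_norm_distance(same))
  expect_true(cl0$degenerate)
  expect_equal(cl0$k, 1L)

  # k range is truncated to n - 1
  cl2 <- cluster_reaction_norms(reaction_norm_distance(norms[1:4, ]),
                                k_range = 2:10)
  expect_lte(cl2$k, 3)
})

test_that("ternary interaction profiles separate G, GM and u-Ox QTLs", {
  g <- make_cross(n_strains = 120, seed = 23)
  mk <- rownames(g$calls)[7]
  gt <- g$calls[mk, ]
  run <- function(effects) {
    ph <- simulate_phenotypes(g, qtl_effect(mk, "tr", effects),
                              env_means = env3, strain_sd = 0.1,
                              residual_sd = 0.2, seed = 8)
    qtl_interaction_profile(ph, "tr", gt)
  }
  # constant effect: G dominates, no significant interactions
  pg <- run(c(SB14_Sk = 1.5, M15_Sk = 1.5, M15 = 1.5))
  expect_gt(pg$g, 0.9)
  expect_true(pg$sig_g)
  expect_false(pg$sig_gm)
  expect_false(pg$sig_uox)
  expect_equal(pg$g + pg$gm + pg$uox, 1, tolerance = 1e-9)

  # effect only in the white must: grape-must interaction dominates
  pgm <- run(c(SB14_Sk = 1.5, M15_Sk = 0, M15 = 0))
  expect_gt(pgm$gm, pgm$uox)
  expect_true(pgm$sig_gm)

  # effect differing between shaken and unshaken red must: u-Ox dominates
  pox <- run(c(SB14_Sk = 1.5, M15_Sk = 1.5, M15 = 0))
  expect_gt(pox$uox, pox$gm)
  expect_true(pox$sig_uox)

  expect_error(
    qtl_interaction_profile(
      simulate_phenotypes(g, NULL, env_means = env3, seed = 1),
      "trait1", setNames(rep("A", length(gt)), names(gt))
    ), "monomorphic"
  )
})
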