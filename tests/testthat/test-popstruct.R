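test_that("F_ST hits its fixed-difference and panmictic limits", {
  ## two populations fixed for different alleles
  gA <- do.call(make_geno, c(rep(list(c("10/10")), 8), list(pop = rep("A", 8),
                                                            ids = sprintf("a%d", 1:8))))
  gB <- do.call(make_geno, c(rep(list(c("20/20")), 8), list(pop = rep("B", 8),
                                                            ids = sprintf("b%d", 1:8))))
  g <- rbind_geno(gA, gB)
  f <- pairwise_fst(g, n_perm = 99, seed = 1)
  expect_equal(f$estimate["A", "B"], 1)
  expect_lt(f$p_value["A", "B"], 0.05)
  ## two samples from one panmictic pool
  set.seed(21)
  freqs <- list(stats::setNames(rep(0.25, 4), 10:13),
                stats::setNames(rep(0.2, 5), 20:24))
  g1 <- sample_pop_geno(50, freqs, "A", ids = sprintf("a%d", 1:50))
  g2 <- sample_pop_geno(50, freqs, "B", ids = sprintf("b%d", 1:50))
  fnull <- pairwise_fst(rbind_geno(g1, g2), n_perm = 0)
  expect_lt(abs(fnull$estimate["A", "B"]), 0.02)
})

test_that("F_ST equals the nested-ANOVA variance-component oracle", {
  set.seed(77)
  for (r in 1:5) {
    cfg <- sim_config(seed = 400 + r, n_pops = 2, n_loci = 2,
                      effective_size = 10, n_generations = 15,
                      migration_matrix = 0)
    g <- gen_metapopulation(cfg)$genotypes
    expect_equal(wc_theta(g)$theta, oracle_theta(g), tolerance = 1e-10)
  }
})

test_that("R_ST limits and oracle equivalence on allele-size decompositions", {
  ## identical size distributions across groups
  set.seed(3)
  freqs <- list(stats::setNames(c(.3, .4, .3), c(10, 12, 14)))
  gA <- sample_pop_geno(40, freqs, "A", sprintf("a%d", 1:40))
  gB <- sample_pop_geno(40, freqs, "B", sprintf("b%d", 1:40))
  r0 <- pairwise_rst(rbind_geno(gA, gB), n_perm = 0)
  expect_lt(abs(r0$estimate["A", "B"]), 0.03)
  ## strongly shifted means, tiny within-variance -> R_ST -> 1
  gC <- do.call(make_geno, c(rep(list(c("10/10")), 6), list(pop = rep("A", 6),
                                                            ids = sprintf("c%d", 1:6))))
  gD <- do.call(make_geno, c(rep(list(c("40/40")), 6), list(pop = rep("B", 6),
                                                            ids = sprintf("d%d", 1:6))))
  r1 <- pairwise_rst(rbind_geno(gC, gD), n_perm = 0)
  expect_gt(r1$estimate["A", "B"], 0.95)
  ## toy set matches the aov-based oracle
  cfg <- sim_config(seed = 11, n_pops = 2, n_loci = 3, effective_size = 12,
                    n_generations = 10, migration_matrix = 0)
  g <- gen_metapopulation(cfg)$genotypes
  expect_equal(pairwise_rst(g, n_perm = 0)$estimate[1, 2], oracle_rst(g),
               tolerance = 1e-10)
})

test_that("AMOVA matches hand-computed sums of squares on a 2x2 hierarchy", {
  ## cluster X: pop1 {AA, AA}, pop2 {AB, AB}; cluster Y: pop3 {CC, CC},
  ## pop4 {CD, CD}. Hand decomposition: SS_T = 5, SS_AC = 3, SS_AP = 2,
  ## SS_WP = 0; sigma2 = (0.5, 0.5, 0).
  g <- make_geno(c("10/10"), c("10/10"), c("10/11"), c("10/11"),
                 c("20/20"), c("20/20"), c("20/21"), c("20/21"),
                 pop = rep(c("p1", "p2", "p3", "p4"), each = 2),
                 ids = sprintf("i%d", 1:8))
  cl <- rep(c("X", "Y"), each = 4)
  am <- amova(g, cluster = cl, n_perm = 99, seed = 1)
  expect_equal(am$components$ss, c(3, 2, 0))
  expect_equal(am$components$df, c(1, 2, 4))
  expect_equal(am$components$sigma2, c(0.5, 0.5, 0))
  expect_equal(sum(am$components$pct), 100, tolerance = 1e-9)
  expect_equal(unname(am$phi["phi_ct"]), 0.5)
  expect_equal(unname(am$phi["phi_sc"]), 1)
})

test_that("AMOVA degenerate limits: identical individuals, disjoint clusters", {
  gid <- do.call(make_geno, c(rep(list(c("10/10", "12/14")), 6),
                              list(pop = rep(c("p1", "p2"), each = 3),
                                   ids = sprintf("i%d", 1:6))))
  am0 <- amova(gid, n_perm = 49)
  expect_equal(am0$components$ss, c(0, 0))
  ## clusters fixed for disjoint alleles -> among-cluster share -> high
  g2 <- make_geno(c("10/10"), c("10/10"), c("30/30"), c("30/30"),
                  pop = c("p1", "p2", "p3", "p4"),
                  ids = sprintf("i%d", 1:4))
  am2 <- amova(g2, cluster = c("X", "X", "Y", "Y"), n_perm = 49)
  expect_gt(am2$components$pct[1], 99)
  ## one-level Phi_PT equals among/(among+within) from its own components
  set.seed(4)
  cfg <- sim_config(seed = 9, n_pops = 2, n_loci = 4, effective_size = 10,
                    n_generations = 15, migration_matrix = 0)
  g3 <- gen_metapopulation(cfg)$genotypes
  am3 <- amova(g3, n_perm = 19)
  s2 <- am3$components$sigma2
  expect_equal(unname(am3$phi["phi_pt"]), s2[1] / sum(s2))
})

test_that("Rousset linearization is exact and strictly increasing", {
  expect_equal(linearize(0), 0)
  expect_equal(linearize(0.5), 1)
  expect_equal(linearize(0.241), 0.241 / 0.759)
  x <- seq(0, 0.95, by = 0.05)
  expect_true(all(diff(linearize(x)) > 0))
  expect_warning(linearize(1), "Inf")
})

test_that("PCoA recovers collinear and planar configurations, keeps negatives", {
  pts <- cbind(c(0, 1, 2, 5), rep(0, 4))
  p1 <- pcoa(as.matrix(dist(pts)))
  expect_gt(p1$explained[1], 99.99)
  ## 2-D recovery up to rotation/reflection
  set.seed(8)
  xy <- matrix(rnorm(20), 10, 2)
  p2 <- pcoa(as.matrix(dist(xy)))
  expect_lt(procrustes_error(p2$coordinates[, 1:2], xy), 1e-8)
  ## cross-check against the classical-scaling reference implementation
  cs <- stats::cmdscale(as.matrix(dist(xy)), k = 2)
  expect_lt(procrustes_error(p2$coordinates[, 1:2], cs), 1e-8)
  ## non-Euclidean matrix: negative eigenvalues reported, not dropped
  d <- matrix(c(0, 1, 1, 1,
                1, 0, 1, 1,
                1, 1, 0, 3,
                1, 1, 3, 0), 4, 4)
  p3 <- pcoa(d)
  expect_true(any(p3$eigenvalues < -1e-8))
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("M ratio arithmetic follows k/(r+1) on ladders and gapped loci", {
  gfull <- make_geno(c("10/11"), c("11/12"), c("10/12"),
                     ids = sprintf("i%d", 1:3))
  bt <- bottleneck_suite(gfull, n_sim = 0, seed = 1)
  expect_equal(bt$m_ratio, 3 / 3)              # k=3, r=2 -> 1.0
  ggap <- make_geno(c("10/14"), c("10/10"), c("14/14"),
                    ids = sprintf("i%d", 1:3))
  bt2 <- bottleneck_suite(ggap, n_sim = 0, seed = 1)
  expect_equal(bt2$m_ratio, 2 / 5)             # k=2, r=4 -> 0.4
  expect_true(bt2$flag_small)
})

test_that("mode-shift histogram uses 0.05 classes and flags L shapes", {
  set.seed(12)
  ## equilibrium-like: many rare alleles -> lowest class modal
  freqs <- list(stats::setNames(c(.72, .1, .06, .04, .04, .02, .02),
                                10:16))
  g <- sample_pop_geno(60, freqs)
  bt <- bottleneck_suite(g, n_sim = 0)
  expect_equal(length(bt$mode_shift$histogram), 20)
  expect_true(bt$mode_shift$l_shaped)
  ## only intermediate-frequency alleles -> shifted mode
  g2 <- sample_pop_geno(60, list(stats::setNames(c(.5, .5), c(10, 12))))
  expect_false(bottleneck_suite(g2, n_sim = 0)$mode_shift$l_shaped)
})

test_that("heterozygosity-excess test separates equilibrium from a crash", {
  ## equilibrium populations should rarely signal excess
  ps <- vapply(1:4, function(r) {
    cfg <- sim_config(seed = 600 + r, n_pops = 1, n_loci = 8,
                      effective_size = 50, n_generations = 150,
                      migration_matrix = 0, mutation_rate = 5e-3)
    g <- gen_metapopulation(cfg)$genotypes
    bottleneck_suite(g, model = "TPM", n_sim = 60, seed = r)$wilcoxon_p
  }, 0)
  expect_gt(mean(ps > 0.05), 0.5)
})
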