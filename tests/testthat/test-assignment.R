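test_that("degenerate K = 1 clustering yields unit memberships and finite lnp", {
  set.seed(2)
  g <- sample_pop_geno(20, list(stats::setNames(c(.5, .5), c(10, 12))))
  cr <- gibbs_cluster(g, K = 1, iterations = 200, burnin = 50, seed = 1)
  expect_true(all(abs(cr$Q - 1) < 1e-12))
  expect_true(is.finite(cr$lnp))
  expect_true(all(abs(rowSums(cr$Q) - 1) < 1e-6))
})

test_that("two well-separated demes are recovered with confident memberships", {
  cfg <- sim_config(seed = 11, n_pops = 2, n_loci = 10, effective_size = 40,
                    n_generations = 120, migration_matrix = 0.005)
  g <- gen_metapopulation(cfg)$genotypes
  cr <- gibbs_cluster(g, K = 2, iterations = 500, burnin = 150, seed = 3)
  expect_true(all(abs(rowSums(cr$Q) - 1) < 1e-6))
  home_col <- c(which.max(colMeans(cr$Q[g$pop == "pop1", ])),
                which.max(colMeans(cr$Q[g$pop == "pop2", ])))
  expect_false(home_col[1] == home_col[2])
  qhome <- ifelse(g$pop == "pop1", cr$Q[, home_col[1]], cr$Q[, home_col[2]])
  expect_gt(mean(qhome > 0.8), 0.95)
})

test_that("replicate runs align by allele-frequency matching", {
  cfg <- sim_config(seed = 12, n_pops = 2, n_loci = 8, effective_size = 30,
                    n_generations = 80, migration_matrix = 0.005)
  g <- gen_metapopulation(cfg)$genotypes
  runs <- lapply(1:2, function(s)
    gibbs_cluster(g, K = 2, iterations = 300, burnin = 100, seed = s))
  al <- align_clusters(runs)
  ## after alignment the two runs agree on the dominant cluster
  agree <- mean(max.col(al[[1]]$Q) == max.col(al[[2]]$Q))
  expect_gt(agree, 0.9)
})

test_that("delta-K arithmetic picks the elbow and guards its preconditions", {
  fake <- function(K, lnp) structure(list(K = K, lnp = lnp),
                                     class = "cluster_result")
  runs <- c(lapply(c(-100.5, -99.5), function(x) fake(1, x)),
            lapply(c(-50.5, -49.5), function(x) fake(2, x)),
            lapply(c(-48.5, -47.5), function(x) fake(3, x)),
            lapply(c(-47.5, -46.5), function(x) fake(4, x)))
  dk <- delta_k(runs)
  expect_equal(dk$best_k, 2)
  ## |L(3) - 2 L(2) + L(1)| / sd = |(-48) - 2(-50) + (-100)| / sqrt(0.5)
  expect_equal(dk$table$delta_k[2], 48 / sqrt(0.5), tolerance = 1e-9)
  expect_error(delta_k(runs[1:4]), "3 consecutive")
  expect_warning(delta_k(c(runs, list(fake(4, -47.5), fake(4, -46.5))[0])), NA)
  ## zero replicate spread -> infinite delta-K flagged
  runs0 <- c(lapply(rep(-100, 2), function(x) fake(1, x)),
             lapply(rep(-50, 2), function(x) fake(2, x)),
             lapply(rep(-48, 2), function(x) fake(3, x)))
  expect_warning(delta_k(runs0), "infinite")
})

test_that("assignment likelihood matches the Dirichlet posterior-predictive", {
  ## single locus, two pops; hand computation of the predictive probability
  gA <- make_geno(c("10/10"), c("10/12"), pop = c("A", "A"), ids = c("a1", "a2"))
  gB <- make_geno(c("12/12"), c("12/12"), pop = c("B", "B"), ids = c("b1", "b2"))
  g <- rbind_geno(gA, gB)
  sc <- assignment_likelihood(g, leave_one_out = FALSE)
  ## pop A counts: 10 -> 3, 12 -> 1 (n = 4); k = 2 alleles, tau = 0.5
  ## P(a1 = 10/10 | A) = (3 + .5)(3 + 1.5)/((4 + 1)(5 + 1))
  expect_equal(sc$log10_A[1], log10(3.5 * 4.5 / (5 * 6)), tolerance = 1e-12)
  ## P(a1 | B): counts 10 -> 0, n = 4
  expect_equal(sc$log10_B[1], log10(0.5 * 1.5 / (5 * 6)), tolerance = 1e-12)
  ## heterozygote gets the factor 2: P(a2 = 10/12 | A)
  expect_equal(sc$log10_A[2], log10(2 * 3.5 * 1.5 / (5 * 6)), tolerance = 1e-12)
  ## equal frequencies everywhere -> equal likelihoods
  set.seed(6)
  freqs <- list(stats::setNames(c(.5, .5), c(10, 12)))
  ge <- rbind_geno(sample_pop_geno(30, freqs, "A", sprintf("a%d", 1:30)),
                   sample_pop_geno(30, freqs, "B", sprintf("b%d", 1:30)))
  sce <- assignment_likelihood(ge, leave_one_out = FALSE)
  ## pooled counts differ by sampling noise only; stat stays small
  expect_lt(stats::median(sce$stat), 0.5)
  ## statistic is nonnegative and 0 iff home is the argmax
  expect_true(all(sce$stat >= 0))
  expect_true(all((sce$stat == 0) == (sce$best == sce$home)))
})

test_that("statistic is invariant to adding a never-best population", {
  set.seed(14)
  fA <- list(stats::setNames(c(.8, .2), c(10, 12)))
  fB <- list(stats::setNames(c(.2, .8), c(10, 12)))
  fC <- list(stats::setNames(c(.5, .5), c(10, 12)))  # same allele support
  gA <- sample_pop_geno(25, fA, "A", sprintf("a%d", 1:25))
  gB <- sample_pop_geno(25, fB, "B", sprintf("b%d", 1:25))
  gC <- sample_pop_geno(25, fC, "C", sprintf("c%d", 1:25))
  s2 <- assignment_likelihood(rbind_geno(gA, gB))
  s3 <- assignment_likelihood(rbind_geno(gA, gB, gC))
  ## rows where C is not the argmax keep their statistic exactly
  keep <- s3$home != "C" & s3$best != "C"
  expect_gt(sum(keep), 20)
  expect_equal(s3$stat[keep], s2$stat[match(s3$id[keep], s2$id)],
               tolerance = 1e-9)
})

test_that("exclusion test: residents never flagged at stat 0; threshold is 100x", {
  cfg <- sim_config(seed = 15, n_pops = 2, n_loci = 8, effective_size = 30,
                    n_generations = 30, migration_matrix = 0)
  g <- gen_metapopulation(cfg)$genotypes
  dm <- detect_first_gen_migrants(g, n_sim = 500, alpha = 0.01, seed = 2)
  expect_false(any(dm$migrant[dm$stat == 0]))
  ## statistic 2.0 corresponds to a 100-fold likelihood ratio (log10 scale)
  expect_equal(10^2.0, 100)
  expect_true(all(dm$stat >= 0))
  expect_error(detect_first_gen_migrants(g[g$pop == "pop1", ]), "2 populations")
})

test_that("resident exclusion p-values are valid (sub-uniform) under panmixia", {
  ## the exclusion statistic has an atom at 0 (home = argmax), so resident
  ## p-values carry matching mass at 1; validity means P(p <= a) <= a + MC
  ## slack at every level, with a non-degenerate lower tail
  set.seed(18)
  freqs <- lapply(1:8, function(l) stats::setNames(rdirichlet_weights(5),
                                                   10:14))
  g <- rbind_geno(sample_pop_geno(100, freqs, "A", sprintf("a%d", 1:100)),
                  sample_pop_geno(100, freqs, "B", sprintf("b%d", 1:100)))
  dm <- detect_first_gen_migrants(g, n_sim = 1000, alpha = 0.01, seed = 3)
  for (a in c(0.01, 0.05, 0.1, 0.25))
    expect_lte(mean(dm$p_value <= a), a + 0.05)
  expect_gt(mean(dm$p_value <= 0.25), 0.05)
  expect_lt(mean(dm$migrant), 0.02)    # false positives bounded near alpha
})

test_that("two-generation ancestry: prior dominance and planted-migrant recovery", {
  cfg <- sim_config(seed = 11, n_pops = 2, n_loci = 10, effective_size = 40,
                    n_generations = 120, migration_matrix = 0.005)
  mp <- gen_metapopulation(cfg)
  mp2 <- plant_migrants(mp, data.frame(source = c("pop1", "pop1"),
                                       dest = c("pop2", "pop2"),
                                       generation = c(1, 2)), seed = 5)
  ## migprior = 0 is the closed-form all-resident answer
  a0 <- immigrant_ancestry(mp2$genotypes, migprior = 0)
  expect_true(all(a0$posterior$gen0 == 1))
  expect_error(immigrant_ancestry(mp2$genotypes, migprior = 1.2), "migprior")
  anc <- immigrant_ancestry(mp2$genotypes, migprior = 0.05, n_iter = 600,
                            burnin = 200, seed = 6)
  post <- anc$posterior
  expect_true(all(abs(post$gen0 + post$gen1_pop1 + post$gen1_pop2 +
                        post$gen2_pop1 + post$gen2_pop2 - 1) < 1e-9))
  migs <- mp2$ledger$migrants
  g1 <- post[post$id == migs$id[migs$generation == 1], ]
  expect_gt(g1$gen1_pop1, 0.9)
  g2 <- post[post$id == migs$id[migs$generation == 2], ]
  expect_gt(g2$gen2_pop1, g2$gen1_pop1)
  ## aggregate migration matrix: rows sum to 1, planted mass appears
  mr <- recent_migration_rates(anc)
  expect_equal(unname(rowSums(mr$m)), c(1, 1), tolerance = 1e-12)
  expect_gt(mr$m["pop2", "pop1"], 0.01)
  expect_true(all(diag(mr$m) <= 1))
})

test_that("parentage LOD: hand example, exclusion, rare-allele support", {
  fr <- list(freq = list(L01 = c(`10` = 0.1, `12` = 0.9)),
             n_copies = c(L01 = 200))
  class(fr) <- "allele_freqs"
  off <- make_geno(c("10/12"), ids = "off")
  par_aa <- make_geno(c("10/10"), ids = "cand")
  ## ratio = [(1-e) p(B) + e 2 p(A) p(B)] / (2 p(A) p(B)); e = 0 -> 1/(2 p(A))
  r0 <- parentage_lod(off, par_aa, fr, error_rate = 0)
  expect_equal(r0$lod, log(1 / (2 * 0.1)), tolerance = 1e-12)
  e <- 0.05
  re <- parentage_lod(off, par_aa, fr, error_rate = e)
  expect_equal(re$lod,
               log(((1 - e) * 0.9 + e * 2 * .1 * .9) / (2 * .1 * .9)),
               tolerance = 1e-12)
  ## Mendelian exclusion at zero error
  off_bb <- make_geno(c("12/12"), ids = "off2")
  par_cc <- make_geno(c("14/14"), ids = "cand2")
  fr2 <- list(freq = list(L01 = c(`12` = 0.5, `14` = 0.5)),
              n_copies = c(L01 = 100))
  class(fr2) <- "allele_freqs"
  expect_equal(parentage_lod(off_bb, par_cc, fr2, error_rate = 0)$lod, -Inf)
  ## candidate sharing a rare allele: positive per-locus support
  expect_gt(exp(r0$per_locus[1]), 1)
  expect_error(parentage_lod(make_geno(c(NA)), make_geno(c("10/10")), fr),
               "shared")
})

test_that("parentage thresholds come from simulation and order sensibly", {
  set.seed(9)
  freqs <- lapply(1:6, function(l) stats::setNames(rdirichlet_weights(6),
                                                   10:15))
  fr <- allele_frequencies(sample_pop_geno(80, freqs))
  thr <- parentage_thresholds(fr, error_rate = 0.02, n_off = 300,
                              n_cand = 25, seed = 4)
  expect_true(is.finite(thr$strict))
  expect_gte(thr$strict, thr$relaxed)
  ## true parents dominate the high-LOD tail
  expect_gt(mean(thr$sims$correct[thr$sims$lod >= thr$strict]), 0.9)
})

test_that("consensus designation handles empty and all-resident evidence", {
  b <- data.frame(id = c("x", "y"),
                  geneclass_stat = c(0, 0), geneclass_p = c(1, 1),
                  structure_migrant_p = c(0, 0), structure_gen1 = c(0, 0),
                  structure_gen2 = c(0, 0),
                  bayesass_migrant_p = c(0, 0), bayesass_gen1 = c(0, 0),
                  bayesass_gen2 = c(0, 0), q_nonhome_max = c(0.1, 0.2))
  out <- designate_migrants(b)
  expect_equal(as.character(out$status), c("resident", "resident"))
  ## missing columns count as failing, not erroring
  out2 <- designate_migrants(data.frame(id = "z", geneclass_stat = 3,
                                        geneclass_p = 0.001))
  expect_equal(as.character(out2$status), "resident")
})
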