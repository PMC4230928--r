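test_that("consensus calling follows the replicate-confirmation rule", {
  ## heterozygote in >= 2 replicates
  expect_equal(consensus_genotype(make_reps(c("10/12"), c("10/12")))$alleles[1, 1, ],
               c(a1 = 10L, a2 = 12L))
  ## homozygote needs 5 consistent replicates
  hom5 <- do.call(make_reps, rep(list(c("10/10")), 5))
  expect_equal(consensus_genotype(hom5)$alleles[1, 1, ], c(a1 = 10L, a2 = 10L))
  hom4 <- do.call(make_reps, rep(list(c("10/10")), 4))
  expect_true(all(is.na(consensus_genotype(hom4)$alleles)))
  ## dropout-consistent mixture resolves to the heterozygote
  mix <- make_reps(c("10/12"), c("10/10"), c("10/12"))
  expect_equal(consensus_genotype(mix)$alleles[1, 1, ], c(a1 = 10L, a2 = 12L))
  ## two confirmed conflicting heterozygotes: missing + flagged
  conf <- make_reps(c("10/12"), c("10/12"), c("13/14"), c("13/14"))
  cg <- consensus_genotype(conf)
  expect_true(all(is.na(cg$alleles)))
  expect_true(attr(cg, "conflict")[1])
})

test_that("individual matching merges recaptures and applies the locus filter", {
  L <- 11
  gt <- sprintf("%d/%d", 10:20, 12:22)
  s <- make_geno(gt, gt, ids = c("s1", "s2"))
  m <- match_individuals(s)
  expect_equal(n_samples(m$individuals), 1)
  expect_equal(length(m$recaptures[[1]]), 2)
  ## three mismatching loci: distinct individuals
  gt2 <- gt; gt2[1:3] <- c("30/31", "32/33", "34/35")
  s2 <- make_geno(gt, gt2, ids = c("s1", "s2"))
  expect_equal(n_samples(match_individuals(s2)$individuals), 2)
  ## a sample typed at 6 of 11 loci is excluded
  gt3 <- gt; gt3[7:11] <- NA
  s3 <- make_geno(gt, gt3, ids = c("s1", "s2"))
  m3 <- match_individuals(s3)
  expect_equal(m3$excluded, "s2")
  ## dropout-consistent single mismatch merges; flagged for review
  gt4 <- gt; gt4[1] <- "10/10"
  s4 <- make_geno(gt, gt4, ids = c("s1", "s2"))
  m4 <- match_individuals(s4)
  expect_equal(n_samples(m4$individuals), 1)
  expect_true(m4$review$merged[1])
  ## non-dropout single mismatch stays separate but is flagged
  gt5 <- gt; gt5[1] <- "30/31"
  s5 <- make_geno(gt, gt5, ids = c("s1", "s2"))
  m5 <- match_individuals(s5)
  expect_equal(n_samples(m5$individuals), 2)
  expect_false(m5$review$merged[1])
  expect_warning(match_individuals(make_geno(c("10/10", NA, NA))), "filter")
})

test_that("individual matching is input-order invariant", {
  set.seed(31)
  cfg <- sim_config(seed = 31, n_pops = 2, n_loci = 11, effective_size = 15,
                    n_generations = 20)
  g <- gen_metapopulation(cfg)$genotypes
  reps <- gen_noninvasive_samples(g, sim_config(dropout_rate = 0.1,
                                                replicate_count = 3), seed = 2)
  cons <- consensus_genotypes(reps, hom_min = 3)
  part <- function(gg) {
    m <- match_individuals(gg)
    sets <- lapply(m$recaptures, sort)
    sets[order(vapply(sets, `[`, "", 1))]
  }
  p1 <- part(cons)
  p2 <- part(cons[sample(n_samples(cons)), ])
  expect_identical(unname(p1), unname(p2))
})

test_that("allele frequencies normalize per locus and drop empty loci", {
  g <- make_geno(c("10/10", NA), c("10/12", NA))
  expect_warning(fr <- allele_frequencies(g), "omitted")
  expect_equal(unname(fr$freq[["L01"]]), c(0.75, 0.25))
  expect_equal(sum(fr$freq[["L01"]]), 1)
  expect_false("L02" %in% names(fr$freq))
})

test_that("sib identity probability matches full enumeration and its properties", {
  ## brute-force oracle at p = q = 0.5
  expect_equal(oracle_pi_sib(c(0.5, 0.5)), 0.59375)
  g <- sample_pop_geno(400, list(stats::setNames(c(.5, .5), c(10, 12))))
  fr <- list(freq = list(L1 = c(`10` = 0.5, `12` = 0.5)),
             n_copies = c(L1 = 800))
  class(fr) <- "allele_freqs"
  is1 <- identity_statistics(fr)
  expect_equal(is1$per_locus$pi_sib, 0.59375)
  ## oracle agreement at an asymmetric 3-allele locus
  p3 <- c(0.5, 0.3, 0.2)
  fr3 <- list(freq = list(L1 = stats::setNames(p3, c(8, 9, 10))),
              n_copies = c(L1 = 1000))
  class(fr3) <- "allele_freqs"
  expect_equal(identity_statistics(fr3)$per_locus$pi_sib, oracle_pi_sib(p3),
               tolerance = 1e-12)
  ## monomorphic locus forces identity
  frm <- list(freq = list(L1 = c(`10` = 1)), n_copies = c(L1 = 100))
  class(frm) <- "allele_freqs"
  ism <- identity_statistics(frm)
  expect_equal(ism$per_locus$pi_sib, 1)
  ## cumulative product over two identical loci
  fr2 <- list(freq = list(L1 = c(`10` = .5, `12` = .5),
                          L2 = c(`10` = .5, `12` = .5)),
              n_copies = c(L1 = 800, L2 = 800))
  class(fr2) <- "allele_freqs"
  expect_equal(unname(identity_statistics(fr2)$cumulative["pi_sib"]),
               0.59375^2, tolerance = 1e-12)
})

test_that("PI <= PI-sib and cumulative PI-sib decreases with added loci", {
  set.seed(17)
  for (r in 1:20) {
    k <- sample(2:8, 1)
    p <- as.numeric(rdirichlet_weights(k))
    fr <- list(freq = list(L1 = stats::setNames(p, seq_len(k) + 9)),
               n_copies = c(L1 = sample(20:200, 1)))
    class(fr) <- "allele_freqs"
    st <- identity_statistics(fr)
    expect_lte(st$per_locus$pi, st$per_locus$pi_sib + 1e-12)
    expect_lt(st$per_locus$pi_sib, 1)       # polymorphic => < 1
  }
})

test_that("diversity summaries: private alleles, He limits, singleton flags", {
  gA <- make_geno(c("10/10"), c("10/10"), pop = c("A", "A"), ids = c("a1", "a2"))
  gB <- make_geno(c("14/14"), c("14/14"), pop = c("B", "B"), ids = c("b1", "b2"))
  g <- rbind_geno(gA, gB)
  d <- diversity_summary(g)
  expect_equal(d$A$per_locus$private, 1)
  expect_equal(d$B$per_locus$private, 1)
  expect_equal(d$A$per_locus$he, 0)
  expect_equal(d$A$per_locus$ho, 0)
  ## He -> 0.5 at p = 0.5, large n (unbiased correction negligible)
  set.seed(5)
  gg <- sample_pop_geno(500, list(stats::setNames(c(.5, .5), c(10, 12))))
  dd <- diversity_summary(gg)
  expect_lt(abs(dd$pop1$per_locus$he - 0.5), 0.03)
  ## allele-count bookkeeping matches an independent tally
  cfg <- sim_config(seed = 8, n_pops = 4, n_loci = 5, effective_size = 20,
                    n_generations = 20)
  gm <- gen_metapopulation(cfg)$genotypes
  ds <- diversity_summary(gm)
  for (p in unique(gm$pop)) {
    gi <- gm[which(gm$pop == p), ]
    tally <- vapply(seq_along(gi$loci), function(l)
      length(unique(stats::na.omit(c(gi$alleles[, l, ])))), 0L)
    expect_equal(ds[[p]]$per_locus$a, tally)
  }
  ## singleton group: He flagged NA
  g1 <- make_geno(c("10/12"), pop = "solo")
  expect_true(is.na(diversity_summary(g1)$solo$per_locus$he))
})

test_that("HWE exact test rejects pure-heterozygote excess, passes monomorphic", {
  allhet <- do.call(make_geno, rep(list(c("10/12")), 50))
  expect_lt(hwe_test(allhet, 1, n_perm = 999, seed = 1), 0.01)
  mono <- do.call(make_geno, rep(list(c("10/10")), 30))
  expect_equal(hwe_test(mono, 1, n_perm = 99), 1)
  expect_error(hwe_test(make_geno(c("10/12")), 1), "at least 5")
})

test_that("LD test flags perfect association and Bonferroni is available", {
  set.seed(9)
  ## locus 2 duplicates locus 1's genotype classes -> perfect association
  a <- sample(c("10/10", "10/12", "12/12"), 60, TRUE)
  b <- ifelse(a == "10/10", "20/20", ifelse(a == "10/12", "20/22", "22/22"))
  g <- do.call(make_geno, lapply(seq_along(a), function(i) c(a[i], b[i])))
  expect_lt(ld_test(g, c(1, 2), n_perm = 499, seed = 2), 0.01)
  ## Bonferroni through the standard adjustment
  p <- c(0.001, 0.02, 0.5)
  expect_equal(stats::p.adjust(p, "bonferroni"), pmin(1, p * 3))
})
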