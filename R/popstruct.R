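#' Weir-Cockerham theta for a set of groups
#'
#' Variance-components estimator of F_ST: components a (among populations),
#' b (among individuals within populations) and c (within individuals) are
#' accumulated over alleles and loci; theta = sum(a) / sum(a + b + c).
#'
#' @param g a [geno_set()]
#' @param groups group labels per individual (defaults to `g$pop`)
#' @return list with `theta` and the summed components `a`, `b`, `c`
#' @export
wc_theta <- function(g, groups = g$pop) {
  groups <- as.character(groups)
  A <- B <- C <- 0
  for (l in seq_along(g$loci)) {
    a1 <- g$alleles[, l, 1]; a2 <- g$alleles[, l, 2]
    ok <- !is.na(a1)
    if (sum(ok) < 2) next
    gl <- groups[ok]; x1 <- a1[ok]; x2 <- a2[ok]
    pops <- unique(gl)
    r <- length(pops)
    if (r < 2) next
    ni <- vapply(pops, function(p) sum(gl == p), 0)
    if (any(ni < 1)) next
    alleles <- unique(c(x1, x2))
    nbar <- mean(ni)
    nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
    for (al in alleles) {
      p_i <- vapply(pops, function(p) {
        idx <- gl == p
        (sum(x1[idx] == al) + sum(x2[idx] == al)) / (2 * sum(idx))
      }, 0)
      h_i <- vapply(pops, function(p) {
        idx <- gl == p
        mean(x1[idx] != x2[idx] & (x1[idx] == al | x2[idx] == al))
      }, 0)
      pbar <- sum(ni * p_i) / sum(ni)
      s2 <- sum(ni * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ni * h_i) / sum(ni)
      if (nbar <= 1) next
      a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                    hbar * (2 * nbar - 1) / (4 * nbar))
      cc <- hbar / 2
      A <- A + a; B <- B + b; C <- C + cc
    }
  }
  denom <- A + B + C
  list(theta = if (denom > 0) A / denom else 0, a = A, b = B, c = C)
}

#' Pairwise F_ST matrix (Weir-Cockerham) with permutation p-values
#'
#' @param g a [geno_set()]
#' @param groups group labels (defaults to `g$pop`)
#' @param n_perm permutations per pair (0 skips testing)
#' @param seed integer seed
#' @return list of class `gen_dist`: `estimate` (symmetric matrix, raw
#'   theta), `clipped` (negatives floored at 0), `p_value`, `estimator`
#' @export
pairwise_fst <- function(g, groups = g$pop, n_perm = 999L, seed = 1L) {
  pairwise_stat_matrix(g, groups, n_perm, seed, estimator = "fst",
                       statfun = function(gi, gr) wc_theta(gi, gr)$theta)
}

#' Pairwise R_ST matrix (allele-size variance components)
#'
#' One-way variance decomposition of microsatellite allele size (repeat
#' count) into among- and within-population components, summed over loci;
#' R_ST = sigma2_among / (sigma2_among + sigma2_within). Permutation tests
#' permute individuals between the pair.
#'
#' @inheritParams pairwise_fst
#' @return as [pairwise_fst()], `estimator = "rst"`
#' @export
pairwise_rst <- function(g, groups = g$pop, n_perm = 999L, seed = 1L) {
  pairwise_stat_matrix(g, groups, n_perm, seed, estimator = "rst",
                       statfun = function(gi, gr) rst_stat(gi, gr))
}

rst_stat <- function(g, groups) {
  SA <- SW <- 0
  for (l in seq_along(g$loci)) {
    a1 <- g$alleles[, l, 1]; a2 <- g$alleles[, l, 2]
    ok <- !is.na(a1)
    if (sum(ok) < 2) next
    sizes <- c(a1[ok], a2[ok])
    gl <- rep(groups[ok], 2)
    pops <- unique(gl)
    if (length(pops) < 2) next
    nj <- vapply(pops, function(p) sum(gl == p), 0)
    N <- sum(nj); r <- length(pops)
    gm <- mean(sizes)
    mj <- vapply(pops, function(p) mean(sizes[gl == p]), 0)
    ssa <- sum(nj * (mj - gm)^2)
    ssw <- sum((sizes - mj[match(gl, pops)])^2)
    if (N - r <= 0) next
    msa <- ssa / (r - 1); msw <- ssw / (N - r)
    n0 <- (N - sum(nj^2) / N) / (r - 1)
    s2a <- (msa - msw) / n0
    SA <- SA + s2a; SW <- SW + msw
  }
  if (SA + SW <= 0) 0 else SA / (SA + SW)
}

pairwise_stat_matrix <- function(g, groups, n_perm, seed, estimator, statfun) {
  groups <- as.character(groups)
  pops <- unique(groups)
  if (length(pops) < 2) stop("need at least 2 groups")
  K <- length(pops)
  est <- pmat <- matrix(0, K, K, dimnames = list(pops, pops))
  set.seed(seed)
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    idx <- which(groups %in% pops[c(i, j)])
    gi <- g[idx, ]; gr <- groups[idx]
    obs <- statfun(gi, gr)
    est[i, j] <- est[j, i] <- obs
    if (n_perm > 0) {
      cnt <- 0L
      for (r in seq_len(n_perm))
        if (statfun(gi, sample(gr)) >= obs - 1e-12) cnt <- cnt + 1L
      pmat[i, j] <- pmat[j, i] <- (cnt + 1) / (n_perm + 1)
    } else pmat[i, j] <- pmat[j, i] <- NA_real_
  }
  structure(list(estimate = est, clipped = pmax(est, 0), p_value = pmat,
                 estimator = estimator, n_perm = n_perm),
            class = "gen_dist")
}

#' @method print gen_dist
#' @export
print.gen_dist <- function(x, ...) {
  cat("Pairwise", toupper(x$estimator), "matrix (raw estimates):\n")
  print(round(x$estimate, 4))
  invisible(x)
}

## per-pair squared genetic distance: allele differences over shared loci
geno_dist2 <- function(g) {
  n <- n_samples(g); L <- length(g$loci)
  a1 <- allele_slice(g, 1); a2 <- allele_slice(g, 2)
  d <- matrix(0, n, n, dimnames = list(g$ids, g$ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- !is.na(a1[i, ]) & !is.na(a1[j, ])
    if (!any(shared)) { d[i, j] <- d[j, i] <- NA; next }
    tot <- 0
    for (l in which(shared)) {
      gi <- c(a1[i, l], a2[i, l]); gj <- c(a1[j, l], a2[j, l])
      ## multiset overlap: 2 - |intersection| allele differences
      inter <- 0
      gj2 <- gj
      for (al in gi) { m <- match(al, gj2); if (!is.na(m)) { inter <- inter + 1; gj2 <- gj2[-m] } }
      tot <- tot + (2 - inter)
    }
    d[i, j] <- d[j, i] <- tot
  }
  d
}

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Partitions the squared inter-individual genetic distance (allele
#' differences summed over shared loci) among clusters, among populations
#' within clusters, and within populations. Significance at each level by
#' permutation: whole populations among clusters (among-cluster level) and
#' individuals among populations within their cluster (among-population
#' level). Negative variance components are floored at zero for the
#' percentage report; raw values are retained.
#'
#' @param g a [geno_set()]
#' @param pop population label per individual
#' @param cluster cluster label per individual (constant within population);
#'   omit for a one-level AMOVA
#' @param n_perm permutations
#' @param seed integer seed
#' @return list of class `amova`: `components` data.frame (source, df, ss,
#'   ms, sigma2, sigma2_raw, pct), `phi` (named vector: phi_ct, phi_sc,
#'   phi_st — or phi_pt for one level), `p_value`
#' @export
amova <- function(g, pop = g$pop, cluster = NULL, n_perm = 999L, seed = 1L) {
  d2 <- geno_dist2(g)
  if (any(is.na(d2))) stop("individual pairs with no shared loci")
  if (is.null(cluster)) return(amova_onelevel(d2, pop, n_perm, seed))
  amova_twolevel(d2, pop, cluster, n_perm, seed)
}

ss_within <- function(d2, f) {
  tot <- 0
  for (lev in unique(f)) {
    idx <- which(f == lev)
    if (length(idx) > 1) tot <- tot + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  tot
}

amova_decomp1 <- function(d2, pop) {
  N <- nrow(d2); G <- length(unique(pop))
  ss_t <- sum(d2[upper.tri(d2)]) / N
  ss_w <- ss_within(d2, pop)
  ss_a <- ss_t - ss_w
  df_a <- G - 1; df_w <- N - G
  ms_a <- ss_a / df_a; ms_w <- if (df_w > 0) ss_w / df_w else 0
  ng <- table(pop)
  n0 <- (N - sum(ng^2) / N) / df_a
  s2w <- ms_w
  s2a <- (ms_a - ms_w) / n0
  list(ss = c(a = ss_a, w = ss_w, t = ss_t), df = c(a = df_a, w = df_w),
       ms = c(a = ms_a, w = ms_w), s2 = c(a = s2a, w = s2w))
}

amova_onelevel <- function(d2, pop, n_perm, seed) {
  dec <- amova_decomp1(d2, pop)
  phi_obs <- phi_from(dec$s2["a"], dec$s2["w"])
  set.seed(seed)
  cnt <- 0L
  for (r in seq_len(n_perm)) {
    pp <- sample(pop)
    dd <- amova_decomp1(d2, pp)
    if (phi_from(dd$s2["a"], dd$s2["w"]) >= phi_obs - 1e-12) cnt <- cnt + 1L
  }
  s2c <- pmax(dec$s2, 0)
  comp <- data.frame(
    source = c("among populations", "within populations"),
    df = dec$df, ss = dec$ss[1:2], ms = dec$ms,
    sigma2_raw = as.numeric(dec$s2), sigma2 = as.numeric(s2c),
    pct = 100 * as.numeric(s2c) / sum(s2c))
  structure(list(components = comp,
                 phi = c(phi_pt = phi_obs),
                 p_value = c(phi_pt = (cnt + 1) / (n_perm + 1))),
            class = "amova")
}

phi_from <- function(sa, sw) {
  tot <- sa + sw
  if (tot <= 0) 0 else as.numeric(sa / tot)
}

amova_twolevel <- function(d2, pop, cluster, n_perm = 999L, seed = 1L) {
  ## drop clusters holding a single population from the among-within level
  tabs <- table(unique(data.frame(pop, cluster))$cluster)
  singles <- names(tabs)[tabs < 2]
  note <- if (length(singles))
    paste("clusters with one population excluded from within-cluster df:",
          paste(singles, collapse = ", ")) else NULL
  dec <- amova_decomp2(d2, pop, cluster)
  set.seed(seed)
  ## permutation at each level
  phi_obs <- dec$phi
  cnt_ct <- cnt_sc <- cnt_st <- 0L
  popmap <- unique(data.frame(pop, cluster, stringsAsFactors = FALSE))
  for (r in seq_len(n_perm)) {
    ## among clusters: permute population assignments to clusters
    perm_cl <- stats::setNames(sample(popmap$cluster), popmap$pop)
    dd <- amova_decomp2(d2, pop, as.character(perm_cl[pop]))
    if (dd$phi["phi_ct"] >= phi_obs["phi_ct"] - 1e-12) cnt_ct <- cnt_ct + 1L
    ## among pops within clusters: permute individuals within cluster
    pp <- pop
    for (cl in unique(cluster)) {
      idx <- which(cluster == cl)
      pp[idx] <- sample(pop[idx])
    }
    dd <- amova_decomp2(d2, pp, cluster)
    if (dd$phi["phi_sc"] >= phi_obs["phi_sc"] - 1e-12) cnt_sc <- cnt_sc + 1L
    ## total: permute individuals freely
    ord <- sample(length(pop))
    dd <- amova_decomp2(d2, pop[ord], cluster[ord])
    if (dd$phi["phi_st"] >= phi_obs["phi_st"] - 1e-12) cnt_st <- cnt_st + 1L
  }
  s2c <- pmax(dec$s2, 0)
  comp <- data.frame(
    source = c("among clusters", "among populations within clusters",
               "within populations"),
    df = as.numeric(dec$df), ss = as.numeric(dec$ss), ms = as.numeric(dec$ms),
    sigma2_raw = as.numeric(dec$s2), sigma2 = as.numeric(s2c),
    pct = 100 * as.numeric(s2c) / sum(s2c))
  p <- c(phi_ct = (cnt_ct + 1) / (n_perm + 1),
         phi_sc = (cnt_sc + 1) / (n_perm + 1),
         phi_st = (cnt_st + 1) / (n_perm + 1))
  structure(list(components = comp, phi = phi_obs, p_value = p, note = note),
            class = "amova")
}

amova_decomp2 <- function(d2, pop, cluster) {
  N <- nrow(d2)
  pops <- unique(pop); P <- length(pops)
  cls <- unique(cluster); C <- length(cls)
  ss_t <- sum(d2[upper.tri(d2)]) / N
  ss_wp <- ss_within(d2, pop)
  ss_wc <- ss_within(d2, cluster)
  ss_ap <- ss_wc - ss_wp
  ss_ac <- ss_t - ss_wc
  df_ac <- C - 1; df_ap <- P - C; df_wp <- N - P
  ms_wp <- if (df_wp > 0) ss_wp / df_wp else 0
  ms_ap <- if (df_ap > 0) ss_ap / df_ap else 0
  ms_ac <- if (df_ac > 0) ss_ac / df_ac else 0
  np <- table(pop)
  nc <- table(cluster)
  clus_of_pop <- vapply(pops, function(p) cluster[match(p, pop)], "")
  sum_np2_by_c <- vapply(cls, function(cl) {
    pp <- pops[clus_of_pop == cl]
    sum(np[pp]^2) / nc[[cl]]
  }, 0)
  n1 <- if (df_ap > 0) (N - sum(sum_np2_by_c)) / df_ap else 1
  n2 <- if (df_ac > 0) (sum(sum_np2_by_c) - sum(np^2) / N) / df_ac else 1
  n3 <- if (df_ac > 0) (N - sum(nc^2) / N) / df_ac else 1
  s2c <- ms_wp
  s2b <- if (df_ap > 0) (ms_ap - s2c) / n1 else 0
  s2a <- if (df_ac > 0) (ms_ac - s2c - n2 * s2b) / n3 else 0
  s2 <- c(a = s2a, b = s2b, c = s2c)
  s2p <- pmax(s2, 0)
  tot <- sum(s2p)
  phi <- c(phi_ct = if (tot > 0) s2p[["a"]] / tot else 0,
           phi_sc = if (s2p[["b"]] + s2p[["c"]] > 0) s2p[["b"]] / (s2p[["b"]] + s2p[["c"]]) else 0,
           phi_st = if (tot > 0) (s2p[["a"]] + s2p[["b"]]) / tot else 0)
  list(ss = c(ac = ss_ac, ap = ss_ap, wp = ss_wp),
       df = c(ac = df_ac, ap = df_ap, wp = df_wp),
       ms = c(ac = ms_ac, ap = ms_ap, wp = ms_wp), s2 = s2, phi = phi)
}

#' Pairwise Phi_PT matrix from one-level AMOVA
#'
#' @inheritParams pairwise_fst
#' @return a `gen_dist` with `estimator = "phi_pt"`
#' @export
pairwise_phipt <- function(g, groups = g$pop, n_perm = 999L, seed = 1L) {
  pairwise_stat_matrix(g, groups, n_perm, seed, estimator = "phi_pt",
                       statfun = function(gi, gr) {
                         dec <- amova_decomp1(geno_dist2(gi), gr)
                         phi_from(max(dec$s2["a"], 0), max(dec$s2["w"], 0))
                       })
}

#' Rousset linearization d / (1 - d)
#'
#' Applied elementwise to matrices; a value of 1 maps to `Inf` with a
#' warning. Strictly increasing on \[0, 1).
#'
#' @param d differentiation value(s) or matrix (`gen_dist` accepted)
#' @return same shape as input
#' @export
linearize <- function(d) {
  if (inherits(d, "gen_dist")) d <- d$clipped
  if (any(d >= 1, na.rm = TRUE)) warning("d = 1 linearizes to Inf")
  d / (1 - d)
}

#' Principal coordinates analysis (metric MDS)
#'
#' Double-centering eigendecomposition of a symmetric distance matrix.
#' Coordinates are returned for axes with positive eigenvalues; negative
#' eigenvalues (non-Euclidean input) are reported, not dropped silently.
#'
#' @param d symmetric zero-diagonal distance matrix (or `gen_dist`)
#' @param squared if `TRUE`, `d` already holds squared distances
#' @return list of class `pcoa`: `coordinates`, `eigenvalues`,
#'   `explained` (percent of the positive-eigenvalue total per axis)
#' @export
pcoa <- function(d, squared = FALSE) {
  if (inherits(d, "gen_dist")) { d <- d$clipped; squared <- TRUE }
  d <- as.matrix(d)
  if (max(abs(d - t(d))) > 1e-8) stop("matrix must be symmetric")
  n <- nrow(d)
  d2 <- if (squared) d else d^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% d2 %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- e$values > 1e-10 * max(abs(e$values), 1e-300)
  coords <- if (any(pos))
    e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]), sum(pos))
  else matrix(0, n, 1)
  rownames(coords) <- rownames(d)
  explained <- if (any(pos)) 100 * e$values[pos] / sum(e$values[pos]) else 0
  structure(list(coordinates = coords, eigenvalues = e$values,
                 explained = explained), class = "pcoa")
}

#' Genetic bottleneck diagnostics for one group
#'
#' Three classic diagnostics: (a) the M ratio, `mean over loci of
#' k / (r + 1)` with `k` the allele count and `r` the allelic size range in
#' repeat units (values below 0.68 suggest a bottleneck); (b) the
#' heterozygosity-excess test — for each locus the expected equilibrium
#' heterozygosity conditional on the observed allele count and sample size
#' is obtained by coalescent simulation under the stepwise (SMM) or
#' two-phase (TPM) mutation model with rejection on the allele count, and a
#' one-tailed Wilcoxon signed-rank test across loci asks whether observed
#' gene diversity systematically exceeds it; (c) the mode-shift test on
#' 0.05-wide allele-frequency classes (L-shaped iff the lowest class is
#' modal).
#'
#' @param g a [geno_set()]
#' @param group label of the group to test (default: all of `g`)
#' @param model `"TPM"` or `"SMM"`
#' @param ss single-step fraction of the TPM
#' @param variance variance of the TPM multi-step tail
#' @param n_sim accepted coalescent simulations per locus
#' @param seed integer seed
#' @return list of class `bottleneck`: `m_ratio`, `m_per_locus`,
#'   `wilcoxon_p` (heterozygosity excess), `dh` standardized differences,
#'   `mode_shift` (class histogram, `l_shaped` flag), `n`, `flag_small`
#' @export
bottleneck_suite <- function(g, group = NULL, model = c("TPM", "SMM"),
                             ss = 0.95, variance = 12, n_sim = 1000L,
                             seed = 1L) {
  model <- match.arg(model)
  if (!is.null(group)) g <- g[which(g$pop == group), ]
  n <- n_samples(g)
  set.seed(seed)
  mval <- numeric(0); dh <- numeric(0)
  freqs_all <- numeric(0)
  for (l in seq_along(g$loci)) {
    a <- g$alleles[, l, 1]; b <- g$alleles[, l, 2]
    ok <- !is.na(a)
    if (sum(ok) < 2) next
    copies <- c(a[ok], b[ok])
    k <- length(unique(copies)); r <- diff(range(copies))
    mval <- c(mval, k / (r + 1))
    p <- as.numeric(table(copies)) / length(copies)
    freqs_all <- c(freqs_all, p)
    if (k < 2) next  # monomorphic: no heterozygosity information
    nn <- length(copies)
    he_obs <- nn / (nn - 1) * (1 - sum(p^2))
    sims <- simulate_eq_het(nn, k, model, ss, variance, n_sim)
    if (length(sims) >= 20 && stats::sd(sims) > 0)
      dh <- c(dh, (he_obs - mean(sims)) / stats::sd(sims))
  }
  wp <- if (length(dh) >= 4)
    stats::wilcox.test(dh, mu = 0, alternative = "greater")$p.value
  else NA_real_
  classes <- cut(freqs_all, breaks = seq(0, 1, by = 0.05), include.lowest = TRUE)
  hist_counts <- table(classes)
  l_shaped <- which.max(hist_counts) == 1L
  structure(list(m_ratio = mean(mval), m_per_locus = mval,
                 wilcoxon_p = wp, dh = dh,
                 mode_shift = list(histogram = hist_counts, l_shaped = l_shaped),
                 n = n, flag_small = n < 5, model = model),
            class = "bottleneck")
}

## coalescent simulation of equilibrium gene diversity conditional on the
## observed allele count: adaptive theta, rejection on k
simulate_eq_het <- function(n_copies, k_obs, model, ss, variance, n_sim,
                            max_batches = 200L) {
  theta <- max(0.5, k_obs - 1)
  acc <- numeric(0)
  pg <- tpm_geom_p(variance)
  batch <- max(20L, ceiling(n_sim / 10))
  for (it in seq_len(max_batches)) {
    ks <- numeric(batch)
    for (s in seq_len(batch)) {
      al <- sim_coalescent_msat(n_copies, theta, model, ss, pg)
      tab <- table(al)
      ks[s] <- length(tab)
      if (ks[s] == k_obs) {
        p <- as.numeric(tab) / n_copies
        acc <- c(acc, n_copies / (n_copies - 1) * (1 - sum(p^2)))
      }
    }
    if (length(acc) >= n_sim) break
    ## steer theta toward the observed allele count
    mk <- mean(ks)
    theta <- theta * exp(0.5 * (k_obs - mk) / max(k_obs, 1))
    theta <- min(max(theta, 0.05), 100)
  }
  acc
}

## one coalescent genealogy with stepwise / two-phase mutations
sim_coalescent_msat <- function(n, theta, model, ss, pg) {
  state <- integer(n)          # allele states relative to the ancestor
  active <- seq_len(n)         # lineage -> leaf-set representative
  leafsets <- as.list(seq_len(n))
  k <- n
  while (k > 1) {
    tk <- stats::rexp(1, k * (k - 1) / 2)
    ## mutations on all k lineages during tk: rate theta/2 each
    nmut <- stats::rpois(1, k * tk * theta / 2)
    if (nmut > 0) for (m in seq_len(nmut)) {
      lin <- sample.int(k, 1)
      step <- if (model == "SMM" || stats::runif(1) < ss) 1L
              else 1L + stats::rgeom(1, pg)
      step <- step * sample(c(-1L, 1L), 1)
      idx <- leafsets[[lin]]
      state[idx] <- state[idx] + step
    }
    pair <- sample.int(k, 2)
    i <- min(pair); j <- max(pair)
    leafsets[[i]] <- c(leafsets[[i]], leafsets[[j]])
    leafsets[[j]] <- NULL
    k <- k - 1L
  }
  state
}
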