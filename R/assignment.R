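## ---- internal genotype coding -------------------------------------------

## integer-code alleles per locus across the whole data set
code_alleles <- function(g) {
  L <- length(g$loci)
  codes <- vector("list", L)
  a1 <- allele_slice(g, 1); a2 <- allele_slice(g, 2)
  c1 <- c2 <- matrix(NA_integer_, n_samples(g), L)
  for (l in seq_len(L)) {
    al <- sort(unique(c(a1[, l], a2[, l])))
    al <- al[!is.na(al)]
    codes[[l]] <- al
    c1[, l] <- match(a1[, l], al)
    c2[, l] <- match(a2[, l], al)
  }
  list(c1 = c1, c2 = c2, alleles = codes,
       k = vapply(codes, length, 0L))
}

## per-population allele-copy count matrices: list per locus of J x k_l
pop_counts <- function(cd, pop) {
  pops <- unique(pop)
  lapply(seq_along(cd$k), function(l) {
    m <- matrix(0L, length(pops), cd$k[l], dimnames = list(pops, NULL))
    for (j in seq_along(pops)) {
      idx <- which(pop == pops[j])
      cc <- c(cd$c1[idx, l], cd$c2[idx, l])
      cc <- cc[!is.na(cc)]
      if (length(cc)) {
        t <- tabulate(cc, cd$k[l])
        m[j, ] <- t
      }
    }
    m
  })
}

## row-wise categorical sampling from an unnormalised weight matrix
sample_rows <- function(w) {
  K <- ncol(w)
  if (K == 1L) return(rep(1L, nrow(w)))
  cs <- w
  for (k in 2:K) cs[, k] <- cs[, k - 1] + cs[, k]
  u <- stats::runif(nrow(w)) * cs[, K]
  max.col(cs >= u, ties.method = "first")
}

rdirichlet1 <- function(shape) {
  x <- stats::rgamma(length(shape), shape)
  if (sum(x) == 0) x <- rep(1, length(shape))
  x / sum(x)
}

## ---- admixture clustering ------------------------------------------------

#' Bayesian admixture clustering by Gibbs sampling
#'
#' The standard admixture model: each allele copy originates from one of `K`
#' clusters; cluster allele frequencies carry an uncorrelated Dirichlet
#' (lambda = 1) prior, individual membership vectors Q a symmetric
#' Dirichlet(alpha) prior with alpha updated by a Metropolis step. The
#' model log-likelihood estimator reported as `lnp` is the usual
#' `mean(logL) - var(logL)/2` over post-burn-in sweeps.
#'
#' @param g a [geno_set()]
#' @param K number of clusters
#' @param iterations total Gibbs sweeps
#' @param burnin sweeps discarded
#' @param locprior if `TRUE`, the membership prior is informed by sampling
#'   locality (locality mean membership, weight `locprior_weight`)
#' @param locprior_weight pseudo-count weight of the locality prior
#' @param alpha initial admixture concentration
#' @param seed integer seed
#' @return list of class `cluster_result`: `K`, `Q` (posterior mean, rows
#'   sum to 1), `P` (posterior-mean cluster allele frequencies), `lnp`,
#'   `loglik` trace, `alpha`, run metadata
#' @export
gibbs_cluster <- function(g, K, iterations = 2000L, burnin = 500L,
                          locprior = FALSE, locprior_weight = 10,
                          alpha = 1, seed = 1L) {
  stopifnot(K >= 1, iterations > burnin)
  set.seed(seed)
  cd <- code_alleles(g)
  n <- n_samples(g); L <- length(g$loci)
  lambda <- 1
  loc <- match(g$pop, unique(g$pop))
  nloc <- max(loc)
  ## init
  P <- lapply(seq_len(L), function(l)
    matrix(rdirichlet_rows(K, rep(lambda, cd$k[l])), K, cd$k[l]))
  Q <- matrix(1 / K, n, K)
  Qsum <- matrix(0, n, K)
  Psum <- lapply(seq_len(L), function(l) matrix(0, K, cd$k[l]))
  loglik <- numeric(iterations)
  nkeep <- 0L
  z1 <- z2 <- matrix(NA_integer_, n, L)
  for (it in seq_len(iterations)) {
    ## allele-copy cluster assignments + data log-likelihood
    ll <- 0
    m_ik <- matrix(0, n, K)                      # membership counts
    cnt <- lapply(seq_len(L), function(l) matrix(0, K, cd$k[l]))
    for (l in seq_len(L)) {
      for (copy in 1:2) {
        a <- if (copy == 1) cd$c1[, l] else cd$c2[, l]
        ok <- which(!is.na(a))
        if (!length(ok)) next
        pf <- t(P[[l]])[a[ok], , drop = FALSE]    # n_ok x K: P[k, allele]
        w <- Q[ok, , drop = FALSE] * pf
        rs <- rowSums(w)
        ll <- ll + sum(log(pmax(rs, 1e-300)))
        z <- sample_rows(w)
        zi <- cbind(ok, z)
        m_ik[zi] <- m_ik[zi] + 1
        for (k in seq_len(K)) {
          sel <- z == k
          if (any(sel)) {
            t <- tabulate(a[ok][sel], cd$k[l])
            cnt[[l]][k, ] <- cnt[[l]][k, ] + t
          }
        }
      }
    }
    loglik[it] <- ll
    ## cluster allele frequencies
    for (l in seq_len(L))
      P[[l]] <- rdirichlet_rows_mat(lambda + cnt[[l]])
    ## membership
    prior <- matrix(alpha, n, K)
    if (locprior) {
      locmean <- apply(Q, 2, function(col) tapply(col, loc, mean))
      if (nloc == 1) locmean <- matrix(locmean, 1, K)
      prior <- prior + locprior_weight * locmean[loc, , drop = FALSE]
    }
    Q <- rdirichlet_rows_mat(prior + m_ik)
    ## Metropolis update of alpha (uniform(0, 10] prior)
    if (!locprior) {
      alpha_new <- alpha * exp(stats::rnorm(1, 0, 0.3))
      if (alpha_new > 0 && alpha_new <= 10) {
        lr <- n * (lgamma(K * alpha_new) - K * lgamma(alpha_new) -
                     lgamma(K * alpha) + K * lgamma(alpha)) +
          (alpha_new - alpha) * sum(log(pmax(Q, 1e-300)))
        if (log(stats::runif(1)) < lr) alpha <- alpha_new
      }
    }
    if (it > burnin) {
      nkeep <- nkeep + 1L
      Qsum <- Qsum + Q
      for (l in seq_len(L)) Psum[[l]] <- Psum[[l]] + P[[l]]
    }
  }
  lk <- loglik[(burnin + 1):iterations]
  lnp <- mean(lk) - stats::var(lk) / 2
  if (!is.finite(lnp)) warning("non-finite log-probability; run flagged")
  Qm <- Qsum / nkeep
  Qm <- Qm / rowSums(Qm)
  rownames(Qm) <- g$ids
  structure(list(K = K, Q = Qm,
                 P = lapply(Psum, function(m) m / nkeep),
                 lnp = lnp, loglik = loglik, alpha = alpha,
                 meta = list(iterations = iterations, burnin = burnin,
                             locprior = locprior, seed = seed)),
            class = "cluster_result")
}

rdirichlet_rows <- function(nr, shape) {
  t(vapply(seq_len(nr), function(i) rdirichlet1(shape), numeric(length(shape))))
}

## independent Dirichlet draws per row of a shape matrix
rdirichlet_rows_mat <- function(shape) {
  x <- matrix(stats::rgamma(length(shape), pmax(shape, 1e-8)), nrow(shape))
  sw <- rowSums(x)
  sw[sw == 0] <- 1
  x / sw
}

#' Align cluster labels of replicate runs by greedy frequency matching
#'
#' @param runs list of `cluster_result` at the same K
#' @return the runs with columns of `Q` (and rows of `P`) permuted to match
#'   the first run
#' @export
align_clusters <- function(runs) {
  if (length(runs) < 2) return(runs)
  ref <- runs[[1]]
  flat <- function(res) do.call(cbind, res$P)   # K x total alleles
  fr <- flat(ref)
  for (r in 2:length(runs)) {
    fx <- flat(runs[[r]])
    K <- ref$K
    perm <- integer(K); taken <- logical(K)
    for (k in seq_len(K)) {
      d <- vapply(seq_len(K), function(m)
        if (taken[m]) Inf else sum((fr[k, ] - fx[m, ])^2), 0)
      perm[k] <- which.min(d); taken[perm[k]] <- TRUE
    }
    runs[[r]]$Q <- runs[[r]]$Q[, perm, drop = FALSE]
    runs[[r]]$P <- lapply(runs[[r]]$P, function(m) m[perm, , drop = FALSE])
  }
  runs
}

#' Evanno delta-K from replicate clustering runs
#'
#' `deltaK(K) = mean(|L(K+1) - 2 L(K) + L(K-1)|) / sd(L(K))`, computed from
#' the per-run model log-probabilities; undefined at the end points.
#'
#' @param runs list of `cluster_result` objects spanning >= 3 consecutive K
#'   values with >= 2 replicate runs each
#' @return list: `table` (data.frame K, mean_lnp, sd_lnp, delta_k),
#'   `best_k` (K maximising delta-K)
#' @export
delta_k <- function(runs) {
  Ks <- vapply(runs, function(x) as.numeric(x$K), 0)
  lnp <- vapply(runs, function(x) as.numeric(x$lnp), 0)
  uk <- sort(unique(Ks))
  if (length(uk) < 3) stop("need at least 3 consecutive K values")
  if (any(diff(uk) != 1)) stop("K values must be consecutive")
  reps <- table(Ks)
  if (any(reps < 2)) stop("need at least 2 replicate runs per K")
  mean_l <- tapply(lnp, Ks, mean)[as.character(uk)]
  sd_l <- tapply(lnp, Ks, stats::sd)[as.character(uk)]
  dk <- rep(NA_real_, length(uk))
  for (i in 2:(length(uk) - 1)) {
    num <- abs(mean_l[i + 1] - 2 * mean_l[i] + mean_l[i - 1])
    dk[i] <- if (sd_l[i] > 0) num / sd_l[i] else Inf
  }
  if (any(is.infinite(dk), na.rm = TRUE))
    warning("zero variance in L(K); infinite delta-K flagged")
  tab <- data.frame(K = uk, mean_lnp = as.numeric(mean_l),
                    sd_lnp = as.numeric(sd_l), delta_k = dk)
  list(table = tab, best_k = uk[which.max(dk)])
}

## ---- assignment likelihoods ----------------------------------------------

## log10 genotype likelihood of individuals (rows of cd) under each
## reference population, Dirichlet(1/k) posterior-predictive (Rannala-
## Mountain). counts: list per locus of J x k_l copy counts. subtract_self:
## n-vector of pop indices whose counts should exclude the individual (LOO).
loglik10_rm <- function(cd, counts, self_pop = NULL) {
  n <- nrow(cd$c1); L <- length(counts); J <- nrow(counts[[1]])
  out <- matrix(0, n, J, dimnames = list(NULL, rownames(counts[[1]])))
  for (l in seq_len(L)) {
    k <- cd$k[l]
    if (k == 0) next
    tau <- 1 / k
    a <- cd$c1[, l]; b <- cd$c2[, l]
    ok <- which(!is.na(a))
    if (!length(ok)) next
    for (j in seq_len(J)) {
      cnt <- counts[[l]][j, ]
      ntot <- sum(cnt)
      ca <- cnt[a[ok]]; cb <- cnt[b[ok]]
      nj <- rep(ntot, length(ok))
      if (!is.null(self_pop)) {
        own <- self_pop[ok] == j
        if (any(own)) {
          ca[own] <- ca[own] - 1
          cb[own] <- cb[own] - 1
          nj[own] <- nj[own] - 2
        }
      }
      het <- a[ok] != b[ok]
      num <- ifelse(het,
                    log10(2) + log10(ca + tau) + log10(cb + tau),
                    log10(ca + tau) + log10(ca + 1 + tau))
      den <- log10(nj + k * tau) + log10(nj + 1 + k * tau)
      out[ok, j] <- out[ok, j] + num - den
    }
  }
  out
}

#' Per-population assignment likelihoods (Bayesian posterior-predictive)
#'
#' For each individual, the log10 likelihood of its multilocus genotype in
#' each reference population under the Dirichlet(1/k) allele prior, with
#' leave-one-out correction for the home population. The exclusion
#' statistic is `log10(Lmax) - log10(Lhome)` (0 iff home is the most likely
#' source; 2.0 means the home likelihood is 100 times below the best).
#'
#' @param g a [geno_set()]
#' @param leave_one_out remove the focal individual from its home counts
#' @return data.frame of class `assignment_score`: `id`, `home`, `stat`,
#'   `best`, plus one `log10_<pop>` column per population
#' @export
assignment_likelihood <- function(g, leave_one_out = TRUE) {
  cd <- code_alleles(g)
  pops <- unique(g$pop)
  counts <- pop_counts(cd, g$pop)
  self <- if (leave_one_out) match(g$pop, pops) else NULL
  ll <- loglik10_rm(cd, counts, self)
  home_idx <- match(g$pop, pops)
  lhome <- ll[cbind(seq_len(nrow(ll)), home_idx)]
  lmax <- apply(ll, 1, max)
  out <- data.frame(id = g$ids, home = g$pop,
                    stat = lmax - lhome, best = pops[max.col(ll)],
                    stringsAsFactors = FALSE)
  colnames(ll) <- paste0("log10_", pops)
  out <- cbind(out, ll)
  class(out) <- c("assignment_score", "data.frame")
  out
}

#' Detect first-generation migrants by Monte-Carlo exclusion
#'
#' Simulates genotypes for each population by drawing allele pairs from its
#' observed frequencies, builds the null distribution of the exclusion
#' statistic, and flags an individual as a first-generation migrant when
#' its exclusion p-value falls below `alpha` AND its statistic is at least
#' `stat_min` (default 2.0, i.e. a 100-fold cross-assignment odds).
#'
#' @param g a [geno_set()]
#' @param n_sim simulated genotypes per population
#' @param alpha type-I error level (0.01 or 0.05 conventionally)
#' @param stat_min minimum log10 likelihood ratio for migrant designation
#' @param seed integer seed
#' @return the [assignment_likelihood()] frame plus columns `p_value`,
#'   `migrant`, `low_power` (home population sampled below 5 individuals)
#' @export
detect_first_gen_migrants <- function(g, n_sim = 10000L, alpha = 0.01,
                                      stat_min = 2.0, seed = 1L) {
  pops <- unique(g$pop)
  if (length(pops) < 2) stop("need at least 2 populations")
  set.seed(seed)
  scores <- assignment_likelihood(g, leave_one_out = TRUE)
  cd <- code_alleles(g)
  counts <- pop_counts(cd, g$pop)
  L <- length(g$loci)
  ## null statistic distribution per home population, by gene-drop
  ## resampling: each batch of simulated genotypes is scored against an
  ## independently resampled home reference, reproducing the sampling-error
  ## penalty a real (left-out) individual pays against its home counts
  n_batch <- 25L
  per_batch <- ceiling(n_sim / n_batch)
  null_stat <- vector("list", length(pops))
  for (j in seq_along(pops)) {
    stats_j <- numeric(0)
    for (b in seq_len(n_batch)) {
      sim <- list(c1 = matrix(NA_integer_, per_batch, L),
                  c2 = matrix(NA_integer_, per_batch, L), k = cd$k)
      counts_b <- counts
      for (l in seq_len(L)) {
        cnt <- counts[[l]][j, ]
        if (sum(cnt) == 0) next
        p <- cnt / sum(cnt)
        sim$c1[, l] <- sample.int(cd$k[l], per_batch, TRUE, p)
        sim$c2[, l] <- sample.int(cd$k[l], per_batch, TRUE, p)
        counts_b[[l]][j, ] <- as.integer(stats::rmultinom(1, sum(cnt), p))
      }
      ll <- loglik10_rm(sim, counts_b)
      stats_j <- c(stats_j, apply(ll, 1, max) - ll[, j])
    }
    null_stat[[j]] <- stats_j[seq_len(n_sim)]
  }
  home_idx <- match(g$pop, pops)
  p_value <- vapply(seq_len(nrow(scores)), function(i) {
    ns <- null_stat[[home_idx[i]]]
    (sum(ns >= scores$stat[i] - 1e-12) + 1) / (length(ns) + 1)
  }, 0)
  n_by_pop <- table(g$pop)
  scores$p_value <- p_value
  scores$migrant <- p_value < alpha & scores$stat >= stat_min
  scores$low_power <- as.integer(n_by_pop[g$pop]) < 5
  scores
}

## ---- two-generation immigrant ancestry -----------------------------------

#' Posterior immigrant-ancestry states over the last two generations
#'
#' Each individual is a resident of its sampled population, a
#' first-generation immigrant from population j, or a second-generation
#' immigrant (exactly one immigrant parent) from j. Prior migrant mass
#' `migprior` is split evenly over the immigrant states; the posterior is
#' sampled by Gibbs alternation of ancestry states and population allele
#' frequencies (Dirichlet(1) prior).
#'
#' @param g a [geno_set()]
#' @param migprior prior probability of non-resident ancestry (in (0,1);
#'   0 returns the closed-form all-resident answer)
#' @param n_iter,burnin MCMC sweeps
#' @param thin keep every `thin`-th post-burn-in sweep for credible intervals
#' @param seed integer seed
#' @return list of class `ancestry_result`: `posterior` data.frame (`id`,
#'   `home`, `gen0`, `migrant_prob`, per-source `gen1_<pop>`, `gen2_<pop>`),
#'   `draws` (thinned state samples, individuals x sweeps), `states`
#'   (state lookup table), `pops`
#' @export
immigrant_ancestry <- function(g, migprior = 0.05, n_iter = 2000L,
                               burnin = 500L, thin = 5L, seed = 1L) {
  if (migprior < 0 || migprior >= 1) stop("migprior must lie in [0, 1)")
  pops <- unique(g$pop)
  J <- length(pops); n <- n_samples(g); L <- length(g$loci)
  home <- match(g$pop, pops)
  ## state table: 1 = resident; then (j, gen) for j != home handled per ind
  states <- expand.grid(src = seq_len(J), gen = 1:2)
  if (migprior == 0) {
    post <- data.frame(id = g$ids, home = g$pop, gen0 = 1, migrant_prob = 0)
    for (j in seq_len(J)) {
      post[[paste0("gen1_", pops[j])]] <- 0
      post[[paste0("gen2_", pops[j])]] <- 0
    }
    return(structure(list(posterior = post, draws = NULL, states = states,
                          pops = pops), class = "ancestry_result"))
  }
  set.seed(seed)
  cd <- code_alleles(g)
  nstate <- 1L + 2L * J            # resident, gen1 x J, gen2 x J (own pop masked)
  log_prior <- matrix(-Inf, n, nstate)
  log_prior[, 1] <- log(1 - migprior)
  pmass <- migprior / (2 * (J - 1))
  for (j in seq_len(J)) {
    log_prior[home != j, 1 + j] <- log(pmass)          # gen1 from j
    log_prior[home != j, 1 + J + j] <- log(pmass)      # gen2 from j
  }
  state <- rep(1L, n)
  keep <- integer(0)
  draws <- matrix(NA_integer_, n, 0)
  post_counts <- matrix(0, n, nstate)
  for (it in seq_len(n_iter)) {
    ## population allele frequencies given states
    P <- vector("list", L)
    for (l in seq_len(L)) {
      sh <- matrix(1, J, cd$k[l])    # Dirichlet(1) prior
      a <- cd$c1[, l]; b <- cd$c2[, l]
      ok <- which(!is.na(a))
      for (i in ok) {
        s <- state[i]
        if (s == 1L) { tgt <- c(home[i], home[i]) }
        else if (s <= 1L + J) { tgt <- c(s - 1L, s - 1L) }
        else { tgt <- c(s - 1L - J, home[i]) }   # one copy each
        sh[tgt[1], a[i]] <- sh[tgt[1], a[i]] + 1
        sh[tgt[2], b[i]] <- sh[tgt[2], b[i]] + 1
      }
      P[[l]] <- rdirichlet_rows_mat(sh)
    }
    ## state likelihoods
    ll <- matrix(0, n, nstate)
    for (l in seq_len(L)) {
      a <- cd$c1[, l]; b <- cd$c2[, l]
      ok <- which(!is.na(a))
      if (!length(ok)) next
      Pl <- P[[l]]
      pa_home <- Pl[cbind(home[ok], a[ok])]
      pb_home <- Pl[cbind(home[ok], b[ok])]
      het <- a[ok] != b[ok]
      ll[ok, 1] <- ll[ok, 1] +
        log(pmax(ifelse(het, 2 * pa_home * pb_home, pa_home^2), 1e-300))
      for (j in seq_len(J)) {
        pa_j <- Pl[j, a[ok]]; pb_j <- Pl[j, b[ok]]
        ll[ok, 1 + j] <- ll[ok, 1 + j] +
          log(pmax(ifelse(het, 2 * pa_j * pb_j, pa_j^2), 1e-300))
        mix <- ifelse(het, pa_home * pb_j + pa_j * pb_home, pa_home * pa_j)
        ll[ok, 1 + J + j] <- ll[ok, 1 + J + j] + log(pmax(mix, 1e-300))
      }
    }
    w <- ll + log_prior
    w <- exp(w - apply(w, 1, max))
    state <- sample_rows(w)
    if (it > burnin) {
      post_counts[cbind(seq_len(n), state)] <- post_counts[cbind(seq_len(n), state)] + 1
      if ((it - burnin) %% thin == 0) draws <- cbind(draws, state)
    }
  }
  pp <- post_counts / rowSums(post_counts)
  post <- data.frame(id = g$ids, home = g$pop, gen0 = pp[, 1],
                     migrant_prob = 1 - pp[, 1])
  for (j in seq_len(J)) {
    post[[paste0("gen1_", pops[j])]] <- pp[, 1 + j]
    post[[paste0("gen2_", pops[j])]] <- pp[, 1 + J + j]
  }
  structure(list(posterior = post, draws = draws, states = states,
                 pops = pops), class = "ancestry_result")
}

#' Recent migration-rate matrix from ancestry posteriors
#'
#' `m[dest <- src]` is the mean, over individuals sampled in `dest`, of the
#' posterior immigrant mass attributed to `src` (gen1 + gen2/2); the
#' diagonal is `1 - sum(off-diagonal)`, the proportion of each population
#' derived from itself per generation. Credible intervals come from the
#' thinned posterior state draws. Groups below `min_n` individuals are
#' excluded (noted), mirroring the usual small-sample exclusion.
#'
#' @param ancestry an [immigrant_ancestry()] result
#' @param min_n minimum sampled individuals for a population to be reported
#' @return list of class `migration_rates`: `m` (rows = destination),
#'   `ci_lower`, `ci_upper`, `excluded`
#' @export
recent_migration_rates <- function(ancestry, min_n = 5L) {
  stopifnot(inherits(ancestry, "ancestry_result"))
  post <- ancestry$posterior
  pops <- ancestry$pops
  nn <- table(post$home)
  keep <- names(nn)[nn >= min_n]
  excluded <- setdiff(pops, keep)
  J <- length(keep)
  m <- matrix(0, J, J, dimnames = list(keep, keep))
  for (d in keep) {
    idx <- post$home == d
    for (s in keep) {
      if (s == d) next
      m[d, s] <- mean(post[[paste0("gen1_", s)]][idx] +
                        0.5 * post[[paste0("gen2_", s)]][idx])
    }
  }
  diag(m) <- 1 - rowSums(m)
  lo <- hi <- matrix(NA_real_, J, J, dimnames = list(keep, keep))
  if (!is.null(ancestry$draws) && ncol(ancestry$draws) >= 20) {
    Jall <- length(pops)
    home <- match(post$home, pops)
    per_sweep <- array(0, c(J, J, ncol(ancestry$draws)))
    for (sw in seq_len(ncol(ancestry$draws))) {
      st <- ancestry$draws[, sw]
      msw <- matrix(0, J, J, dimnames = list(keep, keep))
      for (d in keep) {
        idx <- which(post$home == d)
        for (s in keep) {
          if (s == d) next
          js <- match(s, pops)
          msw[d, s] <- mean((st[idx] == 1 + js) + 0.5 * (st[idx] == 1 + Jall + js))
        }
      }
      diag(msw) <- 1 - rowSums(msw)
      per_sweep[, , sw] <- msw
    }
    lo[] <- apply(per_sweep, 1:2, stats::quantile, 0.025)
    hi[] <- apply(per_sweep, 1:2, stats::quantile, 0.975)
  }
  structure(list(m = m, ci_lower = lo, ci_upper = hi, excluded = excluded),
            class = "migration_rates")
}

## ---- parentage -----------------------------------------------------------

## per-locus likelihood ratio P(offspring | candidate parent)/P(offspring)
## under HW frequencies and a simple stochastic-error model
parentage_locus_ratio <- function(off, cand, p, error_rate) {
  names(p) <- names(p)
  pa <- function(al) { v <- p[as.character(al)]; ifelse(is.na(v), 1e-6, v) }
  o1 <- off[1]; o2 <- off[2]
  p_rand <- if (o1 == o2) pa(o1)^2 else 2 * pa(o1) * pa(o2)
  trans <- 0
  for (x in cand) {
    if (o1 == o2) { if (x == o1) trans <- trans + 0.5 * pa(o1) }
    else {
      if (x == o1) trans <- trans + 0.5 * pa(o2)
      if (x == o2) trans <- trans + 0.5 * pa(o1)
    }
  }
  lp <- (1 - error_rate) * trans + error_rate * p_rand
  as.numeric(lp / p_rand)
}

#' Parent-offspring LOD score
#'
#' `LOD = sum over typed shared loci of ln(likelihood ratio)`, the ratio of
#' the offspring genotype probability given the candidate as one parent
#' (the other parent drawn from the population) to its probability for two
#' random parents. A genotyping-error rate > 0 keeps LOD finite at
#' mismatching loci; with zero error a Mendelian exclusion gives `-Inf`.
#'
#' @param offspring,candidate single-row [geno_set()]s (or row indices into
#'   `g` if `g` is supplied)
#' @param freqs an [allele_frequencies()] table
#' @param error_rate per-locus genotyping error in \[0.01, 0.10\]
#'   conventionally; 0 allowed (enables hard exclusion)
#' @return list: `lod`, `per_locus` named vector, `n_loci`
#' @export
parentage_lod <- function(offspring, candidate, freqs, error_rate = 0.01) {
  stopifnot(inherits(offspring, "geno_set"), inherits(candidate, "geno_set"))
  loci <- intersect(names(freqs$freq), offspring$loci)
  per <- numeric(0)
  for (l in loci) {
    li <- match(l, offspring$loci)
    off <- offspring$alleles[1, li, ]
    cnd <- candidate$alleles[1, match(l, candidate$loci), ]
    if (anyNA(off) || anyNA(cnd)) next
    r <- parentage_locus_ratio(off, cnd, freqs$freq[[l]], error_rate)
    per[l] <- log(r)
  }
  if (!length(per)) stop("no shared typed loci between offspring and candidate")
  list(lod = sum(per), per_locus = per, n_loci = length(per))
}

#' Monte-Carlo LOD confidence thresholds for parentage assignment
#'
#' Simulates offspring and candidate-parent sets from the supplied allele
#' frequencies (true parent sampled with probability `prop_sampled`, loci
#' typed with probability `prop_typed`, genotypes perturbed at
#' `error_rate`), assigns each offspring to its highest-LOD candidate, and
#' returns the smallest LOD at which the success rate among assignments
#' reaches the strict (95%) and relaxed (80%) confidence levels.
#'
#' @param freqs an [allele_frequencies()] table
#' @param error_rate genotyping error rate
#' @param n_off simulated offspring
#' @param n_cand candidate parents per offspring pool
#' @param prop_sampled probability the true parent is in the candidate pool
#' @param prop_typed per-locus typing probability
#' @param seed integer seed
#' @return list: `strict`, `relaxed` LOD thresholds, `sims` data.frame
#' @export
parentage_thresholds <- function(freqs, error_rate = 0.01, n_off = 1000L,
                                 n_cand = 50L, prop_sampled = 0.25,
                                 prop_typed = 0.93, seed = 1L) {
  set.seed(seed)
  loci <- names(freqs$freq)
  draw_geno <- function() lapply(freqs$freq, function(p) {
    al <- as.integer(names(p))
    sample(al, 2, TRUE, p)
  })
  draw_child <- function(p1, p2) mapply(function(a, b, l) {
    c(sample(a, 1), sample(b, 1))
  }, p1, p2, loci, SIMPLIFY = FALSE)
  lodrow <- function(off, cand) {
    tot <- 0
    for (l in loci) {
      if (stats::runif(1) > prop_typed) next
      r <- parentage_locus_ratio(off[[l]], cand[[l]], freqs$freq[[l]], error_rate)
      tot <- tot + log(max(r, 1e-12))
    }
    tot
  }
  best_lod <- numeric(n_off); correct <- logical(n_off)
  for (i in seq_len(n_off)) {
    p1 <- draw_geno(); p2 <- draw_geno()
    off <- draw_child(p1, p2)
    cands <- replicate(n_cand, draw_geno(), simplify = FALSE)
    true_in <- stats::runif(1) < prop_sampled
    if (true_in) cands[[1]] <- p1
    lods <- vapply(cands, function(cn) lodrow(off, cn), 0)
    b <- which.max(lods)
    best_lod[i] <- lods[b]
    correct[i] <- true_in && b == 1L
  }
  ord <- order(best_lod, decreasing = TRUE)
  succ <- cumsum(correct[ord]) / seq_len(n_off)
  thr <- function(conf) {
    ok <- which(succ >= conf)
    if (!length(ok)) return(Inf)
    best_lod[ord][max(ok)]
  }
  list(strict = thr(0.95), relaxed = thr(0.80),
       sims = data.frame(lod = best_lod, correct = correct))
}

## ---- consensus designation -----------------------------------------------

#' Consensus migrant designation from multi-program evidence
#'
#' Applies the conservative consensus rule to per-individual evidence
#' bundles: an individual is a **migrant** only when (i) the exclusion test
#' is significant at the strict level (`geneclass_p < 0.01` and statistic
#' >= 2.0), (ii) the posterior migrant/cross-assignment probability exceeds
#' 0.5 in both Bayesian analyses, and (iii) the first-generation ancestry
#' state dominates (> 0.5) in both. Individuals with immigrant evidence
#' from at least two independent sources (exclusion test significant at
#' 0.05; either Bayesian migrant probability above `admix_floor`; high
#' membership in a single non-home cluster) that fail the full rule are
#' **admixed**; everyone else is a **resident**. High non-home membership
#' (Q > 0.8) corroborates but is not required.
#'
#' @param bundles data.frame with columns `id`, `geneclass_stat`,
#'   `geneclass_p`, `structure_migrant_p`, `structure_gen1`,
#'   `structure_gen2`, `bayesass_migrant_p`, `bayesass_gen1`,
#'   `bayesass_gen2`, and optionally `q_nonhome_max`; missing columns or
#'   `NA` values count as failing the corresponding criterion
#' @param admix_floor minimum posterior migrant mass for a Bayesian source
#'   to count as immigrant evidence
#' @return `bundles` with columns `status` (factor resident/admixed/migrant)
#'   and logical criterion columns `crit_i`, `crit_ii`, `crit_iii`
#' @export
designate_migrants <- function(bundles, admix_floor = 0.1) {
  gv <- function(col, default = NA_real_) {
    if (col %in% names(bundles)) bundles[[col]] else rep(default, nrow(bundles))
  }
  na0 <- function(x) ifelse(is.na(x), 0, x)
  naInf <- function(x) ifelse(is.na(x), Inf, x)
  stat <- na0(gv("geneclass_stat"))
  p <- naInf(gv("geneclass_p"))
  smp <- na0(gv("structure_migrant_p")); bmp <- na0(gv("bayesass_migrant_p"))
  sg1 <- na0(gv("structure_gen1")); bg1 <- na0(gv("bayesass_gen1"))
  qnh <- na0(gv("q_nonhome_max"))
  crit_i <- p < 0.01 & stat >= 2.0
  crit_ii <- smp > 0.5 & bmp > 0.5
  crit_iii <- sg1 > 0.5 & bg1 > 0.5
  migrant <- crit_i & crit_ii & crit_iii
  evidence <- (p < 0.05) + (smp > admix_floor) + (bmp > admix_floor) +
    (qnh > 0.8)
  status <- ifelse(migrant, "migrant",
                   ifelse(evidence >= 2, "admixed", "resident"))
  bundles$crit_i <- crit_i; bundles$crit_ii <- crit_ii
  bundles$crit_iii <- crit_iii
  bundles$status <- factor(status, levels = c("resident", "admixed", "migrant"))
  bundles
}

#' Read a migrant-evidence bundle table
#'
#' Loads a CSV of per-individual multi-program evidence (exclusion
#' statistic and significance class, no-prior cluster memberships, migrant
#' and generation posteriors from two Bayesian analyses) and derives the
#' maximum non-home cluster membership `q_nonhome_max` from the membership
#' columns (`q_*`) and the `home_cluster` column. Printed significance
#' classes are conventionally encoded as representative p-values (0.009
#' for the strict class, 0.04 for the 0.05 class, 1 for not significant)
#' and a below-threshold exclusion statistic as 1.9.
#'
#' @param path CSV path; defaults to the packaged evidence table of 17
#'   putative migrants
#' @return data.frame ready for [designate_migrants()]
#' @export
read_evidence_table <- function(path = system.file("extdata",
                                                   "table3_evidence.csv",
                                                   package = "tigerscape")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  qcols <- grep("^q_", names(df), value = TRUE)
  cluster_of <- sub("^q_", "", qcols)
  df$q_nonhome_max <- vapply(seq_len(nrow(df)), function(i) {
    nonhome <- qcols[toupper(cluster_of) != toupper(df$home_cluster[i])]
    max(unlist(df[i, nonhome]))
  }, 0)
  df
}
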