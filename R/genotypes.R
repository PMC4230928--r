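#' Consensus genotype from replicate amplifications
#'
#' Implements the replicate-confirmation rule used for non-invasive samples:
#' a heterozygote call requires the same allele pair in at least `het_min`
#' replicates; a homozygote requires the same single-allele call in at least
#' `hom_min` replicates (guarding against allelic dropout). Loci meeting
#' neither rule are missing; two distinct heterozygote pairs each confirmed
#' `het_min` times is a conflict (missing, flagged).
#'
#' @param replicates a [geno_set()] whose rows are replicate amplifications
#'   of one sample
#' @param het_min replicates required to confirm a heterozygote
#' @param hom_min replicates required to confirm a homozygote
#' @return one-row [geno_set()]; attribute `conflict` is a logical vector
#'   per locus.
#' @export
consensus_genotype <- function(replicates, het_min = 2L, hom_min = 5L) {
  stopifnot(inherits(replicates, "geno_set"), n_samples(replicates) >= 1)
  L <- length(replicates$loci)
  out <- array(NA_integer_, c(1, L, 2))
  conflict <- logical(L)
  for (l in seq_len(L)) {
    a <- replicates$alleles[, l, 1]; b <- replicates$alleles[, l, 2]
    ok <- !is.na(a)
    if (!any(ok)) next
    key <- paste(a[ok], b[ok])
    het <- a[ok] != b[ok]
    if (any(het)) {
      tab <- table(key[het])
      confirmed <- names(tab)[tab >= het_min]
      if (length(confirmed) > 1L) { conflict[l] <- TRUE; next }
      if (length(confirmed) == 1L) {
        pr <- as.integer(strsplit(confirmed, " ")[[1]])
        out[1, l, ] <- pr
        next
      }
    }
    hom <- !het
    if (any(hom)) {
      tab <- table(key[hom])
      confirmed <- names(tab)[tab >= hom_min]
      if (length(confirmed) == 1L) {
        pr <- as.integer(strsplit(confirmed, " ")[[1]])
        out[1, l, ] <- pr
      }
    }
  }
  g <- geno_set(out, replicates$ids[1], replicates$pop[1], replicates$loci)
  attr(g, "conflict") <- conflict
  g
}

#' Consensus genotypes for a whole replicate set
#'
#' Groups replicate rows by originating sample (the `sample_of` attribute
#' written by [gen_noninvasive_samples()], or ids stripped of a `_r<k>`
#' suffix) and applies [consensus_genotype()] to each group.
#'
#' @param reps a [geno_set()] of replicates
#' @inheritParams consensus_genotype
#' @return a [geno_set()] with one row per sample
#' @export
consensus_genotypes <- function(reps, het_min = 2L, hom_min = 5L) {
  so <- attr(reps, "sample_of")
  if (is.null(so)) so <- sub("_r[0-9]+$", "", reps$ids)
  out <- lapply(unique(so), function(s)
    consensus_genotype(reps[which(so == s), ], het_min, hom_min))
  for (i in seq_along(out)) out[[i]]$ids <- unique(so)[i]
  do.call(rbind_geno, out)
}

#' Match samples into unique individuals
#'
#' Samples typed at fewer than `min_loci` loci are excluded. Samples
#' identical at all shared loci are merged into one individual; pairs
#' mismatching at 1 to `max_mismatch` shared loci are flagged for review and
#' merged only when every mismatch is dropout-consistent (a homozygote
#' versus a heterozygote containing that allele); three or more mismatches
#' always separate individuals. Merging is by connected components
#' (union-find), so the partition does not depend on input order.
#'
#' @param samples a [geno_set()] of consensus genotypes
#' @param min_loci minimum typed loci for a sample to enter matching
#' @param max_mismatch maximum mismatching loci that may still merge
#' @return list: `individuals` (a [geno_set()], one row per individual,
#'   locus calls merged het-over-dropout), `recaptures` (named list mapping
#'   individual id to member sample ids), `review` (data.frame of flagged
#'   pairs), `excluded` (ids failing the locus filter).
#' @export
match_individuals <- function(samples, min_loci = 7L, max_mismatch = 2L) {
  stopifnot(inherits(samples, "geno_set"))
  typed <- rowSums(typed_mask(samples))
  excluded <- samples$ids[typed < min_loci]
  keep <- which(typed >= min_loci)
  if (!length(keep)) {
    warning("no samples pass the minimum-loci filter")
    return(list(individuals = samples[integer(0), ],
                recaptures = list(), review = NULL, excluded = excluded))
  }
  s <- samples[keep, ]
  n <- n_samples(s)
  parent <- seq_len(n)
  findp <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(i, j) { ri <- findp(i); rj <- findp(j); if (ri != rj) parent[rj] <<- ri }
  review <- list()
  a1 <- allele_slice(s, 1); a2 <- allele_slice(s, 2)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- !is.na(a1[i, ]) & !is.na(a1[j, ])
    if (!any(shared)) next
    mis <- shared & (a1[i, ] != a1[j, ] | a2[i, ] != a2[j, ])
    nm <- sum(mis)
    if (nm == 0L) union2(i, j)
    else if (nm <= max_mismatch) {
      dc <- vapply(which(mis), function(l)
        dropout_consistent(c(a1[i, l], a2[i, l]), c(a1[j, l], a2[j, l])), TRUE)
      review[[length(review) + 1L]] <-
        data.frame(sample1 = s$ids[i], sample2 = s$ids[j], mismatches = nm,
                   merged = all(dc))
      if (all(dc)) union2(i, j)
    }
  }
  comp <- vapply(seq_len(n), findp, 0L)
  groups <- split(seq_len(n), comp)
  inds <- vector("list", length(groups))
  recaptures <- list()
  for (k in seq_along(groups)) {
    idx <- groups[[k]]
    merged <- merge_group(s, idx)
    merged$ids <- s$ids[idx[1]]
    inds[[k]] <- merged
    recaptures[[s$ids[idx[1]]]] <- s$ids[idx]
  }
  list(individuals = do.call(rbind_geno, inds), recaptures = recaptures,
       review = if (length(review)) do.call(rbind, review) else NULL,
       excluded = excluded)
}

## homozygote vs heterozygote containing the homozygous allele
dropout_consistent <- function(p1, p2) {
  h1 <- p1[1] == p1[2]; h2 <- p2[1] == p2[2]
  (h1 && !h2 && p1[1] %in% p2) || (h2 && !h1 && p2[1] %in% p1)
}

## merge replicate rows: heterozygote beats dropout homozygote, fill missing
merge_group <- function(s, idx) {
  L <- length(s$loci)
  out <- array(NA_integer_, c(1, L, 2))
  for (l in seq_len(L)) {
    calls <- s$alleles[idx, l, , drop = FALSE]
    ok <- which(!is.na(calls[, 1, 1]))
    if (!length(ok)) next
    het <- calls[ok, 1, 1] != calls[ok, 1, 2]
    pick <- if (any(het)) ok[which(het)[1]] else ok[1]
    out[1, l, ] <- calls[pick, 1, ]
  }
  geno_set(out, s$ids[idx[1]], s$pop[idx[1]], s$loci)
}

#' Per-locus allele frequencies
#'
#' @param g a [geno_set()] of unique individuals
#' @return object of class `allele_freqs`: list with `freq` (per locus, a
#'   named numeric vector over alleles summing to 1) and `n_copies` (gene
#'   copies per locus). Loci with zero calls are omitted with a warning.
#' @export
allele_frequencies <- function(g) {
  stopifnot(inherits(g, "geno_set"), n_samples(g) >= 1)
  freq <- list(); n_copies <- integer()
  for (l in seq_along(g$loci)) {
    al <- c(g$alleles[, l, 1], g$alleles[, l, 2])
    al <- al[!is.na(al)]
    if (!length(al)) { warning("locus ", g$loci[l], " has no calls; omitted"); next }
    tab <- table(al)
    freq[[g$loci[l]]] <- as.numeric(tab / sum(tab))
    names(freq[[g$loci[l]]]) <- names(tab)
    n_copies[g$loci[l]] <- length(al)
  }
  structure(list(freq = freq, n_copies = n_copies), class = "allele_freqs")
}

#' Probability-of-identity statistics
#'
#' Per-locus and cumulative probability that two individuals share a
#' genotype: the standard unrelated-pair form (with the small-sample
#' unbiased correction when gene-copy counts are available) and the
#' conservative full-sibling form
#' `PIsib = 0.25 + 0.5*S2 + 0.5*S2^2 - 0.25*S4` with `Sk = sum(p_i^k)`.
#' Cumulative values are products over loci (independent loci).
#'
#' @param freqs an [allele_frequencies()] table
#' @param unbiased use the sample-size-corrected estimator for PI when
#'   gene-copy counts are present
#' @return list with `per_locus` (data.frame: locus, pi, pi_sib) and
#'   `cumulative` (named vector `pi`, `pi_sib`)
#' @export
identity_statistics <- function(freqs, unbiased = TRUE) {
  stopifnot(inherits(freqs, "allele_freqs"))
  rows <- lapply(names(freqs$freq), function(l) {
    p <- freqs$freq[[l]]
    a2 <- sum(p^2); a3 <- sum(p^3); a4 <- sum(p^4)
    pi_b <- 2 * a2^2 - a4
    n <- freqs$n_copies[[l]]
    pi <- if (unbiased && !is.null(n) && n > 3) {
      (n^3 * (2 * a2^2 - a4) - 2 * n^2 * (a3 + 2 * a2) +
         n * (9 * a2 + 2) - 6) / ((n - 1) * (n - 2) * (n - 3))
    } else pi_b
    pi <- min(max(pi, 0), 1)
    pisib <- 0.25 + 0.5 * a2 + 0.5 * a2^2 - 0.25 * a4
    data.frame(locus = l, pi = pi, pi_sib = pisib)
  })
  per_locus <- do.call(rbind, rows)
  list(per_locus = per_locus,
       cumulative = c(pi = prod(per_locus$pi), pi_sib = prod(per_locus$pi_sib)))
}

#' Diversity summary per locality group
#'
#' Observed heterozygosity, unbiased expected heterozygosity
#' (`n/(n-1) * (1 - sum p^2)` over `n` gene copies), allele count, allelic
#' size range (repeat units), private alleles (alleles observed in exactly
#' one group), and the group's cumulative identity statistics.
#'
#' @param g a [geno_set()]
#' @param by grouping labels (defaults to `g$pop`)
#' @return list per group of class `diversity_summary`: `per_locus`
#'   data.frame (locus, n, ho, he, a, size_range, private), `mean` row, and
#'   `identity` from [identity_statistics()]. Groups of one individual have
#'   `he = NA` (flagged).
#' @export
diversity_summary <- function(g, by = g$pop) {
  stopifnot(inherits(g, "geno_set"))
  groups <- unique(by)
  ## private alleles: which (locus, allele) occur in exactly one group
  seen <- list()
  for (grp in groups) {
    gi <- g[which(by == grp), ]
    for (l in seq_along(g$loci)) {
      al <- unique(c(gi$alleles[, l, 1], gi$alleles[, l, 2]))
      al <- al[!is.na(al)]
      key <- paste(g$loci[l], al)
      for (k in key) seen[[k]] <- c(seen[[k]], grp)
    }
  }
  n_groups_with <- vapply(seen, function(v) length(unique(v)), 0L)
  out <- list()
  for (grp in groups) {
    gi <- g[which(by == grp), ]
    ni <- n_samples(gi)
    rows <- lapply(seq_along(g$loci), function(l) {
      a <- gi$alleles[, l, 1]; b <- gi$alleles[, l, 2]
      ok <- !is.na(a)
      if (!sum(ok)) return(data.frame(locus = g$loci[l], n = 0L, ho = NA,
                                      he = NA, a = 0L, size_range = NA,
                                      private = 0L))
      copies <- c(a[ok], b[ok])
      p <- as.numeric(table(copies)) / length(copies)
      nn <- length(copies)
      he <- if (ni >= 2) nn / (nn - 1) * (1 - sum(p^2)) else NA_real_
      als <- unique(copies)
      priv <- sum(n_groups_with[paste(g$loci[l], als)] == 1L)
      data.frame(locus = g$loci[l], n = sum(ok),
                 ho = mean(a[ok] != b[ok]), he = he,
                 a = length(als), size_range = diff(range(copies)),
                 private = priv)
    })
    per_locus <- do.call(rbind, rows)
    mean_row <- colMeans(per_locus[, c("ho", "he", "a", "size_range")], na.rm = TRUE)
    idstats <- if (ni >= 1 && any(per_locus$n > 0))
      identity_statistics(allele_frequencies(gi)) else NULL
    out[[grp]] <- structure(list(per_locus = per_locus, mean = mean_row,
                                 n_individuals = ni, identity = idstats,
                                 private_total = sum(per_locus$private)),
                            class = "diversity_summary")
  }
  out
}

#' Export diversity summaries as a long CSV keyed by group and locus
#' @param divs result of [diversity_summary()]
#' @param path output path
#' @export
write_diversity_csv <- function(divs, path) {
  rows <- lapply(names(divs), function(g)
    cbind(group = g, divs[[g]]$per_locus))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Monte-Carlo exact test of Hardy-Weinberg equilibrium at one locus
#'
#' The statistic is the conditional probability of the genotype array given
#' the allele counts (Levene); the null is generated by re-pairing permuted
#' gene copies. The p-value counts permuted arrays no more probable than the
#' observed one, with the +1 correction.
#'
#' @param g a [geno_set()]
#' @param locus locus name or index
#' @param n_perm Monte-Carlo permutations
#' @param seed integer seed
#' @return p-value (1 for a monomorphic locus, by convention)
#' @export
hwe_test <- function(g, locus, n_perm = 10000L, seed = 1L) {
  if (is.character(locus)) locus <- match(locus, g$loci)
  a <- g$alleles[, locus, 1]; b <- g$alleles[, locus, 2]
  ok <- !is.na(a)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 5) stop("need at least 5 typed individuals")
  if (length(unique(c(a, b))) < 2) return(1)
  set.seed(seed)
  obs <- log_array_prob(a, b)
  copies <- c(a, b); n <- length(a)
  count <- 0L
  for (r in seq_len(n_perm)) {
    s <- sample(copies)
    lp <- log_array_prob(s[seq_len(n)], s[n + seq_len(n)])
    if (lp <= obs + 1e-12) count <- count + 1L
  }
  (count + 1) / (n_perm + 1)
}

## log conditional probability of a genotype array given allele counts
log_array_prob <- function(a, b) {
  n <- length(a)
  key <- paste(pmin(a, b), pmax(a, b))
  ngeno <- table(key)
  nall <- table(c(a, b))
  h <- sum(a != b)
  lfactorial(n) - sum(lfactorial(ngeno)) + h * log(2) +
    sum(lfactorial(nall)) - lfactorial(2 * n)
}

#' Permutation test of linkage disequilibrium between two loci
#'
#' Statistic: the G-squared log-likelihood-ratio of association between the
#' two single-locus genotype classifications; null by permuting one locus's
#' genotypes across individuals (complete cases only).
#'
#' @param g a [geno_set()]
#' @param loci length-2 vector of locus names or indices
#' @param n_perm permutations
#' @param seed integer seed
#' @return p-value
#' @export
ld_test <- function(g, loci, n_perm = 10000L, seed = 1L) {
  if (is.character(loci)) loci <- match(loci, g$loci)
  g1 <- paste(g$alleles[, loci[1], 1], g$alleles[, loci[1], 2])
  g2 <- paste(g$alleles[, loci[2], 1], g$alleles[, loci[2], 2])
  ok <- !is.na(g$alleles[, loci[1], 1]) & !is.na(g$alleles[, loci[2], 1])
  g1 <- g1[ok]; g2 <- g2[ok]
  if (length(g1) < 5) stop("need at least 5 individuals typed at both loci")
  if (length(unique(g1)) < 2 || length(unique(g2)) < 2) return(1)
  set.seed(seed)
  obs <- g2_stat(g1, g2)
  count <- 0L
  for (r in seq_len(n_perm))
    if (g2_stat(g1, sample(g2)) >= obs - 1e-12) count <- count + 1L
  (count + 1) / (n_perm + 1)
}

## G^2 statistic of a two-way contingency table
g2_stat <- function(x, y) {
  tab <- table(x, y)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  o <- as.numeric(tab); e <- as.numeric(e)
  2 * sum(ifelse(o > 0, o * log(o / e), 0))
}
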