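## Build a geno_set from a compact list spec: one character vector per
## individual, each element "a/b" or NA for a missing locus.
make_geno <- function(..., pop = NULL, ids = NULL, loci = NULL) {
  rows <- list(...)
  n <- length(rows); L <- length(rows[[1]])
  al <- array(NA_integer_, c(n, L, 2))
  for (i in seq_len(n)) for (l in seq_len(L)) {
    v <- rows[[i]][l]
    if (is.na(v)) next
    pr <- as.integer(strsplit(v, "/")[[1]])
    al[i, l, ] <- pr
  }
  geno_set(al, ids = ids, pop = if (is.null(pop)) rep("pop1", n) else pop,
           loci = loci)
}

## replicate rows of one sample as a geno_set (for consensus tests)
make_reps <- function(..., loci = NULL) {
  rows <- list(...)
  g <- do.call(make_geno, c(rows, list(ids = sprintf("s_r%d", seq_along(rows)),
                                       loci = loci)))
  g
}

## two-population HWE sample from given allele frequencies
sample_pop_geno <- function(n, freq_list, pop = "pop1", ids = NULL) {
  L <- length(freq_list)
  al <- array(NA_integer_, c(n, L, 2))
  for (l in seq_len(L)) {
    alleles <- as.integer(names(freq_list[[l]]))
    al[, l, 1] <- sample(alleles, n, TRUE, freq_list[[l]])
    al[, l, 2] <- sample(alleles, n, TRUE, freq_list[[l]])
  }
  geno_set(al, ids = ids, pop = rep(pop, n))
}

## ---- independent oracles --------------------------------------------------

## F_ST via textbook nested random-effects ANOVA on allele indicators
## (moment estimators from raw sums of squares; independent of the
## closed-form algebra used in the package)
oracle_theta <- function(g, groups = g$pop) {
  A <- B <- C <- 0
  for (l in seq_along(g$loci)) {
    a1 <- g$alleles[, l, 1]; a2 <- g$alleles[, l, 2]
    ok <- !is.na(a1)
    if (sum(ok) < 2) next
    gl <- groups[ok]; x1 <- a1[ok]; x2 <- a2[ok]
    pops <- unique(gl); r <- length(pops)
    if (r < 2) next
    ni <- sapply(pops, function(p) sum(gl == p))
    nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
    for (al in unique(c(x1, x2))) {
      y1 <- as.numeric(x1 == al); y2 <- as.numeric(x2 == al)
      mean_ind <- (y1 + y2) / 2
      mean_pop <- sapply(pops, function(p) mean(c(y1[gl == p], y2[gl == p])))
      gm <- mean(c(y1, y2))
      ss_c <- sum((y1 - mean_ind)^2 + (y2 - mean_ind)^2)
      ss_b <- 2 * sum((mean_ind - mean_pop[match(gl, pops)])^2)
      ss_a <- 2 * sum(ni * (mean_pop - gm)^2)
      df_c <- sum(ok); df_b <- sum(ni - 1); df_a <- r - 1
      ms_c <- ss_c / df_c
      ms_b <- if (df_b > 0) ss_b / df_b else 0
      ms_a <- ss_a / df_a
      sc <- ms_c
      sb <- (ms_b - ms_c) / 2
      sa <- (ms_a - ms_b) / (2 * nc)
      A <- A + sa; B <- B + sb; C <- C + sc
    }
  }
  A / (A + B + C)
}

## R_ST oracle: definitional size-variance decomposition written
## independently (explicit group loops, no shared helper)
oracle_rst <- function(g, groups = g$pop) {
  SA <- SW <- 0
  for (l in seq_along(g$loci)) {
    a1 <- g$alleles[, l, 1]; a2 <- g$alleles[, l, 2]
    ok <- !is.na(a1)
    sizes <- c(a1[ok], a2[ok]); gl <- rep(groups[ok], 2)
    pops <- unique(gl)
    if (length(pops) < 2) next
    fit <- stats::aov(sizes ~ factor(gl))
    tab <- summary(fit)[[1]]
    msa <- tab["factor(gl)", "Mean Sq"]; msw <- tab["Residuals", "Mean Sq"]
    nj <- table(gl); N <- sum(nj); r <- length(nj)
    n0 <- (N - sum(nj^2) / N) / (r - 1)
    SA <- SA + (msa - msw) / n0
    SW <- SW + msw
  }
  SA / (SA + SW)
}

## exhaustive least-cost search: DFS over simple paths with branch-and-bound
## pruning (exact: pruning only cuts paths provably not better)
oracle_lcp <- function(cost, src, dst) {
  nr <- nrow(cost); nc <- ncol(cost)
  best <- Inf
  visited <- matrix(FALSE, nr, nc)
  dfs <- function(r, c, acc) {
    if (acc >= best) return()
    if (r == dst[1] && c == dst[2]) { best <<- acc; return() }
    visited[r, c] <<- TRUE
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (visited[r2, c2] || is.na(cost[r2, c2])) next
      step <- sqrt(dr^2 + dc^2) * (cost[r, c] + cost[r2, c2]) / 2
      dfs(r2, c2, acc + step)
    }
    visited[r, c] <<- FALSE
  }
  dfs(src[1], src[2], 0)
  best
}

## effective resistance via dense Laplacian pseudoinverse
oracle_resistance <- function(cost, cellsA, cellsB, cell_size = 1) {
  nr <- nrow(cost); nc <- ncol(cost)
  perm <- which(!is.na(cost))
  id <- match(seq_len(nr * nc), perm)
  n <- length(perm)
  ## contract regions to two supernodes appended at the end
  grp <- rep(0L, n)
  grp[id[cellsA]] <- 1L; grp[id[cellsB]] <- 2L
  ord <- which(grp == 0L)
  node <- integer(n)
  node[ord] <- seq_along(ord)
  node[grp == 1L] <- length(ord) + 1L
  node[grp == 2L] <- length(ord) + 2L
  nn <- length(ord) + 2L
  L <- matrix(0, nn, nn)
  for (cell in perm) {
    r <- (cell - 1) %% nr + 1; c <- (cell - 1) %/% nr + 1
    for (d in list(c(1, 0), c(0, 1))) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 > nr || c2 > nc) next
      cell2 <- (c2 - 1) * nr + r2
      if (is.na(cost[cell2])) next
      g <- 1 / ((cost[cell] + cost[cell2]) / 2 * cell_size)
      i <- node[id[cell]]; j <- node[id[cell2]]
      if (i == j) next
      L[i, j] <- L[i, j] - g; L[j, i] <- L[j, i] - g
      L[i, i] <- L[i, i] + g; L[j, j] <- L[j, j] + g
    }
  }
  Lp <- MASS::ginv(L)
  s <- length(ord) + 1L; t <- length(ord) + 2L
  e <- rep(0, nn); e[s] <- 1; e[t] <- -1
  drop(t(e) %*% Lp %*% e)
}

## exhaustive one-tailed Mantel p over all label permutations
oracle_mantel_exact <- function(x, y) {
  n <- nrow(x)
  vx <- x[lower.tri(x)]
  r_obs <- stats::cor(vx, y[lower.tri(y)])
  perms <- all_perms(seq_len(n))
  cnt <- 0L
  for (p in perms) {
    yp <- y[p, p]
    if (stats::cor(vx, yp[lower.tri(yp)]) >= r_obs - 1e-12) cnt <- cnt + 1L
  }
  cnt / length(perms)
}

all_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

## probability two full sibs share a single-locus genotype, by full
## enumeration over parental genotype pairs under HWE
oracle_pi_sib <- function(p) {
  alleles <- seq_along(p)
  genos <- expand.grid(a = alleles, b = alleles)
  gprob <- p[genos$a] * p[genos$b]                 # ordered genotypes
  tot <- 0
  for (m in seq_len(nrow(genos))) for (f in seq_len(nrow(genos))) {
    pm <- gprob[m] * gprob[f]
    ## child genotype distribution given parents (unordered keys)
    keys <- c()
    probs <- c()
    for (cm in c(genos$a[m], genos$b[m])) for (cf in c(genos$a[f], genos$b[f])) {
      key <- paste(min(cm, cf), max(cm, cf))
      keys <- c(keys, key); probs <- c(probs, 0.25)
    }
    tab <- tapply(probs, keys, sum)
    tot <- tot + pm * sum(tab^2)                   # two sibs identical
  }
  tot
}

## Procrustes distance after optimal rotation/reflection/translation
procrustes_error <- function(X, Y) {
  X <- scale(X, scale = FALSE); Y <- scale(Y, scale = FALSE)
  s <- svd(t(Y) %*% X)
  R <- s$u %*% t(s$v)
  sqrt(sum((X - Y %*% R)^2))
}

rdirichlet_weights <- function(k) { x <- stats::rgamma(k, 1); x / sum(x) }

## all path cells lie inside the corridor mask
cost_mask_path <- function(mask, cells)
  vapply(seq_len(nrow(cells)), function(k) mask[cells[k, 1], cells[k, 2]], TRUE)

## exhaustive 4-neighbour least-cost search (series-resistance bound)
oracle_lcp4 <- function(cost, src, dst) {
  nr <- nrow(cost); nc <- ncol(cost)
  best <- Inf
  visited <- matrix(FALSE, nr, nc)
  dfs <- function(r, c, acc) {
    if (acc >= best) return()
    if (r == dst[1] && c == dst[2]) { best <<- acc; return() }
    visited[r, c] <<- TRUE
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (visited[r2, c2] || is.na(cost[r2, c2])) next
      dfs(r2, c2, acc + (cost[r, c] + cost[r2, c2]) / 2)
    }
    visited[r, c] <<- FALSE
  }
  dfs(src[1], src[2], 0)
  best
}
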