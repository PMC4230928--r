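#' Assemble the spatial and genetic distance-matrix set
#'
#' Builds Euclidean centroid distances (GGD), their log10 transform
#' (logGGD), imports least-cost path/corridor and resistance matrices, and
#' linearizes genetic differentiation matrices (`d/(1-d)`). All matrices
#' share one label set; mismatches are an error naming the offenders.
#'
#' @param centroids matrix with rownames (population labels) and columns
#'   x, y in km
#' @param lcpd,lccd,rd optional labelled symmetric matrices from the
#'   connectivity step
#' @param genetic optional named list of `gen_dist` objects (or matrices)
#'   to linearize
#' @return named list of labelled matrices: `GGD`, `logGGD`, and any of
#'   `LCPD`, `LCCD`, `RD`, `gen_<name>`
#' @export
build_distance_matrices <- function(centroids, lcpd = NULL, lccd = NULL,
                                    rd = NULL, genetic = NULL) {
  labs <- rownames(centroids)
  if (is.null(labs)) stop("centroids need rownames (population labels)")
  ggd <- as.matrix(stats::dist(centroids))
  out <- list(GGD = ggd)
  lg <- ggd
  lg[lg > 0] <- log10(lg[lg > 0])
  diag(lg) <- 0
  out$logGGD <- lg
  check <- function(m, nm) {
    if (!setequal(rownames(m), labs))
      stop(nm, " labels differ from centroids: ",
           paste(symdiff_chr(rownames(m), labs), collapse = ", "))
    m[labs, labs]
  }
  if (!is.null(lcpd)) out$LCPD <- check(lcpd, "LCPD")
  if (!is.null(lccd)) out$LCCD <- check(lccd, "LCCD")
  if (!is.null(rd)) out$RD <- check(rd, "RD")
  if (!is.null(genetic)) for (nm in names(genetic)) {
    m <- genetic[[nm]]
    if (inherits(m, "gen_dist")) m <- m$clipped
    out[[paste0("gen_", nm)]] <- check(linearize(m), nm)
  }
  out
}

symdiff_chr <- function(a, b) union(setdiff(a, b), setdiff(b, a))

## lower-triangle vectorization with pairwise-complete handling of Inf/NA
lt_vec <- function(m) m[lower.tri(m)]

#' Mantel test of matrix correlation
#'
#' Pearson correlation of the vectorized off-diagonal entries, with a
#' one-tailed (positive association) permutation p-value obtained by
#' simultaneous row/column permutation of one matrix; `p = (count of
#' permuted r >= observed + 1) / (n_perm + 1)`. Pairs that are not finite
#' in either matrix (disconnected) are dropped pairwise, with the count
#' recorded.
#'
#' @param x,y symmetric labelled matrices with identical label sets
#' @param n_perm permutations
#' @param seed integer seed
#' @return list of class `mantel_result`: `r`, `p`, `n_perm`, `n_dropped`
#' @export
mantel <- function(x, y, n_perm = 10000L, seed = 1L) {
  m <- align_pair(x, y)
  n <- nrow(m$x)
  if (n < 4) stop("need at least 4 labels")
  vx <- lt_vec(m$x); vy <- lt_vec(m$y)
  fin <- is.finite(vx) & is.finite(vy)
  n_dropped <- sum(!fin)
  if (stats::sd(vx[fin]) == 0 || stats::sd(vy[fin]) == 0)
    stop("constant distance matrix: correlation undefined")
  r_obs <- stats::cor(vx[fin], vy[fin])
  set.seed(seed)
  cnt <- 0L
  for (b in seq_len(n_perm)) {
    prm <- sample.int(n)
    vyp <- lt_vec(m$y[prm, prm])
    f <- is.finite(vx) & is.finite(vyp)
    if (stats::cor(vx[f], vyp[f]) >= r_obs - 1e-12) cnt <- cnt + 1L
  }
  structure(list(r = r_obs, p = (cnt + 1) / (n_perm + 1), n_perm = n_perm,
                 n_dropped = n_dropped), class = "mantel_result")
}

align_pair <- function(x, y) {
  if (!is.null(rownames(x)) && !is.null(rownames(y))) {
    if (!setequal(rownames(x), rownames(y)))
      stop("matrix labels differ: ",
           paste(symdiff_chr(rownames(x), rownames(y)), collapse = ", "))
    y <- y[rownames(x), rownames(x)]
  }
  if (!all(dim(x) == dim(y))) stop("matrix dimensions differ")
  list(x = as.matrix(x), y = as.matrix(y))
}

#' Partial Mantel test controlling for one or more matrices
#'
#' Correlates the residuals of `x` and `y` after elementwise linear
#' regression on the control matrices `z`, permuting the residuals of one
#' matrix under the Freedman-Lane scheme (row/column permutation of the
#' residual matrix); one-tailed for positive association.
#'
#' @param x,y matrices under test
#' @param z a control matrix or list of control matrices
#' @param n_perm permutations
#' @param seed integer seed
#' @return a `mantel_result`; `collinear` flags |r| > 0.999 between a
#'   control and x or y
#' @export
partial_mantel <- function(x, y, z, n_perm = 10000L, seed = 1L) {
  if (!is.list(z)) z <- list(z)
  m <- align_pair(x, y)
  zs <- lapply(z, function(zz) align_pair(m$x, zz)$y)
  n <- nrow(m$x)
  vx <- lt_vec(m$x); vy <- lt_vec(m$y)
  Z <- cbind(1, do.call(cbind, lapply(zs, lt_vec)))
  fin <- is.finite(vx) & is.finite(vy) & apply(is.finite(Z), 1, all)
  collinear <- any(vapply(seq_len(ncol(Z) - 1), function(k) {
    zc <- Z[fin, k + 1]
    abs(stats::cor(zc, vx[fin])) > 0.999 || abs(stats::cor(zc, vy[fin])) > 0.999
  }, TRUE))
  ## residualize both on Z (elementwise OLS)
  rx_v <- stats::lsfit(Z[fin, -1, drop = FALSE], vx[fin])$residuals
  ry_v <- stats::lsfit(Z[fin, -1, drop = FALSE], vy[fin])$residuals
  ## residuals that are numerically zero (a control equals x or y) carry no
  ## signal: the partial correlation is 0 by convention, flagged collinear
  if (stats::sd(ry_v) < 1e-10 * max(stats::sd(vy[fin]), 1e-300) ||
      stats::sd(rx_v) < 1e-10 * max(stats::sd(vx[fin]), 1e-300)) {
    return(structure(list(r = 0, p = 1, n_perm = n_perm,
                          n_dropped = sum(!fin), collinear = TRUE),
                     class = "mantel_result"))
  }
  r_obs <- stats::cor(rx_v, ry_v)
  ## Freedman-Lane: permute the residual MATRIX of y by rows/columns
  ry_m <- matrix(0, n, n)
  ry_full <- rep(NA_real_, length(vy))
  ry_full[fin] <- ry_v
  ry_m[lower.tri(ry_m)] <- ry_full
  ry_m <- ry_m + t(ry_m)
  set.seed(seed)
  cnt <- 0L
  for (b in seq_len(n_perm)) {
    prm <- sample.int(n)
    vp <- lt_vec(ry_m[prm, prm])
    f <- fin & is.finite(vp)
    rp <- stats::lsfit(Z[f, -1, drop = FALSE], vp[f])$residuals
    rxp <- stats::lsfit(Z[f, -1, drop = FALSE], vx[f])$residuals
    if (stats::cor(rxp, rp) >= r_obs - 1e-12) cnt <- cnt + 1L
  }
  structure(list(r = r_obs, p = (cnt + 1) / (n_perm + 1), n_perm = n_perm,
                 n_dropped = sum(!fin), collinear = collinear),
            class = "mantel_result")
}

#' @method print mantel_result
#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel r = %.3f, one-tailed p = %.4g (%d permutations",
              x$r, x$p, x$n_perm))
  if (x$n_dropped > 0) cat(sprintf(", %d pairs dropped", x$n_dropped))
  cat(")\n")
  invisible(x)
}

#' Between/within-cluster indicator matrix
#'
#' 1 where two populations fall in different clusters, 0 within a cluster;
#' used as the control matrix when testing for isolation by distance while
#' holding hierarchical structure fixed.
#'
#' @param clusters named vector: population label -> cluster label
#' @return binary symmetric matrix with zero diagonal
#' @export
cluster_control_matrix <- function(clusters) {
  labs <- names(clusters)
  if (is.null(labs)) stop("clusters must be a named vector")
  m <- outer(clusters, clusters, FUN = `!=`) * 1
  dimnames(m) <- list(labs, labs)
  diag(m) <- 0
  m
}

#' Compare spatial distance models against genetic differentiation
#'
#' Runs the Mantel test of each genetic matrix against each spatial model,
#' the percentage change in fit relative to the straight-line (GGD)
#' baseline, cluster-controlled partial correlations, and pairwise partial
#' tests of the focal model holding GGD fixed.
#'
#' @param dm a [build_distance_matrices()] result
#' @param clusters optional named vector population -> cluster for the
#'   cluster-controlled partials
#' @param n_perm permutations per test
#' @param seed integer seed
#' @return list of class `model_comparison`: `table` (data.frame: genetic,
#'   spatial, r, p, pct_increase_vs_GGD), `partials` (data.frame of
#'   cluster-controlled and GGD-controlled partial r/p)
#' @export
model_comparison_report <- function(dm, clusters = NULL, n_perm = 999L,
                                    seed = 1L) {
  gen_names <- grep("^gen_", names(dm), value = TRUE)
  sp_names <- setdiff(names(dm), gen_names)
  if (!length(gen_names)) stop("no genetic matrices in the set")
  rows <- list(); partials <- list()
  si <- 0L
  for (gn in gen_names) for (sn in sp_names) {
    si <- si + 1L
    mt <- mantel(dm[[gn]], dm[[sn]], n_perm = n_perm, seed = seed + si)
    rows[[length(rows) + 1L]] <-
      data.frame(genetic = gn, spatial = sn, r = mt$r, p = mt$p)
  }
  tab <- do.call(rbind, rows)
  base <- tab$r[match(paste(tab$genetic, "GGD"), paste(tab$genetic, tab$spatial))]
  tab$pct_increase_vs_GGD <- ifelse(base > 0, 100 * (tab$r - base) / base, NA)
  for (gn in gen_names) for (sn in setdiff(sp_names, c("GGD", "logGGD"))) {
    si <- si + 1L
    pm <- partial_mantel(dm[[gn]], dm[[sn]], dm[["GGD"]],
                         n_perm = n_perm, seed = seed + si)
    partials[[length(partials) + 1L]] <-
      data.frame(genetic = gn, spatial = sn, control = "GGD",
                 r = pm$r, p = pm$p)
    if (!is.null(clusters)) {
      cc <- cluster_control_matrix(clusters[rownames(dm[[gn]])])
      si <- si + 1L
      pm2 <- partial_mantel(dm[[gn]], dm[[sn]], cc, n_perm = n_perm,
                            seed = seed + si)
      partials[[length(partials) + 1L]] <-
        data.frame(genetic = gn, spatial = sn, control = "clusters",
                   r = pm2$r, p = pm2$p)
    }
  }
  structure(list(table = tab,
                 partials = if (length(partials)) do.call(rbind, partials) else NULL),
            class = "model_comparison")
}

#' Percentage increase in Mantel fit over a baseline correlation
#' @param r_model,r_baseline Mantel correlations
#' @return `100 * (r_model - r_baseline) / r_baseline`
#' @export
fit_increase_pct <- function(r_model, r_baseline) {
  100 * (r_model - r_baseline) / r_baseline
}

#' Run the full synthetic landscape-genetics pipeline
#'
#' Seeded end-to-end run: landscape, resistance-driven metapopulation
#' drift, noisy scat replicates, consensus genotyping and individual
#' matching, differentiation matrices, occupancy surveys and fit, cost
#' surface, least-cost and resistance distances, and the Mantel model
#' comparison. Migration between demes decays with the resistance distance
#' between their patches, so the generating spatial model is the
#' circuit-theory one.
#'
#' @param config a [sim_config()]
#' @param out_dir optional directory for CSV/ASCII artifacts
#' @param n_perm permutations for the Mantel stage
#' @return list of class `pipeline_result`: `landscape`, `metapop`,
#'   `individuals`, `fst`, `occupancy`, `distances`, `comparison`,
#'   `manifest`
#' @export
run_pipeline <- function(config, out_dir = NULL, n_perm = 499L) {
  stopifnot(inherits(config, "sim_config"))
  land <- gen_landscape(config)
  ## resistance distances between patches on the raw landscape cost
  rough_cost <- matrix(1, nrow(land$habitat), ncol(land$habitat))
  rough_cost[land$habitat == 1] <- 0.1
  rough_cost[land$settlement == 1] <- NA
  regions <- lapply(seq_len(config$n_patches), function(k)
    attr(land$habitat, "patch_id") == k)
  names(regions) <- rownames(land$centroids)[seq_len(config$n_patches)]
  rr <- effective_resistance(rough_cost, regions)
  ## migration decays with resistance
  J <- config$n_pops
  rd <- rr$rd[seq_len(J), seq_len(J)]
  rd_fin <- rd[upper.tri(rd)][is.finite(rd[upper.tri(rd)])]
  if (!length(rd_fin)) stop("all patch pairs are disconnected")
  mig <- exp(-rd / (0.5 * stats::median(rd_fin)))    # exp(-Inf) = 0: no flow
  diag(mig) <- 0
  mig <- mig / max(rowSums(mig)) * 0.15       # cap total emigration at 15%
  diag(mig) <- 1 - rowSums(mig)
  cfg2 <- config; cfg2$migration_matrix <- mig
  meta <- gen_metapopulation(cfg2, land)
  reps <- gen_noninvasive_samples(meta, config, seed = config$seed + 2L)
  cons <- consensus_genotypes(reps, het_min = 2L,
                              hom_min = min(5L, config$replicate_count))
  matched <- match_individuals(cons, min_loci = min(7L, config$n_loci))
  inds <- matched$individuals
  fst <- pairwise_fst(inds, n_perm = 0)
  ## occupancy: truth psi higher inside habitat, surveys everywhere
  G <- 200L
  psi_true <- stats::runif(G, 0.3, 0.8)
  hist <- gen_detection_histories(psi_true, config$detection_base, config,
                                  seed = config$seed + 3L)
  occ <- fit_occupancy(hist, ~ 1, "constant")
  ## cost surface from fitted occupancy applied to the habitat raster
  psi_r <- matrix(mean(occ$psi_hat), nrow(land$habitat), ncol(land$habitat))
  lc <- ifelse(land$settlement == 1, 2L, ifelse(land$habitat == 1, 1L, 0L))
  cost <- build_cost_surface(psi_r, lc, cell_size_km = config$cell_size_km)
  res <- effective_resistance(cost, regions)
  pops_present <- intersect(rownames(land$centroids), unique(inds$pop))
  lcpd <- matrix(0, length(pops_present), length(pops_present),
                 dimnames = list(pops_present, pops_present))
  for (a in seq_along(pops_present)[-length(pops_present)])
    for (b in (a + 1):length(pops_present)) {
      p <- least_cost_path(cost, regions[[pops_present[a]]],
                           regions[[pops_present[b]]])
      lcpd[a, b] <- lcpd[b, a] <- p$cost
    }
  dm <- build_distance_matrices(
    land$centroids[pops_present, , drop = FALSE],
    lcpd = lcpd,
    rd = res$rd[pops_present, pops_present],
    genetic = list(fst = fst$clipped[pops_present, pops_present]))
  cmp <- model_comparison_report(dm, n_perm = n_perm, seed = config$seed + 4L)
  manifest <- list(seed = config$seed, n_pops = J,
                   n_individuals = n_samples(inds),
                   mean_fst = mean(fst$estimate[upper.tri(fst$estimate)]),
                   psi_hat = mean(occ$psi_hat), p_hat = mean(occ$p_hat),
                   timestamp_free = TRUE)
  out <- structure(list(landscape = land, metapop = meta, individuals = inds,
                        fst = fst, occupancy = occ, distances = dm,
                        comparison = cmp, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_genepop(inds, file.path(out_dir, "individuals.gen"))
    write_distance_csv(fst$estimate, file.path(out_dir, "fst.csv"))
    write_asc(cost$cost, file.path(out_dir, "cost.asc"),
              cellsize = config$cell_size_km)
    utils::write.csv(cmp$table, file.path(out_dir, "mantel_table.csv"),
                     row.names = FALSE)
  }
  out
}
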