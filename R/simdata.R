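#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generator: the
#' metapopulation (number of demes, effective sizes, per-generation migration,
#' two-phase microsatellite mutation), the non-invasive genotyping noise
#' (allelic dropout, whole-locus missingness, replicate count), and the
#' landscape / sign-survey design (grid shape, surveys per grid, detection
#' probability). Defaults emulate a microsatellite scat survey of a large
#' territorial carnivore: 11 loci with 4-12 alleles, demes of effective size
#' 50 drifting to pairwise F_ST in the 0.05-0.25 band, dropout 0.1 and
#' missing-locus rate 0.07 (roughly 93% of loci typed), 3-35 replicate sign
#' surveys per grid at detection probability 0.2.
#'
#' @param seed integer seed driving all randomness downstream.
#' @param n_pops number of demes.
#' @param n_loci number of microsatellite loci.
#' @param alleles_per_locus length-2 range of founding allele counts per locus.
#' @param effective_size diploid effective size per deme.
#' @param migration_matrix `n_pops x n_pops` per-generation fractions; rows
#'   must sum to <= 1 with the diagonal equal to 1 - sum(off-diagonal). A
#'   scalar is expanded to a symmetric matrix with that off-diagonal rate.
#' @param n_generations generations of forward-time drift.
#' @param mutation_rate per-locus per-generation mutation probability.
#' @param stepwise_fraction single-step share of the two-phase mutation model.
#' @param tpm_variance variance of the multi-step (geometric) tail.
#' @param dropout_rate per-allele dropout probability per replicate.
#' @param missing_locus_rate per-sample whole-locus failure probability.
#' @param replicate_count genotyping replicates per sample.
#' @param grid_shape `c(rows, cols)` of the survey landscape.
#' @param cell_size_km raster cell size in km.
#' @param surveys_per_grid length-2 range of replicate surveys per grid.
#' @param detection_base per-survey detection probability at occupied grids.
#' @param n_patches habitat patches carved into the landscape.
#' @param settlement_band if `TRUE`, an impermeable settlement band crosses
#'   the non-habitat matrix.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_pops = 4L, n_loci = 11L,
                       alleles_per_locus = c(4L, 12L), effective_size = 50L,
                       migration_matrix = 0.02, n_generations = 100L,
                       mutation_rate = 5e-4, stepwise_fraction = 0.95,
                       tpm_variance = 12, dropout_rate = 0.1,
                       missing_locus_rate = 0.07, replicate_count = 3L,
                       grid_shape = c(20L, 20L), cell_size_km = 10,
                       surveys_per_grid = c(3L, 35L), detection_base = 0.2,
                       n_patches = n_pops, settlement_band = FALSE) {
  if (length(migration_matrix) == 1L) {
    m <- matrix(migration_matrix, n_pops, n_pops)
    diag(m) <- 0
    diag(m) <- 1 - rowSums(m)
    migration_matrix <- m
  }
  stopifnot(nrow(migration_matrix) == n_pops, ncol(migration_matrix) == n_pops)
  off <- migration_matrix; diag(off) <- 0
  if (any(rowSums(off) > 1 + 1e-12)) stop("migration row sums exceed 1")
  if (max(abs(diag(migration_matrix) - (1 - rowSums(off)))) > 1e-8)
    stop("migration diagonal must equal 1 - sum(off-diagonal)")
  probs <- c(mutation_rate, stepwise_fraction, dropout_rate,
             missing_locus_rate, detection_base, migration_matrix)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  stopifnot(n_pops >= 1, n_loci >= 1, effective_size >= 2,
            length(grid_shape) == 2, all(surveys_per_grid >= 0),
            replicate_count >= 1, tpm_variance >= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic landscape raster set
#'
#' Carves `n_patches` mutually disjoint habitat patches into a non-habitat
#' matrix, lays down spatially autocorrelated covariate rasters (forest
#' quality, prey index, human disturbance; smoothed white noise, kernel
#' width 3 cells) and optionally a vertical settlement band through the
#' matrix between the two central patch columns. Settlement cells are always
#' non-habitat.
#'
#' @param config a [sim_config()]
#' @return list of class `sim_landscape` with matrices `habitat` (0/1 with
#'   patch id as attribute `patch_id`), `forest`, `prey`, `disturbance`
#'   (in \[0,1\]), `settlement` (0/1), plus `cell_size_km` and the patch
#'   centroid coordinates `centroids` (km, planar).
#' @export
gen_landscape <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  if (nr < 5 || nc < 5) stop("grid_shape must be at least 5x5")
  set.seed(config$seed)
  np <- config$n_patches
  ## patch centers on a jittered sub-grid so patches never touch
  gr <- ceiling(sqrt(np)); gc <- ceiling(np / gr)
  rows <- round(seq(nr / (2 * gr), nr - nr / (2 * gr), length.out = gr))
  cols <- round(seq(nc / (2 * gc), nc - nc / (2 * gc), length.out = gc))
  centers <- expand.grid(r = rows, c = cols)[seq_len(np), , drop = FALSE]
  rad <- max(1, floor(0.3 * min(nr / gr, nc / gc)))
  habitat <- matrix(0L, nr, nc)
  patch_id <- matrix(0L, nr, nc)
  for (k in seq_len(np)) {
    rr <- pmax(1, centers$r[k] - rad):pmin(nr, centers$r[k] + rad)
    cc <- pmax(1, centers$c[k] - rad):pmin(nc, centers$c[k] + rad)
    for (i in rr) for (j in cc)
      if ((i - centers$r[k])^2 + (j - centers$c[k])^2 <= rad^2 + 0.5) {
        habitat[i, j] <- 1L; patch_id[i, j] <- k
      }
  }
  smooth_noise <- function() {
    z <- matrix(stats::rnorm(nr * nc), nr, nc)
    z <- kernel_smooth(z, width = 3)
    (z - min(z)) / (max(z) - min(z))
  }
  forest <- smooth_noise(); prey <- smooth_noise(); disturbance <- smooth_noise()
  forest <- pmin(1, forest + 0.4 * habitat)   # habitat is forested
  settlement <- matrix(0L, nr, nc)
  if (isTRUE(config$settlement_band)) {
    ## vertical settlement band with one narrow corridor gap (off-centre),
    ## so the matrix is crossable but only through a bottleneck
    band <- max(2, round(nc / 2)); band <- band:min(nc, band + 1)
    settlement[, band] <- 1L
    gap <- max(1, round(nr / 3)) + 0:1
    gap <- gap[gap <= nr]
    settlement[gap, band] <- 0L
    settlement[habitat == 1L] <- 0L
  }
  if (all(settlement == 1L)) stop("degenerate landscape: all settlement")
  attr(habitat, "patch_id") <- patch_id
  cs <- config$cell_size_km
  centroids <- cbind(x = (centers$c - 0.5) * cs, y = (nr - centers$r + 0.5) * cs)
  rownames(centroids) <- sprintf("pop%d", seq_len(np))
  structure(list(habitat = habitat, forest = forest, prey = prey,
                 disturbance = disturbance, settlement = settlement,
                 cell_size_km = cs, centroids = centroids),
            class = "sim_landscape")
}

## box-kernel smoother, reflecting edges
kernel_smooth <- function(z, width = 3) {
  h <- floor(width / 2)
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    rr <- max(1, i - h):min(nr, i + h)
    cc <- max(1, j - h):min(nc, j + h)
    out[i, j] <- mean(z[rr, cc])
  }
  out
}

#' Connected components of a binary raster (4-neighbour flood fill)
#' @param mask logical or 0/1 matrix
#' @return integer matrix of component labels (0 = background)
#' @export
patch_components <- function(mask) {
  mask <- mask > 0
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j] || lab[i, j]) next
    cur <- cur + 1L
    stack <- list(c(i, j)); lab[i, j] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
            mask[q[1], q[2]] && !lab[q[1], q[2]]) {
          lab[q[1], q[2]] <- cur
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
  }
  lab
}

#' Simulate a microsatellite metapopulation by forward-time drift
#'
#' Wright-Fisher demes exchanging gene copies at the configured migration
#' rates, with two-phase mutation (single repeat step with probability
#' `stepwise_fraction`, otherwise a geometric multi-step whose variance is
#' `tpm_variance`). Demes are founded from a common ancestral pool (so all
#' differentiation is accumulated drift) and evolved `n_generations`
#' generations. The returned truth ledger records each individual's deme of
#' origin and the realized pairwise F_ST of the end state.
#'
#' @param config a [sim_config()]
#' @param landscape optional [gen_landscape()] output; its patch centroids
#'   are attached to the ledger so genetic and spatial analyses share labels.
#' @return list of class `sim_metapop`: `genotypes` (a [geno_set()] of all
#'   `n_pops * effective_size` individuals at the final generation) and
#'   `ledger` (list with `origin`, `migrants` (empty data.frame), `fst_true`,
#'   `centroids`).
#' @export
gen_metapopulation <- function(config, landscape = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  J <- config$n_pops; L <- config$n_loci; N <- config$effective_size
  mig <- config$migration_matrix
  ## ancestral allele frequencies per locus: k alleles on a repeat ladder
  founder <- vector("list", L)
  for (l in seq_len(L)) {
    kk <- config$alleles_per_locus[1]:config$alleles_per_locus[2]
    k <- kk[sample.int(length(kk), 1)]
    start <- sample(8:20, 1)
    states <- start + seq_len(k) - 1L
    frq <- as.vector(stats::rgamma(k, 1)); frq <- frq / sum(frq)
    founder[[l]] <- list(states = states, freq = frq)
  }
  ## pops[[j]] is N x L x 2 integer array of repeat counts
  pops <- lapply(seq_len(J), function(j) {
    al <- array(NA_integer_, c(N, L, 2))
    for (l in seq_len(L))
      al[, l, ] <- sample(founder[[l]]$states, 2 * N, TRUE, founder[[l]]$freq)
    al
  })
  pg <- tpm_geom_p(config$tpm_variance)
  for (gen in seq_len(config$n_generations)) {
    newpops <- vector("list", J)
    for (j in seq_len(J)) {
      ## source deme of each gene copy, then parent within deme
      src <- sample.int(J, 2L * N, TRUE, prob = mig[j, ])
      al <- array(NA_integer_, c(N, L, 2))
      for (cp in 1:2) {
        idx <- (cp - 1L) * N + seq_len(N)
        s <- src[idx]
        par <- sample.int(N, N, TRUE)
        which_al <- matrix(sample.int(2L, N * L, TRUE), N, L)
        for (j2 in unique(s)) {
          rows <- which(s == j2)
          for (cc in 1:2) {
            sel <- which_al[rows, , drop = FALSE] == cc
            src_m <- pops[[j2]][par[rows], , cc, drop = FALSE]
            dim(src_m) <- c(length(rows), L)
            tgt <- al[rows, , cp, drop = FALSE]; dim(tgt) <- c(length(rows), L)
            tgt[sel] <- src_m[sel]
            al[rows, , cp] <- tgt
          }
        }
      }
      ## two-phase mutation
      nmut <- stats::rbinom(1, 2L * N * L, config$mutation_rate)
      if (nmut > 0) {
        pos <- sample.int(2L * N * L, nmut)
        step <- ifelse(stats::runif(nmut) < config$stepwise_fraction, 1L,
                       1L + stats::rgeom(nmut, pg))
        step <- step * sample(c(-1L, 1L), nmut, TRUE)
        al[pos] <- pmax(2L, pmin(200L, al[pos] + step))
      }
      newpops[[j]] <- al
    }
    pops <- newpops
  }
  al <- do.call(abind3, pops)
  ids <- sprintf("ind%04d", seq_len(J * N))
  poplab <- rep(sprintf("pop%d", seq_len(J)), each = N)
  g <- geno_set(al, ids, poplab)
  fst <- if (J >= 2) pairwise_fst(g, n_perm = 0)
         else list(estimate = matrix(0, 1, 1, dimnames = list("pop1", "pop1")))
  ledger <- list(origin = stats::setNames(poplab, ids),
                 migrants = data.frame(id = character(), source = character(),
                                       dest = character(), generation = integer()),
                 fst_true = fst$estimate,
                 centroids = if (!is.null(landscape)) landscape$centroids else NULL)
  structure(list(genotypes = g, ledger = ledger, config = config),
            class = "sim_metapop")
}

## geometric parameter so a signed 1+geom step has variance tpm_variance
tpm_geom_p <- function(v) {
  ## E[k^2] for k = 1 + G, G ~ geom(p): (2 - p) / p^2 ; solve = v
  (-1 + sqrt(1 + 8 * v)) / (4 * v)
}

#' Plant known migrants into a simulated metapopulation
#'
#' First-generation migrants are individuals lifted from the source deme and
#' relabelled to the destination; second-generation migrants are new
#' offspring of one source parent and one destination parent (one allele
#' from each parent per locus). Planting happens after drift, immediately
#' before sampling, so "first generation" is defined at sampling time.
#'
#' @param metapop a [gen_metapopulation()] result
#' @param moves data.frame with columns `source`, `dest` (population labels)
#'   and `generation` (1 or 2)
#' @param seed integer seed
#' @return the modified `sim_metapop`; ledger gains one row per migrant.
#' @export
plant_migrants <- function(metapop, moves, seed = 1L) {
  stopifnot(inherits(metapop, "sim_metapop"))
  set.seed(seed)
  g <- metapop$genotypes
  recs <- metapop$ledger$migrants
  pops <- unique(g$pop)
  used <- character()
  for (i in seq_len(nrow(moves))) {
    src <- as.character(moves$source[i]); dst <- as.character(moves$dest[i])
    gen <- as.integer(moves$generation[i])
    if (!src %in% pops || !dst %in% pops) stop("unknown population label: ", src, "/", dst)
    if (src == dst) stop("source and destination must differ")
    if (gen == 1L) {
      cand <- setdiff(g$ids[g$pop == src], used)
      id <- sample(cand, 1)
      g$pop[g$ids == id] <- dst
      used <- c(used, id)
    } else if (gen == 2L) {
      p1 <- sample(setdiff(g$ids[g$pop == src], used), 1)
      p2 <- sample(setdiff(g$ids[g$pop == dst], used), 1)
      a1 <- g$alleles[g$ids == p1, , , drop = FALSE]
      a2 <- g$alleles[g$ids == p2, , , drop = FALSE]
      L <- length(g$loci)
      child <- array(NA_integer_, c(1, L, 2))
      pick1 <- sample.int(2, L, TRUE); pick2 <- sample.int(2, L, TRUE)
      for (l in seq_len(L)) {
        child[1, l, 1] <- a1[1, l, pick1[l]]
        child[1, l, 2] <- a2[1, l, pick2[l]]
      }
      id <- sprintf("mig%03d", nrow(recs) + 1L)
      gc <- geno_set(child, id, dst, g$loci)
      g <- rbind_geno(g, gc)
    } else stop("generation must be 1 or 2")
    recs <- rbind(recs, data.frame(id = id, source = src, dest = dst,
                                   generation = gen))
  }
  if (anyDuplicated(recs$id)) stop("migrant planted twice")
  metapop$genotypes <- g
  metapop$ledger$migrants <- recs
  metapop$ledger$origin <- stats::setNames(
    ifelse(g$ids %in% recs$id, NA_character_, g$pop), g$ids)
  for (i in seq_len(nrow(recs)))
    metapop$ledger$origin[recs$id[i]] <- recs$source[i]
  metapop
}

#' Generate noisy non-invasive genotyping replicates
#'
#' Emulates scat genotyping noise: per replicate, each locus fails entirely
#' with probability `missing_locus_rate`; at typed loci, each allele of a
#' heterozygote drops out independently with probability `dropout_rate`
#' (one surviving allele is read as a false homozygote; both dropping loses
#' the locus).
#'
#' @param g a [geno_set()] of true genotypes (or a `sim_metapop`)
#' @param config a [sim_config()] supplying the noise rates
#' @param seed integer seed
#' @return a [geno_set()] of replicates with ids `<id>_r<k>` and attribute
#'   `sample_of` mapping replicate rows to true individual ids.
#' @export
gen_noninvasive_samples <- function(g, config, seed = 1L) {
  if (inherits(g, "sim_metapop")) g <- g$genotypes
  stopifnot(inherits(g, "geno_set"), inherits(config, "sim_config"))
  set.seed(seed)
  R <- config$replicate_count
  n <- n_samples(g); L <- length(g$loci)
  reps <- vector("list", n * R)
  ids <- character(n * R); pop <- character(n * R); sample_of <- character(n * R)
  k <- 0L
  for (i in seq_len(n)) for (r in seq_len(R)) {
    k <- k + 1L
    al <- g$alleles[i, , , drop = FALSE]
    lost <- stats::runif(L) < config$missing_locus_rate
    drop1 <- stats::runif(L) < config$dropout_rate
    drop2 <- stats::runif(L) < config$dropout_rate
    het <- !is.na(al[1, , 1]) & al[1, , 1] != al[1, , 2]
    for (l in seq_len(L)) {
      if (lost[l] || is.na(al[1, l, 1])) { al[1, l, ] <- NA_integer_; next }
      if (het[l]) {
        if (drop1[l] && drop2[l]) al[1, l, ] <- NA_integer_
        else if (drop1[l]) al[1, l, 1] <- al[1, l, 2]
        else if (drop2[l]) al[1, l, 2] <- al[1, l, 1]
      }
    }
    reps[[k]] <- al
    ids[k] <- sprintf("%s_r%d", g$ids[i], r)
    pop[k] <- g$pop[i]; sample_of[k] <- g$ids[i]
  }
  out <- geno_set(do.call(abind3, reps), ids, pop, g$loci)
  attr(out, "sample_of") <- sample_of
  out
}

#' Generate replicated detection/non-detection survey histories
#'
#' Each grid's occupancy state is drawn once (closure) from its occupancy
#' probability; detections are then independent Bernoulli draws at occupied
#' grids only. Survey counts vary per grid across the configured range;
#' grids with zero surveys are emitted with an empty history and flagged.
#'
#' @param psi numeric vector of true per-grid occupancy probabilities
#' @param p per-survey detection probability: scalar, or vector per grid
#' @param config a [sim_config()] (survey count range)
#' @param covariates optional data.frame of site covariates (one row/grid)
#' @param seed integer seed
#' @return list of class `detection_history`: `grid_id`, `y` (list of 0/1
#'   vectors), `covariates`, `z_true`, `psi_true`, `p_true`, `unsurveyed`
#'   (logical flag for empty histories).
#' @export
gen_detection_histories <- function(psi, p, config, covariates = NULL, seed = 1L) {
  stopifnot(all(psi >= 0 & psi <= 1), all(p >= 0 & p <= 1))
  set.seed(seed)
  G <- length(psi)
  if (length(p) == 1L) p <- rep(p, G)
  kk <- config$surveys_per_grid[1]:config$surveys_per_grid[2]
  k <- kk[sample.int(length(kk), G, TRUE)]
  z <- stats::rbinom(G, 1, psi)
  y <- lapply(seq_len(G), function(i)
    if (k[i] == 0L) numeric(0) else stats::rbinom(k[i], 1, p[i] * z[i]))
  structure(list(grid_id = sprintf("g%04d", seq_len(G)), y = y,
                 covariates = covariates, z_true = z, psi_true = psi,
                 p_true = p, unsurveyed = k == 0L),
            class = "detection_history")
}
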