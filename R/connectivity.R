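#' Build a movement-cost surface from occupancy probability
#'
#' Habitat cells cost `1 - psi` (occupancy probability as habitat
#' suitability); non-habitat cells are permeable at a higher flat cost
#' (`nonhabitat_multiplier` times the maximum habitat cost of 1); human
#' settlement cells are impermeable and excluded from every graph. Costs
#' are floored at a small epsilon so conductances stay finite.
#'
#' @param psi_raster matrix of occupancy probabilities (NA outside habitat)
#' @param landcover integer matrix of the same shape: `habitat_class` cells
#'   take the occupancy-based cost, `settlement_class` cells are
#'   impermeable, all other classes are non-habitat
#' @param nonhabitat_multiplier flat non-habitat cost (> 1)
#' @param habitat_class,settlement_class landcover codes
#' @param cell_size_km cell size in km
#' @return object of class `cost_raster`: `cost` matrix (NA = impermeable),
#'   `impermeable` mask, `cell_size_km`
#' @export
build_cost_surface <- function(psi_raster, landcover,
                               nonhabitat_multiplier = 3,
                               habitat_class = 1L, settlement_class = 2L,
                               cell_size_km = 1) {
  if (!all(dim(psi_raster) == dim(landcover)))
    stop("psi raster and landcover raster shapes differ")
  if (nonhabitat_multiplier <= 1) stop("nonhabitat_multiplier must exceed 1")
  eps <- 1e-6
  cost <- matrix(nonhabitat_multiplier, nrow(landcover), ncol(landcover))
  hab <- landcover == habitat_class
  cost[hab] <- pmax(1 - psi_raster[hab], eps)
  cost[is.na(cost)] <- nonhabitat_multiplier
  imp <- landcover == settlement_class
  cost[imp] <- NA_real_
  structure(list(cost = cost, impermeable = imp,
                 cell_size_km = cell_size_km),
            class = "cost_raster")
}

## lattice graph over permeable cells; returns igraph + cell index map
## neighborhood 8 (paths) or 4 (circuits); edge weight = mean cell cost x
## step length x cell size (for resistance, weight = resistance of the edge)
cost_graph <- function(cost, neighborhood = 8) {
  cm <- if (inherits(cost, "cost_raster")) cost$cost else cost
  cs <- if (inherits(cost, "cost_raster")) cost$cell_size_km else 1
  nr <- nrow(cm); nc <- ncol(cm)
  perm <- which(!is.na(cm))
  node_of <- rep(NA_integer_, nr * nc)
  node_of[perm] <- seq_along(perm)
  offs <- list(c(1, 0), c(0, 1))
  if (neighborhood == 8) offs <- c(offs, list(c(1, 1), c(1, -1)))
  from <- to <- integer(0); wt <- numeric(0)
  for (off in offs) {
    dr <- off[1]; dc <- off[2]
    rows <- seq_len(nr); cols <- seq_len(nc)
    r1 <- rows[rows + dr >= 1 & rows + dr <= nr]
    c1 <- cols[cols + dc >= 1 & cols + dc <= nc]
    if (!length(r1) || !length(c1)) next
    a <- as.vector(outer(r1, (c1 - 1) * nr, `+`))
    b <- a + dr + dc * nr
    ok <- !is.na(cm[a]) & !is.na(cm[b])
    a <- a[ok]; b <- b[ok]
    step <- sqrt(dr^2 + dc^2) * cs
    from <- c(from, node_of[a]); to <- c(to, node_of[b])
    wt <- c(wt, (cm[a] + cm[b]) / 2 * step)
  }
  g <- igraph::make_graph(rbind(from, to), n = length(perm), directed = FALSE)
  igraph::E(g)$weight <- wt
  list(graph = g, perm = perm, node_of = node_of, nr = nr, nc = nc, cs = cs)
}

## region spec (logical mask, cell indices, or (row,col) matrix) -> cell ids
region_cells <- function(region, nr, nc) {
  ## logical (or full-raster-sized numeric) matrix = mask; numeric matrix
  ## with two columns = (row, col) pairs; plain vector = cell indices
  if (is.logical(region)) return(which(region))
  if (is.matrix(region)) {
    if (ncol(region) == 2 && !all(dim(region) == c(nr, nc)))
      return((region[, 2] - 1) * nr + region[, 1])
    if (ncol(region) == 2 && all(region %in% c(0, 1)) == FALSE)
      return((region[, 2] - 1) * nr + region[, 1])
    if (all(dim(region) == c(nr, nc)) && all(region %in% c(0, 1)))
      return(which(region > 0))
    return((region[, 2] - 1) * nr + region[, 1])
  }
  as.integer(region)
}

#' Least-cost path between two regions on a cost raster
#'
#' Dijkstra shortest path on the 8-connected lattice; the edge weight is
#' the mean of the two cell costs times the step length (1 orthogonal,
#' sqrt(2) diagonal) times the cell size. The region-to-region distance is
#' the minimum over all pairs of region boundary cells.
#'
#' @param cost a [build_cost_surface()] result (or plain cost matrix)
#' @param source,target regions: logical masks, cell indices, or two-column
#'   (row, col) matrices
#' @return list of class `path_result`: `cells` ((row, col) matrix along
#'   the path), `cost` (accumulated least cost, `Inf` if disconnected),
#'   `length_km` (geographic path length), `reachable`
#' @export
least_cost_path <- function(cost, source, target) {
  gg <- cost_graph(cost, neighborhood = 8)
  src <- region_cells(source, gg$nr, gg$nc)
  tgt <- region_cells(target, gg$nr, gg$nc)
  src_n <- gg$node_of[src]; tgt_n <- gg$node_of[tgt]
  src_n <- src_n[!is.na(src_n)]; tgt_n <- tgt_n[!is.na(tgt_n)]
  if (!length(src_n) || !length(tgt_n))
    stop("source/target region holds no permeable cell")
  ## virtual terminals with zero-weight spokes: min over boundary pairs
  nv <- igraph::vcount(gg$graph)
  g2 <- igraph::add_vertices(gg$graph, 2)
  s_v <- nv + 1L; t_v <- nv + 2L
  ed <- rbind(c(rbind(s_v, src_n)), c(rbind(t_v, tgt_n)))
  g2 <- igraph::add_edges(g2, c(rbind(s_v, src_n), rbind(t_v, tgt_n)),
                          weight = 0)
  sp <- suppressWarnings(
    igraph::shortest_paths(g2, from = s_v, to = t_v, weights = igraph::E(g2)$weight,
                           output = "both"))
  vp <- as.integer(sp$vpath[[1]])
  if (length(vp) == 0) {
    return(structure(list(cells = NULL, cost = Inf, length_km = NA_real_,
                          reachable = FALSE), class = "path_result"))
  }
  vp <- vp[vp <= nv]                      # strip virtual terminals
  cells_idx <- gg$perm[vp]
  rc <- cbind(row = (cells_idx - 1L) %% gg$nr + 1L,
              col = (cells_idx - 1L) %/% gg$nr + 1L)
  total <- sum(igraph::E(g2)$weight[as.integer(sp$epath[[1]])])
  steps <- diff(rc)
  len <- sum(sqrt(steps[, 1]^2 + steps[, 2]^2)) * gg$cs
  structure(list(cells = rc, cost = total, length_km = len, reachable = TRUE),
            class = "path_result")
}

#' Buffered least-cost corridor and within-corridor cost
#'
#' The corridor is every permeable cell within `buffer_km` of the path;
#' the corridor cost (LCCD) is the least-cost distance recomputed on the
#' graph restricted to the corridor, which can fall below the raw path
#' cost when the corridor admits a cheaper parallel route.
#'
#' @param path a [least_cost_path()] result
#' @param cost the cost raster the path was computed on
#' @param buffer_km corridor half-width in km
#' @return list of class `corridor_result`: `lccd`, `mask` (logical
#'   matrix), `path`
#' @export
corridor_cost <- function(path, cost, buffer_km = 1.5) {
  if (!path$reachable || is.null(path$cells)) stop("path is empty")
  cm <- if (inherits(cost, "cost_raster")) cost$cost else cost
  cs <- if (inherits(cost, "cost_raster")) cost$cell_size_km else 1
  nr <- nrow(cm); nc <- ncol(cm)
  mask <- matrix(FALSE, nr, nc)
  rad <- buffer_km / cs
  rr <- ceiling(rad)
  for (k in seq_len(nrow(path$cells))) {
    pr <- path$cells[k, 1]; pc <- path$cells[k, 2]
    for (i in max(1, pr - rr):min(nr, pr + rr))
      for (j in max(1, pc - rr):min(nc, pc + rr))
        if ((i - pr)^2 + (j - pc)^2 <= rad^2 + 1e-9) mask[i, j] <- TRUE
  }
  sub <- cm
  sub[!mask] <- NA_real_
  ends <- path$cells[c(1, nrow(path$cells)), , drop = FALSE]
  if (is.na(sub[ends[1, 1], ends[1, 2]]) || is.na(sub[ends[2, 1], ends[2, 2]]))
    stop("buffer excludes the path endpoints")
  subcost <- structure(list(cost = sub, impermeable = is.na(sub),
                            cell_size_km = cs), class = "cost_raster")
  p2 <- least_cost_path(subcost, ends[1, , drop = FALSE], ends[2, , drop = FALSE])
  structure(list(lccd = p2$cost, mask = mask, path = p2),
            class = "corridor_result")
}

## Laplacian of the conductance graph with regions collapsed to supernodes.
## Returns sparse Laplacian and the node index of each supernode.
conductance_laplacian <- function(cost, regions, neighborhood = 4) {
  gg <- cost_graph(cost, neighborhood = neighborhood)
  nR <- length(regions)
  memb <- rep(0L, igraph::vcount(gg$graph))    # 0 = ordinary cell
  for (r in seq_len(nR)) {
    cells <- region_cells(regions[[r]], gg$nr, gg$nc)
    nodes <- gg$node_of[cells]; nodes <- nodes[!is.na(nodes)]
    if (!length(nodes)) stop("region ", r, " holds no permeable cell")
    memb[nodes] <- r
  }
  ord <- which(memb == 0L)
  newid <- integer(length(memb))
  newid[ord] <- seq_along(ord)
  for (r in seq_len(nR)) newid[memb == r] <- length(ord) + r
  nn <- length(ord) + nR
  el <- igraph::as_edgelist(gg$graph, names = FALSE)
  cond <- 1 / igraph::E(gg$graph)$weight
  i <- newid[el[, 1]]; j <- newid[el[, 2]]
  keep <- i != j                                # drop intra-region edges
  i <- i[keep]; j <- j[keep]; cond <- cond[keep]
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(cond, cond),
                            dims = c(nn, nn))
  L <- Matrix::Diagonal(x = Matrix::rowSums(A)) - A
  list(L = L, super = length(ord) + seq_len(nR), gg = gg, newid = newid,
       memb = memb, n_ordinary = length(ord))
}

#' Effective resistance distances between source regions
#'
#' Circuit-theory connectivity: each permeable cell is a node, each
#' 4-neighbour edge a resistor of resistance `mean(cost) * cell size`,
#' each source region a supernode. Pairwise effective resistances come
#' from sparse Laplacian solves (grounding one terminal, injecting unit
#' current at the other). Disconnected pairs get `Inf` with a flag.
#'
#' @param cost a [build_cost_surface()] result or cost matrix
#' @param regions named list of regions (masks / cell ids / (row,col))
#' @param neighborhood 4 (default, the circuit convention) or 8
#' @return list of class `resistance_result`: `rd` (symmetric matrix),
#'   `disconnected` (logical matrix)
#' @export
effective_resistance <- function(cost, regions, neighborhood = 4) {
  if (length(regions) < 2) stop("need at least 2 regions")
  cl <- conductance_laplacian(cost, regions, neighborhood)
  nR <- length(regions)
  nms <- names(regions)
  if (is.null(nms)) nms <- sprintf("region%d", seq_len(nR))
  rd <- matrix(0, nR, nR, dimnames = list(nms, nms))
  disc <- matrix(FALSE, nR, nR, dimnames = list(nms, nms))
  for (a in seq_len(nR - 1)) for (b in (a + 1):nR) {
    sa <- cl$super[a]; sb <- cl$super[b]
    v <- solve_current(cl$L, sa, sb)
    if (is.null(v)) { rd[a, b] <- rd[b, a] <- Inf; disc[a, b] <- disc[b, a] <- TRUE }
    else rd[a, b] <- rd[b, a] <- v$potential[sa]
  }
  structure(list(rd = rd, disconnected = disc), class = "resistance_result")
}

## unit current from node s to ground t; returns potentials (v[t]=0)
solve_current <- function(L, s, t) {
  n <- nrow(L)
  keep <- setdiff(seq_len(n), t)
  rhs <- rep(0, n - 1)
  rhs[match(s, keep)] <- 1
  Lr <- L[keep, keep, drop = FALSE]
  v <- try(Matrix::solve(Lr, rhs), silent = TRUE)
  if (inherits(v, "try-error")) return(NULL)
  v <- as.numeric(v)
  if (any(!is.finite(v))) return(NULL)
  ## a numerically singular system (s and t in different graph components)
  ## can return huge finite garbage: validate the residual
  resid <- max(abs(as.numeric(Lr %*% v) - rhs))
  if (resid > 1e-6 * max(1, max(abs(v)))) return(NULL)
  if (max(abs(v)) > 1e12) return(NULL)
  pot <- numeric(n)
  pot[keep] <- v
  list(potential = pot)
}

#' Current map and corridor bottlenecks for one region pair
#'
#' Injects unit current at one region's supernode and extracts it at the
#' other; the per-cell current is half the summed absolute currents of the
#' cell's incident edges (so a cell on a single serial path carries 1).
#' Bottlenecks are the cells above the given percentile of current, within
#' the corridor mask when one is supplied.
#'
#' @param cost cost raster
#' @param regions named list of >= 2 regions (as [effective_resistance()])
#' @param pair length-2 vector naming/indexing the terminal regions
#' @param percentile bottleneck percentile of cell current
#' @param corridor_mask optional logical matrix restricting the ranking
#' @param neighborhood 4 or 8
#' @return list of class `current_map`: `current` (matrix, NA off-graph),
#'   `bottlenecks` (logical matrix), `rd` for the pair
#' @export
current_map_bottlenecks <- function(cost, regions, pair = c(1, 2),
                                    percentile = 95, corridor_mask = NULL,
                                    neighborhood = 4) {
  cl <- conductance_laplacian(cost, regions, neighborhood)
  if (is.character(pair)) pair <- match(pair, names(regions))
  sa <- cl$super[pair[1]]; sb <- cl$super[pair[2]]
  v <- solve_current(cl$L, sa, sb)
  if (is.null(v)) stop("regions are disconnected: infinite resistance")
  pot <- v$potential
  el <- igraph::as_edgelist(cl$gg$graph, names = FALSE)
  cond <- 1 / igraph::E(cl$gg$graph)$weight
  i <- cl$newid[el[, 1]]; j <- cl$newid[el[, 2]]
  icur <- abs((pot[i] - pot[j]) * cond)
  ## per-cell current: half the sum of incident edge currents
  node_cur <- numeric(nrow(cl$L))
  for (k in seq_along(icur)) {
    node_cur[i[k]] <- node_cur[i[k]] + icur[k]
    node_cur[j[k]] <- node_cur[j[k]] + icur[k]
  }
  node_cur <- node_cur / 2
  cm <- if (inherits(cost, "cost_raster")) cost$cost else cost
  cur <- matrix(NA_real_, nrow(cm), ncol(cm))
  ordinary <- which(cl$memb == 0L)
  cur[cl$gg$perm[ordinary]] <- node_cur[cl$newid[ordinary]]
  sel <- !is.na(cur)
  if (!is.null(corridor_mask)) sel <- sel & corridor_mask
  thr <- stats::quantile(cur[sel], percentile / 100, na.rm = TRUE)
  bn <- !is.na(cur) & sel & cur >= thr
  structure(list(current = cur, bottlenecks = bn,
                 rd = pot[sa] - pot[sb]), class = "current_map")
}
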