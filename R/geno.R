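#' Multilocus genotype set
#'
#' The atom of all genetic computation in tigerscape: a set of diploid
#' multilocus microsatellite genotypes. Alleles are stored as repeat counts
#' (positive integers); a missing locus is a pair of `NA`s. Allele pairs are
#' unordered and stored sorted so that `(a,b)` and `(b,a)` compare equal.
#'
#' @param alleles integer array `n x L x 2` of repeat counts (`NA` = missing).
#' @param ids character vector of sample/individual identifiers (unique).
#' @param pop character vector of locality/population labels.
#' @param loci character vector of locus names (defaults to `L1..LL`).
#' @return An object of class `geno_set`: a list with elements `alleles`,
#'   `ids`, `pop`, `loci`.
#' @export
geno_set <- function(alleles, ids = NULL, pop = NULL, loci = NULL) {
  if (length(dim(alleles)) != 3L || dim(alleles)[3] != 2L)
    stop("'alleles' must be an n x L x 2 array")
  n <- dim(alleles)[1]; L <- dim(alleles)[2]
  if (is.null(ids)) ids <- sprintf("ind%03d", seq_len(n))
  if (is.null(pop)) pop <- rep("pop1", n)
  if (is.null(loci)) loci <- sprintf("L%02d", seq_len(L))
  if (anyDuplicated(ids)) stop("sample ids must be unique")
  if (length(ids) != n || length(pop) != n || length(loci) != L)
    stop("dimension mismatch between alleles, ids, pop, loci")
  storage.mode(alleles) <- "integer"
  if (any(alleles <= 0L, na.rm = TRUE)) stop("alleles must be positive repeat counts")
  ## one allele NA => whole locus missing; order pairs (a <= b)
  a <- alleles[, , 1, drop = FALSE]; b <- alleles[, , 2, drop = FALSE]
  miss <- is.na(a) | is.na(b)
  a[miss] <- NA_integer_; b[miss] <- NA_integer_
  lo <- pmin(a, b); hi <- pmax(a, b)
  alleles[, , 1] <- lo; alleles[, , 2] <- hi
  dimnames(alleles) <- list(ids, loci, c("a1", "a2"))
  structure(list(alleles = alleles, ids = as.character(ids),
                 pop = as.character(pop), loci = as.character(loci)),
            class = "geno_set")
}

#' @method print geno_set
#' @export
print.geno_set <- function(x, ...) {
  cat("geno_set:", length(x$ids), "samples,", length(x$loci), "loci,",
      length(unique(x$pop)), "populations\n")
  typed <- mean(!is.na(x$alleles[, , 1]))
  cat(sprintf("  loci typed: %.1f%%; populations: %s\n", 100 * typed,
              paste(unique(x$pop), collapse = ", ")))
  invisible(x)
}

#' Number of samples in a genotype set
#' @param g a `geno_set`
#' @export
n_samples <- function(g) length(g$ids)

#' Subset a genotype set by sample index or id
#' @param x a `geno_set`
#' @param i sample indices, logical mask, or ids
#' @param j locus indices or names (optional)
#' @param ... unused
#' @export
`[.geno_set` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$ids)
  if (is.character(i)) i <- match(i, x$ids)
  if (missing(j)) j <- seq_along(x$loci)
  if (is.character(j)) j <- match(j, x$loci)
  geno_set(x$alleles[i, j, , drop = FALSE], x$ids[i], x$pop[i], x$loci[j])
}

#' Combine genotype sets sharing a locus panel
#' @param ... `geno_set` objects with identical loci
#' @export
rbind_geno <- function(...) {
  gs <- list(...)
  loci <- gs[[1]]$loci
  for (g in gs) if (!identical(g$loci, loci)) stop("loci must match")
  al <- do.call(abind3, lapply(gs, function(g) g$alleles))
  geno_set(al, unlist(lapply(gs, `[[`, "ids")),
           unlist(lapply(gs, `[[`, "pop")), loci)
}

## bind 3-d arrays along dim 1
abind3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  n <- sum(vapply(xs, function(x) dim(x)[1], 0L))
  out <- array(NA_integer_, c(n, d[2], d[3]))
  at <- 0L
  for (x in xs) {
    k <- dim(x)[1]
    if (k) out[at + seq_len(k), , ] <- x
    at <- at + k
  }
  out
}

## n x L matrix slice of allele copy k, dims always kept
allele_slice <- function(g, k) {
  d <- dim(g$alleles)
  m <- g$alleles[, , k, drop = FALSE]
  dim(m) <- d[1:2]
  dimnames(m) <- list(g$ids, g$loci)
  m
}

## locus is typed (both alleles present)
typed_mask <- function(g) !is.na(allele_slice(g, 1))

## heterozygosity indicator matrix (n x L), NA where untyped
het_mask <- function(g) allele_slice(g, 1) != allele_slice(g, 2)
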