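#' Write a genotype set to a GENEPOP file
#'
#' Uses 3-digit diploid allele coding (six digits per locus, `000000` for a
#' missing locus) with one "Pop" block per population label.
#'
#' @param g a [geno_set()]
#' @param path output file path
#' @param title first (comment) line of the file
#' @export
write_genepop <- function(g, path, title = "tigerscape export") {
  if (any(g$alleles > 999, na.rm = TRUE))
    stop("3-digit coding cannot represent alleles > 999 repeat units")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(g$loci, con)
  for (p in unique(g$pop)) {
    writeLines("Pop", con)
    idx <- which(g$pop == p)
    for (i in idx) {
      a <- g$alleles[i, , 1]; b <- g$alleles[i, , 2]
      a[is.na(a)] <- 0L; b[is.na(b)] <- 0L
      codes <- sprintf("%03d%03d", a, b)
      writeLines(sprintf("%s ,  %s", g$ids[i], paste(codes, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a GENEPOP file into a genotype set
#'
#' Accepts loci on separate lines or one comma-separated line; population
#' labels are `pop1..popK` in file order (the conventional GENEPOP file
#' carries no explicit population names).
#'
#' @param path file path
#' @return a [geno_set()]
#' @export
read_genepop <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) < 3L) stop("not a GENEPOP file: too short")
  body <- lines[-1]
  pop_at <- which(toupper(body) %in% c("POP"))
  if (!length(pop_at)) stop("not a GENEPOP file: no Pop line")
  loci_lines <- body[seq_len(pop_at[1] - 1L)]
  loci <- unlist(strsplit(paste(loci_lines, collapse = ","), ","))
  loci <- trimws(loci); loci <- loci[nzchar(loci)]
  L <- length(loci)
  ids <- character(); pop <- character(); rows <- list()
  cur_pop <- 0L
  for (ln in body[-seq_len(pop_at[1] - 1L)]) {
    if (toupper(ln) == "POP") { cur_pop <- cur_pop + 1L; next }
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2L) stop("malformed GENEPOP genotype line: ", ln)
    id <- trimws(parts[1])
    codes <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[ \t]+")[[1]]
    if (length(codes) != L)
      stop("sample ", id, " has ", length(codes), " loci, expected ", L)
    a <- as.integer(substr(codes, 1, 3)); b <- as.integer(substr(codes, 4, 6))
    a[a == 0L] <- NA_integer_; b[b == 0L] <- NA_integer_
    ids <- c(ids, id); pop <- c(pop, sprintf("pop%d", cur_pop))
    rows[[length(rows) + 1L]] <- cbind(a, b)
  }
  al <- array(NA_integer_, c(length(ids), L, 2))
  for (i in seq_along(rows)) { al[i, , 1] <- rows[[i]][, 1]; al[i, , 2] <- rows[[i]][, 2] }
  geno_set(al, ids, pop, loci)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path
#' @return numeric matrix (rows top to bottom, as displayed) with attributes
#'   `cellsize`, `xllcorner`, `yllcorner`; NODATA cells are `NA`.
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"), quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  m[m == nodata] <- NA
  attr(m, "cellsize") <- hdr$cellsize
  attr(m, "xllcorner") <- hdr$xllcorner
  attr(m, "yllcorner") <- hdr$yllcorner
  m
}

#' Write an ESRI ASCII grid
#'
#' @param m numeric matrix (row 1 = top row); `NA` written as NODATA -9999
#' @param path output path
#' @param cellsize cell size (km here; taken from `attr(m, "cellsize")` if set)
#' @param xllcorner,yllcorner lower-left corner coordinates
#' @export
write_asc <- function(m, path, cellsize = attr(m, "cellsize"),
                      xllcorner = 0, yllcorner = 0) {
  if (is.null(cellsize)) cellsize <- 1
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %g", xllcorner),
    sprintf("yllcorner %g", yllcorner),
    sprintf("cellsize %g", cellsize),
    "NODATA_value -9999"), con)
  mm <- m; mm[is.na(mm)] <- -9999
  writeLines(apply(format(mm, trim = TRUE, scientific = FALSE), 1, paste, collapse = " "), con)
  invisible(path)
}

#' Write detection histories as a delimited table
#'
#' One row per grid: `grid_id`, replicate columns `y1..ymax` (`NA` where the
#' grid had fewer surveys), then covariate columns.
#'
#' @param hist a detection-history object from [gen_detection_histories()]
#'   or any list with elements `grid_id`, `y` (list of 0/1 vectors) and
#'   `covariates` (data.frame)
#' @param path output path
#' @export
write_detection_table <- function(hist, path) {
  kmax <- max(vapply(hist$y, length, 0L), 1L)
  ymat <- t(vapply(hist$y, function(v) { length(v) <- kmax; v }, numeric(kmax)))
  colnames(ymat) <- sprintf("y%d", seq_len(kmax))
  df <- data.frame(grid_id = hist$grid_id, ymat, check.names = FALSE)
  if (!is.null(hist$covariates)) df <- cbind(df, hist$covariates)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read detection histories written by [write_detection_table()]
#' @param path file path
#' @return list with `grid_id`, `y` (list of numeric vectors, NAs trimmed
#'   from the tail), `covariates` data.frame
#' @export
read_detection_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  ycols <- grep("^y[0-9]+$", names(df))
  ym <- as.matrix(df[, ycols, drop = FALSE])
  y <- lapply(seq_len(nrow(ym)), function(i) {
    v <- ym[i, ]
    keep <- rev(cumsum(rev(!is.na(v)))) > 0  # trim trailing NAs only
    unname(v[keep])
  })
  cov <- df[, -c(1, ycols), drop = FALSE]
  list(grid_id = df$grid_id, y = y,
       covariates = if (ncol(cov)) cov else NULL)
}

#' Write a labelled symmetric distance matrix as CSV
#' @param m symmetric matrix with dimnames
#' @param path output path
#' @export
write_distance_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}
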