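#' Read an ESRI-style ASCII grid
#'
#' Plain-text raster format: header lines `ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, optional `NODATA_value`, then `nrows` rows of
#' `ncols` values (top row first). This is the required raster format for
#' the package; cells equal to the nodata value become `NA`.
#'
#' @param file path to the grid file.
#' @return list of class `ascii_grid`: `data` (numeric matrix, row 1 =
#'   northernmost), `cellsize`, `xll`, `yll`, `nodata`.
#' @export
read_ascii_grid <- function(file) {
  lines <- readLines(file, warn = FALSE)
  hdr <- list(); i <- 1L
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                   "nodata_value")) {
      hdr[[key]] <- as.numeric(parts[2]); i <- i + 1L
    } else break
  }
  for (k in c("ncols", "nrows"))
    if (is.null(hdr[[k]])) stop("ASCII grid header lacks ", k)
  vals <- as.numeric(unlist(strsplit(trimws(lines[i:length(lines)]), "\\s+")))
  vals <- vals[!is.na(vals) | TRUE]
  nc <- hdr$ncols; nr <- hdr$nrows
  if (length(vals) != nc * nr)
    stop(sprintf("grid body has %d values, expected %d", length(vals), nc * nr))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- hdr$nodata_value
  if (!is.null(nodata)) m[m == nodata] <- NA_real_
  structure(list(data = m,
                 cellsize = if (is.null(hdr$cellsize)) 1 else hdr$cellsize,
                 xll = if (is.null(hdr$xllcorner)) 0 else hdr$xllcorner,
                 yll = if (is.null(hdr$yllcorner)) 0 else hdr$yllcorner,
                 nodata = nodata),
            class = "ascii_grid")
}

#' Write an ESRI-style ASCII grid
#'
#' @param grid an `ascii_grid` or plain numeric matrix.
#' @param file output path.
#' @param nodata value used to encode `NA` cells.
#' @export
write_ascii_grid <- function(grid, file, nodata = -9999) {
  m <- if (inherits(grid, "ascii_grid")) grid$data else as.matrix(grid)
  cellsize <- if (inherits(grid, "ascii_grid")) grid$cellsize else 1
  xll <- if (inherits(grid, "ascii_grid")) grid$xll else 0
  yll <- if (inherits(grid, "ascii_grid")) grid$yll else 0
  m[is.na(m)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(m)), sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %g", xll), sprintf("yllcorner %g", yll),
           sprintf("cellsize %g", cellsize),
           sprintf("NODATA_value %g", nodata))
  body <- apply(m, 1, function(r) paste(format(r, trim = TRUE), collapse = " "))
  writeLines(c(hdr, body), file)
  invisible(file)
}

as_grid_matrix <- function(g) {
  if (inherits(g, "ascii_grid")) g$data else as.matrix(g)
}

#' Predicted niche occupancy (PNO) profile
#'
#' Summarises where along one climate axis a species' modeled suitability
#' mass lies: the climate values of all valid cells are binned (equal
#' width, right-open except the last bin) and each bin is weighted by the
#' total suitability of the cells falling in it, normalised to sum 1.
#' Suitability scores need only be non-negative; any positive rescaling
#' gives the same profile.
#'
#' @param suit suitability grid (`ascii_grid` or matrix), values >= 0.
#' @param clim climate grid of the same shape.
#' @param n_bins number of bins (>= 2).
#' @return object of class `pno_profile`: `edges` (length n_bins + 1),
#'   `mids`, `weights` (sum to 1).
#' @export
compute_pno <- function(suit, clim, n_bins = 100) {
  s <- as_grid_matrix(suit); cl <- as_grid_matrix(clim)
  if (!all(dim(s) == dim(cl)))
    stop("suitability and climate grids have different shapes")
  if (n_bins < 2) stop("n_bins must be >= 2")
  ok <- is.finite(s) & is.finite(cl)
  if (!any(ok)) stop("no valid (finite) cells shared by the two grids")
  s <- s[ok]; cl <- cl[ok]
  if (any(s < 0)) stop("suitability values must be >= 0")
  tot <- sum(s)
  if (tot <= 0) stop("all suitability values are zero")
  rng <- range(cl)
  if (rng[1] == rng[2]) {               # degenerate climate: one bin carries all
    edges <- c(rng[1] - 0.5, rng[1] + 0.5)
    return(pno_profile(edges, 1))
  }
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  idx <- findInterval(cl, edges, rightmost.closed = TRUE, all.inside = TRUE)
  w <- vapply(seq_len(n_bins), function(b) sum(s[idx == b]), numeric(1)) / tot
  pno_profile(edges, w)
}

#' Construct a PNO profile from bin edges and weights
#'
#' @param edges numeric vector of bin edges (length = bins + 1, increasing).
#' @param weights non-negative weights, one per bin; normalised to sum 1.
#' @return a `pno_profile`.
#' @export
pno_profile <- function(edges, weights) {
  edges <- as.numeric(edges); weights <- as.numeric(weights)
  if (length(edges) != length(weights) + 1L)
    stop("length(edges) must equal length(weights) + 1")
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing")
  if (any(weights < 0)) stop("weights must be >= 0")
  tot <- sum(weights)
  if (tot <= 0) stop("weights sum to zero")
  structure(list(edges = edges,
                 mids = (edges[-1] + edges[-length(edges)]) / 2,
                 weights = weights / tot),
            class = "pno_profile")
}

#' Weighted summary statistics of a PNO profile
#'
#' The mean is the weight-weighted mean of bin midpoints; percentiles are
#' obtained by linear interpolation of the cumulative weight across bins.
#'
#' @param profile a [pno_profile].
#' @param probs percentile probabilities (default 5th and 95th).
#' @return list: `mean`, `sd`, `quantiles` (named numeric).
#' @export
pno_stats <- function(profile, probs = c(0.05, 0.95)) {
  stopifnot(inherits(profile, "pno_profile"))
  w <- profile$weights; m <- profile$mids; e <- profile$edges
  mu <- sum(w * m)
  sdv <- sqrt(sum(w * (m - mu)^2))
  cw <- cumsum(w)
  qs <- vapply(probs, function(p) {
    b <- which(cw >= p - 1e-12)[1]
    lo_cum <- if (b == 1) 0 else cw[b - 1]
    frac <- if (w[b] > 0) (p - lo_cum) / w[b] else 0
    frac <- min(max(frac, 0), 1)
    e[b] + frac * (e[b + 1] - e[b])
  }, numeric(1))
  names(qs) <- paste0("q", format(100 * probs, trim = TRUE))
  list(mean = mu, sd = sdv, quantiles = qs)
}

#' Sample values from a PNO profile
#'
#' Independent draws of bin midpoints with the profile's weights.
#'
#' @param profile a [pno_profile].
#' @param n number of draws (>= 1).
#' @param seed optional integer seed; when `NULL` the current RNG stream
#'   is used (so callers that set their own seed stay reproducible).
#' @return numeric vector of length `n`.
#' @export
pno_sample <- function(profile, n, seed = NULL) {
  stopifnot(inherits(profile, "pno_profile"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(length(profile$mids), n, replace = TRUE,
                    prob = profile$weights)
  profile$mids[idx]
}
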