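#' Canonical-ensemble frame weights from boost energies
#'
#' Converts per-frame boost energies into reweighting factors that recover
#' canonical statistics from a boosted ensemble. `method = "exponential"`
#' uses the exact Boltzmann factor \eqn{w_i = e^{\Delta V_i / kT}};
#' `method = "maclaurin"` uses its truncated power series
#' \eqn{w_i = \sum_{j=0}^{k} (\Delta V_i / kT)^j / j!}, which damps the
#' statistical noise the exponential amplifies at large boosts.
#'
#' @param boost A [boost_series()].
#' @param thermo A [thermo_params()].
#' @param method `"exponential"` or `"maclaurin"`.
#' @param k Maclaurin truncation order (>= 0; order 0 means unit weights,
#'   i.e. no reweighting).
#' @param boost_which Which boost enters the factor: `"total"`
#'   (`dV_P + dV_D`, default) or `"dihedral"` (`dV_D` only).
#' @return Object of class `frame_weights`: list with `w` (weights, all
#'   >= 1), `method` (tag `"exponential"` or `"maclaurin:k"`), `kT`.
#' @export
frame_weights <- function(boost, thermo,
                          method = c("exponential", "maclaurin"), k = 10,
                          boost_which = c("total", "dihedral")) {
  stopifnot(inherits(boost, "boost_series"), inherits(thermo, "thermo_params"))
  method <- match.arg(method)
  dV <- applied_boost(boost, match.arg(boost_which))
  if (any(dV < 0)) stop("negative boost energy in input")
  x <- dV / thermo$kT
  if (method == "exponential") {
    w <- exp(x)
    tag <- "exponential"
  } else {
    if (k < 0 || k != round(k)) stop("maclaurin order k must be an integer >= 0")
    w <- rep(1, length(x))
    term <- rep(1, length(x))
    j <- 0
    while (j < k) {
      j <- j + 1
      term <- term * x / j
      w <- w + term
    }
    tag <- sprintf("maclaurin:%d", as.integer(k))
  }
  structure(list(w = w, method = tag, kT = thermo$kT),
            class = "frame_weights")
}

#' @export
print.frame_weights <- function(x, ...) {
  cat(sprintf("frame_weights: %d frames, method %s, kT = %.5g kcal/mol\n",
              length(x$w), x$method, x$kT))
  if (length(x$w))
    cat(sprintf("  weight range: [%.6g, %.6g]\n", min(x$w), max(x$w)))
  invisible(x)
}

.as_weights <- function(weights, n) {
  w <- if (inherits(weights, "frame_weights")) weights$w else as.numeric(weights)
  if (length(w) != n) stop("values and weights must have equal length")
  w
}

#' Weighted histogram over one coordinate
#'
#' Bins `values` into `[edges[b], edges[b+1])` intervals, summing frame
#' weights per bin. Values outside `[edges[1], edges[n])` are excluded and
#' counted. No normalisation is applied here.
#'
#' @param values Numeric coordinate series.
#' @param weights A [frame_weights()] object or numeric vector, same
#'   length as `values`.
#' @param edges Strictly increasing bin edges.
#' @return Object of class `whist`: list with `edges`, `centers`, `sums`
#'   (per-bin weight sums), `counts` (raw counts), `n_excluded`.
#' @export
weighted_histogram <- function(values, weights, edges) {
  if (length(edges) < 2 || any(diff(edges) <= 0))
    stop("edges must be strictly increasing (length >= 2)")
  w <- .as_weights(weights, length(values))
  nb <- length(edges) - 1L
  idx <- findInterval(values, edges)
  ok <- idx >= 1L & idx <= nb & values < edges[nb + 1L]
  f <- factor(idx[ok], levels = seq_len(nb))
  counts <- as.integer(table(f))
  sums <- as.numeric(tapply(w[ok], f, sum))
  sums[is.na(sums)] <- 0
  structure(list(edges = edges, centers = (edges[-1] + edges[-(nb + 1)]) / 2,
                 sums = sums, counts = counts,
                 n_excluded = sum(!ok)),
            class = "whist")
}

#' Reweighted probability and PMF from a weighted histogram
#'
#' Normalises the per-bin weight sums to probabilities
#' \eqn{p_b = s_b / \sum_b s_b} and converts them to a potential of mean
#' force \eqn{PMF_b = -kT \ln(p_b / \max_b p_b)} (kcal/mol), anchored so
#' the most probable bin has PMF exactly 0. Empty bins are masked: they
#' carry `NA`, never 0.
#'
#' @param hist A [weighted_histogram()] result.
#' @param thermo A [thermo_params()].
#' @param coord Coordinate name recorded in the surface metadata.
#' @return Object of class `fes` (free-energy surface, `dim = 1`): list
#'   with `edges` (list of one axis), `centers`, `prob`, `pmf`, `counts`,
#'   `mask` (`TRUE` = empty bin), `kT`, `coord`.
#' @export
pmf_from_histogram <- function(hist, thermo, coord = "rc") {
  stopifnot(inherits(hist, "whist"), inherits(thermo, "thermo_params"))
  if (all(hist$sums == 0)) stop("all bins empty")
  tot <- sum(hist$sums)
  prob <- hist$sums / tot
  mask <- hist$counts == 0L
  prob[mask] <- NA_real_
  pmf <- -thermo$kT * log(prob / max(prob, na.rm = TRUE))
  structure(list(dim = 1L, edges = list(hist$edges), centers = list(hist$centers),
                 prob = prob, pmf = pmf, counts = hist$counts, mask = mask,
                 kT = thermo$kT, coord = coord),
            class = "fes")
}

#' Reweighted 2D free-energy surface
#'
#' 2D analogue of [weighted_histogram()] + [pmf_from_histogram()]: joint
#' binning of `(x, y)` with frame weights, normalisation over occupied
#' cells, and PMF anchoring at the most probable cell. Empty cells are
#' masked (`NA`).
#'
#' @param values_x,values_y Coordinate series (equal length).
#' @param weights A [frame_weights()] or numeric vector.
#' @param edges_x,edges_y Strictly increasing bin edges per axis.
#' @param thermo A [thermo_params()].
#' @param coords Length-2 coordinate names.
#' @return Object of class `fes` with `dim = 2`; `prob`, `pmf`, `counts`,
#'   `mask` are `nx x ny` matrices (x = rows).
#' @export
pmf_2d <- function(values_x, values_y, weights, edges_x, edges_y, thermo,
                   coords = c("x", "y")) {
  stopifnot(inherits(thermo, "thermo_params"))
  if (length(values_x) != length(values_y))
    stop("values_x and values_y must have equal length")
  if (any(diff(edges_x) <= 0) || any(diff(edges_y) <= 0))
    stop("edges must be strictly increasing")
  w <- .as_weights(weights, length(values_x))
  nx <- length(edges_x) - 1L; ny <- length(edges_y) - 1L
  ix <- findInterval(values_x, edges_x)
  iy <- findInterval(values_y, edges_y)
  ok <- ix >= 1L & ix <= nx & values_x < edges_x[nx + 1L] &
        iy >= 1L & iy <= ny & values_y < edges_y[ny + 1L]
  cell <- (iy[ok] - 1L) * nx + ix[ok]
  f <- factor(cell, levels = seq_len(nx * ny))
  counts <- matrix(as.integer(table(f)), nx, ny)
  sums <- as.numeric(tapply(w[ok], f, sum)); sums[is.na(sums)] <- 0
  sums <- matrix(sums, nx, ny)
  if (all(sums == 0)) stop("all bins empty")
  prob <- sums / sum(sums)
  mask <- counts == 0L
  prob[mask] <- NA_real_
  pmf <- -thermo$kT * log(prob / max(prob, na.rm = TRUE))
  structure(list(dim = 2L, edges = list(edges_x, edges_y),
                 centers = list((edges_x[-1] + edges_x[-(nx + 1)]) / 2,
                                (edges_y[-1] + edges_y[-(ny + 1)]) / 2),
                 prob = prob, pmf = pmf, counts = counts, mask = mask,
                 kT = thermo$kT, coord = coords,
                 n_excluded = sum(!ok)),
            class = "fes")
}

#' @export
print.fes <- function(x, ...) {
  cat(sprintf("fes: %dD free-energy surface over %s\n", x$dim,
              paste(x$coord, collapse = " x ")))
  cat(sprintf("  bins: %s; occupied: %d; kT = %.5g kcal/mol\n",
              paste(vapply(x$centers, length, 1L), collapse = " x "),
              sum(!x$mask), x$kT))
  if (x$dim == 1L) {
    i <- which.min(x$pmf)
    cat(sprintf("  PMF minimum at %s = %.4g\n", x$coord, x$centers[[1]][i]))
  } else {
    i <- arrayInd(which.min(x$pmf), dim(x$pmf))
    cat(sprintf("  PMF minimum at (%.4g, %.4g)\n",
                x$centers[[1]][i[1]], x$centers[[2]][i[2]]))
  }
  invisible(x)
}

#' Plot a free-energy surface
#'
#' 1D surfaces are drawn as PMF-vs-coordinate lines (masked bins absent);
#' 2D surfaces as a filled image, with masked cells capped at the largest
#' finite PMF plus one kT for display only (the object is untouched).
#'
#' @param x An `fes` object.
#' @param ... Passed to the underlying base-graphics call.
#' @export
plot.fes <- function(x, ...) {
  if (x$dim == 1L) {
    plot(x$centers[[1]], x$pmf, type = "b", pch = 16,
         xlab = x$coord, ylab = "PMF (kcal/mol)", ...)
  } else {
    z <- x$pmf
    cap <- max(z, na.rm = TRUE) + x$kT
    z[is.na(z)] <- cap
    graphics::image(x$centers[[1]], x$centers[[2]], z,
                    xlab = x$coord[1], ylab = x$coord[2],
                    col = grDevices::hcl.colors(64, "viridis", rev = TRUE),
                    ...)
  }
  invisible(x)
}

#' Write a 1D free-energy surface as TSV
#'
#' Columns: `bin_center`, `probability`, `pmf_kcal_mol`, `count`,
#' `masked_flag`; one `#` header line names columns and units.
#'
#' @param fes A 1D `fes` object.
#' @param path Output file.
#' @param extra Optional text appended to the header comment (e.g. the run
#'   seed).
#' @return `path`, invisibly.
#' @export
write_fes_tsv <- function(fes, path, extra = NULL) {
  stopifnot(inherits(fes, "fes"), fes$dim == 1L)
  df <- data.frame(bin_center = fes$centers[[1]],
                   probability = fes$prob,
                   pmf_kcal_mol = fes$pmf,
                   count = fes$counts,
                   masked_flag = as.integer(fes$mask))
  comment <- sprintf(
    "%s PMF; bin_center (coordinate units), probability, pmf_kcal_mol, count, masked_flag",
    fes$coord)
  if (!is.null(extra)) comment <- paste0(comment, "; ", extra)
  write_result_tsv(df, path, comment = comment)
  invisible(path)
}
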