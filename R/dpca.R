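#' Dihedral principal component analysis
#'
#' Maps every defined backbone angle chi to the periodic feature pair
#' `(cos chi, sin chi)` (the standard circular-safe dPCA embedding: raw
#' angles would break at the +/-180 degree seam), computes the covariance
#' matrix of the features over frames, and eigendecomposes it. Angle
#' columns containing absent values (terminal residues) are excluded.
#'
#' @param series A [dihedral_series()] with at least 2 frames.
#' @return Object of class `pc_model`: list with `mean` (feature means),
#'   `values` (eigenvalues, descending, >= 0), `vectors` (orthonormal
#'   eigenvector matrix, features x components), `proj` (frames x
#'   components projections of the centred features), `feature_names`,
#'   `n_frames`.
#' @export
dpca_fit <- function(series) {
  stopifnot(inherits(series, "dihedral_series"))
  if (series$n_frames < 2) stop("need >= 2 frames for dPCA")
  ang <- cbind(series$phi, series$psi)
  colnames(ang) <- c(paste0("phi.", series$residues),
                     paste0("psi.", series$residues))
  keep <- colSums(is.na(ang)) == 0L
  if (!any(keep)) stop("no fully defined angle columns")
  ang <- ang[, keep, drop = FALSE] * pi / 180
  feats <- matrix(NA_real_, nrow(ang), 2L * ncol(ang))
  fn <- character(2L * ncol(ang))
  for (j in seq_len(ncol(ang))) {
    feats[, 2L * j - 1L] <- cos(ang[, j])
    feats[, 2L * j] <- sin(ang[, j])
    fn[2L * j - 1L] <- paste0("cos.", colnames(ang)[j])
    fn[2L * j] <- paste0("sin.", colnames(ang)[j])
  }
  mu <- colMeans(feats)
  centred <- sweep(feats, 2, mu)
  cv <- stats::cov(feats)
  eig <- eigen(cv, symmetric = TRUE)
  values <- pmax(eig$values, 0)
  proj <- centred %*% eig$vectors
  colnames(proj) <- paste0("PC", seq_len(ncol(proj)))
  structure(list(mean = stats::setNames(mu, fn), values = values,
                 vectors = eig$vectors, proj = proj, feature_names = fn,
                 n_frames = nrow(feats)),
            class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  cat(sprintf("pc_model: %d frames, %d features\n",
              x$n_frames, length(x$feature_names)))
  tot <- sum(x$values)
  k <- min(3L, length(x$values))
  pct <- if (tot > 0) 100 * x$values[seq_len(k)] / tot else rep(0, k)
  cat(sprintf("  top eigenvalues: %s (%s%% of variance)\n",
              paste(signif(x$values[seq_len(k)], 4), collapse = ", "),
              paste(sprintf("%.1f", pct), collapse = ", ")))
  invisible(x)
}

# linear cell index <-> integer grid coordinates for an nd grid
.cell_of <- function(sub, nbins) {
  # sub: matrix n x d of 1-based bin coords
  d <- ncol(sub)
  cell <- sub[, 1]
  mult <- 1L
  if (d > 1) for (j in 2:d) {
    mult <- mult * nbins
    cell <- cell + (sub[, j] - 1L) * mult
  }
  cell
}

#' Most-populated conformational clusters from top principal components
#'
#' Density-grid clustering of the frame projections: an `nd`-dimensional
#' histogram over the top `n_components` PCs (`grid_bins` bins per axis
#' over the observed range); cells holding at least
#' `min_density * n_frames` frames are dense; connected components of
#' dense cells (full diagonal neighbourhood) form basins; frames in
#' non-dense cells are attached to an adjacent basin (within one bin
#' diagonal) or labelled noise. Clusters are ranked by population; each
#' cluster's representative frame is the member nearest the centroid of
#' its members' projections.
#'
#' @param model A [dpca_fit()] result.
#' @param n_components Number of leading PCs to cluster on (default 3).
#' @param grid_bins Bins per axis (default 12; fine enough to separate
#'   distinct backbone conformers, coarse enough that a single basin does
#'   not fragment along the low-variance PCs).
#' @param min_density Dense-cell threshold as a fraction of the frame
#'   count (default 0.002).
#' @param assign_radius Maximum distance (in cells, Chebyshev) at which a
#'   frame in a non-dense cell is still attached to the nearest basin;
#'   beyond it the frame is noise.
#' @return Object of class `cluster_set`: list with `labels` (per frame;
#'   0 = noise), `populations` (descending), `representatives` (frame
#'   index per cluster), `n_clusters`, `n_noise`.
#' @export
cluster_top_pcs <- function(model, n_components = 3, grid_bins = 12,
                            min_density = 0.002, assign_radius = 3) {
  stopifnot(inherits(model, "pc_model"))
  if (n_components > ncol(model$proj))
    stop("n_components exceeds available components")
  P <- model$proj[, seq_len(n_components), drop = FALSE]
  n <- nrow(P); d <- ncol(P)
  nbins <- as.integer(grid_bins)
  sub <- matrix(1L, n, d)
  for (j in seq_len(d)) {
    r <- range(P[, j])
    if (r[2] - r[1] < 1e-12) r <- r + c(-0.5, 0.5)
    w <- (r[2] - r[1]) / nbins
    s <- floor((P[, j] - r[1]) / w) + 1L
    sub[, j] <- pmin.int(as.integer(s), nbins)
  }
  cell <- .cell_of(sub, nbins)
  ncell <- nbins^d
  counts <- tabulate(cell, nbins = ncell)
  thresh <- max(1, ceiling(min_density * n))
  dense <- counts >= thresh
  # neighbour offsets: full (3^d - 1) diagonal neighbourhood
  offs <- as.matrix(expand.grid(rep(list(-1L:1L), d)))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  sub_of_cell <- function(c0) {
    out <- integer(d); c0 <- c0 - 1L
    for (j in seq_len(d)) { out[j] <- c0 %% nbins + 1L; c0 <- c0 %/% nbins }
    out
  }
  basin <- integer(ncell)  # 0 = unassigned
  nb <- 0L
  for (c0 in which(dense)) {
    if (basin[c0] != 0L) next
    nb <- nb + 1L
    queue <- c0; basin[c0] <- nb
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      s0 <- sub_of_cell(cur)
      for (k in seq_len(nrow(offs))) {
        s1 <- s0 + offs[k, ]
        if (any(s1 < 1L) || any(s1 > nbins)) next
        c1 <- .cell_of(matrix(s1, 1), nbins)
        if (dense[c1] && basin[c1] == 0L) { basin[c1] <- nb; queue <- c(queue, c1) }
      }
    }
  }
  labels <- basin[cell]
  # attach frames in non-dense cells to the nearest basin within
  # assign_radius cells (Chebyshev); farther frames are noise
  loose_cells <- unique(cell[labels == 0L])
  if (length(loose_cells) && nb > 0L) {
    dense_cells <- which(dense)
    dsub <- t(vapply(dense_cells, sub_of_cell, integer(d)))
    for (c0 in loose_cells) {
      s0 <- sub_of_cell(c0)
      cheb <- apply(abs(sweep(dsub, 2, s0)), 1, max)
      j <- which.min(cheb)
      if (cheb[j] <= assign_radius)
        labels[cell == c0] <- basin[dense_cells[j]]
    }
  }
  if (nb == 0L) {
    return(structure(list(labels = integer(n), populations = integer(),
                          representatives = integer(), n_clusters = 0L,
                          n_noise = n),
                     class = "cluster_set"))
  }
  pops <- tabulate(labels[labels > 0L], nbins = nb)
  ord <- order(pops, decreasing = TRUE)
  relabel <- integer(nb); relabel[ord] <- seq_len(nb)
  labels[labels > 0L] <- relabel[labels[labels > 0L]]
  pops <- sort(pops, decreasing = TRUE)
  reps <- integer(nb)
  for (k in seq_len(nb)) {
    members <- which(labels == k)
    centroid <- colMeans(P[members, , drop = FALSE])
    dist2 <- rowSums(sweep(P[members, , drop = FALSE], 2, centroid)^2)
    reps[k] <- members[which.min(dist2)]
  }
  structure(list(labels = labels, populations = pops,
                 representatives = reps, n_clusters = nb,
                 n_noise = sum(labels == 0L)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d cluster(s), %d noise frame(s)\n",
              x$n_clusters, x$n_noise))
  if (x$n_clusters)
    cat("  populations:", paste(x$populations, collapse = ", "), "\n")
  invisible(x)
}

#' Write representative cluster structures as single-model PDBs
#'
#' @param clusters A [cluster_top_pcs()] result.
#' @param traj,topo Trajectory and topology the clustering came from.
#' @param dir Output directory; files are named `cluster_<rank>.pdb`.
#' @return Character vector of written paths, invisibly.
#' @export
write_cluster_representatives <- function(clusters, traj, topo, dir = ".") {
  stopifnot(inherits(clusters, "cluster_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(clusters$n_clusters)
  for (k in seq_len(clusters$n_clusters)) {
    f <- clusters$representatives[k]
    paths[k] <- file.path(dir, sprintf("cluster_%d.pdb", k))
    write_topology_pdb(topo, traj$coords[f, , ], paths[k])
  }
  invisible(paths)
}
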