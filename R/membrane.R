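#' Default acyl-chain atom-naming map
#'
#' CHARMM-style lipid naming: sn2 carbons `C2<i>` with hydrogens
#' `H<i>R`/`H<i>S`, sn1 carbons `C3<i>` with hydrogens `H<i>X`/`H<i>Y`,
#' carbon indices counted from the carbonyl carbon = 1 (which bears no
#' hydrogen, so the map starts at carbon 2). Replace or extend for other
#' force-field conventions.
#'
#' @param n_carbons Last chain carbon index covered by the map.
#' @return data.frame with columns `chain`, `carbon`, `carbon_name`,
#'   `hydrogen_name` (one row per C-H bond).
#' @export
default_chain_naming <- function(n_carbons = 18) {
  rows <- list()
  for (i in 2:n_carbons) {
    rows[[length(rows) + 1]] <- data.frame(
      chain = "sn2", carbon = i, carbon_name = paste0("C2", i),
      hydrogen_name = paste0("H", i, c("R", "S")))
    rows[[length(rows) + 1]] <- data.frame(
      chain = "sn1", carbon = i, carbon_name = paste0("C3", i),
      hydrogen_name = paste0("H", i, c("X", "Y")))
  }
  do.call(rbind, rows)
}

#' Chain C-H bond vector set
#'
#' @param vectors data.frame with columns `chain`, `carbon` and unit-vector
#'   components `x`, `y`, `z` (one row per C-H bond observation).
#' @param normal Bilayer normal unit vector (default +z).
#' @return Object of class `chain_vector_set`.
#' @export
chain_vector_set <- function(vectors, normal = c(0, 0, 1)) {
  stopifnot(all(c("chain", "carbon", "x", "y", "z") %in% names(vectors)))
  if (nrow(vectors)) {
    nrm <- sqrt(vectors$x^2 + vectors$y^2 + vectors$z^2)
    if (any(abs(nrm - 1) > 1e-9)) stop("bond vectors must be unit length")
    if (any(vectors$carbon < 2)) stop("carbon indices start at 2 (carbonyl = 1)")
  }
  nn <- sqrt(sum(normal^2))
  if (abs(nn - 1) > 1e-9) stop("normal must be a unit vector")
  structure(list(vectors = vectors, normal = normal),
            class = "chain_vector_set")
}

#' Wrap oriented unit vectors into a chain vector set
#'
#' Convenience for feeding [gen_oriented_vectors()] output (or any n x 3
#' unit-vector matrix) into [scd_profile()], attributing all vectors to one
#' chain/carbon slot.
#'
#' @param vectors n x 3 matrix of unit vectors.
#' @param chain,carbon Chain tag and carbon index to attribute them to.
#' @param normal Bilayer normal.
#' @return A [chain_vector_set()].
#' @export
as_chain_vector_set <- function(vectors, chain = "sn1", carbon = 2,
                                normal = c(0, 0, 1)) {
  v <- as.matrix(vectors)
  chain_vector_set(data.frame(chain = chain, carbon = carbon,
                              x = v[, 1], y = v[, 2], z = v[, 3]),
                   normal = normal)
}

#' Extract C-H bond vectors from a lipid trajectory
#'
#' For every lipid residue, frame and mapped chain carbon, emits one
#' normalised carbon-to-hydrogen vector per resolvable bonded hydrogen
#' (two per CH2). Carbons whose hydrogens cannot be resolved anywhere in
#' the topology are dropped with a warning.
#'
#' @param traj A `traj_frames`.
#' @param topo The matching `topology`.
#' @param naming Atom-naming map as returned by [default_chain_naming()].
#' @param normal Bilayer normal unit vector.
#' @return A [chain_vector_set()].
#' @export
chain_vectors <- function(traj, topo, naming = default_chain_naming(),
                          normal = c(0, 0, 1)) {
  stopifnot(inherits(traj, "traj_frames"), inherits(topo, "topology"),
            traj$n_atoms == topo$n_atoms)
  a <- topo$atoms
  lip <- which(a$mol_class == "lipid")
  if (!length(lip)) stop("no lipid residues in topology")
  res_ids <- unique(a$resid[lip])
  out <- list(); dropped <- character()
  for (r in res_ids) {
    rows <- which(a$resid == r & a$mol_class == "lipid")
    nm <- a$name[rows]
    for (j in seq_len(nrow(naming))) {
      ci <- match(naming$carbon_name[j], nm)
      hi <- match(naming$hydrogen_name[j], nm)
      if (is.na(ci)) next
      if (is.na(hi)) {
        dropped <- c(dropped, paste0(naming$chain[j], ":C", naming$carbon[j]))
        next
      }
      ca <- rows[ci]; ha <- rows[hi]
      v <- traj$coords[, ha, , drop = FALSE] - traj$coords[, ca, , drop = FALSE]
      v <- matrix(v, traj$n_frames, 3)
      nrm <- sqrt(rowSums(v^2))
      out[[length(out) + 1]] <- data.frame(
        chain = naming$chain[j], carbon = naming$carbon[j],
        x = v[, 1] / nrm, y = v[, 2] / nrm, z = v[, 3] / nrm)
    }
  }
  if (length(dropped))
    warning("chain carbon(s) without resolvable hydrogens dropped: ",
            paste(unique(dropped), collapse = ", "))
  vecs <- if (length(out)) do.call(rbind, out)
          else data.frame(chain = character(), carbon = integer(),
                          x = numeric(), y = numeric(), z = numeric())
  chain_vector_set(vecs, normal = normal)
}

#' Deuterium order-parameter profile |S_CD|
#'
#' For each chain and carbon index, computes
#' \eqn{|S_{CD}| = |0.5 \langle 3\cos^2\theta - 1 \rangle|}, with theta
#' the angle between each C-H bond vector and the bilayer normal and the
#' average taken over all lipids, frames and hydrogens before the
#' absolute value.
#'
#' @param vset A [chain_vector_set()] (non-empty).
#' @return Object of class `scd_profile`: data.frame with columns `chain`,
#'   `carbon`, `scd`, `n` (observations per entry).
#' @export
scd_profile <- function(vset) {
  stopifnot(inherits(vset, "chain_vector_set"))
  v <- vset$vectors
  if (nrow(v) == 0L) stop("empty chain vector set")
  costh <- v$x * vset$normal[1] + v$y * vset$normal[2] + v$z * vset$normal[3]
  term <- 3 * costh^2 - 1
  key <- interaction(v$chain, v$carbon, drop = TRUE)
  s <- tapply(term, key, mean)
  n <- tapply(term, key, length)
  parts <- do.call(rbind, strsplit(names(s), "\\."))
  out <- data.frame(chain = parts[, 1], carbon = as.integer(parts[, 2]),
                    scd = abs(0.5 * as.numeric(s)), n = as.integer(n))
  out <- out[order(out$chain, out$carbon), ]
  rownames(out) <- NULL
  structure(out, class = c("scd_profile", "data.frame"))
}

#' @export
plot.scd_profile <- function(x, ...) {
  chains <- unique(x$chain)
  cols <- seq_along(chains)
  plot(range(x$carbon), range(x$scd), type = "n",
       xlab = "carbon index", ylab = "|S_CD|", ...)
  for (i in seq_along(chains)) {
    s <- x[x$chain == chains[i], ]
    graphics::lines(s$carbon, s$scd, type = "b", pch = 16, col = cols[i])
  }
  graphics::legend("topright", legend = chains, col = cols, lty = 1, pch = 16)
  invisible(x)
}

#' Reaction-coordinate series
#'
#' @param values Per-frame scalar values (Angstrom for distances).
#' @param name Coordinate name.
#' @return Object of class `rc_series`.
#' @export
rc_series <- function(values, name = "rc") {
  structure(list(values = as.numeric(values), name = name,
                 n_frames = length(values)),
            class = "rc_series")
}

#' Peptide-to-membrane-center distance series
#'
#' Per frame, the absolute difference between the mass-weighted
#' z centre-of-mass of the peptide selection and that of the membrane
#' selection. When a periodic box is present, peptide atoms are first
#' wrapped to the periodic image nearest the membrane COM along z.
#'
#' @param traj A `traj_frames`.
#' @param topo The matching `topology`.
#' @param peptide_sel,membrane_sel Atom selections: integer indices or
#'   logical vectors over atoms; defaults select by molecule class
#'   (`peptide` and `lipid`).
#' @return An [rc_series()] named `"com_z_distance"`, values in Angstrom.
#' @export
com_z_distance <- function(traj, topo,
                           peptide_sel = topo$atoms$mol_class == "peptide",
                           membrane_sel = topo$atoms$mol_class == "lipid") {
  stopifnot(inherits(traj, "traj_frames"), inherits(topo, "topology"),
            traj$n_atoms == topo$n_atoms)
  pidx <- if (is.logical(peptide_sel)) which(peptide_sel) else as.integer(peptide_sel)
  midx <- if (is.logical(membrane_sel)) which(membrane_sel) else as.integer(membrane_sel)
  if (!length(pidx) || !length(midx)) stop("empty atom selection")
  mp <- topo$atoms$mass[pidx]; mm <- topo$atoms$mass[midx]
  d <- numeric(traj$n_frames)
  for (f in seq_len(traj$n_frames)) {
    zm <- sum(traj$coords[f, midx, 3] * mm) / sum(mm)
    zp_at <- traj$coords[f, pidx, 3]
    if (!is.null(traj$box)) {
      Lz <- traj$box[f, 3]
      zp_at <- zp_at - Lz * round((zp_at - zm) / Lz)
    }
    zp <- sum(zp_at * mp) / sum(mp)
    d[f] <- abs(zp - zm)
  }
  rc_series(d, name = "com_z_distance")
}

#' Reweighted insertion PMF over the peptide-membrane distance
#'
#' Composes [frame_weights()], [weighted_histogram()] and
#' [pmf_from_histogram()] into the reweighted potential of mean force
#' over a distance series. With `boost = NULL` (or a zero-boost series)
#' the weights are all 1 and the PMF is the plain Boltzmann inversion of
#' the sampled histogram.
#'
#' @param series An [rc_series()] (or numeric vector).
#' @param boost A [boost_series()] aligned frame-for-frame with `series`,
#'   or `NULL` for unit weights.
#' @param thermo A [thermo_params()].
#' @param method,k,boost_which Passed to [frame_weights()].
#' @param edges Bin edges; default: `bin_width`-spaced bins spanning the
#'   observed range.
#' @param bin_width Default bin width in Angstrom (used when `edges` is
#'   `NULL`).
#' @return A 1D `fes` object (see [pmf_from_histogram()]).
#' @export
insertion_pmf <- function(series, boost, thermo, method = "exponential",
                          k = 10, boost_which = "total", edges = NULL,
                          bin_width = 1) {
  vals <- if (inherits(series, "rc_series")) series$values else as.numeric(series)
  nm <- if (inherits(series, "rc_series")) series$name else "rc"
  if (is.null(boost)) {
    w <- rep(1, length(vals))
  } else {
    stopifnot(inherits(boost, "boost_series"))
    if (nrow(boost) != length(vals))
      stop("boost series and coordinate series lengths differ")
    w <- frame_weights(boost, thermo, method = method, k = k,
                       boost_which = boost_which)$w
  }
  if (is.null(edges)) {
    lo <- floor(min(vals) / bin_width) * bin_width
    hi <- ceiling(max(vals) / bin_width) * bin_width
    if (hi <= lo) hi <- lo + bin_width
    edges <- seq(lo, hi + bin_width / 2, by = bin_width)
  }
  h <- weighted_histogram(vals, w, edges)
  pmf_from_histogram(h, thermo, coord = nm)
}

#' Residue-headgroup contact fractions
#'
#' For each peptide residue, the fraction of frames in which any of its
#' side-chain heavy atoms lies within `cutoff` of any flagged lipid
#' headgroup heavy atom. "Side chain" means all non-backbone heavy atoms
#' (backbone = N, CA, C, O); for terminal cap / amino-alcohol residues
#' (ACE, NME, PHL) every heavy atom counts, so terminal hydroxyls and the
#' acetyl cap participate. Distances use the minimum-image convention on
#' the periodic axes when a box is present.
#'
#' @param traj A `traj_frames`.
#' @param topo The matching `topology` (headgroup atoms must be flagged).
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 4.5).
#' @return Object of class `contact_table`: data.frame with columns
#'   `resid`, `residue`, `fraction`; attributes `cutoff` and `n_frames`.
#' @export
headgroup_contact_fractions <- function(traj, topo, cutoff = 4.5) {
  stopifnot(inherits(traj, "traj_frames"), inherits(topo, "topology"))
  a <- topo$atoms
  head_idx <- which(a$headgroup & a$element != "H")
  if (!length(head_idx)) stop("no headgroup atoms flagged in topology")
  pep <- which(a$mol_class == "peptide")
  if (!length(pep)) stop("no peptide residues in topology")
  res_ids <- unique(a$resid[pep])
  backbone <- c("N", "CA", "C", "O")
  all_heavy <- c("ACE", "NME", "PHL")
  frac <- numeric(length(res_ids))
  for (ri in seq_along(res_ids)) {
    r <- res_ids[ri]
    rows <- which(a$resid == r & a$mol_class == "peptide" & a$element != "H")
    if (!(a$resname[rows[1]] %in% all_heavy))
      rows <- rows[!(a$name[rows] %in% backbone)]
    if (!length(rows)) { frac[ri] <- 0; next }
    hits <- 0L
    for (f in seq_len(traj$n_frames)) {
      ps <- traj$coords[f, rows, , drop = FALSE][1, , , drop = TRUE]
      if (is.null(dim(ps))) ps <- matrix(ps, ncol = 3)
      hs <- traj$coords[f, head_idx, , drop = FALSE][1, , , drop = TRUE]
      if (is.null(dim(hs))) hs <- matrix(hs, ncol = 3)
      box <- if (is.null(traj$box)) NULL else traj$box[f, ]
      d2min <- Inf
      for (ax in 1:3) {
        dd <- outer(ps[, ax], hs[, ax], "-")
        if (!is.null(box)) dd <- dd - box[ax] * round(dd / box[ax])
        d2min <- if (ax == 1) dd^2 else d2min + dd^2
      }
      if (any(d2min <= cutoff^2)) hits <- hits + 1L
    }
    frac[ri] <- hits / traj$n_frames
  }
  labels <- vapply(res_ids, function(r)
    a$resname[which(a$resid == r & a$mol_class == "peptide")[1]], "")
  structure(data.frame(resid = res_ids, residue = labels, fraction = frac),
            cutoff = cutoff, n_frames = traj$n_frames,
            class = c("contact_table", "data.frame"))
}
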