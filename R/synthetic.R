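# run expr with a local, seeded RNG stream; the caller's RNG state is
# untouched (generators are pure functions of (spec, seed))
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Toy potential with closed-form energies
#'
#' Analytic low-dimensional potentials used as ground truth for the
#' reweighting machinery:
#' \itemize{
#'   \item `harmonic`: \eqn{V(x) = k (x - c)^2 / 2};
#'   \item `double_well_1d`: \eqn{V(x) = B ((x - c)^2 / w^2 - 1)^2}, minima
#'     at \eqn{c \pm w}, barrier height `B` at `c`;
#'   \item `double_well_2d`: the 1D double well in x plus a harmonic term
#'     \eqn{k_y y^2 / 2}.
#' }
#' For the 1D families the analytic free-energy profile is
#' `F(x) = V(x) - min V`.
#'
#' @param family `"harmonic"`, `"double_well_1d"` or `"double_well_2d"`.
#' @param k,center Harmonic force constant (kcal/mol/A^2) and minimum.
#' @param barrier Double-well barrier height (kcal/mol).
#' @param width Half-separation of the double-well minima (A).
#' @param k_y Harmonic constant of the y term (`double_well_2d`).
#' @param domain Length-2 sampling bounds for x (defaults per family).
#' @return Object of class `toy_potential` with elements `family`, `V`
#'   (vectorised energy function), `free_energy` (1D families),
#'   `min_V`, `domain`, `dim`.
#' @export
toy_potential <- function(family = c("harmonic", "double_well_1d",
                                     "double_well_2d"),
                          k = 1, center = 0, barrier = 3, width = 1,
                          k_y = 1, domain = NULL) {
  family <- match.arg(family)
  if (family == "harmonic") {
    if (k <= 0) stop("k must be > 0")
    V <- function(x) 0.5 * k * (x - center)^2
    if (is.null(domain)) domain <- center + c(-6, 6) / sqrt(k)
    obj <- list(family = family, V = V, min_V = 0,
                free_energy = function(x) V(x), domain = domain, dim = 1L)
  } else if (family == "double_well_1d") {
    if (barrier <= 0 || width <= 0) stop("barrier and width must be > 0")
    V <- function(x) barrier * ((x - center)^2 / width^2 - 1)^2
    if (is.null(domain)) domain <- center + c(-1.75, 1.75) * width
    obj <- list(family = family, V = V, min_V = 0,
                free_energy = function(x) V(x), domain = domain, dim = 1L)
  } else {
    if (barrier <= 0 || width <= 0 || k_y <= 0)
      stop("barrier, width and k_y must be > 0")
    V <- function(x, y) barrier * ((x - center)^2 / width^2 - 1)^2 +
      0.5 * k_y * y^2
    if (is.null(domain)) domain <- center + c(-1.75, 1.75) * width
    obj <- list(family = family, V = V, min_V = 0, free_energy = NULL,
                domain = domain, dim = 2L)
  }
  obj$params <- list(k = k, center = center, barrier = barrier,
                     width = width, k_y = k_y)
  structure(obj, class = "toy_potential")
}

#' Sampler specification for boosted toy ensembles
#'
#' @param n_samples Number of recorded samples (>= 0).
#' @param seed RNG seed; fixes the full output stream.
#' @param kT Thermal energy (kcal/mol).
#' @param sampler Currently `"metropolis"` (random-walk Metropolis on the
#'   boosted surface; correct stationary statistics without integrator
#'   error).
#' @param step_size Proposal half-width; `NULL` auto-tunes to 30-50
#'   percent acceptance during burn-in.
#' @param burn_in Discarded equilibration steps.
#' @param thinning Record every `thinning`-th step (>= 1).
#' @param amd Optional [amd_params()]; when present the chain samples the
#'   boosted surface `V*(x) = V(x) + boost_energy(V(x), E_total,
#'   alpha_total)` (mode-1 semantics on the toy potential).
#' @return Object of class `sampler_spec`.
#' @export
sampler_spec <- function(n_samples, seed, kT = 0.59616,
                         sampler = "metropolis", step_size = NULL,
                         burn_in = 2000, thinning = 1, amd = NULL) {
  if (n_samples < 0) stop("n_samples must be >= 0")
  if (thinning < 1) stop("thinning must be >= 1")
  if (!identical(sampler, "metropolis"))
    stop("unknown sampler: ", sampler)
  if (!is.null(amd)) stopifnot(inherits(amd, "amd_params"))
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed),
                 kT = kT, sampler = sampler, step_size = step_size,
                 burn_in = as.integer(burn_in),
                 thinning = as.integer(thinning), amd = amd),
            class = "sampler_spec")
}

# random-walk Metropolis on energy function U (takes n x d matrix rows)
.metropolis <- function(U, x0, step, n_record, thinning, burn_in) {
  d <- length(x0)
  x <- x0; ux <- U(x)
  # burn-in with step tuning toward 30-50% acceptance
  block <- 200L
  nblocks <- max(1L, burn_in %/% block)
  for (b in seq_len(nblocks)) {
    acc <- 0L
    prop <- matrix(stats::runif(block * d, -step, step), block, d)
    lu <- log(stats::runif(block))
    for (i in seq_len(block)) {
      xn <- x + prop[i, ]; un <- U(xn)
      if (lu[i] < (ux - un)) { x <- xn; ux <- un; acc <- acc + 1L }
    }
    r <- acc / block
    if (r < 0.30) step <- step / 1.25 else if (r > 0.50) step <- step * 1.25
  }
  out <- matrix(NA_real_, n_record, d)
  nsteps <- n_record * thinning
  chunk <- 10000L
  done <- 0L; rec <- 0L
  while (done < nsteps) {
    m <- min(chunk, nsteps - done)
    prop <- matrix(stats::runif(m * d, -step, step), m, d)
    lu <- log(stats::runif(m))
    for (i in seq_len(m)) {
      xn <- x + prop[i, ]; un <- U(xn)
      if (lu[i] < (ux - un)) { x <- xn; ux <- un }
      done <- done + 1L
      if (done %% thinning == 0L) { rec <- rec + 1L; out[rec, ] <- x }
    }
  }
  list(samples = out, step = step)
}

#' Sample a (possibly boosted) toy ensemble with per-sample boost records
#'
#' Draws Metropolis samples from the density
#' \eqn{\propto \exp(-V^*(x)/kT)} where \eqn{V^*(x) = V(x) + \Delta V(x)}
#' is the boosted surface (\eqn{\Delta V \equiv 0} without `amd`), and
#' records each sample's boost so that reweighting by
#' \eqn{e^{\Delta V / kT}} recovers the canonical density
#' \eqn{\propto \exp(-V(x)/kT)}.
#'
#' @param potential A [toy_potential()].
#' @param sampler A [sampler_spec()].
#' @return List with `positions` (numeric vector, or n x 2 matrix for 2D
#'   potentials) and `boost` (a [boost_series()] whose `V_P` is the
#'   unboosted energy and `dV_P` the applied boost; mode 1).
#' @export
sample_boosted <- function(potential, sampler) {
  stopifnot(inherits(potential, "toy_potential"),
            inherits(sampler, "sampler_spec"))
  kT <- sampler$kT
  Vfun <- if (potential$dim == 1L) function(x) potential$V(x[1])
          else function(x) potential$V(x[1], x[2])
  boostfun <- if (is.null(sampler$amd)) function(v) 0
    else function(v) boost_energy(v, sampler$amd$E_total,
                                  sampler$amd$alpha_total)
  U <- function(x) { v <- Vfun(x); (v + boostfun(v)) / kT }
  if (sampler$n_samples == 0L) {
    return(list(positions = if (potential$dim == 1L) numeric()
                            else matrix(0, 0, 2),
                boost = boost_series(mode = 1L)))
  }
  x0 <- rep(mean(potential$domain), potential$dim)
  step0 <- if (is.null(sampler$step_size))
    diff(range(potential$domain)) / 10 else sampler$step_size
  res <- .with_seed(sampler$seed,
    .metropolis(U, x0, step0, sampler$n_samples, sampler$thinning,
                sampler$burn_in))
  pos <- res$samples
  V <- if (potential$dim == 1L) potential$V(pos[, 1])
       else potential$V(pos[, 1], pos[, 2])
  dV <- if (is.null(sampler$amd)) rep(0, length(V))
        else boost_energy(V, sampler$amd$E_total, sampler$amd$alpha_total)
  list(positions = if (potential$dim == 1L) pos[, 1] else pos,
       boost = boost_series(step = seq_along(V), V_P = V,
                            V_D = rep(0, length(V)), dV_P = dV,
                            dV_D = rep(0, length(V)), mode = 1L))
}

# von Mises sampler, Best & Fisher (1979) wrapped-Cauchy rejection;
# mu in radians, returns radians in (-pi, pi]
.rvonmises <- function(n, mu, kappa) {
  if (n == 0L) return(numeric())
  if (kappa < 1e-8) {
    th <- stats::runif(n, -pi, pi)
    return(th)
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n); got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3[ok] - 0.5) * acos(f[ok])
    take <- min(length(th), n - got)
    if (take > 0) out[(got + 1):(got + take)] <- th[seq_len(take)]
    got <- got + take
  }
  th <- out + mu
  th - 2 * pi * floor((th + pi) / (2 * pi))  # wrap to (-pi, pi]
}

#' Generate torsion series with planted conformational clusters
#'
#' Each frame is assigned to a cluster by the given weights; its phi/psi
#' vector is then drawn from per-angle von Mises distributions centred on
#' that cluster's mean angles. Ground-truth labels are returned for
#' cluster-recovery tests.
#'
#' @param n_frames Number of frames (>= 0).
#' @param n_residues Number of residues.
#' @param weights Cluster weights, summing to 1 (tolerance 1e-9).
#' @param means Per-cluster circular means in degrees: a list with one
#'   element per cluster, each either length 2 (`c(phi, psi)`, recycled
#'   across residues) or length `2 * n_residues`
#'   (`c(phi_1..phi_n, psi_1..psi_n)`).
#' @param kappas Per-cluster von Mises concentrations (>= 0).
#' @param seed RNG seed.
#' @return List with `series` (a `dihedral_series`) and `labels`
#'   (integer cluster index per frame).
#' @export
gen_torsion_clusters <- function(n_frames, n_residues, weights, means,
                                 kappas, seed) {
  K <- length(weights)
  if (abs(sum(weights) - 1) > 1e-9) stop("cluster weights must sum to 1")
  if (length(means) != K || length(kappas) != K)
    stop("means and kappas must have one entry per cluster")
  if (any(kappas < 0)) stop("concentrations must be >= 0")
  mu <- lapply(means, function(m) {
    if (length(m) == 2L) m <- c(rep(m[1], n_residues), rep(m[2], n_residues))
    if (length(m) != 2L * n_residues)
      stop("each cluster mean must have length 2 or 2*n_residues")
    m * pi / 180
  })
  res_labels <- paste0("RES", seq_len(n_residues))
  if (n_frames == 0L) {
    return(list(series = dihedral_series(
                  phi = matrix(numeric(), 0, n_residues),
                  psi = matrix(numeric(), 0, n_residues),
                  residues = res_labels),
                labels = integer()))
  }
  out <- .with_seed(seed, {
    labels <- sample.int(K, n_frames, replace = TRUE, prob = weights)
    ang <- matrix(NA_real_, n_frames, 2L * n_residues)
    for (k in seq_len(K)) {
      idx <- which(labels == k)
      if (!length(idx)) next
      for (j in seq_len(2L * n_residues))
        ang[idx, j] <- .rvonmises(length(idx), mu[[k]][j], kappas[k])
    }
    list(labels = labels, ang = ang)
  })
  deg <- out$ang * 180 / pi
  deg[deg <= -180] <- deg[deg <= -180] + 360
  list(series = dihedral_series(phi = deg[, seq_len(n_residues), drop = FALSE],
                                psi = deg[, n_residues + seq_len(n_residues),
                                          drop = FALSE],
                                residues = res_labels),
       labels = out$labels)
}

#' Generate unit vectors with a prescribed tilt law about the bilayer normal
#'
#' The polar angle theta (from the +z normal) follows the requested
#' distribution; the azimuth is uniform.
#'
#' @param n Number of vectors (>= 0).
#' @param distribution `"delta"` (all at `theta`), `"isotropic"` (uniform
#'   on the sphere) or `"vmf"` (von Mises-Fisher about +z, concentration
#'   `kappa`).
#' @param theta Polar angle in degrees (for `"delta"`).
#' @param kappa Concentration (for `"vmf"`).
#' @param seed RNG seed.
#' @return List with `vectors` (n x 3 unit-vector matrix) and `normal`
#'   (`c(0, 0, 1)`).
#' @export
gen_oriented_vectors <- function(n, distribution = c("delta", "isotropic",
                                                     "vmf"),
                                 theta = 0, kappa = 10, seed = 1) {
  distribution <- match.arg(distribution)
  if (n < 0) stop("n must be >= 0")
  if (n == 0L)
    return(list(vectors = matrix(numeric(), 0, 3), normal = c(0, 0, 1)))
  vec <- .with_seed(seed, {
    phi <- stats::runif(n, 0, 2 * pi)
    cth <- switch(distribution,
      delta = rep(cos(theta * pi / 180), n),
      isotropic = stats::runif(n, -1, 1),
      vmf = {
        if (kappa < 1e-8) stats::runif(n, -1, 1)
        else {
          u <- stats::runif(n)
          1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
        }
      })
    sth <- sqrt(pmax(0, 1 - cth^2))
    cbind(sth * cos(phi), sth * sin(phi), cth)
  })
  list(vectors = vec, normal = c(0, 0, 1))
}

#' Generate a toy peptide + membrane system
#'
#' Builds two mirror-symmetric leaflets of pseudo-lipids (one headgroup
#' bead `P` plus a ladder of chain beads `C2..C(n+1)` per lipid, PE:PG in
#' 3:1 ratio) about z = 0, and optionally a pseudo-peptide (beads `N`,
#' `CA`, `C`, `CB` per residue) whose atoms all sit exactly at the
#' requested z offset, so the frame-0 peptide-membrane distance equals the
#' offset by construction.
#'
#' @param n_lipids Lipids per leaflet (>= 1).
#' @param headgroup_z Headgroup plane |z| (Angstrom).
#' @param n_chain_beads Chain beads per lipid.
#' @param peptide_residues Character vector of residue names, or `NULL`
#'   for a membrane-only system.
#' @param peptide_z Peptide z offset(s), one value per frame (recycled).
#' @param n_frames Number of frames.
#' @param box Optional box lengths `c(Lx, Ly, Lz)`.
#' @param seed RNG seed (xy jitter of lipid placement).
#' @return List with `topology` and `frames` (a `traj_frames`).
#' @export
gen_toy_membrane_system <- function(n_lipids = 16, headgroup_z = 20,
                                    n_chain_beads = 6,
                                    peptide_residues = NULL,
                                    peptide_z = 28, n_frames = 1,
                                    box = NULL, seed = 1) {
  if (n_lipids < 1) stop("n_lipids must be >= 1")
  side <- ceiling(sqrt(n_lipids))
  spacing <- 8
  grid <- expand.grid(x = seq_len(side), y = seq_len(side))[seq_len(n_lipids), ]
  jit <- .with_seed(seed, matrix(stats::runif(2 * n_lipids, -1, 1),
                                 n_lipids, 2))
  lipid_names <- rep(c("PE", "PE", "PE", "PG"), length.out = n_lipids)
  chain_z <- headgroup_z * (1 - seq_len(n_chain_beads) /
                              (n_chain_beads + 1))
  serial <- integer(); name <- character(); resname <- character()
  resid <- integer(); element <- character(); coords0 <- NULL
  next_serial <- 1L; next_resid <- 1L
  add_atom <- function(nm, el, xyz) {
    serial <<- c(serial, next_serial); next_serial <<- next_serial + 1L
    name <<- c(name, nm); element <<- c(element, el)
    resname <<- c(resname, cur_resname); resid <<- c(resid, next_resid)
    coords0 <<- rbind(coords0, xyz)
  }
  cur_resname <- NULL
  pep_idx <- integer()
  if (!is.null(peptide_residues)) {
    # peptide first: all beads in the z = 0 plane of the peptide frame
    offs <- list(N = c(-0.7, 0.4), CA = c(0, 0), C = c(0.7, 0.4),
                 CB = c(0, -1.2))
    for (i in seq_along(peptide_residues)) {
      cur_resname <- peptide_residues[i]
      base_x <- (i - 1) * 3
      for (nm in names(offs)) {
        el <- substr(nm, 1, 1)
        add_atom(nm, el, c(base_x + offs[[nm]][1], offs[[nm]][2], 0))
        pep_idx <- c(pep_idx, next_serial - 1L)
      }
      next_resid <- next_resid + 1L
    }
  }
  for (leaf in c(1, -1)) {
    for (l in seq_len(n_lipids)) {
      cur_resname <- lipid_names[l]
      x <- (grid$x[l] - (side + 1) / 2) * spacing + jit[l, 1]
      y <- (grid$y[l] - (side + 1) / 2) * spacing + jit[l, 2]
      add_atom("P", "P", c(x, y, leaf * headgroup_z))
      for (cb in seq_len(n_chain_beads))
        add_atom(paste0("C", cb + 1), "C", c(x, y, leaf * chain_z[cb]))
      next_resid <- next_resid + 1L
    }
  }
  topo <- topology(serial = serial, name = name, resname = resname,
                   resid = resid, chain = rep("", length(serial)),
                   element = element,
                   mass = unname(.element_masses[ifelse(element == "NA",
                                                        "NA.", element)]))
  peptide_z <- rep_len(peptide_z, n_frames)
  coords <- array(NA_real_, dim = c(n_frames, nrow(coords0), 3))
  for (f in seq_len(n_frames)) {
    fr <- coords0
    if (length(pep_idx)) {
      rows <- match(pep_idx, serial)
      fr[rows, 3] <- fr[rows, 3] + peptide_z[f]
    }
    coords[f, , ] <- fr
  }
  frames <- traj_frames(coords,
                        box = if (is.null(box)) NULL
                              else matrix(rep(box, n_frames), ncol = 3,
                                          byrow = TRUE))
  list(topology = topo, frames = frames)
}
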