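#' Boltzmann constant in kcal mol^-1 K^-1
#'
#' Value used throughout the package to convert temperature to thermal
#' energy kT.
#' @export
KB_KCAL <- 0.0019872041

#' Thermodynamic parameters
#'
#' Bundle a simulation temperature with the corresponding thermal energy
#' \eqn{k_B T} in kcal/mol.
#'
#' @param temperature Temperature in Kelvin (> 0).
#' @return An object of class `thermo_params` with elements `temperature`
#'   (K) and `kT` (kcal/mol).
#' @examples
#' thermo_params(300)$kT  # 0.59616...
#' @export
thermo_params <- function(temperature = 300) {
  if (!is.numeric(temperature) || length(temperature) != 1L || temperature <= 0)
    stop("temperature must be a single positive number (Kelvin)")
  structure(list(temperature = temperature, kT = KB_KCAL * temperature),
            class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf("thermo_params: T = %g K, kT = %.7g kcal/mol\n",
              x$temperature, x$kT))
  invisible(x)
}

#' Accelerated-MD boost parameters
#'
#' Thresholds and smoothing constants for the aMD boost potential. Mode 1
#' boosts the whole potential, mode 2 only the torsional term, mode 3 both
#' (dual boost).
#'
#' @param mode Boost criterion: 1 (total potential), 2 (dihedral only) or
#'   3 (dual boost).
#' @param E_total,alpha_total Threshold and smoothing constant (kcal/mol)
#'   for the total-potential boost; required for modes 1 and 3.
#' @param E_dih,alpha_dih Threshold and smoothing constant (kcal/mol) for
#'   the torsional boost; required for modes 2 and 3.
#' @return An object of class `amd_params`.
#' @seealso [boost_energy()], [total_boost()], [params_from_classical_averages()]
#' @export
amd_params <- function(mode, E_total = NA_real_, alpha_total = NA_real_,
                       E_dih = NA_real_, alpha_dih = NA_real_) {
  if (!mode %in% c(1L, 2L, 3L)) stop("mode must be 1, 2 or 3")
  mode <- as.integer(mode)
  if (mode %in% c(1L, 3L)) {
    if (!is.finite(E_total) || !is.finite(alpha_total) || alpha_total <= 0)
      stop("modes 1 and 3 require finite E_total and alpha_total > 0")
  }
  if (mode %in% c(2L, 3L)) {
    if (!is.finite(E_dih) || !is.finite(alpha_dih) || alpha_dih <= 0)
      stop("modes 2 and 3 require finite E_dih and alpha_dih > 0")
  }
  structure(list(mode = mode, E_total = E_total, alpha_total = alpha_total,
                 E_dih = E_dih, alpha_dih = alpha_dih),
            class = "amd_params")
}

#' @export
print.amd_params <- function(x, ...) {
  cat(sprintf("amd_params (iamd = %d)\n", x$mode))
  if (x$mode %in% c(1L, 3L))
    cat(sprintf("  total:    E = %g, alpha = %g kcal/mol\n",
                x$E_total, x$alpha_total))
  if (x$mode %in% c(2L, 3L))
    cat(sprintf("  dihedral: E = %g, alpha = %g kcal/mol\n",
                x$E_dih, x$alpha_dih))
  invisible(x)
}

#' aMD boost energy
#'
#' The non-negative boost added to a potential energy `V` lying below the
#' threshold `E`:
#' \deqn{\Delta V = \frac{(E - V)^2}{\alpha + E - V} \quad (V < E), \qquad
#'       \Delta V = 0 \quad (V \ge E).}
#' The boost fills energy wells and so flattens barriers; `alpha` controls
#' how aggressively the modified surface is smoothed.
#'
#' @param V Potential energy (kcal/mol); vectorised.
#' @param E Boost threshold (kcal/mol).
#' @param alpha Smoothing constant (kcal/mol, > 0).
#' @return Boost energies, same length as `V`, all `>= 0`.
#' @examples
#' boost_energy(0, E = 10, alpha = 10)   # 5
#' boost_energy(12, E = 10, alpha = 10)  # 0
#' @export
boost_energy <- function(V, E, alpha) {
  if (!is.numeric(alpha) || any(alpha <= 0)) stop("alpha must be > 0")
  d <- E - V
  ifelse(d > 0, d * d / (alpha + d), 0)
}

#' Per-frame total and dihedral boost under a given iamd mode
#'
#' @param V_P Unboosted total potential energy (kcal/mol); vectorised.
#' @param V_D Unboosted dihedral energy (kcal/mol); vectorised, recycled
#'   against `V_P`.
#' @param params An [amd_params()] object.
#' @return A list with numeric vectors `dV_P` (total-potential boost) and
#'   `dV_D` (dihedral boost), each zero where the corresponding term is not
#'   boosted by the mode.
#' @export
total_boost <- function(V_P, V_D, params) {
  stopifnot(inherits(params, "amd_params"))
  if (!params$mode %in% c(1L, 2L, 3L))
    stop("unknown iamd mode: ", params$mode)
  n <- max(length(V_P), length(V_D))
  V_P <- rep_len(V_P, n); V_D <- rep_len(V_D, n)
  dV_P <- if (params$mode %in% c(1L, 3L))
    boost_energy(V_P, params$E_total, params$alpha_total) else rep(0, n)
  dV_D <- if (params$mode %in% c(2L, 3L))
    boost_energy(V_D, params$E_dih, params$alpha_dih) else rep(0, n)
  list(dV_P = dV_P, dV_D = dV_D)
}

#' Seed boost parameters from classical-run average energies
#'
#' Standard dual-boost recipe: a short conventional MD run provides the
#' average dihedral energy and average total potential energy, from which
#' \itemize{
#'   \item `E_dih = avg_V_dih + dih_per_res * n_residues`
#'   \item `alpha_dih = dih_per_res * n_residues / dih_alpha_div`
#'   \item `E_total = avg_V_tot + tot_per_atom * n_atoms`
#'   \item `alpha_total = tot_per_atom * n_atoms`
#' }
#' with the conventional constants 3.5 kcal/mol per residue, divisor 5, and
#' 0.175 kcal/mol per atom, all overridable.
#'
#' @param avg_V_dih Average dihedral energy from the classical run (kcal/mol).
#' @param avg_V_tot Average total potential energy (kcal/mol).
#' @param n_residues,n_atoms Solute residue count and total atom count (>= 1).
#' @param mode iamd mode for the returned parameter set (default 3, dual boost).
#' @param dih_per_res,dih_alpha_div,tot_per_atom Recipe constants.
#' @return An [amd_params()] object.
#' @examples
#' params_from_classical_averages(avg_V_dih = 180, avg_V_tot = -1000,
#'                                n_residues = 18, n_atoms = 2000)
#' @export
params_from_classical_averages <- function(avg_V_dih, avg_V_tot,
                                           n_residues, n_atoms,
                                           mode = 3,
                                           dih_per_res = 3.5,
                                           dih_alpha_div = 5,
                                           tot_per_atom = 0.175) {
  if (n_residues < 1 || n_atoms < 1)
    stop("n_residues and n_atoms must be >= 1")
  amd_params(mode = mode,
             E_total = avg_V_tot + tot_per_atom * n_atoms,
             alpha_total = tot_per_atom * n_atoms,
             E_dih = avg_V_dih + dih_per_res * n_residues,
             alpha_dih = dih_per_res * n_residues / dih_alpha_div)
}

#' Serialize boost parameters to a flat key=value / YAML mapping
#'
#' @param params An [amd_params()] object.
#' @return A named list with keys `iamd`, `E_total`, `alpha_total`,
#'   `E_dih`, `alpha_dih`, suitable for [yaml::write_yaml()].
#' @export
amd_params_to_config <- function(params) {
  stopifnot(inherits(params, "amd_params"))
  list(iamd = params$mode, E_total = params$E_total,
       alpha_total = params$alpha_total, E_dih = params$E_dih,
       alpha_dih = params$alpha_dih)
}

#' Read boost parameters from a config mapping
#'
#' @param config Named list with keys `iamd` and the `E`/`alpha` pairs the
#'   mode requires (as written by [amd_params_to_config()]).
#' @return An [amd_params()] object.
#' @export
amd_params_from_config <- function(config) {
  if (is.null(config$iamd)) stop("config lacks 'iamd'")
  num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  amd_params(mode = as.integer(config$iamd),
             E_total = num(config$E_total), alpha_total = num(config$alpha_total),
             E_dih = num(config$E_dih), alpha_dih = num(config$alpha_dih))
}
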