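#' Default residue-name to molecule-class lookup
#'
#' Maps PDB residue names to one of the molecule classes `peptide`,
#' `lipid`, `solvent`, `ion`. Residue names not in the map are classed
#' `"unknown"` with a warning at read time. Extend or replace the map via
#' the `class_map` argument of [read_topology()].
#'
#' @return Named character vector (names = residue names, values = classes).
#' @export
default_residue_classes <- function() {
  aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL",
          # non-standard residues common in peptaibols: alpha-aminoisobutyric
          # acid, isovaline, phenylalaninol, and terminal caps
          "AIB", "IVA", "PHL", "ACE", "NME", "NHE", "HIE", "HID", "HIP")
  lip <- c("PE", "PG", "PC", "PS", "PA", "DOPE", "DOPG", "POPE", "POPG",
           "OL", "LIP")
  sol <- c("WAT", "HOH", "TIP3", "SOL", "SPC")
  ion <- c("K+", "NA+", "CL-", "K", "NA", "CL", "MG", "ZN", "IOD")
  c(stats::setNames(rep("peptide", length(aa)), aa),
    stats::setNames(rep("lipid", length(lip)), lip),
    stats::setNames(rep("solvent", length(sol)), sol),
    stats::setNames(rep("ion", length(ion)), ion))
}

#' Default lipid headgroup atom names
#'
#' Heavy atoms of the phosphate/glycerol/amine (or glycerol-OH) headgroup
#' region used to flag headgroup atoms on lipid residues.
#' @return Character vector of atom names.
#' @export
default_headgroup_atoms <- function() {
  c("P", "O11", "O12", "O13", "O14", "O21", "O22", "O31", "O32",
    "N", "C11", "C12", "C13", "C14", "C15")
}

# atomic masses (amu) keyed by element symbol
.element_masses <- c(H = 1.008, D = 2.014, C = 12.011, N = 14.007,
                     O = 15.999, P = 30.973762, S = 32.06, F = 18.998,
                     K = 39.0983, NA. = 22.98977, CL = 35.453, MG = 24.305,
                     FE = 55.845, ZN = 65.38, BR = 79.904, I = 126.904)

# guess an element symbol from PDB element column or atom name
.guess_element <- function(elesy, name) {
  el <- toupper(trimws(elesy))
  if (nzchar(el) && el %in% c(names(.element_masses), "NA")) {
    return(if (el == "NA") "NA." else el)
  }
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  two <- substr(nm, 1, 2)
  if (two %in% c("CL", "BR", "MG", "FE", "ZN")) return(two)
  if (nm %in% c("NA", "K")) return(if (nm == "NA") "NA." else "K")
  one <- substr(nm, 1, 1)
  if (one %in% names(.element_masses)) one else NA_character_
}

#' Build a topology from atom-level fields
#'
#' Low-level constructor used by [read_topology()] and the synthetic-system
#' generator; validates the topology invariants (unique strictly increasing
#' serials, positive masses, one molecule class per residue).
#'
#' @param serial Integer atom serials.
#' @param name Atom names.
#' @param resname Residue names.
#' @param resid Integer residue indices.
#' @param chain Chain tags ("" allowed).
#' @param element Element symbols.
#' @param mass Atomic masses (amu, > 0).
#' @param class_map Residue-name to molecule-class lookup
#'   (default [default_residue_classes()]).
#' @param headgroup_atoms Atom names flagged as headgroup on lipid residues.
#' @return An object of class `topology`: a list with `atoms` (data.frame
#'   with the above columns plus `mol_class` and `headgroup`), `n_atoms`
#'   and `n_residues`.
#' @export
topology <- function(serial, name, resname, resid, chain, element, mass,
                     class_map = default_residue_classes(),
                     headgroup_atoms = default_headgroup_atoms()) {
  n <- length(serial)
  stopifnot(length(name) == n, length(resname) == n, length(resid) == n,
            length(chain) == n, length(element) == n, length(mass) == n)
  if (anyDuplicated(serial))
    stop("duplicate atom serial(s): ",
         paste(unique(serial[duplicated(serial)]), collapse = ", "))
  if (n > 1 && any(diff(serial) <= 0))
    stop("atom serials must be strictly increasing")
  if (any(!is.finite(mass)) || any(mass <= 0))
    stop("all atom masses must be finite and > 0")
  cls <- unname(class_map[resname])
  unknown <- is.na(cls)
  if (any(unknown)) {
    warning("unknown residue name(s) classed 'unknown': ",
            paste(unique(resname[unknown]), collapse = ", "))
    cls[unknown] <- "unknown"
  }
  # one class per residue
  key <- paste(resid, chain)
  per_res <- tapply(cls, key, function(x) length(unique(x)))
  if (any(per_res > 1))
    stop("residue with more than one molecule class (mixed residue names?)")
  hg <- cls == "lipid" & name %in% headgroup_atoms
  atoms <- data.frame(serial = as.integer(serial), name = name,
                      resname = resname, resid = as.integer(resid),
                      chain = chain, element = element, mass = mass,
                      mol_class = cls, headgroup = hg,
                      stringsAsFactors = FALSE)
  structure(list(atoms = atoms, n_atoms = n,
                 n_residues = length(unique(key))),
            class = "topology")
}

#' Read a topology from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d), assigns molecule classes by
#' residue-name lookup and flags lipid headgroup atoms. Masses come from an
#' internal element-mass table; the element is taken from the PDB element
#' column when present, else inferred from the atom name.
#'
#' @inheritParams topology
#' @param path Path to a PDB file.
#' @return A `topology` object.
#' @export
read_topology <- function(path, class_map = default_residue_classes(),
                          headgroup_atoms = default_headgroup_atoms()) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  a <- pdb$atom
  el <- mapply(.guess_element, a$elesy, a$elety, USE.NAMES = FALSE)
  if (any(is.na(el)))
    stop("cannot determine element for atom(s): ",
         paste(unique(a$elety[is.na(el)]), collapse = ", "))
  mass <- unname(.element_masses[el])
  chain <- ifelse(is.na(a$chain), "", a$chain)
  topology(serial = a$eleno, name = a$elety, resname = a$resid,
           resid = a$resno, chain = chain,
           element = sub("\\.$", "", el), mass = mass,
           class_map = class_map, headgroup_atoms = headgroup_atoms)
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d atoms, %d residues\n", x$n_atoms, x$n_residues))
  tab <- table(x$atoms$mol_class[!duplicated(paste(x$atoms$resid, x$atoms$chain))])
  cat("  residues by class:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  headgroup-flagged atoms: %d\n", sum(x$atoms$headgroup)))
  invisible(x)
}

#' Write a topology (with one set of coordinates) to a PDB file
#'
#' @param topo A `topology` object.
#' @param coords n_atoms x 3 coordinate matrix (Angstrom).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology_pdb <- function(topo, coords, path) {
  stopifnot(inherits(topo, "topology"),
            nrow(coords) == topo$n_atoms, ncol(coords) == 3)
  a <- topo$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(coords)),
                   resno = a$resid, resid = a$resname, eleno = a$serial,
                   elety = a$name, chain = ifelse(a$chain == "", " ", a$chain),
                   elesy = a$element)
  invisible(path)
}
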