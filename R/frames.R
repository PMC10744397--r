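#' Trajectory frame set
#'
#' Container for per-frame Cartesian coordinates of all atoms, with
#' optional orthorhombic box lengths and timestamps.
#'
#' @param coords Numeric array of dimension `n_frames x n_atoms x 3`
#'   (Angstrom).
#' @param box Optional `n_frames x 3` matrix of box lengths (Angstrom, > 0),
#'   or `NULL`.
#' @param time_ns Optional numeric vector of frame timestamps (ns).
#' @return An object of class `traj_frames` with elements `coords`, `box`,
#'   `time_ns`, `n_frames`, `n_atoms`.
#' @export
traj_frames <- function(coords, box = NULL, time_ns = NULL) {
  d <- dim(coords)
  if (length(d) != 3L || d[3] != 3L)
    stop("coords must be an n_frames x n_atoms x 3 array")
  if (!is.null(box)) {
    box <- matrix(box, ncol = 3)
    if (nrow(box) != d[1]) stop("box must have one row per frame")
    if (any(!is.finite(box)) || any(box <= 0))
      stop("box lengths must be finite and positive")
  }
  if (!is.null(time_ns) && length(time_ns) != d[1])
    stop("time_ns must have one value per frame")
  structure(list(coords = coords, box = box, time_ns = time_ns,
                 n_frames = d[1], n_atoms = d[2]),
            class = "traj_frames")
}

#' @export
print.traj_frames <- function(x, ...) {
  cat(sprintf("traj_frames: %d frame(s) x %d atoms%s%s\n",
              x$n_frames, x$n_atoms,
              if (is.null(x$box)) "" else ", with box",
              if (is.null(x$time_ns)) "" else ", with timestamps"))
  invisible(x)
}

# count ATOM/HETATM records per MODEL block (0 models => whole file is 1 frame)
.pdb_model_atom_counts <- function(lines) {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0L) return(sum(is_atom))
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends) != length(model_starts))
    stop("unbalanced MODEL/ENDMDL records")
  vapply(seq_along(model_starts), function(i)
    sum(is_atom[model_starts[i]:model_ends[i]]), integer(1))
}

#' Read trajectory frames from a multi-model PDB or a frame table
#'
#' The format is detected from the content: files containing ATOM/HETATM
#' records are parsed as (multi-model) PDB via bio3d; otherwise the file is
#' parsed as the package's whitespace frame-table dialect (see
#' [write_frames()]).
#'
#' @param path Input file.
#' @param topo The matching `topology`; every frame must contain exactly
#'   `topo$n_atoms` atoms.
#' @return A `traj_frames` object, frames in file order, coordinates in
#'   Angstrom.
#' @export
read_frames <- function(path, topo) {
  stopifnot(inherits(topo, "topology"))
  if (!file.exists(path)) stop("no such file: ", path)
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  if (any(grepl("^(ATOM  |HETATM|MODEL)", head_lines))) {
    lines <- readLines(path, warn = FALSE)
    counts <- .pdb_model_atom_counts(lines)
    bad <- which(counts != topo$n_atoms)
    if (length(bad))
      stop(sprintf("frame %d has %d atoms, topology has %d",
                   bad[1], counts[bad[1]], topo$n_atoms))
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    nf <- nrow(xyz)
    coords <- aperm(array(t(xyz), dim = c(3, topo$n_atoms, nf)), c(3, 2, 1))
    return(traj_frames(coords))
  }
  .read_frame_table(path, topo)
}

.read_frame_table <- function(path, topo) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  starts <- grep("^FRAME\\b", lines)
  if (length(starts) == 0L) stop("frame table contains no FRAME records")
  ends <- c(starts[-1] - 1L, length(lines))
  nf <- length(starts)
  na <- topo$n_atoms
  coords <- array(NA_real_, dim = c(nf, na, 3))
  box <- NULL; time_ns <- NULL
  for (i in seq_len(nf)) {
    hdr <- strsplit(trimws(lines[starts[i]]), "\\s+")[[1]]
    if (length(hdr) >= 3) {
      tv <- suppressWarnings(as.numeric(hdr[3]))
      if (is.null(time_ns)) time_ns <- rep(NA_real_, nf)
      time_ns[i] <- tv
    }
    if (length(hdr) >= 6) {
      bv <- suppressWarnings(as.numeric(hdr[4:6]))
      if (is.null(box)) box <- matrix(NA_real_, nf, 3)
      box[i, ] <- bv
    }
    body <- lines[(starts[i] + 1L):ends[i]]
    if (length(body) != na)
      stop(sprintf("frame %d has %d atoms, topology has %d",
                   i, length(body), na))
    vals <- suppressWarnings(
      as.numeric(unlist(strsplit(trimws(body), "\\s+"), use.names = FALSE)))
    if (length(vals) != 3L * na || any(is.na(vals)))
      stop(sprintf("frame %d: malformed coordinate line(s)", i))
    coords[i, , ] <- matrix(vals, ncol = 3, byrow = TRUE)
  }
  if (!is.null(time_ns) && all(is.na(time_ns))) time_ns <- NULL
  if (!is.null(box) && any(is.na(box))) stop("box given for some frames only")
  traj_frames(coords, box = box, time_ns = time_ns)
}

#' Write trajectory frames
#'
#' `format = "table"` writes the package's whitespace frame-table dialect:
#' `#` comment lines, then per frame a separator line
#' `FRAME <index> [<time_ns> [<bx> <by> <bz>]]` followed by one `x y z`
#' line per atom, full precision so that `read_frames(write_frames(x))`
#' is bit-identical. `format = "pdb"` writes a multi-model PDB (via bio3d,
#' fixed 3-decimal PDB precision).
#'
#' @param traj A `traj_frames` object.
#' @param path Output file.
#' @param topo The matching `topology` (required for `format = "pdb"`).
#' @param format `"table"` or `"pdb"`.
#' @return `path`, invisibly.
#' @export
write_frames <- function(traj, path, topo = NULL,
                         format = c("table", "pdb")) {
  stopifnot(inherits(traj, "traj_frames"))
  format <- match.arg(format)
  if (format == "pdb") {
    if (is.null(topo)) stop("format='pdb' requires a topology")
    stopifnot(topo$n_atoms == traj$n_atoms)
    xyz <- t(apply(traj$coords, 1, function(fr) as.numeric(t(fr))))
    if (traj$n_frames == 1L) xyz <- matrix(xyz, nrow = 1)
    a <- topo$atoms
    bio3d::write.pdb(file = path, xyz = xyz,
                     resno = a$resid, resid = a$resname, eleno = a$serial,
                     elety = a$name,
                     chain = ifelse(a$chain == "", " ", a$chain),
                     elesy = a$element)
    return(invisible(path))
  }
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  con <- file(path, open = "wt"); on.exit(close(con))
  writeLines(c("# amdmem frame table",
               "# FRAME <index> [<time_ns> [<bx> <by> <bz>]] ; one 'x y z' line per atom (Angstrom)"),
             con)
  for (i in seq_len(traj$n_frames)) {
    hdr <- paste("FRAME", i)
    if (!is.null(traj$time_ns)) hdr <- paste(hdr, fmt(traj$time_ns[i]))
    else if (!is.null(traj$box)) hdr <- paste(hdr, "NA")  # hold the time slot
    if (!is.null(traj$box))
      hdr <- paste(hdr, paste(fmt(traj$box[i, ]), collapse = " "))
    writeLines(hdr, con)
    m <- traj$coords[i, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, ncol = 3)
    writeLines(paste(fmt(m[, 1]), fmt(m[, 2]), fmt(m[, 3])), con)
  }
  invisible(path)
}
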