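# fixtures are built in code at test time; nothing binary on disk

# minimal PDB writer for hand-crafted fixtures (fixed-column ATOM records)
pdb_atom_line <- function(serial, name, resname, resid, xyz,
                          chain = "A", element = substr(name, 1, 1)) {
  sprintf("ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, name, resname, chain, resid, xyz[1], xyz[2], xyz[3], element)
}

write_toy_pdb <- function(path, df, models = NULL) {
  # df: data.frame(serial, name, resname, resid, x, y, z, element)
  lines <- character()
  emit <- function(d) vapply(seq_len(nrow(d)), function(i)
    pdb_atom_line(d$serial[i], d$name[i], d$resname[i], d$resid[i],
                  c(d$x[i], d$y[i], d$z[i]), element = d$element[i]), "")
  if (is.null(models)) {
    lines <- c(emit(df), "END")
  } else {
    for (m in seq_along(models)) {
      d <- df; d$x <- models[[m]][, 1]; d$y <- models[[m]][, 2]
      d$z <- models[[m]][, 3]
      lines <- c(lines, sprintf("MODEL     %4d", m), emit(d), "ENDMDL")
    }
    lines <- c(lines, "END")
  }
  writeLines(lines, path)
  path
}

# one alanine-like residue: N, CA, C (+ optional O, CB)
toy_residue_df <- function(resid = 1, resname = "ALA", base = c(0, 0, 0),
                           serial0 = 0) {
  data.frame(serial = serial0 + 1:3, name = c("N", "CA", "C"),
             resname = resname, resid = resid,
             x = base[1] + c(0, 1.4, 2.4), y = base[2] + c(0, 0.5, 0),
             z = base[3], element = c("N", "C", "C"))
}

# four points with a prescribed torsion about the z axis (IUPAC convention)
torsion_points <- function(angle_deg) {
  a <- angle_deg * pi / 180
  list(p1 = c(1, 0, -1), p2 = c(0, 0, 0), p3 = c(0, 0, 1),
       p4 = c(cos(a), sin(a), 1))
}

# boost series with explicit dV values (x = dV/kT convenience)
boost_from_dv <- function(dV, mode = 1L) {
  n <- length(dV)
  boost_series(step = seq_len(n) * 1000L, V_P = rep(0, n), V_D = rep(0, n),
               dV_P = dV, dV_D = rep(0, n), mode = mode)
}

expect_fes_invariants <- function(fes) {
  expect_s3_class(fes, "fes")
  p <- fes$prob[!fes$mask]
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_identical(min(fes$pmf[!fes$mask]), 0)
  expect_true(all(is.na(fes$pmf[fes$mask])))
}
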