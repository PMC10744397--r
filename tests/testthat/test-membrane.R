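th <- thermo_params(300)

test_that("S_CD closed forms at delta tilts and the isotropic bound", {
  closed_form <- function(theta) abs(0.5 * (3 * cos(theta * pi / 180)^2 - 1))
  for (theta in c(0, 30, 54.7356, 90)) {
    v <- gen_oriented_vectors(2000, "delta", theta = theta, seed = 31)
    p <- scd_profile(as_chain_vector_set(v$vectors))
    expect_equal(p$scd, closed_form(theta), tolerance = 1e-9)
    expect_equal(p$n, 2000L)
  }
  expect_equal(closed_form(30), 0.625)
  # at the exact magic angle (cos^2 = 1/3) the order parameter vanishes
  magic <- acos(1 / sqrt(3)) * 180 / pi
  v <- gen_oriented_vectors(2000, "delta", theta = magic, seed = 31)
  expect_lt(scd_profile(as_chain_vector_set(v$vectors))$scd, 1e-12)
  v <- gen_oriented_vectors(100000, "isotropic", seed = 32)
  expect_lte(scd_profile(as_chain_vector_set(v$vectors))$scd, 0.02)
  expect_error(scd_profile(chain_vector_set(
    data.frame(chain = character(), carbon = integer(),
               x = numeric(), y = numeric(), z = numeric()))), "empty")
})

test_that("chain_vectors extracts normalized C-H vectors per mapped carbon", {
  # one lipid with a CH2 at carbon 2: both H displaced along +z
  df <- data.frame(serial = 1:3, name = c("C22", "H2R", "H2S"),
                   resname = "PE", resid = 1,
                   x = c(0, 0, 0), y = c(0, 0, 0), z = c(0, 1.1, 2.0),
                   element = c("C", "H", "H"))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(path, df)
  topo <- read_topology(path)
  traj <- read_frames(path, topo)
  vs <- suppressWarnings(chain_vectors(traj, topo))
  expect_equal(nrow(vs$vectors), 2)  # two H on one CH2 carbon
  expect_equal(vs$vectors$z, c(1, 1))
  expect_equal(vs$vectors$chain, c("sn2", "sn2"))
  p <- scd_profile(vs)
  expect_equal(p$scd, 1.0)

  # all-carbon chain with no hydrogens: empty set plus warning
  df2 <- df; df2$name <- c("C22", "C23", "C24"); df2$element <- "C"
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(path2, df2)
  topo2 <- read_topology(path2)
  expect_warning(vs2 <- chain_vectors(read_frames(path2, topo2), topo2),
                 "without resolvable hydrogens")
  expect_equal(nrow(vs2$vectors), 0)
})

test_that("com_z_distance mass-weights and respects constructed geometry", {
  sys <- gen_toy_membrane_system(n_lipids = 9, peptide_residues = "ALA",
                                 peptide_z = 28, seed = 1)
  expect_equal(com_z_distance(sys$frames, sys$topology)$values, 28,
               tolerance = 1e-12)

  # hand mass-weighting: atoms of mass 1 and 3 at z = 10 and 20
  topo <- topology(serial = 1:3, name = c("X1", "X2", "P"),
                   resname = c("QQ", "QQ", "PE"), resid = c(1, 1, 2),
                   chain = rep("", 3), element = c("H", "C", "P"),
                   mass = c(1, 3, 10),
                   class_map = c(QQ = "peptide", PE = "lipid"))
  coords <- array(0, dim = c(1, 3, 3))
  coords[1, , 3] <- c(10, 20, 0)
  traj <- traj_frames(coords)
  d <- com_z_distance(traj, topo)
  expect_equal(d$values, 17.5)  # (1*10 + 3*20)/4

  # peptide exactly at the membrane COM
  coords[1, , 3] <- c(0, 0, 0)
  expect_equal(com_z_distance(traj_frames(coords), topo)$values, 0)
  expect_error(com_z_distance(traj, topo, peptide_sel = integer()), "empty")
})

test_that("com_z_distance is invariant under rigid z translation and wraps images", {
  sys <- gen_toy_membrane_system(n_lipids = 9, peptide_residues = "ALA",
                                 peptide_z = 15, seed = 2)
  d0 <- com_z_distance(sys$frames, sys$topology)$values
  shifted <- sys$frames
  shifted$coords[, , 3] <- shifted$coords[, , 3] + 123.4
  expect_equal(com_z_distance(shifted, sys$topology)$values, d0,
               tolerance = 1e-9)

  # with a box, a peptide displaced by +Lz is the same physical system
  boxed <- gen_toy_membrane_system(n_lipids = 9, peptide_residues = "ALA",
                                   peptide_z = 15, box = c(80, 80, 100),
                                   seed = 2)
  img <- boxed$frames
  pep_rows <- which(boxed$topology$atoms$mol_class == "peptide")
  img$coords[, pep_rows, 3] <- img$coords[, pep_rows, 3] + 100
  expect_equal(com_z_distance(img, boxed$topology)$values,
               com_z_distance(boxed$frames, boxed$topology)$values,
               tolerance = 1e-9)
})

test_that("insertion_pmf locates a planted minimum and degenerate inputs", {
  pot <- toy_potential("harmonic", k = 0.5, center = 28)
  s <- sample_boosted(pot, sampler_spec(20000, seed = 3, kT = th$kT))
  fes <- insertion_pmf(rc_series(s$positions, "com_z_distance"), NULL, th)
  amin <- fes$centers[[1]][which.min(fes$pmf)]
  expect_lte(abs(amin - 28), 1)
  expect_fes_invariants(fes)

  # all frames at the same distance: one occupied bin with PMF zero
  fes1 <- insertion_pmf(rc_series(rep(12.3, 50)), NULL, th)
  expect_equal(sum(!fes1$mask), 1)
  expect_identical(fes1$pmf[!fes1$mask], 0)

  expect_error(insertion_pmf(rc_series(1:5), boost_from_dv(rep(0, 3)), th),
               "lengths differ")
})

test_that("contact fractions hit the constructed extremes and a half case", {
  # peptide far above the membrane: all zero
  far <- gen_toy_membrane_system(n_lipids = 9, headgroup_z = 20,
                                 peptide_residues = c("SER", "GLN"),
                                 peptide_z = 70, seed = 4)
  ct <- headgroup_contact_fractions(far$frames, far$topology, cutoff = 4.5)
  expect_equal(ct$fraction, c(0, 0))

  # peptide sitting on the headgroup plane: CB bead within 3 A in all frames
  near <- gen_toy_membrane_system(n_lipids = 9, headgroup_z = 20,
                                  peptide_residues = "SER",
                                  peptide_z = 21, n_frames = 4, seed = 4)
  ct <- headgroup_contact_fractions(near$frames, near$topology, cutoff = 4.5)
  expect_equal(ct$fraction, 1.0)

  # contact in exactly 5 of 10 frames
  mixed <- gen_toy_membrane_system(n_lipids = 9, headgroup_z = 20,
                                   peptide_residues = "SER",
                                   peptide_z = rep(c(21, 70), each = 5),
                                   n_frames = 10, seed = 4)
  ct <- headgroup_contact_fractions(mixed$frames, mixed$topology,
                                    cutoff = 4.5)
  expect_equal(ct$fraction, 0.5)
  # brute-force oracle for the same system
  a <- mixed$topology$atoms
  side <- which(a$mol_class == "peptide" & !(a$name %in% c("N", "CA", "C", "O")))
  head_idx <- which(a$headgroup)
  hits <- 0
  for (f in 1:10) {
    dmin <- Inf
    for (i in side) for (j in head_idx) {
      dmin <- min(dmin, sqrt(sum((mixed$frames$coords[f, i, ] -
                                  mixed$frames$coords[f, j, ])^2)))
    }
    if (dmin <= 4.5) hits <- hits + 1
  }
  expect_equal(ct$fraction, hits / 10)
})

test_that("contact fractions are monotone non-decreasing in cutoff", {
  sys <- gen_toy_membrane_system(n_lipids = 9, headgroup_z = 20,
                                 peptide_residues = c("SER", "ALA", "GLN"),
                                 peptide_z = seq(22, 40, length.out = 8),
                                 n_frames = 8, seed = 5)
  cuts <- c(2, 3, 4.5, 6, 10, 25)
  prev <- rep(0, 3)
  for (cu in cuts) {
    ct <- headgroup_contact_fractions(sys$frames, sys$topology, cutoff = cu)
    expect_true(all(ct$fraction >= prev - 1e-12))
    prev <- ct$fraction
  }
  expect_error(headgroup_contact_fractions(
    sys$frames, topology(serial = 1, name = "CA", resname = "ALA",
                         resid = 1, chain = "", element = "C", mass = 12)),
    "headgroup")
})
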