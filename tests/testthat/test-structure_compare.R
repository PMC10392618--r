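# minimal hand-written PDB content for parser checks
minimal_pdb <- function() {
  c("HEADER    TEST",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       2.500   1.200   0.300  1.00  0.00           C",
    "ATOM      4  CA ALEU B   5       9.000   9.000   9.000  1.00  0.00           C",
    "ATOM      5  CA BLEU B   5       9.500   9.000   9.000  1.00  0.00           C",
    "HETATM    6  O   HOH A  90      20.000  20.000  20.000  1.00  0.00           O",
    "END")
}

test_that("PDB parsing reads coordinates, chains, altlocs and skips hetero", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(minimal_pdb(), f)
  m <- read_structure(f)
  expect_s3_class(m, "structure_model")
  expect_equal(nrow(m$residues), 2)          # chain A by default
  expect_equal(m$residues$aa, c("A", "G"))
  expect_equal(m$residues$x, c(1.458, 2.5))
  expect_equal(nrow(m$atoms), 3)             # N + 2 CA, no HETATM

  mb <- read_structure(f, chain = "B")
  expect_equal(nrow(mb$residues), 1)
  expect_equal(mb$residues$x, 9.0)           # altloc A kept, B discarded
})

test_that("first model only; CA-only files parse; missing CA drops residue", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      2  CA  ALA A   1       5.000   5.000   5.000  1.00  0.00           C",
    "ENDMDL"), f)
  m <- read_structure(f)
  expect_equal(nrow(m$residues), 1)
  expect_equal(m$residues$x, 0)

  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  N   GLY A   2       1.000   0.000   0.000  1.00  0.00           N"), f)
  expect_warning(m2 <- read_structure(f), "without an alpha-carbon")
  expect_equal(nrow(m2$residues), 1)
})

test_that("structures round-trip through the PDB writer at format precision", {
  helix <- ideal_helix_coords("MKLIVFAGSTWYQNDE")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(helix, f)
  back <- read_structure(f)
  expect_equal(back$residues$aa, helix$residues$aa)
  expect_equal(back$residues$x, helix$residues$x)
  expect_equal(back$residues$y, helix$residues$y)
  expect_equal(back$residues$z, helix$residues$z)
})

test_that("residue pairing ignores identity and handles gaps", {
  a <- ideal_helix_coords("LIVFLIVFLIVF")
  b <- ideal_helix_coords("QTTYQTTYQTTY")   # QTY relabelling, same length
  p <- pair_residues(a, b)
  expect_equal(nrow(p), 12)
  expect_equal(p[, "a"], p[, "b"])

  # drop residues 5..10 of b -> absent from by_resnum pairs
  b_gap <- b
  keep <- !(b$residues$resno %in% 5:10)
  b_gap$residues <- b$residues[keep, ]
  b_gap$atoms <- b$atoms[keep, ]
  p2 <- pair_residues(a, b_gap, mode = "by_resnum")
  expect_equal(nrow(p2), 6)
  expect_false(any(a$residues$resno[p2[, "a"]] %in% 5:10))

  expect_error(pair_residues(a, b_gap, mode = "by_sequence"), "equal lengths")
})

test_that("Kabsch recovers rigid motions exactly", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(c(4, 10, 50), 1)
    a <- matrix(rnorm(3 * n, sd = 5), n, 3)
    b <- apply_rigid(a, random_rigid_transform())
    sp <- kabsch_superpose(a, b)
    expect_lt(sp$rmsd_all, 1e-9)
    R <- sp$rotation
    expect_equal(det(R), 1, tolerance = 1e-6)
    expect_equal(crossprod(R), diag(3), tolerance = 1e-9, ignore_attr = TRUE)
  }
  expect_error(kabsch_superpose(matrix(0, 3, 2), matrix(0, 3, 3)), "equal-size")
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
})

test_that("the collinear two-spacing case gives the closed-form 0.5 A residual", {
  # duplicated +-1 on x vs +-0.5 on x: best proper rotation keeps the axis,
  # leaving 0.5 per point
  a <- rbind(c(1, 0, 0), c(-1, 0, 0), c(1, 0, 0), c(-1, 0, 0))
  b <- rbind(c(0.5, 0, 0), c(-0.5, 0, 0), c(0.5, 0, 0), c(-0.5, 0, 0))
  sp <- kabsch_superpose(a, b)
  expect_equal(sp$rmsd_all, 0.5, tolerance = 1e-9)
  expect_true(sp$degenerate)
})

test_that("Kabsch matches the brute-force rotation-grid oracle", {
  set.seed(32)
  for (rep in 1:3) {
    a <- matrix(rnorm(15), 5, 3)
    b <- matrix(rnorm(15), 5, 3)
    expect_equal(kabsch_superpose(a, b)$rmsd_all, oracle_grid_rmsd(a, b),
                 tolerance = 1e-3)
  }
})

test_that("RMSD is symmetric and invariant under rigid motion of inputs", {
  set.seed(33)
  a <- matrix(rnorm(60), 20, 3)
  b <- matrix(rnorm(60), 20, 3)
  expect_equal(kabsch_superpose(a, b)$rmsd_all,
               kabsch_superpose(b, a)$rmsd_all, tolerance = 1e-9)
  tf <- random_rigid_transform()
  expect_equal(kabsch_superpose(apply_rigid(a, tf), b)$rmsd_all,
               kabsch_superpose(a, b)$rmsd_all, tolerance = 1e-9)
})

test_that("refinement excludes planted outliers and reports both RMSDs", {
  set.seed(34)
  base <- matrix(rnorm(300, sd = 8), 100, 3)
  noisy <- base + matrix(rnorm(300, sd = 0.3), 100, 3)
  out_idx <- c(10, 30, 50, 70, 90)
  noisy[out_idx, ] <- noisy[out_idx, ] + 10 / sqrt(3)  # ~10 A displacement
  a <- model_from_coords(base)
  b <- model_from_coords(noisy)
  sp <- refine_superpose(a, b)
  expect_lt(sp$rmsd_refined, sp$rmsd_all)
  expect_true(all(!out_idx %in% sp$kept))
  clean <- kabsch_superpose(base[-out_idx, ], noisy[-out_idx, ])
  expect_lt(abs(sp$rmsd_refined - clean$rmsd_all), 0.1 * clean$rmsd_all)

  # identical structures: nothing rejected, RMSD 0
  sp0 <- refine_superpose(a, a)
  expect_equal(sp0$rmsd_all, 0, tolerance = 1e-12)
  expect_equal(sp0$n_kept, sp0$n_paired)
})

test_that("refined RMSD never exceeds the all-pair RMSD across cycles", {
  set.seed(35)
  for (rep in 1:5) {
    base <- matrix(rnorm(150, sd = 6), 50, 3)
    noisy <- base + matrix(rnorm(150, sd = 0.8), 50, 3)
    prev <- Inf
    for (cy in 0:4) {
      sp <- refine_superpose(model_from_coords(base), model_from_coords(noisy),
                             cycles = cy)
      expect_lte(sp$rmsd_refined, sp$rmsd_all + 1e-12)
      expect_lte(sp$rmsd_refined, prev + 1e-12)
      prev <- sp$rmsd_refined
    }
  }
})

test_that("transform_structure applies the fitted rigid motion", {
  a <- ideal_helix_coords("LIVFLIVFLIVF")
  tf <- random_rigid_transform()
  b <- a
  xyz <- apply_rigid(as.matrix(a$residues[, c("x", "y", "z")]), tf)
  b$residues$x <- xyz[, 1]; b$residues$y <- xyz[, 2]; b$residues$z <- xyz[, 3]
  b$atoms <- NULL
  sp <- refine_superpose(a, b)
  moved <- transform_structure(b, sp)
  expect_equal(as.matrix(moved$residues[, c("x", "y", "z")]),
               as.matrix(a$residues[, c("x", "y", "z")]),
               tolerance = 1e-6, ignore_attr = TRUE)
})
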