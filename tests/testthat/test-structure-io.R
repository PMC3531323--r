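test_that("PDB parsing handles plain, multi-model and degenerate files", {
  dir <- withr::local_tempdir()

  p1 <- write_tiny_pdb(file.path(dir, "tiny.pdb"))
  s <- read_pdb(p1)
  expect_s3_class(s, "esimap_structure")
  expect_equal(nrow(s), 3L)
  expect_equal(s$resname, c("ALA", "GLY", "SER"))
  expect_equal(s$x, c(3.8, 7.6, 11.4), tolerance = 1e-6)

  # five MODEL blocks -> five structures of equal atom count
  toy <- make_toy_structure(4, charges = c("2" = -1))
  models <- lapply(0:4, function(k) { m <- toy; m$z <- m$z + k; m })
  p2 <- file.path(dir, "ens.pdb")
  write_multimodel_pdb(models, p2)
  ms <- read_pdb(p2, model_index = "all")
  expect_length(ms, 5L)
  expect_true(all(vapply(ms, nrow, integer(1)) == nrow(toy)))
  expect_equal(ms[[3]]$z, toy$z + 2, tolerance = 1e-3)

  # a file with no coordinate records
  p3 <- file.path(dir, "empty.pdb")
  writeLines(c("HEADER    SYNTHETIC", "END"), p3)
  expect_error(read_pdb(p3), class = "esimap_zero_atoms")
})

test_that("alternate locations resolve to highest occupancy then first seen", {
  dir <- withr::local_tempdir()
  lines <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA AGLY A   2       5.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CA BGLY A   2       6.000   0.000   0.000  0.50  0.00           C",
    "END")
  p <- file.path(dir, "alt.pdb")
  writeLines(lines, p)
  s <- read_pdb(p)
  expect_equal(nrow(s), 2L)
  expect_equal(s$x[1], 1.0)  # B has higher occupancy
  expect_equal(s$x[2], 5.0)  # tie -> first seen
})

test_that("write_pdb/read_pdb round-trips coordinates at format precision", {
  dir <- withr::local_tempdir()
  s <- make_toy_structure(5, charges = c("1" = -1, "4" = 1), geometry = "sphere",
                          sphere_radius = 12)
  p <- file.path(dir, "round.pdb")
  write_pdb(s, p)
  r <- read_pdb(p)
  expect_equal(nrow(r), nrow(s))
  expect_lt(max(abs(r$x - s$x)), 1e-3)
  expect_lt(max(abs(r$y - s$y)), 1e-3)
  expect_lt(max(abs(r$z - s$z)), 1e-3)
  expect_equal(r$resname, s$resname)
  expect_equal(r$resno, s$resno)
})

test_that("formal charges follow the model-pKa majority rule", {
  t74 <- titration_model(pH = 7.4)
  expect_equal(residue_formal_charge(c("ASP", "GLU", "LYS", "ARG"), t74),
               c(-1L, -1L, 1L, 1L))
  # His (pKa 6.30), Cys, Tyr are neutral at pH 7.4
  expect_equal(residue_formal_charge(c("HIS", "CYS", "TYR", "ALA"), t74),
               c(0L, 0L, 0L, 0L))
  # protonation flips when the pH crosses the pKa
  expect_equal(residue_formal_charge("HIS", titration_model(pH = 5)), 1L)
  expect_equal(residue_formal_charge("TYR", titration_model(pH = 12)), -1L)
  expect_equal(residue_formal_charge("LYS", titration_model(pH = 12)), 0L)
})

test_that("assign_parameters: bookkeeping, termini, idempotence, unknowns", {
  # D-K-H with neutral termini: (-1) + (+1) + 0 = 0
  s <- toy_dgk(c("ASP", "LYS", "HIS"), charge_termini = FALSE)
  expect_equal(net_charge(s)$rounded, 0L)
  expect_equal(net_charge(s)$raw, 0, tolerance = 1e-6)

  # net charge equals the sum of formal charges (+ cancelling termini)
  for (termini in c(TRUE, FALSE)) {
    t <- titration_model(charge_termini = termini)
    s2 <- toy_dgk(c("ASP", "GLU", "GLY", "LYS"), charge_termini = termini)
    res <- residue_table(s2)
    expect_equal(net_charge(s2)$raw,
                 sum(residue_formal_charge(res$resname, t)),
                 tolerance = 1e-6)
    # per-residue sums match the titration model (termini excepted)
    inner <- res[res$resno %in% 2:3, ]
    expect_equal(inner$charge,
                 as.numeric(residue_formal_charge(inner$resname, t)),
                 tolerance = 1e-6)
  }

  # idempotent
  once <- toy_dgk()
  twice <- suppressWarnings(assign_parameters(once, titration_model()))
  expect_identical(once$charge, twice$charge)
  expect_identical(once$radius, twice$radius)

  # unknown residues are flagged and left neutral
  s3 <- make_toy_structure(2)
  s3$resname <- rep(c("XYZ", "ALA"), each = 5)
  expect_warning(out <- assign_parameters(s3, titration_model(charge_termini = FALSE)),
                 "unknown residue")
  expect_equal(sum(out$charge), 0)

  # radii come from the element table
  expect_true(all(toy_dgk()$radius > 1))
})

test_that("charges land on the canonical charged-group atoms when present", {
  atoms <- data.frame(
    name = c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"),
    resname = "ASP", chain = "A", resno = 1,
    x = seq(0, 7) * 1.6, y = 0, z = 0)
  s <- assign_parameters(new_structure(atoms),
                         titration_model(charge_termini = FALSE))
  expect_equal(s$charge[s$name %in% c("OD1", "OD2")], c(-0.5, -0.5))
  expect_equal(sum(s$charge), -1, tolerance = 1e-12)
  expect_equal(s$charge[s$name == "CB"], 0)
})

test_that("PQR round trip preserves charges and radii", {
  dir <- withr::local_tempdir()
  s <- toy_dgk()
  p <- file.path(dir, "toy.pqr")
  write_pqr(s, p)
  r <- read_pqr(p)
  expect_equal(r$charge, s$charge, tolerance = 1e-4)
  expect_equal(r$radius, s$radius, tolerance = 1e-4)
  expect_equal(r$resno, s$resno)
  expect_equal(net_charge(r)$rounded, net_charge(s)$rounded)

  # unparameterized structures cannot be written
  raw <- make_toy_structure(3)
  expect_error(write_pqr(raw, file.path(dir, "raw.pqr")),
               class = "esimap_unparameterized")
})
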