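test_that("charge spreading is trilinear and conserves total charge", {
  g <- grid_spec(33, 32, c(0, 0, 0))

  # a charge exactly on a node occupies that node alone
  s <- new_structure(data.frame(name = "CB", resname = "LYS", chain = "A",
                                resno = 1, x = 2, y = -3, z = 0))
  s <- assign_parameters(s, titration_model(charge_termini = FALSE))
  rho <- charge_density(s, g)
  cell <- prod(g$h)
  expect_equal(sum(rho$values) * cell, 1, tolerance = 1e-12)
  node <- c(2 - (-16), -3 - (-16), 0 - (-16)) + 1  # h = 1
  expect_equal(rho$values[node[1], node[2], node[3]] * cell, 1,
               tolerance = 1e-12)
  expect_equal(sum(rho$values != 0), 1L)

  # a charge at a cell centre spreads 1/8 to each corner
  s2 <- s
  s2$x <- 2.5; s2$y <- -3.5; s2$z <- 0.5
  rho2 <- charge_density(s2, g)
  w <- rho2$values[rho2$values != 0] * cell
  expect_length(w, 8L)
  expect_equal(w, rep(0.125, 8), tolerance = 1e-12)

  # conservation for a many-atom structure
  s3 <- toy_dgk(c("ASP", "GLU", "GLY", "LYS", "ARG"))
  g3 <- build_gridspec(s3, points = 33)
  rho3 <- charge_density(s3, g3)
  expect_equal(sum(rho3$values) * prod(g3$h), net_charge(s3)$raw,
               tolerance = 1e-10)

  # atoms outside the grid are reported by name
  s4 <- s
  s4$x <- 100
  expect_error(charge_density(s4, g), "outside grid")
})

test_that("dielectric boundary follows the probe-excluded molecular volume", {
  two_atoms <- function(sep) {
    s <- new_structure(data.frame(
      name = c("CA", "CA"), resname = "ALA", chain = "A", resno = 1:2,
      x = c(-sep / 2, sep / 2), y = 0, z = 0))
    s <- assign_parameters(s, titration_model(charge_termini = FALSE))
    s$radius <- 2
    s
  }
  g <- grid_spec(33, 16, c(0, 0, 0))
  mid <- (33 + 1) %/% 2

  # brute-force oracle: the midpoint is protein unless some probe sphere
  # (radius 1.4) can cover it without touching either vdW sphere
  probe_reaches <- function(sep, p = 1.4, r = 2) {
    cand <- as.matrix(expand.grid(x = seq(-6, 6, by = 0.05),
                                  y = seq(-6, 6, by = 0.05), z = 0))
    a1 <- c(-sep / 2, 0, 0); a2 <- c(sep / 2, 0, 0)
    ok <- sqrt(rowSums(sweep(cand, 2, a1)^2)) >= r + p &
          sqrt(rowSums(sweep(cand, 2, a2)^2)) >= r + p
    any(ok & sqrt(rowSums(cand^2)) < p)
  }

  s_close <- two_atoms(4.5)
  prob <- pb_problem(s_close, g)
  eps <- dielectric_map(s_close, g, prob)
  expect_false(probe_reaches(4.5))                    # oracle: excluded
  expect_equal(eps$values[mid, mid, mid], prob$eps_protein)

  s_far <- two_atoms(9)
  eps2 <- dielectric_map(s_far, g, pb_problem(s_far, g))
  expect_true(probe_reaches(9))                       # oracle: probe passes
  expect_equal(eps2$values[mid, mid, mid], prob$eps_solvent)

  # inside a vdW sphere and in bulk solvent
  node_at <- function(x) c(round((x + 16) / 1 + 1), mid, mid)
  i1 <- node_at(-2.25 + 1)                            # 1 A from atom centre
  expect_equal(eps$values[i1[1], i1[2], i1[3]], prob$eps_protein)
  expect_equal(eps$values[1, 1, 1], prob$eps_solvent) # far corner
})

test_that("screening map is zero at 0 mM and reproduces the Debye length", {
  s <- toy_dgk()
  g <- build_gridspec(s, points = 33)

  p0 <- pb_problem(s, g, ionic_strength = 0)
  expect_true(all(kappa_map(s, g, p0)$values == 0))

  p150 <- pb_problem(s, g, ionic_strength = 150)
  k <- kappa_map(s, g, p150)
  bulk <- max(k$values)
  lambda_debye <- 1 / sqrt(bulk / p150$eps_solvent)
  expect_equal(lambda_debye, 7.86, tolerance = 0.01)  # ~7.9 A at 150 mM

  # ion-inaccessible nodes (inside vdW + Stern layer) carry zero screening
  fr <- round((coords_matrix(s)[1, ] - g$origin) / g$h) + 1
  expect_equal(k$values[fr[1], fr[2], fr[3]], 0)
})

test_that("LPBE solver: zero source, linearity and symmetry", {
  # no charges -> identically zero potential
  s0 <- toy_dgk(c("ALA", "GLY", "ALA"), charge_termini = FALSE)
  g0 <- build_gridspec(s0, points = 33)
  phi0 <- solve_lpbe(pb_problem(s0, g0))
  expect_equal(max(abs(phi0$values)), 0)

  # superposition: same dielectric, charges split across two sources
  s <- new_structure(data.frame(
    name = c("NZ", "NZ"), resname = "LYS", chain = "A", resno = 1:2,
    x = c(-4, 4), y = 0, z = 0))
  s <- assign_parameters(s, titration_model(charge_termini = FALSE))
  g <- grid_spec(33, 48, c(0, 0, 0))
  p <- pb_problem(s, g, tol = 1e-10)
  eps <- dielectric_map(s, g, p)
  kap <- kappa_map(s, g, p)
  only <- function(keep) {
    sk <- s
    sk$charge[-keep] <- 0
    sk
  }
  phi12 <- solve_lpbe(pb_problem(only(1:2), g, tol = 1e-10), eps, kap)
  phi1 <- solve_lpbe(pb_problem(only(1), g, tol = 1e-10), eps, kap)
  phi2 <- solve_lpbe(pb_problem(only(2), g, tol = 1e-10), eps, kap)
  scale <- max(abs(phi12$values))
  expect_lt(max(abs(phi12$values - phi1$values - phi2$values)) / scale, 1e-8)

  # mirror-symmetric charges give a mirror-symmetric potential,
  # and a net-positive structure is positive near the boundary
  expect_equal(phi12$values, phi12$values[33:1, , ], tolerance = 1e-6)
  edge <- phi12$values[2, , ]
  expect_true(all(edge > 0))
})

test_that("point-charge potential converges to the Coulomb law on refinement", {
  lB <- bjerrum_kTe()
  errs <- vapply(c(33L, 65L, 129L), function(n) {
    p <- point_charge_problem(points = n, length_A = 64)
    phi <- solve_lpbe(p)
    # one fixed shell (4h of the coarsest grid) so the errors are comparable
    shell_rel_err(phi, function(r) lB / (78.57 * r),
                  r_min = 8, r_max = 16, stride = (n - 1L) %/% 16L)
  }, numeric(1))
  # error shrinks monotonically from 33^3 to 65^3 to 129^3
  expect_lt(errs[2], errs[1])
  expect_lt(errs[3], errs[2])
  expect_lt(errs[3], 0.05)
})
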