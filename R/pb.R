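# physical constants: e^2/(4 pi eps0) in eV*A, Boltzmann constant in eV/K.
# bjerrum_vac(T) = e^2/(4 pi eps0 kT) in A; dividing by a relative dielectric
# gives the usual Bjerrum length (~7.1 A in water at 298 K).
E2_4PIEPS0 <- 14.399645
KB_EV <- 8.617333262e-5
bjerrum_vac <- function(temperature) E2_4PIEPS0 / (KB_EV * temperature)

# 1 mM of 1:1 electrolyte in ions per A^3 (per species)
MM_TO_PER_A3 <- 6.02214076e-7

#' Linearized Poisson-Boltzmann problem definition
#'
#' Bundles a parameterized structure, a grid and the continuum-electrostatics
#' settings: protein dielectric 20, solvent dielectric 78.57, 0 mM monovalent
#' ionic strength, 298.15 K and a 1.4 Angstrom solvent probe defining the
#' dielectric boundary.
#'
#' @param structure a structure with assigned charges and radii.
#' @param spec a `grid_spec` (typically from [build_gridspec()] on the family
#'   parent).
#' @param eps_protein protein (low) dielectric constant.
#' @param eps_solvent solvent dielectric constant.
#' @param ionic_strength monovalent ionic strength, mM.
#' @param temperature temperature, K.
#' @param probe_radius solvent probe radius, Angstrom.
#' @param stern_width ion-exclusion layer added to atomic radii for the
#'   screening map, Angstrom.
#' @param tol relative-residual convergence tolerance of the solver.
#' @param maxit maximum conjugate-gradient iterations.
#' @return list of class `pb_problem`.
#' @export
pb_problem <- function(structure, spec,
                       eps_protein = 20, eps_solvent = 78.57,
                       ionic_strength = 0, temperature = 298.15,
                       probe_radius = 1.4, stern_width = 2.0,
                       tol = 1e-6, maxit = 10000L) {
  stopifnot(inherits(spec, "grid_spec"))
  if (eps_protein <= 0 || eps_solvent <= 0) abort("dielectric constants must be positive")
  if (ionic_strength < 0) abort("ionic strength must be non-negative")
  structure(list(structure = structure, spec = spec,
                 eps_protein = eps_protein, eps_solvent = eps_solvent,
                 ionic_strength = ionic_strength, temperature = temperature,
                 probe_radius = probe_radius, stern_width = stern_width,
                 tol = tol, maxit = as.integer(maxit)),
            class = "pb_problem")
}

#' Spread atomic charges onto the grid
#'
#' Each atomic charge is distributed over its 8 enclosing nodes with trilinear
#' weights; the grid total equals the molecular net charge exactly (charge
#' conservation).
#'
#' @param s a parameterized structure.
#' @param g a `grid_spec`.
#' @return `scalar_field` of charge density, e per Angstrom^3.
#' @export
charge_density <- function(s, g) {
  if (!isTRUE(attr(s, "parameters_assigned"))) {
    abort("parameters not assigned", class = "esimap_unparameterized")
  }
  n <- g$points
  fr <- sweep(sweep(coords_matrix(s), 2, g$origin), 2, g$h, "/")
  bad <- which(apply(fr, 1, function(v) any(v < 0) || any(v > n - 1L)))
  if (length(bad) > 0L) {
    abort(sprintf("atom outside grid: serial %d (%s %s%d)",
                  s$serial[bad[1]], s$name[bad[1]], s$resname[bad[1]],
                  s$resno[bad[1]]))
  }
  i0 <- pmin(matrix(floor(fr), ncol = 3L),
             matrix(rep(n - 2L, each = nrow(fr)), ncol = 3L))
  t3 <- fr - i0
  rho <- numeric(prod(n))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (if (cx) t3[, 1] else 1 - t3[, 1]) *
         (if (cy) t3[, 2] else 1 - t3[, 2]) *
         (if (cz) t3[, 3] else 1 - t3[, 3])
    li <- (i0[, 1] + cx) + n[1] * ((i0[, 2] + cy) + n[2] * (i0[, 3] + cz)) + 1
    acc <- rowsum(w * s$charge, li)
    rho[as.integer(rownames(acc))] <- rho[as.integer(rownames(acc))] + acc[, 1]
  }
  scalar_field(array(rho / prod(g$h), dim = n), g, unit = "e/A^3")
}

# integer node offsets within a ball of the given radius (Angstrom)
ball_offsets <- function(radius, h) {
  r <- floor(radius / h)
  off <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  keep <- (off$dx * h[1])^2 + (off$dy * h[2])^2 + (off$dz * h[3])^2 <= radius^2
  off[keep, , drop = FALSE]
}

# shift a logical array by integer offsets and OR the results (dilation);
# regions shifted in from outside count as FALSE
dilate_mask <- function(mask, offsets) {
  n <- dim(mask)
  out <- array(FALSE, dim = n)
  for (r in seq_len(nrow(offsets))) {
    o <- as.integer(offsets[r, ])
    sx <- max(1, 1 + o[1]):min(n[1], n[1] + o[1])
    sy <- max(1, 1 + o[2]):min(n[2], n[2] + o[2])
    sz <- max(1, 1 + o[3]):min(n[3], n[3] + o[3])
    out[sx, sy, sz] <- out[sx, sy, sz] |
      mask[sx - o[1], sy - o[2], sz - o[3], drop = FALSE]
  }
  out
}

#' Dielectric map with a probe-defined molecular surface
#'
#' The low-dielectric region is the solvent-excluded molecular volume:
#' the union of van der Waals spheres closed morphologically with a
#' probe-radius ball (dilate the vdW volume by the probe — equivalently take
#' the union of spheres of radius r_i + probe — then erode by the probe).
#' Nodes inside get `eps_protein`, all others `eps_solvent`.
#'
#' @param s parameterized structure (radii needed).
#' @param g a `grid_spec`.
#' @param p a `pb_problem` (for the dielectric constants and probe radius).
#' @return dimensionless `scalar_field` of node dielectric values.
#' @export
dielectric_map <- function(s, g, p) {
  in_vdw <- node_min_gap(s, g, offset = 0, cap = 0.5) <= 0
  in_sas <- node_min_gap(s, g, offset = p$probe_radius, cap = 0.5) <= 0
  off <- ball_offsets(p$probe_radius, g$h)
  protein <- in_vdw | (in_sas & !dilate_mask(!in_sas, off))
  eps <- array(p$eps_solvent, dim = g$points)
  eps[protein] <- p$eps_protein
  scalar_field(eps, g, unit = "dimensionless")
}

#' Modified screening map
#'
#' The modified Debye-Huckel screening factor kappa-bar^2 (A^-2), nonzero
#' only in the ion-accessible region (outside the vdW volume inflated by the
#' Stern ion-exclusion layer). Identically zero at 0 mM ionic strength. In
#' bulk solvent kappa-bar^2 / eps_solvent = 1/lambda_D^2 with lambda_D the
#' Debye length.
#'
#' @inheritParams dielectric_map
#' @return `scalar_field` in A^-2.
#' @export
kappa_map <- function(s, g, p) {
  n <- g$points
  if (p$ionic_strength <= 0) {
    return(scalar_field(array(0, dim = n), g, unit = "A^-2"))
  }
  kbar2 <- 8 * pi * bjerrum_vac(p$temperature) * p$ionic_strength * MM_TO_PER_A3
  accessible <- node_min_gap(s, g, offset = p$stern_width, cap = 0.5) > 0
  k <- array(0, dim = n)
  k[accessible] <- kbar2
  scalar_field(k, g, unit = "A^-2")
}

# Debye-Huckel boundary values: sum over atoms of the screened single-sphere
# potential q * lB / (eps_s r) * exp(-kappa (r - R)) / (1 + kappa R), kT/e
dh_boundary <- function(s, g, p) {
  n <- g$points
  lB <- bjerrum_vac(p$temperature)
  kbar2 <- 8 * pi * lB * p$ionic_strength * MM_TO_PER_A3
  kap <- sqrt(kbar2 / p$eps_solvent)
  ax <- grid_axes(g)
  bmask <- array(FALSE, dim = n)
  bmask[c(1, n[1]), , ] <- TRUE
  bmask[, c(1, n[2]), ] <- TRUE
  bmask[, , c(1, n[3])] <- TRUE
  bidx <- which(bmask)
  kk <- (bidx - 1L) %/% (n[1] * n[2])
  jj <- ((bidx - 1L) %% (n[1] * n[2])) %/% n[1]
  ii <- (bidx - 1L) %% n[1]
  bx <- ax[[1]][ii + 1L]; by <- ax[[2]][jj + 1L]; bz <- ax[[3]][kk + 1L]
  phi <- numeric(length(bidx))
  nz <- which(s$charge != 0)
  for (k in nz) {
    r <- sqrt((bx - s$x[k])^2 + (by - s$y[k])^2 + (bz - s$z[k])^2)
    r <- pmax(r, 1e-6)
    scr <- if (kap > 0) exp(-kap * (r - s$radius[k])) / (1 + kap * s$radius[k]) else 1
    phi <- phi + s$charge[k] * lB / (p$eps_solvent * r) * scr
  }
  list(idx = bidx, phi = phi)
}

#' Solve the linearized Poisson-Boltzmann equation
#'
#' Finite-difference 7-point discretization of
#' div(eps grad phi) - kappa-bar^2 phi = -4 pi (e^2/(4 pi eps0 kT)) rho on the
#' problem grid, with harmonic-mean face dielectrics and Dirichlet boundary
#' values from the sum of single-sphere Debye-Huckel potentials of all atomic
#' charges. Solved by Jacobi-preconditioned conjugate gradients to the stated
#' relative residual. The potential is returned in kT/e.
#'
#' @param p a `pb_problem`.
#' @param eps,kappa2,rho optional precomputed maps (else computed here).
#' @param verbose print iteration summary.
#' @return `scalar_field` of potential (kT/e) with attributes `iterations`
#'   and `residual`.
#' @export
solve_lpbe <- function(p, eps = NULL, kappa2 = NULL, rho = NULL, verbose = FALSE) {
  g <- p$spec
  if (is.null(eps)) eps <- dielectric_map(p$structure, g, p)
  if (is.null(kappa2)) kappa2 <- kappa_map(p$structure, g, p)
  if (is.null(rho)) rho <- charge_density(p$structure, g)
  stopifnot(same_grid(eps$spec, g), same_grid(kappa2$spec, g),
            same_grid(rho$spec, g))

  lB <- bjerrum_vac(p$temperature)
  rhs <- 4 * pi * lB * rho$values

  phi0 <- array(0, dim = g$points)
  bc <- dh_boundary(p$structure, g, p)
  phi0[bc$idx] <- bc$phi

  sol <- cg_lpbe(as.numeric(eps$values), as.numeric(kappa2$values),
                 as.numeric(rhs), as.numeric(phi0),
                 as.integer(g$points), as.numeric(g$h),
                 p$tol, p$maxit)
  if (!sol$converged) {
    abort(sprintf("LPBE solver did not converge in %d iterations (relative residual %.3e)",
                  sol$iterations, sol$residual))
  }
  if (verbose) {
    inform(sprintf("LPBE converged in %d iterations (relative residual %.3e)",
                   sol$iterations, sol$residual))
  }
  out <- scalar_field(array(sol$phi, dim = g$points), g, unit = "kT/e")
  attr(out, "iterations") <- sol$iterations
  attr(out, "residual") <- sol$residual
  out
}

#' Solve potentials for a whole perturbation family
#'
#' Builds (or accepts) one grid centred on the parent and solves the LPBE for
#' the parent and every member on that same grid, so the resulting fields are
#' node-aligned for similarity analysis.
#'
#' @param fam a `perturbation_family`.
#' @param spec optional shared `grid_spec`; default [build_gridspec()] on the
#'   parent.
#' @param ... settings passed to [pb_problem()].
#' @param verbose report progress.
#' @return list with `parent` (scalar_field), `members` (named list of
#'   scalar_field) and `spec`.
#' @export
solve_family <- function(fam, spec = NULL, ..., verbose = FALSE) {
  stopifnot(inherits(fam, "perturbation_family"))
  if (is.null(spec)) spec <- build_gridspec(fam$parent)
  solve_one <- function(s, who) {
    if (verbose) inform(paste0("solving LPBE: ", who))
    solve_lpbe(pb_problem(s, spec, ...))
  }
  parent_phi <- solve_one(fam$parent, "parent")
  member_phi <- lapply(seq_along(fam$members), function(i) {
    solve_one(fam$members[[i]], fam$member_labels[i])
  })
  names(member_phi) <- fam$member_labels
  list(parent = parent_phi, members = member_phi, spec = spec)
}
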