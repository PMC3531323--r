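# shared fixture builders for the test suite; everything is generated in code

with_seed_local <- function(seed, code) withr::with_seed(seed, code)

# minimal hand-written PDB content (fixed-column) with n CA atoms
tiny_pdb_lines <- function(resnames = c("ALA", "GLY", "SER"),
                           x = seq_along(resnames) * 3.8) {
  sprintf("ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          seq_along(resnames), resnames, seq_along(resnames), x, 0, 0)
}

write_tiny_pdb <- function(path, resnames = c("ALA", "GLY", "SER"), ...) {
  writeLines(c(tiny_pdb_lines(resnames, ...), "END"), path)
  path
}

# parameterized tripeptide-like toy chain: Asp-Gly-Lys by default
toy_dgk <- function(resnames = c("ASP", "GLY", "LYS"), charge_termini = TRUE) {
  q <- c(ASP = -1L, GLU = -1L, LYS = 1L, ARG = 1L)[resnames]
  q[is.na(q)] <- 0L
  s <- make_toy_structure(length(resnames),
                          charges = stats::setNames(q[q != 0], which(q != 0)))
  s$resname <- rep(resnames, each = 5L)
  suppressWarnings(assign_parameters(
    s, titration_model(charge_termini = charge_termini)))
}

# a point charge with no dielectric cavity: zero radii, homogeneous solvent
point_charge_problem <- function(points = 33L, length_A = 48, q_sign = 1,
                                 eps = 78.57, ionic = 0, ...) {
  s <- new_structure(
    data.frame(name = "CB", resname = if (q_sign > 0) "LYS" else "ASP",
               chain = "A", resno = 1, x = 0, y = 0, z = 0),
    label = "point")
  s <- assign_parameters(s, titration_model(charge_termini = FALSE))
  s$radius <- 0
  g <- grid_spec(points, length_A, c(0, 0, 0))
  pb_problem(s, g, eps_protein = eps, eps_solvent = eps,
             ionic_strength = ionic, ...)
}

bjerrum_kTe <- function(T = 298.15) 14.399645 / (8.617333262e-5 * T)

# sample a solved potential on a sparse lattice shell and compare to an
# analytic radial oracle phi(r)
shell_rel_err <- function(phi, oracle_fun, r_min, r_max, stride = 4L) {
  g <- phi$spec
  ax <- seq(g$origin[1], by = g$h[1], length.out = g$points[1])
  idx <- seq(1L, g$points[1], by = stride)
  pts <- as.matrix(expand.grid(x = ax[idx], y = ax[idx], z = ax[idx]))
  r <- sqrt(rowSums(pts^2))
  keep <- r >= r_min & r <= r_max
  v <- interpolate_field(phi, pts[keep, , drop = FALSE])
  o <- oracle_fun(r[keep])
  max(abs(v - o) / abs(o))
}

# two-clade synthetic homologue family: each group conserves its own charge
# layout at the face columns (group 2's drawn independently, i.e. scrambled
# relative to group 1), plus per-member noise columns
two_clade_family <- function(seed, n1 = 6, n2 = 6, n_cons = 16, n_noise = 4) {
  cols_cons <- seq_len(n_cons)
  cols_noise <- n_cons + seq_len(n_noise)
  nres <- n_cons + n_noise + 2
  f1 <- make_synthetic_family(n1, conserved_columns = cols_cons,
                              scrambled_columns = cols_noise, seed = seed,
                              n_residues = nres)
  f2 <- make_synthetic_family(n2, conserved_columns = cols_cons,
                              scrambled_columns = cols_noise,
                              seed = seed + 1000003L, n_residues = nres)
  rows <- c(f1$alignment$rows, f2$alignment$rows)
  names(rows) <- c(paste0("conserved_", seq_len(n1)),
                   paste0("scrambled_", seq_len(n2)))
  list(alignment = new_alignment(rows), face_columns = seq_len(n_cons + n_noise),
       group1 = seq_len(n1), group2 = n1 + seq_len(n2))
}
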