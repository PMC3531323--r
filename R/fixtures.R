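# run code with a private RNG stream so fixture generators are deterministic
# without disturbing the caller's random state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# five pseudo-atoms (N, CA, C, O, CB) around a CA position given two unit
# tangent vectors; geometry is schematic but collision-free
residue_atoms <- function(ca, t1, t2, resno, resname, chain = "A") {
  pos <- rbind(
    N = ca + 1.4 * t1,
    CA = ca,
    C = ca - 1.2 * t1 + 0.8 * t2,
    O = ca - 1.2 * t1 + 1.9 * t2,
    CB = ca - 1.1 * t2 + 0.6 * t1
  )
  tibble(name = rownames(pos), resname = resname, chain = chain,
         resno = resno, x = unname(pos[, 1]), y = unname(pos[, 2]),
         z = unname(pos[, 3]), element = c("N", "C", "C", "O", "C"))
}

# tangent basis orthogonal to a unit vector
tangent_basis <- function(u) {
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- ref - sum(ref * u) * u
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(u[2] * t1[3] - u[3] * t1[2],
          u[3] * t1[1] - u[1] * t1[3],
          u[1] * t1[2] - u[2] * t1[1])
  list(t1 = t1, t2 = t2)
}

fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

charge_resname <- function(q) ifelse(q > 0, "LYS", ifelse(q < 0, "ASP", "ALA"))

#' Build a synthetic poly-alanine-like test structure
#'
#' Pseudo-residues of five atoms (N, CA, C, O, CB) either along a straight
#' chain with 3.8 Angstrom CA spacing on the x-axis, or scattered over a
#' sphere surface. Requested formal charges are realised by naming residues
#' LYS (+1) or ASP (-1); with the reduced atom set, [assign_parameters()]
#' places the monopole on CB. Deterministic for a fixed seed; atoms closer
#' than 1 Angstrom are rejected.
#'
#' @param n_residues number of residues (> 0).
#' @param charges named or indexed integer vector of formal charges, e.g.
#'   `c("1" = -1, "3" = 1)` (residue index to charge in {-1, 0, +1}).
#' @param geometry `"chain"` or `"sphere"`.
#' @param sphere_radius sphere radius (Angstrom) for `geometry = "sphere"`.
#' @param seed RNG seed (used only for the sphere scatter jitter).
#' @param label structure label.
#' @return An `esimap_structure` (parameters not yet assigned).
#' @export
make_toy_structure <- function(n_residues, charges = NULL, geometry = c("chain", "sphere"),
                               sphere_radius = 16, seed = 1, label = "toy") {
  geometry <- match.arg(geometry)
  n_residues <- as.integer(n_residues)
  if (n_residues < 1L) abort("need at least one residue")
  q <- integer(n_residues)
  if (!is.null(charges)) {
    ii <- as.integer(names(charges) %||% seq_along(charges))
    if (any(ii < 1L | ii > n_residues)) abort("charge index out of range")
    q[ii] <- as.integer(charges)
  }
  rn <- charge_resname(q)
  rows <- with_seed(seed, {
    if (geometry == "chain") {
      lapply(seq_len(n_residues), function(i) {
        residue_atoms(c((i - 1) * 3.8, 0, 0), c(0, 1, 0), c(0, 0, 1),
                      resno = i, resname = rn[i])
      })
    } else {
      u <- fibonacci_directions(n_residues)
      lapply(seq_len(n_residues), function(i) {
        tb <- tangent_basis(u[i, ])
        residue_atoms(sphere_radius * u[i, ], tb$t1, tb$t2,
                      resno = i, resname = rn[i])
      })
    }
  })
  s <- new_structure(dplyr::bind_rows(rows), label = label)
  check_min_separation(s)
  s
}

check_min_separation <- function(s, min_dist = 1) {
  xyz <- coords_matrix(s)
  if (nrow(xyz) > 1L) {
    d <- stats::dist(xyz)
    if (min(d) < min_dist) {
      abort(sprintf("overlapping atoms: minimum separation %.2f A < %.1f A",
                    min(d), min_dist))
    }
  }
  invisible(s)
}

#' Build the electrostatic hot-spot test fixture
#'
#' A sphere-surface pseudo-structure with a cluster of `cluster_size`
#' like-charged (acidic) residues confined to a patch of at most 8 Angstrom
#' diameter, `n_dispersed` isolated acidic residues pairwise at least
#' 15 Angstrom apart (and 15 Angstrom from the cluster), and a neutral
#' scaffold covering the rest of the sphere. Removing one of the co-located
#' cluster charges perturbs the local potential fractionally less than
#' removing an isolated charge, which is the mechanism behind
#' perturbation-resistant "hot-spots".
#'
#' @param cluster_size number of clustered charges (>= 3).
#' @param n_dispersed number of isolated charges (<= 6 on the default
#'   sphere).
#' @param seed RNG seed.
#' @param sphere_radius sphere radius (Angstrom, default 16).
#' @return An `esimap_structure`; attributes `cluster_residues` and
#'   `dispersed_residues` give the residue indices of the two groups.
#' @export
make_hotspot_fixture <- function(cluster_size = 5, n_dispersed = 5, seed = 1,
                                 sphere_radius = 16) {
  if (cluster_size < 3L) abort("cluster_size must be >= 3")
  r <- sphere_radius
  # cluster: pole plus a ring at ~3.5 A geodesic radius
  ring_theta <- 3.5 / r
  k <- cluster_size - 1L
  cluster_u <- rbind(
    c(0, 0, 1),
    t(vapply(seq_len(k), function(i) {
      a <- 2 * pi * (i - 1) / k
      c(sin(ring_theta) * cos(a), sin(ring_theta) * sin(a), cos(ring_theta))
    }, numeric(3)))
  )
  patch_diam <- max(stats::dist(r * cluster_u))
  if (patch_diam > 8) abort("geometry infeasible: cluster patch exceeds 8 A")
  # dispersed: evenly spaced on the equator (pole-to-equator chord = r*sqrt(2))
  if (n_dispersed > 0) {
    a <- 2 * pi * (seq_len(n_dispersed) - 1) / max(n_dispersed, 1L)
    disp_u <- cbind(cos(a), sin(a), 0)
    pts <- r * rbind(cluster_u, disp_u)
    dd <- as.matrix(stats::dist(pts))
    cross <- dd[seq_len(cluster_size), cluster_size + seq_len(n_dispersed), drop = FALSE]
    among <- stats::dist(r * disp_u)
    if ((n_dispersed > 1 && min(among) < 15) || min(cross) < 15) {
      abort("geometry infeasible: dispersed charges cannot be kept 15 A apart")
    }
  } else {
    disp_u <- matrix(numeric(0), ncol = 3)
  }
  charged_u <- rbind(cluster_u, disp_u)
  scaffold_u <- fibonacci_directions(40L)
  keep <- apply(scaffold_u, 1, function(v) {
    min(sqrt(colSums((t(charged_u) - v)^2))) * r > 5.5
  })
  scaffold_u <- scaffold_u[keep, , drop = FALSE]
  all_u <- rbind(charged_u, scaffold_u)
  n_charged <- nrow(charged_u)
  rn <- c(rep("ASP", n_charged), rep("ALA", nrow(scaffold_u)))
  rows <- lapply(seq_len(nrow(all_u)), function(i) {
    tb <- tangent_basis(all_u[i, ])
    residue_atoms(r * all_u[i, ], tb$t1, tb$t2, resno = i, resname = rn[i])
  })
  s <- new_structure(dplyr::bind_rows(rows),
                     label = sprintf("hotspot_c%d_d%d", cluster_size, n_dispersed))
  check_min_separation(s)
  attr(s, "cluster_residues") <- seq_len(cluster_size)
  attr(s, "dispersed_residues") <- cluster_size + seq_len(n_dispersed)
  s
}

#' Build a synthetic homologue family with controlled charge conservation
#'
#' `n_members` toy-chain structures sharing one geometry. Charges at
#' `conserved_columns` are drawn once (uniformly from {-1, +1}) and shared by
#' every member except those listed in `scrambled_members`, for which they
#' are re-drawn per member; charges at `scrambled_columns` are re-drawn per
#' member for everyone. Residue letters follow the charge (+1: K or R, -1: D
#' or E, chosen uniformly), so a gapless alignment is emitted alongside.
#'
#' @param n_members number of members.
#' @param conserved_columns residue indices with family-wide conserved
#'   charges.
#' @param scrambled_columns residue indices with per-member random charges
#'   (disjoint from `conserved_columns`).
#' @param seed RNG seed (the family is reproducible for a fixed seed).
#' @param n_residues chain length (default: covers all columns plus 2).
#' @param scrambled_members member indices whose conserved columns are also
#'   randomized (a "non-conserved" subgroup).
#' @param dir optional directory: writes member PDBs, `family.fasta` and
#'   `manifest.csv` there.
#' @return list of class `synthetic_family`: `structures` (named list),
#'   `alignment` (`esimap_alignment`), `manifest` (tibble), and `dir` when
#'   written.
#' @export
make_synthetic_family <- function(n_members, conserved_columns = integer(0),
                                  scrambled_columns = integer(0), seed = 1,
                                  n_residues = NULL,
                                  scrambled_members = integer(0), dir = NULL) {
  if (length(intersect(conserved_columns, scrambled_columns)) > 0L) {
    abort("conserved and scrambled column sets must be disjoint")
  }
  if (is.null(n_residues)) {
    n_residues <- max(c(conserved_columns, scrambled_columns, 6L)) + 2L
  }
  pick_letter <- function(q) {
    if (q > 0) sample(c("LYS", "ARG"), 1) else sample(c("ASP", "GLU"), 1)
  }
  out <- with_seed(seed, {
    conserved_q <- sample(c(-1L, 1L), length(conserved_columns), replace = TRUE)
    conserved_rn <- vapply(conserved_q, pick_letter, character(1))
    members <- vector("list", n_members)
    seqs <- character(n_members)
    for (mi in seq_len(n_members)) {
      rn <- rep("ALA", n_residues)
      q <- integer(n_residues)
      if (length(conserved_columns) > 0L) {
        if (mi %in% scrambled_members) {
          qq <- sample(c(-1L, 1L), length(conserved_columns), replace = TRUE)
          rn[conserved_columns] <- vapply(qq, pick_letter, character(1))
          q[conserved_columns] <- qq
        } else {
          rn[conserved_columns] <- conserved_rn
          q[conserved_columns] <- conserved_q
        }
      }
      if (length(scrambled_columns) > 0L) {
        qq <- sample(c(-1L, 1L), length(scrambled_columns), replace = TRUE)
        rn[scrambled_columns] <- vapply(qq, pick_letter, character(1))
        q[scrambled_columns] <- qq
      }
      s <- make_toy_structure(n_residues, geometry = "chain", seed = seed,
                              label = sprintf("member_%02d", mi))
      s$resname <- rep(rn, each = 5L)
      members[[mi]] <- s
      seqs[mi] <- paste(AA_321[rn], collapse = "")
    }
    names(members) <- sprintf("member_%02d", seq_len(n_members))
    names(seqs) <- names(members)
    list(members = members, seqs = seqs)
  })
  aln <- new_alignment(out$seqs)
  manifest <- tibble(
    label = names(out$members),
    sequence = unname(out$seqs),
    conserved_scrambled = seq_len(n_members) %in% scrambled_members
  )
  fam <- structure(list(structures = out$members, alignment = aln,
                        manifest = manifest, dir = dir),
                   class = "synthetic_family")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out$members)) {
      write_pdb(out$members[[nm]], file.path(dir, paste0(nm, ".pdb")))
    }
    writeLines(as.vector(rbind(paste0(">", names(out$seqs)), unname(out$seqs))),
               file.path(dir, "family.fasta"))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  fam
}

#' @export
print.synthetic_family <- function(x, ...) {
  cat(sprintf("<synthetic_family: %d members x %d columns>\n",
              length(x$structures), x$alignment$width))
  invisible(x)
}
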