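#' Local electrostatic similarity of two potential values
#'
#' The signed local Hodgkin index `2ab / (a^2 + b^2)`, bounded in [-1, 1]:
#' 1 for identical values, -1 for sign-flipped values, 0 when one value
#' vanishes. When both magnitudes fall below the near-zero guard `eps0`
#' (default 1e-4 kT/e) the pair is treated as identically negligible and
#' scores 1, which avoids 0/0 noise at far-field nodes.
#'
#' @param a,b potential values (kT/e), vectorized.
#' @param eps0 near-zero guard (kT/e).
#' @return dimensionless similarity values in [-1, 1].
#' @export
local_similarity <- function(a, b, eps0 = 1e-4) {
  stopifnot(all(is.finite(a)), all(is.finite(b)))
  denom <- a^2 + b^2
  out <- ifelse(denom == 0, 1, 2 * a * b / ifelse(denom == 0, 1, denom))
  out[abs(a) < eps0 & abs(b) < eps0] <- 1
  out
}

#' Cumulative electrostatic similarity index field
#'
#' For a parent potential and the N member potentials of a perturbation
#' family, all on one shared grid:
#' `ESI(i,j,k) = (1/N) * sum_n local_similarity(phi_parent, phi_member_n)`.
#' The result is bounded in [-1, 1] at every node and is invariant to member
#' order and to common positive rescaling of parent and members together.
#'
#' @param parent `scalar_field` of the parent potential (kT/e).
#' @param members list of member `scalar_field`s on the same grid.
#' @param mask optional logical array restricting the comparison region;
#'   nodes outside the mask are set to `NA` in the output values but the
#'   field object keeps the full grid.
#' @param eps0 near-zero guard passed to [local_similarity()].
#' @return A `scalar_field` of class `esi_field` with attribute `N`.
#' @export
esi_field <- function(parent, members, mask = NULL, eps0 = 1e-4) {
  if (inherits(members, "scalar_field")) members <- list(members)
  if (length(members) == 0L) abort("at least one member potential required")
  for (m in members) {
    if (!same_grid(parent$spec, m$spec)) {
      abort("mismatched GridSpec: all potentials must share the parent-centred grid")
    }
  }
  acc <- array(0, dim = parent$spec$points)
  for (m in members) {
    acc <- acc + local_similarity(parent$values, m$values, eps0 = eps0)
  }
  vals <- acc / length(members)
  out <- scalar_field(vals, parent$spec, unit = "dimensionless")
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == parent$spec$points))
    out$values[!mask] <- NA_real_
  }
  out$mask <- mask
  attr(out, "N") <- length(members)
  class(out) <- c("esi_field", class(out))
  out
}

#' @export
print.esi_field <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("<esi_field %dx%dx%d, N = %d, range [%.4f, %.4f]>\n",
              x$spec$points[1], x$spec$points[2], x$spec$points[3],
              attr(x, "N"), rng[1], rng[2]))
  invisible(x)
}

#' @export
glance.esi_field <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  tibble(N = attr(x, "N"), n_nodes = length(v), min = min(v), max = max(v),
         mean = mean(v), median = stats::median(v))
}

#' PIPSA-style "skin" comparison mask
#'
#' Logical array of nodes in a shell around the molecular surface: distance
#' beyond the vdW surface in `(sigma, sigma + delta]`.
#'
#' @param s parameterized structure.
#' @param g `grid_spec`.
#' @param sigma inner offset beyond the vdW surface (Angstrom).
#' @param delta shell width (Angstrom).
#' @return logical array of dim `g$points`.
#' @export
skin_mask <- function(s, g, sigma = 3, delta = 4) {
  gap <- node_min_gap(s, g, offset = 0, cap = sigma + delta + 1)
  gap > sigma & gap <= sigma + delta
}

#' Summarize an ESI (or any) field over a region's surface shell
#'
#' Statistics of field values over nodes in a shell around the selected
#' atoms: distance beyond the selection's vdW surface in
#' `(offset, offset + width]`, additionally excluding nodes closer than
#' `offset` to any atom of the whole structure (so buried nodes near other
#' parts of the molecule are not counted). With the whole structure selected
#' this is exactly the structure's own surface shell.
#'
#' @param e a `scalar_field` (typically an `esi_field`).
#' @param s the structure the field belongs to.
#' @param residues optional selection: integer `res_index` values (see
#'   [residue_table()]); default all residues.
#' @param label region label for the output row.
#' @param offset inner shell offset beyond the vdW surface (Angstrom,
#'   default 2).
#' @param width shell width (Angstrom, default 5).
#' @return one-row tibble: `region`, `n_nodes`, `mean`, `median`, `q05`,
#'   `q95`.
#' @export
region_summary <- function(e, s, residues = NULL, label = "region",
                           offset = 2, width = 5) {
  idx <- residue_index(s)
  sel <- if (is.null(residues)) rep(TRUE, nrow(s)) else idx %in% residues
  if (!any(sel)) abort("empty region", class = "esimap_empty_region")
  sub <- new_structure(s[sel, , drop = FALSE], label = "region")
  gap_sel <- node_min_gap(sub, e$spec, offset = 0, cap = offset + width + 1)
  shell <- gap_sel > offset & gap_sel <= offset + width
  if (!is.null(residues)) {
    gap_all <- node_min_gap(s, e$spec, offset = 0, cap = offset + 1)
    shell <- shell & gap_all > offset
  }
  v <- e$values[shell]
  v <- v[!is.na(v)]
  if (length(v) == 0L) abort("region shell contains no grid nodes",
                             class = "esimap_empty_region")
  q <- stats::quantile(v, c(0.05, 0.5, 0.95), names = FALSE)
  tibble(region = label, n_nodes = length(v), mean = mean(v),
         median = q[2], q05 = q[1], q95 = q[3])
}
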