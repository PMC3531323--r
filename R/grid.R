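#' Rectilinear grid specification
#'
#' A regular grid of `points` nodes per axis spanning `lengths` Angstrom,
#' centred at `center`. Node spacing along an axis is
#' `h = length / (points - 1)`. Point counts must be odd and at least 33 so
#' that the centre is a node and the finite-difference stencil is well
#' resolved.
#'
#' @param points integer length-3 vector of node counts (nx, ny, nz).
#' @param lengths numeric length-3 vector of edge lengths (Angstrom).
#' @param center numeric length-3 grid centre (Angstrom).
#' @return A list of class `grid_spec` with elements `points`, `lengths`,
#'   `center`, `h` (spacings) and `origin` (position of node (1,1,1)).
#' @export
grid_spec <- function(points, lengths, center = c(0, 0, 0)) {
  points <- as.integer(rep(points, length.out = 3L))
  lengths <- as.numeric(rep(lengths, length.out = 3L))
  center <- as.numeric(center)
  if (any(points < 33L)) abort("grid needs at least 33 points per axis")
  if (any(points %% 2L == 0L)) abort("grid point counts must be odd")
  if (any(lengths <= 0)) abort("grid lengths must be positive")
  h <- lengths / (points - 1L)
  structure(list(points = points, lengths = lengths, center = center,
                 h = h, origin = center - lengths / 2),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec %dx%dx%d, %.6g x %.6g x %.6g A, center (%.6g, %.6g, %.6g), h = (%.6g, %.6g, %.6g) A>\n",
              x$points[1], x$points[2], x$points[3],
              x$lengths[1], x$lengths[2], x$lengths[3],
              x$center[1], x$center[2], x$center[3],
              x$h[1], x$h[2], x$h[3]))
  invisible(x)
}

grid_axes <- function(g) {
  lapply(1:3, function(a) g$origin[a] + (seq_len(g$points[a]) - 1) * g$h[a])
}

same_grid <- function(a, b, tol = 1e-8) {
  all(a$points == b$points) &&
    all(abs(a$lengths - b$lengths) < tol) &&
    all(abs(a$center - b$center) < tol)
}

#' Build a grid centred on a parent structure
#'
#' The grid centre is the geometric centre of the parent's atoms; the same
#' `grid_spec` is intended to be reused for every member of a perturbation
#' family so their potentials are node-aligned. Warns when the grid leaves
#' less than 10 Angstrom of solvent margin around the structure and errors
#' when the structure does not fit at all.
#'
#' @param parent a structure.
#' @param points node counts per axis (default 129).
#' @param lengths edge lengths per axis (Angstrom); default adds a 30 Angstrom
#'   margin to the structure extent, rounded up to whole Angstrom.
#' @return A `grid_spec`.
#' @export
build_gridspec <- function(parent, points = c(129L, 129L, 129L), lengths = NULL) {
  xyz <- coords_matrix(parent)
  ext <- apply(xyz, 2, function(v) diff(range(v)))
  if (is.null(lengths)) lengths <- ceiling(ext + 60)
  g <- grid_spec(points, lengths, center = geometric_center(parent))
  margin <- (lengths - ext) / 2
  if (any(margin < 0)) abort("structure larger than grid")
  if (any(margin < 10)) {
    warn(sprintf("grid margin below 10 A (min %.2f A); boundary artifacts likely",
                 min(margin)))
  }
  g
}

#' Scalar fields on a grid
#'
#' A `scalar_field` wraps an `nx x ny x nz` numeric array of values on a
#' [grid_spec()], with a declared unit (`"kT/e"`, `"dimensionless"`,
#' `"A^-2"`, `"e/A^3"`).
#'
#' @param values numeric array matching `spec$points`.
#' @param spec a `grid_spec`.
#' @param unit unit string.
#' @return A list of class `scalar_field`.
#' @export
scalar_field <- function(values, spec, unit = "dimensionless") {
  values <- as.array(values)
  if (!all(dim(values) == spec$points)) abort("field dimensions do not match grid")
  if (!all(is.finite(values))) abort("field values must be finite")
  structure(list(values = values, spec = spec, unit = unit),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("<scalar_field %dx%dx%d [%s], range [%.4g, %.4g]>\n",
              x$spec$points[1], x$spec$points[2], x$spec$points[3],
              x$unit, min(x$values), max(x$values)))
  invisible(x)
}

#' @export
glance.scalar_field <- function(x, ...) {
  tibble(nx = x$spec$points[1], ny = x$spec$points[2], nz = x$spec$points[3],
         unit = x$unit, min = min(x$values), max = max(x$values),
         mean = mean(x$values))
}

#' Trilinear interpolation of a field at arbitrary points
#'
#' Exact for fields linear in x, y, z.
#'
#' @param f a `scalar_field`.
#' @param xyz n x 3 matrix of positions (Angstrom).
#' @return numeric vector of interpolated values.
#' @export
interpolate_field <- function(f, xyz) {
  xyz <- matrix(xyz, ncol = 3L)
  g <- f$spec
  out <- numeric(nrow(xyz))
  fr <- sweep(sweep(xyz, 2, g$origin), 2, g$h, "/")
  if (any(fr < -1e-9) || any(sweep(fr, 2, g$points - 1L) > 1e-9)) {
    abort("sampling point outside grid")
  }
  fr <- pmax(fr, 0)
  i0 <- pmin(matrix(floor(fr), ncol = 3L), matrix(rep(g$points - 2L, each = nrow(fr)), ncol = 3L))
  t3 <- fr - i0
  n <- g$points
  val <- f$values
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (if (cx) t3[, 1] else 1 - t3[, 1]) *
         (if (cy) t3[, 2] else 1 - t3[, 2]) *
         (if (cz) t3[, 3] else 1 - t3[, 3])
    li <- (i0[, 1] + cx) + n[1] * ((i0[, 2] + cy) + n[2] * (i0[, 3] + cz)) + 1
    out <- out + w * val[li]
  }
  out
}

# distance-beyond-vdW field: for every node, min over atoms of
# (|node - atom| - radius - offset); computed per atom over its local box
node_min_gap <- function(s, g, offset = 0, cap = 6) {
  ax <- grid_axes(g)
  n <- g$points
  d <- array(Inf, dim = n)
  reach <- s$radius + offset + cap
  for (k in seq_len(nrow(s))) {
    p <- c(s$x[k], s$y[k], s$z[k])
    lo <- pmax(ceiling((p - reach[k] - g$origin) / g$h) + 1, 1)
    hi <- pmin(floor((p + reach[k] - g$origin) / g$h) + 1, n)
    if (any(lo > hi)) next
    dx2 <- (ax[[1]][lo[1]:hi[1]] - p[1])^2
    dy2 <- (ax[[2]][lo[2]:hi[2]] - p[2])^2
    dz2 <- (ax[[3]][lo[3]:hi[3]] - p[3])^2
    dd <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+")) - s$radius[k] - offset
    sub <- d[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    d[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- pmin(sub, dd)
  }
  d
}
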