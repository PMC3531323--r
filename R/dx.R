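#' Write a scalar field in OpenDX format (APBS dialect)
#'
#' Regular-grid scalar OpenDX with `gridpositions`, `gridconnections` and an
#' `object 3 class array` data block, three values per line, x-index slowest
#' and z fastest, as written by APBS.
#'
#' @param f a `scalar_field`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dx <- function(f, path) {
  g <- f$spec
  n <- g$points
  vals <- as.vector(aperm(f$values, c(3, 2, 1)))  # z fastest
  ntot <- length(vals)
  pad <- (3 - ntot %% 3) %% 3
  m <- matrix(c(sprintf("%.6e", vals), rep("", pad)), nrow = 3)
  data_lines <- trimws(apply(m, 2, paste, collapse = " "))
  hdr <- c(
    "# OpenDX scalar field written by esimap",
    sprintf("# unit: %s", f$unit),
    sprintf("object 1 class gridpositions counts %d %d %d", n[1], n[2], n[3]),
    sprintf("origin %.6e %.6e %.6e", g$origin[1], g$origin[2], g$origin[3]),
    sprintf("delta %.6e %.6e %.6e", g$h[1], 0, 0),
    sprintf("delta %.6e %.6e %.6e", 0, g$h[2], 0),
    sprintf("delta %.6e %.6e %.6e", 0, 0, g$h[3]),
    sprintf("object 2 class gridconnections counts %d %d %d", n[1], n[2], n[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", ntot)
  )
  ftr <- c(
    'attribute "dep" string "positions"',
    'object "regular positions regular connections" class field',
    'component "positions" value 1',
    'component "connections" value 2',
    'component "data" value 3'
  )
  writeLines(c(hdr, data_lines, ftr), path)
  invisible(path)
}

#' Read an OpenDX scalar field (APBS dialect)
#'
#' @param path path to a DX file.
#' @param unit unit to stamp on the returned field (DX carries none; an
#'   esimap-written comment is honoured when present).
#' @return A `scalar_field`.
#' @export
read_dx <- function(path, unit = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  ln <- readLines(path)
  grab <- function(pattern) {
    hit <- grep(pattern, ln, value = TRUE)
    if (length(hit) == 0L) abort(paste0("malformed DX header: missing ", pattern))
    hit[1]
  }
  cnt <- as.integer(strsplit(trimws(sub(".*gridpositions counts", "",
                                        grab("gridpositions counts"))), "\\s+")[[1]])
  origin <- as.numeric(strsplit(trimws(sub("^\\s*origin", "", grab("^\\s*origin"))),
                                "\\s+")[[1]])
  deltas <- grep("^\\s*delta", ln, value = TRUE)
  if (length(deltas) != 3L) abort("malformed DX header: expected 3 delta lines")
  dmat <- t(vapply(deltas, function(d) {
    as.numeric(strsplit(trimws(sub("^\\s*delta", "", d)), "\\s+")[[1]])
  }, numeric(3)))
  if (any(abs(dmat - diag(diag(dmat))) > 1e-12)) {
    abort("only axis-aligned DX grids are supported")
  }
  h <- diag(dmat)
  items_line <- grab("object 3 class array")
  ntot <- as.integer(sub(".*items\\s+(\\d+)\\s+data follows.*", "\\1", items_line))
  if (ntot != prod(cnt)) abort("malformed DX header: item count mismatch")
  start <- grep("object 3 class array", ln)[1] + 1L
  stop_at <- grep("attribute|^object \"", ln)
  stop_at <- c(stop_at[stop_at > start], length(ln) + 1L)[1] - 1L
  vals <- as.numeric(unlist(strsplit(trimws(ln[start:stop_at]), "\\s+")))
  vals <- vals[!is.na(vals)]
  if (length(vals) != ntot) {
    abort(sprintf("truncated DX data block: expected %d values, found %d",
                  ntot, length(vals)))
  }
  if (is.null(unit)) {
    uhit <- grep("^# unit:", ln, value = TRUE)
    unit <- if (length(uhit) > 0) trimws(sub("^# unit:", "", uhit[1])) else "dimensionless"
  }
  spec <- grid_spec(cnt, h * (cnt - 1L), center = origin + h * (cnt - 1L) / 2)
  values <- aperm(array(vals, dim = rev(cnt)), c(3, 2, 1))
  scalar_field(values, spec, unit = unit)
}
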