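#' Project a grid field onto atoms and residues
#'
#' Each atom is sampled by trilinear interpolation at a point displaced
#' outward from the structure's geometric centre through the atom, by the
#' atom's vdW radius plus `offset` — the value "just outside the surface",
#' which is what surface-coloured figures show. Per-residue values are the
#' mean (or median) over the residue's atoms.
#'
#' @param f a `scalar_field` (potential or ESI).
#' @param s the structure to project onto (atoms must sample inside the
#'   grid).
#' @param offset outward displacement beyond the vdW radius (Angstrom,
#'   default 1.4).
#' @param aggregate `"mean"` (default) or `"median"` residue aggregate.
#' @return list of class `atom_projection`: `atoms` (tibble with `value`),
#'   `residues` (tibble with `value`), `offset`, `unit`.
#' @export
project_to_atoms <- function(f, s, offset = 1.4, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  ctr <- geometric_center(s)
  xyz <- coords_matrix(s)
  dir <- sweep(xyz, 2, ctr)
  nrm <- sqrt(rowSums(dir^2))
  dir <- dir / ifelse(nrm > 1e-12, nrm, 1)
  dir[nrm <= 1e-12, ] <- 0
  pts <- xyz + dir * (s$radius + offset)
  vals <- interpolate_field(f, pts)
  atoms <- tibble(serial = s$serial, name = s$name, resname = s$resname,
                  chain = s$chain, resno = s$resno, value = vals)
  idx <- residue_index(s)
  agg_fun <- if (aggregate == "mean") mean else stats::median
  res <- residue_table(s)
  res$value <- as.numeric(tapply(vals, idx, agg_fun)[as.character(res$res_index)])
  structure(list(atoms = atoms,
                 residues = as_tibble(res[, c("chain", "resno", "resname", "value")]),
                 offset = offset, unit = f$unit),
            class = "atom_projection")
}

#' @export
print.atom_projection <- function(x, ...) {
  cat(sprintf("<atom_projection: %d atoms, %d residues [%s], offset %.2f A>\n",
              nrow(x$atoms), nrow(x$residues), x$unit, x$offset))
  invisible(x)
}

#' @export
tidy.atom_projection <- function(x, ...) x$residues

#' Write a projection as a Chimera attribute file (plus B-factor PDB and CSV)
#'
#' The attribute file carries per-residue values in UCSF Chimera's
#' `defattr` format. Optionally also writes the structure as a PDB with the
#' per-atom values in the B-factor column (clamped to +/-999.99 with a
#' warning) and a per-residue CSV.
#'
#' @param a an `atom_projection`.
#' @param path attribute-file path.
#' @param attribute attribute name (default `"esi"`).
#' @param s optional structure; when given, a PDB with values in the B-factor
#'   column is written next to `path` (extension `.pdb`).
#' @param csv also write `<path>.csv` with chain, resnum, resname, value.
#' @return `path`, invisibly.
#' @export
write_attribute_file <- function(a, path, attribute = "esi", s = NULL,
                                 csv = TRUE) {
  res <- a$residues
  lines <- c(sprintf("attribute: %s", attribute),
             "match mode: 1-to-1",
             "recipient: residues",
             sprintf("\t:%d.%s\t%.6f", res$resno, res$chain, res$value))
  writeLines(lines, path)
  if (!is.null(s)) {
    b <- a$atoms$value
    if (any(abs(b) > 999.99)) {
      warn("projection values exceed the PDB B-factor field width; clamped to +/-999.99")
      b <- pmin(pmax(b, -999.99), 999.99)
    }
    write_pdb(s, paste0(tools::file_path_sans_ext(path), ".pdb"), b = b)
  }
  if (csv) {
    utils::write.csv(
      data.frame(chain = res$chain, resnum = res$resno,
                 resname = res$resname, value = res$value),
      paste0(path, ".csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read back a Chimera residue attribute file
#'
#' @param path attribute file written by [write_attribute_file()].
#' @return tibble with `chain`, `resno`, `value`.
#' @export
read_attribute_file <- function(path) {
  ln <- readLines(path)
  ln <- ln[grepl("^\\t:", ln)]
  m <- regmatches(ln, regexec("^\t:(-?\\d+)\\.(\\S+)\t(\\S+)$", ln))
  tibble(
    chain = vapply(m, `[`, character(1), 3),
    resno = as.integer(vapply(m, `[`, character(1), 2)),
    value = as.numeric(vapply(m, `[`, character(1), 4))
  )
}
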