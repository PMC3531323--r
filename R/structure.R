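#' Molecular structures as atom tables
#'
#' An `esimap_structure` is a tibble with one row per atom and columns
#' `serial`, `name`, `resname`, `chain`, `resno`, `x`, `y`, `z` (Angstrom),
#' `charge` (e, 0 until parameters are assigned), `radius` (Angstrom, 0 until
#' assigned) and `element`, plus a `label` attribute naming the structure.
#' Residues are contiguous runs of `(chain, resno)`.
#'
#' @param atoms data frame with at least `name`, `resname`, `chain`, `resno`,
#'   `x`, `y`, `z`; missing `serial`, `charge`, `radius`, `element` columns are
#'   filled with defaults.
#' @param label character scalar naming the structure.
#' @return A tibble of class `esimap_structure`.
#' @export
new_structure <- function(atoms, label = "structure") {
  atoms <- as_tibble(atoms)
  if (nrow(atoms) == 0L) {
    abort("a structure must contain at least one atom", class = "esimap_empty_structure")
  }
  if (!"serial" %in% names(atoms)) atoms$serial <- seq_len(nrow(atoms))
  if (!"charge" %in% names(atoms)) atoms$charge <- 0
  if (!"radius" %in% names(atoms)) atoms$radius <- 0
  if (!"element" %in% names(atoms)) atoms$element <- guess_element(atoms$name)
  atoms <- atoms[, c("serial", "name", "resname", "chain", "resno",
                     "x", "y", "z", "charge", "radius", "element")]
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("atom coordinates must be finite")
  }
  if (any(atoms$radius < 0)) abort("atom radii must be non-negative")
  attr(atoms, "label") <- label
  class(atoms) <- c("esimap_structure", class(tibble()))
  atoms
}

#' @export
print.esimap_structure <- function(x, ...) {
  cat(sprintf("<esimap_structure '%s': %d atoms, %d residues>\n",
              structure_label(x), nrow(x), nrow(residue_table(x))))
  NextMethod()
}

#' @rdname new_structure
#' @param s a structure.
#' @export
structure_label <- function(s) attr(s, "label") %||% "structure"

`%||%` <- function(a, b) if (is.null(a)) b else a

set_label <- function(s, label) {
  attr(s, "label") <- label
  s
}

#' Per-residue summary of a structure
#'
#' One row per residue (contiguous `(chain, resno)` run, in atom order) with
#' the residue name, atom count and formal charge implied by the summed atomic
#' charges.
#'
#' @param s a structure.
#' @return tibble with columns `chain`, `resno`, `resname`, `n_atoms`,
#'   `charge`.
#' @export
residue_table <- function(s) {
  key <- paste(s$chain, s$resno, sep = "\r")
  idx <- cumsum(c(TRUE, key[-1] != key[-length(key)]))
  tibble(
    res_index = unique(idx),
    chain = s$chain[!duplicated(idx)],
    resno = s$resno[!duplicated(idx)],
    resname = s$resname[!duplicated(idx)],
    n_atoms = as.integer(table(idx)[as.character(unique(idx))]),
    charge = as.numeric(tapply(s$charge, idx, sum)[as.character(unique(idx))])
  )
}

residue_index <- function(s) {
  key <- paste(s$chain, s$resno, sep = "\r")
  cumsum(c(TRUE, key[-1] != key[-length(key)]))
}

guess_element <- function(name) {
  nm <- gsub("[^A-Za-z]", "", name)
  two <- toupper(substr(nm, 1, 2))
  one <- toupper(substr(nm, 1, 1))
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE"), two, one)
}

#' Geometric center of a structure
#'
#' Unweighted mean of the atomic coordinates.
#'
#' @param s a structure.
#' @return numeric length-3 vector (Angstrom).
#' @export
geometric_center <- function(s) {
  c(mean(s$x), mean(s$y), mean(s$z))
}

coords_matrix <- function(s) cbind(s$x, s$y, s$z)
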