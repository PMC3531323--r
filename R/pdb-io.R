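#' Read a PDB file
#'
#' Parses fixed-column ATOM/HETATM records (via bio3d), honouring MODEL/ENDMDL
#' blocks. Alternate locations are resolved to the highest-occupancy record,
#' ties broken by first occurrence.
#'
#' @param path path to a PDB file.
#' @param model_index which MODEL to return (1-based), or `"all"` for a list
#'   of structures, one per MODEL block.
#' @param keep_hetatm keep HETATM records (default TRUE).
#' @return An `esimap_structure`, or a list of them when `model_index = "all"`.
#' @export
read_pdb <- function(path, model_index = 1L, keep_hetatm = TRUE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) abort(paste0("zero atoms parsed from ", path),
                              class = "esimap_zero_atoms")
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) {
    abort(paste0("zero atoms parsed from ", path), class = "esimap_zero_atoms")
  }
  if (!keep_hetatm) {
    keep <- at$type == "ATOM"
    at <- at[keep, , drop = FALSE]
    if (nrow(at) == 0L) abort("zero atoms parsed", class = "esimap_zero_atoms")
  } else {
    keep <- rep(TRUE, nrow(pdb$atom))
  }

  # resolve altloc: highest occupancy, then first seen, per (chain, resno,
  # insert, atom name)
  alt <- at$alt
  sel <- seq_len(nrow(at))
  if (any(!is.na(alt) & alt != "")) {
    occ <- ifelse(is.na(at$o), 1, at$o)
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
    ord <- order(key, -occ, seq_along(key))
    first <- !duplicated(key[ord])
    sel <- sort(ord[first])
    at <- at[sel, , drop = FALSE]
  }

  n_models <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz else matrix(pdb$xyz, nrow = 1L)
  col_idx <- which(keep)[sel]
  xyz_cols <- as.vector(rbind(3L * (col_idx - 1L) + 1L,
                              3L * (col_idx - 1L) + 2L,
                              3L * (col_idx - 1L) + 3L))

  base_label <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
  build <- function(m) {
    v <- xyz[m, xyz_cols]
    mat <- matrix(v, ncol = 3L, byrow = TRUE)
    new_structure(
      tibble(
        serial = at$eleno, name = at$elety, resname = at$resid,
        chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
        resno = at$resno,
        x = mat[, 1], y = mat[, 2], z = mat[, 3],
        element = ifelse(is.na(at$elesy) | at$elesy == "",
                         guess_element(at$elety), at$elesy)
      ),
      label = if (n_models > 1L) sprintf("%s_model%d", base_label, m) else base_label
    )
  }

  if (identical(model_index, "all")) {
    lapply(seq_len(n_models), build)
  } else {
    model_index <- as.integer(model_index)
    if (model_index < 1L || model_index > n_models) {
      abort(sprintf("model_index %d out of range (file has %d model(s))",
                    model_index, n_models))
    }
    build(model_index)
  }
}

#' Write a structure as a PDB file
#'
#' @param s a structure.
#' @param path output path.
#' @param b optional numeric vector of per-atom B-factor values.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path, b = NULL) {
  if (nrow(s) == 0L) abort("cannot write an empty structure")
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(coords_matrix(s))),
    resno = s$resno, resid = s$resname, eleno = s$serial,
    elety = s$name, chain = s$chain,
    o = rep(1, nrow(s)),
    b = if (is.null(b)) rep(0, nrow(s)) else b,
    elesy = s$element
  )
  invisible(path)
}

#' Write a multi-model PDB (e.g. a conformational ensemble)
#'
#' @param structures list of structures with identical atom tables (only
#'   coordinates may differ).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(structures, path) {
  if (length(structures) < 1L) abort("need at least one model")
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(structures)) {
    s <- structures[[m]]
    writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      s$serial, ifelse(nchar(s$name) < 4, paste0(" ", s$name), s$name),
      s$resname, s$chain, s$resno, s$x, s$y, s$z, 1, 0, s$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a structure as a PQR file
#'
#' Whitespace-separated PQR dialect: per-atom partial charge (e) then radius
#' (Angstrom) follow the coordinates. Parameters must have been assigned
#' (see [assign_parameters()]).
#'
#' @param s a structure with assigned parameters.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pqr <- function(s, path) {
  if (nrow(s) == 0L) abort("cannot write an empty structure")
  if (!isTRUE(attr(s, "parameters_assigned"))) {
    abort("parameters not assigned; run assign_parameters() first",
          class = "esimap_unparameterized")
  }
  lines <- sprintf("ATOM  %6d %-4s %-4s %1s %5d %11.4f %11.4f %11.4f %8.4f %7.4f",
                   s$serial, s$name, s$resname, s$chain, s$resno,
                   s$x, s$y, s$z, s$charge, s$radius)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a PQR file
#'
#' Accepts whitespace-separated ATOM/HETATM lines with or without a chain
#' field (10 or 11 tokens).
#'
#' @param path path to a PQR file.
#' @return An `esimap_structure` with `parameters_assigned` set.
#' @export
read_pqr <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  ln <- readLines(path)
  ln <- ln[grepl("^(ATOM|HETATM)", ln)]
  if (length(ln) == 0L) abort("zero atoms parsed", class = "esimap_zero_atoms")
  tok <- strsplit(trimws(ln), "\\s+")
  nt <- lengths(tok)
  if (!all(nt %in% c(10L, 11L))) {
    abort("malformed PQR: expected 10 or 11 whitespace-separated fields per atom line")
  }
  parse_one <- function(t) {
    has_chain <- length(t) == 11L
    i <- if (has_chain) 0L else -1L
    list(serial = as.integer(t[2]), name = t[3], resname = t[4],
         chain = if (has_chain) t[5] else "A",
         resno = as.integer(t[6 + i]),
         x = as.numeric(t[7 + i]), y = as.numeric(t[8 + i]),
         z = as.numeric(t[9 + i]),
         charge = as.numeric(t[10 + i]), radius = as.numeric(t[11 + i]))
  }
  rows <- lapply(tok, parse_one)
  s <- new_structure(
    dplyr::bind_rows(lapply(rows, as_tibble)),
    label = sub("\\.pqr$", "", basename(path), ignore.case = TRUE)
  )
  attr(s, "parameters_assigned") <- TRUE
  s
}
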