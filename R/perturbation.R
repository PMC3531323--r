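#' Perturbation families
#'
#' A `perturbation_family` holds a parent structure plus N member structures
#' (alanine-scan mutants, conformational snapshots, or homologue models) that
#' are compared against the parent on one shared grid.
#'
#' @param parent parent structure (the potential every member is compared to).
#' @param members list of member structures.
#' @param member_labels character labels, e.g. `"E117A"` or `"snapshot_037"`.
#' @param kind one of `"alanine_scan"`, `"ensemble"`, `"homologues"`.
#' @return list of class `perturbation_family`.
#' @export
perturbation_family <- function(parent, members, member_labels,
                                kind = c("alanine_scan", "ensemble", "homologues")) {
  kind <- match.arg(kind)
  if (length(members) == 0L) {
    abort("a perturbation family needs at least one member",
          class = "esimap_empty_family")
  }
  stopifnot(length(members) == length(member_labels))
  structure(list(parent = parent, members = members,
                 member_labels = member_labels, kind = kind,
                 n = length(members)),
            class = "perturbation_family")
}

#' @export
print.perturbation_family <- function(x, ...) {
  cat(sprintf("<perturbation_family [%s]: parent '%s' + %d members>\n",
              x$kind, structure_label(x$parent), x$n))
  invisible(x)
}

#' @export
tidy.perturbation_family <- function(x, ...) {
  nets <- vapply(x$members, function(m) {
    if (isTRUE(attr(m, "parameters_assigned"))) net_charge(m)$raw else NA_real_
  }, numeric(1))
  tibble(label = x$member_labels, kind = x$kind, net_charge = nets)
}

AA_321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT", "CB", "H", "HA", "HN",
                    "H1", "H2", "H3", "HB1", "HB2", "HB3")

#' Computational alanine scan
#'
#' Enumerates every residue with nonzero formal charge at the titration
#' model's pH (Asp, Glu, Lys, Arg at pH 7.4; His is neutral there and is not
#' scanned) and builds one mutant per residue: the target residue's
#' side-chain atoms beyond C-beta are removed, the residue is renamed ALA and
#' parameters are reassigned, so its charge becomes alanine's (zero) while
#' the backbone is untouched. Each mutant's net charge is the parent's minus
#' the target's formal charge.
#'
#' @param parent parameterized parent structure.
#' @param t the `titration_model` used for the parent.
#' @return A `perturbation_family` of kind `"alanine_scan"` with labels like
#'   `"E117A"`.
#' @export
alanine_scan <- function(parent, t = attr(parent, "titration") %||% titration_model()) {
  if (!isTRUE(attr(parent, "parameters_assigned"))) {
    abort("parameters not assigned", class = "esimap_unparameterized")
  }
  targets <- charged_residues(parent, t)
  if (nrow(targets) == 0L) {
    abort("no charged residues to scan: empty family",
          class = "esimap_empty_family")
  }
  idx <- residue_index(parent)
  members <- vector("list", nrow(targets))
  labels <- character(nrow(targets))
  for (r in seq_len(nrow(targets))) {
    in_res <- idx == targets$res_index[r]
    drop <- in_res & !(parent$name %in% BACKBONE_ATOMS)
    m <- parent[!drop, , drop = FALSE]
    m$resname[idx[!drop] == targets$res_index[r]] <- "ALA"
    m <- new_structure(m, label = NA)
    one <- AA_321[toupper(targets$resname[r])]
    if (is.na(one)) one <- "X"
    labels[r] <- if (length(unique(parent$chain)) > 1L) {
      sprintf("%s_%s%dA", targets$chain[r], one, targets$resno[r])
    } else {
      sprintf("%s%dA", one, targets$resno[r])
    }
    m <- suppressWarnings(assign_parameters(m, t))
    m <- set_label(m, paste0(structure_label(parent), "_", labels[r]))
    members[[r]] <- m
  }
  perturbation_family(parent, members, labels, kind = "alanine_scan")
}

#' Load a conformational ensemble as a perturbation family
#'
#' Reads a multi-model PDB (for example snapshots extracted from a molecular
#' dynamics trajectory), takes one designated model — or an external
#' reference structure — as the parent and the remaining models as members.
#'
#' @param path multi-model PDB file (at least 2 models, equal atom counts).
#' @param parent_index 1-based model used as parent (default 1), ignored when
#'   `parent` is given.
#' @param parent optional external parameterized parent structure; then all
#'   models become members.
#' @param t `titration_model` used to parameterize the models.
#' @return A `perturbation_family` of kind `"ensemble"`.
#' @export
load_ensemble <- function(path, parent_index = 1L, parent = NULL,
                          t = titration_model()) {
  models <- read_pdb(path, model_index = "all")
  if (length(models) < 2L && is.null(parent)) {
    abort("ensemble file must contain at least 2 models")
  }
  counts <- vapply(models, nrow, integer(1))
  if (length(unique(counts)) != 1L) {
    abort("mismatched atom counts across models")
  }
  models <- lapply(models, function(m) suppressWarnings(assign_parameters(m, t)))
  if (is.null(parent)) {
    parent_index <- as.integer(parent_index)
    parent <- models[[parent_index]]
    members <- models[-parent_index]
  } else {
    if (!isTRUE(attr(parent, "parameters_assigned"))) {
      parent <- suppressWarnings(assign_parameters(parent, t))
    }
    members <- models
  }
  labels <- sprintf("snapshot_%03d", seq_along(members))
  perturbation_family(parent, members, labels, kind = "ensemble")
}

#' Load a homologue family from a directory of PDB files
#'
#' Members need not share atom counts with the parent: downstream similarity
#' compares potentials on a common grid, not atoms. Non-PDB files in the
#' directory are skipped with a message.
#'
#' @param parent parameterized parent structure.
#' @param member_dir directory containing member PDB files.
#' @param t `titration_model` used to parameterize the members.
#' @return A `perturbation_family` of kind `"homologues"`.
#' @export
load_homologue_family <- function(parent, member_dir, t = titration_model()) {
  if (!dir.exists(member_dir)) abort(paste0("not a directory: ", member_dir))
  files <- sort(list.files(member_dir, full.names = TRUE))
  is_pdb <- grepl("\\.(pdb|ent)$", files, ignore.case = TRUE)
  if (any(!is_pdb)) {
    inform(paste0("skipping non-PDB file(s): ",
                  paste(basename(files[!is_pdb]), collapse = ", ")))
  }
  files <- files[is_pdb]
  if (length(files) == 0L) {
    abort("no PDB files in directory", class = "esimap_empty_family")
  }
  members <- lapply(files, function(f) {
    suppressWarnings(assign_parameters(read_pdb(f), t))
  })
  labels <- sub("\\.(pdb|ent)$", "", basename(files), ignore.case = TRUE)
  if (!isTRUE(attr(parent, "parameters_assigned"))) {
    parent <- suppressWarnings(assign_parameters(parent, t))
  }
  perturbation_family(parent, members, labels, kind = "homologues")
}

#' Write a family as a directory of PQR files plus a manifest
#'
#' @param fam a `perturbation_family` (parameterized members).
#' @param dir output directory (created if needed).
#' @return path of the manifest CSV, invisibly.
#' @export
write_family <- function(fam, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_pqr(fam$parent, file.path(dir, "parent.pqr"))
  for (i in seq_along(fam$members)) {
    write_pqr(fam$members[[i]],
              file.path(dir, paste0(fam$member_labels[i], ".pqr")))
  }
  man <- tidy(fam)
  man <- dplyr::bind_rows(
    tibble(label = "parent", kind = fam$kind,
           net_charge = net_charge(fam$parent)$raw),
    man
  )
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, path, row.names = FALSE)
  invisible(path)
}
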