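#' Titration model: formal charges from model pKa values
#'
#' Formal charges of titratable groups are the majority protonation state at
#' the given pH (no fractional charges): a basic group carries +1 when
#' pH < pKa, an acidic group carries -1 when pH > pKa, otherwise 0. The
#' default model pKa table is the standard textbook set: Asp 3.65, Glu 4.25,
#' Lys 10.53, Arg 12.48, His 6.30, Cys 8.3, Tyr 10.1, N-terminus 8.0,
#' C-terminus 3.1. At pH 7.4 this makes Asp/Glu -1, Lys/Arg +1 and His, Cys,
#' Tyr neutral.
#'
#' @param pH solution pH (default 7.4).
#' @param pka named numeric vector overriding entries of the model pKa table.
#' @param charge_termini charge the chain termini (+1 N-terminus, -1
#'   C-terminus)? Default TRUE; they cancel in the net charge of a single
#'   chain either way.
#' @return A list of class `titration_model`.
#' @export
titration_model <- function(pH = 7.4, pka = NULL, charge_termini = TRUE) {
  tab <- c(ASP = 3.65, GLU = 4.25, LYS = 10.53, ARG = 12.48, HIS = 6.30,
           CYS = 8.3, TYR = 10.1, NTERM = 8.0, CTERM = 3.1)
  if (!is.null(pka)) tab[names(pka)] <- pka
  structure(list(pH = pH, pka = tab, charge_termini = charge_termini),
            class = "titration_model")
}

# +1 for bases below their pKa, -1 for acids above theirs, else 0
ACIDIC_GROUPS <- c("ASP", "GLU", "CYS", "TYR", "CTERM")
BASIC_GROUPS <- c("LYS", "ARG", "HIS", "NTERM")

group_formal_charge <- function(group, t) {
  pka <- unname(t$pka[group])
  ifelse(group %in% BASIC_GROUPS, as.numeric(t$pH < pka),
         ifelse(group %in% ACIDIC_GROUPS, -as.numeric(t$pH > pka), 0))
}

#' @rdname titration_model
#' @param resname 3-letter residue code(s).
#' @param t a `titration_model`.
#' @return `residue_formal_charge()`: integer formal charge(s) in {-1, 0, +1}
#'   (side chain only, termini excluded).
#' @export
residue_formal_charge <- function(resname, t = titration_model()) {
  rn <- toupper(resname)
  # common His tautomer names map to His
  rn[rn %in% c("HSD", "HSE", "HSP", "HID", "HIE", "HIP")] <- "HIS"
  out <- numeric(length(rn))
  known <- rn %in% names(t$pka)
  out[known] <- group_formal_charge(rn[known], t)
  as.integer(round(out))
}

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL",
                 "HSD", "HSE", "HSP", "HID", "HIE", "HIP")

# canonical charged-group atoms per residue; the formal charge is split
# evenly across whichever of these atoms the structure actually has, falling
# back to CB then CA for reduced representations
CHARGE_ATOMS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), LYS = "NZ",
  ARG = c("NH1", "NH2"), HIS = c("ND1", "NE2"), CYS = "SG", TYR = "OH"
)

BONDI_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                 P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, SE = 1.90,
                 FE = 1.70, ZN = 1.39, MG = 1.73, `NA` = 2.27)

#' Assign formal charges and radii to a structure
#'
#' Places each titratable residue's formal charge (from the
#' [titration_model()] at its pH) on the residue's canonical charged-group
#' atoms (Asp OD1/OD2 at -0.5 each, Glu OE1/OE2, Lys NZ at +1, Arg NH1/NH2 at
#' +0.5 each, and so on), zero elsewhere; when those atoms are absent (coarse
#' or synthetic structures) the charge falls back to CB, then CA, then the
#' residue's first atom. Chain termini get +1 (N, first residue of a chain)
#' and -1 (OXT or C, last residue) when the model charges termini. Radii are
#' per-element Bondi van der Waals radii. Unknown residue types get zero
#' charge and are reported with a warning. The operation is idempotent.
#'
#' @param s a structure.
#' @param t a `titration_model`.
#' @return The structure with `charge` and `radius` filled in and the
#'   `parameters_assigned` attribute set.
#' @export
assign_parameters <- function(s, t = titration_model()) {
  label <- structure_label(s)
  s$charge <- 0
  s$radius <- unname(BONDI_RADII[toupper(s$element)])
  s$radius[is.na(s$radius)] <- 1.70

  idx <- residue_index(s)
  res <- residue_table(s)
  rn <- toupper(res$resname)
  rn[rn %in% c("HSD", "HSE", "HSP", "HID", "HIE", "HIP")] <- "HIS"
  unknown <- unique(res$resname[!(rn %in% STANDARD_AA)])
  if (length(unknown) > 0L) {
    warn(paste0("unknown residue type(s) assigned zero charge: ",
                paste(unknown, collapse = ", ")))
  }

  fc <- residue_formal_charge(res$resname, t)
  for (r in seq_len(nrow(res))) {
    if (fc[r] == 0) next
    rows <- which(idx == res$res_index[r])
    targets <- rows[s$name[rows] %in% CHARGE_ATOMS[[rn[r]]]]
    if (length(targets) == 0L) targets <- rows[s$name[rows] == "CB"]
    if (length(targets) == 0L) targets <- rows[s$name[rows] == "CA"]
    if (length(targets) == 0L) targets <- rows[1L]
    s$charge[targets] <- s$charge[targets] + fc[r] / length(targets)
  }

  if (isTRUE(t$charge_termini)) {
    for (ch in unique(s$chain)) {
      rows_ch <- which(s$chain == ch)
      first_res <- idx[rows_ch[1L]]
      last_res <- idx[rows_ch[length(rows_ch)]]
      qn <- group_formal_charge("NTERM", t)
      qc <- group_formal_charge("CTERM", t)
      if (qn != 0) {
        rows <- which(idx == first_res)
        tgt <- rows[s$name[rows] == "N"]
        if (length(tgt) == 0L) tgt <- rows[1L]
        s$charge[tgt] <- s$charge[tgt] + qn / length(tgt)
      }
      if (qc != 0) {
        rows <- which(idx == last_res)
        tgt <- rows[s$name[rows] == "OXT"]
        if (length(tgt) == 0L) tgt <- rows[s$name[rows] == "C"]
        if (length(tgt) == 0L) tgt <- rows[length(rows)]
        s$charge[tgt] <- s$charge[tgt] + qc / length(tgt)
      }
    }
  }

  attr(s, "label") <- label
  attr(s, "parameters_assigned") <- TRUE
  attr(s, "titration") <- t
  s
}

#' Net charge of a parameterized structure
#'
#' @param s a structure with assigned parameters.
#' @return list with `raw` (sum of atomic charges, e) and `rounded`
#'   (nearest integer).
#' @export
net_charge <- function(s) {
  if (!isTRUE(attr(s, "parameters_assigned"))) {
    abort("parameters not assigned; run assign_parameters() first",
          class = "esimap_unparameterized")
  }
  raw <- sum(s$charge)
  list(raw = raw, rounded = as.integer(round(raw)))
}

#' Residues carrying a nonzero formal charge
#'
#' @param s a structure.
#' @param t a `titration_model`.
#' @return tibble of charged residues (`chain`, `resno`, `resname`,
#'   `formal_charge`).
#' @export
charged_residues <- function(s, t = titration_model()) {
  res <- residue_table(s)
  fc <- residue_formal_charge(res$resname, t)
  out <- res[fc != 0, c("res_index", "chain", "resno", "resname")]
  out$formal_charge <- fc[fc != 0]
  as_tibble(out)
}
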