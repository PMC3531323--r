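#' Read an aligned FASTA file
#'
#' All rows must have equal (gapped) length. The reference row is the
#' sequence mapped onto the parent structure for face-restricted column
#' selection.
#'
#' @param path aligned FASTA.
#' @param reference_label label of the reference row (default: first).
#' @return list of class `esimap_alignment`: `labels`, `rows` (named gapped
#'   strings), `reference_label`, `width`.
#' @export
read_alignment <- function(path, reference_label = NULL) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) < 1L) abort("empty alignment")
  rows <- as.character(aa)
  names(rows) <- sub("\\s.*$", "", names(aa))
  new_alignment(rows, reference_label)
}

#' @rdname read_alignment
#' @param rows named character vector of equal-length gapped sequences.
#' @export
new_alignment <- function(rows, reference_label = NULL) {
  if (length(unique(nchar(rows))) != 1L) {
    abort("alignment rows must all have the same length")
  }
  if (is.null(names(rows))) names(rows) <- paste0("seq", seq_along(rows))
  if (is.null(reference_label)) reference_label <- names(rows)[1]
  if (!reference_label %in% names(rows)) {
    abort(paste0("reference label not in alignment: ", reference_label))
  }
  structure(list(labels = names(rows), rows = rows,
                 reference_label = reference_label,
                 width = nchar(rows[[1]])),
            class = "esimap_alignment")
}

#' @export
print.esimap_alignment <- function(x, ...) {
  cat(sprintf("<alignment: %d sequences x %d columns, reference '%s'>\n",
              length(x$rows), x$width, x$reference_label))
  invisible(x)
}

aln_matrix <- function(a, columns = NULL) {
  m <- do.call(rbind, strsplit(toupper(unname(a$rows)), ""))
  rownames(m) <- a$labels
  if (!is.null(columns)) {
    if (length(columns) == 0L) abort("empty column subset")
    m <- m[, columns, drop = FALSE]
  }
  m
}

new_similarity_matrix <- function(values, labels, kind) {
  dimnames(values) <- list(labels, labels)
  structure(list(labels = labels, values = values, kind = kind),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix [%s]: %d x %d>\n", x$kind,
              length(x$labels), length(x$labels)))
  print(x$values, ...)
  invisible(x)
}

#' @export
tidy.similarity_matrix <- function(x, ...) {
  out <- as_tibble(as.data.frame.table(x$values, stringsAsFactors = FALSE))
  names(out) <- c("a", "b", "value")
  out$kind <- x$kind
  out
}

#' Pairwise sequence identity matrix
#'
#' Identity of a pair = matching non-gap positions divided by the number of
#' selected columns where at least one of the two rows is non-gap.
#'
#' @param a an `esimap_alignment`.
#' @param columns optional column subset (integer indices).
#' @return `similarity_matrix` of kind `"identity_fraction"`.
#' @export
pairwise_identity <- function(a, columns = NULL) {
  m <- aln_matrix(a, columns)
  if (nrow(m) < 2L) abort("alignment must contain at least 2 sequences")
  n <- nrow(m)
  gap <- m == "-"
  v <- matrix(1, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    scored <- !(gap[i, ] & gap[j, ])
    match <- m[i, ] == m[j, ] & !gap[i, ] & !gap[j, ]
    v[i, j] <- v[j, i] <- if (any(scored)) sum(match) / sum(scored) else 0
  }
  new_similarity_matrix(v, a$labels, "identity_fraction")
}

CHARGED_POS <- c("K", "R")
CHARGED_NEG <- c("D", "E")

#' Pairwise like-charge position count matrix
#'
#' For each pair of rows, the number of selected columns where both carry a
#' like-charged residue: both in {K, R} or both in {D, E}. Gaps and ambiguous
#' codes never count. The diagonal is each row's own charged-position count.
#'
#' @inheritParams pairwise_identity
#' @return `similarity_matrix` of kind `"charge_count"` (integer counts).
#' @export
pairwise_charge_similarity <- function(a, columns = NULL) {
  m <- aln_matrix(a, columns)
  if (nrow(m) < 2L) abort("alignment must contain at least 2 sequences")
  pos <- m %in% CHARGED_POS
  neg <- m %in% CHARGED_NEG
  dim(pos) <- dim(neg) <- dim(m)
  n <- nrow(m)
  v <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    v[i, j] <- v[j, i] <- sum((pos[i, ] & pos[j, ]) | (neg[i, ] & neg[j, ]))
  }
  new_similarity_matrix(v, a$labels, "charge_count")
}

#' Assign residues to the two functional faces by x-coordinate
#'
#' Using the structure's frame (for C3d, the 1C3D crystal frame): with
#' `mx = mean(x)` over all atoms, a residue belongs to the CR2-face when at
#' least one of its atoms has `x <= mx - margin` and to the thioester-face
#' when at least one atom has `x > mx + margin` (strict); everything else —
#' including the rare residue qualifying for both, which is flagged and
#' demoted so the faces stay disjoint — is `"neither"`.
#'
#' @param s a structure (in the intended frame).
#' @param margin face margin (Angstrom, default 5).
#' @return tibble of class `face_assignment`: `res_index`, `chain`, `resno`,
#'   `resname`, `min_x`, `max_x`, `face`; attribute `mean_x`.
#' @export
assign_faces <- function(s, margin = 5) {
  mx <- mean(s$x)
  idx <- residue_index(s)
  res <- residue_table(s)
  res$min_x <- as.numeric(tapply(s$x, idx, min)[as.character(res$res_index)])
  res$max_x <- as.numeric(tapply(s$x, idx, max)[as.character(res$res_index)])
  cr2 <- res$min_x <= mx - margin
  thio <- res$max_x > mx + margin
  both <- cr2 & thio
  if (any(both)) {
    warn(sprintf("%d residue(s) qualify for both faces; assigned 'neither'",
                 sum(both)))
  }
  res$face <- dplyr::case_when(
    both ~ "neither",
    cr2 ~ "CR2-face",
    thio ~ "thioester-face",
    TRUE ~ "neither"
  )
  out <- as_tibble(res[, c("res_index", "chain", "resno", "resname",
                           "min_x", "max_x", "face")])
  attr(out, "mean_x") <- mx
  attr(out, "margin") <- margin
  class(out) <- c("face_assignment", class(out))
  out
}

#' Alignment columns whose reference residue lies on a face
#'
#' The reference row's non-gap positions are mapped 1:1, in order, onto the
#' structure's residues; the selected columns are those aligned to residues
#' carrying the requested face label.
#'
#' @param a an `esimap_alignment`.
#' @param fa a `face_assignment` for the structure mapped to the reference
#'   row.
#' @param face `"CR2-face"` or `"thioester-face"` (or `"neither"`).
#' @return integer vector of column indices.
#' @export
columns_for_face <- function(a, fa, face = "CR2-face") {
  ref <- strsplit(toupper(a$rows[[a$reference_label]]), "")[[1]]
  non_gap <- which(ref != "-")
  if (length(non_gap) != nrow(fa)) {
    abort(sprintf("reference row has %d residues but the structure has %d",
                  length(non_gap), nrow(fa)))
  }
  non_gap[fa$face == face]
}

#' Hierarchical clustering of a similarity matrix
#'
#' Similarities are converted to distances (`identity_fraction`:
#' `d = 1 - s`; `charge_count`: `d = 1 - c_ij / max(c_ii, c_jj)`, which keeps
#' d in [0, 1] and removes sequence-length and net-charge effects) and
#' clustered agglomeratively with complete linkage (stats::hclust). Ties are
#' resolved deterministically by the input label order.
#'
#' @param m a `similarity_matrix`.
#' @param method linkage method for [stats::hclust()] (default
#'   `"complete"`).
#' @return list of class `esimap_hclust`: `hclust`, `phylo` (ape), `newick`,
#'   `merges` (tibble), `dist`.
#' @export
hcluster <- function(m, method = "complete") {
  v <- m$values
  if (!isTRUE(all.equal(v, t(v), tolerance = 1e-12))) {
    abort("similarity matrix must be symmetric")
  }
  d <- switch(m$kind,
    identity_fraction = 1 - v,
    charge_count = {
      self <- diag(v)
      denom <- outer(self, self, pmax)
      denom[denom == 0] <- 1
      1 - v / denom
    },
    abort(paste0("unknown similarity kind: ", m$kind))
  )
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = method)
  phylo <- ape::as.phylo(hc)
  merges <- tibble(
    step = seq_len(nrow(hc$merge)),
    left = hc$merge[, 1], right = hc$merge[, 2],
    height = hc$height
  )
  structure(list(hclust = hc, phylo = phylo,
                 newick = ape::write.tree(phylo), merges = merges,
                 dist = d, kind = m$kind),
            class = "esimap_hclust")
}

#' @export
print.esimap_hclust <- function(x, ...) {
  cat(sprintf("<esimap_hclust [%s, %s linkage]: %d leaves>\n",
              x$kind, x$hclust$method, length(x$hclust$labels)))
  invisible(x)
}

#' @export
tidy.esimap_hclust <- function(x, ...) x$merges

#' Cut a charge/identity dendrogram into k groups
#'
#' @param x an `esimap_hclust`.
#' @param k number of groups.
#' @return named integer vector of group memberships.
#' @export
cut_groups <- function(x, k = 2) {
  stats::cutree(x$hclust, k = k)
}

#' Write a dendrogram in Newick format
#'
#' @param x an `esimap_hclust`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(x, path) {
  ape::write.tree(x$phylo, file = path)
  invisible(path)
}

#' Write a similarity matrix as CSV
#'
#' @param m a `similarity_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_similarity_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m$values), path, row.names = TRUE)
  invisible(path)
}
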