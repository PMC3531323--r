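test_that("pairwise identity scores gapped alignments correctly", {
  a <- new_alignment(c(s1 = "AK-D", s2 = "AR-D"))
  m <- pairwise_identity(a)
  expect_equal(m$values["s1", "s2"], 2 / 3)     # 3 scored columns, 2 matches
  expect_equal(unname(diag(m$values)), c(1, 1))

  ident <- pairwise_identity(new_alignment(c(x = "KDEA", y = "KDEA")))
  expect_equal(ident$values["x", "y"], 1)

  disjoint <- pairwise_identity(new_alignment(c(x = "KDEA", y = "RNQG")))
  expect_equal(disjoint$values["x", "y"], 0)

  # a gap aligned to a residue is scored (as a mismatch)
  gappy <- pairwise_identity(new_alignment(c(x = "K-EA", y = "KDEA")))
  expect_equal(gappy$values["x", "y"], 3 / 4)
})

test_that("charge-position counts follow the K/R, D/E rule", {
  a <- new_alignment(c(x = "KDEA", y = "RDEG"))
  m <- pairwise_charge_similarity(a)
  expect_equal(m$values["x", "y"], 3)         # K/R, D/D, E/E
  expect_equal(m$values["x", "x"], 3)         # own charged count
  expect_equal(m$values["y", "y"], 3)

  opposite <- pairwise_charge_similarity(new_alignment(c(x = "KKKK", y = "DDDD")))
  expect_equal(opposite$values["x", "y"], 0)

  # gaps and ambiguous codes never count as charged
  amb <- pairwise_charge_similarity(new_alignment(c(x = "K-BD", y = "KKBD")))
  expect_equal(amb$values["x", "y"], 2)        # K/K and D/D only

  # column restriction is monotone: subsets never increase counts
  rows <- with_seed_local(9, {
    letters_pool <- c("K", "R", "D", "E", "A", "G", "S")
    vapply(1:4, function(i)
      paste(sample(letters_pool, 12, replace = TRUE), collapse = ""),
      character(1))
  })
  names(rows) <- paste0("m", 1:4)
  aln <- new_alignment(rows)
  full <- pairwise_charge_similarity(aln)
  sub <- pairwise_charge_similarity(aln, columns = 1:6)
  expect_true(all(sub$values <= full$values))
  # symmetry and diagonal dominance
  expect_equal(full$values, t(full$values))
  # each row's self-count bounds its similarity to every other row
  expect_true(all(sweep(full$values, 1, diag(full$values), "<=")))
  # row order never matters
  perm <- new_alignment(rows[c(3, 1, 4, 2)])
  mp <- pairwise_charge_similarity(perm)
  expect_equal(mp$values[names(rows), names(rows)], full$values)
})

test_that("face assignment follows the x-coordinate rule with strict bounds", {
  # single-atom residues at controlled x; mean(x) = 0 by symmetry
  xs <- c(-6, -5, -1, 1, 5, 6)
  atoms <- data.frame(name = "CA", resname = "ALA", chain = "A",
                      resno = seq_along(xs), x = xs, y = 0, z = 0)
  fa <- assign_faces(new_structure(atoms), margin = 5)
  expect_equal(attr(fa, "mean_x"), 0)
  expect_equal(fa$face,
               c("CR2-face",        # x = -6 <= -5
                 "CR2-face",        # x = -5 <= -5 (inclusive)
                 "neither", "neither",
                 "neither",         # x = +5 is NOT > +5 (strict)
                 "thioester-face")) # x = +6 > +5
  # faces are disjoint by construction
  expect_false(any(fa$face == "CR2-face" & fa$face == "thioester-face"))

  # a residue spanning the middle is neither
  span <- data.frame(name = c("CA", "CB"), resname = "ALA", chain = "A",
                     resno = 1, x = c(-1, 1), y = 0, z = 0)
  mid <- rbind(span,
               data.frame(name = "CA", resname = "ALA", chain = "A",
                          resno = 2, x = 0, y = 3, z = 0))
  fa2 <- assign_faces(new_structure(mid), margin = 5)
  expect_true(all(fa2$face == "neither"))
})

test_that("face-restricted column selection maps reference residues in order", {
  xs <- c(-8, -7, -6, 1, 2, 3, 4, 5, 6, 7) * 2
  atoms <- data.frame(name = "CA", resname = "ALA", chain = "A",
                      resno = seq_along(xs), x = xs, y = 0, z = 0)
  s <- new_structure(atoms)
  fa <- assign_faces(s, margin = 5)
  expect_equal(which(fa$face == "CR2-face"), 1:3)

  # gapless alignment: columns are the residue positions themselves
  rows <- c(ref = "DDDAAAAAAA", other = "EEEAAAAAAA")
  a <- new_alignment(rows, reference_label = "ref")
  expect_equal(columns_for_face(a, fa, "CR2-face"), 1:3)

  # gapped reference: columns shift past the gaps
  rows2 <- c(ref = "--DDDAAAA-AAA", other = "KKEEEAAAAGAAA")
  a2 <- new_alignment(rows2, reference_label = "ref")
  expect_equal(columns_for_face(a2, fa, "CR2-face"), 3:5)

  # length mismatch between reference row and structure is an error
  bad <- new_alignment(c(ref = "DDD", other = "EEE"))
  expect_error(columns_for_face(bad, fa, "CR2-face"), "residues")
})

test_that("hierarchical clustering is deterministic and recovers ultrametrics", {
  # closest pair merges first
  labs <- c("A", "B", "C")
  v <- matrix(c(1, 0.9, 0.1,
                0.9, 1, 0.1,
                0.1, 0.1, 1), 3, 3, dimnames = list(labs, labs))
  m <- structure(list(labels = labs, values = v, kind = "identity_fraction"),
                 class = "similarity_matrix")
  hc <- hcluster(m)
  expect_setequal(-c(hc$merges$left[1], hc$merges$right[1]), c(1L, 2L))
  expect_equal(hc$merges$height[1], 0.1, tolerance = 1e-12)

  # identical rows merge at zero height
  a <- new_alignment(c(x = "KDEA", y = "KDEA", z = "DDDD"))
  hz <- hcluster(pairwise_identity(a))
  expect_equal(min(hz$merges$height), 0)

  # charge-count distance transform: d = 1 - c_ij / max(c_ii, c_jj)
  cm <- pairwise_charge_similarity(new_alignment(c(x = "KDEA", y = "RDEG",
                                                   z = "KDKK")))
  hq <- hcluster(cm)
  expect_equal(hq$dist["x", "y"], 1 - 3 / 3, tolerance = 1e-12)
  expect_equal(hq$dist["x", "z"], 1 - 2 / 4, tolerance = 1e-12)

  # 4-leaf ultrametric recovery, checked against a brute-force oracle that
  # scores all three unrooted pairings by the three-point condition
  for (seed in 1:5) {
    hts <- with_seed_local(seed, sort(stats::runif(3, 0.1, 1)))
    # generating tree: (A,B) at h1, (C,D) at h2, root at h3
    d <- matrix(2 * hts[3], 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
    diag(d) <- 0
    d["A", "B"] <- d["B", "A"] <- 2 * hts[1]
    d["C", "D"] <- d["D", "C"] <- 2 * hts[2]
    oracle_pairing <- function(d) {
      splits <- list(c("A", "B"), c("A", "C"), c("A", "D"))
      score <- vapply(splits, function(p) {
        q <- setdiff(LETTERS[1:4], p)
        d[p[1], p[2]] + d[q[1], q[2]]
      }, numeric(1))
      splits[[which.min(score)]]
    }
    sim <- structure(list(labels = LETTERS[1:4], values = 1 - d,
                          kind = "identity_fraction"),
                     class = "similarity_matrix")
    hu <- hcluster(sim)
    grp <- cut_groups(hu, 2)
    pair <- oracle_pairing(d)
    expect_equal(grp[pair[1]], grp[pair[2]], ignore_attr = TRUE)
    expect_equal(length(unique(grp)), 2L)
    # merge heights reproduce the generating heights (complete linkage on an
    # ultrametric returns the tree's own heights)
    expect_equal(sort(hu$merges$height), sort(2 * hts), tolerance = 1e-12)
  }

  # non-symmetric input is rejected
  bad <- structure(list(labels = labs, values = matrix(stats::runif(9), 3, 3),
                        kind = "identity_fraction"),
                   class = "similarity_matrix")
  expect_error(hcluster(bad), "symmetric")

  # Newick export parses back to the same topology
  tree <- ape::read.tree(text = hc$newick)
  expect_setequal(tree$tip.label, labs)
})
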