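test_that("mutual information matches hand-computed and oracle values", {
  # a constant column carries no information
  aln <- ProteinAlignment(paste0("s", 1:4), c("AD", "AE", "AD", "AE"))
  expect_equal(mutualInformation(aln, 1, 2), 0)

  # 20 distinct residues perfectly coupled: MI = log20(20) = 1
  perfect <- ProteinAlignment(paste0("s", 1:20),
                              paste0(AA <- c("A","C","D","E","F","G","H","I","K","L",
                                             "M","N","P","Q","R","S","T","V","W","Y"), AA))
  expect_equal(mutualInformation(perfect, 1, 2), 1)

  # 2x2 joint table: MI = log20(2)
  half <- ProteinAlignment(paste0("s", 1:4), c("AD", "AD", "CE", "CE"))
  expect_equal(mutualInformation(half, 1, 2), log(2) / log(20), tolerance = 1e-12)
  expect_equal(mutualInformation(half, 1, 2),
               bruteMI(alnColumn(half, 1), alnColumn(half, 2)), tolerance = 1e-12)
})

test_that("rows with gaps or missing residues are excluded pairwise", {
  aln <- ProteinAlignment(paste0("s", 1:5), c("AD", "AD", "CE", "CE", "-D"))
  # row 5 is dropped for this pair: same value as the clean 4-row alignment
  expect_equal(mutualInformation(aln, 1, 2), log(2) / log(20), tolerance = 1e-12)
  xAln <- ProteinAlignment(paste0("s", 1:3), c("AD", "XD", "-E"))
  expect_error(mutualInformation(xAln, 1, 2),
               class = "coevolib_insufficient_data_error")
})

test_that("MI matrix equals the brute-force per-pair oracle entry for entry", {
  aln <- randomAlignment(30, 10, gapRate = 0.1, seed = 11)
  m <- scores(miMatrix(aln))
  expect_true(isSymmetric(m))
  for (i in 1:9) {
    for (j in (i + 1):10) {
      expect_equal(m[i, j], bruteMI(alnColumn(aln, i), alnColumn(aln, j)),
                   tolerance = 1e-12)
    }
  }
})

test_that("MI respects symmetry, nonnegativity and the entropy upper bound", {
  for (seed in c(21, 22, 23)) {
    aln <- randomAlignment(15, 12, gapRate = 0.15, seed = seed)
    enc <- coevolib:::encodeAlignment(aln)
    m <- scores(miMatrix(aln))
    expect_true(isSymmetric(m))
    off <- m[upper.tri(m)]
    expect_true(all(off >= 0, na.rm = TRUE))
    # the entropy bound holds on the pairwise-complete row subset MI is
    # computed from
    for (i in seq_len(ncol(m) - 1)) {
      for (j in seq.int(i + 1, ncol(m))) {
        if (is.na(m[i, j])) next
        ok <- !is.na(enc[, i]) & !is.na(enc[, j])
        hA <- coevolib:::columnEntropy(enc[ok, i])
        hB <- coevolib:::columnEntropy(enc[ok, j])
        expect_lte(m[i, j], min(hA, hB) + 1e-9)
      }
    }
  }
})

test_that("insufficient-data pairs become recorded missing entries, not errors", {
  aln <- ProteinAlignment(paste0("s", 1:3), c("A-D", "C-E", "D-F"))
  m <- scores(miMatrix(aln))
  expect_true(is.na(m[1, 2]))
  expect_true(is.na(m[2, 3]))
  expect_false(is.na(m[1, 3]))
})

test_that("row-column weighting reproduces the hand-worked three-column case", {
  mi <- new("MIMatrix",
            scores = matrix(c(NA, 0.4, 0.2, 0.4, NA, 0.1, 0.2, 0.1, NA), 3, 3,
                            dimnames = list(1:3, 1:3)),
            nSeqs = 10L)
  r <- rcwMatrix(mi, n = 10)
  # 0.4 / ((0.6 + 0.5 - 0.8) / 9) = 12
  expect_equal(scores(r)[1, 2], 12)
  expect_equal(scores(r)[1, 3], 0.2 / ((0.6 + 0.3 - 0.4) / 9))
  expect_error(rcwMatrix(mi, n = 1), class = "coevolib_invalid_n_error")
})

test_that("weighted scores are zero exactly where MI is zero, and equal MI gives equal RCW", {
  flat <- matrix(0.3, 4, 4, dimnames = list(1:4, 1:4)); diag(flat) <- NA
  r <- rcwMatrix(new("MIMatrix", scores = flat, nSeqs = 50L))
  off <- scores(r)[upper.tri(scores(r))]
  expect_equal(length(unique(round(off, 12))), 1)

  withZero <- matrix(c(NA, 0, 0.2, 0, NA, 0.1, 0.2, 0.1, NA), 3, 3,
                     dimnames = list(1:3, 1:3))
  r2 <- rcwMatrix(new("MIMatrix", scores = withZero, nSeqs = 50L))
  expect_equal(scores(r2)[1, 2], 0)
  expect_gt(scores(r2)[1, 3], 0)
})

test_that("pair ranking is invariant to the normalization convention", {
  aln <- randomAlignment(40, 12, seed = 33)
  mi <- miMatrix(aln)
  rSeq <- scores(rcwMatrix(mi, nMode = "sequences"))
  rCol <- scores(rcwMatrix(mi, nMode = "columns"))
  utSeq <- rSeq[upper.tri(rSeq)]
  utCol <- rCol[upper.tri(rCol)]
  expect_equal(order(-utSeq), order(-utCol))
  # n enters as a common positive factor
  expect_equal(utSeq / utCol, rep((40 - 1) / (12 - 1), length(utSeq)),
               tolerance = 1e-12)
})

test_that("selection reports pairs in query numbering with wild-type residues", {
  sim <- simulateCoevolvingAlignment(150, 12, list(c(2, 9)), coupling = 1, seed = 4)
  aln <- sim$alignment
  rcw <- rcwMatrix(miMatrix(aln))
  cmap <- columnToQueryMap(aln)
  top1 <- selectCoevolvingPairs(rcw, cmap, rule = "topk", topK = 1)
  expect_equal(nrow(top1), 1)
  expect_equal(c(top1$siteA, top1$siteB), c(2, 9))
  expect_equal(top1$wtA, cmap$wt[cmap$residue == top1$siteA])
  expect_true(top1$siteA < top1$siteB)
  expect_equal(attr(top1, "sites"), c(2, 9))

  # a threshold above every score selects nothing, without error
  expect_message(
    none <- selectCoevolvingPairs(rcw, cmap, rule = "zscore", z = 1e6),
    "no pairs")
  expect_equal(nrow(none), 0)
})

test_that("zscore selection keeps only standout pairs", {
  sim <- simulateCoevolvingAlignment(200, 20, list(c(3, 11), c(5, 17)),
                                     coupling = 1, seed = 9)
  rcw <- rcwMatrix(miMatrix(sim$alignment))
  cmap <- columnToQueryMap(sim$alignment)
  sel <- selectCoevolvingPairs(rcw, cmap, rule = "zscore", z = 2)
  got <- mapply(function(a, b) paste(sort(c(a, b)), collapse = "-"),
                sel$siteA, sel$siteB)
  expect_true(all(c("3-11", "5-17") %in% got))
  expect_equal(sel$rank, seq_len(nrow(sel)))
  expect_true(all(diff(sel$rcw) <= 0))
})

test_that("site distance statistics match hand-computed geometry", {
  two <- matrix(c(0, 0, 0, 5, 0, 0), ncol = 3, byrow = TRUE,
                dimnames = list(c(1, 2), NULL))
  expect_equal(unname(siteDistanceStats(c(1, 2), two)), c(5, 0))

  tri <- matrix(c(0, 0, 0, 3, 0, 0, 0, 4, 0), ncol = 3, byrow = TRUE,
                dimnames = list(c(10, 20, 30), NULL))
  st <- siteDistanceStats(c(10, 20, 30), tri)
  expect_equal(unname(st["mean"]), 4)  # distances 3, 4, 5
  expect_equal(unname(st["sd"]), 1)

  expect_error(siteDistanceStats(10, tri),
               class = "coevolib_insufficient_sites_error")
  expect_error(siteDistanceStats(c(10, 99), tri),
               class = "coevolib_missing_coordinate_error")
})
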