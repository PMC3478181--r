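IUPAC_LETTERS <- c(A = 1, C = 1, G = 1, T = 1, M = 2, R = 2, W = 2, S = 2,
                   Y = 2, K = 2, V = 3, H = 3, D = 3, B = 3, N = 4)

test_that("degenerate expansion size is the product of per-letter degeneracies", {
  # across all 15 IUPAC letters, in varying positions
  set.seed(7)
  for (i in 1:20) {
    letters3 <- sample(names(IUPAC_LETTERS), 3, replace = TRUE)
    code <- paste(letters3, collapse = "")
    expect_equal(length(expandDegenerateCodon(code)),
                 prod(IUPAC_LETTERS[letters3]), info = code)
  }
  expect_equal(expandDegenerateCodon("ATG"), "ATG")
  expect_equal(length(expandDegenerateCodon("NNN")), 64)
  expect_error(expandDegenerateCodon("NNZ"), class = "coevolib_invalid_code_error")
})

test_that("NNK covers 32 codons, all 20 amino acids and exactly one stop", {
  exp <- expandDegenerateCodon("NNK")
  expect_length(exp, 32)
  expect_true(all(substr(exp, 3, 3) %in% c("G", "T")))
  tr <- translateCodonSet(exp)
  expect_length(tr$aminoAcids, 20)
  expect_equal(tr$stopCodons, "TAG")
  # every amino acid encoded at least once
  aa <- Biostrings::GENETIC_CODE[exp]
  expect_true(all(table(aa[aa != "*"]) >= 1))
})

test_that("codon translation separates amino acids from stops and validates input", {
  expect_equal(translateCodonSet("ATG"), list(aminoAcids = "M", stopCodons = character(0)))
  expect_equal(translateCodonSet(c("TAA", "TGA", "TAG"))$stopCodons,
               c("TAA", "TAG", "TGA"))
  expect_error(translateCodonSet("AUG"), class = "coevolib_invalid_codon_error")
})

test_that("minimum codon changes is the positionwise Hamming distance and a metric", {
  expect_equal(minCodonChanges("GGC", "GGG"), 1)
  expect_equal(minCodonChanges("AAT", "TGT"), 2)
  expect_equal(minCodonChanges("ACT", "ACT"), 0)
  expect_error(minCodonChanges("AC", "ACT"), class = "coevolib_invalid_codon_error")

  set.seed(11)
  codons <- replicate(12, paste(sample(c("A", "C", "G", "T"), 3, TRUE), collapse = ""))
  for (i in 1:10) {
    trip <- sample(codons, 3)
    dxy <- minCodonChanges(trip[1], trip[2])
    dyx <- minCodonChanges(trip[2], trip[1])
    dyz <- minCodonChanges(trip[2], trip[3])
    dxz <- minCodonChanges(trip[1], trip[3])
    expect_equal(dxy, dyx)
    expect_lte(dxz, dxy + dyz)
    expect_equal(minCodonChanges(trip[1], trip[1]), 0)
  }
})

test_that("primer construction centers the degenerate codon with verbatim flanks", {
  cds <- paste(rep("GCTGAAGTT", 20), collapse = "")  # 60 codons
  p <- designPrimerPair(cds, site = 20, code = "NNK", primerLength = 33)
  expect_s4_class(p, "PrimerPair")
  expect_equal(nchar(p@forward), 33)
  expect_equal(p@degenerateOffset, 15L)
  expect_equal(substr(p@forward, 16, 18), "NNK")
  # flanks copied verbatim from the CDS around codon 20 (bases 58-60)
  expect_equal(substr(p@forward, 1, 15), substr(cds, 43, 57))
  expect_equal(substr(p@forward, 19, 33), substr(cds, 61, 75))
  # reverse is the exact reverse complement, base by base
  expect_equal(p@reverse,
               as.character(Biostrings::reverseComplement(Biostrings::DNAString(p@forward))))

  # even flank total (length 34): extra base on the 5' side
  p34 <- designPrimerPair(cds, site = 20, primerLength = 34)
  expect_equal(p34@degenerateOffset, 16L)

  expect_error(designPrimerPair(cds, site = 2, primerLength = 33),
               class = "coevolib_flank_too_short_error")
  expect_error(designPrimerPair(substr(cds, 1, 100), site = 10),
               class = "coevolib_frame_error")
})

test_that("melting temperature follows the GC/length estimate with expected GC for degenerate bases", {
  # all-GC primer of length 33: Tm = 81.5 + 0.41*100 - 675/33
  gcOnly <- strrep("G", 33)
  expect_equal(coevolib:::primerTm(gcOnly), 81.5 + 41 - 675 / 33, tolerance = 1e-12)
  # N contributes 0.5, K contributes 0.5 expected GC
  expect_equal(coevolib:::primerTm("NNK"),
               81.5 + 0.41 * (100 * 1.5 / 3) - 675 / 3, tolerance = 1e-12)
})

test_that("two-site library accounting multiplies independent NNK draws", {
  cds <- paste(rep("GCTGAAGTT", 20), collapse = "")
  # site 10's primer dips below the 78 C guideline: warned, not rejected
  expect_warning(des <- libraryDesign(cds, sites = c(10, 30), code = "NNK"),
                 class = "coevolib_low_tm_warning")
  expect_equal(des@codonCombinations, 1024)
  expect_equal(des@aminoAcidCombinations, 400)
  expect_equal(des@stopFraction, 1 - (31 / 32)^2, tolerance = 1e-12)
  expect_length(des@primers, 2)
  expect_equal(unname(des@wildTypeCodons),
               c(substr(cds, 28, 30), substr(cds, 88, 90)))
})

test_that("library coverage follows the uniform-sampling expectation", {
  expect_equal(unname(libraryCoverage(1024, 0)), c(0, 0))
  big <- libraryCoverage(1024, 1e7)
  expect_equal(unname(big["expectedDistinct"]), 1024, tolerance = 1e-9)
  expect_equal(unname(big["completeness"]), 1, tolerance = 1e-9)
  expect_equal(unname(libraryCoverage(1024, 1001)["expectedDistinct"]),
               1024 * (1 - (1023 / 1024)^1001), tolerance = 1e-12)

  # Monte-Carlo cross-check of the closed form
  set.seed(99)
  mc <- mean(replicate(300, length(unique(sample.int(64, 100, replace = TRUE)))))
  expect_equal(unname(libraryCoverage(64, 100)["expectedDistinct"]), mc,
               tolerance = 0.02)

  # monotone nondecreasing in screening effort
  eff <- vapply(c(0, 10, 100, 1000, 5000),
                function(L) unname(libraryCoverage(1024, L)["expectedDistinct"]),
                numeric(1))
  expect_true(all(diff(eff) >= 0))
})
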