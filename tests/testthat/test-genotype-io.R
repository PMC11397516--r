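test_that("VCF GT fields map to the 0/1/2 dosage coding", {
  f <- tempfile(fileext = ".vcf")
  writeTestVcf(f, matrix(c("0/0", "0/1", "1/1"), 3, 1))
  g <- readGenotypes(f, format = "vcf")
  expect_identical(unname(genoCodes(g)[1, ]), c(0L, 1L, 2L))
  expect_identical(snpMap(g)$snp_id, sprintf("rs%03d", 1:3))
  expect_identical(snpMap(g)$pos, c(100L, 200L, 300L))
})

test_that("VCF parsing handles phased, missing and multi-sample calls", {
  f <- tempfile(fileext = ".vcf")
  writeTestVcf(f, matrix(c("0|1", "./.", "1|1", "0/0"), 2, 2, byrow = TRUE))
  g <- readGenotypes(f, format = "vcf")
  expect_identical(unname(genoCodes(g)),
                   matrix(c(1L, NA, 2L, 0L), 2, 2))
})

test_that("degenerate and non-biallelic VCF inputs are rejected", {
  f <- tempfile(fileext = ".vcf")
  writeLines(character(0), f)
  expect_error(readGenotypes(f, format = "vcf"), "empty")
  f2 <- tempfile(fileext = ".vcf")
  writeTestVcf(f2, matrix(c("0/0", "1/2"), 2, 1), alt = c("T", "T,G"))
  expect_error(readGenotypes(f2, format = "vcf"), "non-biallelic")
})

test_that("matrix format round-trips codes, ids and map exactly", {
  g <- simulateGenotypes(20, 50, missingRate = 0.05, seed = 7)
  mf <- tempfile(fileext = ".tsv")
  mp <- tempfile(fileext = ".map.tsv")
  writeGenotypes(g, mf, mapFile = mp)
  g2 <- readGenotypes(mf, format = "matrix", mapFile = mp)
  expect_identical(genoCodes(g2), genoCodes(g))
  expect_identical(accessionIds(g2), accessionIds(g))
  expect_identical(snpMap(g2), snpMap(g))
})

test_that("VCF and matrix representations of the same calls agree", {
  gt <- matrix(c("0/0", "0/1", "1/1", "0/1", "./.", "0/0"), 3, 2)
  f <- tempfile(fileext = ".vcf")
  writeTestVcf(f, gt)
  gv <- readGenotypes(f, format = "vcf")
  mf <- tempfile(fileext = ".tsv")
  mp <- tempfile(fileext = ".map.tsv")
  writeGenotypes(gv, mf, mapFile = mp)
  gm <- readGenotypes(mf, format = "matrix", mapFile = mp)
  expect_identical(genoCodes(gm), genoCodes(gv))
  expect_identical(snpMap(gm), snpMap(gv))
})

test_that("matrix reader rejects out-of-range codes", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("accession\ts1\ts2", "a1\t0\t3"), f)
  expect_error(readGenotypes(f, format = "matrix"), "0, 1, 2 or NA")
})

test_that("trait tables are validated on read", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("accession\ttrait", "A\t1.5", "B\t2.5"), f)
  tr <- readTraits(f)
  expect_identical(tr, c(A = 1.5, B = 2.5))

  writeLines(c("accession\ttrait", "A\t1.5", "A\t2.5"), f)
  expect_error(readTraits(f), "duplicated")

  writeLines(c("accession\ttrait", "A\t1.5", "B\tabc"), f)
  expect_error(readTraits(f), "row 3")
})

test_that("synthetic trait files round-trip with finite values", {
  g <- tinyPanel()
  f <- tempfile(fileext = ".tsv")
  writeTraits(traitValues(g), f)
  tr <- readTraits(f)
  expect_length(tr, 30)
  expect_true(all(is.finite(tr)))
  expect_equal(tr, traitValues(g))
})

test_that("GenotypeSet enforces its invariants", {
  expect_error(GenotypeSet(matrix(c(0L, 5L), 1, 2)), "0, 1 or 2")
  codes <- matrix(0L, 2, 2, dimnames = list(c("a", "a"), c("s1", "s2")))
  expect_error(GenotypeSet(codes), "unique")
  g <- GenotypeSet(matrix(0:1, 2, 2, dimnames = list(c("a", "b"), NULL)))
  expect_error(traitValues(g, "t") <- c(a = 1), "missing for accessions")
})
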