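test_that("pixel encoding is one-hot per genotype state", {
  expect_identical(encodePixel(0L), c(R = 1, G = 0, B = 0))
  expect_identical(encodePixel(1L), c(R = 0, G = 1, B = 0))
  expect_identical(encodePixel(2L), c(R = 0, G = 0, B = 1))
  expect_identical(encodePixel(NA_integer_), c(R = 0, G = 0, B = 0))
  expect_error(encodePixel(3L), "0, 1, 2 or NA")
})

test_that("cyclic row-major layout repeats the SNP list", {
  a <- encodeAIO(c(0L, 1L, 2L), width = 3, height = 2)
  px <- aioPixels(a)
  for (y in 1:2) {
    expect_identical(px[y, 1, ], c(1, 0, 0))
    expect_identical(px[y, 2, ], c(0, 1, 0))
    expect_identical(px[y, 3, ], c(0, 0, 1))
  }
  # SNP 1 of 6642 appears at 0-based pixel offsets 0, 6642, 13284 at 128x128
  idx <- snpPixelIndex(128, 128, 6642)
  flat <- as.vector(t(idx))                  # row-major pixel order
  expect_identical(which(flat == 1L) - 1L, c(0L, 6642L, 13284L))
})

test_that("every SNP occupies floor or ceiling of 16384/n pixels", {
  for (n in c(100L, 300L, 6642L, 16384L)) {
    idx <- snpPixelIndex(128, 128, n)
    counts <- tabulate(idx, nbins = n)
    expect_true(all(counts %in% c(16384L %/% n, 16384L %/% n + 1L)))
    expect_identical(sum(counts), 16384L)
  }
})

test_that("encode/decode round trip is the identity, missing included", {
  set.seed(42)
  for (rep in 1:5) {
    v <- sample(c(0L, 1L, 2L, NA), 100, replace = TRUE)
    a <- encodeAIO(v, width = 16, height = 16)
    expect_identical(decodeAIO(a), v)
  }
  # default layout
  v <- sample(c(0L, 1L, 2L, NA), 100, replace = TRUE)
  expect_identical(decodeAIO(encodeAIO(v)), v)
})

test_that("channel sums count the non-missing pixels", {
  v <- c(0L, NA, 2L, 1L, NA)
  a <- encodeAIO(v, width = 5, height = 4)
  px <- aioPixels(a)
  idx <- snpPixelIndex(5, 4, 5)
  expect_equal(sum(px), sum(!is.na(v[idx])))
})

test_that("degenerate encodings are rejected", {
  expect_error(encodeAIO(integer(0)), "empty")
  expect_error(encodeAIO(rep(0L, 10), width = 3, height = 3), "too small")
  expect_error(encodeAIO(c(0L, 7L), width = 2, height = 2), "position 2")
})

test_that("decoding detects corrupted images", {
  a <- encodeAIO(c(0L, 1L, 2L), width = 3, height = 2)
  px <- aioPixels(a)
  px[2, 1, 1] <- 0; px[2, 1, 2] <- 1        # SNP 1 conflicting placement
  b <- new("AIO", pixels = px, nSnps = 3L, accession = NA_character_)
  expect_error(decodeAIO(b), "conflicting")
  bad <- px; bad[1, 1, 2] <- 1              # two channels on
  expect_error(decodeAIO(new("AIO", pixels = bad, nSnps = 3L,
                             accession = NA_character_)),
               "one-hot")
  zero <- new("AIO", pixels = array(0, c(2, 3, 3)), nSnps = 5L,
              accession = NA_character_)
  expect_identical(decodeAIO(zero), rep(NA_integer_, 5))
})
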