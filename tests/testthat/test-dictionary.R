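test_that("block extraction yields the expected block count and content", {
  a <- encodeAIO(rep(c(0L, 1L, 2L), length.out = 500), width = 128,
                 height = 128, accession = "x1")
  b <- extractBlocks(list(a), blockSide = 16)
  expect_identical(nrow(b$blocks), 64L)
  expect_identical(ncol(b$blocks), 16L * 16L * 3L)
  # first block must equal the top-left 16x16 patch, flattened channel-wise
  expect_identical(b$blocks[1, ], as.vector(aioPixels(a)[1:16, 1:16, ]))

  many <- replicate(10, a, simplify = FALSE)
  expect_identical(nrow(extractBlocks(many, 16)$blocks), 640L)
  expect_error(extractBlocks(list(a), blockSide = 15), "configuration error")
})

test_that("planted orthonormal dictionaries are recovered to ~zero error", {
  set.seed(5)
  d <- 48
  A <- qr.Q(qr(matrix(rnorm(d * 4), d, 4)))
  C <- matrix(rexp(200 * 4), 200, 4) * matrix(rbinom(800, 1, 0.6), 200, 4)
  X <- C %*% t(A)
  dict <- learnDictionary(X, nAtoms = 4, targetError = 1e-7,
                          maxSparsity = 4, maxIter = 50, seed = 1)
  expect_lt(dict@trainError, 1e-6)
  expect_true(dict@converged)
  expect_equal(unname(sqrt(rowSums(dictAtoms(dict)^2))), rep(1, 4))
})

test_that("constant blocks collapse onto a single proportional atom", {
  X <- matrix(rep(c(1, 0, 2), each = 20), 5, 12, byrow = TRUE)
  X <- matrix(rep(X[1, ], 5), 5, 12, byrow = TRUE)
  dict <- learnDictionary(X, nAtoms = 1, targetError = 1e-9,
                          maxSparsity = 1, maxIter = 10, seed = 1)
  expect_lt(dict@trainError, 1e-9)
  a1 <- dictAtoms(dict)[1, ]
  expect_equal(abs(sum(a1 * X[1, ])), sqrt(sum(X[1, ]^2)), tolerance = 1e-8)
})

test_that("dictionary learning is reproducible under a fixed seed", {
  g <- tinyPanel()
  blocks <- extractBlocks(AIOpred:::.encodeAll(g, 16), 4)
  d1 <- suppressWarnings(learnDictionary(blocks, nAtoms = 8, maxIter = 5,
                                         seed = 3))
  d2 <- suppressWarnings(learnDictionary(blocks, nAtoms = 8, maxIter = 5,
                                         seed = 3))
  expect_identical(dictAtoms(d1), dictAtoms(d2))
  expect_error(learnDictionary(blocks$blocks[1:4, ], nAtoms = 8),
               "at least as many blocks")
})

test_that("the iteration cap is reported when the error target is missed", {
  g <- tinyPanel()
  blocks <- extractBlocks(AIOpred:::.encodeAll(g, 16), 4)
  expect_warning(d <- learnDictionary(blocks, nAtoms = 8,
                                      targetError = 1e-4, maxIter = 2,
                                      seed = 1),
                 "iteration cap")
  expect_false(d@converged)
  expect_identical(d@iterations, 2L)
})

test_that("OMP recovers exact coefficients for orthonormal atoms", {
  set.seed(8)
  A <- qr.Q(qr(matrix(rnorm(27 * 3), 27, 3)))       # 3 orthonormal atoms
  dict <- new("SnpDictionary", atoms = t(A), blockSide = 3L,
              targetError = 1e-9, maxSparsity = 10L, trainError = 0,
              iterations = 1L, converged = TRUE, seed = 1L)
  # a block equal to one atom
  sc <- sparseCode(matrix(A[, 2], 1, 27), dict)
  expect_equal(as.numeric(sc@coef[1, ]), c(0, 1, 0), tolerance = 1e-10)
  # 2*atom_a + 3*atom_b has the closed-form decomposition {2, 3}
  x <- 2 * A[, 1] + 3 * A[, 3]
  sc2 <- sparseCode(matrix(x, 1, 27), dict)
  expect_equal(as.numeric(sc2@coef[1, ]), c(2, 0, 3), tolerance = 1e-10)
  expect_lt(sc2@relres[1], 1e-10)
  expect_error(sparseCode(matrix(0, 1, 5), dict), "does not match")
})

test_that("OMP residuals decrease with the sparsity budget, atoms unrepeated", {
  set.seed(9)
  D <- matrix(rnorm(6 * 20), 6, 20)
  D <- D / sqrt(rowSums(D^2))
  x <- matrix(rnorm(20), 1, 20)
  res <- sapply(1:5, function(s) {
    cd <- AIOpred:::.omp_encode_batch(x, D, s, 0)
    expect_lte(anyDuplicated(cd$j), 0L)       # never the same atom twice
    cd$relres[1]
  })
  expect_true(all(diff(res) <= 1e-12))
  expect_true(all(res > 0))
})
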