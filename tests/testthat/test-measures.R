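test_that("block census counts 3x3 configurations and conserves eta", {
  # all-quiescent diagram: no non-quiescent positions, 64 interior windows
  h0 <- block_census(matrix(0L, 10, 10))
  expect_equal(h0$eta, 0L)
  expect_equal(h0$nu_zero, 64L)
  expect_equal(sum(h0$counts[-1L]), 0L)

  # one interior 1 is seen by exactly nine windows, each a distinct one-hot
  m1 <- matrix(0L, 10, 10); m1[5L, 5L] <- 1L
  h1 <- block_census(m1)
  expect_equal(h1$eta, 9L)
  pos <- h1$counts[-1L][h1$counts[-1L] > 0L]
  expect_equal(length(pos), 9L)
  expect_true(all(pos == 1L))
  # the nine configurations are the nine powers of two
  expect_setequal(which(h1$counts > 0L) - 1L, c(0L, 2L^(0:8)))

  # every interior window of a checkerboard contains 1s
  cb <- outer(1:10, 1:10, function(i, j) (i + j) %% 2L)
  expect_equal(block_census(cb)$eta, 64L)

  expect_error(block_census(matrix(0L, 2, 5)), "3x3")
})

test_that("census matches a position-by-position oracle on random fields", {
  set.seed(41)
  for (i in 1:8) {
    L <- matrix(as.integer(stats::runif(15 * 12) < stats::runif(1)), 15, 12)
    got <- block_census(L)
    want <- oracle_census(L)
    expect_equal(got$eta, want$eta)
    expect_equal(got$nu_zero, want$nu_zero)
    expect_equal(sort(got$counts[-1L][got$counts[-1L] > 0L]), want$counts)
    # conservation: non-zero configuration counts sum exactly to eta
    expect_identical(sum(got$counts[-1L]), got$eta)
  }
})

test_that("entropy and diversity follow their closed forms", {
  m1 <- matrix(0L, 10, 10); m1[5L, 5L] <- 1L
  h1 <- block_census(m1)
  expect_equal(shannon_entropy(h1), log(9))       # nine equiprobable configs
  expect_equal(simpson_diversity(h1), 1 / 9)
  expect_equal(shannon_entropy(h1, base = 2), log2(9))

  # all-quiescent: both measures are zero by convention
  h0 <- block_census(matrix(0L, 6, 6))
  expect_equal(shannon_entropy(h0), 0)
  expect_equal(simpson_diversity(h0), 0)

  # a single recurring configuration: zero entropy, full concentration
  ones <- block_census(matrix(1L, 8, 8))
  expect_equal(shannon_entropy(ones), 0)
  expect_equal(simpson_diversity(ones), 1)

  # uniform over m configurations gives S = 1/m on any diagram
  set.seed(43)
  L <- matrix(as.integer(stats::runif(20 * 20) < 0.5), 20, 20)
  h <- block_census(L)
  p <- h$counts[-1L][h$counts[-1L] > 0L] / h$eta
  expect_equal(simpson_diversity(h), sum(p^2))
  # S = 1 exactly when H = 0 (eta > 0)
  expect_true((simpson_diversity(ones) == 1) == (shannon_entropy(ones) == 0))
  expect_false(simpson_diversity(h) == 1)
  expect_gt(shannon_entropy(h), 0)
})

test_that("space filling and expressiveness are simple ratios", {
  expect_equal(space_filling(matrix(1L, 5, 5)), 1)
  expect_equal(space_filling(matrix(0L, 5, 5)), 0)
  cb <- outer(1:10, 1:10, function(i, j) (i + j) %% 2L)
  expect_equal(space_filling(cb), 0.5)

  expect_equal(expressiveness(1.9, 0.5), 3.8)
  expect_equal(expressiveness(1.2, 0.1), 12)
  expect_equal(expressiveness(0, 0.7), 0)
  expect_warning(e0 <- expressiveness(1, 0), "undefined")
  expect_equal(e0, 0)
})

test_that("measures are invariant under mirroring and interior translation", {
  d <- unclass(ca_evolve("f7", init_random(80, 0.5, seed = 17), steps = 60))
  mir <- d[, ncol(d):1]
  expect_equal(shannon_entropy(block_census(mir)),
               shannon_entropy(block_census(d)))
  expect_equal(simpson_diversity(block_census(mir)),
               simpson_diversity(block_census(d)))
  expect_equal(space_filling(mir), space_filling(d))

  # translating a pattern within the interior leaves the census unchanged
  m1 <- matrix(0L, 12, 12); m1[4L, 4L] <- 1L
  m2 <- matrix(0L, 12, 12); m2[8L, 9L] <- 1L
  expect_equal(block_census(m1)$counts, block_census(m2)$counts)
})

test_that("deflate size behaves as a compressibility measure", {
  set.seed(47)
  quiet <- matrix(0L, 501, 500)
  noisy <- matrix(as.integer(stats::runif(501 * 500) < 0.5), 501, 500)
  expect_lt(lz_complexity(quiet), lz_complexity(noisy))
  expect_identical(lz_complexity(noisy), lz_complexity(noisy))
  expect_identical(lz_complexity(noisy, "png-fixed"),
                   lz_complexity(noisy, "png-fixed"))

  # the pinned PNG's on-disk size is the png-fixed measure
  d <- ca_evolve("f7", init_random(120, 0.5, seed = 5), steps = 120)
  tf <- withr::local_tempfile(fileext = ".png")
  write_diagram(d, tf, "png")
  expect_equal(file.info(tf)$size, lz_complexity(d, "png-fixed"))
})

test_that("measure records assemble the full complexity vector coherently", {
  rec <- measure_rule("f7", cells = 120, steps = 120, seed = 2)
  expect_s3_class(rec, "tbl_df")
  expect_equal(rec$arity, 2L)
  expect_equal(rec$lz_per_n, rec$lz_deflate / 2)
  expect_equal(rec$E * rec$D, rec$H, tolerance = 1e-12)
  expect_true(rec$S >= 0 && rec$S <= 1 && rec$D >= 0 && rec$D <= 1)

  # constant-false: only the initial row contributes mass
  row0 <- init_random(120, 0.5, seed = 2)
  rec0 <- measure_rule("const0", cells = 120, steps = 120, seed = 2)
  expect_equal(rec0$D, sum(row0) / (121 * 120))

  # chaotic XOR is more complex than saturating OR under the same seed
  rec_or <- measure_rule("f2", cells = 120, steps = 120, seed = 2)
  expect_gt(rec$H, rec_or$H)
  expect_gt(rec$lz_deflate, rec_or$lz_deflate)
  expect_gt(1 - rec$S, 1 - rec_or$S)   # XOR's census is the more diverse
})

test_that("catalogue-wide measurement returns one coherent row per id", {
  ids <- c("f2", "f7", "f8", "f23")
  tab <- measure_catalog(ids, cells = 100, steps = 100, seed = 3)
  expect_equal(tab$id, ids)
  expect_true(all(tab$E[tab$D > 0] * tab$D[tab$D > 0] - tab$H[tab$D > 0] < 1e-12))
  expect_equal(tab$seed, rep(3L, 4L))
})
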