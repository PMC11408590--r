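test_that("neighbourhood layouts exclude the centre and are symmetric", {
  for (k in c(2L, 4L, 8L)) {
    off <- neighbourhood_offsets(k)
    expect_length(off, k)
    expect_false(0L %in% off)
    expect_equal(off, sort(off))
    expect_equal(off, -rev(off))
  }
  expect_error(neighbourhood_offsets(3), "arity")
})

test_that("single steps match hand-iterated updates", {
  xor2 <- get_rule("f7")
  or2 <- get_rule("f2")
  and2 <- get_rule("f23")

  expect_equal(ca_step(c(0, 0, 1, 0, 0), xor2), c(0L, 1L, 0L, 1L, 0L))
  r1 <- ca_step(c(0, 0, 1, 0, 0), or2)
  expect_equal(r1, c(0L, 1L, 0L, 1L, 0L))        # OR of side neighbours
  expect_equal(ca_step(r1, or2), c(1L, 0L, 1L, 0L, 1L))
  # AND of the two neighbours never fires around a lone seed
  expect_equal(ca_step(c(0, 0, 1, 0, 0), and2), rep(0L, 5L))
})

test_that("vectorised stepping agrees with a per-cell oracle on random rows", {
  set.seed(31)
  for (i in 1:12) {
    rs <- random_sop_text()
    tab <- truth_table(parse_sop(rs$text, arity = rs$arity))
    config <- as.integer(stats::runif(40) < 0.5)
    for (b in c("fixed", "periodic")) {
      expect_equal(ca_step(config, tab, b),
                   oracle_step(config, tab$outputs, tab$arity,
                               if (b == "fixed") "zero" else "periodic"),
                   info = paste(rs$text, b))
    }
  }
})

test_that("evolution stores the initial row and every synchronous image", {
  d <- ca_evolve("f7", init_single_seed(21), steps = 10)
  expect_s3_class(d, "ca_diagram")
  expect_equal(dim(unclass(d)), c(11L, 21L))
  expect_equal(unclass(d)[1L, ], init_single_seed(21))
  for (t in 1:10)
    expect_equal(unclass(d)[t + 1L, ], ca_step(unclass(d)[t, ], get_rule("f7")))

  # constant-false: everything after the initial row is quiescent
  dc <- ca_evolve("const0", init_random(30, 0.5, seed = 3), steps = 5)
  expect_true(all(unclass(dc)[-1L, ] == 0L))

  # NAND fires everywhere on an all-zero row
  dn <- ca_evolve("f1", integer(30), steps = 1)
  expect_equal(unclass(dn)[2L, ], rep(1L, 30L))
})

test_that("single-seed XOR evolution is Pascal's triangle mod 2", {
  steps <- 40L
  d <- ca_evolve("f7", init_single_seed(101), steps = steps)
  expect_equal(unclass(d)[, ], oracle_sierpinski(steps, 101))
})

test_that("initial-condition builders honour their contracts", {
  expect_equal(init_single_seed(5), c(0L, 0L, 1L, 0L, 0L))
  expect_equal(which(init_two_seeds(500, 200) == 1L), c(50L, 450L))
  expect_equal(which(init_two_seeds(9, 2) == 1L), c(3L, 7L))
  expect_error(init_two_seeds(500, 260), "out of range")
  expect_error(init_two_seeds(500, 0), "out of range")

  expect_equal(init_random(10, 0, seed = 5), integer(10))
  expect_equal(init_random(10, 1, seed = 5), rep(1L, 10L))
  expect_equal(init_random(200, 0.5, seed = 9), init_random(200, 0.5, seed = 9))
  expect_false(identical(init_random(200, 0.5, seed = 9),
                         init_random(200, 0.5, seed = 10)))
})

test_that("period detection finds short cycles and rejects chaos", {
  expect_equal(detect_period(matrix(0L, 40, 6)), 1L)
  alt <- matrix(rep(c(0L, 1L), each = 6, times = 20), ncol = 6, byrow = TRUE)
  expect_equal(detect_period(alt), 2L)
  expect_error(detect_period(matrix(0L, 10, 6)), "rows")

  d <- ca_evolve("f7", init_random(500, 0.5, seed = 4), steps = 500)
  expect_true(is.na(detect_period(d, max_period = 16L)))
})

test_that("periodic-boundary evolution is shift equivariant", {
  rot <- function(x, s) x[((seq_along(x) - 1L + s) %% length(x)) + 1L]
  init <- init_random(64, 0.4, seed = 8)
  for (id in c("f7", "f11", "f36")) {
    d0 <- unclass(ca_evolve(id, init, steps = 30, boundary = "periodic"))
    d1 <- unclass(ca_evolve(id, rot(init, 5L), steps = 30, boundary = "periodic"))
    expect_equal(d1, t(apply(d0, 1L, rot, 5L)), ignore_attr = TRUE, info = id)
  }
})

test_that("absorbing boundaries confine differences to the light cone", {
  init1 <- init_random(201, 0.5, seed = 12)
  init2 <- init1
  flip <- 101L
  init2[flip] <- 1L - init2[flip]
  for (id in c("f7", "f20")) {
    radius <- max(neighbourhood_offsets(get_rule(id)$arity))
    d1 <- unclass(ca_evolve(id, init1, steps = 40))
    d2 <- unclass(ca_evolve(id, init2, steps = 40))
    for (t in 0:40) {
      changed <- which(d1[t + 1L, ] != d2[t + 1L, ])
      if (length(changed))
        expect_true(all(abs(changed - flip) <= radius * t), info = id)
    }
  }
})
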