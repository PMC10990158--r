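test_that("truth tables enumerate gates correctly and carry uniform weight", {
  tt_and <- and2_table()
  expect_equal(nrow(tt_and), 4L)
  expect_equal(tt_and$y, c(0L, 0L, 0L, 1L))
  expect_equal(tt_and$prob, rep(0.25, 4))

  tt_xor <- xor2_table()
  expect_equal(tt_xor$y, c(0L, 1L, 1L, 0L))

  # lexicographic order, input 1 most significant
  expect_equal(tt_and$x1, c(0L, 0L, 1L, 1L))
  expect_equal(tt_and$x2, c(0L, 1L, 0L, 1L))

  tt10 <- truth_table(generate_circuit(10, 9, seed = 3))
  expect_equal(nrow(tt10), 1024L)
  expect_equal(sum(tt10$prob), 1, tolerance = 1e-12)
})

test_that("truth-table rows agree with direct circuit evaluation", {
  circ <- generate_circuit(6, 7, seed = 11)
  tt <- truth_table(circ)
  X <- as.matrix(tt[paste0("x", 1:6)])
  expect_equal(tt$y, eval_circuit(circ, X))
})

test_that("subset information matches hand-enumerable values", {
  tt_and <- and2_table()
  tt_xor <- xor2_table()
  # counting oracle: H(Y) = h(1/4), H(Y|X1) = 0.5 -> 0.811278 - 0.5
  expect_equal(subset_information(tt_and, 1), 0.311278, tolerance = 1e-6)
  # parity hides single inputs
  expect_equal(subset_information(tt_xor, 1), 0)
  expect_equal(subset_information(tt_xor, integer(0)), 0)
  # Y deterministic given all inputs: I = H(Y)
  hy <- -0.25 * log2(0.25) - 0.75 * log2(0.75)
  expect_equal(subset_information(tt_and, 1:2), hy, tolerance = 1e-12)
  expect_equal(subset_information(tt_xor, 1:2), 1, tolerance = 1e-12)
})

test_that("subset frontier equals an independent brute-force enumeration", {
  circ <- generate_circuit(3, 3, seed = 5)
  tt <- truth_table(circ)
  fr <- subset_frontier(tt)
  expect_equal(nrow(fr), 8L)

  # independent oracle: direct probability bookkeeping over explicit subsets
  brute_mi <- function(tt, subset) {
    p1 <- sum(tt$prob[tt$y == 1])
    hy <- ifelse(p1 %in% c(0, 1), 0, -p1 * log2(p1) - (1 - p1) * log2(1 - p1))
    if (!length(subset)) return(0)
    key <- apply(as.matrix(tt[paste0("x", subset)]), 1, paste, collapse = "")
    hyx <- 0
    for (k in unique(key)) {
      pk <- sum(tt$prob[key == k])
      pk1 <- sum(tt$prob[key == k & tt$y == 1]) / pk
      if (pk1 > 0 && pk1 < 1) {
        hyx <- hyx - pk * (pk1 * log2(pk1) + (1 - pk1) * log2(1 - pk1))
      }
    }
    hy - hyx
  }
  for (i in seq_len(nrow(fr))) {
    expect_equal(fr$mi_bits[i], brute_mi(tt, fr$subset[[i]]),
                 tolerance = 1e-12)
  }
  env <- attr(fr, "envelope")
  expect_equal(env$mi_bits[env$size == 0], 0)
  expect_equal(env$mi_bits[env$size == 3], subset_information(tt, 1:3))
  expect_true(all(diff(env$mi_bits) >= -1e-9))
})

test_that("10-input frontier has one entry per subset and 45 pairs", {
  tt <- truth_table(generate_circuit(10, 9, seed = 7))
  fr <- subset_frontier(tt)
  expect_equal(nrow(fr), 1024L)
  expect_equal(sum(fr$size == 2), 45L)
})

test_that("subset information is monotone under subset inclusion", {
  circ <- generate_circuit(8, 8, seed = 13)
  tt <- truth_table(circ)
  fr <- subset_frontier(tt)
  mi <- fr$mi_bits
  masks <- 0:(2^8 - 1)
  # S subset of T iff bitand(S, T) == S; check every pair via mask arithmetic
  for (s in masks) {
    supersets <- masks[bitwAnd(masks, s) == s]
    expect_true(all(mi[supersets + 1] >= mi[s + 1] - 1e-9))
  }
})

test_that("seeded generation is deterministic and validates arguments", {
  expect_identical(generate_circuit(10, 9, seed = 7),
                   generate_circuit(10, 9, seed = 7))
  expect_false(identical(generate_circuit(10, 9, seed = 7),
                         generate_circuit(10, 9, seed = 8)))
  expect_error(generate_circuit(0, 3), class = "dibs_invalid_argument")
  expect_error(generate_circuit(5, 0), class = "dibs_invalid_argument")
  expect_error(generate_circuit(10, 3), class = "dibs_invalid_argument")
  expect_error(subset_information(and2_table(), 5),
               class = "dibs_invalid_argument")
  big <- boolean_circuit(21, list(list(op = "AND", args = c(1, 2))))
  expect_error(truth_table(big), class = "dibs_enumeration_too_large")
})

test_that("every input of a generated circuit influences the output", {
  for (seed in 1:5) {
    circ <- generate_circuit(7, 8, seed = seed)
    tt <- truth_table(circ)
    # flipping any single input must change the output on some assignment
    X <- as.matrix(tt[paste0("x", 1:7)])
    for (i in 1:7) {
      Xf <- X
      Xf[, i] <- 1L - Xf[, i]
      expect_true(any(eval_circuit(circ, Xf) != tt$y),
                  label = sprintf("seed %d input %d", seed, i))
    }
  }
})

test_that("circuit JSON and truth-table CSV round-trip", {
  circ <- generate_circuit(5, 6, seed = 2)
  fj <- withr::local_tempfile(fileext = ".json")
  write_circuit(circ, fj)
  expect_identical(read_circuit(fj)$gates, circ$gates)

  tt <- truth_table(circ)
  fc <- withr::local_tempfile(fileext = ".csv")
  write_truth_table(tt, fc)
  back <- read_truth_table(fc)
  expect_equal(back$y, tt$y)
  expect_equal(back$prob, tt$prob)
  expect_equal(subset_information(back, c(1, 3)),
               subset_information(tt, c(1, 3)))
})
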