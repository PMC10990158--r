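make_plane_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tt <- and2_table()
      sw <- dib_sweep(tt, beta_start = 1e-4, beta_end = 2, n_steps = 2500,
                      warmup = 750, latent_dim = 2, decoder_hidden = c(32, 32),
                      n_checkpoints = 8, seed = 5)
      plane <- info_plane(sw, tt, K = 512, n_batches = 4,
                          n_label_samples = 8, seed = 6)
      cache <<- list(tt = tt, sw = sw, plane = plane)
    }
    cache
  }
})

test_that("a fresh model sits at the information-plane origin", {
  tt <- and2_table()
  sw <- dib_sweep(tt, beta_start = 1, beta_end = 1, n_steps = 2,
                  latent_dim = 2, decoder_hidden = c(8), n_checkpoints = 2,
                  lr = 0, channel_init_sd = 0,
                  seed = 1)  # lr 0: parameters stay at initialization
  plane <- info_plane(sw, tt, checkpoints = 1, K = 256, n_batches = 4,
                      seed = 2)
  expect_lt(abs(plane$total_bits), 0.02)
  expect_lt(abs(plane$predictive_bits), 0.02)
})

test_that("info_plane yields one ordered point per checkpoint", {
  fx <- make_plane_fixture()
  plane <- fx$plane
  expect_equal(nrow(plane), length(fx$sw$checkpoints))
  expect_true(!is.unsorted(plane$total_bits))
  expect_true(all(vapply(plane$allocation, function(a)
    abs(sum(a)) >= -1e-9, logical(1))))
  expect_true(all(unlist(plane$allocation) >= -0.01))
  expect_true(all(plane$accuracy >= 0 & plane$accuracy <= 1))
  # totals are the sum of the allocation vector
  expect_equal(plane$total_bits,
               vapply(plane$allocation, sum, numeric(1)),
               tolerance = 1e-9)
  # final point of the sweep recovers H(Y) on the deterministic circuit
  expect_equal(max(plane$predictive_bits), attr(plane, "entropy_bits"),
               tolerance = 0.05)
})

test_that("allocation heatmaps conserve the per-checkpoint totals", {
  fx <- make_plane_fixture()
  alloc <- allocation_heatmap(fx$plane)
  sums <- tapply(alloc$bits, alloc$checkpoint, sum)
  totals <- fx$plane$total_bits[match(as.integer(names(sums)),
                                      fx$plane$checkpoint)]
  expect_equal(as.numeric(sums), unname(totals), tolerance = 1e-6)
  single <- allocation_heatmap(fx$plane[1, ])
  expect_equal(nrow(single), 2L)
  expect_equal(sum(single$bits), fx$plane$total_bits[1], tolerance = 1e-9)
})

test_that("informative_subsets applies the bits threshold", {
  expect_identical(informative_subsets(c(a = 0, b = 0, c = 0)), character(0))
  expect_identical(
    informative_subsets(c(f1 = 0.5, f2 = 0.05, f3 = 0.2), 0.1),
    c("f1", "f3"))
  expect_identical(informative_subsets(c(f1 = 0.5, f2 = 0, f3 = 1e-4), 0),
                   c("f1", "f3"))
  fx <- make_plane_fixture()
  plane <- informative_subsets(fx$plane)
  expect_true(all(vapply(seq_len(nrow(plane)), function(i)
    all(plane$allocation[[i]][plane$informative[[i]]] >= 0.1), logical(1))))
})

test_that("distinguishability matrices follow the Bhattacharyya closed form", {
  # channel at the prior: all values indistinguishable
  ch0 <- encoder_basis("v", center = 0, scale = 1)
  D0 <- distinguishability_matrix(ch0, grid = seq(-2, 2, length.out = 8))
  expect_true(all(D0 == 0))

  # two well-separated encodings: fully distinguishable
  ch1 <- make_binary_channel(list(10, -10), list(0.01, 0.01))
  D1 <- distinguishability_matrix(ch1, grid = c(0, 1))
  expect_equal(D1[1, 2], 1, tolerance = 1e-9)

  # equal scales 1, means 0 and 2: 1 - exp(-4/8) = 0.3935
  ch2 <- make_binary_channel(list(0, 2), list(1, 1))
  D2 <- distinguishability_matrix(ch2, grid = c(0, 1))
  expect_equal(D2[1, 2], 1 - exp(-0.5), tolerance = 1e-9)
  # cross-check against numerical quadrature of the Bhattacharyya integral
  bc_quad <- stats::integrate(function(u)
    sqrt(stats::dnorm(u, 0, 1) * stats::dnorm(u, 2, 1)), -15, 15,
    rel.tol = 1e-10)$value
  expect_equal(D2[1, 2], 1 - bc_quad, tolerance = 1e-8)

  expect_true(isSymmetric(unclass(D2)))
  expect_equal(diag(D2), c(0, 0))
  expect_error(distinguishability_matrix(ch2, grid = 1),
               class = "dibs_invalid_argument")
})

test_that("detect_threshold recovers cuts and matches a brute-force scan", {
  grid <- 1:6
  D <- matrix(1, 6, 6)
  D[1:3, 1:3] <- 0
  D[4:6, 4:6] <- 0
  D <- structure(D, class = c("dib_distinguishability", class(D)),
                 grid = grid, feature = "v")
  th <- detect_threshold(D)
  expect_false(th$degenerate)
  expect_equal(th$cut_index, 3L)
  expect_equal(th$cutoff, 3.5)
  expect_equal(th$error, 0)
  expect_equal(th$within_mean, 0)
  expect_equal(th$between_mean, 1)

  # degenerate all-zero matrix is flagged
  D0 <- structure(matrix(0, 4, 4),
                  class = c("dib_distinguishability", "matrix", "array"),
                  grid = 1:4, feature = "v")
  expect_true(detect_threshold(D0)$degenerate)

  # noisy two-block matrix: same cut as an independent re-implementation
  set.seed(9)
  N <- matrix(stats::runif(64, 0, 0.15), 8, 8)
  N <- (N + t(N)) / 2
  Dn <- matrix(1, 8, 8)
  Dn[1:5, 1:5] <- 0
  Dn[6:8, 6:8] <- 0
  Dn <- pmin(pmax(Dn + N, 0), 1)
  diag(Dn) <- 0
  Dn <- structure(Dn, class = c("dib_distinguishability", class(Dn)),
                  grid = 1:8, feature = "v")
  th_n <- detect_threshold(Dn)
  brute <- vapply(1:7, function(cut) {
    b1 <- 1:cut; b2 <- (cut + 1):8
    offd <- function(M) M[row(M) != col(M)]
    blocks <- list(offd(Dn[b1, b1, drop = FALSE]),
                   offd(Dn[b2, b2, drop = FALSE]),
                   as.vector(Dn[b1, b2, drop = FALSE]))
    sum(vapply(blocks, function(b)
      if (length(b)) sum((b - mean(b))^2) else 0, numeric(1)))
  }, numeric(1))
  expect_equal(th_n$cut_index, which.min(brute))
  expect_equal(th_n$cut_index, 5L)
})

test_that("conditional histograms report overlap correctly", {
  set.seed(3)
  same <- tibble::tibble(v = stats::rnorm(4000), y = rep(0:1, 2000))
  h_same <- conditional_histograms(same, "v", bins = 24)
  expect_gt(attr(h_same, "overlap"), 0.9)

  disjoint <- tibble::tibble(v = c(stats::runif(500, 0, 1),
                                   stats::runif(500, 2, 3)),
                             y = rep(0:1, each = 500))
  h_disj <- conditional_histograms(disjoint, "v", bins = 30)
  expect_equal(attr(h_disj, "overlap"), 0)
  expect_error(conditional_histograms(disjoint[disjoint$y == 0, ], "v"),
               class = "dibs_degenerate_labels")
})
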