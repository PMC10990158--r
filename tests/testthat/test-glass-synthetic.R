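glass_cache <- new.env(parent = emptyenv())

small_glass <- function() {
  if (is.null(glass_cache$small)) {
    glass_cache$small <- synthesize_neighborhoods(
      600, planted_rule(shell = 8, type = "A", noise = 0), seed = 21)
  }
  glass_cache$small
}

test_that("noise-free labels are exactly recomputable from the rule", {
  nb <- small_glass()
  tau <- attr(nb, "threshold")
  centers <- attr(nb, "shell_centers")
  occ <- vapply(nb$particles, function(p) {
    r <- sqrt(p$x^2 + p$y^2)
    sum(exp(-(r[p$type == "A"] - centers[8])^2 / (2 * 0.1^2)))
  }, numeric(1))
  expect_equal(nb$label, as.integer(occ < tau))
  # median threshold balances the classes
  expect_equal(mean(nb$label), 0.5, tolerance = 0.01)
})

test_that("median thresholding balances classes at scale", {
  nb <- synthesize_neighborhoods(10000, planted_rule(noise = 0.1),
                                 seed = 31)
  expect_equal(mean(nb$label), 0.5, tolerance = 0.02)
  glass_cache$n1e4 <- nb
})

test_that("hard-core geometry is respected", {
  nb <- small_glass()
  params <- attr(nb, "params")
  for (i in sample(nrow(nb), 25)) {
    p <- nb$particles[[i]]
    expect_true(all(p$x^2 + p$y^2 <= params$r_max^2 + 1e-9))
    d <- as.matrix(stats::dist(cbind(p$x, p$y)))
    expect_gte(min(d[upper.tri(d)]), params$hard_core)
    expect_true(p$is_center[1] && p$x[1] == 0 && p$y[1] == 0)
    expect_true(all(p$type %in% c("A", "B")))
  }
  expect_error(synthesize_neighborhoods(10, hard_core = 2, density = 1),
               class = "dibs_packing_error")
  expect_error(synthesize_neighborhoods(1), class = "dibs_invalid_argument")
})

test_that("radial features implement the Gaussian shell smearing", {
  centers <- shell_centers()
  # empty neighborhood: all-zero features
  empty <- tibble::tibble(type = character(), x = numeric(), y = numeric())
  expect_equal(unname(radial_density_features(empty)),
               rep(0, 100))
  # a single type-A particle exactly at a shell center contributes 1
  single <- tibble::tibble(type = "A", x = centers[8], y = 0)
  f <- radial_density_features(single)
  expect_equal(unname(f["A08"]), 1)
  expect_equal(sum(f[paste0("B", sprintf("%02d", 1:50))]), 0)
  # table form matches the single-neighborhood form row by row
  nb <- small_glass()[1:5, ]
  ft <- radial_density_features(nb)
  for (i in 1:5) {
    fi <- radial_density_features(nb$particles[[i]])
    expect_equal(unname(unlist(ft[i, names(fi)])), unname(fi),
                 tolerance = 1e-12)
  }
})

test_that("mean features of an ideal gas match the annulus integral", {
  # homogeneous Poisson configurations: E[feature_k] = rho_t * int 2 pi r
  # exp(-(r - r_k)^2 / 2w^2) dr over the disc
  nb <- synthesize_neighborhoods(3000, planted_rule(noise = 0.5),
                                 hard_core = 0, seed = 41)
  ft <- radial_density_features(nb)
  centers <- shell_centers()
  params <- attr(nb, "params")
  for (k in c(10, 30)) {
    vals <- ft[[sprintf("A%02d", k)]]
    rho_a <- params$density * params$frac_a
    oracle <- rho_a * stats::integrate(function(r)
      2 * pi * r * exp(-(r - centers[k])^2 / (2 * 0.1^2)),
      0, params$r_max)$value
    se <- stats::sd(vals) / sqrt(length(vals))
    expect_lt(abs(mean(vals) - oracle), 3 * se + 0.02 * oracle)
  }
})

test_that("radial distribution functions behave like the generating process", {
  nb <- small_glass()
  g_aa <- radial_distribution_function(nb, "AA")
  # no pairs below the hard core
  expect_true(all(g_aa$g[g_aa$r < 0.5] == 0))
  # first peak at or beyond the hard-core radius
  expect_gte(g_aa$r[which.max(g_aa$g)], 0.5)
  # ideal gas: flat at 1 within counting noise
  ideal <- synthesize_neighborhoods(2000, planted_rule(noise = 0.5),
                                    hard_core = 0, seed = 51)
  g_i <- radial_distribution_function(ideal, "AA", dr = 0.25)
  sel <- g_i$r > 0.4 & g_i$r < 4.8
  expect_true(all(abs(g_i$g[sel] - 1) < 0.05))
  expect_error(radial_distribution_function(nb[1:50, ], "AA"),
               class = "dibs_invalid_argument")
})

test_that("the linear baseline separates, chances and recovers as planted", {
  # linearly separable blobs: perfect held-out accuracy
  set.seed(61)
  blobs <- tibble::tibble(
    f1 = c(stats::rnorm(300, -4, 0.5), stats::rnorm(300, 4, 0.5)),
    f2 = stats::rnorm(600),
    y = rep(0:1, each = 300))
  fit <- linear_baseline(blobs, seed = 1)
  expect_equal(fit$accuracy, 1)
  expect_gt(abs(fit$weights["f1"]), abs(fit$weights["f2"]))

  # label noise 0.5: labels carry nothing, accuracy is chance
  nb50 <- synthesize_neighborhoods(6000, planted_rule(noise = 0.5),
                                   seed = 71)
  ft50 <- radial_density_features(nb50)
  fit50 <- linear_baseline(dplyr::select(ft50, -"id"), seed = 2)
  expect_lt(abs(fit50$accuracy - 0.5), 0.05)

  # noise-free planted rule: the largest weight sits on the planted shell
  nb0 <- small_glass()
  ft0 <- radial_density_features(nb0)
  fit0 <- linear_baseline(dplyr::select(ft0, -"id"), seed = 3)
  top <- names(which.max(abs(fit0$weights)))
  expect_true(top %in% c("A07", "A08", "A09"))
  expect_error(linear_baseline(dplyr::mutate(blobs, y = 0)),
               class = "dibs_degenerate_labels")
})

test_that("neighborhood text files round-trip", {
  nb <- small_glass()[1:8, ]
  f <- withr::local_tempfile(fileext = ".xyz")
  write_neighborhoods(nb, f)
  back <- read_neighborhoods(f)
  expect_equal(back$label, nb$label)
  expect_equal(back$n_particles, nb$n_particles)
  for (i in 1:8) {
    expect_equal(back$particles[[i]]$x, nb$particles[[i]]$x,
                 tolerance = 1e-7)
    expect_equal(back$particles[[i]]$type, nb$particles[[i]]$type)
  }
  expect_equal(attr(back, "params")$r_max, attr(nb, "params")$r_max)
})
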