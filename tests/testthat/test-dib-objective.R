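test_that("beta schedules are geometric and validated", {
  expect_equal(beta_schedule(1, 1, 5)$beta, rep(1, 5))
  expect_equal(beta_schedule(1, 1e-4, 5)$beta, 10^(0:-4), tolerance = 1e-12)
  expect_error(beta_schedule(0, 1, 5), class = "dibs_invalid_argument")
  expect_error(beta_schedule(1, -2, 5), class = "dibs_invalid_argument")
  expect_error(beta_schedule(1, 0.1, 0), class = "dibs_invalid_argument")
})

test_that("the loss at initialization equals H(Y) in nats", {
  tt <- and2_table()
  model <- dib_model(tt, latent_dim = 4, decoder_hidden = c(16, 16))
  hy_nats <- -(0.25 * log(0.25) + 0.75 * log(0.75))
  # channels at the prior, decoder at the label marginal
  loss <- dib_loss(model, tt, beta = 0, seed = 1)
  expect_equal(as.numeric(loss), hy_nats, tolerance = 1e-9)
  expect_equal(attr(loss, "kl_bits"), 0, tolerance = 1e-9)
  # beta scales the (zero) compression term only
  expect_equal(as.numeric(dib_loss(model, tt, beta = 10, seed = 1)),
               hy_nats, tolerance = 1e-6)
  expect_error(dib_loss(model, tt, beta = -1),
               class = "dibs_invalid_argument")
})

test_that("fully bottlenecked and unconstrained endpoints behave as expected", {
  # XOR-2, checkpoint at the largest beta (end of the squeeze): nothing
  # transmitted, nothing predicted
  tt_xor <- xor2_table()
  sw <- dib_sweep(tt_xor, beta_start = 5e-5, beta_end = 5, n_steps = 7000,
                  warmup = 1500, latent_dim = 2, decoder_hidden = c(32, 32),
                  n_checkpoints = 12, seed = 2)
  # channels open during the burn-in (XOR is only learnable jointly) ...
  kl_trace <- vapply(sw$checkpoints, `[[`, numeric(1), "kl_bits")
  expect_gt(max(kl_trace), 2)
  # ... and the ramp squeezes everything back out
  m_end <- checkpoint_model(sw, length(sw$checkpoints))
  lat <- encode(m_end$channels$x1, c(0, 1))
  expect_lt(mean(kl_to_prior(lat)), 0.05)
  p_end <- predictive_info(m_end, tt_xor, n_samples = 8, seed = 3)
  expect_lt(abs(p_end$predictive_bits), 0.05)

  # AND-2, checkpoint at the smallest beta (weak bottleneck): predictive
  # information reaches H(Y)
  tt_and <- and2_table()
  sw2 <- dib_sweep(tt_and, beta_start = 1e-4, beta_end = 1, n_steps = 3000,
                   warmup = 1500, latent_dim = 4, decoder_hidden = c(32, 32),
                   n_checkpoints = 12, seed = 3)
  betas <- vapply(sw2$checkpoints, `[[`, numeric(1), "beta")
  m_open <- checkpoint_model(sw2, which(betas == min(betas))[
    sum(betas == min(betas))])
  pf <- predictive_info(m_open, tt_and, n_samples = 32, seed = 5)
  expect_equal(pf$predictive_bits, 0.811278, tolerance = 0.03)
  expect_equal(pf$accuracy, 1)
})

test_that("sweeps are reproducible under a fixed seed", {
  tt <- and2_table()
  sw1 <- dib_sweep(tt, beta_start = 1e-3, beta_end = 1, n_steps = 400,
                   warmup = 100, latent_dim = 2, decoder_hidden = c(8),
                   n_checkpoints = 5, seed = 9)
  sw2 <- dib_sweep(tt, beta_start = 1e-3, beta_end = 1, n_steps = 400,
                   warmup = 100, latent_dim = 2, decoder_hidden = c(8),
                   n_checkpoints = 5, seed = 9)
  expect_identical(vapply(sw1$checkpoints, `[[`, numeric(1), "loss"),
                   vapply(sw2$checkpoints, `[[`, numeric(1), "loss"))
  expect_identical(sw1$model$channels$x1$params, sw2$model$channels$x1$params)
})

test_that("inputs with identical roles receive near-identical allocations", {
  tt <- or2_table()
  # prior-start channels: two inputs face no cold-start lock, and a
  # symmetric start keeps the comparison clean at every checkpoint
  sw <- dib_sweep(tt, beta_start = 1e-4, beta_end = 2, n_steps = 8000,
                  warmup = 2400, latent_dim = 4, decoder_hidden = c(32, 32),
                  channel_init_sd = 0, n_checkpoints = 15, seed = 4)
  for (ci in seq_along(sw$checkpoints)) {
    m <- checkpoint_model(sw, ci)
    i1 <- mi_exact_discrete(m$channels$x1, n_mc = 2e4, seed = 100 + ci)
    i2 <- mi_exact_discrete(m$channels$x2, n_mc = 2e4, seed = 200 + ci)
    expect_lt(abs(i1$mi_bits - i2$mi_bits), 0.1)
  }
})

test_that("information shrinks monotonically as beta grows along the ramp", {
  tt <- and2_table()
  warmup <- 1200
  sw <- dib_sweep(tt, beta_start = 1e-4, beta_end = 2, n_steps = 4000,
                  warmup = warmup, latent_dim = 2,
                  decoder_hidden = c(32, 32), n_checkpoints = 20, seed = 6)
  steps <- vapply(sw$checkpoints, `[[`, numeric(1), "step")
  ramp <- which(steps >= warmup)  # burn-in grows info; the ramp squeezes it
  kl <- vapply(sw$checkpoints[ramp], `[[`, numeric(1), "kl_bits")
  # smooth over adjacent checkpoints to tolerate stochastic wiggle; info
  # may still grow while beta is negligible, so monotone decrease is
  # required from the trajectory's peak onward
  sm <- stats::filter(kl, rep(1 / 3, 3), sides = 2)
  sm <- sm[!is.na(sm)]
  sm <- sm[which.max(sm):length(sm)]
  expect_true(all(diff(sm) < 0.1))
  # predictive information non-decreasing in total utilized information
  pred <- vapply(ramp, function(ci) {
    predictive_info(checkpoint_model(sw, ci), tt, n_samples = 8,
                    seed = ci)$predictive_bits
  }, numeric(1))
  o <- order(kl)
  ps <- stats::filter(pred[o], rep(1 / 3, 3), sides = 2)
  ps <- ps[!is.na(ps)]
  expect_true(all(diff(ps) > -0.1))
})

test_that("data-processing holds along a sweep on a circuit", {
  tt <- or2_table()
  hy <- subset_information(tt, 1:2)
  sw <- dib_sweep(tt, beta_start = 1e-4, beta_end = 2, n_steps = 2500,
                  warmup = 750, latent_dim = 2, decoder_hidden = c(32, 32),
                  n_checkpoints = 10, seed = 8)
  for (ci in seq_along(sw$checkpoints)) {
    m <- checkpoint_model(sw, ci)
    tot <- sum(vapply(c("x1", "x2"), function(f)
      mi_exact_discrete(m$channels[[f]], n_mc = 2e4,
                        seed = 300 + ci)$mi_bits, numeric(1)))
    pred <- predictive_info(m, tt, n_samples = 16,
                            seed = 400 + ci)$predictive_bits
    expect_lte(pred, tot + 0.05)
    expect_lte(pred, hy + 0.05)
  }
})
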