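# Per-particle measurement basis: one shared compression channel per
# particle type maps each particle's (x, y) position to a Gaussian latent;
# a permutation-invariant set network predicts the label from the pooled
# compressed set. The per-particle information cost is the KL to the prior
# — the quantity the distributed objective penalizes — which yields
# positional information maps without any positional supervision.

set_onehot <- function(type) {
  cbind(A = as.numeric(type == "A"), B = as.numeric(type == "B"))
}

flatten_neighborhoods <- function(neighborhoods, drop_center = FALSE) {
  flat <- tidyr::unnest(neighborhoods[, c("id", "particles")], "particles")
  if (drop_center && "is_center" %in% names(flat)) {
    flat <- flat[!flat$is_center, ]
  }
  list(coords = cbind(flat$x, flat$y), type = flat$type,
       nbr = match(flat$id, neighborhoods$id))
}

#' Train a beta-annealed sweep in the per-particle basis
#'
#' Every particle of a type is compressed in parallel by that type's shared
#' MLP channel; latent samples (tagged with a type one-hot) pass through a
#' shared per-element network and are sum-pooled (scaled by the mean
#' particle count) before a decoder predicts the neighborhood label. The
#' bottleneck strength anneals geometrically as in [dib_sweep()], with the
#' per-neighborhood compression cost equal to the summed per-particle KL.
#'
#' @param neighborhoods A `dib_neighborhoods` table with labels.
#' @param latent_dim Per-particle latent dimension.
#' @param encoder_hidden Hidden sizes of the per-type channel MLPs.
#' @param phi_hidden,rho_hidden Hidden sizes of the per-element and
#'   post-pooling networks.
#' @param beta_start,beta_end,n_steps Annealing schedule.
#' @param warmup Steps held at `beta_start` before the geometric ramp.
#' @param batch_size Neighborhoods per minibatch.
#' @param channel_init_sd Random mean-head initialization scale for the
#'   per-type channels (0 starts them exactly at the prior).
#' @param lr Adam learning rate.
#' @param n_checkpoints Log-spaced checkpoints to keep.
#' @param seed Seed (local to the call).
#' @return A `dib_set_sweep` with the trained `dib_set_model` and
#'   checkpoints.
#' @export
dib_set_sweep <- function(neighborhoods, latent_dim = 4,
                          encoder_hidden = c(32, 32), phi_hidden = 32,
                          rho_hidden = 32, beta_start = 3e-5, beta_end = 1,
                          n_steps = 3000, warmup = round(0.3 * n_steps),
                          batch_size = 32, lr = 1e-3, channel_init_sd = 0.5,
                          n_checkpoints = 50, seed = 1L) {
  stopifnot(inherits(neighborhoods, "dib_neighborhoods"))
  n_steps <- check_positive_int(n_steps, "n_steps")
  warmup <- as.integer(warmup)
  schedule <- sweep_schedule(beta_start, beta_end, n_steps, warmup)
  flat <- flatten_neighborhoods(neighborhoods)
  n <- nrow(neighborhoods)
  y <- neighborhoods$label
  yf <- factor(y)
  if (nlevels(yf) < 2L) {
    abort_dibs("Need at least two label classes.", "degenerate_labels")
  }
  yi <- as.integer(yf)
  n_classes <- nlevels(yf)
  coord_scale <- stats::sd(as.vector(flat$coords))
  n_scale <- nrow(flat$coords) / n  # mean particle count, fixed
  rows_by_nbr <- split(seq_len(nrow(flat$coords)), flat$nbr)
  ckpt_steps <- sweep_checkpoint_steps(n_steps, n_checkpoints, warmup)

  with_local_seed(seed, {
    channels <- list(
      A = encoder_mlp("A", input_dim = 2L, hidden = encoder_hidden,
                      latent_dim = latent_dim, center = c(0, 0),
                      scale = rep(coord_scale, 2),
                      init_sd = channel_init_sd, act = "relu"),
      B = encoder_mlp("B", input_dim = 2L, hidden = encoder_hidden,
                      latent_dim = latent_dim, center = c(0, 0),
                      scale = rep(coord_scale, 2),
                      init_sd = channel_init_sd, act = "relu"))
    phi <- mlp_new(c(latent_dim + 2L, phi_hidden, phi_hidden), act = "relu")
    marg <- tabulate(yi, n_classes) / n
    rho <- mlp_new(c(phi_hidden, rho_hidden, n_classes), act = "relu",
                   zero_last = TRUE, out_bias = log(pmax(marg, 1e-12)))
    params <- list(A = channels$A$params, B = channels$B$params,
                   phi = phi$params, rho = rho$params)
    opt <- adam_new()
    checkpoints <- vector("list", length(ckpt_steps))
    ck <- 1L

    for (step in seq_len(n_steps)) {
      beta <- schedule$beta[step]
      sel <- sample.int(n, min(batch_size, n))
      B <- length(sel)
      rows <- unlist(rows_by_nbr[sel], use.names = FALSE)
      pidx <- rep(seq_len(B), lengths(rows_by_nbr[sel]))
      coords <- flat$coords[rows, , drop = FALSE]
      type <- flat$type[rows]
      P <- length(rows)
      U <- matrix(0, P, latent_dim)
      fws <- list(); epss <- list(); trows <- list()
      kl_sum <- 0
      for (t in c("A", "B")) {
        channels[[t]]$params <- params[[t]]
        rt <- which(type == t)
        trows[[t]] <- rt
        if (!length(rt)) next
        fw <- encoder_forward(channels[[t]], coords[rt, , drop = FALSE])
        e <- matrix(stats::rnorm(length(fw$mean)), nrow = nrow(fw$mean))
        U[rt, ] <- fw$mean + fw$scale * e
        kl_sum <- kl_sum + sum(0.5 * (fw$mean^2 + fw$scale^2 - 1 -
                                        2 * log(fw$scale)))
        fws[[t]] <- fw; epss[[t]] <- e
      }
      Z <- cbind(U, set_onehot(type))
      phi$params <- params$phi
      rho$params <- params$rho
      fph <- mlp_forward(phi, Z)
      pooled <- rowsum(fph$out, pidx) / n_scale
      frh <- mlp_forward(rho, pooled)
      probs <- softmax_rows(frh$out)
      yb <- yi[sel]
      ce <- -mean(log(pmax(probs[cbind(seq_len(B), yb)], 1e-300)))
      loss <- beta * kl_sum / B + ce
      if (!is.finite(loss)) {
        abort_dibs(sprintf("Non-finite loss at step %d.", step),
                   "training_failure")
      }
      G_logits <- probs
      G_logits[cbind(seq_len(B), yb)] <- G_logits[cbind(seq_len(B), yb)] - 1
      G_logits <- G_logits / B
      bk_rho <- mlp_backward(rho, frh, G_logits)
      G_phi_out <- bk_rho$g_input[pidx, , drop = FALSE] / n_scale
      bk_phi <- mlp_backward(phi, fph, G_phi_out)
      G_u <- bk_phi$g_input[, seq_len(latent_dim), drop = FALSE]
      grads <- list(A = NULL, B = NULL, phi = bk_phi$grads,
                    rho = bk_rho$grads)
      for (t in c("A", "B")) {
        rt <- trows[[t]]
        if (!length(rt)) { grads[[t]] <- zeros_like(params[[t]]); next }
        fw <- fws[[t]]
        g_mean <- G_u[rt, , drop = FALSE] + (beta / B) * fw$mean
        g_scale <- G_u[rt, , drop = FALSE] * epss[[t]] +
          (beta / B) * (fw$scale - 1 / fw$scale)
        g_pre <- g_scale * pre_to_scale_grad(fw$pre)
        grads[[t]] <- encoder_backward(channels[[t]], fw, g_mean, g_pre)
      }
      st <- adam_step(params, grads, opt, lr = lr)
      params <- st$params
      opt <- st$state
      if (ck <= length(ckpt_steps) && step == ckpt_steps[ck]) {
        checkpoints[[ck]] <- list(step = step, beta = beta, params = params,
                                  ce_nats = ce, kl_bits = kl_sum / B / LOG2)
        ck <- ck + 1L
      }
    }
    channels$A$params <- params$A
    channels$B$params <- params$B
    phi$params <- params$phi
    rho$params <- params$rho
    model <- structure(list(channels = channels, phi = phi, rho = rho,
                            n_scale = n_scale, latent_dim = latent_dim,
                            label_levels = levels(yf)),
                       class = "dib_set_model")
    structure(list(model = model, checkpoints = checkpoints,
                   checkpoint_steps = ckpt_steps, schedule = schedule,
                   config = list(latent_dim = latent_dim,
                                 beta_start = beta_start,
                                 beta_end = beta_end, n_steps = n_steps,
                                 batch_size = batch_size, lr = lr,
                                 seed = seed)),
              class = "dib_set_sweep")
  })
}

#' Materialize the set model at a sweep checkpoint
#'
#' @param sweep A `dib_set_sweep`.
#' @param checkpoint Checkpoint index (`NULL` for the final model).
#' @return A `dib_set_model`.
#' @export
set_checkpoint_model <- function(sweep, checkpoint = NULL) {
  stopifnot(inherits(sweep, "dib_set_sweep"))
  model <- sweep$model
  if (is.null(checkpoint)) return(model)
  if (checkpoint < 1 || checkpoint > length(sweep$checkpoints)) {
    abort_dibs("Checkpoint index out of range.", "invalid_argument")
  }
  p <- sweep$checkpoints[[checkpoint]]$params
  model$channels$A$params <- p$A
  model$channels$B$params <- p$B
  model$phi$params <- p$phi
  model$rho$params <- p$rho
  model
}

#' Encode a neighborhood's particles with the per-type channels
#'
#' Each particle is encoded by its type's shared channel; the per-particle
#' information cost is the KL of its latent to the prior. Duplicate
#' positions receive identical latents and costs; the total neighborhood
#' cost is the sum of the per-particle costs.
#'
#' @param model A `dib_set_model` (or a list with `channels$A`/`$B`).
#' @param particles Tibble with columns `type`, `x`, `y` (may be empty).
#' @return Tibble: `type`, `x`, `y`, `kl_bits`; attribute `latent` holds the
#'   [gaussian_latent()] rows in the same order.
#' @export
encode_neighborhood_set <- function(model, particles) {
  particles <- tibble::as_tibble(particles)
  if (!nrow(particles)) {
    out <- tibble::tibble(type = character(), x = numeric(), y = numeric(),
                          kl_bits = numeric())
    attr(out, "latent") <- NULL
    return(out)
  }
  if (!all(particles$type %in% c("A", "B"))) {
    abort_dibs("Unknown particle type; channels cover types A and B.",
               "invalid_argument")
  }
  mean <- matrix(0, nrow(particles), model$latent_dim)
  scale <- matrix(1, nrow(particles), model$latent_dim)
  for (t in c("A", "B")) {
    rt <- which(particles$type == t)
    if (!length(rt)) next
    fw <- encoder_forward(model$channels[[t]],
                          cbind(particles$x[rt], particles$y[rt]))
    mean[rt, ] <- fw$mean
    scale[rt, ] <- fw$scale
  }
  lat <- gaussian_latent(mean, scale)
  out <- tibble::tibble(type = particles$type, x = particles$x,
                        y = particles$y, kl_bits = kl_to_prior(lat))
  attr(out, "latent") <- lat
  out
}

#' Predict a label distribution from a particle set
#'
#' Deterministically encodes the set (latent means), pools the shared
#' per-element network's outputs by summation and decodes a label
#' distribution. The output is invariant to the ordering of the particles;
#' an empty set yields the decoder's learned bias distribution.
#'
#' @param model A `dib_set_model`.
#' @param particles Tibble with `type`, `x`, `y` (may be empty).
#' @param sample Draw one reparameterized latent sample instead of using
#'   the latent means.
#' @param seed Optional seed for the sampled variant.
#' @return Named probability vector over the label levels.
#' @export
set_predict <- function(model, particles, sample = FALSE, seed = NULL) {
  particles <- tibble::as_tibble(particles)
  if (nrow(particles)) {
    enc <- encode_neighborhood_set(model, particles)
    lat <- attr(enc, "latent")
    U <- if (sample) sample_latent(lat, seed = seed) else lat$mean
    Z <- cbind(U, set_onehot(particles$type))
    pooled <- matrix(colSums(mlp_forward(model$phi, Z)$out), nrow = 1) /
      model$n_scale
  } else {
    pooled <- matrix(0, 1, model$phi$sizes[length(model$phi$sizes)])
  }
  probs <- drop(softmax_rows(mlp_forward(model$rho, pooled)$out))
  names(probs) <- model$label_levels
  probs
}

#' Positional information map
#'
#' Bins the per-particle information cost (KL bits) of every particle in a
#' dataset by position on a square grid, per particle type, and radially by
#' annulus — the map of where in the neighborhood the compression scheme
#' spends its bits. Empty cells are flagged with `NA` cost, not zero.
#'
#' @param model A `dib_set_model`.
#' @param neighborhoods A `dib_neighborhoods` table.
#' @param grid_n Cells per axis over `[-r_max, r_max]^2`.
#' @param dr Annulus width for the radial average.
#' @param max_neighborhoods Optional cap on neighborhoods used.
#' @param include_center Keep the reference particle pinned at the origin
#'   (excluded by default: its position carries no neighborhood structure).
#' @return List of class `dib_posmap`: `cells` (tibble `type`, `x`, `y`,
#'   `bits`, `n`), `radial` (tibble `type`, `r`, `bits`, `n`), and the grid
#'   definition. Cell occupancies sum to the number of particles used.
#' @export
positional_info_map <- function(model, neighborhoods, grid_n = 50, dr = 0.1,
                                max_neighborhoods = NULL,
                                include_center = FALSE) {
  stopifnot(inherits(neighborhoods, "dib_neighborhoods"))
  if (!nrow(neighborhoods)) {
    abort_dibs("Need a nonempty dataset.", "invalid_argument")
  }
  if (!is.null(max_neighborhoods) && nrow(neighborhoods) > max_neighborhoods) {
    neighborhoods <- neighborhoods[seq_len(max_neighborhoods), ]
  }
  params <- attr(neighborhoods, "params")
  r_max <- if (!is.null(params) && !is.null(params$r_max)) params$r_max else 5
  flat <- flatten_neighborhoods(neighborhoods, drop_center = !include_center)
  kl <- numeric(nrow(flat$coords))
  for (t in c("A", "B")) {
    rt <- which(flat$type == t)
    if (!length(rt)) next
    fw <- encoder_forward(model$channels[[t]],
                          flat$coords[rt, , drop = FALSE])
    kl[rt] <- kl_to_prior(gaussian_latent(fw$mean, fw$scale))
  }
  edges <- seq(-r_max, r_max, length.out = grid_n + 1L)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  ix <- findInterval(flat$coords[, 1], edges, rightmost.closed = TRUE,
                     all.inside = TRUE)
  iy <- findInterval(flat$coords[, 2], edges, rightmost.closed = TRUE,
                     all.inside = TRUE)
  cell <- paste(flat$type, ix, iy)
  agg <- rowsum(cbind(kl, 1), cell)
  parts <- strsplit(rownames(agg), " ")
  cells <- tibble::tibble(
    type = vapply(parts, `[[`, character(1), 1L),
    x = mids[as.integer(vapply(parts, `[[`, character(1), 2L))],
    y = mids[as.integer(vapply(parts, `[[`, character(1), 3L))],
    bits = agg[, 1] / agg[, 2],
    n = as.integer(agg[, 2]))
  r <- sqrt(rowSums(flat$coords^2))
  rbin <- floor(r / dr)
  rkey <- paste(flat$type, rbin)
  ragg <- rowsum(cbind(kl, 1), rkey)
  rparts <- strsplit(rownames(ragg), " ")
  radial <- dplyr::arrange(tibble::tibble(
    type = vapply(rparts, `[[`, character(1), 1L),
    r = (as.numeric(vapply(rparts, `[[`, character(1), 2L)) + 0.5) * dr,
    bits = ragg[, 1] / ragg[, 2],
    n = as.integer(ragg[, 2])), .data$type, .data$r)
  structure(list(cells = cells, radial = radial,
                 grid = list(edges = edges, r_max = r_max, dr = dr),
                 n_particles = nrow(flat$coords)),
            class = "dib_posmap")
}

#' Azimuthal profile of the per-particle information cost
#'
#' Mean per-particle KL bits in angular sectors within a radial band — the
#' check that a trained channel transmits radial rather than azimuthal
#' information.
#'
#' @param model A `dib_set_model`.
#' @param neighborhoods A `dib_neighborhoods` table.
#' @param type Particle type.
#' @param r_band Radial band `c(r_lo, r_hi)`.
#' @param n_theta Number of angular sectors.
#' @return Tibble: `theta`, `bits`, `n`.
#' @export
azimuthal_profile <- function(model, neighborhoods, type = "A",
                              r_band = c(0.8, 1.2), n_theta = 8) {
  flat <- flatten_neighborhoods(neighborhoods, drop_center = TRUE)
  rt <- which(flat$type == type)
  coords <- flat$coords[rt, , drop = FALSE]
  fw <- encoder_forward(model$channels[[type]], coords)
  kl <- kl_to_prior(gaussian_latent(fw$mean, fw$scale))
  r <- sqrt(rowSums(coords^2))
  sel <- r >= r_band[1] & r < r_band[2]
  theta <- atan2(coords[sel, 2], coords[sel, 1]) + pi
  tbin <- pmin(floor(theta / (2 * pi / n_theta)), n_theta - 1)
  agg <- rowsum(cbind(kl[sel], 1), tbin)
  tibble::tibble(theta = (as.numeric(rownames(agg)) + 0.5) * 2 * pi / n_theta,
                 bits = agg[, 1] / agg[, 2], n = as.integer(agg[, 2]))
}

#' Positional distinguishability field
#'
#' Distinguishability (`1 -` Bhattacharyya coefficient) between a channel's
#' encoding at a reference position and at every point of a position grid —
#' the field that reveals the radial structure of a trained per-particle
#' compression scheme.
#'
#' @param channel A `dib_encoder` over positions (an MLP channel from a
#'   `dib_set_model`).
#' @param reference Reference position `c(x, y)`.
#' @param grid Matrix / data frame of positions (`x`, `y` columns); default
#'   a 50x50 grid over `[-5, 5]^2`.
#' @return Tibble of class `dib_posfield`: `x`, `y`, `distinguishability`.
#' @export
positional_distinguishability <- function(channel, reference = c(1, 0),
                                          grid = NULL) {
  if (is.null(grid)) {
    ax <- seq(-5, 5, length.out = 50)
    grid <- as.matrix(expand.grid(x = ax, y = ax))
  }
  grid <- as.matrix(grid)
  dimnames(grid) <- NULL
  fw_ref <- encoder_forward(channel, matrix(unname(reference), nrow = 1))
  fw <- encoder_forward(channel, grid)
  logbc <- numeric(nrow(grid))
  for (k in seq_len(ncol(fw$mean))) {
    s2a <- fw_ref$scale[1, k]^2
    s2 <- fw$scale[, k]^2
    ssum <- s2a + s2
    logbc <- logbc + 0.25 * log(4 * s2a * s2 / ssum^2) -
      (fw$mean[, k] - fw_ref$mean[1, k])^2 / (4 * ssum)
  }
  out <- tibble::tibble(x = grid[, 1], y = grid[, 2],
                        distinguishability = pmin(pmax(1 - exp(logbc), 0), 1))
  class(out) <- c("dib_posfield", class(out))
  attr(out, "reference") <- reference
  out
}
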