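# The distributed information bottleneck objective and the beta-annealed
# training sweep. One stochastic compression channel per feature feeds a
# shared decoder; the loss is
#     beta * sum_i E[KL(p(u_i|x_i) || r(u_i))] + E[-log q(y | u_1..u_N)]
# in nats. Annealing beta from strong to weak bottleneck traces a continuum
# of compression/prediction trade-offs in a single optimization.

#' Geometric bottleneck-strength schedule
#'
#' @param beta_start,beta_end Positive endpoints of the sweep (inclusive).
#' @param n_steps Number of optimization steps.
#' @return A `dib_beta_schedule`: tibble with columns `step`, `beta`.
#' @examples
#' beta_schedule(1, 1e-4, 5)
#' @export
beta_schedule <- function(beta_start = 1, beta_end = 3e-5, n_steps = 30000) {
  if (!is.numeric(beta_start) || !is.numeric(beta_end) ||
      length(beta_start) != 1 || length(beta_end) != 1 ||
      !is.finite(beta_start) || !is.finite(beta_end) ||
      beta_start <= 0 || beta_end <= 0) {
    abort_dibs("`beta_start` and `beta_end` must be positive finite numbers.",
               "invalid_argument")
  }
  n_steps <- check_positive_int(n_steps, "n_steps")
  beta <- if (n_steps == 1L) beta_start else
    exp(seq(log(beta_start), log(beta_end), length.out = n_steps))
  out <- tibble::tibble(step = seq_len(n_steps), beta = beta)
  class(out) <- c("dib_beta_schedule", class(out))
  out
}

# ---- data preparation ------------------------------------------------------

# Split a tabular dataset into feature columns, labels, and row weights.
# Binary 0/1 columns get table channels; other numeric columns get basis
# channels standardized on the data.
prepare_dib_data <- function(data, label = "y", weights = NULL,
                             latent_dim = NULL) {
  data <- tibble::as_tibble(data)
  if (!label %in% names(data)) {
    abort_dibs(sprintf("Label column '%s' not found.", label),
               "invalid_argument")
  }
  wcol <- weights
  if (is.null(wcol) && "prob" %in% names(data)) wcol <- "prob"
  w <- if (!is.null(wcol) && wcol %in% names(data)) data[[wcol]] else
    rep(1 / nrow(data), nrow(data))
  w <- w / sum(w)
  feat_names <- setdiff(names(data), c(label, wcol))
  if (!length(feat_names)) {
    abort_dibs("No feature columns found.", "invalid_argument")
  }
  yf <- factor(data[[label]])
  if (nlevels(yf) < 2L) {
    abort_dibs("The dataset must contain at least two label classes.",
               "degenerate_labels")
  }
  features <- lapply(feat_names, function(f) data[[f]])
  names(features) <- feat_names
  binary <- vapply(features, function(v) all(v %in% c(0, 1)), logical(1))
  list(features = features, binary = binary, y = as.integer(yf),
       label_levels = levels(yf), w = w, label = label)
}

build_channels <- function(prep, latent_dim, init_sd = 0) {
  channels <- vector("list", length(prep$features))
  names(channels) <- names(prep$features)
  for (f in names(prep$features)) {
    v <- prep$features[[f]]
    if (prep$binary[[f]]) {
      channels[[f]] <- encoder_table(f, levels = c(0, 1),
                                     latent_dim = latent_dim,
                                     init_sd = init_sd)
    } else {
      s <- stats::sd(v)
      if (!is.finite(s) || s == 0) s <- 1
      channels[[f]] <- encoder_basis(
        f, center = mean(v), scale = s, latent_dim = latent_dim,
        quantiles = stats::quantile(v, probs = seq(0.005, 0.995,
                                                   length.out = 64),
                                    names = FALSE),
        init_sd = init_sd)
    }
  }
  channels
}

# A dib_model holds the channels and the decoder with current parameters.
new_dib_model <- function(channels, decoder, label_levels, label) {
  structure(list(channels = channels, decoder = decoder,
                 label_levels = label_levels, label = label),
            class = "dib_model")
}

#' Assemble a distributed-bottleneck model for a dataset
#'
#' Builds one compression channel per feature column (binary columns get
#' exact value-table channels, continuous columns get standardized
#' basis-expansion channels) and a tanh MLP decoder over the concatenated
#' latent samples. Channels start at the prior and the decoder starts at the
#' empirical label marginal, so the freshly built model transmits and
#' predicts zero bits.
#'
#' @param data Data frame with feature columns and a label column; an
#'   optional `prob` column is used as exact row weights (e.g. a truth
#'   table).
#' @param label Name of the label column.
#' @param latent_dim Latent dimension per channel.
#' @param decoder_hidden Hidden layer sizes of the decoder MLP.
#' @param seed Seed for decoder weight initialization.
#' @return A `dib_model`.
#' @export
dib_model <- function(data, label = "y", latent_dim = 4,
                      decoder_hidden = c(128, 128), seed = 1L) {
  prep <- prepare_dib_data(data, label)
  channels <- build_channels(prep, latent_dim)
  n_classes <- length(prep$label_levels)
  marg <- as.vector(rowsum(prep$w, prep$y))
  decoder <- with_local_seed(seed, mlp_new(
    c(latent_dim * length(channels), decoder_hidden, n_classes),
    zero_last = TRUE, out_bias = log(pmax(marg, 1e-12))))
  new_dib_model(channels, decoder, prep$label_levels, prep$label)
}

# ---- loss ------------------------------------------------------------------

softmax_rows <- function(Z) {
  m <- Z[cbind(seq_len(nrow(Z)), max.col(Z, ties.method = "first"))]
  E <- exp(Z - m)
  E / rowSums(E)
}

# forward pass of the full model on a batch; returns loss pieces and caches
dib_forward <- function(model, features, y, w, sample = TRUE) {
  chans <- model$channels
  d_list <- vapply(chans, function(c) c$d, integer(1))
  U <- matrix(0, nrow = length(y), ncol = sum(d_list))
  fws <- vector("list", length(chans))
  eps <- vector("list", length(chans))
  kl_ch <- numeric(length(chans))
  off <- 0L
  for (i in seq_along(chans)) {
    ch <- chans[[i]]
    fw <- encoder_forward(ch, features[[ch$feature]])
    fws[[i]] <- fw
    e <- if (sample) matrix(stats::rnorm(length(fw$mean)), nrow = nrow(fw$mean))
         else matrix(0, nrow = nrow(fw$mean), ncol = ncol(fw$mean))
    eps[[i]] <- e
    U[, off + seq_len(ch$d)] <- fw$mean + fw$scale * e
    kl_ch[i] <- sum(w * (0.5 * rowSums(fw$mean^2 + fw$scale^2 - 1 -
                                         2 * log(fw$scale))))
    off <- off + ch$d
  }
  dec <- mlp_forward(model$decoder, U)
  probs <- softmax_rows(dec$out)
  p_true <- probs[cbind(seq_along(y), y)]
  ce <- -sum(w * log(pmax(p_true, 1e-300)))
  list(fws = fws, eps = eps, U = U, dec = dec, probs = probs,
       kl_ch = kl_ch, ce = ce, d_list = d_list)
}

#' Distributed-bottleneck training loss
#'
#' Evaluates `beta * sum_i mean KL_i + cross-entropy` (nats) for a model on a
#' batch, with one reparameterized latent sample per datum. With `beta = 0`,
#' channels at the prior and the marginal decoder, the loss equals `H(Y)` in
#' nats.
#'
#' @param model A `dib_model`.
#' @param data Data frame of features + label (+ optional `prob` weights).
#' @param beta Bottleneck strength (>= 0).
#' @param label Label column name.
#' @param seed Optional seed for the latent draw.
#' @return Scalar loss (nats) with attributes `ce` and `kl_bits`.
#' @export
dib_loss <- function(model, data, beta, label = model$label, seed = NULL) {
  if (!is.numeric(beta) || length(beta) != 1 || !is.finite(beta) || beta < 0) {
    abort_dibs("`beta` must be a non-negative number.", "invalid_argument")
  }
  prep <- prepare_dib_data(data, label)
  if (!setequal(names(prep$features), names(model$channels))) {
    abort_dibs("Data features do not match the model's channels.",
               "invalid_argument")
  }
  y <- match(as.character(tibble::as_tibble(data)[[label]]),
             model$label_levels)
  if (anyNA(y)) {
    abort_dibs("Labels outside the model's label set.", "invalid_argument")
  }
  fw <- with_local_seed(seed,
    dib_forward(model, prep$features, y, prep$w, sample = TRUE))
  loss <- beta * sum(fw$kl_ch) + fw$ce
  structure(loss, ce = fw$ce, kl_bits = sum(fw$kl_ch) / LOG2)
}

# ---- training sweep --------------------------------------------------------

collect_params <- function(model) {
  list(ch = lapply(model$channels, function(c) c$params),
       dec = model$decoder$params)
}

assign_params <- function(model, params) {
  for (f in names(model$channels)) model$channels[[f]]$params <- params$ch[[f]]
  model$decoder$params <- params$dec
  model
}

log_spaced_steps <- function(n_steps, n_checkpoints) {
  unique(pmax(1L, round(exp(seq(log(1), log(n_steps),
                                length.out = min(n_checkpoints, n_steps))))))
}

# schedule with an optional constant-beta burn-in before the geometric ramp
sweep_schedule <- function(beta_start, beta_end, n_steps, warmup) {
  if (warmup >= n_steps) {
    abort_dibs("`warmup` must be smaller than `n_steps`.", "invalid_argument")
  }
  if (warmup == 0L) return(beta_schedule(beta_start, beta_end, n_steps))
  ramp <- beta_schedule(beta_start, beta_end, n_steps - warmup)
  out <- tibble::tibble(step = seq_len(n_steps),
                        beta = c(rep(beta_start, warmup), ramp$beta))
  class(out) <- class(ramp)
  out
}

# checkpoints even in step over the ramp (even in log beta), plus a few
# log-spaced early ones and the end of the burn-in
sweep_checkpoint_steps <- function(n_steps, n_checkpoints, warmup) {
  if (warmup == 0L) return(log_spaced_steps(n_steps, n_checkpoints))
  early <- log_spaced_steps(warmup, max(3L, n_checkpoints %/% 10L))
  ramp <- round(seq(warmup, n_steps,
                    length.out = max(2L, n_checkpoints - length(early))))
  sort(unique(c(early, warmup, ramp)))
}

#' Train a beta-annealed distributed-bottleneck sweep
#'
#' Runs a single continuous Adam optimization while the bottleneck strength
#' is annealed geometrically between `beta_start` and `beta_end`, saving
#' parameter checkpoints along the way. The default direction starts at a
#' weak bottleneck (small `beta_start`) with a constant-beta burn-in —
#' channels open freely and the decoder fits the full relationship — and
#' then ramps beta up, squeezing information back out channel by channel.
#' (The opposite direction is available by swapping the endpoints; opening
#' channels against an already-specialized decoder plateaus easily, which is
#' why squeezing is the default.) One latent sample per datum per step
#' (reparameterized); the loss is the [dib_loss()] objective. Datasets with
#' a `prob` column (truth tables) train full-batch with exact row weighting;
#' otherwise minibatches are drawn.
#'
#' @inheritParams dib_model
#' @param beta_start,beta_end,n_steps Annealing schedule (see
#'   [beta_schedule()]).
#' @param warmup Steps held at `beta_start` before the geometric ramp.
#' @param channel_init_sd Random mean-head initialization scale for the
#'   channels (see [encoder_table()]); slightly informative channels at the
#'   weak-bottleneck start let every channel couple to the decoder. Set 0 to
#'   start all channels exactly at the prior.
#' @param batch_size Minibatch size; `NULL` trains full-batch.
#' @param lr Adam learning rate.
#' @param n_checkpoints Number of log-spaced checkpoints to keep.
#' @param seed Seed controlling initialization, sampling and batching.
#' @param verbose Print progress lines.
#' @return A `dib_sweep` object: the model template, a list of checkpoints
#'   (`step`, `beta`, parameter snapshot, loss components) and the run
#'   configuration.
#' @export
dib_sweep <- function(data, label = "y", beta_start = 3e-5, beta_end = 1,
                      n_steps = 30000, warmup = round(0.3 * n_steps),
                      batch_size = NULL, latent_dim = 4,
                      decoder_hidden = c(128, 128), lr = 1e-3,
                      channel_init_sd = 1, n_checkpoints = 100, seed = 1L,
                      verbose = FALSE) {
  n_steps <- check_positive_int(n_steps, "n_steps")
  warmup <- as.integer(warmup)
  schedule <- sweep_schedule(beta_start, beta_end, n_steps, warmup)
  prep <- prepare_dib_data(data, label)
  n <- length(prep$y)
  ckpt_steps <- sweep_checkpoint_steps(n_steps, n_checkpoints, warmup)
  full_batch <- is.null(batch_size) || batch_size >= n

  with_local_seed(seed, {
    channels <- build_channels(prep, latent_dim, init_sd = channel_init_sd)
    n_classes <- length(prep$label_levels)
    marg <- as.vector(rowsum(prep$w, prep$y))
    decoder <- mlp_new(c(latent_dim * length(channels), decoder_hidden,
                         n_classes),
                       zero_last = TRUE, out_bias = log(pmax(marg, 1e-12)))
    model <- new_dib_model(channels, decoder, prep$label_levels, prep$label)
    params <- collect_params(model)
    opt <- adam_new()
    checkpoints <- vector("list", length(ckpt_steps))
    ck <- 1L
    feat_all <- prep$features

    for (step in seq_len(n_steps)) {
      beta <- schedule$beta[step]
      if (full_batch) {
        feats <- feat_all; y <- prep$y; w <- prep$w
      } else {
        idx <- sample.int(n, batch_size)
        feats <- lapply(feat_all, function(v) v[idx])
        y <- prep$y[idx]
        w <- rep(1 / batch_size, batch_size)
      }
      model <- assign_params(model, params)
      fw <- dib_forward(model, feats, y, w, sample = TRUE)
      loss <- beta * sum(fw$kl_ch) + fw$ce
      if (!is.finite(loss)) {
        abort_dibs(sprintf(
          "Non-finite loss at step %d (beta=%.3g, ce=%.3g, kl=%.3g).",
          step, beta, fw$ce, sum(fw$kl_ch)), "training_failure")
      }
      # backprop: cross-entropy head
      G_logits <- fw$probs
      G_logits[cbind(seq_along(y), y)] <-
        G_logits[cbind(seq_along(y), y)] - 1
      G_logits <- G_logits * w
      bk <- mlp_backward(model$decoder, fw$dec, G_logits)
      grads <- list(ch = vector("list", length(model$channels)), dec = bk$grads)
      names(grads$ch) <- names(model$channels)
      off <- 0L
      for (i in seq_along(model$channels)) {
        ch <- model$channels[[i]]
        fwi <- fw$fws[[i]]
        G_u <- bk$g_input[, off + seq_len(ch$d), drop = FALSE]
        g_mean <- G_u + beta * w * fwi$mean
        g_scale <- G_u * fw$eps[[i]] +
          beta * w * (fwi$scale - 1 / fwi$scale)
        g_pre <- g_scale * pre_to_scale_grad(fwi$pre)
        grads$ch[[i]] <- encoder_backward(ch, fwi, g_mean, g_pre)
        off <- off + ch$d
      }
      st <- adam_step(params, grads, opt, lr = lr)
      params <- st$params
      opt <- st$state
      if (ck <= length(ckpt_steps) && step == ckpt_steps[ck]) {
        checkpoints[[ck]] <- list(step = step, beta = beta, params = params,
                                  ce_nats = fw$ce,
                                  kl_bits = sum(fw$kl_ch) / LOG2,
                                  loss = loss)
        if (verbose) {
          message(sprintf(
            "step %6d  beta %.3e  ce %.4f nats  kl %7.3f bits",
            step, beta, fw$ce, sum(fw$kl_ch) / LOG2))
        }
        ck <- ck + 1L
      }
    }
    model <- assign_params(model, params)
    structure(list(
      model = model, checkpoints = checkpoints,
      checkpoint_steps = ckpt_steps, schedule = schedule,
      features = names(prep$features), label = prep$label,
      label_levels = prep$label_levels,
      config = list(beta_start = beta_start, beta_end = beta_end,
                    n_steps = n_steps, warmup = warmup,
                    batch_size = batch_size,
                    latent_dim = latent_dim, decoder_hidden = decoder_hidden,
                    lr = lr, n_checkpoints = n_checkpoints, seed = seed)),
      class = "dib_sweep")
  })
}

#' Materialize the model stored at a sweep checkpoint
#'
#' @param sweep A `dib_sweep`.
#' @param checkpoint Checkpoint index (1-based; `NULL` for the final model).
#' @return A `dib_model` with that checkpoint's parameters.
#' @export
checkpoint_model <- function(sweep, checkpoint = NULL) {
  stopifnot(inherits(sweep, "dib_sweep"))
  if (is.null(checkpoint)) return(sweep$model)
  if (checkpoint < 1 || checkpoint > length(sweep$checkpoints)) {
    abort_dibs("Checkpoint index out of range.", "invalid_argument")
  }
  assign_params(sweep$model, sweep$checkpoints[[checkpoint]]$params)
}

#' @export
print.dib_sweep <- function(x, ...) {
  cat(sprintf(
    "<dib_sweep> %d channels, %d steps, beta %.3g -> %.3g, %d checkpoints\n",
    length(x$features), x$config$n_steps, x$config$beta_start,
    x$config$beta_end, length(x$checkpoints)))
  invisible(x)
}

#' @export
print.dib_model <- function(x, ...) {
  cat(sprintf("<dib_model> %d channels -> decoder (%s classes)\n",
              length(x$channels), length(x$label_levels)))
  invisible(x)
}
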