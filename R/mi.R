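# Per-channel mutual-information estimation on frozen channels.
# Training penalizes an upper bound (the KL cost); for reporting, a channel's
# transmitted information I(U;X) is bracketed by a contrastive lower bound
# and a leave-one-out upper bound on mixtures of the closed-form Gaussian
# encodings, and (for enumerable features) checked against an exact
# Monte-Carlo evaluation of the mixture integral.

row_logsumexp <- function(A) {
  m <- A[cbind(seq_len(nrow(A)), max.col(A, ties.method = "first"))]
  m + log(rowSums(exp(A - m)))
}

# contrastive / leave-one-out bound contributions for one batch.
# Returns c(lower, upper) in nats.
bound_batch <- function(channel, xk) {
  K <- length(xk)
  uv <- unique(xk)
  if (length(uv) <= 64L) {
    fw <- encoder_forward(channel, uv)
    g <- match(xk, uv)
    mean_j <- fw$mean[g, , drop = FALSE]
    scale_j <- fw$scale[g, , drop = FALSE]
    u <- mean_j + scale_j * matrix(stats::rnorm(length(mean_j)), nrow = K)
    L <- vapply(seq_along(uv), function(v)
      gaussian_log_density(u, fw$mean[v, ], fw$scale[v, ]),
      numeric(K))                       # K x V
    counts <- tabulate(g, nbins = length(uv))
    A <- sweep(L, 2L, log(counts), "+")
    m <- A[cbind(seq_len(K), max.col(A, ties.method = "first"))]
    tot <- rowSums(exp(A - m))          # sum_k p(u_j|x_k) / exp(m)
    self <- L[cbind(seq_len(K), g)]
    lower <- mean(self - (m + log(tot)) + log(K))
    loo <- m + log(pmax(tot - exp(self - m), 1e-300))
    upper <- mean(self - loo + log(K - 1))
  } else {
    fw <- encoder_forward(channel, xk)
    u <- fw$mean + fw$scale * matrix(stats::rnorm(length(fw$mean)), nrow = K)
    self <- numeric(K)
    lse <- numeric(K)
    loo <- numeric(K)
    chunk <- 1024L
    log_scale_sums <- rowSums(log(fw$scale))
    const <- 0.5 * ncol(u) * log(2 * pi)
    for (start in seq(1L, K, by = chunk)) {
      j <- start:min(start + chunk - 1L, K)
      A <- matrix(0, length(j), K)
      for (k in seq_len(ncol(u))) {
        A <- A - 0.5 * outer(u[j, k], fw$mean[, k], "-")^2 *
          rep(1 / fw$scale[, k]^2, each = length(j))
      }
      A <- A - rep(log_scale_sums, each = length(j)) - const
      m <- A[cbind(seq_along(j), max.col(A, ties.method = "first"))]
      tot <- rowSums(exp(A - m))
      self[j] <- A[cbind(seq_along(j), j)]
      lse[j] <- m + log(tot)
      loo[j] <- m + log(pmax(tot - exp(self[j] - m), 1e-300))
    }
    lower <- mean(self - lse + log(K))
    upper <- mean(self - loo + log(K - 1))
  }
  c(lower, upper)
}

draw_feature_batch <- function(x, K) {
  if (is.data.frame(x)) {
    x$value[sample.int(length(x$value), K, replace = TRUE, prob = x$prob)]
  } else {
    x[sample.int(length(x), K, replace = TRUE)]
  }
}

#' Bracketing bounds on a channel's transmitted information
#'
#' Estimates `I(U; X)` for a frozen channel with a contrastive lower bound,
#' `mean_j log[ p(u_j|x_j) / ((1/K) sum_k p(u_j|x_k)) ]`, and a leave-one-out
#' upper bound that excludes the matching term from the mixture. Both use the
#' closed-form Gaussian encodings, are averaged over `n_batches` independent
#' batches of size `K`, and are reported in bits with across-batch standard
#' errors. The lower bound is capped at `log2(K)` by construction, so `K`
#' must comfortably exceed `2^I`.
#'
#' @param channel A `dib_encoder`.
#' @param x Feature values to sample from: a numeric vector (resampled with
#'   replacement), or a data frame with columns `value`, `prob` giving an
#'   exact pmf. Defaults to the uniform pmf over a table channel's levels.
#' @param K Batch size (>= 2).
#' @param n_batches Number of independent batches.
#' @param seed Optional seed (local to the call).
#' @return One-row tibble of class `dib_mi_estimate`: `lower_bits`,
#'   `upper_bits`, `gap_bits`, `std_error`, `se_lower`, `se_upper`,
#'   `n_samples`.
#' @export
mi_bounds <- function(channel, x = NULL, K = 4096, n_batches = 32,
                      seed = NULL) {
  K <- check_positive_int(K, "K")
  if (K < 2L) abort_dibs("`K` must be at least 2.", "invalid_argument")
  n_batches <- check_positive_int(n_batches, "n_batches")
  if (is.null(x)) {
    if (channel$type != "table") {
      abort_dibs("`x` is required for non-table channels.", "invalid_argument")
    }
    x <- data.frame(value = channel$levels,
                    prob = rep(1 / length(channel$levels),
                               length(channel$levels)))
  }
  est <- with_local_seed(seed, {
    vapply(seq_len(n_batches), function(b)
      bound_batch(channel, draw_feature_batch(x, K)), numeric(2))
  })
  lower <- est[1, ] / LOG2
  upper <- est[2, ] / LOG2
  se_l <- stats::sd(lower) / sqrt(n_batches)
  se_u <- stats::sd(upper) / sqrt(n_batches)
  out <- tibble::tibble(
    lower_bits = mean(lower), upper_bits = mean(upper),
    gap_bits = mean(upper) - mean(lower),
    std_error = max(se_l, se_u, na.rm = TRUE),
    se_lower = se_l, se_upper = se_u,
    n_samples = K * n_batches, K = K, n_batches = n_batches)
  class(out) <- c("dib_mi_estimate", class(out))
  out
}

#' Exact mixture evaluation of a discrete channel's information
#'
#' For a channel over an enumerable feature (support of at most 64 values),
#' `I(U; X) = sum_x p(x) E_{u ~ p(u|x)}[log2 p(u|x) - log2 sum_x' p(x')
#' p(u|x')]` is evaluated by unbiased Monte Carlo over the known Gaussian
#' mixture. Serves as the oracle that the bracketing bounds must contain.
#'
#' @param channel A `dib_encoder` over a discrete feature.
#' @param pmf Data frame `value`, `prob`; defaults to uniform over a table
#'   channel's levels.
#' @param n_mc Number of Monte-Carlo draws.
#' @param seed Optional seed (local to the call).
#' @return List with `mi_bits`, `std_error`, `n_mc`.
#' @export
mi_exact_discrete <- function(channel, pmf = NULL, n_mc = 1e5, seed = NULL) {
  if (is.null(pmf)) {
    if (channel$type != "table") {
      abort_dibs("`pmf` is required for non-table channels.",
                 "invalid_argument")
    }
    pmf <- data.frame(value = channel$levels,
                      prob = rep(1 / length(channel$levels),
                                 length(channel$levels)))
  }
  if (nrow(pmf) > 64L) {
    abort_dibs("Discrete support is limited to 64 values.",
               "invalid_argument")
  }
  n_mc <- check_positive_int(n_mc, "n_mc")
  fw <- encoder_forward(channel, pmf$value)
  V <- nrow(pmf)
  with_local_seed(seed, {
    g <- sample.int(V, n_mc, replace = TRUE, prob = pmf$prob)
    u <- fw$mean[g, , drop = FALSE] +
      fw$scale[g, , drop = FALSE] * matrix(stats::rnorm(n_mc * channel$d),
                                           nrow = n_mc)
    L <- vapply(seq_len(V), function(v)
      gaussian_log_density(u, fw$mean[v, ], fw$scale[v, ]), numeric(n_mc))
    A <- sweep(L, 2L, log(pmf$prob), "+")
    mix <- row_logsumexp(A)
    integrand <- (L[cbind(seq_len(n_mc), g)] - mix) / LOG2
    list(mi_bits = mean(integrand),
         std_error = stats::sd(integrand) / sqrt(n_mc),
         n_mc = n_mc)
  })
}

#' Predictive information of a model on a dataset
#'
#' Lower-bounds `I(U; Y)` as `H(Y) - E[-log2 q(y|u)]`, the label entropy
#' minus the decoder's cross-entropy with latents sampled from the channels,
#' averaged over `n_samples` latent draws. Also reports argmax classification
#' accuracy (row-weight aware, so truth-table datasets are scored exactly).
#'
#' @param model A `dib_model` (or `dib_sweep`, whose final model is used).
#' @param data Data frame of features + label (+ optional `prob` weights).
#' @param n_samples Number of latent draws averaged over.
#' @param seed Optional seed (local to the call).
#' @return One-row tibble: `predictive_bits`, `accuracy`, `entropy_bits`,
#'   `ce_bits`.
#' @export
predictive_info <- function(model, data, n_samples = 16, seed = NULL) {
  if (inherits(model, "dib_sweep")) model <- model$model
  prep <- prepare_dib_data(data, model$label)
  y <- match(as.character(tibble::as_tibble(data)[[model$label]]),
             model$label_levels)
  if (anyNA(y)) {
    abort_dibs("Labels outside the model's label set.", "invalid_argument")
  }
  hy <- entropy_bits(as.vector(rowsum(prep$w, y)))
  with_local_seed(seed, {
    ce <- 0
    probs_acc <- NULL
    for (s in seq_len(n_samples)) {
      fw <- dib_forward(model, prep$features, y, prep$w, sample = TRUE)
      ce <- ce + fw$ce / LOG2
      probs_acc <- if (is.null(probs_acc)) fw$probs else probs_acc + fw$probs
    }
    ce <- ce / n_samples
    pred <- max.col(probs_acc, ties.method = "first")
    tibble::tibble(predictive_bits = hy - ce,
                   accuracy = sum(prep$w * (pred == y)),
                   entropy_bits = hy, ce_bits = ce)
  })
}
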