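# Per-feature stochastic compression channels. A channel deterministically
# maps a raw feature value to a diagonal-Gaussian distribution in latent
# space; the information cost of the channel is the KL divergence to the
# fixed standard-Gaussian prior. Three parameterizations are provided:
#  * "table": one (mean, pre-scale) row per discrete feature value — the form
#    any flexible map collapses to on a finite domain (e.g. binary inputs);
#  * "basis": Gaussian-bump basis expansion of a standardized scalar with a
#    trained linear head — smooth, cheap, and expressive enough for
#    threshold-like compressions of continuous measurements;
#  * "mlp": a small tanh network for multi-dimensional inputs (per-particle
#    positions).
# Heads are zero-initialized by default, so a fresh channel sits exactly at
# the prior (zero transmitted bits). Training sweeps instead draw small
# random mean-heads (`init_sd > 0`): starting the anneal at a weak
# bottleneck with slightly informative channels lets the decoder couple to
# every channel at once, whereas exactly-at-prior channels facing an already
# specialized decoder stall (the decoder learns to ignore pure-noise latent
# dimensions, which kills the gradient that would open them).

#' Diagonal-Gaussian latent distributions
#'
#' A batch of diagonal-Gaussian distributions in latent space, one per encoded
#' value: `mean` and `scale` are `n x d` matrices with strictly positive
#' scales.
#'
#' @param mean,scale Numeric matrices (or vectors for a single distribution)
#'   of equal dimensions.
#' @return A `gaussian_latent` object.
#' @export
gaussian_latent <- function(mean, scale) {
  if (is.null(dim(mean))) mean <- matrix(mean, nrow = 1)
  if (is.null(dim(scale))) scale <- matrix(scale, nrow = 1)
  if (!all(dim(mean) == dim(scale))) {
    abort_dibs("`mean` and `scale` must have identical dimensions.",
               "invalid_argument")
  }
  if (any(!is.finite(mean)) || any(!is.finite(scale))) {
    abort_dibs("Latent parameters must be finite.", "invalid_value")
  }
  if (any(scale <= 0)) {
    abort_dibs("Latent scales must be strictly positive.", "invalid_value")
  }
  structure(list(mean = mean, scale = scale, dim = ncol(mean)),
            class = "gaussian_latent")
}

#' Compression channel constructors
#'
#' `encoder_table()` parameterizes one latent Gaussian per discrete feature
#' value; `encoder_basis()` expands a standardized continuous scalar in fixed
#' Gaussian bumps (plus linear and constant terms) and applies a trained
#' linear head; `encoder_mlp()` wraps a small tanh network for vector-valued
#' inputs. All start exactly at the prior (0 transmitted bits).
#'
#' @param feature Feature id (character).
#' @param levels Discrete feature values served by a table channel.
#' @param latent_dim Latent dimensionality `d`.
#' @param center,scale Standardization applied to a continuous feature before
#'   the basis expansion (stored with the channel).
#' @param n_basis Number of Gaussian bumps spanning the standardized range.
#' @param quantiles Optional reference quantiles of the training values,
#'   stored for default distinguishability grids.
#' @param input_dim Input dimensionality of an MLP channel.
#' @param hidden Hidden layer sizes of an MLP channel.
#' @param init_sd Standard deviation of the random mean-head initialization;
#'   0 (the default) starts the channel exactly at the prior.
#' @param act Hidden activation of an MLP channel (`"tanh"` or `"relu"`).
#' @return A `dib_encoder`.
#' @name encoders
NULL

#' @rdname encoders
#' @export
encoder_table <- function(feature, levels = c(0, 1), latent_dim = 4,
                          init_sd = 0) {
  latent_dim <- check_positive_int(latent_dim, "latent_dim")
  P <- matrix(0, nrow = length(levels), ncol = 2L * latent_dim)
  if (init_sd > 0) {
    P[, seq_len(latent_dim)] <- stats::rnorm(length(levels) * latent_dim,
                                             sd = init_sd)
  }
  structure(list(
    type = "table", feature = as.character(feature),
    levels = levels, d = latent_dim,
    params = list(P = P)),
    class = c("encoder_table", "dib_encoder"))
}

#' @rdname encoders
#' @export
encoder_basis <- function(feature, center = 0, scale = 1, latent_dim = 2,
                          n_basis = 12, quantiles = NULL, init_sd = 0) {
  latent_dim <- check_positive_int(latent_dim, "latent_dim")
  centers <- seq(-2.5, 2.5, length.out = n_basis)
  width <- 1.3 * (centers[2] - centers[1])
  P <- matrix(0, nrow = n_basis + 2L, ncol = 2L * latent_dim)
  if (init_sd > 0) {
    P[, seq_len(latent_dim)] <- stats::rnorm((n_basis + 2L) * latent_dim,
                                             sd = init_sd / sqrt(n_basis + 2))
  }
  structure(list(
    type = "basis", feature = as.character(feature),
    center = center, scale = scale, d = latent_dim,
    basis_centers = centers, basis_width = width,
    quantiles = quantiles,
    params = list(P = P)),
    class = c("encoder_basis", "dib_encoder"))
}

#' @rdname encoders
#' @export
encoder_mlp <- function(feature, input_dim, hidden = c(32, 32), latent_dim = 4,
                        center = rep(0, input_dim), scale = rep(1, input_dim),
                        init_sd = 0, act = "tanh") {
  latent_dim <- check_positive_int(latent_dim, "latent_dim")
  net <- mlp_new(c(input_dim, hidden, 2L * latent_dim), act = act,
                 zero_last = TRUE)
  if (init_sd > 0) {
    nl <- length(net$params$W)
    fan_in <- nrow(net$params$W[[nl]])
    net$params$W[[nl]][, seq_len(latent_dim)] <-
      stats::rnorm(fan_in * latent_dim, sd = init_sd / sqrt(fan_in))
  }
  structure(list(
    type = "mlp", feature = as.character(feature),
    input_dim = input_dim, d = latent_dim,
    center = center, scale = scale,
    net = net, params = net$params),
    class = c("encoder_mlp", "dib_encoder"))
}

# ---- forward machinery -----------------------------------------------------

basis_expand <- function(channel, values) {
  z <- (values - channel$center) / channel$scale
  B <- exp(-outer(z, channel$basis_centers, "-")^2 / (2 * channel$basis_width^2))
  cbind(B, z, 1)
}

# internal: forward pass returning mean/pre/scale and a cache for backprop
encoder_forward <- function(channel, values) {
  d <- channel$d
  if (channel$type == "table") {
    idx <- match(values, channel$levels)
    if (anyNA(idx)) {
      abort_dibs(sprintf("Channel '%s': value outside its discrete domain.",
                         channel$feature), "invalid_value")
    }
    H <- channel$params$P[idx, , drop = FALSE]
    cache <- list(idx = idx)
  } else if (channel$type == "basis") {
    Phi <- basis_expand(channel, values)
    H <- Phi %*% channel$params$P
    cache <- list(Phi = Phi)
  } else {
    X <- sweep(sweep(as.matrix(values), 2L, channel$center, "-"),
               2L, channel$scale, "/")
    net <- channel$net
    net$params <- channel$params
    fwd <- mlp_forward(net, X)
    H <- fwd$out
    cache <- list(fwd = fwd)
  }
  pre <- H[, d + seq_len(d), drop = FALSE]
  list(mean = H[, seq_len(d), drop = FALSE],
       pre = pre, scale = pre_to_scale(pre), cache = cache)
}

# internal: backprop through the head given gradients w.r.t. mean and pre
encoder_backward <- function(channel, fw, g_mean, g_pre) {
  GH <- cbind(g_mean, g_pre)
  if (channel$type == "table") {
    gP <- rowsum(GH, fw$cache$idx)
    P <- matrix(0, nrow = length(channel$levels), ncol = ncol(GH))
    P[as.integer(rownames(gP)), ] <- gP
    list(P = P)
  } else if (channel$type == "basis") {
    list(P = crossprod(fw$cache$Phi, GH))
  } else {
    net <- channel$net
    net$params <- channel$params
    mlp_backward(net, fw$cache$fwd, GH)$grads
  }
}

#' Encode feature values to latent distributions
#'
#' The map is deterministic: identical values always receive identical latent
#' distributions. A freshly constructed channel encodes every value to the
#' prior (mean 0, scale 1).
#'
#' @param channel A `dib_encoder`.
#' @param values Feature values (vector; or rows of a matrix for MLP
#'   channels).
#' @return A [gaussian_latent()] with one row per value.
#' @export
encode <- function(channel, values) {
  if (!inherits(channel, "dib_encoder")) {
    abort_dibs("`channel` must be a dib_encoder.", "invalid_argument")
  }
  if (any(!is.finite(as.matrix(values)))) {
    abort_dibs("Feature values must be finite.", "invalid_value")
  }
  fw <- encoder_forward(channel, values)
  gaussian_latent(fw$mean, fw$scale)
}

#' Sample latent codes by reparameterization
#'
#' Draws `mean + scale * eps` with standard-normal `eps` — the differentiable
#' sampling contract used during training.
#'
#' @param latent A [gaussian_latent()].
#' @param seed Optional seed for a reproducible, RNG-state-preserving draw.
#' @return Matrix of samples, one row per distribution.
#' @export
sample_latent <- function(latent, seed = NULL) {
  stopifnot(inherits(latent, "gaussian_latent"))
  n <- nrow(latent$mean)
  d <- ncol(latent$mean)
  eps <- with_local_seed(seed, matrix(stats::rnorm(n * d), nrow = n))
  latent$mean + latent$scale * eps
}

#' Information cost of latent distributions
#'
#' Closed-form KL divergence to the standard-Gaussian prior,
#' `0.5 * sum_d(mean^2 + scale^2 - 1 - 2 log scale)` nats, returned in bits.
#' This is the channel's per-datum transmission cost and the quantity the
#' bottleneck penalizes.
#'
#' @param latent A [gaussian_latent()].
#' @return Numeric vector of KL divergences in bits (one per distribution).
#' @export
kl_to_prior <- function(latent) {
  stopifnot(inherits(latent, "gaussian_latent"))
  if (any(latent$scale <= 0)) {
    abort_dibs("Latent scales must be strictly positive.", "invalid_value")
  }
  kl_nats <- 0.5 * rowSums(latent$mean^2 + latent$scale^2 - 1 -
                             2 * log(latent$scale))
  pmax(kl_nats, 0) / LOG2
}

# log N(u; mean, scale) summed over dims, for a common batch of u rows
# u: n x d; mean/scale: single distribution (length d) -> length-n vector
gaussian_log_density <- function(u, mean, scale) {
  d <- length(mean)
  -0.5 * colSums((t(u) - mean)^2 / scale^2) - sum(log(scale)) -
    0.5 * d * log(2 * pi)
}

# Bhattacharyya coefficient between two sets of diagonal Gaussians, computed
# for all pairs: returns m x m matrix. mean/scale are m x d.
bhattacharyya_matrix <- function(mean, scale) {
  m <- nrow(mean)
  logbc <- matrix(0, m, m)
  for (k in seq_len(ncol(mean))) {
    mu <- mean[, k]; s2 <- scale[, k]^2
    ssum <- outer(s2, s2, "+")
    dmu <- outer(mu, mu, "-")
    logbc <- logbc + 0.25 * log(4 * outer(s2, s2) / ssum^2) - dmu^2 / (4 * ssum)
  }
  exp(logbc)
}

#' @export
print.dib_encoder <- function(x, ...) {
  cat(sprintf("<dib_encoder:%s> feature '%s', latent dim %d\n",
              x$type, x$feature, x$d))
  invisible(x)
}

#' @export
print.gaussian_latent <- function(x, ...) {
  cat(sprintf("<gaussian_latent> %d distribution(s), dim %d\n",
              nrow(x$mean), x$dim))
  invisible(x)
}
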