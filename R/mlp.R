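# Minimal dense feed-forward network with manual backpropagation. The
# workhorse behind decoders and the per-particle encoder channels;
# everything trains with Adam on CPU. Hidden activation is tanh (smooth;
# default) or relu (cheaper per element and quicker to carve sharp
# decision surfaces, used by the larger per-particle nets).

mlp_new <- function(sizes, act = c("tanh", "relu"), zero_last = FALSE,
                    out_bias = NULL, init_sd = NULL) {
  stopifnot(length(sizes) >= 2)
  act <- match.arg(act)
  n_layers <- length(sizes) - 1L
  W <- vector("list", n_layers)
  b <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    fan_in <- sizes[l]
    sd_l <- if (is.null(init_sd)) 1 / sqrt(fan_in) else init_sd
    W[[l]] <- matrix(stats::rnorm(fan_in * sizes[l + 1], sd = sd_l),
                     nrow = fan_in, ncol = sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  if (zero_last) W[[n_layers]][] <- 0
  if (!is.null(out_bias)) b[[n_layers]] <- out_bias
  structure(list(params = list(W = W, b = b), sizes = sizes, act = act),
            class = "dibs_mlp")
}

# forward pass; returns output (linear last layer) and activations for backprop
mlp_forward <- function(net, X) {
  W <- net$params$W; b <- net$params$b
  relu <- identical(net$act, "relu")
  n_layers <- length(W)
  acts <- vector("list", n_layers + 1L)
  acts[[1L]] <- X
  H <- X
  for (l in seq_len(n_layers)) {
    Z <- H %*% W[[l]]
    Z <- Z + rep(b[[l]], each = nrow(Z))
    H <- if (l < n_layers) {
      if (relu) Z * (Z > 0) else tanh(Z)
    } else Z
    acts[[l + 1L]] <- H
  }
  list(out = H, acts = acts)
}

# backward pass: G is dLoss/dOutput (same shape as out).
# Returns parameter gradients (same shapes as params) and dLoss/dInput.
mlp_backward <- function(net, cache, G) {
  W <- net$params$W
  relu <- identical(net$act, "relu")
  n_layers <- length(W)
  gW <- vector("list", n_layers)
  gb <- vector("list", n_layers)
  D <- G  # gradient w.r.t. pre-activation of the current layer
  for (l in rev(seq_len(n_layers))) {
    A_in <- cache$acts[[l]]
    gW[[l]] <- crossprod(A_in, D)
    gb[[l]] <- colSums(D)
    D <- D %*% t(W[[l]])
    if (l > 1L) {  # through the activation of layer l-1
      D <- if (relu) D * (A_in > 0) else D * (1 - A_in * A_in)
    }
  }
  list(grads = list(W = gW, b = gb), g_input = D)
}
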