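# The training engine is hand-rolled, so its gradients are checked against
# finite differences and its optimizer against a simple convergence task.

test_that("relu backprop matches finite-difference gradients", {
  set.seed(31)
  net <- dibs:::mlp_new(c(3, 6, 2), act = "relu")
  X <- matrix(rnorm(15), 5, 3)
  target <- matrix(rnorm(10), 5, 2)
  loss_of <- function(net) {
    out <- dibs:::mlp_forward(net, X)$out
    0.5 * sum((out - target)^2)
  }
  fwd <- dibs:::mlp_forward(net, X)
  bk <- dibs:::mlp_backward(net, fwd, fwd$out - target)
  h <- 1e-6
  for (l in 1:2) {
    for (idx in seq_len(min(8, length(net$params$W[[l]])))) {
      net2 <- net
      net2$params$W[[l]][idx] <- net2$params$W[[l]][idx] + h
      fd <- (loss_of(net2) - loss_of(net)) / h
      expect_equal(bk$grads$W[[l]][idx], fd, tolerance = 1e-4)
    }
  }
})

test_that("mlp backprop matches finite-difference gradients", {
  set.seed(11)
  net <- dibs:::mlp_new(c(3, 4, 2))
  X <- matrix(rnorm(12), 4, 3)
  target <- matrix(rnorm(8), 4, 2)
  loss_of <- function(net) {
    out <- dibs:::mlp_forward(net, X)$out
    0.5 * sum((out - target)^2)
  }
  fwd <- dibs:::mlp_forward(net, X)
  bk <- dibs:::mlp_backward(net, fwd, fwd$out - target)
  h <- 1e-6
  for (l in 1:2) {
    W <- net$params$W[[l]]
    for (idx in seq_len(min(6, length(W)))) {
      net2 <- net
      net2$params$W[[l]][idx] <- net2$params$W[[l]][idx] + h
      fd <- (loss_of(net2) - loss_of(net)) / h
      expect_equal(bk$grads$W[[l]][idx], fd, tolerance = 1e-4)
    }
    for (idx in seq_along(net$params$b[[l]])) {
      net2 <- net
      net2$params$b[[l]][idx] <- net2$params$b[[l]][idx] + h
      fd <- (loss_of(net2) - loss_of(net)) / h
      expect_equal(bk$grads$b[[l]][idx], fd, tolerance = 1e-4)
    }
  }
  # gradient w.r.t. the input
  for (idx in 1:4) {
    X2 <- X
    X2[idx] <- X2[idx] + h
    out2 <- dibs:::mlp_forward(net, X2)$out
    fd <- (0.5 * sum((out2 - target)^2) - loss_of(net)) / h
    expect_equal(bk$g_input[idx], fd, tolerance = 1e-4)
  }
})

test_that("encoder head gradients match finite differences", {
  set.seed(21)
  for (type in c("table", "basis", "mlp")) {
    ch <- switch(type,
      table = encoder_table("x", latent_dim = 2),
      basis = encoder_basis("v", center = 0.2, scale = 1.4, latent_dim = 2),
      mlp = encoder_mlp("p", input_dim = 2, hidden = c(5), latent_dim = 2))
    if (type == "table") {
      ch$params$P <- matrix(rnorm(8, sd = 0.4), 2, 4)
      vals <- c(0, 1, 1, 0)
    } else if (type == "basis") {
      ch$params$P <- matrix(rnorm(length(ch$params$P), sd = 0.2),
                            nrow = nrow(ch$params$P))
      vals <- c(-0.8, 0.3, 1.7)
    } else {
      vals <- matrix(rnorm(6), 3, 2)
    }
    # synthetic smooth loss of the head outputs
    gm <- matrix(rnorm(2 * nrow(as.matrix(vals))), ncol = 2)
    gp <- matrix(rnorm(2 * nrow(as.matrix(vals))), ncol = 2)
    loss_of <- function(ch) {
      fw <- dibs:::encoder_forward(ch, vals)
      sum(gm * fw$mean) + sum(gp * fw$pre)
    }
    fw <- dibs:::encoder_forward(ch, vals)
    grads <- dibs:::encoder_backward(ch, fw, gm, gp)
    flat <- unlist(grads)
    h <- 1e-6
    base <- loss_of(ch)
    set.seed(3)
    pick <- sample(seq_along(flat), min(10, length(flat)))
    num <- vapply(pick, function(i) {
      ch2 <- ch
      p <- unlist(ch2$params)
      p[i] <- p[i] + h
      ch2$params <- utils::relist(p, ch2$params)
      (loss_of(ch2) - base) / h
    }, numeric(1))
    expect_equal(unname(flat[pick]), num, tolerance = 1e-4,
                 label = paste("encoder", type))
  }
})

test_that("adam minimizes a simple regression loss", {
  set.seed(5)
  net <- dibs:::mlp_new(c(2, 8, 1))
  X <- matrix(rnorm(60), 30, 2)
  yt <- matrix(X[, 1] - 2 * X[, 2], ncol = 1)
  state <- dibs:::adam_new()
  params <- net$params
  losses <- numeric(300)
  for (t in 1:300) {
    net$params <- params
    fwd <- dibs:::mlp_forward(net, X)
    losses[t] <- mean((fwd$out - yt)^2)
    bk <- dibs:::mlp_backward(net, fwd, 2 * (fwd$out - yt) / nrow(X))
    st <- dibs:::adam_step(params, bk$grads, state, lr = 0.02)
    params <- st$params
    state <- st$state
  }
  expect_lt(losses[300], 0.05 * losses[1])
})
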