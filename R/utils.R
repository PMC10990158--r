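# Internal utilities: conditions, numerics, seeding, Adam.

LOG2 <- log(2)
# softplus offset chosen so that a zero pre-scale maps to scale 1 exactly
SOFTPLUS_OFFSET <- log(exp(1) - 1)
SCALE_FLOOR <- 1e-6

abort_dibs <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("dibs_", class), "dibs_error"), ...)
}

check_positive_int <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 || x != round(x)) {
    abort_dibs(sprintf("`%s` must be a positive integer, got %s.", name,
                       paste(format(x), collapse = ",")),
               "invalid_argument")
  }
  as.integer(x)
}

#' @keywords internal
softplus <- function(x) {
  # numerically stable log(1 + exp(x)), branch-free
  pmax(x, 0) + log1p(exp(-abs(x)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# pre-scale -> positive scale, equal to 1 at pre = 0
pre_to_scale <- function(pre) SCALE_FLOOR + softplus(pre + SOFTPLUS_OFFSET)
pre_to_scale_grad <- function(pre) sigmoid(pre + SOFTPLUS_OFFSET)

# Shannon entropy of a probability vector, bits
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# binary entropy h(q) in bits, vectorized, h(0)=h(1)=0
binary_entropy_bits <- function(q) {
  h <- numeric(length(q))
  ok <- q > 0 & q < 1
  qq <- q[ok]
  h[ok] <- -qq * log2(qq) - (1 - qq) * log2(1 - qq)
  h
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# run code with a local, restored RNG state
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# fast tibble constructor for hot loops (skips tibble's validation)
fast_tibble <- function(...) {
  cols <- list(...)
  structure(cols, class = c("tbl_df", "tbl", "data.frame"),
            row.names = .set_row_names(length(cols[[1L]])),
            names = names(cols))
}

# ---- Adam over (possibly nested) lists of numeric arrays -------------------

zeros_like <- function(p) {
  if (is.list(p)) return(lapply(p, zeros_like))
  array(0, dim = if (is.null(dim(p))) length(p) else dim(p))
}

adam_new <- function() list(t = 0L, m = NULL, v = NULL)

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  if (is.null(state$m)) {
    state$m <- zeros_like(params)
    state$v <- zeros_like(params)
  }
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      for (k in seq_along(p)) {
        r <- rec(p[[k]], g[[k]], m[[k]], v[[k]])
        p[[k]] <- r$p; m[[k]] <- r$m; v[[k]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / c1) / (sqrt(v / c2) + eps)
    list(p = p, m = m, v = v)
  }
  r <- rec(params, grads, state$m, state$v)
  list(params = r$p, state = list(t = state$t, m = r$m, v = r$v))
}
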