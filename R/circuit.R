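#' Construct a Boolean circuit
#'
#' A Boolean circuit is a directed acyclic wiring of two-or-more-input logic
#' gates (`AND`, `OR`, `XOR`) over `n_inputs` binary input nodes. Nodes are
#' numbered `1..n_inputs` for the inputs and `n_inputs + g` for gate `g`; a
#' gate may only reference inputs or earlier gates.
#'
#' @param n_inputs Number of binary input nodes.
#' @param gates List of gates, each `list(op = "AND"|"OR"|"XOR", args = ids)`
#'   with at least two operand node ids referencing inputs or earlier gates.
#' @param output Node id of the circuit output (defaults to the last gate).
#' @return A `dib_circuit` object.
#' @examples
#' and2 <- boolean_circuit(2, list(list(op = "AND", args = c(1, 2))))
#' truth_table(and2)
#' @export
boolean_circuit <- function(n_inputs, gates, output = NULL) {
  n_inputs <- check_positive_int(n_inputs, "n_inputs")
  if (!is.list(gates) || length(gates) < 1L) {
    abort_dibs("`gates` must be a non-empty list.", "invalid_argument")
  }
  ops <- c("AND", "OR", "XOR")
  for (g in seq_along(gates)) {
    gate <- gates[[g]]
    if (!is.list(gate) || is.null(gate$op) || is.null(gate$args)) {
      abort_dibs("Each gate needs `op` and `args`.", "invalid_argument")
    }
    if (!gate$op %in% ops) {
      abort_dibs(sprintf("Gate %d operator must be one of AND, OR, XOR.", g),
                 "invalid_argument")
    }
    args <- as.integer(gate$args)
    if (length(args) < 2L || anyDuplicated(args) ||
        any(args < 1L | args >= n_inputs + g)) {
      abort_dibs(sprintf(
        "Gate %d operands must be >= 2 distinct ids of inputs or earlier gates.", g),
        "invalid_argument")
    }
    gates[[g]]$args <- args
  }
  n_nodes <- n_inputs + length(gates)
  output <- if (is.null(output)) n_nodes else check_positive_int(output, "output")
  if (output > n_nodes) {
    abort_dibs("`output` references a non-existent node.", "invalid_argument")
  }
  structure(list(n_inputs = n_inputs, gates = gates, output = output),
            class = "dib_circuit")
}

#' Generate a random Boolean circuit
#'
#' Draws a seeded random wiring of 2-input `AND`/`OR`/`XOR` gates such that
#' every input node is an ancestor of the output. Operands are drawn
#' coverage-first: nodes that do not yet feed any gate are consumed before
#' already-used nodes, which guarantees connectivity when
#' `n_gates >= n_inputs - 1` (with 2-input gates, fewer gates cannot connect
#' all inputs to the output). For circuits with at most 12 inputs, draws in
#' which some input is logically absorbed (flipping it never changes the
#' output) are rejected and redrawn, so every input genuinely carries
#' information. The same seed always yields the same circuit.
#'
#' @param n_inputs,n_gates Circuit size (both >= 1; see connectivity note).
#' @param seed Integer seed; the draw is local and does not disturb the
#'   session RNG.
#' @return A `dib_circuit`.
#' @examples
#' generate_circuit(10, 9, seed = 7)
#' @export
generate_circuit <- function(n_inputs, n_gates, seed = 1L) {
  n_inputs <- check_positive_int(n_inputs, "n_inputs")
  n_gates <- check_positive_int(n_gates, "n_gates")
  if (n_inputs < 2L) {
    abort_dibs("2-input gates need at least two circuit inputs.",
               "invalid_argument")
  }
  if (n_gates < n_inputs - 1L) {
    abort_dibs(sprintf(
      paste("With 2-input gates, %d gate(s) cannot connect all %d inputs to",
            "the output; need n_gates >= n_inputs - 1."), n_gates, n_inputs),
      "invalid_argument")
  }
  ops <- c("AND", "OR", "XOR")
  with_local_seed(seed, {
    result <- NULL
    for (attempt in 1:1000) {
      used <- logical(n_inputs + n_gates)  # node already feeds some gate?
      gates <- vector("list", n_gates)
      for (g in seq_len(n_gates)) {
        pool <- seq_len(n_inputs + g - 1L)
        fresh <- pool[!used[pool]]
        take <- min(2L, length(fresh))
        args <- if (take > 0L) fresh[sample.int(length(fresh), take)] else integer()
        if (take < 2L) {
          rest <- setdiff(pool, args)
          args <- c(args, rest[sample.int(length(rest), 2L - take)])
        }
        used[args] <- TRUE
        gates[[g]] <- list(op = ops[sample.int(3L, 1L)], args = as.integer(args))
      }
      circ <- boolean_circuit(n_inputs, gates)
      if (all(seq_len(n_inputs) %in% circuit_ancestors(circ)) &&
          circuit_inputs_relevant(circ)) {
        result <- circ
        break
      }
    }
    if (is.null(result)) {
      abort_dibs("Failed to draw a connected circuit.", "invalid_argument")
    }
    result
  })
}

# For small circuits, verify each input is functionally relevant: flipping
# it changes the output on at least one assignment. Ancestry alone can leave
# an input logically absorbed (e.g. OR(x, AND(x, z)) ignores z), and an
# absorbed input carries no information about the output.
circuit_inputs_relevant <- function(circuit, max_inputs = 12L) {
  n <- circuit$n_inputs
  if (n > max_inputs) return(TRUE)
  rows <- 2L^n
  X <- matrix(0L, nrow = rows, ncol = n)
  for (i in seq_len(n)) {
    X[, i] <- rep(rep(0:1, each = 2L^(n - i)), times = 2L^(i - 1L))
  }
  y <- eval_circuit(circuit, X)
  for (i in seq_len(n)) {
    Xf <- X
    Xf[, i] <- 1L - Xf[, i]
    if (all(eval_circuit(circuit, Xf) == y)) return(FALSE)
  }
  TRUE
}

# node ids that are ancestors of the output (including the output itself)
circuit_ancestors <- function(circuit) {
  n_in <- circuit$n_inputs
  anc <- logical(n_in + length(circuit$gates))
  anc[circuit$output] <- TRUE
  for (g in rev(seq_along(circuit$gates))) {
    if (anc[n_in + g]) anc[circuit$gates[[g]]$args] <- TRUE
  }
  which(anc)
}

#' Evaluate a Boolean circuit on input assignments
#'
#' @param circuit A `dib_circuit`.
#' @param X Matrix (or data frame) of 0/1 input values, one column per input.
#' @return Integer vector of output bits, one per row of `X`.
#' @export
eval_circuit <- function(circuit, X) {
  X <- as.matrix(X)
  if (ncol(X) != circuit$n_inputs) {
    abort_dibs("`X` must have one column per circuit input.", "invalid_argument")
  }
  if (!all(X %in% c(0, 1))) {
    abort_dibs("Inputs must be 0/1.", "invalid_value")
  }
  vals <- matrix(0L, nrow = nrow(X), ncol = circuit$n_inputs + length(circuit$gates))
  vals[, seq_len(circuit$n_inputs)] <- as.integer(X)
  for (g in seq_along(circuit$gates)) {
    gate <- circuit$gates[[g]]
    a <- vals[, gate$args, drop = FALSE]
    v <- switch(gate$op,
      AND = as.integer(rowSums(a) == ncol(a)),
      OR  = as.integer(rowSums(a) > 0L),
      XOR = as.integer(rowSums(a) %% 2L))
    vals[, circuit$n_inputs + g] <- v
  }
  vals[, circuit$output]
}

#' Enumerate the truth table of a circuit
#'
#' Enumerates all `2^N` input assignments in lexicographic order (input 1 is
#' the most significant bit) and tabulates the output together with a uniform
#' row probability `2^-N`, so the table is the exact joint distribution
#' `p(x1, ..., xN, y)`.
#'
#' @param circuit A `dib_circuit` with at most 20 inputs.
#' @return A tibble of class `dib_truth_table` with columns `x1..xN`, `y`,
#'   `prob`.
#' @export
truth_table <- function(circuit) {
  n <- circuit$n_inputs
  if (n > 20L) {
    abort_dibs("Truth-table enumeration is limited to 20 inputs.",
               "enumeration_too_large")
  }
  rows <- 2L^n
  X <- matrix(0L, nrow = rows, ncol = n)
  for (i in seq_len(n)) {
    X[, i] <- rep(rep(0:1, each = 2L^(n - i)), times = 2L^(i - 1L))
  }
  colnames(X) <- paste0("x", seq_len(n))
  y <- eval_circuit(circuit, X)
  out <- tibble::as_tibble(as.data.frame(X))
  out$y <- y
  out$prob <- rep(1 / rows, rows)
  class(out) <- c("dib_truth_table", class(out))
  attr(out, "n_inputs") <- n
  out
}

table_parts <- function(table) {
  n <- attr(table, "n_inputs")
  if (is.null(n)) n <- sum(grepl("^x[0-9]+$", names(table)))
  list(X = as.matrix(table[paste0("x", seq_len(n))]),
       y = table$y,
       prob = if ("prob" %in% names(table)) table$prob else
         rep(1 / nrow(table), nrow(table)),
       n = n)
}

# I(X_S; Y) in bits from key vector, binary y and row probabilities
mi_key_y <- function(key, y, prob) {
  p1 <- sum(prob[y == 1])
  hy <- binary_entropy_bits(p1)
  pk <- rowsum(prob, key)
  pk1 <- rowsum(prob * (y == 1), key)
  hycond <- sum(pk * binary_entropy_bits(pk1 / pk))
  max(hy - hycond, 0)
}

#' Exact mutual information between a subset of inputs and the output
#'
#' Marginalizes the truth-table joint distribution to compute
#' `I(X_S; Y) = H(Y) - H(Y | X_S)` exactly, in bits.
#'
#' @param table A `dib_truth_table` (or data frame with `x*`, `y`, `prob`).
#' @param subset Integer vector of input indices (may be empty).
#' @return Mutual information in bits.
#' @examples
#' and2 <- boolean_circuit(2, list(list(op = "AND", args = c(1, 2))))
#' subset_information(truth_table(and2), 1)  # 0.3112781
#' @export
subset_information <- function(table, subset) {
  parts <- table_parts(table)
  subset <- as.integer(subset)
  if (length(subset) && (anyNA(subset) || any(subset < 1L | subset > parts$n))) {
    abort_dibs("`subset` indices must lie in 1..n_inputs.", "invalid_argument")
  }
  if (!length(subset)) return(0)
  key <- as.vector(parts$X[, subset, drop = FALSE] %*% 2^(seq_along(subset) - 1))
  mi_key_y(key, parts$y, parts$prob)
}

#' All-subsets information frontier
#'
#' Computes `I(X_S; Y)` for every subset `S` of the inputs and the
#' per-cardinality upper envelope `max_{|S| = k} I(X_S; Y)` — the discrete
#' information allocations that a distributed-bottleneck sweep traces.
#'
#' @param table A `dib_truth_table` with at most 14 inputs.
#' @return A tibble of class `dib_frontier` with columns `subset` (list),
#'   `size`, `mi_bits`, and an `envelope` attribute
#'   (tibble `size`, `mi_bits`).
#' @export
subset_frontier <- function(table) {
  parts <- table_parts(table)
  n <- parts$n
  if (n > 14L) {
    abort_dibs("Subset enumeration is limited to 14 inputs.",
               "enumeration_too_large")
  }
  masks <- 0:(2L^n - 1L)
  weights <- 2^(0:(n - 1))
  mi <- numeric(length(masks))
  size <- integer(length(masks))
  subsets <- vector("list", length(masks))
  for (m in masks) {
    idx <- which(bitwAnd(m, bitwShiftL(1L, 0:(n - 1L))) != 0L)
    subsets[[m + 1L]] <- idx
    size[m + 1L] <- length(idx)
    if (length(idx) == 0L) { mi[m + 1L] <- 0; next }
    key <- as.vector(parts$X[, idx, drop = FALSE] %*% weights[seq_along(idx)])
    mi[m + 1L] <- mi_key_y(key, parts$y, parts$prob)
  }
  out <- tibble::tibble(subset = subsets, size = size, mi_bits = mi)
  env <- out |>
    dplyr::group_by(.data$size) |>
    dplyr::summarise(mi_bits = max(.data$mi_bits), .groups = "drop")
  class(out) <- c("dib_frontier", class(out))
  attr(out, "envelope") <- env
  attr(out, "n_inputs") <- n
  out
}

#' Read/write circuits and truth tables
#'
#' Circuits serialize to JSON as `{n_inputs, gates: [{op, args}], output}`;
#' truth tables to CSV with header `x1..xN,y,prob`.
#'
#' @param circuit,table Objects to write.
#' @param path File path.
#' @return `read_circuit()` a `dib_circuit`; `read_truth_table()` a
#'   `dib_truth_table`; writers return the path invisibly.
#' @name circuit-io
NULL

#' @rdname circuit-io
#' @export
write_circuit <- function(circuit, path) {
  jsonlite::write_json(
    list(n_inputs = circuit$n_inputs,
         gates = lapply(circuit$gates, function(g) list(op = g$op, args = g$args)),
         output = circuit$output),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname circuit-io
#' @export
read_circuit <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  boolean_circuit(raw$n_inputs,
                  lapply(raw$gates, function(g)
                    list(op = g$op, args = unlist(g$args))),
                  output = raw$output)
}

#' @rdname circuit-io
#' @export
write_truth_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname circuit-io
#' @export
read_truth_table <- function(path) {
  df <- utils::read.csv(path)
  n <- sum(grepl("^x[0-9]+$", names(df)))
  out <- tibble::as_tibble(df)
  if (!"prob" %in% names(out)) out$prob <- rep(1 / nrow(out), nrow(out))
  if (abs(sum(out$prob) - 1) > 1e-12) {
    abort_dibs("Truth-table probabilities must sum to 1.", "invalid_value")
  }
  class(out) <- c("dib_truth_table", class(out))
  attr(out, "n_inputs") <- n
  out
}

#' @export
print.dib_circuit <- function(x, ...) {
  cat(sprintf("<dib_circuit> %d inputs, %d gates, output node %d\n",
              x$n_inputs, length(x$gates), x$output))
  for (g in seq_along(x$gates)) {
    cat(sprintf("  node %d = %s(%s)\n", x$n_inputs + g, x$gates[[g]]$op,
                paste(x$gates[[g]]$args, collapse = ", ")))
  }
  invisible(x)
}
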