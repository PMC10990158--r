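# Analysis artifacts derived from a trained sweep: information-plane
# trajectories, per-feature allocation heatmaps, informative-subset
# identification, distinguishability matrices and threshold summaries.

channel_eval_input <- function(channel, values, w) {
  if (channel$type == "table") {
    agg <- rowsum(w, values)
    data.frame(value = as.numeric(rownames(agg)), prob = agg[, 1] / sum(agg))
  } else if (channel$type == "basis" && !is.null(channel$quantiles)) {
    # discretize onto the channel's stored quantile grid: the grouped bound
    # path is ~30x cheaper than the K x K mixture and the smooth basis
    # encoders are near-constant within a quantile bin
    grid <- sort(unique(channel$quantiles))
    cuts <- (grid[-1] + grid[-length(grid)]) / 2
    idx <- findInterval(values, cuts) + 1L
    agg <- rowsum(w, idx)
    data.frame(value = grid[as.integer(rownames(agg))],
               prob = agg[, 1] / sum(agg))
  } else {
    values
  }
}

#' Information-plane trajectory of a sweep
#'
#' For each checkpoint, estimates every channel's transmitted information
#' (midpoint of the [mi_bounds()] bracket) and the predictive information
#' and accuracy of the decoder ([predictive_info()]), giving one point of
#' the distributed information plane: predictive bits versus total utilized
#' bits, with the per-feature allocation attached.
#'
#' @param sweep A `dib_sweep`.
#' @param data Dataset to evaluate on (defaults to requiring explicit data).
#' @param checkpoints Indices of checkpoints to evaluate (default all).
#' @param K,n_batches Batch size and batch count for the per-channel bounds.
#' @param n_label_samples Latent draws for the predictive-information term.
#' @param seed Optional evaluation seed (local).
#' @return Tibble of class `dib_info_plane`, ordered by `total_bits`, with
#'   columns `checkpoint`, `step`, `beta`, `total_bits`, `predictive_bits`,
#'   `accuracy` and a list-column `allocation` of named per-channel bits.
#' @export
info_plane <- function(sweep, data, checkpoints = NULL, K = 1024,
                       n_batches = 4, n_label_samples = 8, seed = NULL) {
  stopifnot(inherits(sweep, "dib_sweep"))
  if (is.null(checkpoints)) checkpoints <- seq_along(sweep$checkpoints)
  if (!length(checkpoints)) {
    abort_dibs("Need at least one checkpoint.", "invalid_argument")
  }
  prep <- prepare_dib_data(data, sweep$label)
  eval_inputs <- lapply(sweep$model$channels, function(ch)
    channel_eval_input(ch, prep$features[[ch$feature]], prep$w))
  rows <- with_local_seed(seed, lapply(checkpoints, function(ci) {
    model <- checkpoint_model(sweep, ci)
    alloc <- vapply(names(model$channels), function(f) {
      est <- tryCatch(
        mi_bounds(model$channels[[f]], eval_inputs[[f]], K = K,
                  n_batches = n_batches),
        error = function(e) abort_dibs(
          sprintf("MI estimation failed at checkpoint %d, channel '%s': %s",
                  ci, f, conditionMessage(e)), "estimation_failure"))
      (est$lower_bits + est$upper_bits) / 2
    }, numeric(1))
    pred <- predictive_info(model, data, n_samples = n_label_samples)
    tibble::tibble(
      checkpoint = ci,
      step = sweep$checkpoints[[ci]]$step,
      beta = sweep$checkpoints[[ci]]$beta,
      total_bits = sum(alloc),
      predictive_bits = pred$predictive_bits,
      accuracy = pred$accuracy,
      allocation = list(alloc))
  }))
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$total_bits)
  class(out) <- c("dib_info_plane", class(out))
  attr(out, "features") <- sweep$features
  attr(out, "entropy_bits") <- entropy_bits(as.vector(rowsum(prep$w, prep$y)))
  out
}

#' Per-feature information allocation heatmap
#'
#' Rearranges the allocations of an information-plane trajectory into a
#' long feature-by-checkpoint table of transmitted bits (rows ordered by
#' feature id, columns by total utilized information), the form plotted as
#' an allocation heatmap.
#'
#' @param plane A `dib_info_plane`.
#' @return Tibble of class `dib_allocation` with columns `feature`,
#'   `checkpoint`, `total_bits`, `bits`.
#' @export
allocation_heatmap <- function(plane) {
  stopifnot(inherits(plane, "dib_info_plane"))
  feats <- names(plane$allocation[[1]])
  same <- vapply(plane$allocation, function(a) identical(names(a), feats),
                 logical(1))
  if (!all(same)) {
    abort_dibs("Checkpoints carry inconsistent feature sets.",
               "invalid_argument")
  }
  out <- tidyr::unnest_longer(
    dplyr::select(plane, "checkpoint", "total_bits", "allocation"),
    "allocation", values_to = "bits", indices_to = "feature")
  out <- dplyr::arrange(out[, c("feature", "checkpoint", "total_bits",
                                "bits")],
                        match(.data$feature, feats), .data$total_bits)
  class(out) <- c("dib_allocation", class(out))
  attr(out, "features") <- feats
  out
}

#' Features carrying at least a threshold of information
#'
#' Identifies the subset of features whose estimated per-channel information
#' meets a threshold (default 0.1 bits) — the informative-subset readout
#' annotated along an information-plane trajectory.
#'
#' @param x A named numeric vector of per-channel bits, or a
#'   `dib_info_plane` (each point gets its subset).
#' @param threshold_bits Non-negative threshold in bits.
#' @return Character vector of feature ids, or the plane with an added
#'   `informative` list-column.
#' @export
informative_subsets <- function(x, threshold_bits = 0.1) {
  if (!is.numeric(threshold_bits) || threshold_bits < 0) {
    abort_dibs("`threshold_bits` must be >= 0.", "invalid_argument")
  }
  if (inherits(x, "dib_info_plane")) {
    x$informative <- lapply(x$allocation, function(a)
      names(a)[a >= threshold_bits & a > 0])
    return(x)
  }
  names(x)[x >= threshold_bits & x > 0]
}

#' Distinguishability matrix of a compression channel
#'
#' Quantifies, for every pair of raw feature values, how separable their
#' latent encodings are: `1 - BC(p(u|x_a), p(u|x_b))` with `BC` the
#' Bhattacharyya coefficient (closed form for diagonal Gaussians). 0 means
#' the two values are indistinguishable to the predictive model, 1 fully
#' distinguishable.
#'
#' @param channel A `dib_encoder`.
#' @param grid Feature values to compare (default: the channel's stored
#'   training quantiles, or its discrete levels).
#' @return An `m x m` matrix of class `dib_distinguishability` (attributes
#'   `grid`, `feature`): symmetric, zero diagonal, entries in `[0, 1]`.
#' @export
distinguishability_matrix <- function(channel, grid = NULL) {
  if (is.null(grid)) {
    grid <- if (channel$type == "table") channel$levels else channel$quantiles
  }
  if (is.null(grid) || length(grid) < 2L) {
    abort_dibs("Need a grid of at least two feature values.",
               "invalid_argument")
  }
  grid <- sort(unique(grid))
  if (channel$type == "basis") {
    z <- abs((grid - channel$center) / channel$scale)
    if (any(z > 4)) {
      rlang::warn("Grid values lie far outside the standardization range.")
    }
  }
  fw <- encoder_forward(channel, grid)
  D <- 1 - bhattacharyya_matrix(fw$mean, fw$scale)
  D <- pmin(pmax((D + t(D)) / 2, 0), 1)
  diag(D) <- 0
  structure(D, class = c("dib_distinguishability", class(D)),
            grid = grid, feature = channel$feature)
}

#' Detect a threshold-like compression scheme
#'
#' Scans all cut positions of a distinguishability matrix's value grid and
#' finds the two-block constant approximation (one constant per within-block
#' region, one for the between-block region, diagonal excluded) with the
#' smallest squared error — the learned cutoff when a channel compresses a
#' continuous measurement to a simple threshold.
#'
#' @param matrix A `dib_distinguishability` with at least 3 grid values.
#' @return List of class `dib_threshold`: `cutoff` (midpoint of the grid
#'   values flanking the best cut), `cut_index`, `within_mean`,
#'   `between_mean`, `error`, `degenerate`.
#' @export
detect_threshold <- function(matrix) {
  stopifnot(inherits(matrix, "dib_distinguishability"))
  grid <- attr(matrix, "grid")
  m <- nrow(matrix)
  if (m < 3L) {
    abort_dibs("Need at least 3 grid values.", "invalid_argument")
  }
  D <- unclass(matrix)
  if (max(D) < 1e-10) {
    return(structure(list(cutoff = NA_real_, cut_index = NA_integer_,
                          within_mean = 0, between_mean = 0, error = 0,
                          degenerate = TRUE), class = "dib_threshold"))
  }
  off <- row(D) != col(D)
  best <- NULL
  for (cut in seq_len(m - 1L)) {
    b1 <- seq_len(cut)
    b2 <- (cut + 1L):m
    w1 <- D[b1, b1, drop = FALSE][off[b1, b1, drop = FALSE]]
    w2 <- D[b2, b2, drop = FALSE][off[b2, b2, drop = FALSE]]
    bt <- as.vector(D[b1, b2, drop = FALSE])
    sse <- 0
    for (blk in list(w1, w2, bt)) {
      if (length(blk)) sse <- sse + sum((blk - mean(blk))^2)
    }
    if (is.null(best) || sse < best$error) {
      within <- c(w1, w2)
      best <- list(cutoff = (grid[cut] + grid[cut + 1L]) / 2,
                   cut_index = cut,
                   within_mean = if (length(within)) mean(within) else 0,
                   between_mean = mean(bt),
                   error = sse, degenerate = FALSE)
    }
  }
  structure(best, class = "dib_threshold")
}

#' Class-conditional histograms of a feature
#'
#' Histograms of a feature's values conditioned on a binary label, on a
#' shared grid, with the overlap statistic
#' `sum min(density_0, density_1) * binwidth`.
#'
#' @param data Data frame with the feature and label columns.
#' @param feature Feature column name.
#' @param label Label column name (must have exactly two observed classes).
#' @param bins Number of shared bins.
#' @return Tibble of class `dib_cond_hist` with columns `mid`, `density_0`,
#'   `density_1` and attributes `overlap`, `feature`, `classes`.
#' @export
conditional_histograms <- function(data, feature, label = "y", bins = 32) {
  data <- tibble::as_tibble(data)
  if (!feature %in% names(data)) {
    abort_dibs(sprintf("Feature '%s' not found.", feature),
               "invalid_argument")
  }
  yf <- factor(data[[label]])
  if (nlevels(yf) != 2L) {
    abort_dibs("Conditional histograms need exactly two label classes.",
               "degenerate_labels")
  }
  v <- data[[feature]]
  breaks <- seq(min(v), max(v), length.out = bins + 1L)
  if (breaks[1] == breaks[bins + 1L]) breaks <- breaks[1] + c(-0.5, 0.5)
  h0 <- graphics::hist(v[yf == levels(yf)[1]], breaks = breaks, plot = FALSE)
  h1 <- graphics::hist(v[yf == levels(yf)[2]], breaks = breaks, plot = FALSE)
  bw <- diff(breaks)
  out <- tibble::tibble(mid = h0$mids, density_0 = h0$density,
                        density_1 = h1$density)
  class(out) <- c("dib_cond_hist", class(out))
  attr(out, "overlap") <- sum(pmin(h0$density, h1$density) * bw)
  attr(out, "feature") <- feature
  attr(out, "classes") <- levels(yf)
  out
}
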