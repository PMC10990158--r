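# broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an information-plane trajectory
#'
#' One row per (checkpoint, feature) with the allocated bits, alongside the
#' checkpoint's totals.
#'
#' @param x A `dib_info_plane`.
#' @param ... Unused.
#' @return A tibble: `checkpoint`, `step`, `beta`, `feature`, `bits`,
#'   `total_bits`, `predictive_bits`, `accuracy`.
#' @method tidy dib_info_plane
#' @export
tidy.dib_info_plane <- function(x, ...) {
  tidyr::unnest_longer(
    dplyr::select(tibble::as_tibble(x), "checkpoint", "step", "beta",
                  "total_bits", "predictive_bits", "accuracy", "allocation"),
    "allocation", values_to = "bits", indices_to = "feature")[
      , c("checkpoint", "step", "beta", "feature", "bits", "total_bits",
          "predictive_bits", "accuracy")]
}

#' Glance at an information-plane trajectory
#'
#' @param x A `dib_info_plane`.
#' @param ... Unused.
#' @return One-row tibble: number of points, final total/predictive bits,
#'   final accuracy, label entropy.
#' @method glance dib_info_plane
#' @export
glance.dib_info_plane <- function(x, ...) {
  last <- x[which.max(x$total_bits), ]
  tibble::tibble(n_points = nrow(x),
                 max_total_bits = last$total_bits,
                 max_predictive_bits = max(x$predictive_bits),
                 accuracy_at_max = last$accuracy,
                 entropy_bits = attr(x, "entropy_bits"))
}

#' Tidy a trained sweep
#'
#' One row per checkpoint with the training-time loss components.
#'
#' @param x A `dib_sweep` or `dib_set_sweep`.
#' @param ... Unused.
#' @return Tibble: `checkpoint`, `step`, `beta`, `ce_nats`, `kl_bits`.
#' @method tidy dib_sweep
#' @export
tidy.dib_sweep <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$checkpoints), function(i) {
    ck <- x$checkpoints[[i]]
    tibble::tibble(checkpoint = i, step = ck$step, beta = ck$beta,
                   ce_nats = ck$ce_nats, kl_bits = ck$kl_bits)
  }))
}

#' @rdname tidy.dib_sweep
#' @method tidy dib_set_sweep
#' @export
tidy.dib_set_sweep <- tidy.dib_sweep

#' Glance at a trained sweep
#'
#' @param x A `dib_sweep`.
#' @param ... Unused.
#' @return One-row tibble with the sweep configuration and final loss
#'   components.
#' @method glance dib_sweep
#' @export
glance.dib_sweep <- function(x, ...) {
  last <- x$checkpoints[[length(x$checkpoints)]]
  tibble::tibble(n_channels = length(x$features),
                 n_steps = x$config$n_steps,
                 n_checkpoints = length(x$checkpoints),
                 beta_start = x$config$beta_start,
                 beta_end = x$config$beta_end,
                 final_ce_nats = last$ce_nats,
                 final_kl_bits = last$kl_bits)
}

#' Tidy a softness baseline
#'
#' @param x A `dib_softness`.
#' @param ... Unused.
#' @return Tibble: `feature`, `weight`.
#' @method tidy dib_softness
#' @export
tidy.dib_softness <- function(x, ...) {
  tibble::tibble(feature = names(x$weights), weight = unname(x$weights))
}

#' Tidy a subset frontier
#'
#' @param x A `dib_frontier`.
#' @param ... Unused.
#' @return Tibble: `subset` (comma-joined ids), `size`, `mi_bits`.
#' @method tidy dib_frontier
#' @export
tidy.dib_frontier <- function(x, ...) {
  tibble::tibble(
    subset = vapply(x$subset, function(s) paste(s, collapse = ","),
                    character(1)),
    size = x$size, mi_bits = x$mi_bits)
}
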