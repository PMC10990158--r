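# Synthetic stand-in for a sheared binary-glass dataset: 2D two-type local
# particle neighborhoods with a planted, shell-localized rearrangement rule,
# the radial-band density featurization, center-referenced radial
# distribution functions, and the linear (softness-style) SVM baseline.

#' Radial shell grid
#'
#' Default grid of 50 shell centers per particle type, uniform on
#' `(r_min, r_max]` in simulation length units.
#'
#' @param n_shells Number of shells per type.
#' @param r_min,r_max Radial range.
#' @return Numeric vector of shell-center radii.
#' @export
shell_centers <- function(n_shells = 50, r_min = 0.25, r_max = 5) {
  r_min + seq_len(n_shells) * (r_max - r_min) / n_shells
}

#' Planted rearrangement rule
#'
#' Ground-truth labeling mechanism for the synthetic neighborhoods: the true
#' Gaussian-smeared occupancy of one radial shell (for one particle type) is
#' thresholded — low occupancy means "rearrangement" (label 1), mimicking
#' predictive signal concentrated in a near-center low-density band — and
#' the label is flipped with probability `noise`.
#'
#' @param shell Index of the informative shell (into [shell_centers()]).
#' @param type Particle type carrying the signal, `"A"` or `"B"`.
#' @param threshold Occupancy threshold; `NULL` uses the dataset median so
#'   classes are balanced by construction.
#' @param noise Label-flip probability in `[0, 0.5]`.
#' @return A `dib_planted_rule`.
#' @export
planted_rule <- function(shell = 8, type = "A", threshold = NULL,
                         noise = 0.1) {
  shell <- check_positive_int(shell, "shell")
  if (!type %in% c("A", "B")) {
    abort_dibs("`type` must be 'A' or 'B'.", "invalid_argument")
  }
  if (!is.numeric(noise) || noise < 0 || noise > 0.5) {
    abort_dibs("`noise` must lie in [0, 0.5].", "invalid_argument")
  }
  structure(list(shell = shell, type = type, threshold = threshold,
                 noise = noise),
            class = "dib_planted_rule")
}

rule_occupancy <- function(particles_r, particles_type, rule, centers,
                           width) {
  r0 <- centers[rule$shell]
  sum(exp(-(particles_r[particles_type == rule$type] - r0)^2 /
            (2 * width^2)))
}

#' Synthesize labeled particle neighborhoods
#'
#' Generates `n` 2D local neighborhoods: a type-A particle at the origin
#' (the candidate rearrangement locus) surrounded by a hard-core
#' (minimum-distance) point process at the stated number density inside a
#' disc of radius `r_max`, with types drawn A with probability `frac_a`.
#' Labels come from the planted rule applied to the true shell occupancy,
#' flipped with probability `rule$noise`; with the default median threshold
#' the classes are balanced by construction.
#'
#' @param n Number of neighborhoods (>= 2).
#' @param rule A [planted_rule()].
#' @param r_max Neighborhood radius (simulation units).
#' @param density Number density of particles.
#' @param frac_a Fraction of type-A (small) particles.
#' @param hard_core Minimum inter-particle distance (0 for an ideal gas).
#' @param shell_width Gaussian shell width used for the rule occupancy (and
#'   the default featurization).
#' @param seed Seed (local to the call).
#' @return Tibble of class `dib_neighborhoods`: `id`, `label`,
#'   `n_particles`, and list-column `particles` (tibbles with `type`, `x`,
#'   `y`, `is_center`). Attributes record the generator parameters, the
#'   materialized threshold and the true occupancies.
#' @export
synthesize_neighborhoods <- function(n, rule = planted_rule(), r_max = 5,
                                     density = 1, frac_a = 0.65,
                                     hard_core = 0.5, shell_width = 0.1,
                                     seed = 1L) {
  n <- check_positive_int(n, "n")
  if (n < 2L) abort_dibs("`n` must be at least 2.", "invalid_argument")
  if (!inherits(rule, "dib_planted_rule")) {
    abort_dibs("`rule` must be a dib_planted_rule.", "invalid_argument")
  }
  coverage <- density * pi * (hard_core / 2)^2
  if (coverage > 0.45) {
    abort_dibs(sprintf(
      "Density %.3g with hard core %.3g is beyond the random packing limit.",
      density, hard_core), "packing_error")
  }
  centers <- shell_centers(r_max = r_max)
  if (rule$shell > length(centers)) {
    abort_dibs("Rule shell index exceeds the shell grid.", "invalid_argument")
  }
  hc2 <- hard_core^2
  inv2w2 <- 1 / (2 * shell_width^2)
  out <- with_local_seed(seed, {
    counts <- pmax(stats::rpois(n, density * pi * r_max^2), 1L)
    particles <- vector("list", n)
    occ <- numeric(n)
    for (i in seq_len(n)) {
      np <- counts[i]
      # sentinel coordinates keep the rejection test allocation-free
      xs <- rep.int(1e6, np); ys <- rep.int(1e6, np)
      xs[1] <- 0; ys[1] <- 0  # center particle at the origin
      placed <- 1L
      attempts <- 0L
      max_attempts <- 400L * np
      pool_n <- 0L; pool_i <- 0L
      while (placed < np) {
        if (pool_i >= pool_n) {  # refill uniform-in-disc proposal pool
          pool_n <- 4L * np
          rr <- r_max * sqrt(stats::runif(pool_n))
          th <- stats::runif(pool_n, 0, 2 * pi)
          pool_x <- rr * cos(th); pool_y <- rr * sin(th)
          pool_i <- 0L
        }
        pool_i <- pool_i + 1L
        attempts <- attempts + 1L
        if (attempts > max_attempts) {
          abort_dibs("Could not place particles at the requested density.",
                     "packing_error")
        }
        cx <- pool_x[pool_i]; cy <- pool_y[pool_i]
        if (hc2 > 0 && min((xs - cx)^2 + (ys - cy)^2) < hc2) next
        placed <- placed + 1L
        xs[placed] <- cx; ys[placed] <- cy
      }
      type <- c("A", c("B", "A")[(stats::runif(np - 1L) < frac_a) + 1L])
      r <- sqrt(xs^2 + ys^2)
      r0 <- centers[rule$shell]
      rsel <- r[type == rule$type]
      occ[i] <- sum(exp(-(rsel - r0)^2 * inv2w2))
      particles[[i]] <- fast_tibble(
        type = type, x = xs, y = ys,
        is_center = c(TRUE, rep(FALSE, np - 1L)))
    }
    tau <- if (is.null(rule$threshold)) stats::median(occ) else rule$threshold
    label_clean <- as.integer(occ < tau)
    flip <- stats::runif(n) < rule$noise
    label <- as.integer(xor(label_clean == 1L, flip))
    list(particles = particles, occ = occ, tau = tau, label = label,
         label_clean = label_clean, counts = counts)
  })
  res <- tibble::tibble(id = seq_len(n), label = out$label,
                        n_particles = out$counts,
                        particles = out$particles)
  class(res) <- c("dib_neighborhoods", class(res))
  attr(res, "params") <- list(r_max = r_max, density = density,
                              frac_a = frac_a, hard_core = hard_core,
                              shell_width = shell_width, seed = seed)
  attr(res, "rule") <- rule
  attr(res, "threshold") <- out$tau
  attr(res, "occupancy") <- out$occ
  attr(res, "label_clean") <- out$label_clean
  attr(res, "shell_centers") <- centers
  res
}

feature_names_radial <- function(n_shells = 50) {
  c(sprintf("A%02d", seq_len(n_shells)), sprintf("B%02d", seq_len(n_shells)))
}

#' Radial-band density features
#'
#' The 100-dimensional featurization of a neighborhood: for each particle
#' type and each shell center `r_k`, the Gaussian-smeared shell count
#' `sum_p exp(-(r_p - r_k)^2 / (2 w^2))` over particles of that type
#' (type A block first). Applied to a whole `dib_neighborhoods` table it
#' returns one feature row per neighborhood plus the label.
#'
#' @param neighborhoods A `dib_neighborhoods` table, or a single particle
#'   tibble with columns `type`, `x`, `y`.
#' @param centers Shell-center radii (default [shell_centers()] over the
#'   generating `r_max`).
#' @param width Gaussian shell width `w`.
#' @return For a table: tibble of class `dib_radial_features` (`id`,
#'   feature columns, `y`). For a single neighborhood: named numeric vector
#'   of length `2 * length(centers)`.
#' @export
radial_density_features <- function(neighborhoods, centers = NULL,
                                    width = 0.1) {
  single <- !inherits(neighborhoods, "dib_neighborhoods")
  if (is.null(centers)) {
    centers <- attr(neighborhoods, "shell_centers")
    if (is.null(centers)) centers <- shell_centers()
  }
  nms <- feature_names_radial(length(centers))
  smear <- function(r, type) {
    # rows: particles, cols: shells; summed per type block
    f <- numeric(2L * length(centers))
    names(f) <- nms
    for (t in c("A", "B")) {
      sel <- type == t
      if (any(sel)) {
        E <- exp(-outer(r[sel], centers, "-")^2 / (2 * width^2))
        block <- if (t == "A") seq_along(centers) else
          length(centers) + seq_along(centers)
        f[block] <- colSums(E)
      }
    }
    f
  }
  if (single) {
    p <- tibble::as_tibble(neighborhoods)
    if (!nrow(p)) {
      f <- numeric(2L * length(centers)); names(f) <- nms
      return(f)
    }
    return(smear(sqrt(p$x^2 + p$y^2), p$type))
  }
  flat <- tidyr::unnest(neighborhoods[, c("id", "particles")], "particles")
  flat$r <- sqrt(flat$x^2 + flat$y^2)
  n <- nrow(neighborhoods)
  M <- matrix(0, nrow = n, ncol = 2L * length(centers),
              dimnames = list(NULL, nms))
  for (t in c("A", "B")) {
    sub <- flat[flat$type == t, ]
    if (!nrow(sub)) next
    block <- if (t == "A") seq_along(centers) else
      length(centers) + seq_along(centers)
    chunk <- 200000L
    for (start in seq(1L, nrow(sub), by = chunk)) {
      j <- start:min(start + chunk - 1L, nrow(sub))
      E <- exp(-outer(sub$r[j], centers, "-")^2 / (2 * width^2))
      S <- rowsum(E, sub$id[j])
      rows <- as.integer(rownames(S))
      M[rows, block] <- M[rows, block] + S
    }
  }
  out <- tibble::as_tibble(as.data.frame(M))
  out <- dplyr::bind_cols(tibble::tibble(id = neighborhoods$id), out)
  out$y <- neighborhoods$label
  class(out) <- c("dib_radial_features", class(out))
  attr(out, "shell_centers") <- centers
  attr(out, "width") <- width
  out
}

#' Center-referenced radial distribution function
#'
#' System-averaged radial density of type A (`pair = "AA"`) or type B
#' (`pair = "AB"`) particles around the type-A center particle, normalized
#' by the annulus area and the partner type's mean density so that an ideal
#' gas gives `g(r) = 1`.
#'
#' @param neighborhoods A `dib_neighborhoods` table (>= 100 neighborhoods
#'   for stable averaging).
#' @param pair `"AA"` or `"AB"`.
#' @param dr Radial bin width.
#' @return Tibble of class `dib_rdf` with columns `r`, `g`, `pair`.
#' @export
radial_distribution_function <- function(neighborhoods, pair = c("AA", "AB"),
                                         dr = 0.1) {
  pair <- match.arg(pair)
  stopifnot(inherits(neighborhoods, "dib_neighborhoods"))
  if (nrow(neighborhoods) < 100L) {
    abort_dibs("Need at least 100 neighborhoods for a stable average.",
               "invalid_argument")
  }
  params <- attr(neighborhoods, "params")
  r_max <- if (!is.null(params)) params$r_max else 5
  tt <- if (pair == "AA") "A" else "B"
  flat <- tidyr::unnest(neighborhoods[, c("id", "particles")], "particles")
  flat <- flat[!flat$is_center & flat$type == tt, ]
  r <- sqrt(flat$x^2 + flat$y^2)
  edges <- seq(0, r_max, by = dr)
  counts <- graphics::hist(r, breaks = edges, plot = FALSE)$counts
  area <- pi * diff(edges^2)
  rho <- length(r) / (nrow(neighborhoods) * pi * r_max^2)
  g <- counts / (nrow(neighborhoods) * area * rho)
  out <- tibble::tibble(r = (edges[-1] + edges[-length(edges)]) / 2,
                        g = g, pair = pair)
  class(out) <- c("dib_rdf", class(out))
  out
}

#' Linear softness-style baseline
#'
#' Maximum-margin linear classifier (SVM) on standardized radial-density
#' features with an 80/20 split: the learned weight vector is the softness
#' direction, and the held-out accuracy is the linear baseline that the
#' distributed-bottleneck model is compared against.
#'
#' @param data Feature table with a label column (e.g. from
#'   [radial_density_features()]).
#' @param label Label column name.
#' @param split Training fraction.
#' @param max_train Cap on training rows passed to the SVM solver.
#' @param cost SVM cost parameter.
#' @param seed Seed for the split (local).
#' @return List of class `dib_softness`: `weights` (named), `intercept`,
#'   `accuracy` (held-out), `n_train`, `n_test`.
#' @export
linear_baseline <- function(data, label = "y", split = 0.8,
                            max_train = 10000, cost = 1, seed = 1L) {
  data <- tibble::as_tibble(data)
  feats <- setdiff(names(data), c(label, "id"))
  yf <- factor(data[[label]])
  if (nlevels(yf) < 2L) {
    abort_dibs("Both classes must be present.", "degenerate_labels")
  }
  X <- as.matrix(data[feats])
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  X <- sweep(sweep(X, 2L, mu, "-"), 2L, sdv, "/")
  with_local_seed(seed, {
    n <- nrow(X)
    train <- sample.int(n, round(split * n))
    test <- setdiff(seq_len(n), train)
    if (length(train) > max_train) train <- train[seq_len(max_train)]
    fit <- e1071::svm(X[train, , drop = FALSE], yf[train],
                      kernel = "linear", cost = cost, scale = FALSE)
    w <- drop(t(fit$coefs) %*% fit$SV)
    names(w) <- feats
    pred <- stats::predict(fit, X[test, , drop = FALSE])
    structure(list(weights = w, intercept = -fit$rho,
                   accuracy = mean(pred == yf[test]),
                   n_train = length(train), n_test = length(test)),
              class = "dib_softness")
  })
}

#' Read/write neighborhoods as extended-XYZ-like text
#'
#' Plain-text exchange format: per neighborhood a count line, a comment line
#' `label=<l> r_max=<r> id=<id>`, then one `type x y` row per particle (the
#' first row is the center particle).
#'
#' @param neighborhoods A `dib_neighborhoods` table.
#' @param path File path.
#' @return `read_neighborhoods()` a `dib_neighborhoods`; the writer returns
#'   the path invisibly.
#' @name neighborhood-io
NULL

#' @rdname neighborhood-io
#' @export
write_neighborhoods <- function(neighborhoods, path) {
  params <- attr(neighborhoods, "params")
  r_max <- if (!is.null(params)) params$r_max else 5
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(neighborhoods))) {
    p <- neighborhoods$particles[[i]]
    writeLines(c(
      as.character(nrow(p)),
      sprintf("label=%d r_max=%g id=%d", neighborhoods$label[i], r_max,
              neighborhoods$id[i]),
      sprintf("%s %.8f %.8f", p$type, p$x, p$y)), con)
  }
  invisible(path)
}

#' @rdname neighborhood-io
#' @export
read_neighborhoods <- function(path) {
  lines <- readLines(path)
  i <- 1L
  ids <- integer(); labels <- integer(); plist <- list(); counts <- integer()
  r_max <- 5
  while (i <= length(lines)) {
    np <- as.integer(lines[i])
    hdr <- lines[i + 1L]
    get_num <- function(key) {
      m <- regmatches(hdr, regexpr(paste0(key, "=[-0-9.eE+]+"), hdr))
      as.numeric(sub(paste0(key, "="), "", m))
    }
    label <- as.integer(get_num("label"))
    r_max <- get_num("r_max")
    id <- as.integer(get_num("id"))
    rows <- strsplit(lines[i + 1L + seq_len(np)], " +")
    type <- vapply(rows, `[[`, character(1), 1L)
    x <- as.numeric(vapply(rows, `[[`, character(1), 2L))
    y <- as.numeric(vapply(rows, `[[`, character(1), 3L))
    plist[[length(plist) + 1L]] <- tibble::tibble(
      type = type, x = x, y = y,
      is_center = c(TRUE, rep(FALSE, np - 1L)))
    ids <- c(ids, id); labels <- c(labels, label); counts <- c(counts, np)
    i <- i + 2L + np
  }
  out <- tibble::tibble(id = ids, label = labels, n_particles = counts,
                        particles = plist)
  class(out) <- c("dib_neighborhoods", class(out))
  attr(out, "params") <- list(r_max = r_max)
  attr(out, "shell_centers") <- shell_centers(r_max = r_max)
  out
}

#' @export
print.dib_softness <- function(x, ...) {
  top <- names(sort(abs(x$weights), decreasing = TRUE))[1:3]
  cat(sprintf(
    "<dib_softness> held-out accuracy %.3f (train %d / test %d); top |w|: %s\n",
    x$accuracy, x$n_train, x$n_test, paste(top, collapse = ", ")))
  invisible(x)
}
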