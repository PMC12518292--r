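#' Per-channel pixel statistics
#'
#' Computes mean, standard deviation, minimum and maximum per spectral
#' channel, pooled over all pixels of all plots in the dataset (the
#' population the clipping and scaling rules are defined on). The standard
#' deviation convention is recorded in the result so downstream oracles can
#' match it; the default is the population form (divide by n).
#'
#' @param dataset a [cae_dataset()].
#' @param sd_type `"population"` (divide by n, default) or `"sample"`
#'   (divide by n - 1).
#' @return a tibble with one row per channel: `band`, `mean`, `sd`, `min`,
#'   `max`, `n_pixels`, `sd_type`.
#' @export
channel_stats <- function(dataset, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(inherits(dataset, "cae_dataset"))
  if (n_plots(dataset) == 0) stop("empty dataset")
  C <- dim(dataset$pixels)[4]
  rows <- lapply(seq_len(C), function(ch) {
    v <- as.vector(dataset$pixels[, , , ch])
    n <- length(v)
    m <- mean(v)
    ss <- sum((v - m)^2)
    s <- sqrt(ss / if (sd_type == "population") n else max(n - 1, 1))
    tibble::tibble(band = dataset$bands[ch], mean = m, sd = s,
                   min = min(v), max = max(v), n_pixels = n,
                   sd_type = sd_type)
  })
  dplyr::bind_rows(rows)
}

#' Clip channel outliers to mean +/- k standard deviations
#'
#' Every pixel in channel `c` is replaced by
#' `min(max(x, mean_c - k sd_c), mean_c + k sd_c)`; in-range pixels are
#' unchanged. With `per_image = FALSE` (default) the statistics are pooled
#' over the whole dataset; with `per_image = TRUE` they are computed per
#' image per channel.
#'
#' @param dataset a [cae_dataset()].
#' @param stats channel statistics from [channel_stats()]; computed from
#'   `dataset` when `NULL`.
#' @param k clipping width in standard deviations (default 3; must be > 0).
#' @param per_image use per-image rather than pooled statistics.
#' @return the clipped dataset.
#' @export
clip_outliers <- function(dataset, stats = NULL, k = 3, per_image = FALSE) {
  stopifnot(inherits(dataset, "cae_dataset"))
  if (k <= 0) stop("k must be positive")
  C <- dim(dataset$pixels)[4]
  if (per_image) {
    for (i in seq_len(n_plots(dataset))) {
      for (ch in seq_len(C)) {
        v <- dataset$pixels[i, , , ch]
        m <- mean(v)
        s <- sqrt(mean((v - m)^2))
        dataset$pixels[i, , , ch] <- pmin(pmax(v, m - k * s), m + k * s)
      }
    }
    return(dataset)
  }
  if (is.null(stats)) stats <- channel_stats(dataset)
  stopifnot(nrow(stats) == C)
  for (ch in seq_len(C)) {
    lo <- stats$mean[ch] - k * stats$sd[ch]
    hi <- stats$mean[ch] + k * stats$sd[ch]
    dataset$pixels[, , , ch] <- pmin(pmax(dataset$pixels[, , , ch], lo), hi)
  }
  dataset
}

#' Min-max normalize each channel into [0, 1]
#'
#' Applies `x -> (x - min_c) / (max_c - min_c)` per channel with statistics
#' recomputed after clipping (pass them explicitly or leave `NULL` to
#' recompute from the clipped data). A constant channel (`max == min`) maps
#' to 0.
#'
#' @inheritParams clip_outliers
#' @return the normalized dataset (all pixels in `[0, 1]`).
#' @export
minmax_normalize <- function(dataset, stats = NULL, per_image = FALSE) {
  stopifnot(inherits(dataset, "cae_dataset"))
  C <- dim(dataset$pixels)[4]
  if (per_image) {
    for (i in seq_len(n_plots(dataset))) {
      for (ch in seq_len(C)) {
        v <- dataset$pixels[i, , , ch]
        rng <- max(v) - min(v)
        dataset$pixels[i, , , ch] <-
          if (rng > 0) (v - min(v)) / rng else 0 * v
      }
    }
    return(dataset)
  }
  if (is.null(stats)) stats <- channel_stats(dataset)
  stopifnot(nrow(stats) == C)
  for (ch in seq_len(C)) {
    rng <- stats$max[ch] - stats$min[ch]
    dataset$pixels[, , , ch] <-
      if (rng > 0) (dataset$pixels[, , , ch] - stats$min[ch]) / rng
      else 0 * dataset$pixels[, , , ch]
  }
  dataset
}

#' Full preprocessing chain: clip, then min-max normalize
#'
#' Runs [clip_outliers()] with dataset-pooled statistics, recomputes the
#' channel statistics on the clipped data, and applies [minmax_normalize()]
#' with those. Both statistics tables are stored on the result (`$stats`) so
#' a trained model can reapply the identical transform to new imagery.
#'
#' @param dataset a raw [cae_dataset()].
#' @param k clipping width in standard deviations.
#' @param per_image compute statistics per image instead of pooled over the
#'   dataset.
#' @return the preprocessed dataset (`$preprocessed` is `TRUE`).
#' @export
preprocess <- function(dataset, k = 3, per_image = FALSE) {
  stopifnot(inherits(dataset, "cae_dataset"))
  clip_stats <- if (per_image) NULL else channel_stats(dataset)
  dataset <- clip_outliers(dataset, stats = clip_stats, k = k,
                           per_image = per_image)
  norm_stats <- if (per_image) NULL else channel_stats(dataset)
  dataset <- minmax_normalize(dataset, stats = norm_stats,
                              per_image = per_image)
  dataset$preprocessed <- TRUE
  dataset$stats <- list(clip = clip_stats, normalize = norm_stats, k = k,
                        per_image = per_image)
  dataset
}

#' Flatten a plot image to a feature vector
#'
#' The fixed flattening order is column-major over `(W, H, C)` with channel
#' as the slowest-varying axis (R's native array order), so an 11 x 22 x 6
#' image becomes a length-1452 vector. [unflatten_image()] inverts it.
#'
#' @param image a `W x H x C` array.
#' @return a numeric vector of length `W * H * C`.
#' @export
flatten_image <- function(image) {
  stopifnot(length(dim(image)) == 3)
  as.vector(image)
}

#' Invert [flatten_image()]
#'
#' @param v a numeric vector of length `prod(dim)`.
#' @param dim the target `c(W, H, C)` shape.
#' @return a `W x H x C` array.
#' @export
unflatten_image <- function(v, dim) {
  stopifnot(length(v) == prod(dim), length(dim) == 3)
  array(v, dim = dim)
}

#' Flatten every plot of a dataset into a feature matrix
#'
#' @param dataset a [cae_dataset()].
#' @return an `n_plots x (W*H*C)` matrix with plot ids as row names, rows in
#'   metadata order, columns in [flatten_image()] order.
#' @export
flatten_images <- function(dataset) {
  stopifnot(inherits(dataset, "cae_dataset"))
  d <- dim(dataset$pixels)
  n <- d[1]
  # pixels is plot-major; aperm so each row is one plot's (W, H, C) vector
  x <- matrix(aperm(dataset$pixels, c(2, 3, 4, 1)), nrow = prod(d[-1]),
              ncol = n)
  x <- t(x)
  rownames(x) <- dataset$meta$plot_id
  x
}
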