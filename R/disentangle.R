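#' Project features onto principal components
#'
#' Centered (unscaled) PCA. Component signs are fixed by the convention that
#' the largest-magnitude loading of each component is positive, so results
#' are deterministic. Explained-variance ratios are taken against the total
#' variance of all input dimensions, so they are nonincreasing, each in
#' `[0, 1]`, and their cumulative sum is at most 1.
#'
#' @param x a numeric matrix or data frame (rows = samples).
#' @param n_components number of components to keep (default 3). Capped at
#'   `min(n_samples - 1, n_features)`.
#' @return an object of class `cae_projection`: `scores` (tibble
#'   `PC1..PCk`), `explained_variance_ratio`, `cumulative_variance`,
#'   `rotation`, `center`.
#' @export
pca_project <- function(x, n_components = 3) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 samples")
  total_var <- sum(apply(x, 2, var))
  if (total_var == 0) stop("degenerate input: zero variance")
  k <- min(n_components, nrow(x) - 1, ncol(x))
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  rot <- p$rotation[, seq_len(k), drop = FALSE]
  scores <- p$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ratio <- p$sdev[seq_len(k)]^2 / total_var
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(
    list(scores = tibble::as_tibble(scores),
         explained_variance_ratio = ratio,
         cumulative_variance = cumsum(ratio),
         rotation = rot, center = p$center,
         n_components = k),
    class = "cae_projection"
  )
}

#' @export
print.cae_projection <- function(x, ...) {
  cat("<cae_projection> ", nrow(x$scores), " samples x ", x$n_components,
      " components\n", sep = "")
  cat("  variance ratios:",
      paste(sprintf("%.3f", x$explained_variance_ratio), collapse = ", "),
      " (cumulative ", sprintf("%.3f", max(x$cumulative_variance)), ")\n",
      sep = "")
  invisible(x)
}

#' Silhouette score of labelled points
#'
#' Standard silhouette: for each point, `a` is its mean distance to the
#' other members of its own cluster and `b` the smallest mean distance to
#' any other cluster; `s = (b - a) / max(a, b)`. Points in singleton
#' clusters score 0. The overall score is the mean over points. Euclidean
#' distances.
#'
#' @param points numeric matrix or data frame of coordinates.
#' @param labels cluster labels, one per row; at least 2 distinct labels,
#'   and at least one label with 2 or more members.
#' @return an object of class `silhouette_report`: `score`, `by_label`
#'   (tibble `label`, `mean_silhouette`, `n`), `n`, `labels`.
#' @export
silhouette_score <- function(points, labels) {
  points <- as.matrix(points)
  if (nrow(points) == 0) stop("empty input")
  labels <- as.character(labels)
  if (length(labels) != nrow(points)) stop("one label per row required")
  lv <- sort(unique(labels))
  if (length(lv) < 2) stop("need at least 2 distinct labels")
  if (max(table(labels)) < 2) stop("need at least one label with >= 2 members")
  cl <- as.integer(factor(labels, levels = lv))
  sil <- cluster::silhouette(cl, dist(points))
  widths <- sil[, "sil_width"]
  by_label <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(label = labels, s = widths), .data$label),
    mean_silhouette = mean(.data$s), n = dplyr::n(), .groups = "drop"
  )
  structure(list(score = mean(widths), by_label = by_label,
                 n = nrow(points), labels = lv),
            class = "silhouette_report")
}

#' @export
print.silhouette_report <- function(x, ...) {
  cat("<silhouette_report> overall ", sprintf("%.3f", x$score), " over ",
      x$n, " points, ", length(x$labels), " labels\n", sep = "")
  invisible(x)
}

# Select latent block columns by prefix, with a clear error.
.latent_block <- function(latents, prefix) {
  cols <- grep(paste0("^", prefix, "_"), names(latents), value = TRUE)
  if (length(cols) == 0) stop("no ", prefix, "_* columns in latent table")
  as.matrix(latents[, cols, drop = FALSE])
}

# PCA to at most n_components then silhouette; skips the projection when the
# feature space is already at or below the target dimension or when
# use_pca = FALSE (full-dimension mode).
.project_silhouette <- function(x, labels, n_components, use_pca) {
  x <- as.matrix(x)
  pr <- NULL
  pts <- if (use_pca && ncol(x) > 1) {
    pr <- pca_project(x, n_components = n_components)
    as.matrix(pr$scores)
  } else x
  out <- silhouette_score(pts, labels)
  out$projection <- pr
  out
}

#' Macro-environment disentanglement score
#'
#' Quantifies how well the macro-environment latent block separates the
#' trial locations: the per-image `ze_*` block is projected to its top
#' principal components and the silhouette is computed under environment
#' labels. `mode = "mean_imputed"` instead keeps the full per-image latent
#' but replaces the genotype and micro blocks by their dataset means, the
#' averaging reading of the protocol.
#'
#' @param latents a latent table from [extract_latents()] (needs
#'   `environment_id` and the block columns).
#' @param mode `"ze"` (default) or `"mean_imputed"`.
#' @param n_components principal components for the projection (default 3).
#' @param use_pca set `FALSE` to score in the full feature space.
#' @return a [silhouette_score()] report.
#' @export
macro_env_silhouette <- function(latents, mode = c("ze", "mean_imputed"),
                                 n_components = 3, use_pca = TRUE) {
  mode <- match.arg(mode)
  if (dplyr::n_distinct(latents$environment_id) < 2) {
    stop("need at least 2 environments")
  }
  x <- if (mode == "ze") {
    .latent_block(latents, "ze")
  } else {
    full <- cbind(.latent_block(latents, "zg"), .latent_block(latents, "ze"),
                  .latent_block(latents, "zp"))
    gcols <- seq_len(ncol(.latent_block(latents, "zg")))
    pcols <- ncol(full) - rev(seq_len(ncol(.latent_block(latents, "zp")))) + 1
    full[, gcols] <- matrix(colMeans(full[, gcols, drop = FALSE]),
                            nrow(full), length(gcols), byrow = TRUE)
    full[, pcols] <- matrix(colMeans(full[, pcols, drop = FALSE]),
                            nrow(full), length(pcols), byrow = TRUE)
    full
  }
  .project_silhouette(x, latents$environment_id, n_components, use_pca)
}

#' Micro-environment disentanglement score
#'
#' Same pipeline as [macro_env_silhouette()] on the per-image micro block
#' `zp_*`, with one class per environment x replicate combination
#' (`E * R` classes).
#'
#' @inheritParams macro_env_silhouette
#' @return a [silhouette_score()] report.
#' @export
micro_env_silhouette <- function(latents, n_components = 3, use_pca = TRUE) {
  labels <- paste0(latents$environment_id, ":", latents$replicate_id)
  if (dplyr::n_distinct(labels) < 2) {
    stop("need at least 2 environment x replicate classes")
  }
  .project_silhouette(.latent_block(latents, "zp"), labels, n_components,
                      use_pca)
}

#' Raw-pixel baseline silhouette
#'
#' The comparator for [macro_env_silhouette()]: preprocessed flattened
#' pixels are projected to the top principal components and scored under
#' environment labels — how well the raw imagery alone separates locations.
#'
#' @param dataset a [cae_dataset()] (preprocessed, or preprocessed here with
#'   defaults).
#' @param n_components principal components (default 3).
#' @param use_pca set `FALSE` to score the full pixel space.
#' @return a [silhouette_score()] report.
#' @export
raw_baseline_silhouette <- function(dataset, n_components = 3,
                                    use_pca = TRUE) {
  stopifnot(inherits(dataset, "cae_dataset"))
  if (dplyr::n_distinct(dataset$meta$environment_id) < 2) {
    stop("need at least 2 environments")
  }
  if (!dataset$preprocessed) dataset <- preprocess(dataset)
  .project_silhouette(flatten_images(dataset), dataset$meta$environment_id,
                      n_components, use_pca)
}
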