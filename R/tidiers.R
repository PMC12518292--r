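#' Tidy the training history of a fitted autoencoder
#'
#' @param x a `cae_fit` or `ae_fit`.
#' @param ... unused.
#' @return a tibble in long form: `epoch`, `component`
#'   (`recon`/`corr`/`total`), `loss`.
#' @export
tidy.cae_fit <- function(x, ...) {
  tidyr::pivot_longer(x$history, -"epoch", names_to = "component",
                      values_to = "loss")
}

#' @rdname tidy.cae_fit
#' @export
tidy.ae_fit <- tidy.cae_fit

#' One-row summary of a fitted autoencoder
#'
#' @param x a `cae_fit` or `ae_fit`.
#' @param ... unused.
#' @return a tibble with the final losses, epoch count, and parameter count.
#' @export
glance.cae_fit <- function(x, ...) {
  count_params <- function(p) {
    if (is.numeric(p)) length(p) else sum(vapply(p, count_params, numeric(1)))
  }
  last <- x$history[nrow(x$history), ]
  tibble::tibble(
    epochs = max(x$history$epoch),
    recon = last$recon,
    corr = if ("corr" %in% names(last)) last$corr else NA_real_,
    total = last$total,
    lambda = if (!is.null(x$config$lambda)) x$config$lambda else NA_real_,
    n_parameters = count_params(x$model[c("encoder", "decoder")]) +
      (if (!is.null(x$model$fusion)) count_params(x$model$fusion) else 0)
  )
}

#' @rdname glance.cae_fit
#' @export
glance.ae_fit <- glance.cae_fit

#' Tidy a principal-component projection
#'
#' @param x a [pca_project()] result.
#' @param ... unused.
#' @return the scores tibble with a `.row` column.
#' @export
tidy.cae_projection <- function(x, ...) {
  dplyr::mutate(x$scores, .row = dplyr::row_number(), .before = 1)
}

#' @rdname tidy.cae_projection
#' @export
glance.cae_projection <- function(x, ...) {
  tibble::tibble(
    n_components = x$n_components,
    cumulative_variance = max(x$cumulative_variance),
    !!!setNames(as.list(x$explained_variance_ratio),
                paste0("variance_ratio_", seq_len(x$n_components)))
  )
}

#' Tidy a silhouette report
#'
#' @param x a [silhouette_score()] report.
#' @param ... unused.
#' @return the per-label tibble.
#' @export
tidy.silhouette_report <- function(x, ...) x$by_label

#' @rdname tidy.silhouette_report
#' @export
glance.silhouette_report <- function(x, ...) {
  tibble::tibble(score = x$score, n = x$n, n_labels = length(x$labels))
}

#' Per-fold cross-validation results as a plain tibble
#'
#' @param x a [experiment1()] result.
#' @param ... unused.
#' @return the per-fold tibble without the result class.
#' @export
tidy.cv_result <- function(x, ...) tibble::as_tibble(x)

#' Summarize cross-validation results per feature set
#'
#' @param x a [experiment1()] result.
#' @param ... unused.
#' @return a tibble with mean and standard deviation of `R^2` and RMSE per
#'   feature set.
#' @export
glance.cv_result <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$feature_set),
    r2_mean = mean(.data$r2), r2_sd = sd(.data$r2),
    rmse_mean = mean(.data$rmse), rmse_sd = sd(.data$rmse),
    folds = dplyr::n(), .groups = "drop"
  )
}

#' Plot training-loss curves
#'
#' @param object a `cae_fit` or `ae_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cae_fit <- function(object, ...) {
  ggplot2::ggplot(tidy.cae_fit(object),
                  ggplot2::aes(x = .data$epoch, y = .data$loss,
                               colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "loss (log scale)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cae_fit
#' @export
autoplot.ae_fit <- autoplot.cae_fit

#' Plot a labelled principal-component projection
#'
#' @param object a [pca_project()] result.
#' @param labels optional label vector (one per sample) used for colour.
#' @param ... unused.
#' @return a ggplot of PC1 vs PC2.
#' @export
autoplot.cae_projection <- function(object, labels = NULL, ...) {
  df <- object$scores
  if (!is.null(labels)) df$label <- as.character(labels)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::theme_minimal() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained_variance_ratio[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained_variance_ratio[2])
    )
  if (is.null(labels)) p + ggplot2::geom_point()
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$label)) +
    ggplot2::labs(colour = NULL)
}

#' Plot per-fold cross-validation accuracy
#'
#' @param object a [experiment1()] result.
#' @param metric `"r2"` or `"rmse"`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cv_result <- function(object, metric = c("r2", "rmse"), ...) {
  metric <- match.arg(metric)
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$feature_set,
                               y = .data[[metric]])) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = if (metric == "r2") expression(R^2)
                  else "RMSE") +
    ggplot2::theme_minimal()
}
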