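#' Pearson correlation coefficient
#'
#' Computed from the explicit sum form
#' `r = sum((p_i - pbar)(k_i - kbar)) / sqrt(sum((p_i - pbar)^2) sum((k_i - kbar)^2))`.
#' When either vector has zero variance the correlation is undefined and 0
#' is returned, the convention the correlation penalty relies on so that
#' constant latent dimensions contribute nothing.
#'
#' @param x,y numeric vectors of equal length `n >= 2`.
#' @return a scalar in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2) stop("need at least 2 observations")
  xc <- x - mean(x)
  yc <- y - mean(y)
  den <- sqrt(sum(xc^2) * sum(yc^2))
  if (den == 0) return(0)
  r <- sum(xc * yc) / den
  max(-1, min(1, r))
}

#' Correlation loss over a latent batch matrix
#'
#' For a batch matrix `L` (rows = images, columns = latent dimensions `D`)
#' the loss is the sum of the absolute off-diagonal entries of the `D x D`
#' Pearson correlation matrix of the columns, counted once per unordered
#' pair: `sum_{i<j} |r_ij|`, which lies in `[0, D(D-1)/2]`. Diagonal terms
#' are removed by subtracting the identity. Denominators carry an `eps`
#' guard so zero-variance columns yield zero correlation and finite
#' gradients.
#'
#' @param L a numeric matrix with at least 3 rows.
#' @param eps variance guard added inside the column-norm square root.
#' @return a nonnegative scalar.
#' @export
correlation_loss <- function(L, eps = 1e-12) {
  L <- as.matrix(L)
  if (nrow(L) < 3) stop("need at least 3 rows for a stable correlation")
  D <- ncol(L)
  if (D < 2) return(0)
  S <- .standardize_cols(L, eps)
  R <- crossprod(S)
  sum(abs(R[upper.tri(R)]))
}

# Columns centered and divided by the eps-guarded norm of the centered
# column; zero-variance columns map to zero columns.
.standardize_cols <- function(L, eps = 1e-12) {
  Lc <- sweep(L, 2, colMeans(L), "-")
  nrm <- sqrt(colSums(Lc^2) + eps)
  sweep(Lc, 2, nrm, "/")
}

# Gradient of correlation_loss with respect to L. Derivation: with
# s_i = C l_i / ||C l_i|| (C the centering projection) and
# loss = sum_{i<j} |s_i . s_j|, d loss / d s_i = sum_{j != i} sign(r_ij) s_j;
# back through the normalization, grad_ci = (g_i - s_i (s_i . g_i)) / nrm_i,
# and through centering, grad_i = grad_ci - mean(grad_ci).
.correlation_loss_grad <- function(L, eps = 1e-12) {
  L <- as.matrix(L)
  D <- ncol(L)
  if (D < 2) return(matrix(0, nrow(L), D))
  Lc <- sweep(L, 2, colMeans(L), "-")
  nrm <- sqrt(colSums(Lc^2) + eps)
  S <- sweep(Lc, 2, nrm, "/")
  Wsign <- sign(crossprod(S))
  diag(Wsign) <- 0
  GS <- S %*% Wsign
  proj <- colSums(S * GS)
  Gc <- sweep(GS - sweep(S, 2, proj, "*"), 2, nrm, "/")
  sweep(Gc, 2, colMeans(Gc), "-")
}

#' Mean-squared reconstruction loss
#'
#' Mean over all elements of the squared differences between inputs and
#' reconstructions.
#'
#' @param inputs,reconstructions numeric arrays of matching shape.
#' @return a nonnegative scalar.
#' @export
reconstruction_loss <- function(inputs, reconstructions) {
  if (!identical(dim(inputs), dim(reconstructions)) ||
      length(inputs) != length(reconstructions)) {
    stop("shape mismatch between inputs and reconstructions")
  }
  mean((inputs - reconstructions)^2)
}

#' Combined training objective
#'
#' `recon + lambda * corr`; `lambda = 0` recovers a pure autoencoder
#' objective.
#'
#' @param recon reconstruction loss.
#' @param corr correlation loss.
#' @param lambda nonnegative correlation weight.
#' @return a scalar.
#' @export
total_loss <- function(recon, corr, lambda = 1) {
  if (lambda < 0) stop("lambda must be nonnegative")
  recon + lambda * corr
}
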