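#' Latent partition configuration
#'
#' Dimensions of the three latent blocks per image: `zg` genotype features
#' shared by all plots of a genotype, `ze` macro-environment features shared
#' by the plots of that genotype at one location, and `zp` micro-environment
#' features unique to each plot. The default `6-6-1` is the configuration
#' used for all downstream prediction.
#'
#' @param zg,ze,zp block dimensions, each >= 1.
#' @return a list of class `latent_config` with the per-image latent width
#'   `d = zg + ze + zp`.
#' @export
latent_config <- function(zg = 6, ze = 6, zp = 1) {
  dims <- c(zg = zg, ze = ze, zp = zp)
  if (any(dims < 1) || any(dims != round(dims))) {
    stop("zg, ze, zp must be integers >= 1")
  }
  structure(list(zg = zg, ze = ze, zp = zp, d = zg + ze + zp),
            class = "latent_config")
}

#' Genotype-group layout
#'
#' A genotype group is the ordered set of `N = E * R` images of one genotype
#' spanning `E` environments with `R` replicates each, ordered
#' environment-major, replicate-minor: positions `(e-1)*R + 1 .. (e-1)*R + R`
#' belong to environment `e`, and the micro index of a position is the
#' position itself. For `E = 5, R = 2`, position 5 is environment 3,
#' micro index 5.
#'
#' @param n_environments number of environments `E` (>= 1).
#' @param n_replicates replicates per environment `R` (>= 1).
#' @return a list of class `group_layout` with fields `E`, `R`, `N` and a
#'   `positions` tibble (`position`, `environment`, `micro`).
#' @export
group_layout <- function(n_environments, n_replicates) {
  stopifnot(n_environments >= 1, n_replicates >= 1,
            n_environments == round(n_environments),
            n_replicates == round(n_replicates))
  E <- as.integer(n_environments); R <- as.integer(n_replicates)
  N <- E * R
  structure(
    list(E = E, R = R, N = N,
         positions = tibble::tibble(
           position = seq_len(N),
           environment = rep(seq_len(E), each = R),
           micro = seq_len(N)
         )),
    class = "group_layout"
  )
}

#' Fused-vector slice indices for one group position
#'
#' The fused vector is laid out as `[Zg | Ze_1 .. Ze_E | Zp_1 .. Zp_N]`. For
#' a group position `n` with environment `e` and micro index `i = n`, this
#' returns the column indices of the genotype block, of environment block
#' `e`, and of micro block `i`.
#'
#' @param latent a [latent_config()].
#' @param layout a [group_layout()].
#' @param position group position in `1..N`.
#' @return a list with integer vectors `zg`, `ze`, `zp` and scalars
#'   `environment`, `micro`.
#' @export
fused_slices <- function(latent, layout, position) {
  stopifnot(inherits(latent, "latent_config"), inherits(layout, "group_layout"))
  if (position < 1 || position > layout$N) {
    stop("position out of range 1..", layout$N)
  }
  e <- layout$positions$environment[position]
  i <- layout$positions$micro[position]
  list(
    zg = seq_len(latent$zg),
    ze = latent$zg + (e - 1) * latent$ze + seq_len(latent$ze),
    zp = latent$zg + layout$E * latent$ze + (i - 1) * latent$zp +
      seq_len(latent$zp),
    environment = e,
    micro = i
  )
}

#' Length of the fused vector
#'
#' `zg + E * ze + N * zp` for a given partition and layout.
#'
#' @inheritParams fused_slices
#' @return integer length.
#' @export
fused_length <- function(latent, layout) {
  latent$zg + layout$E * latent$ze + layout$N * latent$zp
}

# ---------------------------------------------------------------------------
# Layer stacks. Weights use the fan-in-scaled normal initialization
# conventional for SELU networks (mean 0, sd 1/sqrt(fan_in)); biases start
# at zero. Hidden activations are SELU; the encoder output is linear and the
# decoder output is a sigmoid.

.selu_lambda <- 1.0507009873554805
.selu_alpha <- 1.6732632423543772

.selu <- function(x) {
  # pmin/pmax split avoids ifelse(); expm1(pmin(x, 0)) is 0 for x > 0
  .selu_lambda * (pmax(x, 0) + .selu_alpha * expm1(pmin(x, 0)))
}

# SELU derivative expressed through the activation value a = selu(x):
# lambda for x > 0, a + lambda * alpha for x <= 0.
.selu_grad_from_act <- function(a) {
  pos <- a > 0
  pos * .selu_lambda + (!pos) * (a + .selu_lambda * .selu_alpha)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.init_linear <- function(fan_in, fan_out) {
  list(W = matrix(rnorm(fan_in * fan_out, sd = sqrt(1 / fan_in)),
                  fan_in, fan_out),
       b = numeric(fan_out))
}

.init_mlp <- function(widths) {
  lapply(seq_len(length(widths) - 1), function(i) {
    .init_linear(widths[i], widths[i + 1])
  })
}

# Forward through an MLP; activations: "selu" on all hidden layers, `out`
# ("linear", "sigmoid") on the last. Returns list(out, acts) where acts[[i]]
# is the post-activation output of layer i (acts[[0]] conceptually = x).
.mlp_forward <- function(layers, x, out = c("linear", "sigmoid")) {
  out <- match.arg(out)
  acts <- vector("list", length(layers))
  a <- x
  for (i in seq_along(layers)) {
    z <- a %*% layers[[i]]$W
    z <- sweep(z, 2, layers[[i]]$b, "+")
    a <- if (i < length(layers)) .selu(z)
         else if (out == "sigmoid") .sigmoid(z) else z
    acts[[i]] <- a
  }
  list(out = a, acts = acts)
}

#' Construct an untrained compositional autoencoder
#'
#' Builds the encoder (`input -> 2200 -> 2000 -> 1000 -> zg+ze+zp`, SELU
#' hidden layers, linear output), the fusion layer (a single affine map
#' `N(zg+ze+zp) -> zg + E ze + N zp`, no activation) and the decoder
#' (`zg+ze+zp -> 2024 -> 3000 -> 2200 -> input`, SELU hidden layers, sigmoid
#' output). Widths are the reference configuration; smaller widths may be
#' supplied for quick experiments.
#'
#' @param input_dim flattened image length `W * H * C` (1452 for the default
#'   11 x 22 x 6 plots).
#' @param latent a [latent_config()].
#' @param layout a [group_layout()].
#' @param hidden_encoder,hidden_decoder hidden-layer widths.
#' @param seed optional integer seed for the weight initialization.
#' @return a list of class `cae_model`.
#' @export
cae_model <- function(input_dim, latent = latent_config(),
                      layout = group_layout(5, 2),
                      hidden_encoder = c(2200, 2000, 1000),
                      hidden_decoder = c(2024, 3000, 2200),
                      seed = NULL) {
  stopifnot(input_dim >= 1)
  if (!is.null(seed)) set.seed(seed)
  enc_widths <- c(input_dim, hidden_encoder, latent$d)
  dec_widths <- c(latent$d, hidden_decoder, input_dim)
  structure(
    list(
      encoder = .init_mlp(enc_widths),
      fusion = .init_linear(layout$N * latent$d, fused_length(latent, layout)),
      decoder = .init_mlp(dec_widths),
      latent = latent, layout = layout, input_dim = input_dim,
      hidden_encoder = hidden_encoder, hidden_decoder = hidden_decoder,
      seed = seed
    ),
    class = "cae_model"
  )
}

#' Construct an untrained vanilla autoencoder baseline
#'
#' Same encoder and decoder stacks as [cae_model()] applied per image with
#' no fusion layer; the latent width is `zg + ze + zp` so the baseline is
#' directly comparable to the compositional model.
#'
#' @inheritParams cae_model
#' @return a list of class `ae_model`.
#' @export
ae_model <- function(input_dim, latent = latent_config(),
                     hidden_encoder = c(2200, 2000, 1000),
                     hidden_decoder = c(2024, 3000, 2200),
                     seed = NULL) {
  stopifnot(input_dim >= 1)
  if (!is.null(seed)) set.seed(seed)
  structure(
    list(
      encoder = .init_mlp(c(input_dim, hidden_encoder, latent$d)),
      decoder = .init_mlp(c(latent$d, hidden_decoder, input_dim)),
      latent = latent, input_dim = input_dim,
      hidden_encoder = hidden_encoder, hidden_decoder = hidden_decoder,
      seed = seed
    ),
    class = "ae_model"
  )
}

#' @export
print.cae_model <- function(x, ...) {
  cat("<cae_model> input ", x$input_dim,
      " | encoder ", paste(c(x$input_dim, x$hidden_encoder, x$latent$d),
                           collapse = " -> "),
      " | fusion ", x$layout$N * x$latent$d, " -> ",
      fused_length(x$latent, x$layout),
      " | decoder ", paste(c(x$latent$d, x$hidden_decoder, x$input_dim),
                           collapse = " -> "), "\n", sep = "")
  cat("  latent (zg, ze, zp) = (", x$latent$zg, ", ", x$latent$ze, ", ",
      x$latent$zp, "), layout E = ", x$layout$E, ", R = ", x$layout$R,
      "\n", sep = "")
  invisible(x)
}

#' Encode preprocessed feature vectors
#'
#' @param model a [cae_model()] or [ae_model()].
#' @param x a numeric vector of length `input_dim` or a matrix with that
#'   many columns.
#' @return a matrix of per-image latents (`n x (zg+ze+zp)`); a vector input
#'   returns a one-row matrix dropped to a vector.
#' @export
encode <- function(model, x) {
  single <- is.null(dim(x))
  if (single) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$input_dim) {
    stop("input length ", ncol(x), " != configured input width ",
         model$input_dim)
  }
  z <- .mlp_forward(model$encoder, x, out = "linear")$out
  if (single) drop(z) else z
}

#' Fuse the ordered latents of one genotype group
#'
#' Concatenates the `N` per-image latents in group order and applies the
#' affine fusion map, producing the partitioned vector
#' `[Zg | Ze_1..Ze_E | Zp_1..Zp_N]`.
#'
#' @param model a [cae_model()].
#' @param latents an `N x (zg+ze+zp)` matrix, rows in group-layout order.
#' @return the fused vector of length `zg + E ze + N zp`.
#' @export
fuse <- function(model, latents) {
  stopifnot(inherits(model, "cae_model"))
  if (is.null(dim(latents))) latents <- matrix(latents, nrow = 1)
  if (nrow(latents) != model$layout$N || ncol(latents) != model$latent$d) {
    stop("expected ", model$layout$N, " latents of width ", model$latent$d)
  }
  zc <- as.vector(t(latents))
  drop(zc %*% model$fusion$W + model$fusion$b)
}

#' Assemble the disentangled latent of one group position
#'
#' Slices the fused vector for the image at `position`: the shared genotype
#' block, the environment block of that position's environment, and the
#' micro block of that position.
#'
#' @param fused the fused vector from [fuse()].
#' @param position group position in `1..N`.
#' @param latent a [latent_config()].
#' @param layout a [group_layout()].
#' @return a list with numeric vectors `zg`, `ze`, `zp`, the `environment`
#'   and `micro` indices, and `vector` (their concatenation of length
#'   `zg + ze + zp`).
#' @export
assemble_replicate_latent <- function(fused, position, latent, layout) {
  if (length(fused) != fused_length(latent, layout)) {
    stop("fused vector length ", length(fused), " != ",
         fused_length(latent, layout))
  }
  sl <- fused_slices(latent, layout, position)
  out <- list(zg = fused[sl$zg], ze = fused[sl$ze], zp = fused[sl$zp],
              environment = sl$environment, micro = sl$micro)
  out$vector <- c(out$zg, out$ze, out$zp)
  out
}

#' Decode disentangled latents into reconstructions
#'
#' @param model a [cae_model()] or [ae_model()].
#' @param z a latent vector of length `zg + ze + zp` or a matrix with that
#'   many columns.
#' @return reconstructions in `(0, 1)` (sigmoid output), same row count.
#' @export
decode <- function(model, z) {
  single <- is.null(dim(z))
  if (single) z <- matrix(z, nrow = 1)
  if (ncol(z) != model$latent$d) {
    stop("latent length ", ncol(z), " != ", model$latent$d)
  }
  xhat <- .mlp_forward(model$decoder, z, out = "sigmoid")$out
  if (single) drop(xhat) else xhat
}

#' Full forward pass for one genotype group
#'
#' Encodes the `N` images sequentially, fuses their latents, assembles the
#' per-image disentangled latents, and decodes each.
#'
#' @param model a [cae_model()].
#' @param x an `N x input_dim` matrix of preprocessed images in group-layout
#'   order.
#' @return a list with `reconstructions` (`N x input_dim`), `fused`, and
#'   `latents` (list of `N` results of [assemble_replicate_latent()]).
#' @export
forward_group <- function(model, x) {
  stopifnot(inherits(model, "cae_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (nrow(x) != model$layout$N) {
    stop("incomplete group: expected ", model$layout$N, " images, got ",
         nrow(x))
  }
  z <- encode(model, x)
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  fv <- fuse(model, z)
  lat <- lapply(seq_len(model$layout$N), function(n) {
    assemble_replicate_latent(fv, n, model$latent, model$layout)
  })
  L <- do.call(rbind, lapply(lat, `[[`, "vector"))
  list(reconstructions = decode(model, L), fused = fv, latents = lat)
}

#' Vanilla-autoencoder forward pass
#'
#' @param model an [ae_model()].
#' @param x a vector of length `input_dim` or a matrix with that many
#'   columns.
#' @return a list with `latent` and `reconstruction`.
#' @export
ae_forward <- function(model, x) {
  stopifnot(inherits(model, "ae_model"))
  z <- encode(model, x)
  list(latent = z, reconstruction = decode(model, z))
}
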