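#' Training configuration
#'
#' Hyperparameters of the training loops. Defaults: the Adam optimizer at
#' learning rate `1e-4`, batches of 8 genotype groups (80 images for the
#' 5-environment, 2-replicate layout), 200 epochs, and correlation weight
#' `lambda = 1`. The correlation penalty is computed over the per-image
#' disentangled latents by default (`corr_mode = "latent"`, rows = images,
#' columns = the `zg + ze + zp` dimensions); `corr_mode = "fused"` instead
#' decorrelates the columns of the full fused vectors across groups.
#'
#' @param epochs number of passes over the grouped data (>= 1).
#' @param batch_groups genotype groups per batch (compositional model).
#' @param batch_images images per batch (vanilla autoencoder).
#' @param learning_rate Adam step size.
#' @param lambda nonnegative correlation-loss weight.
#' @param corr_mode `"latent"` or `"fused"` (see above).
#' @param hidden_encoder,hidden_decoder hidden widths of the encoder and
#'   decoder stacks (see [cae_model()]); reduce for quick experiments.
#' @param seed integer seed governing initialization and batch shuffling.
#' @return a list of class `training_config`.
#' @export
training_config <- function(epochs = 200, batch_groups = 8, batch_images = 80,
                            learning_rate = 1e-4, lambda = 1,
                            corr_mode = c("latent", "fused"),
                            hidden_encoder = c(2200, 2000, 1000),
                            hidden_decoder = c(2024, 3000, 2200),
                            seed = 42) {
  corr_mode <- match.arg(corr_mode)
  if (epochs < 1) stop("epochs must be >= 1")
  if (lambda < 0) stop("lambda must be nonnegative")
  structure(list(epochs = as.integer(epochs),
                 batch_groups = as.integer(batch_groups),
                 batch_images = as.integer(batch_images),
                 learning_rate = learning_rate, lambda = lambda,
                 corr_mode = corr_mode,
                 hidden_encoder = hidden_encoder,
                 hidden_decoder = hidden_decoder,
                 seed = as.integer(seed)),
            class = "training_config")
}

# ---------------------------------------------------------------------------
# Group bookkeeping: a complete genotype group holds exactly R plots of that
# genotype in each of the E environments, ordered environment-major (sorted
# environment ids) and replicate-minor (sorted replicate ids).

.build_groups <- function(meta, layout = NULL) {
  envs <- sort(unique(meta$environment_id))
  E <- length(envs)
  R <- if (is.null(layout)) {
    max(dplyr::count(meta, .data$genotype_id, .data$environment_id)$n)
  } else layout$R
  if (is.null(layout)) layout <- group_layout(E, R)
  if (layout$E != E) {
    stop("layout expects ", layout$E, " environments, data has ", E)
  }
  meta2 <- dplyr::arrange(
    dplyr::mutate(meta, .row = dplyr::row_number()),
    .data$genotype_id, match(.data$environment_id, envs), .data$replicate_id
  )
  split_rows <- split(meta2, meta2$genotype_id)
  complete <- vapply(split_rows, function(d) {
    nrow(d) == layout$N &&
      all(table(factor(d$environment_id, levels = envs)) == layout$R)
  }, logical(1))
  if (!any(complete)) stop("no complete genotype groups in the dataset")
  dropped <- names(split_rows)[!complete]
  if (length(dropped) > 0) {
    warning(length(dropped), " genotype group(s) dropped as incomplete: ",
            paste(head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  }
  kept <- split_rows[complete]
  idx <- do.call(rbind, lapply(kept, function(d) d$.row))
  list(layout = layout, genotypes = names(kept), idx = idx, envs = envs,
       dropped = dropped)
}

# Batched forward pass through the full compositional model. X rows must be
# group-major (G consecutive blocks of N images in layout order).
.cae_forward <- function(model, X, n_groups) {
  d <- model$latent$d; N <- model$layout$N
  enc <- .mlp_forward(model$encoder, X, out = "linear")
  z <- enc$out
  zt <- t(z); dim(zt) <- c(d * N, n_groups)
  Zc <- t(zt)
  Fm <- sweep(Zc %*% model$fusion$W, 2, model$fusion$b, "+")
  L <- matrix(0, nrow(X), d)
  for (n in seq_len(N)) {
    sl <- fused_slices(model$latent, model$layout, n)
    L[seq(n, nrow(X), by = N), ] <- Fm[, c(sl$zg, sl$ze, sl$zp), drop = FALSE]
  }
  dec <- .mlp_forward(model$decoder, L, out = "sigmoid")
  list(enc = enc, z = z, Zc = Zc, Fm = Fm, L = L, dec = dec,
       Xhat = dec$out)
}

# Backward pass for one MLP. `dout` is the loss gradient with respect to the
# final activation; returns per-layer weight gradients and the gradient with
# respect to the input.
.mlp_backward <- function(layers, x, acts, dout, out = c("linear", "sigmoid")) {
  out <- match.arg(out)
  nl <- length(layers)
  a_last <- acts[[nl]]
  delta <- if (out == "sigmoid") dout * a_last * (1 - a_last) else dout
  grads <- vector("list", nl)
  dx <- NULL
  for (k in rev(seq_len(nl))) {
    a_prev <- if (k == 1) x else acts[[k - 1]]
    grads[[k]] <- list(W = crossprod(a_prev, delta), b = colSums(delta))
    dprev <- tcrossprod(delta, layers[[k]]$W)
    if (k > 1) delta <- dprev * .selu_grad_from_act(acts[[k - 1]])
    else dx <- dprev
  }
  list(grads = grads, dx = dx)
}

# Full backward pass for the compositional model.
.cae_backward <- function(model, X, fw, lambda, corr_mode) {
  d <- model$latent$d; N <- model$layout$N
  B <- nrow(X); G <- B / N
  dXhat <- 2 * (fw$Xhat - X) / length(X)
  dec_bw <- .mlp_backward(model$decoder, fw$L, fw$dec$acts, dXhat,
                          out = "sigmoid")
  dL <- dec_bw$dx
  if (lambda > 0 && corr_mode == "latent" && B >= 3) {
    dL <- dL + lambda * .correlation_loss_grad(fw$L)
  }
  dF <- matrix(0, G, ncol(fw$Fm))
  for (n in seq_len(N)) {
    sl <- fused_slices(model$latent, model$layout, n)
    cols <- c(sl$zg, sl$ze, sl$zp)
    dF[, cols] <- dF[, cols] + dL[seq(n, B, by = N), , drop = FALSE]
  }
  if (lambda > 0 && corr_mode == "fused" && G >= 3) {
    dF <- dF + lambda * .correlation_loss_grad(fw$Fm)
  }
  fus_grad <- list(W = crossprod(fw$Zc, dF), b = colSums(dF))
  dZc <- tcrossprod(dF, model$fusion$W)
  dzt <- t(dZc); dim(dzt) <- c(d, B)
  dz <- t(dzt)
  enc_bw <- .mlp_backward(model$encoder, X, fw$enc$acts, dz, out = "linear")
  list(encoder = enc_bw$grads, fusion = fus_grad, decoder = dec_bw$grads)
}

# Flatten an arbitrary nesting of numeric leaves into one list, in a
# deterministic order. The returned list holds references to (not copies of)
# the leaves, which is what the in-place Adam kernel relies on.
.flat_leaves <- function(x) {
  if (is.numeric(x)) return(list(x))
  do.call(c, lapply(x, .flat_leaves))
}

#' Train the compositional autoencoder
#'
#' Minimizes `reconstruction + lambda * correlation` by minibatch Adam over
#' complete genotype groups. Incomplete groups (a genotype missing any
#' environment x replicate slot) are dropped with a warning, since the
#' fusion layer needs a fixed group size. The run is deterministic for a
#' given seed. The returned history holds the reconstruction and
#' correlation components separately per epoch; epoch 0 records the losses
#' of the freshly initialized model on the full grouped data.
#'
#' @param dataset a [cae_dataset()]; preprocessed with [preprocess()] first,
#'   or it will be preprocessed here with default settings.
#' @param latent a [latent_config()].
#' @param config a [training_config()].
#' @param layout optional [group_layout()]; inferred from the metadata when
#'   `NULL`.
#' @param hidden_encoder,hidden_decoder hidden widths; default to the
#'   configuration's.
#' @return an object of class `cae_fit`: fields `model`, `history` (tibble
#'   `epoch`, `recon`, `corr`, `total`), `config`, `genotypes`, `stats`.
#' @export
train_cae <- function(dataset, latent = latent_config(),
                      config = training_config(), layout = NULL,
                      hidden_encoder = config$hidden_encoder,
                      hidden_decoder = config$hidden_decoder) {
  stopifnot(inherits(dataset, "cae_dataset"))
  if (n_plots(dataset) == 0) stop("empty dataset")
  if (!dataset$preprocessed) {
    message("dataset is not preprocessed; applying preprocess() defaults")
    dataset <- preprocess(dataset)
  }
  X_all <- flatten_images(dataset)
  grp <- .build_groups(dataset$meta, layout)
  layout <- grp$layout
  G <- length(grp$genotypes)

  set.seed(config$seed)
  model <- cae_model(ncol(X_all), latent, layout,
                     hidden_encoder = hidden_encoder,
                     hidden_decoder = hidden_decoder)
  # The Adam kernel updates the model's weight arrays in place through this
  # flat view; m/v are fresh zero arrays of the same shapes.
  leaves <- .flat_leaves(list(model$encoder, model$fusion, model$decoder))
  m <- lapply(leaves, function(x) x * 0)
  v <- lapply(leaves, function(x) x * 0)
  step <- 0

  eval_full <- function() {
    rows <- as.vector(t(grp$idx))
    fw <- .cae_forward(model, X_all[rows, , drop = FALSE], G)
    corr <- if (config$corr_mode == "latent") correlation_loss(fw$L)
            else correlation_loss(fw$Fm)
    recon <- reconstruction_loss(X_all[rows, , drop = FALSE], fw$Xhat)
    c(recon = recon, corr = corr)
  }
  l0 <- eval_full()
  history <- tibble::tibble(epoch = 0L, recon = l0[["recon"]],
                            corr = l0[["corr"]],
                            total = total_loss(l0[["recon"]], l0[["corr"]],
                                               config$lambda))

  n_batches <- ceiling(G / config$batch_groups)
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(G)
    ep_recon <- 0; ep_corr <- 0; ep_n <- 0
    for (bt in seq_len(n_batches)) {
      gsel <- perm[seq.int((bt - 1) * config$batch_groups + 1,
                           min(bt * config$batch_groups, G))]
      rows <- as.vector(t(grp$idx[gsel, , drop = FALSE]))
      Xb <- X_all[rows, , drop = FALSE]
      fw <- .cae_forward(model, Xb, length(gsel))
      Lmat <- if (config$corr_mode == "latent") fw$L else fw$Fm
      corr <- if (nrow(Lmat) >= 3 && ncol(Lmat) >= 2) correlation_loss(Lmat)
              else 0
      recon <- reconstruction_loss(Xb, fw$Xhat)
      gr <- .cae_backward(model, Xb, fw, config$lambda, config$corr_mode)
      step <- step + 1
      .adam_step_inplace(leaves,
                         .flat_leaves(list(gr$encoder, gr$fusion, gr$decoder)),
                         m, v, config$learning_rate,
                         1 - 0.9^step, 1 - 0.999^step)
      w <- length(gsel)
      ep_recon <- ep_recon + w * recon
      ep_corr <- ep_corr + w * corr
      ep_n <- ep_n + w
    }
    history <- dplyr::bind_rows(history, tibble::tibble(
      epoch = as.integer(epoch), recon = ep_recon / ep_n,
      corr = ep_corr / ep_n,
      total = total_loss(ep_recon / ep_n, ep_corr / ep_n, config$lambda)
    ))
  }
  structure(list(model = model, history = history, config = config,
                 genotypes = grp$genotypes, dropped = grp$dropped,
                 envs = grp$envs, stats = dataset$stats),
            class = "cae_fit")
}

#' Train the vanilla autoencoder baseline
#'
#' Same encoder/decoder stacks trained per image with the reconstruction
#' loss only — no grouping, no fusion, no correlation penalty.
#'
#' @inheritParams train_cae
#' @return an object of class `ae_fit` with fields `model`, `history`
#'   (`epoch`, `recon`, `total`), `config`, `stats`.
#' @export
train_ae <- function(dataset, latent = latent_config(),
                     config = training_config(),
                     hidden_encoder = config$hidden_encoder,
                     hidden_decoder = config$hidden_decoder) {
  stopifnot(inherits(dataset, "cae_dataset"))
  if (n_plots(dataset) == 0) stop("empty dataset")
  if (!dataset$preprocessed) {
    message("dataset is not preprocessed; applying preprocess() defaults")
    dataset <- preprocess(dataset)
  }
  X_all <- flatten_images(dataset)
  n <- nrow(X_all)

  set.seed(config$seed)
  model <- ae_model(ncol(X_all), latent,
                    hidden_encoder = hidden_encoder,
                    hidden_decoder = hidden_decoder)
  leaves <- .flat_leaves(list(model$encoder, model$decoder))
  m <- lapply(leaves, function(x) x * 0)
  v <- lapply(leaves, function(x) x * 0)
  step <- 0

  fw_full <- ae_forward(model, X_all)
  history <- tibble::tibble(epoch = 0L,
                            recon = reconstruction_loss(X_all,
                                                        fw_full$reconstruction))
  history$total <- history$recon

  n_batches <- ceiling(n / config$batch_images)
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    ep_recon <- 0; ep_n <- 0
    for (bt in seq_len(n_batches)) {
      rows <- perm[seq.int((bt - 1) * config$batch_images + 1,
                           min(bt * config$batch_images, n))]
      Xb <- X_all[rows, , drop = FALSE]
      enc <- .mlp_forward(model$encoder, Xb, out = "linear")
      dec <- .mlp_forward(model$decoder, enc$out, out = "sigmoid")
      recon <- reconstruction_loss(Xb, dec$out)
      dXhat <- 2 * (dec$out - Xb) / length(Xb)
      dec_bw <- .mlp_backward(model$decoder, enc$out, dec$acts, dXhat,
                              out = "sigmoid")
      enc_bw <- .mlp_backward(model$encoder, Xb, enc$acts, dec_bw$dx,
                              out = "linear")
      step <- step + 1
      .adam_step_inplace(leaves,
                         .flat_leaves(list(enc_bw$grads, dec_bw$grads)),
                         m, v, config$learning_rate,
                         1 - 0.9^step, 1 - 0.999^step)
      ep_recon <- ep_recon + length(rows) * recon
      ep_n <- ep_n + length(rows)
    }
    history <- dplyr::bind_rows(history, tibble::tibble(
      epoch = as.integer(epoch), recon = ep_recon / ep_n,
      total = ep_recon / ep_n))
  }
  structure(list(model = model, history = history, config = config,
                 stats = dataset$stats),
            class = "ae_fit")
}

#' Extract per-plot latent features from a trained model
#'
#' For a compositional fit, runs the full grouped forward pass and returns
#' one row per image with the disentangled blocks in columns `zg_*`, `ze_*`,
#' `zp_*` (genotype block constant within a group, environment block shared
#' by replicates at one location). For a vanilla-autoencoder fit, returns
#' per-image latents in columns `z_*`.
#'
#' @param fit a `cae_fit` or `ae_fit`.
#' @param dataset the dataset to encode (preprocessed, or preprocessed here
#'   with defaults).
#' @return a tibble with `plot_id`, `genotype_id`, `environment_id`,
#'   `replicate_id` and the latent columns; rows follow the dataset's
#'   metadata order, restricted to complete groups for compositional fits.
#' @export
extract_latents <- function(fit, dataset) {
  stopifnot(inherits(dataset, "cae_dataset"))
  if (!dataset$preprocessed) {
    message("dataset is not preprocessed; applying preprocess() defaults")
    dataset <- preprocess(dataset)
  }
  X_all <- flatten_images(dataset)
  meta_cols <- dplyr::select(dataset$meta, "plot_id", "genotype_id",
                             "environment_id", "replicate_id")
  if (inherits(fit, "ae_fit")) {
    z <- encode(fit$model, X_all)
    colnames(z) <- paste0("z_", seq_len(ncol(z)))
    return(dplyr::bind_cols(meta_cols, tibble::as_tibble(z)))
  }
  stopifnot(inherits(fit, "cae_fit"))
  model <- fit$model
  grp <- .build_groups(dataset$meta, model$layout)
  rows <- as.vector(t(grp$idx))
  chunk <- 64L  # groups per forward chunk, to bound activation memory
  G <- length(grp$genotypes)
  Lparts <- lapply(split(seq_len(G), ceiling(seq_len(G) / chunk)),
                   function(gs) {
    r <- as.vector(t(grp$idx[gs, , drop = FALSE]))
    .cae_forward(model, X_all[r, , drop = FALSE], length(gs))$L
  })
  L <- do.call(rbind, Lparts)
  colnames(L) <- c(paste0("zg_", seq_len(model$latent$zg)),
                   paste0("ze_", seq_len(model$latent$ze)),
                   paste0("zp_", seq_len(model$latent$zp)))
  out <- dplyr::bind_cols(meta_cols[rows, ], tibble::as_tibble(L))
  dplyr::arrange(out, match(.data$plot_id, dataset$meta$plot_id))
}
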