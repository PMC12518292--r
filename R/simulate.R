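#' Simulation configuration for synthetic trial imagery
#'
#' Defines a replicated multi-environment maize trial imaged once: each of
#' `n_genotypes` hybrids is grown in `n_replicates` plots at each of
#' `n_environments` locations, and every plot is a `width x height x channels`
#' 12-bit multispectral image. Images are driven by three latent factor sets
#' — a per-genotype vector (length `dg`), a per-environment vector (length
#' `de`) placed on a sphere of radius `env_separation`, and a per-plot
#' micro-environment vector (length `dp`, s.d. `micro_sd`) — mapped to pixel
#' reflectance through a fixed random linear map, a low-frequency spatial
#' pattern, and a logistic squash onto the 12-bit range. Yields follow an
#' additive genotype + environment + interaction model in bushels/acre.
#'
#' @param n_genotypes number of genotypes (default 84, the trial size the
#'   generator emulates).
#' @param n_environments number of locations `E` (default 5; at least 2 is
#'   required by the disentanglement protocol).
#' @param n_replicates replicate plots per genotype per location (default 2).
#' @param width,height,channels image shape (defaults 11, 22, 6).
#' @param dg,de,dp true factor dimensions for genotype, environment and
#'   micro-environment.
#' @param env_separation radius of the sphere on which environment factor
#'   means are placed; the single dial for between-location contrast. The
#'   default is calibrated so that a PCA-3 silhouette of the raw flattened
#'   pixels under location labels lands near 0.3, the regime in which raw
#'   imagery separates locations only weakly.
#' @param micro_sd standard deviation of the per-plot micro factors; the only
#'   within-location, between-replicate source of image variation.
#' @param pixel_noise_sd additive per-pixel sensor noise, in 12-bit counts.
#' @param spatial_amp amplitude of the fixed low-frequency spatial pattern
#'   added per channel (keeps images from being spatially constant).
#' @param yield_base intercept of the yield model, bu/ac.
#' @param yield_g_sd,yield_e_sd scale of the genotype and environment main
#'   effects on yield, bu/ac per unit factor score.
#' @param gxe_strength scale of the bilinear genotype-by-environment
#'   interaction term, bu/ac per unit interaction score.
#' @param yield_noise_sd residual yield noise, bu/ac.
#' @param timepoint label attached to every plot (one acquisition per
#'   simulated dataset).
#' @param seed integer seed; identical seeds give bit-identical datasets.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genotypes = 84, n_environments = 5, n_replicates = 2,
                       width = 11, height = 22, channels = 6,
                       dg = 6, de = 6, dp = 2,
                       env_separation = 2, micro_sd = 0.5,
                       pixel_noise_sd = 40, spatial_amp = 0.5,
                       yield_base = 180, yield_g_sd = 20, yield_e_sd = 30,
                       gxe_strength = 8, yield_noise_sd = 12,
                       timepoint = "TP1", seed = 1) {
  counts <- c(n_genotypes = n_genotypes, n_environments = n_environments,
              n_replicates = n_replicates, width = width, height = height,
              channels = channels, dg = dg, de = de, dp = dp)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("all counts and dimensions must be integers >= 1")
  }
  nonneg <- c(env_separation = env_separation, micro_sd = micro_sd,
              pixel_noise_sd = pixel_noise_sd, spatial_amp = spatial_amp,
              yield_g_sd = yield_g_sd, yield_e_sd = yield_e_sd,
              gxe_strength = gxe_strength, yield_noise_sd = yield_noise_sd)
  if (any(nonneg < 0)) stop("scale parameters must be nonnegative")
  structure(
    list(n_genotypes = n_genotypes, n_environments = n_environments,
         n_replicates = n_replicates, width = width, height = height,
         channels = channels, dg = dg, de = de, dp = dp,
         env_separation = env_separation, micro_sd = micro_sd,
         pixel_noise_sd = pixel_noise_sd, spatial_amp = spatial_amp,
         yield_base = yield_base, yield_g_sd = yield_g_sd,
         yield_e_sd = yield_e_sd, gxe_strength = gxe_strength,
         yield_noise_sd = yield_noise_sd, timepoint = timepoint, seed = seed),
    class = "sim_config"
  )
}

#' Simulate a replicated multi-environment trial dataset
#'
#' Draws genotype factors `g_k ~ N(0, I_dg)`, places environment factors
#' `e_l` deterministically (seeded) on a sphere of radius `env_separation`,
#' and per-plot micro factors `p_i ~ N(0, micro_sd^2 I_dp)`. Each plot's
#' reflectance is `round(4095 * plogis(A [g; e; p] + b + s))` where `A`, `b`
#' are fixed seeded draws and `s` is a fixed low-frequency spatial pattern;
#' optional sensor noise is added and values are clipped back into the
#' 12-bit range `[0, 4095]` and re-rounded. Yield per plot is
#' `yield_base + w_g'g + w_e'e + gxe_strength * g'Me + N(0, yield_noise_sd^2)`
#' with fixed seeded `w_g`, `w_e`, `M`.
#'
#' @param config a [sim_config()].
#' @return a [cae_dataset()] with metadata, 12-bit integer pixels, a yield
#'   table (bu/ac) and a ground-truth factor table; generator coefficients
#'   are kept in `$sim`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  set.seed(cf$seed)
  G <- cf$n_genotypes; E <- cf$n_environments; R <- cf$n_replicates
  P <- cf$width * cf$height * cf$channels
  dtot <- cf$dg + cf$de + cf$dp

  # Fixed structural draws (order matters for reproducibility).
  A <- matrix(rnorm(P * dtot, sd = 1 / sqrt(dtot)), P, dtot)
  b <- rnorm(P, sd = 0.3)
  w_g <- rnorm(cf$dg); w_g <- cf$yield_g_sd * w_g / sqrt(sum(w_g^2))
  w_e <- rnorm(cf$de); w_e <- cf$yield_e_sd * w_e / sqrt(sum(w_e^2))
  M <- matrix(rnorm(cf$dg * cf$de, sd = 1 / sqrt(cf$dg * cf$de)), cf$dg, cf$de)

  # Environment means on a sphere of radius env_separation.
  Emat <- matrix(rnorm(E * cf$de), E, cf$de)
  Emat <- Emat / sqrt(rowSums(Emat^2)) * cf$env_separation
  if (cf$env_separation == 0) Emat[] <- 0

  # Fixed low-frequency spatial basis per channel.
  phase <- runif(cf$channels, 0, 2 * pi)
  phase2 <- runif(cf$channels, 0, 2 * pi)
  spatial <- array(0, dim = c(cf$width, cf$height, cf$channels))
  for (ch in seq_len(cf$channels)) {
    sw <- sin(2 * pi * (seq_len(cf$width) - 1) / cf$width + phase[ch])
    sh <- cos(2 * pi * (seq_len(cf$height) - 1) / cf$height + phase2[ch])
    spatial[, , ch] <- cf$spatial_amp * outer(sw, sh)
  }
  s_vec <- as.vector(spatial)

  Gfac <- matrix(rnorm(G * cf$dg), G, cf$dg)

  n_total <- G * E * R
  meta <- tidyr::expand_grid(
    genotype_id = sprintf("G%03d", seq_len(G)),
    environment_id = sprintf("ENV%d", seq_len(E)),
    replicate_id = seq_len(R)
  )
  meta$plot_id <- sprintf("%s_%s_R%d", meta$genotype_id, meta$environment_id,
                          meta$replicate_id)
  meta$timepoint <- cf$timepoint
  meta <- dplyr::select(meta, "plot_id", "genotype_id", "environment_id",
                        "replicate_id", "timepoint")

  Pfac <- matrix(rnorm(n_total * cf$dp, sd = cf$micro_sd), n_total, cf$dp)

  g_idx <- rep(seq_len(G), each = E * R)
  e_idx <- rep(rep(seq_len(E), each = R), times = G)
  U <- cbind(Gfac[g_idx, , drop = FALSE], Emat[e_idx, , drop = FALSE], Pfac)

  # n_total x P reflectance, squashed onto the 12-bit range.
  act <- U %*% t(A)
  act <- sweep(act, 2, b + s_vec, "+")
  dn <- round(4095 * stats::plogis(act))
  if (cf$pixel_noise_sd > 0) {
    dn <- dn + matrix(rnorm(n_total * P, sd = cf$pixel_noise_sd), n_total, P)
    dn <- round(pmin(pmax(dn, 0), 4095))
  }
  pixels <- array(NA_real_, dim = c(n_total, cf$width, cf$height, cf$channels))
  pixels[] <- dn  # both are plot-major with (W, H, C) in C-last order

  g_score <- as.vector(Gfac %*% w_g)[g_idx]
  # Standardize the E location projections so yield_e_sd controls the
  # realized between-location spread exactly (the configured variance
  # shares must be recoverable from the data, and E is small enough that
  # raw projections would scatter far from their nominal scale).
  e_proj <- as.vector(Emat %*% w_e)
  e_spread <- sqrt(mean((e_proj - mean(e_proj))^2))
  e_proj <- if (e_spread > 0) {
    (e_proj - mean(e_proj)) / e_spread * cf$yield_e_sd
  } else rep(0, E)
  e_score <- e_proj[e_idx]
  gxe_score <- rowSums((Gfac[g_idx, , drop = FALSE] %*% M) *
                         Emat[e_idx, , drop = FALSE])
  yield <- cf$yield_base + g_score + e_score + cf$gxe_strength * gxe_score +
    rnorm(n_total, sd = cf$yield_noise_sd)

  truth <- tibble::as_tibble(as.data.frame(U))
  names(truth) <- c(paste0("g_", seq_len(cf$dg)), paste0("e_", seq_len(cf$de)),
                    paste0("p_", seq_len(cf$dp)))
  truth <- dplyr::bind_cols(tibble::tibble(plot_id = meta$plot_id), truth)

  cae_dataset(
    pixels, meta,
    yields = tibble::tibble(plot_id = meta$plot_id, yield_bu_ac = yield),
    truth = truth,
    bands = cae_default_bands()[seq_len(cf$channels)],
    sim = list(
      config = unclass(cf),
      w_g = w_g, w_e = w_e, M = M, env_means = Emat,
      yield_components = list(
        g_score = g_score, e_score = e_score,
        gxe_score = cf$gxe_strength * gxe_score
      )
    )
  )
}
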