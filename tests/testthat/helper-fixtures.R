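# Small shared fixtures. All data are generated in code; nothing is read
# from disk except in explicit round-trip tests.

# A compact trial: 6 genotypes x 3 environments x 2 replicates of 5 x 4 x 6
# images. Small enough that every structural test runs in well under a
# second.
tiny_config <- function(...) {
  defaults <- list(n_genotypes = 6, n_environments = 3, n_replicates = 2,
                   width = 5, height = 4, channels = 6, dp = 2, seed = 7)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

tiny_dataset <- function(...) simulate_dataset(tiny_config(...))

# Narrow network widths for training tests where only behavior, not
# capacity, matters.
tiny_training <- function(...) {
  training_config(hidden_encoder = c(32, 24, 16),
                  hidden_decoder = c(16, 24, 32), ...)
}

# An ordinary-least-squares regressor honoring the fit/predict contract;
# used where exact recovery of a linear target makes expectations sharp.
lm_regressor <- function() {
  structure(
    list(
      label = "lm",
      fit = function(x, y) {
        stats::lm.fit(cbind(1, as.matrix(x)), y)
      },
      predict = function(model, x) {
        as.numeric(cbind(1, as.matrix(x)) %*% model$coefficients)
      }
    ),
    class = "regressor_spec"
  )
}

# Brute-force silhouette oracle: direct O(n^2) a(i)/b(i) computation with
# singleton clusters scored 0.
brute_silhouette <- function(points, labels) {
  points <- as.matrix(points)
  n <- nrow(points)
  dmat <- as.matrix(dist(points))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(dmat[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(dmat[i, which(labels == l)])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Independent scalar vegetation-index oracle: each formula re-derived
# pixelwise from plain arithmetic, without the package's vectorized guard
# structure. VEG's exponent pair is written as (0.667, 0.333) directly.
oracle_vi_pixel <- function(name, R, G, B, N, RE) {
  eps <- 1e-12
  switch(name,
    NDVI  = (N - R) / (N + R + eps),
    GNDVI = (N - G) / (N + G + eps),
    NDRE  = (N - RE) / (N + RE + eps),
    RDVI  = (N - R) / sqrt(max(N + R, 0) + eps),
    EVI   = 2.5 * (N - R) / (N + 6 * R - 7.5 * B + 1 + eps),
    SAVI  = 1.5 * (N - R) / (N + R + 0.5 + eps),
    NGRDI = (G - R) / (G + R + eps),
    GLI   = (2 * G - R - B) / (2 * G + R + B + eps),
    VARI  = (G - R) / (G + R - B + eps),
    RGBVI = (G * G - R * B) / (G * G + R * B + eps),
    VEG   = G / (max(R, 0)^0.667 * max(B, 0)^0.333 + eps),
    ExG   = 2 * G / (R + G + B + eps) - R / (R + G + B + eps) -
            B / (R + G + B + eps),
    ExR   = 1.4 * R / (R + G + B + eps) - G / (R + G + B + eps))
}

# Brute-force correlation-loss oracle: explicit double loop over column
# pairs using stats::cor.
brute_correlation_loss <- function(L) {
  D <- ncol(L)
  total <- 0
  for (i in seq_len(D)) {
    for (j in seq_len(D)) {
      if (j > i) {
        sdi <- sd(L[, i]); sdj <- sd(L[, j])
        r <- if (sdi == 0 || sdj == 0) 0 else stats::cor(L[, i], L[, j])
        total <- total + abs(r)
      }
    }
  }
  total
}
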