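#' Names of the supported vegetation indices
#'
#' The 13 indices computed by [compute_vi()] and [vi_table()], in the fixed
#' column order of the feature table.
#'
#' @return a character vector of index names.
#' @export
vi_names <- function() {
  c("GLI", "NGRDI", "VARI", "VEG", "RGBVI", "ExG", "ExR",
    "NDVI", "GNDVI", "EVI", "SAVI", "NDRE", "RDVI")
}

# Per-pixel formulas. R, G, B, N (NIR), RE are same-shaped arrays; eps guards
# every denominator. EVI/SAVI use the standard published coefficient sets
# (EVI: 2.5, 6, 7.5, L = 1; SAVI: L = 0.5). VEG uses a = 0.667. ExG/ExR act
# on chromatic coordinates r = R/(R+G+B) etc.
.vi_pixel <- function(name, R = NULL, G = NULL, B = NULL, N = NULL,
                      RE = NULL, eps = 1e-12) {
  switch(
    name,
    NDVI  = (N - R) / (N + R + eps),
    GNDVI = (N - G) / (N + G + eps),
    NDRE  = (N - RE) / (N + RE + eps),
    RDVI  = (N - R) / sqrt(pmax(N + R, 0) + eps),
    EVI   = 2.5 * (N - R) / (N + 6 * R - 7.5 * B + 1 + eps),
    SAVI  = 1.5 * (N - R) / (N + R + 0.5 + eps),
    NGRDI = (G - R) / (G + R + eps),
    GLI   = (2 * G - R - B) / (2 * G + R + B + eps),
    VARI  = (G - R) / (G + R - B + eps),
    RGBVI = (G^2 - R * B) / (G^2 + R * B + eps),
    VEG   = G / (pmax(R, 0)^0.667 * pmax(B, 0)^(1 - 0.667) + eps),
    ExG   = {
      tot <- R + G + B + eps
      2 * G / tot - R / tot - B / tot
    },
    ExR   = {
      tot <- R + G + B + eps
      1.4 * R / tot - G / tot
    },
    stop("unknown vegetation index: ", name)
  )
}

# Band requirements per index (names refer to the dataset band vocabulary).
.vi_bands <- function(name) {
  switch(name,
    NDVI = c("nir", "red"),
    GNDVI = c("nir", "green"),
    NDRE = c("nir", "rededge"),
    RDVI = c("nir", "red"),
    EVI = c("nir", "red", "blue"),
    SAVI = c("nir", "red"),
    NGRDI = c("green", "red"),
    GLI = c("green", "red", "blue"),
    VARI = c("green", "red", "blue"),
    RGBVI = c("green", "red", "blue"),
    VEG = c("green", "red", "blue"),
    ExG = c("red", "green", "blue"),
    ExR = c("red", "green", "blue"),
    stop("unknown vegetation index: ", name)
  )
}

#' Compute one vegetation index for a plot image
#'
#' The index is evaluated per pixel from the formulas below and then averaged
#' over the plot's pixels (per-pixel-then-mean aggregation). Denominators are
#' guarded by `eps = 1e-12`. Formulas: NDVI = (N-R)/(N+R);
#' GNDVI = (N-G)/(N+G); NDRE = (N-RE)/(N+RE); RDVI = (N-R)/sqrt(N+R);
#' EVI = 2.5 (N-R)/(N+6R-7.5B+1); SAVI = 1.5 (N-R)/(N+R+0.5);
#' NGRDI = (G-R)/(G+R); GLI = (2G-R-B)/(2G+R+B); VARI = (G-R)/(G+R-B);
#' RGBVI = (G^2-RB)/(G^2+RB); VEG = G/(R^0.667 B^0.333); ExG = 2g-r-b and
#' ExR = 1.4r-g on chromatic coordinates r = R/(R+G+B) etc.
#'
#' Indices are intended to be computed on clipped but not min-max-normalized
#' reflectance: min-max scaling is an affine per-channel map that distorts
#' ratio indices.
#'
#' @param image a `W x H x C` array.
#' @param name one of [vi_names()].
#' @param bands band names of the image's channels.
#' @param eps denominator guard.
#' @return the plot-level index value (a scalar).
#' @export
compute_vi <- function(image, name, bands = cae_default_bands(),
                       eps = 1e-12) {
  stopifnot(length(dim(image)) == 3)
  if (!name %in% vi_names()) stop("unknown vegetation index: ", name)
  need <- .vi_bands(name)
  missing_b <- setdiff(need, bands)
  if (length(missing_b) > 0) {
    stop("index ", name, " needs missing band(s): ",
         paste(missing_b, collapse = ", "))
  }
  get_band <- function(b) {
    if (!b %in% bands) return(NULL)
    image[, , match(b, bands)]
  }
  px <- .vi_pixel(name,
                  R = get_band("red"), G = get_band("green"),
                  B = get_band("blue"), N = get_band("nir"),
                  RE = get_band("rededge"), eps = eps)
  mean(px)
}

#' Vegetation-index feature table for a dataset
#'
#' One row per plot, one column per index in the fixed [vi_names()] order.
#'
#' @param dataset a [cae_dataset()]; recommended input is the clipped,
#'   un-normalized dataset (see [compute_vi()]).
#' @param indices subset of [vi_names()] to compute.
#' @param eps denominator guard.
#' @return a tibble with `plot_id` and one numeric column per index.
#' @export
vi_table <- function(dataset, indices = vi_names(), eps = 1e-12) {
  stopifnot(inherits(dataset, "cae_dataset"))
  bad <- setdiff(indices, vi_names())
  if (length(bad) > 0) stop("unknown vegetation index: ",
                            paste(bad, collapse = ", "))
  vals <- vapply(seq_len(n_plots(dataset)), function(i) {
    img <- plot_image(dataset, i)
    vapply(indices, function(nm) {
      compute_vi(img, nm, bands = dataset$bands, eps = eps)
    }, numeric(1))
  }, numeric(length(indices)))
  vals <- if (length(indices) == 1) matrix(vals, ncol = 1) else t(vals)
  colnames(vals) <- indices
  dplyr::bind_cols(tibble::tibble(plot_id = dataset$meta$plot_id),
                   tibble::as_tibble(vals))
}
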