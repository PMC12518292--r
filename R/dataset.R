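#' Plot-image dataset container
#'
#' A `cae_dataset` bundles the pixel arrays of all plots of one acquisition
#' timepoint with their identity metadata, and optionally yields and (for
#' synthetic data) the generating factors. Pixels are held as a single
#' `n_plots x W x H x C` numeric array so that channel statistics pooled over
#' the whole dataset are cheap to compute.
#'
#' @param pixels numeric array of dimension `n x W x H x C` (reflectance
#'   counts, nonnegative) or a list of `W x H x C` arrays.
#' @param meta a data frame with one row per plot and columns `plot_id`,
#'   `genotype_id`, `environment_id`, `replicate_id`, `timepoint`.
#' @param yields optional data frame with `plot_id` and `yield_bu_ac`.
#' @param truth optional data frame of generating factors (`plot_id`, `g_*`,
#'   `e_*`, `p_*`) for synthetic data.
#' @param bands character vector of band names, length `C`.
#' @param resolution_m ground sampling distance in metres per pixel.
#' @param sim optional list of generator internals (yield-model coefficients
#'   and configuration) carried along for diagnostics.
#'
#' @return An object of class `cae_dataset`.
#' @export
cae_dataset <- function(pixels, meta, yields = NULL, truth = NULL,
                        bands = cae_default_bands(), resolution_m = 0.3,
                        sim = NULL) {
  if (is.list(pixels) && !is.array(pixels)) {
    stopifnot(length(pixels) >= 1)
    d <- dim(pixels[[1]])
    stopifnot(length(d) == 3)
    arr <- array(NA_real_, dim = c(length(pixels), d))
    for (i in seq_along(pixels)) {
      if (!identical(dim(pixels[[i]]), d)) {
        stop("all plot images must share the same W x H x C shape")
      }
      arr[i, , , ] <- pixels[[i]]
    }
    pixels <- arr
  }
  stopifnot(is.array(pixels), length(dim(pixels)) == 4)
  meta <- tibble::as_tibble(meta)
  req <- c("plot_id", "genotype_id", "environment_id", "replicate_id", "timepoint")
  missing_cols <- setdiff(req, names(meta))
  if (length(missing_cols) > 0) {
    stop("metadata is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(meta) != dim(pixels)[1]) {
    stop("metadata rows (", nrow(meta), ") != number of images (",
         dim(pixels)[1], ")")
  }
  if (anyDuplicated(meta$plot_id)) stop("duplicated plot_id in metadata")
  if (length(bands) != dim(pixels)[4]) {
    stop("length(bands) must equal the channel count")
  }
  if (!all(is.finite(pixels))) stop("all pixels must be finite")
  structure(
    list(
      pixels = pixels,
      meta = meta,
      yields = if (!is.null(yields)) tibble::as_tibble(yields) else NULL,
      truth = if (!is.null(truth)) tibble::as_tibble(truth) else NULL,
      bands = bands,
      resolution_m = resolution_m,
      preprocessed = FALSE,
      stats = NULL,
      sim = sim
    ),
    class = "cae_dataset"
  )
}

#' @export
print.cae_dataset <- function(x, ...) {
  d <- dim(x$pixels)
  cat("<cae_dataset> ", d[1], " plots of ", d[2], " x ", d[3], " x ", d[4],
      " (", paste(x$bands, collapse = ","), ")\n", sep = "")
  cat("  genotypes: ", dplyr::n_distinct(x$meta$genotype_id),
      "  environments: ", dplyr::n_distinct(x$meta$environment_id),
      "  replicates: ", max(x$meta$replicate_id), "\n", sep = "")
  cat("  yields: ", ifelse(is.null(x$yields), "no", "yes"),
      "  ground truth: ", ifelse(is.null(x$truth), "no", "yes"),
      "  preprocessed: ", x$preprocessed, "\n", sep = "")
  invisible(x)
}

#' Number of plots in a dataset
#' @param dataset a [cae_dataset()].
#' @return integer count of plots.
#' @export
n_plots <- function(dataset) dim(dataset$pixels)[1]

#' Extract one plot image
#'
#' @param dataset a [cae_dataset()].
#' @param plot_id the plot identifier (or integer row index).
#' @return a `W x H x C` numeric array.
#' @export
plot_image <- function(dataset, plot_id) {
  i <- if (is.numeric(plot_id)) plot_id else match(plot_id, dataset$meta$plot_id)
  if (is.na(i) || i < 1 || i > n_plots(dataset)) {
    stop("unknown plot: ", plot_id)
  }
  arr <- dataset$pixels[i, , , , drop = FALSE]
  dim(arr) <- dim(dataset$pixels)[-1]
  arr
}

#' Combined plot/genotype/environment/yield table
#'
#' Joins the metadata and yield tables into the tabular form the yield
#' evaluation protocols consume.
#'
#' @param dataset a [cae_dataset()] carrying yields.
#' @return a tibble with `plot_id`, `genotype_id`, `environment_id`,
#'   `replicate_id` and `yield_bu_ac`.
#' @export
yield_table <- function(dataset) {
  if (is.null(dataset$yields)) stop("dataset carries no yields")
  dplyr::inner_join(
    dplyr::select(dataset$meta, "plot_id", "genotype_id", "environment_id",
                  "replicate_id"),
    dataset$yields,
    by = "plot_id"
  )
}

# ---------------------------------------------------------------------------
# On-disk format: one multi-page 16-bit TIFF per plot (one single-band page
# per spectral band, band-sequential) plus CSV side tables. 12-bit counts are
# stored exactly in the 16-bit container.

#' Write a plot image as a multi-page 16-bit TIFF
#'
#' Each spectral band is stored as one single-band 16-bit page, in band
#' order. Values must be integers in `[0, 65535]`; the simulator emits
#' 12-bit counts in `[0, 4095]`.
#'
#' @param image a `W x H x C` array of integer counts.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_plot_tiff <- function(image, path) {
  stopifnot(length(dim(image)) == 3)
  if (any(image < 0) || any(image > 65535) ||
      max(abs(image - round(image))) > 1e-9) {
    stop("image must contain integers in [0, 65535]")
  }
  pages <- lapply(seq_len(dim(image)[3]), function(ch) {
    t(image[, , ch]) / 65535   # tiff wants H x W in [0, 1]
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF plot image
#'
#' Inverse of [write_plot_tiff()]: reads each page as one band and returns a
#' `W x H x C` array of integer counts.
#'
#' @param path file path.
#' @param n_bands expected number of bands; an error is raised on mismatch.
#' @return a `W x H x C` numeric array of integer counts.
#' @export
read_plot_tiff <- function(path, n_bands = 6) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != n_bands) {
    stop("band-count mismatch in ", path, ": found ", length(pages),
         ", expected ", n_bands)
  }
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  img <- array(NA_real_, dim = c(w, h, n_bands))
  for (ch in seq_len(n_bands)) img[, , ch] <- t(pages[[ch]])
  img
}

#' Attach metadata to a list of plot images
#'
#' Builds a [cae_dataset()] from named images and a metadata table keyed by
#' `plot_id`. Every image must have a metadata row; unmatched plot ids are
#' reported in the error.
#'
#' @param images named list of `W x H x C` arrays (names are plot ids).
#' @param meta metadata data frame keyed by `plot_id`.
#' @param ... passed to [cae_dataset()].
#' @return a [cae_dataset()] with rows in the order of `images`.
#' @export
attach_metadata <- function(images, meta, ...) {
  meta <- tibble::as_tibble(meta)
  missing_ids <- setdiff(names(images), meta$plot_id)
  if (length(missing_ids) > 0) {
    stop("missing metadata rows for plot_id: ",
         paste(missing_ids, collapse = ", "))
  }
  meta <- meta[match(names(images), meta$plot_id), ]
  cae_dataset(images, meta, ...)
}

#' Write a dataset to a directory
#'
#' Emits `images/<plot_id>.tif` (one multi-page 16-bit TIFF per plot),
#' `metadata.csv`, and, when present, `yields.csv`, `ground_truth.csv`, and a
#' `dataset.json` descriptor (bands, resolution, generator coefficients).
#' Round-trips losslessly through [read_dataset()] for integer-valued pixels.
#'
#' @param dataset a [cae_dataset()] with integer pixel counts.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop("cannot create directory: ", dir)
  img_dir <- file.path(dir, "images")
  dir.create(img_dir, showWarnings = FALSE)
  for (i in seq_len(n_plots(dataset))) {
    write_plot_tiff(plot_image(dataset, i),
                    file.path(img_dir, paste0(dataset$meta$plot_id[i], ".tif")))
  }
  readr::write_csv(dataset$meta, file.path(dir, "metadata.csv"))
  if (!is.null(dataset$yields)) {
    readr::write_csv(dataset$yields, file.path(dir, "yields.csv"))
  }
  if (!is.null(dataset$truth)) {
    readr::write_csv(dataset$truth, file.path(dir, "ground_truth.csv"))
  }
  desc <- list(bands = dataset$bands, resolution_m = dataset$resolution_m,
               sim = dataset$sim)
  jsonlite::write_json(desc, file.path(dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory containing `images/` and `metadata.csv`.
#' @return a [cae_dataset()].
#' @export
read_dataset <- function(dir) {
  meta <- readr::read_csv(file.path(dir, "metadata.csv"),
                          show_col_types = FALSE)
  desc_path <- file.path(dir, "dataset.json")
  desc <- if (file.exists(desc_path)) {
    jsonlite::read_json(desc_path, simplifyVector = TRUE)
  } else list(bands = cae_default_bands(), resolution_m = 0.3, sim = NULL)
  n_bands <- length(desc$bands)
  images <- lapply(meta$plot_id, function(id) {
    read_plot_tiff(file.path(dir, "images", paste0(id, ".tif")), n_bands)
  })
  names(images) <- meta$plot_id
  yields_path <- file.path(dir, "yields.csv")
  truth_path <- file.path(dir, "ground_truth.csv")
  attach_metadata(
    images, meta,
    yields = if (file.exists(yields_path)) {
      readr::read_csv(yields_path, show_col_types = FALSE)
    } else NULL,
    truth = if (file.exists(truth_path)) {
      readr::read_csv(truth_path, show_col_types = FALSE)
    } else NULL,
    bands = desc$bands,
    resolution_m = desc$resolution_m,
    sim = desc$sim
  )
}
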