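#' Convert maize yield between bushels/acre and tons/hectare
#'
#' Uses the grain-trade constants 56 lb per bushel (at 15.5% moisture),
#' 0.45359237 kg per lb and 4046.8564224 square metres per acre, giving
#' 1 bu/ac = 0.0627677 t/ha.
#'
#' @param value nonnegative yield value(s).
#' @param from,to `"bu_ac"` or `"t_ha"`.
#' @return converted value(s).
#' @export
convert_yield <- function(value, from = "bu_ac", to = "t_ha") {
  if (any(value < 0)) stop("yield must be nonnegative")
  units <- c("bu_ac", "t_ha")
  if (!from %in% units || !to %in% units) stop("unknown yield unit")
  factor_bu_to_t_ha <- 56 * 0.45359237 / 4046.8564224 * 10
  if (from == to) value
  else if (from == "bu_ac") value * factor_bu_to_t_ha
  else value / factor_bu_to_t_ha
}

#' Genotype-grouped k-fold assignment
#'
#' Shuffles the genotypes with the given seed and deals them round-robin
#' into `k` folds, so every genotype's plots land in exactly one fold and
#' fold genotype-counts differ by at most 1 (84 genotypes into 5 folds give
#' counts 17, 17, 17, 17, 16).
#'
#' @param genotypes character vector of genotype ids (duplicates allowed;
#'   the unique set is folded).
#' @param k number of folds (2 <= k <= number of genotypes).
#' @param seed integer seed for the shuffle.
#' @return a tibble `genotype_id`, `fold`.
#' @export
grouped_kfold <- function(genotypes, k = 5, seed = 1) {
  gs <- unique(as.character(genotypes))
  if (k < 2) stop("k must be at least 2")
  if (k > length(gs)) stop("k exceeds the number of genotypes")
  set.seed(seed)
  shuffled <- sample(gs)
  tibble::tibble(genotype_id = shuffled,
                 fold = rep_len(seq_len(k), length(shuffled)))
}

#' Gradient-boosted tree regressor specification
#'
#' The default downstream learner: an XGBoost regressor with fixed,
#' documented hyperparameters and single-threaded deterministic training.
#' Any object with `fit(x, y) -> model` and `predict(model, x) -> numeric`
#' can be plugged into the evaluation protocols in its place.
#'
#' @param nrounds boosting rounds.
#' @param eta learning rate.
#' @param max_depth maximum tree depth.
#' @param subsample,colsample_bytree row/column subsampling rates (1 =
#'   deterministic, the default).
#' @param seed seed set before fitting.
#' @return a list of class `regressor_spec` with `fit` and `predict`.
#' @export
xgb_regressor <- function(nrounds = 600, eta = 0.05, max_depth = 3,
                          subsample = 1, colsample_bytree = 1, seed = 1) {
  structure(
    list(
      label = sprintf("xgboost(nrounds=%d, eta=%g, max_depth=%d)",
                      nrounds, eta, max_depth),
      fit = function(x, y) {
        set.seed(seed)
        xgboost::xgb.train(
          params = list(objective = "reg:squarederror", eta = eta,
                        max_depth = max_depth, subsample = subsample,
                        colsample_bytree = colsample_bytree, nthread = 1,
                        seed = seed),
          data = xgboost::xgb.DMatrix(as.matrix(x), label = y),
          nrounds = nrounds, verbose = 0
        )
      },
      predict = function(model, x) {
        as.numeric(predict(model, xgboost::xgb.DMatrix(as.matrix(x))))
      }
    ),
    class = "regressor_spec"
  )
}

#' Fit a regressor on training rows and predict test rows
#'
#' @param features numeric matrix or data frame of predictors (no id
#'   columns).
#' @param y numeric target aligned with `features` rows.
#' @param train_idx,test_idx disjoint row indices.
#' @param regressor a [xgb_regressor()]-style specification.
#' @return numeric predictions for `test_idx` rows.
#' @export
fit_predict <- function(features, y, train_idx, test_idx,
                        regressor = xgb_regressor()) {
  features <- as.matrix(features)
  if (nrow(features) != length(y)) stop("features/target misalignment")
  if (length(train_idx) == 0) stop("empty training set")
  if (length(intersect(train_idx, test_idx)) > 0) {
    stop("train and test indices overlap")
  }
  fitted <- regressor$fit(features[train_idx, , drop = FALSE], y[train_idx])
  regressor$predict(fitted, features[test_idx, , drop = FALSE])
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot`; can be negative out of sample.
#'
#' @param y observed values (must not be constant).
#' @param y_hat predictions.
#' @return a scalar `<= 1`.
#' @export
r_squared <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("length mismatch")
  if (length(y) < 2) stop("need at least 2 observations")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("zero-variance observations")
  1 - sum((y - y_hat)^2) / ss_tot
}

#' Root-mean-square error
#'
#' @inheritParams r_squared
#' @return a nonnegative scalar in the units of `y`.
#' @export
rmse <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("length mismatch")
  sqrt(mean((y - y_hat)^2))
}

# Align a named list of feature tables with a yield table by plot_id.
.align_features <- function(features, yields) {
  if (!is.list(features) || is.data.frame(features)) {
    features <- list(features = features)
  }
  if (is.null(names(features)) || any(names(features) == "")) {
    stop("feature tables must be named")
  }
  lapply(features, function(tb) {
    tb <- tibble::as_tibble(tb)
    if (!"plot_id" %in% names(tb)) stop("feature table needs a plot_id column")
    missing_ids <- setdiff(yields$plot_id, tb$plot_id)
    if (length(missing_ids) > 0) {
      stop("feature table lacks rows for ", length(missing_ids), " plot(s)")
    }
    tb <- tb[match(yields$plot_id, tb$plot_id), ]
    as.matrix(dplyr::select(tb, -"plot_id"))
  })
}

#' Genotype-grouped cross-validated yield prediction
#'
#' The unseen-genotype protocol: folds group plots by genotype, so test
#' genotypes never occur in training. For each named feature set a
#' gradient-boosted regressor is fitted per fold and scored by `R^2` and
#' RMSE; RMSE is reported in t/ha (the yield table's bu/ac values are
#' converted before scoring) unless `convert_to_t_ha = FALSE`.
#'
#' @param features a named list of per-plot feature tables (each with
#'   `plot_id` plus numeric columns), or a single table.
#' @param yields a table with `plot_id`, `genotype_id` and `yield_bu_ac`
#'   (see [yield_table()]).
#' @param k number of folds (default 5).
#' @param seed seed for the fold assignment.
#' @param regressor a [xgb_regressor()]-style specification.
#' @param convert_to_t_ha score in t/ha (default) or in the input unit.
#' @return a tibble of class `cv_result` with one row per feature set and
#'   fold: `feature_set`, `fold`, `r2`, `rmse`, `n_test`.
#' @export
experiment1 <- function(features, yields, k = 5, seed = 1,
                        regressor = xgb_regressor(),
                        convert_to_t_ha = TRUE) {
  yields <- tibble::as_tibble(yields)
  stopifnot(all(c("plot_id", "genotype_id", "yield_bu_ac") %in% names(yields)))
  feats <- .align_features(features, yields)
  y <- if (convert_to_t_ha) convert_yield(yields$yield_bu_ac) else
    yields$yield_bu_ac
  folds <- grouped_kfold(yields$genotype_id, k = k, seed = seed)
  fold_of <- folds$fold[match(yields$genotype_id, folds$genotype_id)]
  out <- purrr::map_dfr(names(feats), function(nm) {
    purrr::map_dfr(seq_len(k), function(f) {
      test_idx <- which(fold_of == f)
      train_idx <- which(fold_of != f)
      pred <- fit_predict(feats[[nm]], y, train_idx, test_idx, regressor)
      tibble::tibble(feature_set = nm, fold = f,
                     r2 = r_squared(y[test_idx], pred),
                     rmse = rmse(y[test_idx], pred),
                     n_test = length(test_idx))
    })
  })
  class(out) <- c("cv_result", class(out))
  attr(out, "unit") <- if (convert_to_t_ha) "t_ha" else "bu_ac"
  out
}

#' Overlap of top-ranked genotypes
#'
#' `100 * |top_f(true) intersect top_f(pred)| / |top_f(true)|` where the top
#' set holds the `floor(fraction * n)` (at least 1) highest-yielding
#' genotypes. Ties are broken by genotype id (stable, documented order).
#'
#' @param y_true,y_pred named numeric vectors over the same genotype ids.
#' @param fraction top fraction in `(0, 1)`, e.g. 0.25 or 0.50.
#' @return overlap percentage in `[0, 100]`.
#' @export
top_fraction_overlap <- function(y_true, y_pred, fraction) {
  if (length(y_true) == 0) stop("empty input")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  if (!setequal(names(y_true), names(y_pred))) {
    stop("genotype key sets differ")
  }
  top_set <- function(v) {
    ord <- order(-v, names(v))
    names(v)[ord][seq_len(max(1, floor(fraction * length(v))))]
  }
  tt <- top_set(y_true)
  tp <- top_set(y_pred[names(y_true)])
  100 * length(intersect(tt, tp)) / length(tt)
}

#' Leave-one-location-out rank-overlap evaluation
#'
#' For each location, a regressor is trained on the plots of all other
#' locations and predicts that location's plots. True and predicted yields
#' are averaged per genotype within the held-out location, genotypes are
#' ranked by each, and the overlap of the top-`fraction` sets is reported.
#'
#' @param features a per-plot feature table with `plot_id` (or a named list
#'   of length 1).
#' @param yields a table with `plot_id`, `genotype_id`, `environment_id`,
#'   `yield_bu_ac`.
#' @param fractions top fractions to evaluate (default `c(0.25, 0.5)`).
#' @param regressor a [xgb_regressor()]-style specification.
#' @return a tibble `location`, `fraction`, `overlap_pct`, `n_genotypes`.
#' @export
experiment2 <- function(features, yields, fractions = c(0.25, 0.5),
                        regressor = xgb_regressor()) {
  yields <- tibble::as_tibble(yields)
  stopifnot(all(c("plot_id", "genotype_id", "environment_id", "yield_bu_ac")
                %in% names(yields)))
  envs <- sort(unique(yields$environment_id))
  if (length(envs) < 2) stop("need at least 2 locations")
  feats <- .align_features(features, yields)[[1]]
  y <- yields$yield_bu_ac
  purrr::map_dfr(envs, function(loc) {
    test_idx <- which(yields$environment_id == loc)
    train_idx <- which(yields$environment_id != loc)
    pred <- fit_predict(feats, y, train_idx, test_idx, regressor)
    per_geno <- dplyr::summarise(
      dplyr::group_by(
        tibble::tibble(genotype_id = yields$genotype_id[test_idx],
                       true = y[test_idx], pred = pred),
        .data$genotype_id),
      true = mean(.data$true), pred = mean(.data$pred), .groups = "drop")
    purrr::map_dfr(fractions, function(f) {
      tibble::tibble(
        location = loc, fraction = f,
        overlap_pct = top_fraction_overlap(
          setNames(per_geno$true, per_geno$genotype_id),
          setNames(per_geno$pred, per_geno$genotype_id), f),
        n_genotypes = nrow(per_geno))
    })
  })
}

#' Unseen-environment yield prediction
#'
#' Trains the regressor on every location except the held-out one and
#' reports the RMSE on the held-out location, in the unit of the input
#' yield table. Feature extraction may legitimately have seen the held-out
#' imagery (unsupervised); the supervised training rows must not include
#' it, which this function enforces.
#'
#' @param features a per-plot feature table with `plot_id`.
#' @param yields a table with `plot_id`, `genotype_id`, `environment_id`,
#'   `yield_bu_ac`.
#' @param holdout_env the held-out `environment_id`.
#' @param regressor a [xgb_regressor()]-style specification.
#' @return a tibble `holdout_env`, `rmse`, `r2`, `n_test`, `unit`.
#' @export
experiment3 <- function(features, yields, holdout_env,
                        regressor = xgb_regressor()) {
  yields <- tibble::as_tibble(yields)
  if (!holdout_env %in% yields$environment_id) {
    stop("holdout environment not present: ", holdout_env)
  }
  if (all(yields$environment_id == holdout_env)) {
    stop("holdout environment is the only location; nothing to train on")
  }
  feats <- .align_features(features, yields)[[1]]
  test_idx <- which(yields$environment_id == holdout_env)
  train_idx <- which(yields$environment_id != holdout_env)
  if (length(intersect(train_idx, test_idx)) > 0) {
    stop("leakage: held-out plots present in the training rows")
  }
  y <- yields$yield_bu_ac
  pred <- fit_predict(feats, y, train_idx, test_idx, regressor)
  tibble::tibble(holdout_env = holdout_env,
                 rmse = rmse(y[test_idx], pred),
                 r2 = r_squared(y[test_idx], pred),
                 n_test = length(test_idx), unit = "bu_ac")
}

#' Cross-correlation between two feature tables
#'
#' Pearson correlation between every column of `a` and every column of `b`,
#' rows aligned by `plot_id` when present (otherwise by position).
#'
#' @param a,b numeric feature tables (optionally with `plot_id`).
#' @return a matrix with `a`'s columns as rows and `b`'s columns as columns.
#' @export
feature_cross_correlation <- function(a, b) {
  a <- tibble::as_tibble(a); b <- tibble::as_tibble(b)
  if ("plot_id" %in% names(a) && "plot_id" %in% names(b)) {
    if (!setequal(a$plot_id, b$plot_id)) stop("plot_id sets differ")
    b <- b[match(a$plot_id, b$plot_id), ]
    a <- dplyr::select(a, -"plot_id"); b <- dplyr::select(b, -"plot_id")
  }
  if (nrow(a) != nrow(b)) stop("row misalignment")
  am <- as.matrix(a); bm <- as.matrix(b)
  out <- matrix(NA_real_, ncol(am), ncol(bm),
                dimnames = list(colnames(am), colnames(bm)))
  for (i in seq_len(ncol(am))) {
    for (j in seq_len(ncol(bm))) {
      out[i, j] <- pearson_r(am[, i], bm[, j])
    }
  }
  out
}
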