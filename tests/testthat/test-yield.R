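test_that("yield unit conversion uses the grain-trade constants", {
  expect_equal(convert_yield(0), 0)
  # 100 bu/ac * 56 lb/bu * 0.45359237 kg/lb / 4046.8564224 m2/ac * 10
  expect_equal(convert_yield(100), 6.276766, tolerance = 1e-6)
  x <- runif(5, 50, 250)
  expect_equal(convert_yield(2 * x), 2 * convert_yield(x))
  expect_equal(convert_yield(convert_yield(x), from = "t_ha", to = "bu_ac"),
               x)
  expect_error(convert_yield(-1), "nonnegative")
  expect_error(convert_yield(1, from = "kg"), "unknown yield unit")
})

test_that("grouped folds partition genotypes near-evenly", {
  gs <- sprintf("G%02d", 1:84)
  f <- grouped_kfold(gs, k = 5, seed = 3)
  expect_setequal(f$genotype_id, gs)
  expect_equal(sort(as.integer(table(f$fold)), decreasing = TRUE),
               c(17, 17, 17, 17, 16))
  expect_false(any(duplicated(f$genotype_id)))  # one fold per genotype
  expect_identical(grouped_kfold(gs, k = 5, seed = 3), f)
  fold_map <- function(x) x$fold[order(x$genotype_id)]
  expect_false(identical(fold_map(grouped_kfold(gs, k = 5, seed = 4)),
                         fold_map(f)))
  expect_error(grouped_kfold(gs, k = 1), "at least 2")
  expect_error(grouped_kfold(gs[1:3], k = 5), "exceeds")
})

test_that("fit quality metrics follow their definitions", {
  y <- c(0, 2); yh <- c(1, 1)
  expect_equal(rmse(y, yh), 1)
  expect_equal(r_squared(y, yh), 0)
  y2 <- rnorm(10)
  expect_equal(r_squared(y2, y2), 1)
  expect_equal(rmse(y2, y2), 0)
  expect_equal(r_squared(y2, rep(mean(y2), 10)), 0)
  expect_error(r_squared(rep(1, 5), rnorm(5)), "zero-variance")
  expect_error(rmse(1:3, 1:4), "length")
})

test_that("the boosted regressor memorizes and repeats deterministically", {
  set.seed(10)
  x <- matrix(rnorm(80), 20, 4)
  y <- rnorm(20)
  rg <- xgb_regressor(nrounds = 400, max_depth = 6)
  p_all <- rg$predict(rg$fit(x, y), x)  # memorizable toy set, deep trees
  expect_lt(rmse(y, p_all), 0.05)
  expect_identical(rg$predict(rg$fit(x, y), x), p_all)
  expect_error(fit_predict(x, y, integer(0), 1:3, rg), "empty training")
  expect_error(fit_predict(x, y, 1:10, 5:12, rg), "overlap")
  expect_error(fit_predict(x, y[1:19], 1:10, 11:19, rg), "misalignment")
})

test_that("top-fraction overlap counts set intersections", {
  y <- setNames(c(4, 3, 2, 1), paste0("G", 1:4))
  expect_equal(top_fraction_overlap(y, y, 0.5), 100)
  expect_equal(top_fraction_overlap(y, setNames(rev(unname(y)), names(y)),
                                    0.5), 0)
  # 9-genotype top set with 5 matches
  set.seed(2)
  yt <- setNames(seq(37, 1), paste0("G", 1:37))  # top 25% = floor(9.25) = 9
  yp <- yt
  yp[paste0("G", 6:9)] <- -(1:4)  # push 4 of the true top 9 out
  expect_equal(top_fraction_overlap(yt, yp, 0.25), 100 * 5 / 9,
               tolerance = 1e-10)
  expect_error(top_fraction_overlap(yt, yp[-1], 0.25), "differ")
  expect_error(top_fraction_overlap(yt, yt, 0), "fraction")
})

test_that("random-ranking overlap is calibrated to the fraction", {
  set.seed(17)
  n <- 40
  for (frac in c(0.25, 0.5)) {
    m <- floor(frac * n)
    draws <- replicate(400, {
      top_fraction_overlap(setNames(sample(n), paste0("G", 1:n)),
                           setNames(sample(n), paste0("G", 1:n)), frac)
    })
    # hypergeometric mean overlap percentage is 100 * m / n
    mc_sd <- sd(draws) / sqrt(length(draws))
    expect_lt(abs(mean(draws) - 100 * m / n), 3 * mc_sd + 1e-9)
  }
})

test_that("grouped cross-validation reports per-fold scores in t/ha", {
  set.seed(30)
  n_g <- 12
  yt <- tidyr::expand_grid(genotype_id = sprintf("G%02d", 1:n_g),
                           environment_id = paste0("E", 1:2),
                           replicate_id = 1:2)
  yt$plot_id <- paste0("P", seq_len(nrow(yt)))
  g_eff <- rnorm(n_g, sd = 30)
  yt$yield_bu_ac <- 180 + g_eff[match(yt$genotype_id,
                                      sprintf("G%02d", 1:n_g))] +
    rnorm(nrow(yt), sd = 2)
  feats <- tibble::tibble(plot_id = yt$plot_id,
                          f1 = convert_yield(yt$yield_bu_ac) + rnorm(nrow(yt), sd = .01),
                          f2 = rnorm(nrow(yt)))
  cv <- experiment1(list(A = feats, B = feats), yt, k = 4, seed = 1,
                    regressor = lm_regressor())
  expect_equal(nrow(cv), 8)
  expect_equal(unique(cv$fold), 1:4)
  # identical features under two labels give identical results
  expect_equal(cv$r2[cv$feature_set == "A"], cv$r2[cv$feature_set == "B"])
  expect_gt(mean(cv$r2), 0.95)  # f1 is the (converted) target plus noise
  g <- glance(cv)
  expect_equal(nrow(g), 2)
  expect_true(all(c("r2_mean", "rmse_sd") %in% names(g)))
  expect_error(experiment1(list(A = feats[-1, ]), yt, k = 4),
               "lacks rows")
})

test_that("leave-one-location-out ranking recovers a perfect predictor", {
  set.seed(31)
  n_g <- 16
  yt <- tidyr::expand_grid(genotype_id = sprintf("G%02d", 1:n_g),
                           environment_id = paste0("E", 1:3),
                           replicate_id = 1:2)
  yt$plot_id <- paste0("P", seq_len(nrow(yt)))
  g_eff <- rnorm(n_g, sd = 25)
  yt$yield_bu_ac <- 150 + g_eff[match(yt$genotype_id,
                                      sprintf("G%02d", 1:n_g))]
  feats <- tibble::tibble(plot_id = yt$plot_id, f1 = yt$yield_bu_ac)
  ro <- experiment2(feats, yt, regressor = lm_regressor())
  expect_equal(nrow(ro), 6)  # 3 locations x 2 fractions
  expect_true(all(ro$overlap_pct == 100))
  expect_true(all(ro$n_genotypes == n_g))
  yt1 <- dplyr::filter(yt, environment_id == "E1")
  expect_error(experiment2(feats, yt1), "2 locations")
})

test_that("unseen-environment evaluation guards leakage and scores rmse", {
  set.seed(32)
  yt <- tidyr::expand_grid(genotype_id = sprintf("G%02d", 1:10),
                           environment_id = paste0("E", 1:3),
                           replicate_id = 1:2)
  yt$plot_id <- paste0("P", seq_len(nrow(yt)))
  yt$yield_bu_ac <- 100 + rnorm(nrow(yt), sd = 10)
  feats <- tibble::tibble(plot_id = yt$plot_id, f1 = yt$yield_bu_ac)
  r <- experiment3(feats, yt, "E2", regressor = lm_regressor())
  expect_lt(r$rmse, 1e-6)  # feature equals the target: perfect predictor
  expect_identical(r$unit, "bu_ac")
  expect_equal(r$n_test, 20)
  expect_error(experiment3(feats, yt, "E9"), "not present")
})

test_that("feature cross-correlation reuses the Pearson definition", {
  set.seed(33)
  a <- tibble::tibble(plot_id = paste0("P", 1:20), u = rnorm(20),
                      v = rnorm(20))
  m_aa <- feature_cross_correlation(a, a)
  expect_equal(diag(m_aa), c(u = 1, v = 1))
  b <- tibble::tibble(plot_id = sample(a$plot_id), w = rnorm(20))
  b$dup_u <- a$u[match(b$plot_id, a$plot_id)]
  m_ab <- feature_cross_correlation(a, b)
  expect_equal(m_ab["u", "dup_u"], 1)
  expect_equal(m_ab["v", "w"],
               stats::cor(a$v, b$w[match(a$plot_id, b$plot_id)]),
               tolerance = 1e-12)
  expect_error(feature_cross_correlation(a, b[-1, ]), "differ")
})
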