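test_that("principal-component projection matches eigen-decomposition", {
  # rank-1 data: first ratio 1, the rest 0
  set.seed(1)
  u <- rnorm(20); w <- rnorm(4)
  x1 <- outer(u, w)
  p1 <- pca_project(x1, 3)
  expect_equal(p1$explained_variance_ratio[1], 1, tolerance = 1e-12)
  expect_equal(p1$explained_variance_ratio[-1], c(0, 0), tolerance = 1e-9)

  # isotropic 4-point square: two equal ratios of 0.5
  sq <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  p2 <- pca_project(sq, 2)
  expect_equal(p2$explained_variance_ratio, c(0.5, 0.5), tolerance = 1e-12)

  # variance ratios equal the covariance eigenvalues over their sum
  x <- matrix(rnorm(60 * 7), 60, 7)
  p3 <- pca_project(x, 3)
  ev <- eigen(stats::cov(x), symmetric = TRUE)$values
  expect_lt(max(abs(p3$explained_variance_ratio - (ev / sum(ev))[1:3])),
            1e-8)
  expect_true(all(diff(p3$explained_variance_ratio) <= 1e-12))
  expect_lte(max(p3$cumulative_variance), 1 + 1e-12)

  # full-rank projection preserves pairwise distances (a rotation)
  p4 <- pca_project(x, 7)
  expect_equal(as.matrix(dist(as.matrix(p4$scores))), as.matrix(dist(x)),
               tolerance = 1e-8, ignore_attr = TRUE)

  # deterministic sign convention: repeated calls agree
  expect_identical(pca_project(x, 3)$scores, p3$scores)
  expect_error(pca_project(matrix(1, 5, 3)), "zero variance")
})

test_that("silhouette matches the hand-worked two-cluster example", {
  pts <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  lab <- c("A", "A", "B", "B")
  rep <- silhouette_score(pts, lab)
  # brute-force a/b per point: mean of (10.05-0.1)/10.05 and (9.95-0.1)/9.95
  expect_equal(rep$score, brute_silhouette(pts, lab), tolerance = 1e-12)
  expect_equal(rep$score, 0.99, tolerance = 1e-3)
  expect_equal(nrow(rep$by_label), 2)
  # label permutation leaves the score unchanged
  expect_equal(silhouette_score(pts, c("B", "B", "A", "A"))$score, rep$score)
  # two identical point clouds cannot score positively
  same <- rbind(pts, pts)
  expect_lte(silhouette_score(same, rep(c("A", "B"), each = 4))$score, 0)
  expect_error(silhouette_score(pts, rep("A", 4)), "2 distinct")
  expect_error(silhouette_score(pts[0, , drop = FALSE], character(0)),
               "empty")
})

test_that("silhouette agrees with the brute-force oracle", {
  set.seed(5)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    k <- sample(2:4, 1)
    pts <- matrix(rnorm(n * 3), n, 3)
    lab <- sample(letters[1:k], n, replace = TRUE)
    if (length(unique(lab)) < 2 || max(table(lab)) < 2) next
    expect_lt(abs(silhouette_score(pts, lab)$score -
                    brute_silhouette(pts, lab)), 1e-9)
  }
  # singleton clusters score 0, matching the oracle
  pts <- matrix(c(0, 0.2, 5), ncol = 1)
  lab <- c("A", "A", "B")
  expect_lt(abs(silhouette_score(pts, lab)$score -
                  brute_silhouette(pts, lab)), 1e-12)
})

test_that("latent-block silhouettes use the right blocks and labels", {
  # hand-built latent table: Ze separates environments perfectly, Zp is
  # noise
  set.seed(8)
  meta <- tidyr::expand_grid(genotype_id = paste0("G", 1:8),
                             environment_id = paste0("E", 1:3),
                             replicate_id = 1:2)
  n <- nrow(meta)
  env_mean <- matrix(rnorm(3 * 2, sd = 8), 3, 2)
  lat <- dplyr::mutate(
    meta,
    plot_id = paste0("P", dplyr::row_number()),
    zg_1 = rep(rnorm(8), each = 6),
    ze_1 = env_mean[as.integer(factor(environment_id)), 1] + rnorm(n, sd = .1),
    ze_2 = env_mean[as.integer(factor(environment_id)), 2] + rnorm(n, sd = .1),
    zp_1 = rnorm(n)
  )
  macro <- macro_env_silhouette(lat)
  expect_gt(macro$score, 0.8)
  expect_equal(length(macro$labels), 3)
  micro <- micro_env_silhouette(lat)
  expect_equal(length(micro$labels), 6)  # E * R classes
  expect_true(micro$score >= -1 && micro$score <= 1)
  expect_equal(micro_env_silhouette(lat)$score, micro$score)

  # mean-imputed mode uses the full latent but is driven by Ze
  mi <- macro_env_silhouette(lat, mode = "mean_imputed")
  expect_gt(mi$score, 0.8)

  # degenerate: identical Ze everywhere cannot separate environments
  lat2 <- dplyr::mutate(lat, ze_1 = 1, ze_2 = 1)
  expect_error(macro_env_silhouette(lat2), "zero variance")

  lat3 <- dplyr::filter(lat, environment_id == "E1")
  expect_error(macro_env_silhouette(lat3), "2 environments")
})

test_that("the raw-pixel baseline separates far-apart environments", {
  # two environments with a huge channel offset: near-perfect separation
  set.seed(44)
  imgs <- lapply(1:8, function(i) {
    offset <- if (i <= 4) 500 else 3500
    array(offset + runif(4 * 3 * 6, 0, 100), dim = c(4, 3, 6))
  })
  names(imgs) <- paste0("P", 1:8)
  meta <- tibble::tibble(plot_id = paste0("P", 1:8),
                         genotype_id = paste0("G", rep(1:4, 2)),
                         environment_id = rep(c("E1", "E2"), each = 4),
                         replicate_id = 1L, timepoint = "TP1")
  ds <- attach_metadata(imgs, meta)
  rep <- raw_baseline_silhouette(ds)
  expect_gt(rep$score, 0.9)
  expect_equal(raw_baseline_silhouette(ds)$score, rep$score)
  expect_true(rep$score <= 1)
})
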