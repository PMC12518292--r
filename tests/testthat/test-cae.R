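zero_weights <- function(model) {
  z <- function(l) lapply(l, function(lay) list(W = lay$W * 0, b = lay$b * 0))
  model$encoder <- z(model$encoder)
  model$decoder <- z(model$decoder)
  if (!is.null(model$fusion)) {
    model$fusion <- list(W = model$fusion$W * 0, b = model$fusion$b * 0)
  }
  model
}

test_that("encoder emits zg+ze+zp dimensions deterministically", {
  m <- cae_model(40, latent_config(6, 6, 1), group_layout(5, 2),
                 hidden_encoder = c(12, 10, 8), hidden_decoder = c(8, 10, 12),
                 seed = 1)
  x <- runif(40)
  z <- encode(m, x)
  expect_length(z, 13)
  expect_identical(encode(m, x), z)
  expect_equal(encode(zero_weights(m), x), rep(0, 13))
  expect_error(encode(m, runif(39)), "input width")
})

test_that("fusion dimensions follow zg + E ze + N zp", {
  lat <- latent_config(6, 6, 1); lay <- group_layout(5, 2)
  expect_equal(lay$N * lat$d, 130)
  expect_equal(fused_length(lat, lay), 46)
  m <- cae_model(20, lat, lay, hidden_encoder = c(8, 8, 8),
                 hidden_decoder = c(8, 8, 8), seed = 2)
  fv <- fuse(m, matrix(runif(10 * 13), 10, 13))
  expect_length(fv, 46)
  expect_equal(fuse(zero_weights(m), matrix(runif(130), 10, 13)), rep(0, 46))
  expect_error(fuse(m, matrix(0, 9, 13)), "expected 10")

  # degenerate single-image layout
  lay1 <- group_layout(1, 1)
  expect_equal(fused_length(lat, lay1), lat$d)
  m1 <- cae_model(20, lat, lay1, hidden_encoder = c(8, 8, 8),
                  hidden_decoder = c(8, 8, 8), seed = 3)
  expect_length(fuse(m1, matrix(runif(13), 1, 13)), 13)
})

test_that("latent assembly reproduces the reference 5x2 slot mapping", {
  lat <- latent_config(6, 6, 1); lay <- group_layout(5, 2)
  fv <- seq_len(fused_length(lat, lay))  # identifiable entries
  a1 <- assemble_replicate_latent(fv, 1, lat, lay)
  a2 <- assemble_replicate_latent(fv, 2, lat, lay)
  a5 <- assemble_replicate_latent(fv, 5, lat, lay)
  # replicates in environment 1 share Zg and Ze but not Zp
  expect_identical(a1$zg, a2$zg)
  expect_identical(a1$ze, a2$ze)
  expect_false(identical(a1$zp, a2$zp))
  expect_equal(a1$environment, 1); expect_equal(a2$environment, 1)
  # the 5th image is environment 3, micro slot 5
  expect_equal(a5$environment, 3)
  expect_equal(a5$micro, 5)
  expect_identical(a5$ze, fv[6 + 2 * 6 + 1:6])
  expect_identical(a5$zp, fv[6 + 5 * 6 + 5])
  expect_length(a5$vector, 13)
  expect_error(assemble_replicate_latent(fv, 11, lat, lay), "out of range")
})

test_that("assembled latents tile the fused Ze/Zp blocks exactly once", {
  set.seed(20)
  for (case in 1:20) {
    lat <- latent_config(sample(1:5, 1), sample(1:5, 1), sample(1:3, 1))
    lay <- group_layout(sample(2:5, 1), sample(1:3, 1))
    expect_equal(fused_length(lat, lay),
                 lat$zg + lay$E * lat$ze + lay$E * lay$R * lat$zp)
    seen_ze <- integer(0); seen_zp <- integer(0)
    for (n in seq_len(lay$N)) {
      sl <- fused_slices(lat, lay, n)
      expect_equal(sl$zg, seq_len(lat$zg))
      if (n %% lay$R == 1 || lay$R == 1) seen_ze <- c(seen_ze, sl$ze)
      seen_zp <- c(seen_zp, sl$zp)
    }
    expect_equal(sort(unique(seen_ze)),
                     lat$zg + seq_len(lay$E * lat$ze))
    expect_equal(sort(seen_zp),
                     lat$zg + lay$E * lat$ze + seq_len(lay$N * lat$zp))
  }
})

test_that("decoder output is sigmoid-bounded with the input width", {
  lat <- latent_config(2, 2, 1)
  m <- cae_model(30, lat, group_layout(2, 2), hidden_encoder = c(8, 8, 8),
                 hidden_decoder = c(8, 8, 8), seed = 4)
  z <- rnorm(5)
  xh <- decode(m, z)
  expect_length(xh, 30)
  expect_true(all(xh > 0 & xh < 1))
  expect_identical(decode(m, z), xh)
  expect_equal(decode(zero_weights(m), z), rep(0.5, 30))
  expect_error(decode(m, rnorm(4)), "latent length")
})

test_that("the grouped forward pass shares Zg and swaps Zp with replicates", {
  lat <- latent_config(3, 2, 2); lay <- group_layout(3, 2)
  m <- cae_model(24, lat, lay, hidden_encoder = c(10, 9, 8),
                 hidden_decoder = c(8, 9, 10), seed = 5)
  X <- matrix(runif(lay$N * 24), lay$N, 24)
  fw <- forward_group(m, X)
  expect_equal(dim(fw$reconstructions), dim(X))
  expect_true(all(fw$reconstructions > 0 & fw$reconstructions < 1))
  zg_all <- do.call(rbind, lapply(fw$latents, `[[`, "zg"))
  expect_true(all(apply(zg_all, 2, function(c) length(unique(c)) == 1)))
  expect_identical(fw$latents[[1]]$ze, fw$latents[[2]]$ze)

  # the assembled latents tile the fused vector: position n reads exactly
  # its environment's Ze slot and its own Zp slot
  for (n in seq_len(lay$N)) {
    sl <- fused_slices(lat, lay, n)
    expect_equal(fw$latents[[n]]$ze, fw$fused[sl$ze])
    expect_equal(fw$latents[[n]]$zp, fw$fused[sl$zp])
  }

  expect_error(forward_group(m, X[1:5, ]), "incomplete group")
})

test_that("the vanilla baseline reconstructs per image", {
  lat <- latent_config(2, 2, 1)
  m <- ae_model(18, lat, hidden_encoder = c(8, 7, 6),
                hidden_decoder = c(6, 7, 8), seed = 6)
  x <- runif(18)
  out <- ae_forward(m, x)
  expect_length(out$latent, lat$d)
  expect_length(out$reconstruction, 18)
  expect_true(all(out$reconstruction > 0 & out$reconstruction < 1))
  expect_identical(ae_forward(m, x)$reconstruction, out$reconstruction)
  expect_error(ae_forward(m, runif(17)), "input width")
})
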