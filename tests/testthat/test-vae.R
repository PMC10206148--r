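test_that("KL divergence matches its closed form", {
  expect_identical(kl_divergence(rep(0, 10), rep(0, 10)), 0)
  expect_equal(kl_divergence(1, 0), 0.5)
  # matrix form: one row at the prior, one displaced
  m <- rbind(c(0, 0), c(1, 1))
  lv <- matrix(0, 2, 2)
  expect_equal(kl_divergence(m, lv), c(0, 1))
  # non-negative for random posteriors
  set.seed(1)
  expect_true(all(kl_divergence(matrix(rnorm(50), 10),
                                matrix(rnorm(50), 10)) >= 0))
})

test_that("training memorises a degenerate constant-patch dataset", {
  patches <- toy_patches(200, c(0.4, 0.5, 0.6), side = 16, noise = 0)
  cfg <- vae_config(latent_dim = 4, patch_size = 16, epochs = 10,
                    batch_size = 32, learning_rate = 1e-3,
                    hidden_dim = 16, input_side = 8, seed = 1)
  vae <- train_vae(patches, cfg)
  hist <- vae$loss_history
  expect_equal(nrow(hist), 10)
  # reconstruction error decreases monotonically across epoch means
  expect_true(all(diff(hist$recon) <= 1e-6))
  expect_lte(hist$loss[10], hist$loss[1])
  expect_true(all(is.finite(hist$loss)))
  expect_true(all(hist$kl >= -1e-8))
})

test_that("training validates its inputs", {
  patches <- toy_patches(4, c(0.5, 0.5, 0.5), side = 16)
  expect_error(train_vae(patches, vae_config(patch_size = 16,
                                             batch_size = 32)),
               "batch_size")
  bad <- toy_patches(40, c(0.5, 0.5, 0.5), side = 16)
  bad[[1]][1, 1, 1] <- 2
  expect_error(train_vae(bad, vae_config(patch_size = 16, batch_size = 8,
                                         epochs = 1)),
               "\\[0, 1\\]")
})

test_that("encoding is deterministic with the contracted shape", {
  patches <- toy_patches(40, c(0.3, 0.6, 0.2), side = 16, noise = 0.05)
  cfg <- vae_config(latent_dim = 6, patch_size = 16, epochs = 3,
                    batch_size = 8, hidden_dim = 16, input_side = 8,
                    seed = 2)
  vae <- train_vae(patches, cfg)
  f1 <- encode_patches(vae, patches)
  f2 <- encode_patches(vae, patches)
  expect_identical(f1, f2)
  expect_equal(dim(f1), c(40, 6))
  expect_true(all(is.finite(f1)))
  # patch size mismatch is an argument error
  expect_error(encode_patches(vae, toy_patches(2, c(0.5, 0.5, 0.5),
                                               side = 32)),
               "patch_size")
})

test_that("visually distinct patch populations separate in feature space", {
  red <- toy_patches(48, c(0.9, 0.1, 0.1), side = 16, noise = 0.03,
                     seed = 1)
  gray <- toy_patches(48, c(0.5, 0.5, 0.5), side = 16, noise = 0.03,
                      seed = 2)
  cfg <- vae_config(latent_dim = 8, patch_size = 16, epochs = 10,
                    batch_size = 16, hidden_dim = 16, input_side = 8,
                    seed = 3)
  vae <- train_vae(c(red, gray), cfg)
  f <- encode_patches(vae, c(red, gray))
  is_red <- rep(c(TRUE, FALSE), each = 48)
  centroid_red <- colMeans(f[is_red, ])
  centroid_gray <- colMeans(f[!is_red, ])
  dist_to <- function(x, c) sqrt(rowSums((x - rep(c, each = nrow(x)))^2))
  inter <- mean(c(dist_to(f[is_red, ], centroid_gray),
                  dist_to(f[!is_red, ], centroid_red)))
  intra <- mean(c(dist_to(f[is_red, ], centroid_red),
                  dist_to(f[!is_red, ], centroid_gray)))
  expect_gt(inter, intra)
  # the rare population sits farther from the majority centroid than the
  # majority's own spread (the anomaly structure the workflow exploits)
  expect_gt(mean(dist_to(f[is_red, ], centroid_gray)),
            2 * mean(dist_to(f[!is_red, ], centroid_gray)))
})

test_that("planted fauna sit farther from the background centroid", {
  survey <- small_survey()
  patches <- dplyr::bind_rows(lapply(survey$scenes, function(sc) {
    extract_patches(sc$image, segment_image(sc$image),
                    parent_id = sc$scene_id)
  }))
  truth <- dplyr::bind_rows(lapply(survey$scenes, `[[`, "ground_truth"))
  is_fauna <- faunadetect:::label_flagged_by_truth(patches, truth)
  expect_gt(sum(is_fauna), 5)
  vae <- train_vae(patches, vae_config(latent_dim = 16, patch_size = 64,
                                       epochs = 8, hidden_dim = 64,
                                       seed = 1))
  f <- encode_patches(vae, patches)
  centroid <- colMeans(f[!is_fauna, ])
  d <- sqrt(rowSums((f - rep(centroid, each = nrow(f)))^2))
  expect_gt(mean(d[is_fauna]), mean(d[!is_fauna]))
})

test_that("2-D PCA projection reports exact variance on planar data", {
  set.seed(4)
  basis <- qr.Q(qr(matrix(rnorm(100 * 2), 100, 2)))
  coords <- matrix(rnorm(60 * 2, sd = c(3, 1)), 60, 2, byrow = TRUE)
  X <- coords %*% t(basis)
  p <- project_2d(X)
  expect_equal(sum(p$explained_variance), 1.0, tolerance = 1e-9)
  expect_gte(p$explained_variance[1], p$explained_variance[2])

  # duplicated rows project identically
  Xd <- X[rep(1:10, each = 2), ]
  pd <- project_2d(Xd)
  expect_equal(pd$scores$PC1[seq(1, 19, 2)], pd$scores$PC1[seq(2, 20, 2)])

  # isotropic cloud: components carry comparable variance
  set.seed(5)
  iso <- project_2d(matrix(rnorm(3000 * 3), 3000, 3))
  expect_lt(abs(iso$explained_variance[1] - iso$explained_variance[2]),
            0.1)

  expect_error(project_2d(X[1:2, ]), "3 rows")
  expect_error(project_2d(matrix(1, 5, 4)), "degenerate")
})
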