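# Aggregate segmentation: edge-amount loss, threshold semantics, UNet
# behaviour on degenerate inputs.

test_that("edge-amount loss matches hand arithmetic", {
  truth <- matrix(c(2L, 0L, 0L, 0L), 2, 2)     # true edge mean 0.25
  pred <- matrix(0.25, 2, 2)
  expect_equal(edge_amount_loss(pred, truth, 1), 0)
  # pred edge mean 0.10 vs true 0.05, lambda 1 -> 0.05
  t2 <- matrix(0L, 10, 10); t2[1:5, 1] <- 2L   # true mean 0.05
  p2 <- matrix(0.10, 10, 10)
  expect_equal(edge_amount_loss(p2, t2, 1), 0.05)
  # symmetry of |.|
  t3 <- matrix(0L, 10, 10); t3[1:10, 1] <- 2L  # true mean 0.10
  p3 <- matrix(0.05, 10, 10)
  expect_equal(edge_amount_loss(p3, t3, 1), 0.05)
  expect_equal(edge_amount_loss(p2, t2, 2.5), 0.125)
  expect_gte(edge_amount_loss(matrix(stats::runif(25), 5), t2[1:5, 1:5], 1), 0)
})

test_that("with lambda = 0 the tile loss is exactly weighted cross-entropy", {
  set.seed(8)
  logits <- array(stats::rnorm(8 * 8 * 3), c(8, 8, 3))
  y <- matrix(sample(0:2, 64, TRUE), 8, 8)
  w <- c(0.4, 12, 30)
  lo <- tauwm:::agg_tile_loss(logits, y, w, 0)
  p <- tauwm:::softmax_rows(matrix(logits, 64, 3))
  yv <- as.integer(y) + 1L
  ce <- -log(p[cbind(1:64, yv)])
  expect_equal(lo$loss, sum(w[yv] * ce) / sum(w[yv]), tolerance = 1e-12)
})

test_that("response thresholding only moves pixels toward background", {
  set.seed(9)
  resp <- array(stats::runif(16 * 16 * 3), c(16, 16, 3))
  for (ch in 1:3) resp[, , ch] <- resp[, , ch] /
    (resp[, , 1] + resp[, , 2] + resp[, , 3])
  counts <- vapply(c(0.2, 0.4, 0.5, 0.7, 0.9), function(th)
    sum(tauwm:::threshold_responses(resp, th) != 0L), numeric(1))
  expect_true(all(diff(counts) <= 0))
  # uniform low-confidence responses go to background entirely
  flat <- array(rep(c(0.34, 0.33, 0.33), each = 25), c(5, 5, 3))
  expect_true(all(tauwm:::threshold_responses(flat, 0.5) == 0L))
  # legal labels only
  expect_true(all(tauwm:::threshold_responses(resp, 0.5) %in% 0:2))
})

test_that("all-background tiles train to predict background", {
  set.seed(10)
  tiles <- lapply(1:6, function(i)
    list(x = array(stats::runif(32 * 32 * 3, 0.75, 0.95), c(32, 32, 3)),
         y = matrix(0L, 32, 32)))
  cfg <- aggregate_train_config("test", epochs = 2L, base_width = 4L,
                                n_folds = 1L, augment = FALSE)
  expect_warning(m <- tauwm:::train_unet_once(tiles, cfg), "absent")
  pred <- predict_aggregate_mask(m, tiles[[1]]$x, tile_px = 32L)
  expect_true(all(pred == 0L))
})

test_that("training loss trajectory is reproducible for a fixed seed", {
  g <- small_slide()
  set.seed(3)
  tiles <- sample_aggregate_tiles(g$slide, g$truth$pixel_mask, 48L, 6L)
  cfg <- aggregate_train_config("test", epochs = 2L, base_width = 4L,
                                n_folds = 1L, seed = 21L)
  m1 <- train_aggregate_model(tiles, cfg)
  m2 <- train_aggregate_model(tiles, cfg)
  expect_equal(m1$history, m2$history, tolerance = 1e-12)
  expect_true(all(m1$history >= 0))
})
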