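# Region model: splits, patch extraction, consensus, post-processing.

test_that("geometry identities: microns to pixels", {
  expect_identical(region_train_config("full")$patch_px, 256L)
  expect_identical(mil_config("full")$patch_px, 224L)
  expect_identical(region_train_config("full", patch_um = 64)$patch_px, 128L)
})

test_that("cross-validation split balances diseases across folds", {
  dis <- rep(c("AD", "PSP", "CBD"), each = 2)
  f <- crossval_split(dis, 3L, seed = 1)
  tab <- table(dis, f)
  expect_true(all(apply(tab, 1, function(r) max(r) - min(r) <= 1)))
  # 7 slides of one disease over 3 folds -> sizes {3, 2, 2}
  f7 <- crossval_split(rep("AD", 7), 3L, seed = 2)
  expect_setequal(as.integer(table(f7)), c(3L, 2L, 2L))
  expect_identical(crossval_split(dis, 3L, seed = 9),
                   crossval_split(dis, 3L, seed = 9))
  expect_error(crossval_split(c("AD", "PSP"), 3L), "fewer")
})

test_that("extracted patch labels agree with centre-pixel lookup", {
  g <- small_slide()
  cfg <- region_train_config("test")
  set.seed(2)
  ex <- extract_region_patches(g$slide, g$truth$region_mask, cfg, n = 120L)
  expect_identical(ex$labels, g$truth$region_mask[ex$centers] + 1L)
  expect_true(all(vapply(ex$patches, function(p)
    all(dim(p) == c(cfg$patch_px, cfg$patch_px, 3)), logical(1))))
  # requesting zero patches yields an empty set
  e0 <- extract_region_patches(g$slide, g$truth$region_mask, cfg, n = 0L)
  expect_length(e0$patches, 0)
  tiny <- g$slide; tiny$pixels <- tiny$pixels[1:64, 1:64, , drop = FALSE]
  expect_error(extract_region_patches(tiny, g$truth$region_mask[1:64, 1:64], cfg),
               "smaller")
})

test_that("average-then-argmax consensus matches hand arithmetic", {
  r1 <- array(c(0.40, 0.35, 0.25), c(1, 1, 3))
  r2 <- array(c(0.40, 0.35, 0.25), c(1, 1, 3))
  r3 <- array(c(0.10, 0.80, 0.10), c(1, 1, 3))
  # average (0.30, 0.50, 0.20) -> CTX although two models favour class 0
  expect_identical(consensus_argmax(list(r1, r2, r3))[1, 1], 1L)
  # identical models: consensus equals single-model argmax
  expect_identical(consensus_argmax(list(r1, r1, r1)),
                   consensus_argmax(list(r1)))
  # tie-break toward the lowest class index
  t1 <- array(c(0.4, 0.4, 0.2), c(1, 1, 3))
  expect_identical(consensus_argmax(list(t1))[1, 1], 0L)
  expect_error(consensus_argmax(list(r1, array(0, c(2, 2, 3)))), "differ")
})

test_that("average-then-argmax equals majority vote when models agree", {
  set.seed(3)
  for (t in 1:50) {
    win <- sample(0:2, 1)
    mk <- function() {
      v <- stats::runif(3); v[win + 1] <- max(v) + stats::runif(1, 0.05, 0.5)
      array(v / sum(v), c(1, 1, 3))
    }
    rs <- list(mk(), mk(), mk())
    votes <- vapply(rs, function(r) which.max(r[1, 1, ]) - 1L, integer(1))
    expect_identical(consensus_argmax(rs)[1, 1],
                     as.integer(names(which.max(table(votes)))))
  }
})

test_that("post-processing removes small islands and fills small holes", {
  m <- matrix(1L, 100, 100)          # all cortex
  m[10:40, 10:41] <- 2L              # 31x32 = 992-px WM island -> removed
  out <- postprocess_region_mask(m, 1000L)
  expect_true(all(out == 1L))
  m2 <- matrix(1L, 100, 100)
  m2[10:49, 10:34] <- 2L             # 40x25 = 1000 px -> retained
  out2 <- postprocess_region_mask(m2, 1000L)
  expect_identical(out2, m2)
  # 500-px background hole inside WM is filled with WM; flood-fill oracle
  m3 <- matrix(2L, 80, 80)
  m3[30:49, 30:54] <- 0L             # 20x25 = 500-px hole
  out3 <- postprocess_region_mask(m3, 1000L)
  expect_true(all(out3 == 2L))
  oracle <- flood_fill_label(matrix(as.integer(m3 == 0L), 80), 8L)
  expect_identical(sum(oracle > 0), 500L)   # the hole the rule must fill
  # idempotence
  g <- small_slide()
  once <- postprocess_region_mask(g$truth$region_mask, 1000L)
  expect_identical(postprocess_region_mask(once, 1000L), once)
  # never creates a new label
  expect_true(all(unique(as.integer(once)) %in% 0:2))
})

test_that("single-class training is rejected unless weights are forced", {
  cfg <- region_train_config("test", epochs = 1L, augment = FALSE)
  set.seed(1)
  px <- lapply(1:6, function(i) array(stats::runif(128 * 128 * 3),
                                      c(128, 128, 3)))
  expect_error(train_region_model(px, rep(2L, 6), cfg), "single class")
  cfg2 <- region_train_config("test", epochs = 10L, lr = 0.05,
                              augment = FALSE, class_weights = c(1, 1, 1),
                              widths = c(4L, 8L), batch_size = 2L)
  m <- train_region_model(px[1:4], rep(2L, 4), cfg2)
  expect_gte(mean(predict_region_patches(m, px[1:4]) == 2L), 0.99)
})

test_that("region training is reproducible for a fixed seed", {
  set.seed(4)
  px <- lapply(1:8, function(i) {
    cl <- (i - 1) %% 2
    array(stats::runif(64 * 64 * 3, cl * 0.4, cl * 0.4 + 0.3), c(64, 64, 3))
  })
  lb <- rep(1:2, 4)
  cfg <- region_train_config("test", epochs = 2L, widths = c(4L, 8L),
                             augment = FALSE, patch_um = 32, seed = 11L)
  m1 <- train_region_model(px, lb, cfg)
  m2 <- train_region_model(px, lb, cfg)
  expect_equal(m1$history, m2$history, tolerance = 1e-12)
})
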