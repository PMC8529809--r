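# Artifact QC: texture features, embedding check, random-forest filter.

test_that("co-occurrence texture statistics match direct oracles", {
  # constant-intensity object: contrast 0, energy 1
  g <- matrix(3L, 8, 8)
  s <- tauwm:::glcm_stats_cpp(g, 8L)
  expect_equal(s[1], 0)
  expect_equal(s[3], 1)
  # checkerboard at 2 levels: horizontal/vertical pairs all differ ->
  # contrast strictly greater than the constant patch's
  cb <- outer(1:8, 1:8, function(i, j) (i + j) %% 2L)
  storage.mode(cb) <- "integer" 
  s2 <- tauwm:::glcm_stats_cpp(cb, 2L)
  expect_gt(s2[1], s[1])
  # direct oracle for the horizontal offset of the checkerboard:
  # every horizontal neighbour pair is (0,1) or (1,0) -> contrast 1
  horiz <- table(cb[, -8], cb[, -1])
  p01 <- (horiz["0", "1"] + horiz["1", "0"]) / sum(horiz)
  expect_equal(p01, 1)
  # repeated call is identical
  expect_identical(tauwm:::glcm_stats_cpp(cb, 2L), tauwm:::glcm_stats_cpp(cb, 2L))
})

test_that("texture features distinguish artifacts on a rendered slide", {
  g <- small_slide()
  inst <- label_aggregates(g$truth$pixel_mask, 30L, g$truth$region_mask, "s")
  tex <- compute_texture_features(inst[[1]], g$slide$pixels)
  expect_named(tex, tauwm:::TEXTURE_NAMES)
  expect_identical(tex, compute_texture_features(inst[[1]], g$slide$pixels))
  # single-pixel instance: zeros plus the degenerate flag
  tex1 <- compute_texture_features(list(pixels = cbind(5L, 5L)),
                                   g$slide$pixels)
  expect_true(all(tex1 == 0))
  expect_true(attr(tex1, "degenerate"))
})

test_that("artifact filter separates constructed classes and partitions input", {
  set.seed(17)
  n <- 300
  X <- rbind(matrix(stats::rnorm(n * 4, 0), n, 4),
             matrix(stats::rnorm(n * 4, 10), n, 4))   # 10 sigma apart
  y <- rep(c(FALSE, TRUE), each = n)
  colnames(X) <- c("a", "b", "c", "d")
  filt <- train_artifact_filter(X, y, qc_config(rf_trees = 50L))
  expect_gte(filt$holdout_accuracy, 0.95)
  df <- as.data.frame(X)
  df$id <- seq_len(nrow(df))
  res <- filter_artifacts(df, filt)
  expect_identical(sort(c(res$kept$id, res$flagged$id)), df$id)
  expect_identical(intersect(res$kept$id, res$flagged$id), integer(0))
  expect_gte(mean(res$table$is_artifact == y), 0.95)
  expect_error(train_artifact_filter(X, rep(TRUE, nrow(X)), qc_config()),
               "both")
})

test_that("embedding check reports separation and is reproducible", {
  set.seed(18)
  n <- 40
  X <- rbind(matrix(stats::rnorm(n * 6, 0), n, 6),
             matrix(stats::rnorm(n * 6, 10), n, 6))
  y <- rep(c(FALSE, TRUE), each = n)
  out <- qc_embedding_check(X, y, qc_config(seed = 5L))
  expect_identical(nrow(out$embedding), nrow(X))
  expect_gt(out$silhouette, 0.5)
  out2 <- qc_embedding_check(X, y, qc_config(seed = 5L))
  expect_equal(out$embedding, out2$embedding, tolerance = 1e-8)
  expect_error(qc_embedding_check(X, rep(TRUE, nrow(X)), qc_config()), "both")
  expect_error(qc_embedding_check(X[1:10, ], y[1:10], qc_config()), "50")
})

test_that("QC filtering moves medians at most by the removed-rank span", {
  # removing a fraction q of objects can move the median no further than
  # the (0.5 - q, 0.5 + q) quantile span of the unfiltered distribution;
  # profiles with and without QC must also differ only through removed rows
  g <- small_slide()
  tb <- qc_feature_table(g$slide, g$truth$pixel_mask, g$truth$region_mask,
                         truth = g$truth)
  q <- mean(tb$true_artifact)
  expect_lt(q, 0.15)
  for (f in FEATURE_NAMES) {
    v <- tb[[f]]
    med0 <- stats::median(v)
    med1 <- stats::median(v[!tb$true_artifact])
    span <- stats::quantile(v, c(max(0, 0.5 - q), min(1, 0.5 + q)))
    expect_gte(med1, span[[1]] - 1e-9)
    expect_lte(med1, span[[2]] + 1e-9)
  }
  kept <- tb[!tb$true_artifact, ]
  expect_identical(nrow(kept) + sum(tb$true_artifact), nrow(tb))
})
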