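# MIL: bagging, pooling invariances, vote combination.

rand_patch <- function(side = 32L) array(stats::runif(side * side * 3),
                                         c(side, side, 3))

tiny_mil <- function() cached("tiny_mil_model", {
  set.seed(12)
  tauwm:::mil_model_new(mil_config("test", widths = c(4L, 8L),
                                   strides = c(2L, 2L), embedding_dim = 16L,
                                   pool_stem = 1L))
})

test_that("make_bags partitions patches and propagates labels", {
  set.seed(11)
  ps <- lapply(1:64, function(i) rand_patch())
  bags <- make_bags(ps, "PSP", bag_size = 32L, slide_id = "s1")
  expect_length(bags, 2)
  expect_true(all(vapply(bags, function(b) b$label == "PSP", logical(1))))
  expect_identical(sum(vapply(bags, function(b) length(b$patches), 0L)), 64L)
  # fewer patches than bag size -> one smaller bag
  b2 <- make_bags(ps[1:5], "AD", bag_size = 32L)
  expect_length(b2, 1)
  expect_length(b2[[1]]$patches, 5)
  # reproducible membership under a fixed seed
  set.seed(42); ba <- make_bags(ps, "AD", 16L)
  set.seed(42); bb <- make_bags(ps, "AD", 16L)
  expect_identical(lapply(ba, function(b) b$patches),
                   lapply(bb, function(b) b$patches))
})

test_that("bag score is the permutation-invariant mean of instance scores", {
  m <- tiny_mil()
  ps <- lapply(1:5, function(i) rand_patch())
  scores <- t(vapply(ps, function(p) predict_patch(m, p)$scores, numeric(3)))
  bag_fwd <- function(px) colMeans(t(vapply(px, function(p)
    predict_patch(m, p)$scores, numeric(3))))
  expect_equal(bag_fwd(ps), bag_fwd(rev(ps)), tolerance = 1e-12)
  # bag of identical patches: bag score equals the instance score
  expect_equal(bag_fwd(ps[c(1, 1, 1)]), scores[1, ], tolerance = 1e-12)
})

test_that("slide prediction is the modal patch class", {
  m <- tiny_mil()
  p <- rand_patch()
  cls <- predict_patch(m, p)$class
  out <- predict_slide(m, list(p, p, p))
  expect_identical(out$class, cls)
  expect_identical(unname(out$votes[cls]), 3L)
  expect_equal(sum(out$fractions), 1)
})

test_that("combining region vote fractions follows the tie rules", {
  f <- function(v) stats::setNames(v, DISEASES)
  expect_identical(combine_region_predictions(f(c(0.7, 0.2, 0.1)),
                                              f(c(0.6, 0.3, 0.1))), "AD")
  # hand case: average (0.4, 0.4, 0.2); ctx 0.6 beats wm 0.5 -> class 1 (AD)
  expect_identical(combine_region_predictions(f(c(0.6, 0.3, 0.1)),
                                              f(c(0.2, 0.5, 0.3))), "AD")
  # one uniform vector: result is the other's argmax
  expect_identical(combine_region_predictions(f(rep(1 / 3, 3)),
                                              f(c(0.1, 0.2, 0.7))), "CBD")
  # full tie everywhere -> lowest index
  expect_identical(combine_region_predictions(f(rep(1 / 3, 3)),
                                              f(rep(1 / 3, 3))), "AD")
})

test_that("class-weighted bag loss with equal counts equals unweighted", {
  set.seed(13)
  ps <- lapply(1:6, function(i) rand_patch())
  bags <- c(make_bags(ps[1:2], "AD", 2L), make_bags(ps[3:4], "PSP", 2L),
            make_bags(ps[5:6], "CBD", 2L))
  cfg_w <- mil_config("test", widths = c(4L, 8L), strides = c(2L, 2L),
                      embedding_dim = 8L, pool_stem = 1L, epochs = 1L,
                      cutout = FALSE, seed = 31L)
  cfg_u <- cfg_w; cfg_u$class_weights <- c(1, 1, 1)
  m_w <- train_mil(bags, cfg_w)
  m_u <- train_mil(bags, cfg_u)
  expect_equal(m_w$history, m_u$history, tolerance = 1e-12)
})

test_that("single-disease training data is rejected", {
  ps <- lapply(1:4, function(i) rand_patch())
  bags <- make_bags(ps, "AD", 2L)
  expect_error(train_mil(bags, mil_config("test")), "two diseases")
})
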