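# Burden arithmetic, line fits, profiles, clustering, Mann-Whitney.

test_that("burden is a pixel fraction with edge pixels excluded", {
  rm <- matrix(1L, 10, 10)
  pm <- matrix(0L, 10, 10)
  pm[1, 1:7] <- 1L
  pm[2, 1:5] <- 2L                      # edge pixels do not count
  expect_equal(compute_burden(rm, pm, "CTX"), 0.07)
  expect_equal(compute_burden(rm, matrix(0L, 10, 10), "CTX"), 0)
  expect_equal(compute_burden(rm, matrix(1L, 10, 10), "CTX"), 1)
  expect_error(compute_burden(rm, pm, "WM"), "empty")
  # monotone when aggregate pixels are added
  pm2 <- pm; pm2[5, 1:3] <- 1L
  expect_gt(compute_burden(rm, pm2, "CTX"), compute_burden(rm, pm, "CTX"))
})

test_that("least-squares burden line matches closed forms", {
  r <- data.frame(ctx_burden = c(0, 1, 2), wm_burden = c(0, 1, 4))
  f <- fit_burden_line(r)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, -1 / 3, tolerance = 1e-12)
  expect_identical(f$n_slides, 3L)
  # exactly collinear points return the exact slope and intercept
  r2 <- data.frame(ctx_burden = c(1, 2, 3, 4), wm_burden = 0.4 * c(1, 2, 3, 4) + 0.1)
  f2 <- fit_burden_line(r2)
  expect_equal(f2$slope, 0.4, tolerance = 1e-12)
  expect_equal(f2$intercept, 0.1, tolerance = 1e-12)
  f3 <- fit_burden_line(r2, intercept = FALSE)
  expect_equal(f3$intercept, 0)
  expect_error(fit_burden_line(data.frame(ctx_burden = c(1, 1),
                                          wm_burden = c(1, 2))), "identical")
})

test_that("slide profiles are medians with the documented invariances", {
  ft <- data.frame(slide_id = "s", area = c(1, 2, 9), major_axis_length = 1:3,
                   minor_axis_length = 1:3, length = c(2, 4, 8),
                   width = 1:3, extent = c(0.2, 0.5, 0.9),
                   eccentricity = c(0.1, 0.6, 0.9), curvature = c(0, 1, 3),
                   solidity = c(0.5, 0.8, 1))
  p <- slide_profile(ft, "AD")
  expect_equal(unname(p$median_features["area"]), 2)
  expect_equal(unname(p$median_features["length"]), 4)
  expect_identical(p$n_aggregates, 3L)
  # single aggregate: profile equals its features
  p1 <- slide_profile(ft[2, ], "AD")
  expect_equal(unname(p1$median_features), unname(unlist(ft[2, FEATURE_NAMES])))
  # duplicating every instance leaves the profile unchanged
  p2 <- slide_profile(rbind(ft, ft), "AD")
  expect_equal(p2$median_features, p$median_features)
  expect_warning(expect_null(slide_profile(ft[0, ], "AD")), "excluded")
})

test_that("profile clustering uses correlation distance and average linkage", {
  set.seed(14)
  base <- matrix(stats::rnorm(5 * 9), 5, 9,
                 dimnames = list(paste0("s", 1:5), FEATURE_NAMES))
  # the metric: an affine transform of a profile is at correlation
  # distance zero
  x <- base[1, ]
  expect_equal(1 - stats::cor(x, 2.5 * x + 7), 0, tolerance = 1e-12)
  # two identical profiles merge first
  prof <- rbind(base, s6 = base[1, ])
  hc <- cluster_profiles(prof)
  first <- sort(abs(hc$merge[1, ]))
  expect_identical(rownames(prof)[first], c("s1", "s6"))
  # three separated groups cluster purely at k = 3
  centers <- matrix(stats::rnorm(3 * 9, sd = 1), 3, 9)
  prof3 <- do.call(rbind, lapply(1:3, function(g)
    matrix(rep(centers[g, ], 6), 6, byrow = TRUE) +
      matrix(stats::rnorm(6 * 9, sd = 0.02), 6)))
  rownames(prof3) <- paste0("p", 1:18)
  colnames(prof3) <- FEATURE_NAMES
  ct <- stats::cutree(cluster_profiles(prof3), k = 3)
  truth <- rep(1:3, each = 6)
  purity <- mean(vapply(split(ct, truth), function(v)
    max(table(v)) / length(v), numeric(1)))
  expect_equal(purity, 1.0)
  # zero-variance feature dropped with a warning
  prof0 <- prof3; prof0[, 2] <- 5
  expect_warning(cluster_profiles(prof0), "zero-variance")
  # deterministic leaf order
  expect_identical(cluster_profiles(prof3)$order, cluster_profiles(prof3)$order)
  expect_error(cluster_profiles(prof3[1:2, ]), "three")
})

test_that("Mann-Whitney comparisons match exact enumeration and Bonferroni", {
  vals <- list(AD = c(1, 2, 3), PSP = c(4, 5, 6), CBD = c(1.5, 2.5, 3.5))
  out <- compare_feature_across_diseases(vals)
  expect_identical(nrow(out), 3L)
  row <- out[out$group1 == "AD" & out$group2 == "PSP", ]
  expect_equal(row$U, 0)
  expect_equal(row$p_raw, 0.1)
  expect_equal(row$p_raw, mw_exact_p(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(row$p_corrected, 0.3)
  expect_false(row$significant)
  # identical groups -> corrected p = 1, not significant
  same <- list(a = c(1, 5, 9, 12), b = c(1, 5, 9, 12), c = c(2, 4, 8, 16))
  out2 <- compare_feature_across_diseases(same)
  r2 <- out2[out2$group1 == "a" & out2$group2 == "b", ]
  expect_equal(r2$p_corrected, 1)
  expect_false(r2$significant)
  # corrected p is capped at 1
  expect_true(all(out2$p_corrected <= 1))
  expect_error(compare_feature_across_diseases(list(a = 1:3, b = numeric(0))),
               "empty")
  # large groups switch to the normal approximation without error
  set.seed(15)
  big <- list(a = stats::rnorm(30), b = stats::rnorm(30, 2), c = stats::rnorm(30))
  out3 <- compare_feature_across_diseases(big)
  expect_true(out3$significant[out3$group1 == "a" & out3$group2 == "b"])
})

test_that("OLS slope recovery is unbiased over repeated synthetic fits", {
  set.seed(16)
  slopes <- replicate(50, {
    x <- stats::runif(12, 0.01, 0.05)
    y <- 1 / 3 * x * stats::rlnorm(12, 0, 0.15)
    fit_burden_line(data.frame(ctx_burden = x, wm_burden = y))$slope
  })
  mc_se <- stats::sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 1 / 3), 2 * mc_se + 0.01)
})
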