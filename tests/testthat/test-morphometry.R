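# Instance extraction and the nine morphometric features.

test_that("aggregate labelling follows the separator and area rules", {
  m <- matrix(0L, 20, 20)
  m[5:8, 3:8] <- 1L        # blob A (24 px)
  m[5:8, 10:15] <- 1L      # blob B (24 px)
  m[5:8, 9] <- 2L          # 1-px edge line separating them
  inst <- label_aggregates(m, min_area_px = 10L)
  expect_length(inst, 2)
  # edge pixels are never members
  all_px <- do.call(rbind, lapply(inst, `[[`, "pixels"))
  expect_true(all(m[all_px + 1L] == 1L))
  # 29-px object removed, 30-px retained
  m2 <- matrix(0L, 30, 30)
  m2[2:6, 2:7] <- 1L                       # 5 x 6 = 30 px
  m2[20:24, 20:25] <- 1L; m2[24, 25] <- 0L # 29 px
  inst2 <- label_aggregates(m2, min_area_px = 30L)
  expect_length(inst2, 1)
  expect_identical(inst2[[1]]$n_px, 30L)
})

test_that("connected components match a flood-fill oracle on random masks", {
  set.seed(77)
  for (t in 1:100) {
    m <- matrix(as.integer(stats::runif(64 * 64) < 0.35), 64, 64)
    ours <- tauwm:::cc_label_cpp(m, 8L)
    oracle <- flood_fill_label(m, 8L)
    expect_true(same_partition(ours, oracle))
  }
})

test_that("features of a solid square match closed forms", {
  px <- as.matrix(expand.grid(row = 0:9, col = 0:9))
  f <- compute_features(list(pixels = px), mpp = 0.5)
  expect_length(f, 9)
  expect_named(f, FEATURE_NAMES)
  expect_equal(f[["area"]], 25)       # 100 px * 0.25 um^2
  expect_equal(f[["extent"]], 1)
  expect_equal(f[["solidity"]], 1)
  expect_lt(f[["eccentricity"]], 0.05)
})

test_that("ellipse eccentricity matches the moment closed form", {
  m <- raster_ellipse(40, 10)
  px <- which(m == 1L, arr.ind = TRUE) - 1L
  f <- compute_features(list(pixels = px), mpp = 1)
  expect_lt(abs(f[["eccentricity"]] - sqrt(1 - (10 / 40)^2)), 0.02)
  expect_lt(abs(f[["major_axis_length"]] - 80) / 80, 0.05)
  expect_lt(abs(f[["minor_axis_length"]] - 20) / 20, 0.05)
})

test_that("bar vs arc: curvature and skeleton length behave analytically", {
  mpp <- 0.5
  # straight bar, 3 px wide, 60 px long
  bar <- matrix(0L, 20, 70)
  bar[9:11, 5:64] <- 1L
  fb <- compute_features(list(pixels = which(bar == 1L, arr.ind = TRUE) - 1L),
                         mpp = mpp)
  # semicircular arc with the same skeleton length: r = L / pi
  L_px <- 59
  r <- L_px / pi
  th <- seq(0, pi, length.out = 400)
  ci <- round(30 + r * sin(th)); cj <- round(40 + r * cos(th))
  arc <- matrix(0L, 60, 80)
  for (t in seq_along(ci))
    arc[(ci[t] - 1):(ci[t] + 1), (cj[t] - 1):(cj[t] + 1)] <- 1L
  fa <- compute_features(list(pixels = which(arc == 1L, arr.ind = TRUE) - 1L),
                         mpp = mpp)
  expect_lt(fb[["curvature"]], 0.01)
  expect_gt(fa[["curvature"]], fb[["curvature"]])
  # curvature of a semicircle is 1/r (in um): r_um = r * mpp
  expect_lt(abs(fa[["curvature"]] - 1 / (r * mpp)) / (1 / (r * mpp)), 0.35)
  expect_lt(abs(fa[["length"]] - fb[["length"]]) / fb[["length"]], 0.1)
  expect_equal(fb[["width"]], 3 * mpp)
})

test_that("rotations and flips leave invariant features unchanged", {
  set.seed(5)
  sh <- sample_aggregate_shape("CBD", mpp = 0.5)
  px <- which(sh$mask == 1L, arr.ind = TRUE) - 1L
  f0 <- compute_features(list(pixels = px), mpp = 0.5)
  rot90 <- cbind(px[, 2], max(px[, 1]) - px[, 1])
  flip <- cbind(max(px[, 1]) - px[, 1], px[, 2])
  for (p2 in list(rot90, flip)) {
    f2 <- compute_features(list(pixels = p2), mpp = 0.5)
    for (nm in c("area", "solidity", "eccentricity", "extent"))
      expect_equal(f2[[nm]], f0[[nm]], tolerance = 1e-12)
    for (nm in c("length", "width", "curvature"))
      expect_lt(abs(f2[[nm]] - f0[[nm]]) / max(f0[[nm]], 0.02), 0.05)
  }
})

test_that("features scale correctly with mpp", {
  set.seed(6)
  sh <- sample_aggregate_shape("PSP", mpp = 0.5)
  px <- which(sh$mask == 1L, arr.ind = TRUE) - 1L
  f1 <- compute_features(list(pixels = px), mpp = 0.5)
  f2 <- compute_features(list(pixels = px), mpp = 1.0)
  expect_equal(f2[["area"]], 4 * f1[["area"]])
  for (nm in c("major_axis_length", "minor_axis_length", "length", "width"))
    expect_equal(f2[[nm]], 2 * f1[[nm]])
  for (nm in c("extent", "eccentricity", "solidity"))
    expect_equal(f2[[nm]], f1[[nm]])
  expect_equal(f2[["curvature"]], f1[["curvature"]] / 2)
})

test_that("single-pixel and degenerate instances fall back sanely", {
  f <- compute_features(list(pixels = cbind(5L, 5L)), mpp = 0.5)
  expect_equal(f[["curvature"]], 0)
  expect_gt(f[["area"]], 0)
  expect_lt(f[["eccentricity"]], 1)
  expect_error(compute_features(list(pixels = cbind(integer(0), integer(0))),
                                mpp = 0.5), "empty")
})

test_that("feature invariant ranges hold on a generated slide", {
  g <- small_slide()
  ft <- aggregate_features(g$truth$pixel_mask, g$truth$region_mask,
                           mpp = 0.5, slide_id = "s")
  expect_true(all(ft$area > 0))
  expect_true(all(ft$eccentricity >= 0 & ft$eccentricity < 1))
  expect_true(all(ft$solidity > 0 & ft$solidity <= 1))
  expect_true(all(ft$extent > 0 & ft$extent <= 1))
  expect_true(all(ft$minor_axis_length <= ft$major_axis_length + 1e-9))
  expect_true(all(ft$n_px >= 30))
  expect_true(all(ft$region %in% c("CTX", "WM")))
})

test_that("disease ordering emerges in slide-level medians", {
  coh <- cached("artifact_cohort", {
    generate_cohort(rep(DISEASES, each = 3), seeds = 300 + 1:9,
                    slide_size = c(640L, 640L))
  })
  med <- lapply(DISEASES, function(d) {
    rows <- do.call(rbind, lapply(which(rep(DISEASES, each = 3) == d),
      function(i) aggregate_features(coh[[i]]$truth$pixel_mask,
                                     coh[[i]]$truth$region_mask, 0.5, 30L,
                                     paste0("s", i))))
    vapply(FEATURE_NAMES, function(f) stats::median(rows[[f]]), numeric(1))
  })
  names(med) <- DISEASES
  expect_gt(med$CBD[["area"]], med$PSP[["area"]])
  expect_gt(med$CBD[["area"]], med$AD[["area"]])
  expect_gt(med$PSP[["eccentricity"]], med$AD[["eccentricity"]])
  expect_gt(med$PSP[["eccentricity"]], med$CBD[["eccentricity"]])
  expect_gt(med$AD[["curvature"]], med$PSP[["curvature"]])
})
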