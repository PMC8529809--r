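# Synthetic slide generator: spec validation, burden geometry, shapes,
# artifacts, rendering.

test_that("spec invariants are enforced", {
  expect_error(synthetic_spec("AD", burden_slope = 0))
  expect_error(synthetic_spec("AD", burden_slope = 1.5))
  expect_error(synthetic_spec("AD", artifact_rate = 0.6))
  expect_error(synthetic_spec("AD", mpp = -1))
  sp <- synthetic_spec("PSP")
  sp$shape_params$thickness_um <- 0
  expect_error(tauwm:::validate_spec(sp), "thickness")
  expect_error(generate_slide(synthetic_spec("AD", slide_size = c(400L, 400L))),
               "too small")
})

test_that("zero burden range yields an empty slide", {
  g <- generate_slide(synthetic_spec("AD", slide_size = c(512L, 512L),
                                     ctx_burden_range = c(0, 0)), seed = 1L)
  expect_identical(max(g$truth$instance_map), 0L)
  expect_equal(compute_burden(g$truth$region_mask, g$truth$pixel_mask, "CTX"), 0)
  expect_equal(compute_burden(g$truth$region_mask, g$truth$pixel_mask, "WM"), 0)
})

test_that("generation is bit-identical for a fixed (spec, seed)", {
  spec <- synthetic_spec("PSP", slide_size = c(512L, 512L))
  a <- generate_slide(spec, seed = 7L)
  b <- generate_slide(spec, seed = 7L)
  expect_identical(a$slide$pixels, b$slide$pixels)
  expect_identical(a$truth$instance_map, b$truth$instance_map)
  expect_identical(a$truth$artifact_ids, b$truth$artifact_ids)
})

test_that("ground-truth structure invariants hold", {
  g <- small_slide()
  tr <- g$truth
  # instance pixels are exactly the aggregate-class pixels
  expect_true(all(tr$pixel_mask[tr$instance_map > 0L] == 1L))
  expect_true(all(tr$instance_map[tr$pixel_mask == 1L] > 0L))
  expect_true(all(tr$artifact_ids %in% tr$instance_map))
  expect_setequal(unique(as.integer(tr$region_mask)), 0:2)
  # every instance is a single 8-connected component
  ids <- setdiff(unique(as.integer(tr$instance_map)), 0L)
  for (id in sample(ids, min(10, length(ids)))) {
    m <- matrix(as.integer(tr$instance_map == id), nrow(tr$instance_map))
    expect_identical(max(tauwm:::cc_label_cpp(m, 8L)), 1L)
  }
})

test_that("disease shape distributions order as described", {
  set.seed(42)
  feat_of <- function(disease, n = 300) {
    t(replicate(n, {
      sh <- sample_aggregate_shape(disease, mpp = 0.5)
      px <- which(sh$mask == 1L, arr.ind = TRUE) - 1L
      f <- compute_features(list(pixels = px), mpp = 0.5)
      c(area = f[["area"]], ecc = f[["eccentricity"]])
    }))
  }
  ad <- feat_of("AD"); psp <- feat_of("PSP"); cbd <- feat_of("CBD")
  # PSP long/thin/straight: higher moment eccentricity than CBD blobs
  expect_gt(mean(psp[, "ecc"]), mean(cbd[, "ecc"]))
  # CBD large blobs: larger pixel area than AD curls
  expect_gt(mean(cbd[, "area"]), mean(ad[, "area"]))
})

test_that("degenerate and minimal shapes behave", {
  sp <- tauwm:::default_shape_params("AD")
  sp$thickness_um <- 0
  expect_error(sample_aggregate_shape("AD", sp), "degenerate")
  set.seed(1)
  sp2 <- tauwm:::default_shape_params("AD")
  sp2$length_meanlog <- log(0.5); sp2$length_sdlog <- 0.01
  sp2$thickness_um <- 0.5
  sh <- sample_aggregate_shape("AD", sp2)
  expect_gte(sum(sh$mask), 1)
  expect_identical(max(tauwm:::cc_label_cpp(sh$mask, 8L)), 1L)
})

test_that("artifact injection hits its rate and size contract", {
  # pool objects across a cached cohort of all three diseases
  coh <- cached("artifact_cohort", {
    generate_cohort(rep(DISEASES, each = 3), seeds = 300 + 1:9,
                    slide_size = c(640L, 640L))
  })
  meta <- do.call(rbind, lapply(coh, function(g) g$truth$meta))
  n <- nrow(meta)
  expect_gt(n, 500)
  frac <- mean(meta$is_artifact)
  p <- 0.04
  tol <- 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(frac - p), tol)
  # artifacts are smaller (equivalent diameter) than true aggregates over
  # the PSP/CBD worlds (pooled; PSP curves alone are equally slender)
  eqd <- 2 * sqrt(meta$n_px / pi)
  dis <- rep(rep(DISEASES, each = 3), vapply(coh, function(g)
    nrow(g$truth$meta), 0L))
  pc <- dis %in% c("PSP", "CBD")
  expect_lt(mean(eqd[meta$is_artifact & pc]), mean(eqd[!meta$is_artifact & pc]))
  expect_lt(mean(eqd[meta$is_artifact & dis == "CBD"]),
            mean(eqd[!meta$is_artifact & dis == "CBD"]))
  # zero rate -> no artifacts
  g0 <- generate_slide(synthetic_spec("CBD", slide_size = c(512L, 512L),
                                      artifact_rate = 0), seed = 2L)
  expect_length(g0$truth$artifact_ids, 0)
})

test_that("cohort burden ratio recovers the disease slope (CBD = 3/4)", {
  coh <- cached("cbd_ratio_cohort", {
    generate_cohort(rep("CBD", 20), seeds = 400 + 1:20,
                    slide_size = c(512L, 512L))
  })
  ratio <- vapply(coh, function(g) {
    tr <- g$truth
    wm <- sum(tr$pixel_mask == 1L & tr$region_mask == 2L) / sum(tr$region_mask == 2L)
    ctx <- sum(tr$pixel_mask == 1L & tr$region_mask == 1L) / sum(tr$region_mask == 1L)
    wm / ctx
  }, numeric(1))
  se <- stats::sd(ratio) / sqrt(length(ratio))
  expect_lt(abs(mean(ratio) - 0.75), 3 * se)
})

test_that("Beer-Lambert rendering is invertible by colour deconvolution", {
  g <- small_slide()
  spec <- synthetic_spec("CBD", slide_size = c(640L, 640L))
  dec <- deconvolve_stains(g$slide$pixels, spec$stain_od)
  tr <- g$truth
  true_agg <- tr$pixel_mask == 1L & !(tr$instance_map %in% tr$artifact_ids)
  # aggregate pixels render near concentration 1 (speckled, clamped >= 0.45)
  expect_gt(mean(dec$dab[true_agg]), 0.8)
  # tissue without DAB projects onto the DAB vector only at noise level
  empty <- tr$pixel_mask == 0L
  expect_lt(mean(abs(dec$dab[empty])), 0.05)
  # empty layout: no pixel's OD projects onto DAB above the noise floor
  g0 <- generate_slide(synthetic_spec("AD", slide_size = c(512L, 512L),
                                      ctx_burden_range = c(0, 0)), seed = 5L)
  dec0 <- deconvolve_stains(g0$slide$pixels, spec$stain_od)
  expect_lt(max(abs(dec0$dab)), 0.15)
  expect_error(render_stain(
    structure(list(region_mask = tr$region_mask,
                   instance_map = tr$instance_map[1:10, 1:10],
                   artifact_ids = integer(0)), class = "tauwm_truth"),
    spec), "mismatch")
})

test_that("every rendered object is recoverable by DAB thresholding", {
  g <- small_slide()
  spec <- synthetic_spec("CBD", slide_size = c(640L, 640L))
  dab <- deconvolve_stains(g$slide$pixels, spec$stain_od)$dab
  th <- dab > 0.25   # documented recovery threshold
  tr <- g$truth
  ids <- setdiff(unique(as.integer(tr$instance_map)), 0L)
  ious <- vapply(ids, function(id) {
    obj <- tr$instance_map == id
    # object footprint: its pixels plus its 1-px edge ring
    foot <- obj | (dilate_mask(obj, 1L) & tr$pixel_mask == 2L)
    near <- dilate_mask(foot, 2L)
    sum(th & foot) / sum((th & near) | foot)
  }, numeric(1))
  expect_gte(min(ious), 0.95)
})
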