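# Synthetic benchmark protocols.
#
# Each protocol generates its stated-world cohort, runs the relevant stage
# with the desk-scale ("test") preset, and measures one headline quantity.
# The acceptance script and the acceptance test suite both call these, so
# the measured numbers always come from the same code path.

bench_seed <- function(seed, offset) {
  (abs(as.integer(seed)) %% 100000L) * 10000L + offset
}

#' Region-model benchmark: held-out patch accuracy
#'
#' Generates 6 synthetic slides (2 per disease), trains the small FCN with
#' the test preset on two of three slide-level folds, and evaluates patch
#' accuracy on the held-out fold's stratified patches.
#'
#' @param seed integer seed controlling cohort and training.
#' @param slide_size generated slide size.
#' @return list with `value` (accuracy, %), `n` (evaluation patches),
#'   `model`, `cohort`, `diseases`.
#' @export
benchmark_region <- function(seed = 1L, slide_size = c(640L, 640L)) {
  dis <- rep(DISEASES, each = 2)
  coh <- generate_cohort(dis, seeds = bench_seed(seed, 1:6), slide_size = slide_size)
  cfg <- region_train_config("test", seed = bench_seed(seed, 7))
  folds <- crossval_split(dis, 3L, seed = bench_seed(seed, 8))
  set.seed(bench_seed(seed, 9))
  tr_p <- list(); tr_l <- integer(0)
  for (i in which(folds != 1L)) {
    ex <- extract_region_patches(coh[[i]]$slide, coh[[i]]$truth$region_mask, cfg)
    tr_p <- c(tr_p, ex$patches); tr_l <- c(tr_l, ex$labels)
  }
  model <- train_region_model(tr_p, tr_l, cfg)
  te_p <- list(); te_l <- integer(0)
  for (i in which(folds == 1L)) {
    ex <- extract_region_patches(coh[[i]]$slide, coh[[i]]$truth$region_mask, cfg)
    te_p <- c(te_p, ex$patches); te_l <- c(te_l, ex$labels)
  }
  acc <- region_patch_accuracy(model, te_p, te_l)
  list(value = 100 * acc, n = length(te_l), model = model, cohort = coh,
       diseases = dis)
}

#' Aggregate-model benchmark: held-out pixel accuracy
#'
#' Generates annotation tiles from 4 of 6 synthetic slides, trains the
#' reduced UNet with the test preset (twofold slide-level CV, better fold
#' kept), and evaluates 3-class pixel accuracy on tiles from the 2 held-out
#' slides.
#'
#' @param seed integer seed.
#' @param slide_size generated slide size.
#' @return list with `value` (pixel accuracy, %), `n` (pixels evaluated),
#'   `model`, `cohort`, `diseases`.
#' @export
benchmark_aggregate <- function(seed = 1L, slide_size = c(640L, 640L)) {
  dis <- rep(DISEASES, 2)
  coh <- generate_cohort(dis, seeds = bench_seed(seed, 11:16),
                         slide_size = slide_size)
  cfg <- aggregate_train_config("test", seed = bench_seed(seed, 17))
  set.seed(bench_seed(seed, 18))
  mk <- function(ix) {
    tl <- list()
    for (i in ix) {
      t <- sample_aggregate_tiles(coh[[i]]$slide, coh[[i]]$truth$pixel_mask,
                                  cfg$tile_px, cfg$tiles_per_slide)
      tl <- c(tl, lapply(t, function(z) {
        z$slide_id <- coh[[i]]$slide$slide_id; z$disease <- dis[i]; z
      }))
    }
    tl
  }
  tr <- mk(1:4); te <- mk(5:6)
  model <- train_aggregate_model(tr, cfg)
  acc <- aggregate_pixel_accuracy(model, te)
  list(value = 100 * acc, n = length(te) * cfg$tile_px^2, model = model,
       cohort = coh, diseases = dis)
}

#' MIL benchmark: held-out patch-level disease classification accuracy
#'
#' Generates 12 synthetic slides (4 per disease, 1024 px so each disease
#' contributes enough distinct aggregates), samples region-restricted
#' patches, trains the mean-pooled MIL classifier with the test preset under
#' slide-level cross validation, and evaluates patch accuracy on each
#' requested fold's held-out slides.
#'
#' @param seed integer seed.
#' @param region `"WM"` or `"CTX"`.
#' @param folds which folds of the threefold split to train/evaluate
#'   (default all three).
#' @param keep_cohort also return the generated cohort and models (large).
#' @return list with `value` (mean patch accuracy, %), `n` (patches
#'   evaluated), `fold_accuracy` (and with `keep_cohort` the `cohort` and
#'   `models`).
#' @export
benchmark_mil <- function(seed = 1L, region = c("WM", "CTX"), folds = 1:3,
                          keep_cohort = FALSE) {
  region <- match.arg(region)
  dis <- rep(DISEASES, each = 4)
  coh <- generate_cohort(dis, seeds = bench_seed(seed, 21:32),
                         slide_size = c(1024L, 1024L))
  cfg <- mil_config("test", seed = bench_seed(seed, 33))
  split <- crossval_split(dis, 3L, seed = bench_seed(seed, 34))
  fold_acc <- numeric(0)
  n_eval <- 0L
  models <- list()
  for (f in folds) {
    gc(FALSE)
    set.seed(bench_seed(seed, 40 + f))
    sampler <- function(ep) {
      bags <- list()
      for (i in which(split != f)) {
        sp <- sample_region_patches(coh[[i]]$slide, coh[[i]]$truth$region_mask,
                                    region, cfg$patches_per_slide_train,
                                    cfg$patch_px,
                                    focus_frac = cfg$train_focus_frac)
        bags <- c(bags, make_bags(sp$patches, dis[i], cfg$bag_size,
                                  coh[[i]]$slide$slide_id, region))
      }
      bags
    }
    model <- train_mil(sampler(1L), cfg, bag_sampler = sampler)
    per_slide <- vapply(which(split == f), function(i) {
      sp <- sample_region_patches(coh[[i]]$slide, coh[[i]]$truth$region_mask,
                                  region, cfg$patches_per_slide_eval,
                                  cfg$patch_px)
      n_eval <<- n_eval + length(sp$patches)
      mil_patch_accuracy(model, sp$patches, rep(dis[i], length(sp$patches)))
    }, numeric(1))
    fold_acc <- c(fold_acc, mean(per_slide))
    models[[length(models) + 1L]] <- model
  }
  out <- list(value = 100 * mean(fold_acc), n = n_eval,
              fold_accuracy = fold_acc, split = split, diseases = dis)
  if (keep_cohort) {
    out$cohort <- coh
    out$models <- models
  }
  out
}

#' QC benchmark: flagged-artifact fraction recovered by the random forest
#'
#' Generates slides with the default 4% artifact injection rate until at
#' least `min_objects` detected objects exist, labels a 200-object-per-slide
#' training subset against the ground truth, trains the artifact filter,
#' applies it to the remaining objects, and reports the flagged fraction.
#'
#' @param seed integer seed.
#' @param n_per_disease slides per disease (default 9, about 2300 objects).
#' @param min_objects required object count across the cohort.
#' @param slide_size generated slide size.
#' @return list with `value` (flagged fraction of the applied set, %), `n`
#'   (applied objects), `injected_rate`, `holdout_accuracy`, `features`.
#' @export
benchmark_qc <- function(seed = 1L, n_per_disease = 9L, min_objects = 2000L,
                         slide_size = c(640L, 640L)) {
  cfg <- qc_config(seed = bench_seed(seed, 50))
  tabs <- list()
  dis <- rep(DISEASES, n_per_disease)
  k <- 0L
  n_obj <- 0L
  while (n_obj < min_objects) {
    k <- k + 1L
    if (k > length(dis)) dis <- c(dis, DISEASES)  # top up if needed
    spec <- synthetic_spec(dis[k], slide_size = slide_size)
    g <- generate_slide(spec, seed = bench_seed(seed, 100 + k),
                        slide_id = sprintf("qc_%s_%02d", dis[k], k))
    tb <- qc_feature_table(g$slide, g$truth$pixel_mask, g$truth$region_mask,
                           truth = g$truth, cfg = cfg)
    if (!is.null(tb)) {
      tabs[[length(tabs) + 1L]] <- tb
      n_obj <- n_obj + nrow(tb)
    }
  }
  feats <- do.call(rbind, tabs)
  set.seed(bench_seed(seed, 51))
  sub <- unlist(lapply(split(seq_len(nrow(feats)), feats$slide_id),
                       function(ix) if (length(ix) <= cfg$subset_per_slide) ix
                       else sample(ix, cfg$subset_per_slide)))
  X <- as.matrix(feats[, qc_feature_cols()])
  filt <- train_artifact_filter(X[sub, , drop = FALSE],
                                feats$true_artifact[sub], cfg)
  rest <- setdiff(seq_len(nrow(feats)), sub)
  if (!length(rest)) rest <- seq_len(nrow(feats))
  res <- filter_artifacts(feats[rest, , drop = FALSE], filt)
  list(value = 100 * mean(res$table$is_artifact), n = length(rest),
       injected_rate = 100 * mean(feats$true_artifact),
       holdout_accuracy = filt$holdout_accuracy, features = feats,
       filter = filt)
}

#' Burden-slope benchmark: recovery of the WM:CTX burden ratio
#'
#' Generates `n` slides of one disease and fits the least-squares line of
#' WM burden on cortical burden from ground-truth masks (isolating the
#' burden arithmetic and the fit from segmentation). Optionally the same
#' slides are re-measured through trained region and aggregate models.
#'
#' @param seed integer seed.
#' @param disease disease whose slope is recovered.
#' @param n number of slides (default 20).
#' @param slide_size generated slide size.
#' @param region_models,aggregate_model optional trained models; when both
#'   are given a full-pipeline slope is also computed on `n_pipeline`
#'   slides.
#' @param n_pipeline slides re-measured through the models.
#' @return list with `fit` (ground-truth [fit_burden_line()]), `records`,
#'   and optionally `fit_pipeline`.
#' @export
benchmark_burden <- function(seed = 1L, disease = "PSP", n = 20L,
                             slide_size = c(512L, 512L),
                             region_models = NULL, aggregate_model = NULL,
                             n_pipeline = 6L) {
  coh <- generate_cohort(rep(disease, n), seeds = bench_seed(seed, 200 + 1:n),
                         slide_size = slide_size)
  masks <- lapply(coh, function(g)
    list(slide_id = g$slide$slide_id, disease = disease,
         region_mask = g$truth$region_mask, pixel_mask = g$truth$pixel_mask))
  rec <- burden_records(masks)
  out <- list(fit = fit_burden_line(rec), records = rec)
  if (!is.null(region_models) && !is.null(aggregate_model)) {
    sub <- seq_len(min(n_pipeline, n))
    pmasks <- lapply(coh[sub], function(g) {
      rm <- postprocess_region_mask(
        predict_regions_consensus(region_models, g$slide))
      pm <- predict_aggregate_mask(aggregate_model, g$slide,
                                   tile_px = max(dim(g$slide$pixels)))
      list(slide_id = g$slide$slide_id, disease = disease,
           region_mask = rm, pixel_mask = pm)
    })
    prec <- burden_records(pmasks)
    out$fit_pipeline <- fit_burden_line(prec)
    out$records_pipeline <- prec
    out$records_truth_subset <- rec[sub, ]
  }
  out
}
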