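# End-to-end pipeline orchestration with deterministic seeding and a run
# manifest. Stages run in dependency order:
#   simulate -> region -> aggregate -> features -> qc -> stats -> classify
#   -> interpret
# Each stage registers its outputs (with md5 hashes and the stage seed) in
# manifest.json; a disabled stage is replayed from its files on disk, so any
# single stage can be re-run in isolation.

#' Pipeline stage names, in dependency order
#' @export
PIPELINE_STAGES <- c("simulate", "region", "aggregate", "features", "qc",
                     "stats", "classify", "interpret")

#' Pipeline configuration
#'
#' @param out_dir output directory.
#' @param scale `"test"` (desk-scale presets) or `"full"` (full protocol
#'   sizes).
#' @param n_per_disease synthetic slides per disease.
#' @param slide_size generated slide size in px.
#' @param seed global seed; per-stage seeds are derived as
#'   `(seed * 131 + stage_index) mod 2^31`.
#' @param stages character vector of enabled stages (default all).
#' @param region_cfg,aggregate_cfg,qc_cfg,mil_cfg stage configurations;
#'   defaults follow `scale`.
#' @param area_threshold_px region-mask post-processing threshold.
#' @param min_area_px aggregate minimum area.
#' @return list of class `tauwm_pipeline_cfg`.
#' @export
pipeline_config <- function(out_dir, scale = c("test", "full"),
                            n_per_disease = 4L, slide_size = c(640L, 640L),
                            seed = 1L, stages = PIPELINE_STAGES,
                            region_cfg = NULL, aggregate_cfg = NULL,
                            qc_cfg = NULL, mil_cfg = NULL,
                            area_threshold_px = 1000L, min_area_px = 30L) {
  scale <- match.arg(scale)
  preset <- if (scale == "test") "test" else "full"
  cfg <- list(out_dir = out_dir, scale = scale,
              n_per_disease = as.integer(n_per_disease),
              slide_size = as.integer(slide_size), seed = as.integer(seed),
              stages = stages,
              region_cfg = region_cfg %||% region_train_config(preset),
              aggregate_cfg = aggregate_cfg %||% aggregate_train_config(preset),
              qc_cfg = qc_cfg %||% qc_config(),
              mil_cfg = mil_cfg %||% mil_config(preset),
              area_threshold_px = area_threshold_px,
              min_area_px = min_area_px)
  class(cfg) <- "tauwm_pipeline_cfg"
  cfg
}

stage_seed <- function(cfg, stage) {
  idx <- match(stage, PIPELINE_STAGES)
  as.integer((as.numeric(cfg$seed) * 131 + idx) %% 2147483647)
}

#' Validate a pipeline configuration
#'
#' Checks the structural invariants (patch sizes consistent with mpp, fold
#' counts vs cohort size, threshold ranges) and reports violations without
#' raising.
#'
#' @param cfg a [pipeline_config()].
#' @return list with `ok` and a character vector `errors`.
#' @export
validate_config <- function(cfg) {
  errs <- character(0)
  rc <- cfg$region_cfg
  if (rc$patch_px != round(rc$patch_um / rc$mpp))
    errs <- c(errs, "region patch_px inconsistent with patch_um / mpp")
  mc <- cfg$mil_cfg
  if (mc$patch_px != round(mc$patch_um / mc$mpp))
    errs <- c(errs, "mil patch_px inconsistent with patch_um / mpp")
  if (cfg$n_per_disease * 3 < rc$n_folds)
    errs <- c(errs, "fewer slides than region folds")
  if (cfg$n_per_disease < mc$n_folds)
    errs <- c(errs, "fewer slides per disease than MIL folds")
  ac <- cfg$aggregate_cfg
  if (ac$response_threshold <= 0 || ac$response_threshold >= 1)
    errs <- c(errs, "response threshold outside (0, 1)")
  if (ac$edge_loss_weight < 0)
    errs <- c(errs, "negative edge loss weight")
  if (any(cfg$slide_size < 512))
    errs <- c(errs, "slide size below 512 px")
  list(ok = length(errs) == 0, errors = errs)
}

register <- function(run, stage, files) {
  files <- files[file.exists(files)]
  run$manifest[[stage]] <- list(
    seed = stage_seed(run$cfg, stage),
    enabled = stage %in% run$cfg$stages,
    files = lapply(files, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  run
}

#' Run the pipeline end-to-end
#'
#' Executes the enabled stages in dependency order on a synthetic cohort,
#' writing every stage's outputs under `cfg$out_dir` and a `manifest.json`
#' recording files, hashes and per-stage seeds. Disabled stages are replayed
#' from their existing outputs; a missing upstream output fails with the
#' first unmet dependency.
#'
#' @param cfg a [pipeline_config()].
#' @return the manifest (invisibly also written as JSON).
#' @export
run_pipeline <- function(cfg) {
  v <- validate_config(cfg)
  if (!v$ok) stop("invalid config: ", paste(v$errors, collapse = "; "))
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  run <- list(cfg = cfg, manifest = list())
  on <- function(st) st %in% cfg$stages
  need <- function(path, stage) {
    if (!all(file.exists(path)))
      stop("missing upstream output for stage '", stage, "': ",
           paste(path[!file.exists(path)], collapse = ", "))
    path
  }
  p <- function(...) file.path(out, ...)

  # ---- simulate ----
  man_csv <- p("cohort.csv")
  if (on("simulate")) {
    set.seed(stage_seed(cfg, "simulate"))
    diseases <- rep(DISEASES, each = cfg$n_per_disease)
    seeds <- stage_seed(cfg, "simulate") %% 100000L + seq_along(diseases)
    rows <- list()
    for (i in seq_along(diseases)) {
      spec <- synthetic_spec(diseases[i], slide_size = cfg$slide_size)
      g <- generate_slide(spec, seed = seeds[i],
                          slide_id = sprintf("%s_%02d", diseases[i], i))
      sid <- g$slide$slide_id
      write_ppm(g$slide$pixels, p(paste0(sid, ".ppm")))
      write_pgm(g$truth$region_mask, p(paste0(sid, "_region.pgm")))
      write_pgm(g$truth$pixel_mask, p(paste0(sid, "_pixels.pgm")))
      write_pgm(g$truth$instance_map, p(paste0(sid, "_instances.pgm")))
      writeLines(jsonlite::toJSON(list(artifact_ids = g$truth$artifact_ids),
                                  auto_unbox = FALSE),
                 p(paste0(sid, "_artifacts.json")))
      rows[[i]] <- data.frame(slide_id = sid, disease = diseases[i],
                              seed = seeds[i], mpp = spec$mpp)
    }
    write_manifest(do.call(rbind, rows), man_csv)
  }
  run <- register(run, "simulate",
                  c(man_csv, list.files(out, "\\.(ppm|pgm)$", full.names = TRUE)))
  manifest_df <- read_manifest(need(man_csv, "simulate"))
  load_slide <- function(sid) {
    row <- manifest_df[manifest_df$slide_id == sid, ]
    new_slide(read_ppm(p(paste0(sid, ".ppm"))), row$mpp, sid, row$disease)
  }

  # ---- region ----
  region_files <- p(paste0(manifest_df$slide_id, "_regionpred.pgm"))
  if (on("region")) {
    set.seed(stage_seed(cfg, "region"))
    rc <- cfg$region_cfg
    folds <- crossval_split(manifest_df$disease, rc$n_folds,
                            stage_seed(cfg, "region"))
    models <- lapply(seq_len(rc$n_folds), function(f) {
      tr <- which(folds != f)
      ps <- list(); ls <- integer(0)
      for (i in tr) {
        sid <- manifest_df$slide_id[i]
        ex <- extract_region_patches(load_slide(sid),
                                     read_pgm(p(paste0(sid, "_region.pgm"))), rc)
        ps <- c(ps, ex$patches); ls <- c(ls, ex$labels)
      }
      train_region_model(ps, ls, rc)
    })
    for (sid in manifest_df$slide_id) {
      mask <- predict_regions_consensus(models, load_slide(sid))
      mask <- postprocess_region_mask(mask, cfg$area_threshold_px)
      write_pgm(mask, p(paste0(sid, "_regionpred.pgm")))
    }
  }
  run <- register(run, "region", region_files)

  # ---- aggregate ----
  pixel_files <- p(paste0(manifest_df$slide_id, "_pixelpred.pgm"))
  if (on("aggregate")) {
    set.seed(stage_seed(cfg, "aggregate"))
    ac <- cfg$aggregate_cfg
    tiles <- list()
    for (i in seq_len(nrow(manifest_df))) {
      sid <- manifest_df$slide_id[i]
      tl <- sample_aggregate_tiles(load_slide(sid),
                                   read_pgm(p(paste0(sid, "_pixels.pgm"))),
                                   ac$tile_px, ac$tiles_per_slide)
      tiles <- c(tiles, lapply(tl, function(t) {
        t$slide_id <- sid; t$disease <- manifest_df$disease[i]; t
      }))
    }
    model <- train_aggregate_model(tiles, ac)
    for (sid in manifest_df$slide_id) {
      mask <- predict_aggregate_mask(model, load_slide(sid))
      write_pgm(mask, p(paste0(sid, "_pixelpred.pgm")))
    }
  }
  run <- register(run, "aggregate", pixel_files)

  # ---- features ----
  feat_csv <- p("features.csv")
  if (on("features")) {
    need(region_files, "features"); need(pixel_files, "features")
    set.seed(stage_seed(cfg, "features"))
    tabs <- lapply(seq_len(nrow(manifest_df)), function(i) {
      sid <- manifest_df$slide_id[i]
      qc_feature_table(load_slide(sid),
                       read_pgm(p(paste0(sid, "_pixelpred.pgm"))),
                       read_pgm(p(paste0(sid, "_regionpred.pgm"))),
                       cfg = cfg$qc_cfg, mpp = manifest_df$mpp[i],
                       min_area_px = cfg$min_area_px)
    })
    utils::write.csv(do.call(rbind, tabs), feat_csv, row.names = FALSE)
  }
  run <- register(run, "features", feat_csv)

  # ---- qc ----
  qc_csv <- p("features_qc.csv")
  if (on("qc")) {
    feats <- utils::read.csv(need(feat_csv, "qc"))
    set.seed(stage_seed(cfg, "qc"))
    # label training subset against ground-truth instance maps
    lab <- logical(nrow(feats))
    for (sid in unique(feats$slide_id)) {
      inst_map <- read_pgm(p(paste0(sid, "_instances.pgm")))
      art <- jsonlite::read_json(p(paste0(sid, "_artifacts.json")),
                                 simplifyVector = TRUE)$artifact_ids
      rows <- which(feats$slide_id == sid)
      for (r in rows) {
        ids <- inst_map[(feats$bb_r0[r] + 1):(feats$bb_r1[r] + 1),
                        (feats$bb_c0[r] + 1):(feats$bb_c1[r] + 1)]
        ids <- ids[ids > 0]
        lab[r] <- length(ids) > 0 &&
          as.integer(names(which.max(table(ids)))) %in% art
      }
    }
    sub <- unlist(lapply(split(seq_len(nrow(feats)), feats$slide_id),
                         function(ix) if (length(ix) <= cfg$qc_cfg$subset_per_slide)
                           ix else sample(ix, cfg$qc_cfg$subset_per_slide)))
    X <- as.matrix(feats[, qc_feature_cols()])
    if (length(unique(lab[sub])) < 2) {
      warning("labelled subset has a single class; QC filter skipped")
      feats$is_artifact <- FALSE
      utils::write.csv(feats, qc_csv, row.names = FALSE)
    } else {
      filt <- train_artifact_filter(X[sub, , drop = FALSE], lab[sub],
                                    cfg$qc_cfg)
      res <- filter_artifacts(feats, filt)
      utils::write.csv(res$table, qc_csv, row.names = FALSE)
    }
  } else if (!file.exists(qc_csv) && file.exists(feat_csv)) {
    # QC disabled: downstream statistics consume unfiltered features
    utils::write.csv(utils::read.csv(feat_csv), qc_csv, row.names = FALSE)
  }
  run <- register(run, "qc", qc_csv)

  # ---- stats ----
  stat_files <- p(c("burden.csv", "fits.json", "profiles.csv", "stats.csv"))
  if (on("stats")) {
    feats <- utils::read.csv(need(qc_csv, "stats"))
    masks <- lapply(seq_len(nrow(manifest_df)), function(i) {
      sid <- manifest_df$slide_id[i]
      list(slide_id = sid, disease = manifest_df$disease[i],
           region_mask = read_pgm(p(paste0(sid, "_regionpred.pgm"))),
           pixel_mask = read_pgm(p(paste0(sid, "_pixelpred.pgm"))))
    })
    ok <- vapply(masks, function(m)
      all(c(1L, 2L) %in% m$region_mask), logical(1))
    if (any(!ok))
      warning("slides without both segmented regions skipped for burden: ",
              paste(vapply(masks[!ok], `[[`, "", "slide_id"), collapse = ", "))
    burden <- if (any(ok)) burden_records(masks[ok]) else
      data.frame(slide_id = character(0), disease = character(0),
                 ctx_burden = numeric(0), wm_burden = numeric(0))
    utils::write.csv(burden, stat_files[1], row.names = FALSE)
    fits <- lapply(split(burden, burden$disease), function(b)
      tryCatch(fit_burden_line(b), error = function(e) NULL))
    if (!length(fits)) fits <- list()
    writeLines(jsonlite::toJSON(fits, auto_unbox = TRUE, digits = NA,
                                null = "null"), stat_files[2])
    dis <- stats::setNames(manifest_df$disease, manifest_df$slide_id)
    prof <- cohort_profiles(feats, dis)
    utils::write.csv(data.frame(slide_id = rownames(prof$profiles),
                                disease = prof$diseases, prof$profiles),
                     stat_files[3], row.names = FALSE)
    st <- if (nrow(prof$profiles)) do.call(rbind, lapply(FEATURE_NAMES,
      function(f) {
        med <- prof$profiles[, f]
        vals <- split(med, prof$diseases)
        if (any(vapply(vals, length, 0L) < 3)) return(NULL)
        cmp <- compare_feature_across_diseases(vals)
        cmp$feature <- f
        cmp
      })) else NULL
    if (is.null(st))
      st <- data.frame(group1 = character(0), group2 = character(0),
                       U = numeric(0), p_raw = numeric(0),
                       p_corrected = numeric(0), significant = logical(0),
                       feature = character(0))
    utils::write.csv(st, stat_files[4], row.names = FALSE)
  }
  run <- register(run, "stats", stat_files)

  try_patches <- function(...) tryCatch(sample_region_patches(...),
                                        error = function(e) NULL)

  # ---- classify ----
  cls_files <- p(c("patch_predictions.csv", "slide_predictions.csv"))
  if (on("classify")) {
    need(region_files, "classify")
    set.seed(stage_seed(cfg, "classify"))
    mc <- cfg$mil_cfg
    folds <- crossval_split(manifest_df$disease, mc$n_folds,
                            stage_seed(cfg, "classify"))
    patch_rows <- list(); slide_rows <- list()
    for (region in c("CTX", "WM")) {
      for (f in seq_len(mc$n_folds)) {
        bags <- list()
        for (i in which(folds != f)) {
          sid <- manifest_df$slide_id[i]
          sp <- try_patches(load_slide(sid),
                            read_pgm(p(paste0(sid, "_regionpred.pgm"))),
                            region, mc$patches_per_slide_train, mc$patch_px,
                            focus_frac = mc$train_focus_frac %||% 0)
          if (is.null(sp)) {
            warning("no ", region, " patch centres in ", sid, "; skipped")
            next
          }
          bags <- c(bags, make_bags(sp$patches, manifest_df$disease[i],
                                    mc$bag_size, sid, region))
        }
        model <- train_mil(bags, mc)
        for (i in which(folds == f)) {
          sid <- manifest_df$slide_id[i]
          sp <- try_patches(load_slide(sid),
                            read_pgm(p(paste0(sid, "_regionpred.pgm"))),
                            region, mc$patches_per_slide_eval, mc$patch_px)
          if (is.null(sp)) next
          pred <- predict_slide(model, sp$patches)
          patch_rows[[length(patch_rows) + 1L]] <-
            data.frame(slide_id = sid, region = region, fold = f,
                       disease = manifest_df$disease[i],
                       t(pred$fractions))
          slide_rows[[length(slide_rows) + 1L]] <-
            data.frame(slide_id = sid, region = region, fold = f,
                       disease = manifest_df$disease[i], predicted = pred$class)
        }
      }
    }
    utils::write.csv(do.call(rbind, patch_rows), cls_files[1], row.names = FALSE)
    utils::write.csv(do.call(rbind, slide_rows), cls_files[2], row.names = FALSE)
  }
  run <- register(run, "classify", cls_files)

  # ---- interpret ----
  int_files <- p(c("embeddings.csv", "umap.csv", "overlay.csv"))
  if (on("interpret")) {
    need(region_files, "interpret"); need(qc_csv, "interpret")
    set.seed(stage_seed(cfg, "interpret"))
    mc <- cfg$mil_cfg
    # small dedicated WM model for embedding extraction
    bags <- list()
    for (i in seq_len(nrow(manifest_df))) {
      sid <- manifest_df$slide_id[i]
      sp <- try_patches(load_slide(sid),
                        read_pgm(p(paste0(sid, "_regionpred.pgm"))),
                        "WM", mc$patches_per_slide_train, mc$patch_px,
                        focus_frac = mc$train_focus_frac %||% 0)
      if (is.null(sp)) next
      bags <- c(bags, make_bags(sp$patches, manifest_df$disease[i],
                                mc$bag_size, sid, "WM"))
    }
    model <- train_mil(bags, mc)
    feats <- utils::read.csv(qc_csv)
    boxes <- list(); patches <- list()
    half <- mc$patch_px %/% 2L
    for (i in seq_len(nrow(manifest_df))) {
      sid <- manifest_df$slide_id[i]
      sp <- try_patches(load_slide(sid),
                        read_pgm(p(paste0(sid, "_regionpred.pgm"))),
                        "WM", max(10L, mc$patches_per_slide_eval %/% 4L),
                        mc$patch_px)
      if (is.null(sp)) next
      patches <- c(patches, sp$patches)
      boxes[[length(boxes) + 1L]] <- data.frame(
        slide_id = sid, disease = manifest_df$disease[i],
        r0 = sp$centers[, 1] - half, c0 = sp$centers[, 2] - half,
        size = mc$patch_px)
    }
    boxes <- do.call(rbind, boxes)
    emb <- extract_embeddings(model, patches)
    utils::write.csv(emb, int_files[1], row.names = FALSE)
    um <- project_umap(emb, 5L, 1.0, stage_seed(cfg, "interpret"))
    utils::write.csv(data.frame(boxes, umap1 = um[, 1], umap2 = um[, 2]),
                     int_files[2], row.names = FALSE)
    ov <- overlay_patch_features(boxes, feats)
    utils::write.csv(ov, int_files[3], row.names = FALSE)
  }
  run <- register(run, "interpret", int_files)

  writeLines(jsonlite::toJSON(run$manifest, auto_unbox = TRUE, digits = NA),
             p("manifest.json"))
  invisible(run$manifest)
}
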