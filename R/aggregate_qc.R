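# Aggregate quality control: nuclear-staining artifact detection.
#
# Texture (gray-level co-occurrence) features on the DAB optical-density
# patch of each object augment the nine morphometric features; a UMAP
# embedding with a silhouette score sanity-checks that artifacts separate,
# and a random-forest classifier flags them for removal from all downstream
# statistics.

TEXTURE_NAMES <- c("glcm_contrast", "glcm_correlation", "glcm_energy",
                   "glcm_homogeneity")

#' QC configuration
#'
#' @param rf_trees number of random-forest trees (default 200).
#' @param subset_per_slide labelled objects sampled per slide for training
#'   (default 200).
#' @param holdout_fraction stratified holdout fraction for the reported
#'   accuracy (default 0.25).
#' @param glcm_levels gray levels used for the co-occurrence matrix.
#' @param od_max optical-density value mapped to the top gray level.
#' @param umap_params list passed to [project_umap()].
#' @param seed RNG seed.
#' @return list of class `tauwm_qc_cfg`.
#' @export
qc_config <- function(rf_trees = 200L, subset_per_slide = 200L,
                      holdout_fraction = 0.25, glcm_levels = 8L,
                      od_max = 1.2, umap_params = list(n_neighbors = 5L,
                                                       min_dist = 1.0),
                      seed = 1L) {
  stopifnot(subset_per_slide > 0, holdout_fraction > 0, holdout_fraction < 1)
  structure(list(rf_trees = rf_trees, subset_per_slide = subset_per_slide,
                 holdout_fraction = holdout_fraction,
                 glcm_levels = glcm_levels, od_max = od_max,
                 umap_params = umap_params, seed = seed),
            class = "tauwm_qc_cfg")
}

#' Gray-level co-occurrence texture features of one aggregate
#'
#' Computes contrast, correlation, energy and homogeneity of the symmetric
#' co-occurrence matrix at 1-px offset, averaged over 4 orientations, on the
#' object's DAB optical-density patch quantized to `glcm_levels` over the
#' fixed range `[0, od_max]` (fixed quantization keeps staining strength
#' visible to the statistics). Pixels outside the object are ignored.
#'
#' @param instance as from [label_aggregates()].
#' @param pixels the slide's RGB array.
#' @param stain_od stain optical-density vectors (list `hem`, `dab`).
#' @param cfg a [qc_config()].
#' @return named numeric vector of 4 texture statistics; single-pixel
#'   objects return zeros with attribute `degenerate = TRUE`.
#' @export
compute_texture_features <- function(instance, pixels,
                                     stain_od = list(hem = c(0.65, 0.70, 0.29),
                                                     dab = c(0.27, 0.57, 0.78)),
                                     cfg = qc_config()) {
  px <- instance$pixels
  if (nrow(px) < 2) {
    out <- stats::setNames(numeric(4), TEXTURE_NAMES)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  r0 <- min(px[, 1]); r1 <- max(px[, 1]); c0 <- min(px[, 2]); c1 <- max(px[, 2])
  sub <- pixels[(r0 + 1L):(r1 + 1L), (c0 + 1L):(c1 + 1L), , drop = FALSE]
  od <- -log(pmax(matrix(sub, ncol = 3), 0.5) / 255)
  M <- cbind(stain_od$hem, stain_od$dab)
  dab <- solve(crossprod(M), t(M) %*% t(od))[2, ]
  q <- pmin(pmax(floor(dab / cfg$od_max * cfg$glcm_levels), 0),
            cfg$glcm_levels - 1L)
  g <- matrix(-1L, r1 - r0 + 1L, c1 - c0 + 1L)
  inmask <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
  inmask[cbind(px[, 1] - r0 + 1L, px[, 2] - c0 + 1L)] <- TRUE
  g[inmask] <- as.integer(q[as.vector(inmask)])
  stats::setNames(glcm_stats_cpp(g, cfg$glcm_levels), TEXTURE_NAMES)
}

#' Morphometric + texture QC feature matrix for a slide
#'
#' @param slide a `tauwm_slide`.
#' @param pixel_mask aggregate-class mask used for instance extraction.
#' @param region_mask optional region raster.
#' @param truth optional `tauwm_truth`; when given, instances are matched to
#'   ground-truth artifact labels by pixel overlap.
#' @param cfg a [qc_config()].
#' @param mpp,min_area_px passed to morphometry.
#' @return data frame: feature table plus 4 texture columns and (with
#'   `truth`) a logical `true_artifact` column.
#' @export
qc_feature_table <- function(slide, pixel_mask, region_mask = NULL,
                             truth = NULL, cfg = qc_config(), mpp = 0.5,
                             min_area_px = 30L) {
  inst <- label_aggregates(pixel_mask, min_area_px, region_mask,
                           slide$slide_id)
  if (!length(inst)) return(NULL)
  feats <- t(vapply(inst, compute_features, numeric(9), mpp = mpp))
  tex <- t(vapply(inst, compute_texture_features, numeric(4),
                  pixels = slide$pixels, cfg = cfg))
  bb <- t(vapply(inst, function(it)
    c(min(it$pixels[, 1]), max(it$pixels[, 1]),
      min(it$pixels[, 2]), max(it$pixels[, 2])), numeric(4)))
  out <- data.frame(slide_id = slide$slide_id,
                    instance_id = vapply(inst, `[[`, 0L, "instance_id"),
                    region = vapply(inst, `[[`, "", "region"),
                    n_px = vapply(inst, `[[`, 0L, "n_px"),
                    bb_r0 = bb[, 1], bb_r1 = bb[, 2],
                    bb_c0 = bb[, 3], bb_c1 = bb[, 4])
  out <- cbind(out, as.data.frame(feats), as.data.frame(tex))
  if (!is.null(truth)) {
    out$true_artifact <- vapply(inst, function(it) {
      ids <- truth$instance_map[it$pixels + 1L]
      ids <- ids[ids > 0L]
      if (!length(ids)) return(FALSE)
      as.integer(names(which.max(table(ids)))) %in% truth$artifact_ids
    }, logical(1))
  }
  out$is_artifact <- FALSE
  out
}

qc_feature_cols <- function() c(FEATURE_NAMES, TEXTURE_NAMES)

# simple mean silhouette for labelled points (Euclidean)
silhouette_score <- function(x, labels) {
  x <- as.matrix(x)
  d <- as.matrix(stats::dist(x))
  labs <- unique(labels)
  s <- vapply(seq_len(nrow(x)), function(i) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) sum(d[i, own]) / (sum(own) - 1) else 0
    b <- min(vapply(labs[labs != labels[i]], function(l)
      mean(d[i, labels == l]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Embedding sanity check for artifact separability
#'
#' Projects the (z-scored) QC features of sampled objects with UMAP and
#' reports the silhouette of the true artifact labels in the embedding.
#'
#' @param features numeric matrix of QC features.
#' @param labels logical/character artifact labels (both classes required).
#' @param cfg a [qc_config()].
#' @param seed seed for the projection.
#' @return list with `embedding` (n x 2) and `silhouette`.
#' @export
qc_embedding_check <- function(features, labels, cfg = qc_config(),
                               seed = cfg$seed) {
  if (nrow(features) < 50) stop("need at least 50 objects")
  if (length(unique(labels)) < 2) stop("both classes must be present")
  z <- scale(as.matrix(features))
  z[, attr(z, "scaled:scale") == 0] <- 0
  emb <- do.call(project_umap,
                 c(list(x = z, seed = seed), cfg$umap_params))
  list(embedding = emb, silhouette = silhouette_score(emb, labels))
}

#' Train the random-forest artifact filter
#'
#' Stratified holdout (default 25%) reports the accuracy; the forest is a
#' gini CART ensemble with bootstrap resampling and sqrt-p feature
#' subsampling.
#'
#' @param features numeric matrix (rows = objects).
#' @param is_artifact logical labels.
#' @param cfg a [qc_config()].
#' @return object of class `tauwm_artifact_filter` with `holdout_accuracy`.
#' @export
train_artifact_filter <- function(features, is_artifact, cfg = qc_config()) {
  features <- as.matrix(features)
  if (length(unique(is_artifact)) < 2)
    stop("training data must contain both aggregates and artifacts")
  set.seed(cfg$seed)
  y <- as.integer(is_artifact)
  hold <- unlist(lapply(split(seq_along(y), y), function(ix)
    sample(ix, max(1L, round(cfg$holdout_fraction * length(ix))))))
  tr <- setdiff(seq_along(y), hold)
  mtry <- max(1L, floor(sqrt(ncol(features))))
  forest <- rf_train_cpp(features[tr, , drop = FALSE], y[tr], 2L,
                         cfg$rf_trees, mtry, 5L, 25L)
  pred <- max.col(rf_predict_cpp(forest, features[hold, , drop = FALSE], 2L), ties.method = "first") - 1L
  structure(list(forest = forest, feature_names = colnames(features),
                 holdout_accuracy = mean(pred == y[hold]), cfg = cfg),
            class = "tauwm_artifact_filter")
}

#' Apply the artifact filter to a feature table
#'
#' Sets `is_artifact` from the forest vote and returns kept and flagged
#' subsets; kept and flagged partition the input exactly.
#'
#' @param feature_df QC feature table (must contain the filter's feature
#'   columns).
#' @param filter a `tauwm_artifact_filter`.
#' @return list with `table` (flagged column set), `kept`, `flagged`.
#' @export
filter_artifacts <- function(feature_df, filter) {
  X <- as.matrix(feature_df[, filter$feature_names, drop = FALSE])
  votes <- rf_predict_cpp(filter$forest, X, 2L)
  feature_df$is_artifact <- max.col(votes, ties.method = "first") - 1L == 1L
  list(table = feature_df,
       kept = feature_df[!feature_df$is_artifact, , drop = FALSE],
       flagged = feature_df[feature_df$is_artifact, , drop = FALSE])
}
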