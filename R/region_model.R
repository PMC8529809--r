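# Region (background / cortex / white-matter) segmentation.
#
# A small fully convolutional patch classifier: stacked stride-2 3x3 conv
# blocks followed by a 1x1 conv to 3 logit channels (output stride =
# prod(strides) = 16 by default). During training the spatial logit map of a
# patch is mean-pooled into patch logits ("does the patch centre lie in
# BG/CTX/WM"); at slide level the stack runs fully convolutionally and the
# logit map is box-smoothed over one patch footprint before the softmax, so
# inference matches the pooled training head.

REGION_CLASSES <- c("BG", "CTX", "WM")

#' Training configuration for the region model
#'
#' Full-scale defaults follow the protocol this package mirrors: 256-px (128-um) patches, Adam with
#' learning rate 1e-4, 20 epochs, threefold slide-level cross validation,
#' inverse-frequency class weights, flip + hue/saturation augmentation. The
#' `"test"` preset shrinks widths, epochs and patch counts (and raises the
#' learning rate to compensate for the few gradient steps) for desk-scale
#' runs.
#'
#' @param preset `"full"` or `"test"`.
#' @param ... overrides for any field.
#' @return list of class `tauwm_region_cfg`.
#' @export
region_train_config <- function(preset = c("full", "test"), ...) {
  preset <- match.arg(preset)
  cfg <- list(patch_um = 128, mpp = 0.5, lr = 1e-4, optimizer = "adam",
              epochs = 20L, n_folds = 3L, widths = c(16L, 32L, 64L, 128L),
              batch_size = 8L, patches_per_slide = 600L,
              hue_range = 0.05, sat_range = 0.1, augment = TRUE,
              class_weights = NULL, seed = 1L)
  if (preset == "test") {
    cfg$widths <- c(8L, 16L, 32L, 64L)
    cfg$epochs <- 10L
    cfg$lr <- 1e-3
    cfg$patch_um <- 64
    cfg$patches_per_slide <- 64L
  }
  ov <- list(...)
  cfg[names(ov)] <- ov
  cfg$patch_px <- as.integer(round(cfg$patch_um / cfg$mpp))
  class(cfg) <- "tauwm_region_cfg"
  cfg
}

#' Slide-level stratified cross-validation split
#'
#' Partitions slides into `k` folds at the slide level so that per-disease
#' counts across folds differ by at most one (shuffled round-robin within
#' each disease).
#'
#' @param diseases character vector, one label per slide.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer fold assignment (1..k) per slide.
#' @export
crossval_split <- function(diseases, k = 3L, seed = 1L) {
  n <- length(diseases)
  if (n < k) stop("fewer slides than folds")
  tab <- table(diseases)
  if (any(tab < 1)) stop("empty disease group")
  set.seed(seed)
  fold <- integer(n)
  for (d in names(tab)) {
    idx <- sample(which(diseases == d))
    start <- sample.int(k, 1L)
    fold[idx] <- ((start + seq_along(idx) - 2L) %% k) + 1L
  }
  fold
}

#' Extract labelled region patches from one slide
#'
#' Samples `patch_px`-square patches fully inside the slide, stratified with
#' equal counts per region class present (without replacement when enough
#' centres exist). The label is the region-mask value at the patch's centre
#' pixel.
#'
#' @param slide a `tauwm_slide`.
#' @param region_mask integer matrix in `{0, 1, 2}` aligned to the slide.
#' @param cfg a [region_train_config()].
#' @param n total number of patches requested.
#' @return list with `patches` (list of `c(p, p, 3)` arrays in `[0, 1]`),
#'   `labels` (1 = BG, 2 = CTX, 3 = WM) and `centers` (1-based row/col).
#' @export
extract_region_patches <- function(slide, region_mask, cfg,
                                   n = cfg$patches_per_slide) {
  p <- cfg$patch_px
  d <- dim(slide$pixels)
  if (d[1] < p || d[2] < p) stop("slide smaller than patch")
  if (n <= 0)
    return(list(patches = list(), labels = integer(0),
                centers = matrix(0L, 0, 2)))
  half <- p %/% 2L
  # valid centre c spans rows (c - half + 1):(c + half)
  ri <- (half):(d[1] - half)
  ci <- (half):(d[2] - half)
  inner <- region_mask[ri, ci, drop = FALSE]
  classes <- sort(unique(as.integer(inner)))
  per <- ceiling(n / length(classes))
  centers <- NULL
  for (cl in classes) {
    cand <- which(inner == cl)
    take <- min(per, length(cand))
    pick <- if (length(cand) <= take) cand else sample(cand, take)
    centers <- rbind(centers,
                     cbind((pick - 1L) %% nrow(inner) + ri[1],
                           (pick - 1L) %/% nrow(inner) + ci[1]))
  }
  if (nrow(centers) > n) centers <- centers[sample(nrow(centers), n), , drop = FALSE]
  labels <- region_mask[centers] + 1L
  img <- slide$pixels / 255
  patches <- lapply(seq_len(nrow(centers)), function(t) {
    i <- centers[t, 1]; j <- centers[t, 2]
    img[(i - half + 1L):(i + half), (j - half + 1L):(j + half), , drop = FALSE]
  })
  list(patches = patches, labels = labels, centers = centers)
}

region_model_new <- function(cfg) {
  nlev <- length(cfg$widths)
  layers <- convstack_new(cfg$widths, rep(2L, nlev))
  layers[[nlev + 1L]] <- conv_layer(cfg$widths[nlev], 3L, k = 1L, stride = 1L,
                                    pad = 0L, act = "linear")
  structure(list(layers = layers, cfg = cfg,
                 output_stride = as.integer(2L^nlev),
                 classes = REGION_CLASSES),
            class = "tauwm_region_model")
}

region_patch_logits <- function(model, x) {
  r <- convstack_fw(model$layers[-length(model$layers)], norm_img(x))
  h <- conv_fw(model$layers[[length(model$layers)]], r$out)
  map <- h$out
  npos <- prod(dim(map)[1:2])
  logits <- colMeans(matrix(map, npos, 3))
  list(logits = logits, caches = r$caches, head_cache = h$cache,
       map_dim = dim(map))
}

#' Train the region patch classifier
#'
#' Weighted categorical cross-entropy on mean-pooled patch logits; class
#' weights default to inverse relative frequency `N / (K * N_c)`; Adam
#' optimizer; flips and hue/saturation jitter as augmentation.
#'
#' @param patches list of patch arrays in `[0, 1]`.
#' @param labels integer labels (1 = BG, 2 = CTX, 3 = WM).
#' @param cfg a [region_train_config()].
#' @return a `tauwm_region_model` with a `history` of per-epoch mean losses.
#' @export
train_region_model <- function(patches, labels, cfg = region_train_config()) {
  present <- sort(unique(labels))
  if (length(present) < 2 && is.null(cfg$class_weights))
    stop("training patches contain a single class")
  set.seed(cfg$seed)
  model <- region_model_new(cfg)
  w <- cfg$class_weights
  if (is.null(w)) {
    cnt <- tabulate(labels, 3L)
    w <- ifelse(cnt > 0, length(labels) / (3 * pmax(cnt, 1)), 0)
  }
  nl <- length(model$layers)
  params <- layers_params(model$layers)
  opt <- opt_init(cfg$optimizer, lr = cfg$lr)
  history <- numeric(cfg$epochs)
  n <- length(patches)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(n)
    losses <- numeric(0)
    for (start in seq(1, n, by = cfg$batch_size)) {
      ids <- ord[start:min(start + cfg$batch_size - 1L, n)]
      gacc <- NULL
      bl <- 0
      model$layers <- layers_set_params(model$layers, params)
      for (id in ids) {
        x <- patches[[id]]
        if (cfg$augment) x <- augment_patch(x, cfg$hue_range, cfg$sat_range)
        fw <- region_patch_logits(model, x)
        ce <- softmax_ce(matrix(fw$logits, 1), labels[id], w)
        bl <- bl + ce$loss
        npos <- prod(fw$map_dim[1:2])
        dmap <- array(rep(ce$dlogits / npos, each = npos), fw$map_dim)
        hb <- conv_bw(model$layers[[nl]], fw$head_cache, dmap)
        g <- convstack_bw(model$layers[-nl], fw$caches,
                          array(hb$dx, c(fw$map_dim[1:2],
                                         cfg$widths[length(cfg$widths)])))
        g[[paste0("W", nl)]] <- hb$dW
        g[[paste0("b", nl)]] <- hb$db
        gacc <- if (is.null(gacc)) g else
          stats::setNames(lapply(names(g), function(nm) gacc[[nm]] + g[[nm]]),
                          names(g))
      }
      gacc <- lapply(gacc, function(g) g / length(ids))
      st <- opt_step(opt, params, gacc)
      opt <- st$opt; params <- st$params
      losses <- c(losses, bl / length(ids))
    }
    history[ep] <- mean(losses)
  }
  model$layers <- layers_set_params(model$layers, params)
  model$class_weights <- w
  model$history <- history
  model
}

#' Classify patches with a trained region model
#'
#' @param model a `tauwm_region_model`.
#' @param patches list of patch arrays.
#' @return integer predicted labels (1 = BG, 2 = CTX, 3 = WM).
#' @export
predict_region_patches <- function(model, patches) {
  vapply(patches, function(x) {
    lg <- region_patch_logits(model, x)$logits
    which.max(lg)            # ties resolve to the lowest index
  }, integer(1))
}

#' Class activation map of one model over a whole slide
#'
#' Runs the conv stack fully convolutionally, box-smooths the logit map over
#' one patch footprint, and applies a softmax; responses sum to one per
#' position.
#'
#' @param model a `tauwm_region_model`.
#' @param slide a `tauwm_slide`.
#' @return list with `responses` (H' x W' x 3) and `output_stride`.
#' @export
predict_region_responses <- function(model, slide) {
  x <- norm_img(slide$pixels / 255)
  nl <- length(model$layers)
  r <- convstack_fw(model$layers[-nl], x)
  h <- conv_fw(model$layers[[nl]], r$out)
  map <- h$out
  win <- max(1L, model$cfg$patch_px %/% model$output_stride)
  for (ch in 1:3) map[, , ch] <- box_mean_cpp(map[, , ch], win)
  p <- softmax_rows(matrix(map, ncol = 3))
  list(responses = array(p, dim(map)), output_stride = model$output_stride)
}

#' Average the activation maps of several models, take the argmax
#'
#' Implements average-then-argmax consensus: responses are averaged
#' elementwise across models and each position is assigned the class with
#' the maximum average response (ties toward the lowest class index).
#'
#' @param responses list of H' x W' x 3 arrays.
#' @return integer matrix in `{0 = BG, 1 = CTX, 2 = WM}` at map resolution.
#' @export
consensus_argmax <- function(responses) {
  d <- dim(responses[[1]])
  for (r in responses)
    if (!all(dim(r) == d)) stop("model response resolutions differ")
  avg <- Reduce(`+`, responses) / length(responses)
  m <- matrix(avg, ncol = 3)
  matrix(max.col(m, ties.method = "first") - 1L, d[1], d[2])
}

#' Consensus region mask for a slide
#'
#' Computes every model's activation map, averages, argmaxes, and upsamples
#' (nearest neighbour) back to slide resolution.
#'
#' @param models list of `tauwm_region_model`.
#' @param slide a `tauwm_slide`.
#' @return integer matrix `{0 = BG, 1 = CTX, 2 = WM}`, same size as the slide.
#' @export
predict_regions_consensus <- function(models, slide) {
  if (!length(models)) stop("need at least one model")
  rs <- lapply(models, function(m) predict_region_responses(m, slide))
  os <- unique(vapply(rs, `[[`, 0L, "output_stride"))
  if (length(os) != 1) stop("model response resolutions differ")
  lab <- consensus_argmax(lapply(rs, `[[`, "responses"))
  d <- dim(slide$pixels)
  up <- lab[rep(seq_len(nrow(lab)), each = os), rep(seq_len(ncol(lab)), each = os)]
  up[seq_len(d[1]), seq_len(d[2]), drop = FALSE]
}

#' Remove small islands and fill small holes in a region mask
#'
#' Per class, connected components smaller than `area_threshold_px` are
#' reassigned to the majority label of their adjacent pixels (this removes
#' small islands and fills small holes in one rule). Components at or above
#' the threshold are retained. Repeats until stable, so the operation is
#' idempotent.
#'
#' @param mask integer matrix in `{0, 1, 2}`.
#' @param area_threshold_px area threshold in pixels (default 1000).
#' @return cleaned mask, same labels.
#' @export
postprocess_region_mask <- function(mask, area_threshold_px = 1000L) {
  H <- nrow(mask); W <- ncol(mask)
  for (iter in 1:10) {
    changed <- FALSE
    for (cl in c(0L, 1L, 2L)) {
      lab <- cc_label_cpp(matrix(as.integer(mask == cl), H), 8L)
      nlab <- max(lab)
      if (nlab == 0) next
      sizes <- tabulate(lab[lab > 0], nlab)
      for (co in which(sizes < area_threshold_px)) {
        px <- which(lab == co, arr.ind = TRUE)
        nb <- rbind(cbind(px[, 1] + 1L, px[, 2]), cbind(px[, 1] - 1L, px[, 2]),
                    cbind(px[, 1], px[, 2] + 1L), cbind(px[, 1], px[, 2] - 1L))
        nb <- nb[nb[, 1] >= 1 & nb[, 1] <= H & nb[, 2] >= 1 & nb[, 2] <= W, ,
                 drop = FALSE]
        vals <- mask[nb]
        vals <- vals[vals != cl]
        if (!length(vals)) next
        mask[px] <- as.integer(names(which.max(table(vals))))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  mask
}

#' Patch classification accuracy of a region model
#'
#' @param model trained model.
#' @param patches,labels evaluation set as from [extract_region_patches()].
#' @return fraction of correctly classified patches.
#' @export
region_patch_accuracy <- function(model, patches, labels) {
  mean(predict_region_patches(model, patches) == labels)
}
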