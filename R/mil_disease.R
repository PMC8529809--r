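# Multiple-instance disease classification (AD / PSP / CBD).
#
# Bags of region-restricted image patches share one slide-level label. A
# small CNN backbone embeds each patch (global mean pool, then a dense
# 1024-unit penultimate layer) and produces three one-vs-rest sigmoid
# scores; the bag score is the mean of its instance scores (permutation
# invariant), trained with class-weighted binary cross-entropy.

#' Training configuration for the MIL disease classifier
#'
#' Full-scale defaults follow the protocol this package mirrors: 224-px (112-um) patches, 10,000
#' training / 1000 evaluation patches per slide, SGD with learning rate 1e-4
#' and momentum 0.5, 3 epochs, threefold slide-level cross validation,
#' 1024-d embedding. The `"test"` preset cuts patch counts and widths and
#' raises the learning rate/epochs to fit the reduced step count.
#'
#' @param preset `"full"` or `"test"`.
#' @param ... overrides.
#' @return list of class `tauwm_mil_cfg`.
#' @export
mil_config <- function(preset = c("full", "test"), ...) {
  preset <- match.arg(preset)
  cfg <- list(patch_um = 112, mpp = 0.5,
              patches_per_slide_train = 10000L, patches_per_slide_eval = 1000L,
              bag_size = 32L, optimizer = "sgd", lr = 1e-4, momentum = 0.5,
              epochs = 3L, n_folds = 3L, embedding_dim = 1024L,
              widths = c(16L, 32L, 64L, 128L), pool_stem = 1L,
              augment = TRUE, hue_range = 0.05, sat_range = 0.1,
              cutout = FALSE, cutout_prob = 1, train_focus_frac = 0,
              weight_decay = 0, class_weights = NULL, seed = 1L)
  if (preset == "test") {
    cfg$patches_per_slide_train <- 64L
    cfg$patches_per_slide_eval <- 40L
    cfg$widths <- c(8L, 8L, 16L, 32L, 48L)
    cfg$strides <- rep(2L, 5L)
    cfg$optimizer <- "adam"
    cfg$lr <- 2e-3
    cfg$epochs <- 10L
    cfg$bag_size <- 8L
    cfg$augment <- FALSE
    cfg$cutout <- TRUE
    cfg$cutout_prob <- 0.5
    cfg$train_focus_frac <- 0.5
    cfg$weight_decay <- 5e-4
  }
  ov <- list(...)
  cfg[names(ov)] <- ov
  cfg$patch_px <- as.integer(round(cfg$patch_um / cfg$mpp))
  class(cfg) <- "tauwm_mil_cfg"
  cfg
}

#' Sample patches restricted to one region of a slide
#'
#' Patch centres are drawn uniformly from pixels of the requested region,
#' with the patch fully inside the slide. With `focus_frac > 0`, that
#' fraction of centres is drawn from DAB-positive pixels (optical density
#' above `focus_od`, computed from the image itself): used at training time
#' so that every disease contributes stain-bearing patches and the
#' classifier must rely on aggregate appearance rather than patch density
#' alone. Evaluation sampling stays uniform (`focus_frac = 0`).
#'
#' @param slide a `tauwm_slide`.
#' @param region_mask integer region raster.
#' @param region `"CTX"` or `"WM"`.
#' @param n number of patches.
#' @param patch_px patch side.
#' @param focus_frac fraction of patch centres drawn from DAB-positive
#'   pixels (default 0 = uniform).
#' @param focus_od DAB optical-density threshold defining positive pixels.
#' @return list with `patches` and `centers`.
#' @export
sample_region_patches <- function(slide, region_mask, region = c("WM", "CTX"),
                                  n, patch_px = 224L, focus_frac = 0,
                                  focus_od = 0.3) {
  region <- match.arg(region)
  rid <- if (region == "WM") 2L else 1L
  d <- dim(slide$pixels)
  half <- patch_px %/% 2L
  ri <- half:(d[1] - half); ci <- half:(d[2] - half)
  inner <- region_mask[ri, ci, drop = FALSE]
  cand <- which(inner == rid)
  if (!length(cand)) stop("region has no valid patch centres")
  pick <- sample(cand, n, replace = length(cand) < n)
  if (focus_frac > 0) {
    dab <- deconvolve_stains(slide$pixels,
                             list(hem = c(0.65, 0.70, 0.29),
                                  dab = c(0.27, 0.57, 0.78)))$dab
    pos <- which(inner == rid & dab[ri, ci] > focus_od)
    if (length(pos)) {
      nf <- min(round(focus_frac * n), n)
      if (nf > 0)
        pick[seq_len(nf)] <- sample(pos, nf, replace = length(pos) < nf)
    }
  }
  centers <- cbind((pick - 1L) %% nrow(inner) + ri[1],
                   (pick - 1L) %/% nrow(inner) + ci[1])
  img <- slide$pixels / 255
  patches <- lapply(seq_len(n), function(t) {
    i <- centers[t, 1]; j <- centers[t, 2]
    img[(i - half + 1L):(i + half), (j - half + 1L):(j + half), , drop = FALSE]
  })
  list(patches = patches, centers = centers)
}

#' Group patches of one slide/region into bags
#'
#' Random partition into bags of `bag_size`; every bag inherits the
#' slide-level disease label. Fewer patches than `bag_size` yield a single
#' smaller bag.
#'
#' @param patches list of patch arrays from one slide and region.
#' @param label disease label of the slide.
#' @param bag_size patches per bag.
#' @param slide_id,region bag metadata.
#' @return list of bags `list(patches, label, slide_id, region)`.
#' @export
make_bags <- function(patches, label, bag_size = 32L, slide_id = "slide",
                      region = "WM") {
  n <- length(patches)
  if (n == 0) return(list())
  ord <- sample(n)
  starts <- seq(1L, n, by = bag_size)
  lapply(starts, function(s) {
    ids <- ord[s:min(s + bag_size - 1L, n)]
    list(patches = patches[ids], label = label, slide_id = slide_id,
         region = region)
  })
}

# cutout augmentation: blank 1-2 random rectangles with a light background
# tone. Within-patch aggregate count correlates with disease in a small
# cohort; erasing random subregions decorrelates that shortcut and pushes
# the classifier toward aggregate appearance.
cutout_patch <- function(x) {
  d <- dim(x)
  bg <- c(0.93, 0.91, 0.96)
  for (k in seq_len(sample(1:2, 1))) {
    h <- sample.int(floor(d[1] * 0.45), 1L) + 10L
    w <- sample.int(floor(d[2] * 0.45), 1L) + 10L
    i <- sample.int(d[1] - h + 1L, 1L); j <- sample.int(d[2] - w + 1L, 1L)
    for (ch in 1:3) x[i:(i + h - 1L), j:(j + w - 1L), ch] <- bg[ch]
  }
  x
}

mil_model_new <- function(cfg) {
  nlev <- length(cfg$widths)
  strides <- cfg$strides %||% rep(2L, nlev)
  ks <- cfg$kernels %||% rep(3L, nlev)
  backbone <- convstack_new(cfg$widths, strides, k = ks)
  # spatial pooling concatenates the per-channel mean and max over positions:
  # sparse aggregates leave most positions empty, so the max channel carries
  # the "a distinctive structure is present somewhere" signal
  emb <- dense_layer(2L * cfg$widths[nlev], cfg$embedding_dim, act = "relu")
  out <- dense_layer(cfg$embedding_dim, 3L, act = "linear")
  structure(list(backbone = backbone, emb = emb, out = out, cfg = cfg,
                 classes = DISEASES), class = "tauwm_mil_model")
}

# fixed 2x2 min-pool stem (no learnable parameters; gradients stop at the
# image). Min rather than mean: stain is dark-on-light, so the darkest pixel
# of each 2x2 cell preserves 1-2 px strokes that averaging would wash out.
pool2 <- function(x) {
  d <- dim(x)
  io <- seq(1, d[1] - 1, by = 2); jo <- seq(1, d[2] - 1, by = 2)
  pmin(x[io, jo, , drop = FALSE], x[io + 1, jo, , drop = FALSE],
       x[io, jo + 1, , drop = FALSE], x[io + 1, jo + 1, , drop = FALSE])
}

mil_patch_fw <- function(model, x) {
  ps <- model$cfg$pool_stem %||% 1L
  while (ps > 1L) { x <- pool2(x); ps <- ps %/% 2L }
  r <- convstack_fw(model$backbone, norm_img(x))
  d <- dim(r$out)
  npos <- d[1] * d[2]
  m <- matrix(r$out, npos, d[3])
  argmx <- max.col(t(m), ties.method = "first")
  pooled <- c(colMeans(m), m[cbind(argmx, seq_len(d[3]))])
  fe <- dense_fw(model$emb, matrix(pooled, 1))
  fo <- dense_fw(model$out, matrix(fe$out, 1))
  list(scores = 1 / (1 + exp(-fo$out)), logits = fo$out,
       embedding = fe$out,
       caches = list(conv = r$caches, emb = fe$cache, out = fo$cache,
                     pooled_dim = d, argmx = argmx))
}

mil_patch_bw <- function(model, caches, dlogits) {
  bo <- dense_bw(model$out, caches$out, dlogits)
  be <- dense_bw(model$emb, caches$emb, bo$dx)
  d <- caches$pooled_dim
  npos <- d[1] * d[2]
  dmean <- be$dx[seq_len(d[3])]
  dmax <- be$dx[d[3] + seq_len(d[3])]
  dm <- matrix(rep(dmean / npos, each = npos), npos, d[3])
  dm[cbind(caches$argmx, seq_len(d[3]))] <-
    dm[cbind(caches$argmx, seq_len(d[3]))] + dmax
  gb <- convstack_bw(model$backbone, caches$conv, array(dm, d))
  gb$emb.W <- be$dW; gb$emb.b <- be$db
  gb$out.W <- bo$dW; gb$out.b <- bo$db
  gb
}

mil_params <- function(model) {
  p <- layers_params(model$backbone)
  p$emb.W <- model$emb$W; p$emb.b <- model$emb$b
  p$out.W <- model$out$W; p$out.b <- model$out$b
  p
}

mil_set_params <- function(model, p) {
  model$backbone <- layers_set_params(model$backbone, p)
  model$emb$W <- p$emb.W; model$emb$b <- p$emb.b
  model$out$W <- p$out.W; model$out$b <- p$out.b
  model
}

#' Train a MIL disease classifier on bags
#'
#' The bag score is the mean of the per-patch sigmoid scores; the loss is
#' class-weighted binary cross-entropy of the three one-vs-rest bag scores
#' against the one-hot slide label.
#'
#' @param bags list of bags from [make_bags()].
#' @param cfg a [mil_config()].
#' @param bag_sampler optional function(epoch) returning a fresh list of
#'   bags; when supplied, every epoch trains on newly sampled patches
#'   (mirrors the full-scale protocol's large per-slide patch supply at desk
#'   scale).
#' @return a `tauwm_mil_model` with training `history`.
#' @export
train_mil <- function(bags, cfg = mil_config(), bag_sampler = NULL) {
  labs <- vapply(bags, `[[`, "", "label")
  if (length(unique(labs)) < 2) stop("need at least two diseases to train")
  set.seed(cfg$seed)
  model <- mil_model_new(cfg)
  y <- match(labs, DISEASES)
  w <- cfg$class_weights
  if (is.null(w)) {
    cnt <- tabulate(y, 3L)
    w <- ifelse(cnt > 0, length(y) / (3 * pmax(cnt, 1)), 0)
  }
  params <- mil_params(model)
  opt <- opt_init(cfg$optimizer, lr = cfg$lr, momentum = cfg$momentum,
                  weight_decay = cfg$weight_decay %||% 0)
  history <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    if (!is.null(bag_sampler) && ep > 1L) {
      bags <- list()   # release the previous epoch's patches before sampling
      gc(FALSE)
      bags <- bag_sampler(ep)
      labs <- vapply(bags, `[[`, "", "label")
      y <- match(labs, DISEASES)
    }
    ord <- sample(length(bags))
    tl <- 0
    for (id in ord) {
      bag <- bags[[id]]
      model <- mil_set_params(model, params)
      px <- bag$patches
      if (isTRUE(cfg$augment))
        px <- lapply(px, augment_patch, hue_range = cfg$hue_range,
                     sat_range = cfg$sat_range)
      if (isTRUE(cfg$cutout) && stats::runif(1) < (cfg$cutout_prob %||% 1))
        px <- lapply(px, cutout_patch)
      fws <- lapply(px, function(x) mil_patch_fw(model, x))
      scores <- do.call(rbind, lapply(fws, `[[`, "scores"))
      s <- pmin(pmax(colMeans(scores), 1e-7), 1 - 1e-7)
      target <- as.numeric(DISEASES == bag$label)
      wb <- w[y[id]]
      tl <- tl + wb * sum(-(target * log(s) + (1 - target) * log(1 - s)))
      dds <- wb * (-(target / s) + (1 - target) / (1 - s))   # dL/d bagscore
      gacc <- NULL
      np <- length(bag$patches)
      for (t in seq_len(np)) {
        sig <- fws[[t]]$scores
        dlogit <- dds * sig * (1 - sig) / np
        g <- mil_patch_bw(model, fws[[t]]$caches, drop(dlogit))
        gacc <- if (is.null(gacc)) g else
          stats::setNames(lapply(names(g), function(nm) gacc[[nm]] + g[[nm]]),
                          names(g))
      }
      st <- opt_step(opt, params, gacc)
      opt <- st$opt; params <- st$params
    }
    history[ep] <- tl / length(bags)
  }
  model <- mil_set_params(model, params)
  model$class_weights <- w
  model$history <- history
  model
}

#' Per-patch disease scores and class
#'
#' @param model a trained `tauwm_mil_model`.
#' @param patch one patch array.
#' @return list with `scores` (3 sigmoids) and `class` (disease name).
#' @export
predict_patch <- function(model, patch) {
  fw <- mil_patch_fw(model, patch)
  s <- drop(fw$scores)
  list(scores = s, class = DISEASES[which.max(s)])
}

#' Slide-level prediction by majority vote over patches
#'
#' @param model trained model.
#' @param patches evaluation patches of one slide (the full-scale protocol
#'   uses 1000 per slide).
#' @return list with `class`, `votes` (counts) and `fractions`.
#' @export
predict_slide <- function(model, patches) {
  cls <- vapply(patches, function(p) predict_patch(model, p)$class, "")
  votes <- table(factor(cls, levels = DISEASES))
  list(class = DISEASES[which.max(votes)], votes = c(votes),
       fractions = c(votes) / length(cls))
}

#' Combine cortex and white-matter patch votes
#'
#' Averages the two models' patch-vote fractions and takes the argmax. Ties
#' are broken toward the class with the larger single-model fraction, then
#' the lowest class index.
#'
#' @param ctx_fractions,wm_fractions named numeric vote fractions over the
#'   three diseases.
#' @return predicted disease name.
#' @export
combine_region_predictions <- function(ctx_fractions, wm_fractions) {
  stopifnot(length(ctx_fractions) == 3, length(wm_fractions) == 3)
  avg <- (ctx_fractions + wm_fractions) / 2
  m <- max(avg)
  tied <- which(avg >= m - 1e-12)
  if (length(tied) == 1) return(DISEASES[tied])
  best_single <- pmax(ctx_fractions, wm_fractions)[tied]
  DISEASES[tied[which.max(best_single)]]
}

#' Patch accuracy of a MIL model
#'
#' @param model trained model.
#' @param patches,labels evaluation patches with true disease labels.
#' @return fraction of patches assigned their slide's disease.
#' @export
mil_patch_accuracy <- function(model, patches, labels) {
  pred <- vapply(patches, function(p) predict_patch(model, p)$class, "")
  mean(pred == labels)
}
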