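# Aggregate segmentation: background / aggregate / edge pixel classifier.
#
# A small UNet (3 resolution levels, configurable base width) with a
# per-pixel weighted cross-entropy loss plus an image-level "edge amount"
# penalty that pushes the predicted mean edge probability toward the ground
# truth's mean edge indicator (guards against over-/under-splitting of
# aggregates). Inference runs tiled with 50% overlap and response averaging;
# winning aggregate/edge responses below the response threshold fall back to
# background.

AGG_CLASSES <- c("background", "aggregate", "edge")

#' Training configuration for the aggregate model
#'
#' Full-scale defaults follow the protocol this package mirrors: 400-px tiles, SGD with learning
#' rate 1e-3 and momentum 0.5, 50 epochs, twofold slide-level cross
#' validation, response threshold 0.5, edge-amount loss weight 1. The
#' `"test"` preset uses 96-px tiles, base width 8 and fewer epochs.
#'
#' @param preset `"full"` or `"test"`.
#' @param ... overrides.
#' @return list of class `tauwm_agg_cfg`.
#' @export
aggregate_train_config <- function(preset = c("full", "test"), ...) {
  preset <- match.arg(preset)
  cfg <- list(tile_px = 400L, optimizer = "sgd", lr = 1e-3, momentum = 0.5,
              epochs = 50L, n_folds = 2L, edge_loss_weight = 1.0,
              response_threshold = 0.5, base_width = 16L,
              tiles_per_slide = 60L, augment = TRUE,
              class_weights = NULL, seed = 1L)
  if (preset == "test") {
    cfg$tile_px <- 64L
    cfg$base_width <- 8L
    cfg$epochs <- 16L
    cfg$tiles_per_slide <- 40L
    cfg$optimizer <- "adam"
  }
  ov <- list(...)
  cfg[names(ov)] <- ov
  class(cfg) <- "tauwm_agg_cfg"
  cfg
}

#' Image-level edge-amount loss
#'
#' `lambda * |mean(predicted edge probability) - mean(true edge indicator)|`.
#' Non-negative; zero exactly when the two means agree.
#'
#' @param pred_edge_prob numeric raster of predicted edge probabilities.
#' @param true_mask integer raster in `{0, 1, 2}` (2 = edge).
#' @param lambda weight.
#' @return scalar loss.
#' @export
edge_amount_loss <- function(pred_edge_prob, true_mask, lambda = 1) {
  lambda * abs(mean(pred_edge_prob) - mean(true_mask == 2L))
}

# ---- UNet ----------------------------------------------------------------

unet_new <- function(base_width = 16L, in_ch = 3L) {
  w <- base_width
  layers <- list(
    e1a = conv_layer(in_ch, w), e1b = conv_layer(w, w),
    d1 = conv_layer(w, 2 * w, stride = 2L), e2 = conv_layer(2 * w, 2 * w),
    d2 = conv_layer(2 * w, 4 * w, stride = 2L), bb = conv_layer(4 * w, 4 * w),
    u1 = conv_layer(4 * w, 2 * w), m1 = conv_layer(4 * w, 2 * w),
    u2 = conv_layer(2 * w, w), m2 = conv_layer(2 * w, w),
    head = conv_layer(w, 3L, k = 1L, pad = 0L, act = "linear"))
  structure(list(layers = layers, base_width = w), class = "tauwm_unet")
}

abind3 <- function(a, b) {
  d <- dim(a)
  array(c(a, b), c(d[1], d[2], d[3] + dim(b)[3]))
}

unet_fw <- function(net, x) {
  L <- net$layers
  x <- norm_img(x)
  c1a <- conv_fw(L$e1a, x);  c1b <- conv_fw(L$e1b, c1a$out)
  cd1 <- conv_fw(L$d1, c1b$out); c2 <- conv_fw(L$e2, cd1$out)
  cd2 <- conv_fw(L$d2, c2$out);  cb <- conv_fw(L$bb, cd2$out)
  up1 <- upsample2_fw(cb$out)
  cu1 <- conv_fw(L$u1, up1)
  cm1 <- conv_fw(L$m1, abind3(cu1$out, c2$out))
  up2 <- upsample2_fw(cm1$out)
  cu2 <- conv_fw(L$u2, up2)
  cm2 <- conv_fw(L$m2, abind3(cu2$out, c1b$out))
  ch <- conv_fw(L$head, cm2$out)
  list(logits = ch$out,
       caches = list(c1a = c1a, c1b = c1b, cd1 = cd1, c2 = c2, cd2 = cd2,
                     cb = cb, cu1 = cu1, cm1 = cm1, cu2 = cu2, cm2 = cm2,
                     ch = ch))
}

unet_bw <- function(net, caches, dlogits) {
  L <- net$layers; C <- caches
  g <- list()
  bh <- conv_bw(L$head, C$ch$cache, dlogits)
  g$head <- bh
  bm2 <- conv_bw(L$m2, C$cm2$cache, bh$dx); g$m2 <- bm2
  w <- net$base_width
  d <- dim(bm2$dx)
  du2 <- bm2$dx[, , seq_len(w), drop = FALSE]
  dskip1 <- bm2$dx[, , w + seq_len(w), drop = FALSE]
  bu2 <- conv_bw(L$u2, C$cu2$cache, du2); g$u2 <- bu2
  bm1 <- conv_bw(L$m1, C$cm1$cache, upsample2_bw(bu2$dx)); g$m1 <- bm1
  du1 <- bm1$dx[, , seq_len(2 * w), drop = FALSE]
  dskip2 <- bm1$dx[, , 2 * w + seq_len(2 * w), drop = FALSE]
  bu1 <- conv_bw(L$u1, C$cu1$cache, du1); g$u1 <- bu1
  bb_ <- conv_bw(L$bb, C$cb$cache, upsample2_bw(bu1$dx)); g$bb <- bb_
  bd2 <- conv_bw(L$d2, C$cd2$cache, bb_$dx); g$d2 <- bd2
  b2 <- conv_bw(L$e2, C$c2$cache, bd2$dx + dskip2); g$e2 <- b2
  bd1 <- conv_bw(L$d1, C$cd1$cache, b2$dx); g$d1 <- bd1
  b1b <- conv_bw(L$e1b, C$c1b$cache, bd1$dx + dskip1); g$e1b <- b1b
  b1a <- conv_bw(L$e1a, C$c1a$cache, b1b$dx); g$e1a <- b1a
  out <- list()
  for (nm in names(g)) {
    out[[paste0(nm, ".W")]] <- g[[nm]]$dW
    out[[paste0(nm, ".b")]] <- g[[nm]]$db
  }
  out
}

unet_params <- function(net) {
  out <- list()
  for (nm in names(net$layers)) {
    out[[paste0(nm, ".W")]] <- net$layers[[nm]]$W
    out[[paste0(nm, ".b")]] <- net$layers[[nm]]$b
  }
  out
}

unet_set_params <- function(net, params) {
  for (nm in names(net$layers)) {
    net$layers[[nm]]$W <- params[[paste0(nm, ".W")]]
    net$layers[[nm]]$b <- params[[paste0(nm, ".b")]]
  }
  net
}

# per-pixel weighted CE + edge-amount term; returns loss and dlogits array
agg_tile_loss <- function(logits, y, w, lambda) {
  d <- dim(logits)
  n <- d[1] * d[2]
  lm <- matrix(logits, n, 3)
  p <- softmax_rows(lm)
  yv <- as.integer(y) + 1L
  wi <- w[yv]
  ce <- -log(pmax(p[cbind(seq_len(n), yv)], 1e-12))
  loss_ce <- sum(wi * ce) / sum(wi)
  dl <- p
  dl[cbind(seq_len(n), yv)] <- dl[cbind(seq_len(n), yv)] - 1
  dl <- dl * (wi / sum(wi))
  true_edge <- mean(yv == 3L)
  pred_edge <- mean(p[, 3])
  loss_edge <- abs(pred_edge - true_edge)
  s <- sign(pred_edge - true_edge)
  # d mean(p_edge) / d logits = p_e * (1[c=e] - p_c) / n
  dedge <- p[, 3] * (cbind(0, 0, 1) [rep(1, n), ] - p) / n
  dl <- dl + lambda * s * dedge
  list(loss = loss_ce + lambda * loss_edge, dlogits = array(dl, d))
}

#' Sample annotation tiles from a slide and its pixel mask
#'
#' @param slide a `tauwm_slide`.
#' @param pixel_mask integer ground-truth raster in `{0, 1, 2}`.
#' @param tile_px tile side.
#' @param n number of tiles.
#' @return list of `list(x, y)` pairs (image in `[0, 1]`, label matrix).
#' @export
sample_aggregate_tiles <- function(slide, pixel_mask, tile_px, n) {
  d <- dim(slide$pixels)
  if (d[1] < tile_px || d[2] < tile_px) stop("slide smaller than tile")
  img <- slide$pixels / 255
  lapply(seq_len(n), function(t) {
    i <- sample.int(d[1] - tile_px + 1L, 1L)
    j <- sample.int(d[2] - tile_px + 1L, 1L)
    list(x = img[i:(i + tile_px - 1L), j:(j + tile_px - 1L), , drop = FALSE],
         y = pixel_mask[i:(i + tile_px - 1L), j:(j + tile_px - 1L)])
  })
}

train_unet_once <- function(tiles, cfg) {
  net <- unet_new(cfg$base_width)
  w <- cfg$class_weights
  if (is.null(w)) {
    cnt <- numeric(3)
    for (t in tiles) cnt <- cnt + tabulate(as.integer(t$y) + 1L, 3L)
    if (any(cnt == 0))
      warning("class absent from all tiles; its weight set to zero")
    tot <- sum(cnt)
    w <- ifelse(cnt > 0, tot / (3 * pmax(cnt, 1)), 0)
  }
  params <- unet_params(net)
  opt <- opt_init(cfg$optimizer, lr = cfg$lr, momentum = cfg$momentum)
  history <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(length(tiles))
    tl <- 0
    for (id in ord) {
      x <- tiles[[id]]$x; y <- tiles[[id]]$y
      if (cfg$augment) {
        if (stats::runif(1) < 0.5) {
          x <- x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
          y <- y[, rev(seq_len(ncol(y)))]
        }
        if (stats::runif(1) < 0.5) {
          x <- x[rev(seq_len(dim(x)[1])), , , drop = FALSE]
          y <- y[rev(seq_len(nrow(y))), ]
        }
      }
      net <- unet_set_params(net, params)
      fw <- unet_fw(net, x)
      lo <- agg_tile_loss(fw$logits, y, w, cfg$edge_loss_weight)
      tl <- tl + lo$loss
      g <- unet_bw(net, fw$caches, lo$dlogits)
      st <- opt_step(opt, params, g)
      opt <- st$opt; params <- st$params
    }
    history[ep] <- tl / length(tiles)
  }
  net <- unet_set_params(net, params)
  structure(list(net = net, cfg = cfg, class_weights = w, history = history),
            class = "tauwm_agg_model")
}

#' Train the aggregate segmentation model
#'
#' Tiles are grouped by slide; a twofold slide-level split (equal diseases
#' per fold when labels are supplied) trains one model per fold and the model
#' with the higher cross-validation pixel accuracy is returned. With
#' `n_folds = 1` a single model is trained on everything.
#'
#' @param tiles list of `list(x, y, slide_id, disease)` tiles.
#' @param cfg an [aggregate_train_config()].
#' @return a `tauwm_agg_model` (with `cv_accuracy` when folds were used).
#' @export
train_aggregate_model <- function(tiles, cfg = aggregate_train_config()) {
  set.seed(cfg$seed)
  if (cfg$n_folds <= 1L) return(train_unet_once(tiles, cfg))
  sid <- vapply(tiles, function(t) t$slide_id %||% "s", "")
  slides <- unique(sid)
  dis <- vapply(slides, function(s)
    (tiles[[match(s, sid)]]$disease) %||% "X", "")
  fold <- crossval_split(dis, k = cfg$n_folds, seed = cfg$seed)
  best <- NULL
  for (f in seq_len(cfg$n_folds)) {
    tr <- tiles[sid %in% slides[fold != f]]
    te <- tiles[sid %in% slides[fold == f]]
    m <- train_unet_once(tr, cfg)
    acc <- mean(vapply(te, function(t) {
      pr <- predict_aggregate_tile(m, t$x)
      mean(pr == t$y)
    }, numeric(1)))
    m$cv_accuracy <- acc
    if (is.null(best) || acc > best$cv_accuracy) best <- m
  }
  best
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# raw responses for one tile (softmax over the 3 classes)
aggregate_tile_responses <- function(model, x) {
  fw <- unet_fw(model$net, x)
  d <- dim(fw$logits)
  array(softmax_rows(matrix(fw$logits, ncol = 3)), d)
}

predict_aggregate_tile <- function(model, x,
                                   response_threshold = model$cfg$response_threshold) {
  resp <- aggregate_tile_responses(model, x)
  threshold_responses(resp, response_threshold)
}

# argmax with background fallback when the winning non-background response
# is below the threshold
threshold_responses <- function(resp, threshold) {
  d <- dim(resp)
  m <- matrix(resp, ncol = 3)
  cl <- max.col(m, ties.method = "first")
  win <- m[cbind(seq_len(nrow(m)), cl)]
  cl[cl != 1L & win < threshold] <- 1L
  matrix(cl - 1L, d[1], d[2])
}

#' Segment a whole slide into background / aggregate / edge
#'
#' Tiled inference with 50% overlap: per-pixel responses are averaged across
#' overlapping tiles, then argmaxed with the background fallback below
#' `response_threshold`.
#'
#' @param model a `tauwm_agg_model`.
#' @param slide a `tauwm_slide` (or an RGB array).
#' @param response_threshold response threshold (default from the config).
#' @param tile_px inference tile size (default from the config).
#' @param return_responses also return the averaged response array.
#' @return integer mask `{0, 1, 2}`; if `return_responses`, a list
#'   `(labels, responses)`.
#' @export
predict_aggregate_mask <- function(model, slide,
                                   response_threshold = model$cfg$response_threshold,
                                   tile_px = model$cfg$tile_px,
                                   return_responses = FALSE) {
  img <- if (inherits(slide, "tauwm_slide")) slide$pixels / 255 else slide
  d <- dim(img)
  tile_px <- min(tile_px, d[1], d[2])
  step <- max(1L, tile_px %/% 2L)
  acc <- array(0, c(d[1], d[2], 3))
  cnt <- matrix(0, d[1], d[2])
  is_ <- unique(c(seq(1L, max(1L, d[1] - tile_px + 1L), by = step),
                  d[1] - tile_px + 1L))
  js_ <- unique(c(seq(1L, max(1L, d[2] - tile_px + 1L), by = step),
                  d[2] - tile_px + 1L))
  for (i in is_) for (j in js_) {
    ri <- i:(i + tile_px - 1L); rj <- j:(j + tile_px - 1L)
    resp <- aggregate_tile_responses(model, img[ri, rj, , drop = FALSE])
    acc[ri, rj, ] <- acc[ri, rj, , drop = FALSE] + resp
    cnt[ri, rj] <- cnt[ri, rj] + 1
  }
  for (ch in 1:3) acc[, , ch] <- acc[, , ch] / cnt
  labels <- threshold_responses(acc, response_threshold)
  if (return_responses) list(labels = labels, responses = acc) else labels
}

#' Pixel accuracy of an aggregate model on labelled tiles
#'
#' @param model trained model; `tiles` as in [train_aggregate_model()].
#' @return mean fraction of correctly labelled pixels.
#' @export
aggregate_pixel_accuracy <- function(model, tiles) {
  mean(vapply(tiles, function(t)
    mean(predict_aggregate_tile(model, t$x) == t$y), numeric(1)))
}
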