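# Minimal CPU convolutional-network engine.
#
# Images are numeric arrays dim c(H, W, C) with values roughly in [0, 1].
# Convolutions are expressed as im2col (C++) followed by a BLAS matrix
# product; backprop is hand-derived. This is deliberately small: the models
# in this package are desk-scale stand-ins for the GPU networks they mirror.

# centre/scale an RGB image before the first conv layer: stained-slide
# pixels cluster near white, so raw [0,1] inputs are poorly conditioned
norm_img <- function(x) (x - 0.8) * 2

he_init <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

#' @noRd
conv_layer <- function(cin, cout, k = 3, stride = 1, pad = NULL, act = "relu") {
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  list(type = "conv", cin = cin, cout = cout, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad), act = act,
       W = he_init(k * k * cin, cout), b = numeric(cout))
}

dense_layer <- function(din, dout, act = "linear") {
  list(type = "dense", din = din, dout = dout, act = act,
       W = he_init(din, dout), b = numeric(dout))
}

conv_fw <- function(layer, x) {
  d <- dim(x)
  cols <- im2col_cpp(x, d[1], d[2], d[3], layer$k, layer$stride, layer$pad)
  y <- cols %*% layer$W
  y <- y + rep(layer$b, each = nrow(y))
  ho <- (d[1] + 2 * layer$pad - layer$k) %/% layer$stride + 1L
  wo <- (d[2] + 2 * layer$pad - layer$k) %/% layer$stride + 1L
  pre <- y
  if (layer$act == "relu") y <- pmax(y, 0)
  list(out = array(y, c(ho, wo, layer$cout)),
       cache = list(cols = cols, pre = pre, din = d))
}

conv_bw <- function(layer, cache, dy) {
  # dy: array (ho, wo, cout) or matrix (ho*wo, cout)
  dy <- matrix(dy, ncol = layer$cout)
  if (layer$act == "relu") dy <- dy * (cache$pre > 0)
  dW <- crossprod(cache$cols, dy)
  db <- colSums(dy)
  dcols <- tcrossprod(dy, layer$W)
  dx <- col2im_cpp(dcols, cache$din[1], cache$din[2], cache$din[3],
                   layer$k, layer$stride, layer$pad)
  list(dW = dW, db = db, dx = dx)
}

dense_fw <- function(layer, x) {
  pre <- drop(x %*% layer$W) + layer$b
  out <- if (layer$act == "relu") pmax(pre, 0) else pre
  list(out = out, cache = list(x = x, pre = pre))
}

dense_bw <- function(layer, cache, dy) {
  if (layer$act == "relu") dy <- dy * (cache$pre > 0)
  list(dW = outer(drop(cache$x), dy), db = dy, dx = drop(layer$W %*% dy))
}

upsample2_fw <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
}

upsample2_bw <- function(dy) {
  d <- dim(dy)
  io <- seq(1, d[1], by = 2); jo <- seq(1, d[2], by = 2)
  dy[io, jo, , drop = FALSE] + dy[io + 1, jo, , drop = FALSE] +
    dy[io, jo + 1, , drop = FALSE] + dy[io + 1, jo + 1, , drop = FALSE]
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Weighted softmax cross-entropy over rows.
# y: integer class (1-based); w: per-class weights. Returns loss and dlogits.
softmax_ce <- function(logits, y, w) {
  p <- softmax_rows(logits)
  n <- nrow(p)
  wi <- w[y]
  ll <- -log(pmax(p[cbind(seq_len(n), y)], 1e-12))
  loss <- sum(wi * ll) / sum(wi)
  d <- p
  d[cbind(seq_len(n), y)] <- d[cbind(seq_len(n), y)] - 1
  d <- d * (wi / sum(wi))
  list(loss = loss, dlogits = d)
}

# ---- optimiser ------------------------------------------------------------

opt_init <- function(kind = c("sgd", "adam"), lr = 1e-3, momentum = 0.5,
                     weight_decay = 0) {
  kind <- match.arg(kind)
  list(kind = kind, lr = lr, momentum = momentum, weight_decay = weight_decay,
       beta1 = 0.9, beta2 = 0.999, eps = 1e-8, t = 0L, state = list())
}

# params/grads: flat named lists of matrices/vectors; returns updated
# params and optimiser.
opt_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (opt$weight_decay > 0 && grepl("W", nm))
      g <- g + opt$weight_decay * params[[nm]]
    if (opt$kind == "sgd") {
      v <- opt$state[[nm]]
      if (is.null(v)) v <- g * 0
      v <- opt$momentum * v + g
      opt$state[[nm]] <- v
      params[[nm]] <- params[[nm]] - opt$lr * v
    } else {
      st <- opt$state[[nm]]
      if (is.null(st)) st <- list(m = g * 0, v = g * 0)
      st$m <- opt$beta1 * st$m + (1 - opt$beta1) * g
      st$v <- opt$beta2 * st$v + (1 - opt$beta2) * g * g
      opt$state[[nm]] <- st
      mhat <- st$m / (1 - opt$beta1^opt$t)
      vhat <- st$v / (1 - opt$beta2^opt$t)
      params[[nm]] <- params[[nm]] - opt$lr * mhat / (sqrt(vhat) + opt$eps)
    }
  }
  list(opt = opt, params = params)
}

# helpers to move layer weights to/from a flat list
layers_params <- function(layers) {
  out <- list()
  for (i in seq_along(layers)) {
    if (!is.null(layers[[i]]$W)) {
      out[[paste0("W", i)]] <- layers[[i]]$W
      out[[paste0("b", i)]] <- layers[[i]]$b
    }
  }
  out
}

layers_set_params <- function(layers, params) {
  for (i in seq_along(layers)) {
    if (!is.null(layers[[i]]$W)) {
      layers[[i]]$W <- params[[paste0("W", i)]]
      layers[[i]]$b <- params[[paste0("b", i)]]
    }
  }
  layers
}

# ---- augmentations --------------------------------------------------------

hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 1) * 6
  i <- pmin(floor(h), 5)
  f <- h - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  n <- length(h)
  gather <- function(code) {
    out <- numeric(n)
    out[code == 1] <- v[code == 1]
    out[code == 2] <- p[code == 2]
    out[code == 3] <- q[code == 3]
    out[code == 4] <- t[code == 4]
    out
  }
  # codes: 1=v, 2=p, 3=q, 4=t
  rc <- c(1, 3, 2, 2, 4, 1)[i + 1]
  gc <- c(4, 1, 1, 3, 2, 2)[i + 1]
  bc <- c(2, 2, 4, 1, 1, 3)[i + 1]
  cbind(gather(rc), gather(gc), gather(bc))
}

# random flips plus additive hue/saturation jitter, mirroring the named
# augmentations; x in [0,1], dim c(H, W, 3)
augment_patch <- function(x, hue_range = 0.05, sat_range = 0.1) {
  if (stats::runif(1) < 0.5) x <- x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
  if (stats::runif(1) < 0.5) x <- x[rev(seq_len(dim(x)[1])), , , drop = FALSE]
  dh <- stats::runif(1, -hue_range, hue_range)
  ds <- stats::runif(1, -sat_range, sat_range)
  d <- dim(x)
  m <- matrix(x, ncol = 3)
  hsv <- t(grDevices::rgb2hsv(t(m) * 255, maxColorValue = 255))
  rgb <- hsv_to_rgb(hsv[, 1] + dh, pmin(pmax(hsv[, 2] + ds, 0), 1), hsv[, 3])
  array(rgb, d)
}

# ---- plain sequential conv stack (used by region FCN and MIL backbone) ----

convstack_new <- function(widths, strides, in_ch = 3, k = 3) {
  stopifnot(length(widths) == length(strides))
  if (length(k) == 1) k <- rep(k, length(widths))
  layers <- list()
  cin <- in_ch
  for (i in seq_along(widths)) {
    layers[[i]] <- conv_layer(cin, widths[i], k = k[i], stride = strides[i])
    cin <- widths[i]
  }
  layers
}

convstack_fw <- function(layers, x) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- conv_fw(layers[[i]], x)
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

convstack_bw <- function(layers, caches, dy) {
  grads <- list()
  for (i in rev(seq_along(layers))) {
    r <- conv_bw(layers[[i]], caches[[i]], dy)
    grads[[paste0("W", i)]] <- r$dW
    grads[[paste0("b", i)]] <- r$db
    dy <- r$dx
  }
  grads
}
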