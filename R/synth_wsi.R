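# Synthetic AT8-IHC slide generator.
#
# Emulates the data regime of AT8-stained frontal-lobe sections: a background
# margin, a cortical band and a white-matter band; DAB-brown tau aggregates on
# a hematoxylin-toned tissue; disease-specific aggregate shapes (AD short and
# curly, PSP long/thin/straight, CBD large round blobs); disease-specific
# WM:CTX burden ratios; and rare weak nuclear-staining artifacts. Every slide
# comes with pixel-perfect ground truth so downstream models are trainable
# and testable without external data.

#' The three tauopathy labels
#' @export
DISEASES <- c("AD", "PSP", "CBD")

default_burden_slopes <- c(AD = 0.10, PSP = 1 / 3, CBD = 3 / 4)

default_shape_params <- function(disease) {
  switch(disease,
    AD = list(mode = "curve",
              length_meanlog = log(8), length_sdlog = 0.35,   # um
              thickness_um = 1.5, thickness_sdlog = 0.10,
              turning_rate = 0.9),                            # rad/um
    PSP = list(mode = "curve",
               length_meanlog = log(25), length_sdlog = 0.30,
               thickness_um = 1.0, thickness_sdlog = 0.10,
               turning_rate = 0.04),
    CBD = list(mode = "blob",
               diam_meanlog = log(8), diam_sdlog = 0.25,      # equiv diam, um
               aspect_range = c(1.0, 1.6)),
    stop("unknown disease: ", disease))
}

#' Specification of a synthetic AT8 slide
#'
#' Collects every generative parameter for one synthetic whole-slide image:
#' physical resolution, tissue layout size, disease-specific aggregate shape
#' distributions, the cortical burden range and the WM:CTX burden slope,
#' the nuclear-artifact rate, and the optical-density stain vectors used for
#' Beer-Lambert rendering.
#'
#' @param disease one of `"AD"`, `"PSP"`, `"CBD"`.
#' @param mpp microns per pixel (default 0.5, i.e. 20X).
#' @param slide_size integer `c(H, W)` in pixels; at least 512 each.
#' @param burden_slope WM/CTX burden ratio; defaults per disease
#'   (AD 0.10, PSP 1/3, CBD 3/4).
#' @param ctx_burden_range interval the per-slide cortical aggregate area
#'   fraction is drawn from.
#' @param burden_noise_sd sdlog of the multiplicative lognormal noise applied
#'   to the slope per slide.
#' @param shape_params per-disease shape distribution; see
#'   `default_shape_params`.
#' @param artifact_rate fraction of rendered objects that are nuclear
#'   artifacts, in `[0, 0.5)`.
#' @param stain_od list with 3-vectors `hem` and `dab` of optical densities.
#' @param noise_sd sd of additive Gaussian pixel noise in 8-bit units.
#' @param seed default seed used by [generate_slide()].
#' @return object of class `tauwm_spec`.
#' @export
synthetic_spec <- function(disease = c("AD", "PSP", "CBD"), mpp = 0.5,
                           slide_size = c(1536L, 1536L),
                           burden_slope = NULL,
                           ctx_burden_range = c(0.005, 0.06),
                           burden_noise_sd = 0.15,
                           shape_params = NULL,
                           artifact_rate = 0.04,
                           stain_od = list(hem = c(0.65, 0.70, 0.29),
                                           dab = c(0.27, 0.57, 0.78)),
                           noise_sd = 2.0,
                           seed = 1L) {
  disease <- match.arg(disease)
  if (is.null(burden_slope)) burden_slope <- default_burden_slopes[[disease]]
  if (is.null(shape_params)) shape_params <- default_shape_params(disease)
  spec <- structure(list(
    disease = disease, mpp = mpp, slide_size = as.integer(slide_size),
    burden_slope = burden_slope, ctx_burden_range = ctx_burden_range,
    burden_noise_sd = burden_noise_sd, shape_params = shape_params,
    artifact_rate = artifact_rate, stain_od = stain_od,
    noise_sd = noise_sd, seed = as.integer(seed)), class = "tauwm_spec")
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  stopifnot(spec$mpp > 0,
            spec$burden_slope > 0, spec$burden_slope <= 1,
            spec$artifact_rate >= 0, spec$artifact_rate < 0.5,
            length(spec$slide_size) == 2,
            diff(spec$ctx_burden_range) >= 0,
            min(spec$ctx_burden_range) >= 0,
            max(spec$ctx_burden_range) <= 1)
  if (identical(spec$shape_params$mode, "curve")) {
    if (spec$shape_params$thickness_um <= 0)
      stop("degenerate shape parameters: thickness must be positive")
  }
  invisible(spec)
}

new_slide <- function(pixels, mpp, slide_id, disease = NULL) {
  structure(list(pixels = pixels, mpp = mpp, slide_id = slide_id,
                 disease = disease), class = "tauwm_slide")
}

#' @export
print.tauwm_slide <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<tauwm_slide %s: %dx%d px @ %.3g um/px, disease=%s>\n",
              x$slide_id, d[1], d[2], x$mpp,
              if (is.null(x$disease)) "NA" else x$disease))
  invisible(x)
}

# ---- tissue layout --------------------------------------------------------

# Parallel bands with wavy boundaries: background margin (top), cortex band,
# white-matter band. Fractions roughly 0.2 / 0.4 / 0.4.
synth_region_layout <- function(H, W) {
  j <- seq_len(W)
  amp <- 0.03 * H
  b1 <- 0.20 * H + amp * sin(2 * pi * j / W * stats::runif(1, 1, 3) +
                             stats::runif(1, 0, 2 * pi))
  b2 <- 0.60 * H + amp * sin(2 * pi * j / W * stats::runif(1, 1, 3) +
                             stats::runif(1, 0, 2 * pi))
  rows <- matrix(seq_len(H), H, W)
  b1m <- matrix(b1, H, W, byrow = TRUE)
  b2m <- matrix(b2, H, W, byrow = TRUE)
  lab <- matrix(0L, H, W)
  lab[rows > b1m & rows <= b2m] <- 1L
  lab[rows > b2m] <- 2L
  lab
}

# ---- aggregate shapes -----------------------------------------------------

disk_offsets <- function(r) {
  ri <- ceiling(r)
  g <- expand.grid(di = -ri:ri, dj = -ri:ri)
  g[g$di^2 + g$dj^2 <= r^2 + 1e-9, , drop = FALSE]
}

#' Sample one aggregate shape
#'
#' Draws a single aggregate silhouette from the disease-specific shape
#' distribution. AD and PSP shapes are thickened random-walk curves whose
#' tangent direction receives Gaussian increments with sd
#' `turning_rate * step`; CBD shapes are noisy filled ellipses parameterised
#' by equivalent diameter and aspect ratio.
#'
#' @param disease `"AD"`, `"PSP"` or `"CBD"` (selects the default parameters
#'   when `shape_params` is `NULL`).
#' @param shape_params list as produced by `default_shape_params`.
#' @param mpp microns per pixel used to convert physical sizes to the raster.
#' @return list with `mask` (binary integer matrix, one 8-connected
#'   component) and `anchor` (the shape centre, 0-based row/col).
#' @export
sample_aggregate_shape <- function(disease, shape_params = NULL, mpp = 0.5) {
  if (is.null(shape_params)) shape_params <- default_shape_params(disease)
  sp <- shape_params
  if (identical(sp$mode, "curve")) {
    if (sp$thickness_um <= 0) stop("degenerate shape parameters")
    len_um <- stats::rlnorm(1, sp$length_meanlog, sp$length_sdlog)
    thick_um <- sp$thickness_um * stats::rlnorm(1, 0, sp$thickness_sdlog)
    step_um <- mpp                      # one pixel per step
    n <- max(1L, ceiling(len_um / step_um))
    dtheta <- stats::rnorm(n, 0, sp$turning_rate * step_um)
    theta <- stats::runif(1, 0, 2 * pi) + cumsum(dtheta)
    pi_ <- cumsum(c(0, cos(theta))) / mpp * step_um
    pj_ <- cumsum(c(0, sin(theta))) / mpp * step_um
    r_px <- max(0.6, thick_um / 2 / mpp)
    pts <- cbind(round(pi_), round(pj_))
    offs <- disk_offsets(r_px)
    cells <- unique(cbind(rep(pts[, 1], each = nrow(offs)) + offs$di,
                          rep(pts[, 2], each = nrow(offs)) + offs$dj))
  } else {
    d_um <- stats::rlnorm(1, sp$diam_meanlog, sp$diam_sdlog)
    ratio <- stats::runif(1, sp$aspect_range[1], sp$aspect_range[2])
    a <- d_um / 2 * sqrt(ratio) / mpp   # semi-axes in px
    b <- d_um / 2 / sqrt(ratio) / mpp
    th <- stats::runif(1, 0, pi)
    ph0 <- stats::runif(1, 0, 2 * pi)
    wob <- stats::runif(1, 0.02, 0.10)
    ri <- ceiling(a) + 2L
    g <- expand.grid(di = -ri:ri, dj = -ri:ri)
    u <- g$di * cos(th) + g$dj * sin(th)
    v <- -g$di * sin(th) + g$dj * cos(th)
    phi <- atan2(v / max(b, 1e-9), u / max(a, 1e-9))
    rr <- 1 + wob * sin(3 * phi + ph0)
    keep <- (u / a)^2 + (v / b)^2 <= rr^2
    cells <- cbind(g$di[keep], g$dj[keep])
    if (nrow(cells) == 0) cells <- cbind(0L, 0L)
  }
  i0 <- min(cells[, 1]); j0 <- min(cells[, 2])
  m <- matrix(0L, max(cells[, 1]) - i0 + 1L, max(cells[, 2]) - j0 + 1L)
  m[cbind(cells[, 1] - i0 + 1L, cells[, 2] - j0 + 1L)] <- 1L
  # keep the component containing the shape origin (guards rare raster splits)
  lab <- cc_label_cpp(m, 8L)
  keep_lab <- lab[1 - i0, 1 - j0]
  if (is.na(keep_lab) || keep_lab == 0) keep_lab <- lab[which(lab > 0)[1]]
  m[lab != keep_lab] <- 0L
  list(mask = m, anchor = c(-i0, -j0))
}

# ---- object placement -----------------------------------------------------

# Stamp non-overlapping objects into one region until the aggregate pixel
# count reaches the target; a 2-px halo keeps neighbouring objects (and their
# edge rings) separable. An object is only added when doing so brings the
# count closer to the target than stopping (keeps coverage unbiased).
place_in_region <- function(state, region_id, target_px, spec, artifact = FALSE) {
  H <- nrow(state$instance_map); W <- ncol(state$instance_map)
  region_ok <- state$region == region_id
  count <- state$region_px_count[[as.character(region_id)]]
  fails <- 0L
  n_target <- if (artifact) target_px else Inf  # artifact mode: target = count of objects
  placed <- 0L
  repeat {
    if (artifact) {
      if (placed >= n_target) break
    } else if (count >= target_px) break
    if (fails > 400L) break
    if (artifact) {
      d_um <- stats::runif(1, 4, 6.5)
      r_px <- d_um / 2 / spec$mpp
      sq <- stats::runif(1, 0.85, 1)   # slight ellipticity
      offs <- disk_offsets(r_px)
      keep <- (offs$di * sq)^2 + offs$dj^2 <= r_px^2
      offs <- offs[keep, , drop = FALSE]
      i0 <- min(offs$di); j0 <- min(offs$dj)
      m <- matrix(0L, max(offs$di) - i0 + 1L, max(offs$dj) - j0 + 1L)
      m[cbind(offs$di - i0 + 1L, offs$dj - j0 + 1L)] <- 1L
      sh <- list(mask = m, anchor = c(-i0, -j0))
    } else {
      sh <- sample_aggregate_shape(spec$disease, spec$shape_params, spec$mpp)
    }
    hm <- nrow(sh$mask); wm <- ncol(sh$mask)
    if (hm >= H - 2 || wm >= W - 2) { fails <- fails + 1L; next }
    oi <- sample.int(H - hm - 1L, 1L)
    oj <- sample.int(W - wm - 1L, 1L)
    sub_i <- oi:(oi + hm - 1L); sub_j <- oj:(oj + wm - 1L)
    cells <- which(sh$mask == 1L, arr.ind = TRUE)
    abs_i <- cells[, 1] + oi - 1L; abs_j <- cells[, 2] + oj - 1L
    idx <- cbind(abs_i, abs_j)
    if (!all(region_ok[idx])) { fails <- fails + 1L; next }
    # halo-2 occupancy check
    halo_i <- pmin(pmax(rep(abs_i, 5) + rep(c(0, -2, 2, 0, 0), each = length(abs_i)), 1L), H)
    halo_j <- pmin(pmax(rep(abs_j, 5) + rep(c(0, 0, 0, -2, 2), each = length(abs_j)), 1L), W)
    if (any(state$occupied[cbind(halo_i, halo_j)])) { fails <- fails + 1L; next }
    npx <- length(abs_i)
    if (!artifact && (count + npx - target_px) > (target_px - count)) break
    id <- state$next_id
    state$next_id <- id + 1L
    state$instance_map[idx] <- id
    # occupy a 2-px dilation
    for (di in -2:2) for (dj in -2:2) {
      ii <- pmin(pmax(abs_i + di, 1L), H); jj <- pmin(pmax(abs_j + dj, 1L), W)
      state$occupied[cbind(ii, jj)] <- TRUE
    }
    state$meta[[length(state$meta) + 1L]] <-
      data.frame(instance_id = id, region = region_id,
                 is_artifact = artifact, n_px = npx)
    if (artifact) placed <- placed + 1L else count <- count + npx
    fails <- 0L
  }
  state$region_px_count[[as.character(region_id)]] <- count
  state
}

edge_ring <- function(inst) {
  H <- nrow(inst); W <- ncol(inst)
  obj <- inst > 0L
  dil <- obj
  shift <- function(m, di, dj) {
    out <- matrix(FALSE, H, W)
    si <- max(1, 1 + di):min(H, H + di); ti <- si - di
    sj <- max(1, 1 + dj):min(W, W + dj); tj <- sj - dj
    out[si, sj] <- m[ti, tj]
    out
  }
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    dil <- dil | shift(obj, di, dj)
  }
  dil & !obj
}

#' Generate one synthetic slide with ground truth
#'
#' Lays out the three tissue zones, fills cortex and white matter with
#' non-overlapping aggregates to the sampled burden targets
#' (WM target = slope x cortical burden x lognormal noise), injects nuclear
#' artifacts, and renders the stained RGB image via Beer-Lambert optics.
#' Deterministic for a fixed `(spec, seed)`.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed; defaults to `spec$seed`.
#' @param slide_id identifier stored on the slide.
#' @return list with `slide` (`tauwm_slide`) and `truth` (`tauwm_truth` with
#'   `region_mask`, `pixel_mask`, `instance_map`, `artifact_ids`, `meta`).
#' @export
generate_slide <- function(spec, seed = spec$seed,
                           slide_id = sprintf("%s_s%04d", spec$disease, seed)) {
  validate_spec(spec)
  H <- spec$slide_size[1]; W <- spec$slide_size[2]
  if (H < 512 || W < 512)
    stop("slide too small to fit the three tissue zones (need >= 512 px)")
  set.seed(seed)
  region <- synth_region_layout(H, W)
  ctx_cov <- stats::runif(1, spec$ctx_burden_range[1], spec$ctx_burden_range[2])
  wm_cov <- spec$burden_slope * ctx_cov *
    stats::rlnorm(1, 0, spec$burden_noise_sd)
  state <- list(instance_map = matrix(0L, H, W),
                occupied = matrix(FALSE, H, W),
                region = region, next_id = 1L, meta = list(),
                region_px_count = list(`1` = 0L, `2` = 0L))
  if (ctx_cov > 0) {
    state <- place_in_region(state, 1L, round(ctx_cov * sum(region == 1L)), spec)
    state <- place_in_region(state, 2L, round(wm_cov * sum(region == 2L)), spec)
  }
  truth <- structure(list(region_mask = region,
                          instance_map = state$instance_map,
                          pixel_mask = NULL,
                          artifact_ids = integer(0),
                          meta = if (length(state$meta))
                            do.call(rbind, state$meta) else
                            data.frame(instance_id = integer(0),
                                       region = integer(0),
                                       is_artifact = logical(0),
                                       n_px = integer(0)),
                          occupied = state$occupied,
                          next_id = state$next_id,
                          mpp = spec$mpp),
                     class = "tauwm_truth")
  truth <- inject_artifacts(truth, spec)
  truth$pixel_mask <- {
    pm <- matrix(0L, H, W)
    pm[truth$instance_map > 0L] <- 1L
    pm[edge_ring(truth$instance_map)] <- 2L
    pm
  }
  truth$occupied <- NULL; truth$next_id <- NULL
  slide <- render_stain(truth, spec, slide_id = slide_id)
  list(slide = slide, truth = truth)
}

#' Inject nuclear-staining artifacts into a layout
#'
#' Adds round, nucleus-scale (5-8 um diameter) objects, rendered later with
#' weaker DAB, so that artifacts make up approximately `artifact_rate` of all
#' objects. Their instance labels are recorded in `artifact_ids`.
#'
#' @param truth a `tauwm_truth` layout (before rendering).
#' @param spec the generating [synthetic_spec()].
#' @return updated `tauwm_truth`.
#' @export
inject_artifacts <- function(truth, spec) {
  if (spec$artifact_rate <= 0) return(truth)
  n_obj <- nrow(truth$meta)
  if (n_obj == 0) return(truth)
  state <- list(instance_map = truth$instance_map,
                occupied = if (!is.null(truth$occupied)) truth$occupied else
                  truth$instance_map > 0L,
                region = truth$region_mask,
                next_id = if (!is.null(truth$next_id)) truth$next_id else
                  max(truth$instance_map) + 1L,
                meta = list(),
                region_px_count = list(`1` = 0L, `2` = 0L))
  p <- spec$artifact_rate
  for (rid in c(1L, 2L)) {
    n_r <- sum(truth$meta$region == rid & !truth$meta$is_artifact)
    n_art <- stats::rbinom(1, size = round(n_r / (1 - p)), prob = p)
    if (n_art > 0)
      state <- place_in_region(state, rid, n_art, spec, artifact = TRUE)
  }
  add <- if (length(state$meta)) do.call(rbind, state$meta) else NULL
  truth$instance_map <- state$instance_map
  truth$occupied <- state$occupied
  truth$next_id <- state$next_id
  if (!is.null(add)) {
    truth$meta <- rbind(truth$meta, add)
    truth$artifact_ids <- sort(c(truth$artifact_ids, add$instance_id))
  }
  truth
}

# ---- rendering ------------------------------------------------------------

# smoothed white-noise field in [-1, 1]-ish range
noise_field <- function(H, W, smooth_px) {
  f <- matrix(stats::rnorm(H * W), H, W)
  f <- box_mean_cpp(f, smooth_px)
  f <- box_mean_cpp(f, smooth_px)
  f / max(stats::sd(f), 1e-9)
}

#' Render a laid-out slide into a stained RGB image
#'
#' Beer-Lambert rendering: `RGB = 255 * exp(-(c_hem * V_hem + c_dab * V_dab))`
#' per channel. Tissue pixels receive hematoxylin tone (cortex darker and
#' textured with sparse basophilic nuclei clusters, white matter paler and
#' smoother, background near-white); aggregate and edge pixels receive DAB
#' concentration (edges at 60% of the object concentration; nuclear artifacts
#' at roughly half strength with a smooth profile, true aggregates speckled).
#' Additive Gaussian noise with sd `spec$noise_sd` (8-bit units) is applied.
#'
#' @param truth a `tauwm_truth` layout.
#' @param spec the generating [synthetic_spec()].
#' @param slide_id identifier for the rendered slide.
#' @return a `tauwm_slide`.
#' @export
render_stain <- function(truth, spec, slide_id = "synthetic") {
  region <- truth$region_mask
  H <- nrow(region); W <- ncol(region)
  if (!is.null(truth$instance_map) &&
      !all(dim(truth$instance_map) == c(H, W)))
    stop("layout and spec size mismatch")
  hem <- matrix(0.03, H, W)
  tex <- noise_field(H, W, 7)
  hem[region == 1L] <- 0.55 + 0.13 * tex[region == 1L]
  hem[region == 2L] <- 0.30 + 0.04 * tex[region == 2L]
  # sparse nuclei clusters in the cortex (hematoxylin-dense dots)
  ctx_idx <- which(region == 1L)
  n_nuc <- round(length(ctx_idx) / 1800)
  if (n_nuc > 0) {
    centers <- sample(ctx_idx, n_nuc)
    ci <- (centers - 1L) %% H + 1L
    cj <- (centers - 1L) %/% H + 1L
    offs <- disk_offsets(3.2)
    ii <- pmin(pmax(rep(ci, each = nrow(offs)) + offs$di, 1L), H)
    jj <- pmin(pmax(rep(cj, each = nrow(offs)) + offs$dj, 1L), W)
    hem[cbind(ii, jj)] <- pmax(hem[cbind(ii, jj)], 1.05)
  }
  dab <- matrix(0, H, W)
  inst <- truth$instance_map
  if (!is.null(inst) && any(inst > 0L)) {
    art <- inst * 0L
    if (length(truth$artifact_ids))
      art[inst %in% truth$artifact_ids] <- 1L
    obj_px <- inst > 0L
    speckle <- matrix(stats::rnorm(H * W, 0, 0.22), H, W)
    conc <- ifelse(art == 1L, 0.50 + 0.02 * speckle,
                   pmax(0.45, 1.0 + speckle))
    dab[obj_px] <- conc[obj_px]
    # edges at 60% of neighbouring object concentration
    edge <- edge_ring(inst)
    dab[edge] <- 0.6 * mean(conc[obj_px])
    hem[obj_px | edge] <- pmax(hem[obj_px | edge], 0.15)
  }
  vh <- spec$stain_od$hem; vd <- spec$stain_od$dab
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    od <- hem * vh[ch] + dab * vd[ch]
    img[, , ch] <- 255 * exp(-od)
  }
  img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
  img <- round(pmin(pmax(img, 0), 255))
  storage.mode(img) <- "integer"
  new_slide(img, spec$mpp, slide_id, spec$disease)
}

#' Color-deconvolve an RGB image into stain concentrations
#'
#' Least-squares inversion of the Beer-Lambert model with the two stain
#' optical-density vectors; returns per-pixel hematoxylin and DAB
#' concentration maps.
#'
#' @param pixels 8-bit RGB array `c(H, W, 3)`.
#' @param stain_od list with `hem` and `dab` 3-vectors.
#' @return list of matrices `hem` and `dab`.
#' @export
deconvolve_stains <- function(pixels, stain_od) {
  d <- dim(pixels)
  od <- -log(pmax(matrix(pixels, ncol = 3), 0.5) / 255)
  M <- cbind(stain_od$hem, stain_od$dab)
  co <- solve(crossprod(M), t(M) %*% t(od))   # 2 x n
  list(hem = matrix(co[1, ], d[1], d[2]),
       dab = matrix(co[2, ], d[1], d[2]))
}

#' Generate a synthetic cohort
#'
#' @param diseases character vector, one entry per slide.
#' @param seeds integer vector of per-slide seeds (same length).
#' @param ... passed to [synthetic_spec()] (e.g. `slide_size`).
#' @return list of `list(slide, truth)` entries.
#' @export
generate_cohort <- function(diseases, seeds = seq_along(diseases), ...) {
  stopifnot(length(diseases) == length(seeds))
  lapply(seq_along(diseases), function(i) {
    spec <- synthetic_spec(disease = diseases[i], ...)
    generate_slide(spec, seed = seeds[i])
  })
}
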