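# Per-aggregate morphometry.
#
# Aggregates are 8-connected islands of aggregate-class pixels; edge-class
# pixels act as separators and never as members. Each instance is profiled
# with nine size/shape features: area, major/minor axis length, skeleton
# length, width, extent, eccentricity, curvature, solidity. Length-type
# features are in microns, area in square microns; extent, eccentricity and
# solidity are unitless.

#' Names of the nine morphometric features
#' @export
FEATURE_NAMES <- c("area", "major_axis_length", "minor_axis_length", "length",
                   "width", "extent", "eccentricity", "curvature", "solidity")

#' Extract aggregate instances from a pixel-class mask
#'
#' Labels 8-connected components of the aggregate class (label 1). Edge
#' pixels (label 2) separate neighbouring aggregates and are not members.
#' Components smaller than `min_area_px` pixels are discarded.
#'
#' @param pixel_mask integer matrix in `{0 = background, 1 = aggregate,
#'   2 = edge}`.
#' @param min_area_px minimum component area in pixels (default 30).
#' @param region_mask optional region labels (1 = CTX, 2 = WM); an instance's
#'   region is the majority region over its pixels.
#' @param slide_id identifier copied onto every instance.
#' @return list of instances, each with `instance_id`, `pixels` (0-based
#'   `(row, col)` matrix), `n_px`, `region` (`"CTX"`/`"WM"`/`NA`), `slide_id`.
#' @export
label_aggregates <- function(pixel_mask, min_area_px = 30L,
                             region_mask = NULL, slide_id = "slide") {
  stopifnot(is.matrix(pixel_mask))
  lab <- cc_label_cpp(matrix(as.integer(pixel_mask == 1L),
                             nrow(pixel_mask)), 8L)
  n <- max(lab)
  if (n == 0) return(list())
  idx <- which(lab > 0L)
  ord <- order(lab[idx])
  idx <- idx[ord]
  sizes <- tabulate(lab[idx], n)
  H <- nrow(pixel_mask)
  rows <- (idx - 1L) %% H
  cols <- (idx - 1L) %/% H
  stops <- cumsum(sizes)
  starts <- c(1L, utils::head(stops, -1L) + 1L)
  out <- list()
  k <- 0L
  for (i in seq_len(n)) {
    if (sizes[i] < min_area_px) next
    sel <- starts[i]:stops[i]
    px <- cbind(row = rows[sel], col = cols[sel])
    region <- NA_character_
    if (!is.null(region_mask)) {
      rv <- region_mask[cbind(px[, 1] + 1L, px[, 2] + 1L)]
      rv <- rv[rv %in% c(1L, 2L)]
      if (length(rv))
        region <- c("CTX", "WM")[which.max(tabulate(rv, 2L))]
    }
    k <- k + 1L
    out[[k]] <- list(instance_id = k, pixels = px, n_px = sizes[i],
                     region = region, slide_id = slide_id)
  }
  out
}

# convex hull area in "pixels contained" convention: count grid points whose
# centres lie inside/on the hull of the instance's pixel centres
hull_pixel_count <- function(px) {
  u <- unique(px)
  if (nrow(u) <= 2) return(nrow(u))
  h <- grDevices::chull(u[, 1], u[, 2])
  hx <- u[h, 1]; hy <- u[h, 2]
  if (length(h) <= 2) return(nrow(u))
  r0 <- min(u[, 1]):max(u[, 1]); c0 <- min(u[, 2]):max(u[, 2])
  g <- expand.grid(r = r0, c = c0)
  inside <- point_in_poly(g$r, g$c, hx, hy)
  sum(inside)
}

# even-odd rule with on-edge tolerance
point_in_poly <- function(x, y, px, py) {
  n <- length(px)
  inside <- rep(FALSE, length(x))
  onedge <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- px[i]; yi <- py[i]; xj <- px[j]; yj <- py[j]
    # on-segment test
    len2 <- (xj - xi)^2 + (yj - yi)^2
    if (len2 > 1e-12) {   # skip degenerate (repeated-vertex) segments
      d <- abs((xj - xi) * (y - yi) - (yj - yi) * (x - xi))
      t <- ((x - xi) * (xj - xi) + (y - yi) * (yj - yi)) / len2
      onedge <- onedge | (d < 1e-7 * sqrt(len2) & t >= -1e-9 & t <= 1 + 1e-9)
    }
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi + 1e-300) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside | onedge
}

# longest geodesic path along the medial-axis skeleton; ties broken toward
# the lexicographically smallest endpoint pair
skeleton_path <- function(mask) {
  sk <- thin_cpp(mask)
  pts <- which(sk == 1L, arr.ind = TRUE)
  if (nrow(pts) == 0) return(NULL)
  pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
  far_point <- function(res) {
    d <- res$dist
    m <- max(d, na.rm = TRUE)
    cand <- which(abs(d - m) < 1e-9 & d >= 0, arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    cand[1, ]
  }
  r0 <- skel_geodesic_cpp(sk, pts[1, 1] - 1L, pts[1, 2] - 1L)
  # restrict to this skeleton's connected part
  p1 <- far_point(r0)
  r1 <- skel_geodesic_cpp(sk, p1[1] - 1L, p1[2] - 1L)
  p2 <- far_point(r1)
  # walk back from p2 to p1 via predecessors
  H <- nrow(sk)
  path <- list()
  cur <- (p2[1] - 1L) + (p2[2] - 1L) * H
  repeat {
    i <- cur %% H; j <- cur %/% H
    path[[length(path) + 1L]] <- c(i + 1L, j + 1L)
    nxt <- r1$prev[i + 1L, j + 1L]
    if (nxt < 0) break
    cur <- nxt
  }
  path <- do.call(rbind, rev(path))
  list(skeleton = sk, path = path,
       geodesic_len = r1$dist[p2[1], p2[2]])
}

#' Compute the nine morphometric features of one aggregate
#'
#' Area is pixel count times `mpp^2`; major/minor axis lengths come from the
#' ellipse with matching second central moments (with the 1/12-pixel
#' variance correction, which keeps eccentricity strictly below 1 for
#' 1-px-thin shapes); extent is area over axis-aligned bounding-box area;
#' solidity is area over convex-hull area; length is the arc length of the
#' longest geodesic path along the medial-axis skeleton; width is twice the
#' median distance-to-background along that path (minus the half-pixel
#' offsets, so a 3-px bar has width 3 px); curvature is the mean absolute
#' turning rate of the smoothed path tangent (smoothing window of 5 path
#' samples), in rad/um.
#'
#' @param instance as returned by [label_aggregates()] (needs `pixels`).
#' @param mpp microns per pixel.
#' @return named numeric vector of length 9 (see `FEATURE_NAMES`).
#' @export
compute_features <- function(instance, mpp) {
  px <- instance$pixels
  n <- nrow(px)
  if (n == 0) stop("empty instance")
  area <- n * mpp^2
  r <- px[, 1]; cc <- px[, 2]
  cov <- if (n == 1) matrix(0, 2, 2) else
    stats::cov(cbind(r, cc)) * (n - 1) / n
  cov <- cov + diag(1 / 12, 2)
  ev <- eigen(cov, symmetric = TRUE)$values
  major <- 4 * sqrt(ev[1]) * mpp
  minor <- 4 * sqrt(ev[2]) * mpp
  ecc <- sqrt(max(0, 1 - ev[2] / ev[1]))
  bbox <- (diff(range(r)) + 1) * (diff(range(cc)) + 1)
  extent <- n / bbox
  solidity <- min(1, n / hull_pixel_count(px))

  # skeleton-based length / width / curvature on the cropped mask
  i0 <- min(r); j0 <- min(cc)
  m <- matrix(0L, diff(range(r)) + 1L, diff(range(cc)) + 1L)
  m[cbind(r - i0 + 1L, cc - j0 + 1L)] <- 1L
  sp <- skeleton_path(m)
  if (is.null(sp) || nrow(sp$path) < 2) {
    len <- mpp
    width <- 2 * sqrt(n / pi) * mpp   # fall back to equivalent-disk width
    if (n <= 2) width <- mpp
    curv <- 0
  } else {
    len <- (sp$geodesic_len + 1) * mpp
    # distance to background for path pixels (candidates: background pixels
    # 4-adjacent to the object in the padded crop)
    pm <- matrix(0L, nrow(m) + 2L, ncol(m) + 2L)
    pm[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
    obj <- which(pm == 1L, arr.ind = TRUE)
    shift2 <- function(m, di, dj) cbind(m[, 1] + di, m[, 2] + dj)
    cand <- unique(rbind(shift2(obj, 1L, 0L), shift2(obj, -1L, 0L),
                         shift2(obj, 0L, 1L), shift2(obj, 0L, -1L)))
    cand <- cand[pm[cand] == 0L, , drop = FALSE]
    pp <- sp$path + 1L  # padded coordinates
    dmin <- vapply(seq_len(nrow(pp)), function(t) {
      sqrt(min((cand[, 1] - pp[t, 1])^2 + (cand[, 2] - pp[t, 2])^2))
    }, numeric(1))
    width_px <- max(1, 2 * stats::median(dmin) - 1)
    width <- width_px * mpp
    # curvature on the smoothed, decimated path (position smoothing with a
    # 5-sample window, then every 3rd sample: suppresses raster zig-zag
    # while keeping genuine turning)
    if (nrow(sp$path) >= 3) {
      w <- min(5L, nrow(sp$path))
      sr <- as.numeric(stats::filter(sp$path[, 1], rep(1 / w, w), sides = 2))
      sc <- as.numeric(stats::filter(sp$path[, 2], rep(1 / w, w), sides = 2))
      keep <- !is.na(sr)
      sr <- sr[keep]; sc <- sc[keep]
      # arc length along the smoothed path; compensate the samples lost to
      # the smoothing filter ((w-1) in total) and the ends eroded by
      # thinning (about (width-1)/2 px each)
      if (length(sr) >= 2) {
        sm_len <- sum(sqrt(diff(sr)^2 + diff(sc)^2))
        len <- (sm_len + (w - 1) + width_px - 1) * mpp
      }
      if (length(sr) >= 7) {
        dec <- seq(1, length(sr), by = 3)
        sr <- sr[dec]; sc <- sc[dec]
      }
      if (length(sr) >= 3) {
        dr <- diff(sr); dc <- diff(sc)
        seg <- sqrt(dr^2 + dc^2)
        ok <- seg > 1e-9
        th <- atan2(dc[ok], dr[ok])
        seg <- seg[ok]
        if (length(th) >= 2) {
          dth <- diff(th)
          dth <- atan2(sin(dth), cos(dth))   # wrap to (-pi, pi]
          ds <- (utils::head(seg, -1) + utils::tail(seg, -1)) / 2 * mpp
          curv <- sum(abs(dth)) / max(sum(ds), 1e-9)
        } else curv <- 0
      } else curv <- 0
    } else curv <- 0
  }
  c(area = area, major_axis_length = major, minor_axis_length = minor,
    length = len, width = width, extent = extent, eccentricity = ecc,
    curvature = curv, solidity = solidity)
}

#' Feature table for all aggregates of one slide
#'
#' Convenience wrapper: labels aggregates in a pixel mask and computes the
#' nine features for each, returning one row per instance.
#'
#' @param pixel_mask,region_mask,min_area_px,slide_id see
#'   [label_aggregates()].
#' @param mpp microns per pixel.
#' @return data frame with columns `slide_id`, `instance_id`, `region`,
#'   `n_px`, the nine features, and `is_artifact` (initialised `FALSE`).
#' @export
aggregate_features <- function(pixel_mask, region_mask = NULL, mpp = 0.5,
                               min_area_px = 30L, slide_id = "slide") {
  inst <- label_aggregates(pixel_mask, min_area_px, region_mask, slide_id)
  if (!length(inst)) {
    out <- data.frame(slide_id = character(0), instance_id = integer(0),
                      region = character(0), n_px = integer(0),
                      bb_r0 = numeric(0), bb_r1 = numeric(0),
                      bb_c0 = numeric(0), bb_c1 = numeric(0))
    for (f in FEATURE_NAMES) out[[f]] <- numeric(0)
    out$is_artifact <- logical(0)
    return(out)
  }
  feats <- t(vapply(inst, compute_features, numeric(9), mpp = mpp))
  bb <- t(vapply(inst, function(it)
    c(min(it$pixels[, 1]), max(it$pixels[, 1]),
      min(it$pixels[, 2]), max(it$pixels[, 2])), numeric(4)))
  out <- data.frame(slide_id = slide_id,
                    instance_id = vapply(inst, `[[`, 0L, "instance_id"),
                    region = vapply(inst, `[[`, "", "region"),
                    n_px = vapply(inst, `[[`, 0L, "n_px"),
                    bb_r0 = bb[, 1], bb_r1 = bb[, 2],
                    bb_c0 = bb[, 3], bb_c1 = bb[, 4])
  out <- cbind(out, as.data.frame(feats))
  out$is_artifact <- FALSE
  out
}
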