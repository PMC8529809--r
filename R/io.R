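# File interfaces.
#
# No PNG/TIFF codec is available in this R environment, so raster I/O uses
# portable anymap: PPM (P6) for RGB slides, PGM (P5) for indexed masks
# (region: 0=BG,1=CTX,2=WM; pixel: 0=background,1=aggregate,2=edge) and
# 16-bit PGM for instance maps. Region annotations are read from
# QuPath-dialect GeoJSON polygons; tabular outputs are CSV; specs and fits
# are JSON.

#' Write an RGB slide as binary PPM (P6)
#'
#' @param pixels integer array `c(H, W, 3)` in 0..255.
#' @param path output path.
#' @export
write_ppm <- function(pixels, path) {
  d <- dim(pixels)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P6\n%d %d\n255\n", d[2], d[1]), con, eos = NULL)
  # PNM is row-major, channel-interleaved
  v <- aperm(pixels, c(3, 2, 1))
  writeBin(as.raw(as.integer(v)), con)
}

#' Read a binary PPM (P6) slide
#'
#' @param path input path.
#' @return integer array `c(H, W, 3)`.
#' @export
read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- pnm_header(con)
  stopifnot(hdr$magic == "P6")
  raw <- readBin(con, "raw", hdr$w * hdr$h * 3L)
  v <- as.integer(raw)
  aperm(array(v, c(3, hdr$w, hdr$h)), c(3, 2, 1))
}

#' Write an integer mask as PGM (P5; 16-bit when values exceed 255)
#'
#' @param mask integer matrix.
#' @param path output path.
#' @export
write_pgm <- function(mask, path) {
  mx <- max(mask, 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  if (mx <= 255) {
    writeChar(sprintf("P5\n%d %d\n255\n", ncol(mask), nrow(mask)), con,
              eos = NULL)
    writeBin(as.raw(as.integer(t(mask))), con)
  } else {
    writeChar(sprintf("P5\n%d %d\n65535\n", ncol(mask), nrow(mask)), con,
              eos = NULL)
    v <- as.integer(t(mask))
    writeBin(as.raw(rbind(v %/% 256L, v %% 256L)), con)
  }
}

#' Read a PGM (P5) mask
#'
#' @param path input path.
#' @return integer matrix.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- pnm_header(con)
  stopifnot(hdr$magic == "P5")
  if (hdr$maxval <= 255) {
    v <- as.integer(readBin(con, "raw", hdr$w * hdr$h))
  } else {
    raw <- as.integer(readBin(con, "raw", 2L * hdr$w * hdr$h))
    v <- raw[c(TRUE, FALSE)] * 256L + raw[c(FALSE, TRUE)]
  }
  matrix(v, hdr$h, hdr$w, byrow = TRUE)
}

pnm_header <- function(con) {
  tok <- character(0)
  while (length(tok) < 4) {
    line <- readLines(con, 1)
    line <- sub("#.*", "", line)
    tok <- c(tok, strsplit(trimws(line), "\\s+")[[1]])
    tok <- tok[nzchar(tok)]
  }
  list(magic = tok[1], w = as.integer(tok[2]), h = as.integer(tok[3]),
       maxval = as.integer(tok[4]))
}

#' Rasterize QuPath-dialect GeoJSON region annotations
#'
#' Reads polygon features whose classification name is `"Cortex"` or
#' `"White Matter"` (anything else is background) and rasterizes them into a
#' region mask. Coordinates are `(x, y)` pixel positions, 0-based.
#'
#' @param path GeoJSON file.
#' @param H,W raster size.
#' @return integer matrix `{0 = BG, 1 = CTX, 2 = WM}`.
#' @export
read_qupath_regions <- function(path, H, W) {
  gj <- jsonlite::read_json(path)
  feats <- if (!is.null(gj$features)) gj$features else list(gj)
  mask <- matrix(0L, H, W)
  for (f in feats) {
    nm <- tryCatch(f$properties$classification$name, error = function(e) NULL)
    lab <- switch(nm %||% "", "Cortex" = 1L, "White Matter" = 2L, 0L)
    if (lab == 0L) next
    geom <- f$geometry
    if (is.null(geom) || !geom$type %in% c("Polygon", "MultiPolygon")) next
    polys <- if (geom$type == "Polygon") list(geom$coordinates) else
      geom$coordinates
    for (poly in polys) {
      ring <- poly[[1]]   # exterior ring only
      xs <- vapply(ring, function(p) as.numeric(p[[1]]), 0)
      ys <- vapply(ring, function(p) as.numeric(p[[2]]), 0)
      n <- length(xs)
      if (n > 1 && xs[1] == xs[n] && ys[1] == ys[n]) {  # drop closing vertex
        xs <- xs[-n]; ys <- ys[-n]
      }
      g <- expand.grid(r = seq_len(H) - 1L, c = seq_len(W) - 1L)
      inside <- point_in_poly(g$c, g$r, xs, ys)   # x = col, y = row
      mask[cbind(g$r + 1L, g$c + 1L)[inside, , drop = FALSE]] <- lab
    }
  }
  mask
}

#' Write a cohort manifest CSV
#'
#' @param manifest data frame (slide_id, disease, seed, paths...).
#' @param path output CSV.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) utils::read.csv(path)
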