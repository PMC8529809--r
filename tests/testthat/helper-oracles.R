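# Independent oracles used across tests.

# brute-force flood fill (queue-based) connected-component labelling
flood_fill_label <- function(mask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  if (connectivity == 8L) {
    di <- c(-1, -1, -1, 0, 0, 1, 1, 1); dj <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  } else {
    di <- c(-1, 1, 0, 0); dj <- c(0, 0, -1, 1)
  }
  for (j0 in seq_len(W)) for (i0 in seq_len(H)) {
    if (!mask[i0, j0] || lab[i0, j0]) next
    nxt <- nxt + 1L
    queue <- list(c(i0, j0))
    lab[i0, j0] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (t in seq_along(di)) {
        ii <- p[1] + di[t]; jj <- p[2] + dj[t]
        if (ii < 1 || jj < 1 || ii > H || jj > W) next
        if (mask[ii, jj] && !lab[ii, jj]) {
          lab[ii, jj] <- nxt
          queue[[length(queue) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# partitions agree up to relabelling?
same_partition <- function(a, b) {
  ka <- paste(a[a > 0], b[a > 0])
  length(unique(ka)) == length(unique(a[a > 0])) &&
    length(unique(ka)) == length(unique(b[b > 0]))
}

# exact two-sided Mann-Whitney p by enumeration of all assignments
mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  combs <- utils::combn(length(pooled), n)
  u_obs <- sum(rank(pooled)[seq_len(n)]) - n * (n + 1) / 2
  m <- length(pooled) - n
  us <- apply(combs, 2, function(ix)
    sum(rank(pooled)[ix]) - n * (n + 1) / 2)
  # two-sided: fraction of assignments at least as extreme as observed
  mu <- n * m / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# rasterize a filled ellipse (pixel-centre test)
raster_ellipse <- function(a, b, size = 2 * ceiling(a) + 5) {
  c0 <- (size + 1) / 2
  g <- expand.grid(i = seq_len(size), j = seq_len(size))
  m <- matrix(0L, size, size)
  keep <- ((g$i - c0) / a)^2 + ((g$j - c0) / b)^2 <= 1
  m[cbind(g$i, g$j)[keep, , drop = FALSE]] <- 1L
  m
}

# Chebyshev dilation by r (test-sized masks only)
dilate_mask <- function(m, r = 1L) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  for (di in -r:r) for (dj in -r:r) {
    si <- max(1, 1 + di):min(H, H + di)
    sj <- max(1, 1 + dj):min(W, W + dj)
    out[si, sj] <- out[si, sj] | m[si - di, sj - dj]
  }
  out
}
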