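# Slide-level cohort statistics: tau burden and per-disease burden-line
# fits, median morphometric profiles, correlation-distance hierarchical
# clustering, and Mann-Whitney comparisons with Bonferroni correction
# across the three disease pairs.

#' Tau burden of a region
#'
#' Fraction of the region's area occupied by aggregate-class pixels; edge
#' pixels count as non-aggregate.
#'
#' @param region_mask integer raster `{0 = BG, 1 = CTX, 2 = WM}`.
#' @param pixel_mask integer raster `{0, 1 = aggregate, 2 = edge}`.
#' @param region `"CTX"` or `"WM"`.
#' @return burden fraction in `[0, 1]`.
#' @export
compute_burden <- function(region_mask, pixel_mask, region = c("CTX", "WM")) {
  region <- match.arg(region)
  stopifnot(all(dim(region_mask) == dim(pixel_mask)))
  rid <- if (region == "CTX") 1L else 2L
  in_region <- region_mask == rid
  n <- sum(in_region)
  if (n == 0) stop("region ", region, " is empty")
  sum(pixel_mask[in_region] == 1L) / n
}

#' Burden records for a cohort of slides
#'
#' @param masks list of `list(slide_id, disease, region_mask, pixel_mask)`.
#' @return data frame with `slide_id`, `disease`, `ctx_burden`, `wm_burden`.
#' @export
burden_records <- function(masks) {
  do.call(rbind, lapply(masks, function(m)
    data.frame(slide_id = m$slide_id, disease = m$disease,
               ctx_burden = compute_burden(m$region_mask, m$pixel_mask, "CTX"),
               wm_burden = compute_burden(m$region_mask, m$pixel_mask, "WM"))))
}

#' Least-squares line of WM burden on cortical burden
#'
#' Ordinary least squares with intercept (a through-origin fit is available
#' with `intercept = FALSE`).
#'
#' @param records data frame with `ctx_burden` and `wm_burden` (one disease).
#' @param intercept include an intercept (default TRUE).
#' @return list `(disease, slope, intercept, n_slides, slope_se)`.
#' @export
fit_burden_line <- function(records, intercept = TRUE) {
  x <- records$ctx_burden; y <- records$wm_burden
  if (length(x) < 2) stop("need at least two slides")
  if (length(unique(x)) < 2) stop("all cortical burdens identical")
  fit <- if (intercept) stats::lm(y ~ x) else stats::lm(y ~ x - 1)
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  list(disease = if (!is.null(records$disease)) records$disease[1] else NA,
       slope = unname(co["x"]),
       intercept = if (intercept) unname(co["(Intercept)"]) else 0,
       n_slides = length(x), slope_se = unname(se["x"]))
}

#' Median morphometric profile of one slide's white-matter aggregates
#'
#' @param features feature table rows for one slide (post-QC, WM region).
#' @param disease disease label stored on the profile.
#' @return list `(slide_id, disease, median_features, n_aggregates)` or
#'   `NULL` (with a warning) when no aggregates remain.
#' @export
slide_profile <- function(features, disease = NA) {
  if (!nrow(features)) {
    warning("slide excluded: no aggregates after QC")
    return(NULL)
  }
  med <- vapply(FEATURE_NAMES, function(f) stats::median(features[[f]]),
                numeric(1))
  list(slide_id = features$slide_id[1], disease = disease,
       median_features = med, n_aggregates = nrow(features))
}

#' Build the slide x feature profile matrix for a cohort
#'
#' Keeps WM, non-artifact instances; one row per slide with its per-feature
#' medians.
#'
#' @param features pooled feature table with `slide_id` and optional
#'   `is_artifact`.
#' @param diseases named vector mapping slide_id to disease.
#' @return list with `profiles` (matrix), `diseases`, `n_aggregates`.
#' @export
cohort_profiles <- function(features, diseases) {
  f <- features
  if (!is.null(f$is_artifact)) f <- f[!f$is_artifact, , drop = FALSE]
  if (!is.null(f$region)) f <- f[f$region %in% "WM", , drop = FALSE]
  sids <- unique(f$slide_id)
  prof <- t(vapply(sids, function(s) {
    sub <- f[f$slide_id == s, , drop = FALSE]
    vapply(FEATURE_NAMES, function(ft) stats::median(sub[[ft]]), numeric(1))
  }, numeric(length(FEATURE_NAMES))))
  if (!length(sids)) prof <- matrix(numeric(0), 0, length(FEATURE_NAMES))
  colnames(prof) <- FEATURE_NAMES
  rownames(prof) <- sids
  list(profiles = prof, diseases = diseases[sids],
       n_aggregates = vapply(sids, function(s) sum(f$slide_id == s), 0L))
}

#' Hierarchical clustering of slide profiles
#'
#' Features are z-scored across slides (sample sd; zero-variance features
#' dropped with a warning); the slide-slide distance is 1 - Pearson
#' correlation between profile vectors; agglomeration uses average linkage.
#'
#' @param profiles numeric matrix, slides x features.
#' @return an `hclust` object (deterministic merge order and leaf order).
#' @export
cluster_profiles <- function(profiles) {
  if (nrow(profiles) < 3) stop("need at least three profiles")
  sds <- apply(profiles, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance feature(s): ",
            paste(colnames(profiles)[sds == 0], collapse = ", "))
    profiles <- profiles[, sds > 0, drop = FALSE]
  }
  z <- scale(profiles)
  d <- stats::as.dist(1 - stats::cor(t(z)))
  stats::hclust(d, method = "average")
}

#' Mann-Whitney comparisons of one feature across the three diseases
#'
#' Two-sided Mann-Whitney U per disease pair: exact distribution when both
#' groups have at most `exact_max` values and no ties, tie-corrected normal
#' approximation otherwise. P-values are Bonferroni-multiplied by the number
#' of pairs (3) and capped at 1; calls are significant at corrected
#' p < 0.05.
#'
#' @param values named list of numeric vectors, one per disease.
#' @param exact_max exact/approximate switch (default 8 per group).
#' @param alpha significance level on the corrected scale.
#' @return data frame with one row per pair: `group1`, `group2`, `U`,
#'   `p_raw`, `p_corrected`, `significant`.
#' @export
compare_feature_across_diseases <- function(values, exact_max = 8L,
                                            alpha = 0.05) {
  if (any(vapply(values, length, 0L) == 0)) stop("empty group")
  groups <- names(values)
  pairs <- utils::combn(groups, 2)
  n_pairs <- ncol(pairs)
  out <- lapply(seq_len(n_pairs), function(k) {
    x <- values[[pairs[1, k]]]; y <- values[[pairs[2, k]]]
    ties <- any(duplicated(c(x, y)))
    exact <- length(x) <= exact_max && length(y) <= exact_max && !ties
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = !exact))
    data.frame(group1 = pairs[1, k], group2 = pairs[2, k],
               U = unname(wt$statistic), p_raw = wt$p.value)
  })
  out <- do.call(rbind, out)
  out$p_corrected <- pmin(out$p_raw * n_pairs, 1)
  out$significant <- out$p_corrected < alpha
  out
}
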