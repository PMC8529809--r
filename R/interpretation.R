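# Interpretation of the learned disease classifier: penultimate-layer
# embeddings of patches, a 2-D UMAP projection, and overlays of per-patch
# mean hand-crafted features, connecting learned and morphometric
# descriptors.

#' Extract penultimate-layer embeddings for patches
#'
#' Deterministic forward pass through the MIL backbone up to the 1024-unit
#' penultimate layer; identical patches give identical rows.
#'
#' @param model a trained `tauwm_mil_model`.
#' @param patches list of patch arrays.
#' @return numeric matrix, one row per patch, `embedding_dim` columns.
#' @export
extract_embeddings <- function(model, patches) {
  t(vapply(patches, function(p) drop(mil_patch_fw(model, p)$embedding),
           numeric(model$cfg$embedding_dim)))
}

#' 2-D UMAP projection
#'
#' Projects a feature matrix to two dimensions with UMAP (default
#' `n_neighbors = 5`, `min_dist = 1`), delegating to the Python
#' `umap-learn` implementation (no R implementation is available in this
#' environment); reproducible for a fixed seed.
#'
#' @param x numeric matrix (rows = observations).
#' @param n_neighbors,min_dist UMAP parameters.
#' @param seed integer random state.
#' @return numeric matrix `nrow(x)` x 2.
#' @export
project_umap <- function(x, n_neighbors = 5L, min_dist = 1.0, seed = 1L) {
  x <- as.matrix(x)
  if (nrow(x) < n_neighbors + 1)
    stop("need at least n_neighbors + 1 rows")
  python <- Sys.which("python")
  if (python == "") stop("python with umap-learn is required for project_umap")
  fin <- tempfile(fileext = ".csv"); fout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  utils::write.table(x, fin, sep = ",", row.names = FALSE, col.names = FALSE)
  code <- sprintf(paste0(
    "import numpy, warnings, umap\n",
    "warnings.filterwarnings('ignore')\n",
    "X = numpy.loadtxt('%s', delimiter=',', ndmin=2)\n",
    "e = umap.UMAP(n_neighbors=%d, min_dist=%g, random_state=%d).fit_transform(X)\n",
    "numpy.savetxt('%s', e, delimiter=',')\n"),
    fin, as.integer(n_neighbors), min_dist, as.integer(seed), fout)
  res <- system2(python, c("-c", shQuote(code)), stdout = TRUE, stderr = TRUE)
  if (!file.exists(fout))
    stop("umap-learn failed: ", paste(res, collapse = "\n"))
  as.matrix(utils::read.table(fout, sep = ","))
}

#' Mean hand-crafted features of the aggregates inside each patch
#'
#' For each patch rectangle, averages the requested features over kept
#' (non-artifact) aggregates whose pixels intersect the patch. Patches
#' containing no aggregates are flagged missing (`NA` feature values).
#'
#' @param patch_boxes data frame with `slide_id`, `r0`, `c0` (0-based
#'   top-left corner) and `size` (patch side, px).
#' @param features feature table from [aggregate_features()] (with bbox
#'   columns `bb_r0`, `bb_r1`, `bb_c0`, `bb_c1`), already QC-filtered or
#'   carrying `is_artifact`.
#' @param cols feature columns to average.
#' @return `patch_boxes` with the mean feature columns and a `missing` flag.
#' @export
overlay_patch_features <- function(patch_boxes, features,
                                   cols = c("area", "eccentricity",
                                            "minor_axis_length")) {
  if (!is.null(features$is_artifact))
    features <- features[!features$is_artifact, , drop = FALSE]
  out <- patch_boxes
  for (cl in cols) out[[cl]] <- NA_real_
  out$missing <- TRUE
  for (t in seq_len(nrow(patch_boxes))) {
    b <- patch_boxes[t, ]
    f <- features[features$slide_id == b$slide_id &
                    features$bb_r1 >= b$r0 & features$bb_r0 < b$r0 + b$size &
                    features$bb_c1 >= b$c0 & features$bb_c0 < b$c0 + b$size, ,
                  drop = FALSE]
    if (nrow(f)) {
      for (cl in cols) out[[cl]][t] <- mean(f[[cl]])
      out$missing[t] <- FALSE
    }
  }
  out
}
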