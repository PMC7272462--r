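#' Weighted structural network construction
#'
#' Raw tractography output arrives as a square, (near-)symmetric matrix of
#' streamline counts between pairs of parcellation regions. Analysis-ready
#' networks are obtained by symmetrizing, zeroing the main diagonal (no
#' self-connections), suppressing noise edges below a streamline-count
#' threshold, and normalizing by the total fiber count so that subjects with
#' different overall tract yields are comparable.
#'
#' @name network-build
NULL

#' Validate a streamline-count matrix
#'
#' Checks that `m` is a square numeric matrix of finite, nonnegative values.
#'
#' @param m matrix to validate.
#' @param what label used in error messages.
#' @return `m`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_count_matrix <- function(m, what = "streamline-count matrix") {
  if (!is.matrix(m) || !is.numeric(m))
    stop(what, " must be a numeric matrix")
  if (nrow(m) != ncol(m))
    stop(what, " must be square, got ", nrow(m), "x", ncol(m))
  if (anyNA(m) || any(!is.finite(m)))
    stop(what, " contains missing or non-finite values")
  if (any(m < 0))
    stop(what, " contains negative entries")
  invisible(m)
}

#' Symmetrize a connectivity matrix
#'
#' Tractography does not distinguish afferent from efferent fibers, so the
#' matrix should be symmetric; tiny asymmetries can arise from file round
#' trips. Asymmetry within `tol` (relative to the largest entry) is averaged
#' away; larger asymmetry is treated as a data error.
#'
#' @param m square numeric matrix.
#' @param tol relative asymmetry tolerance.
#' @return symmetric matrix `(m + t(m)) / 2`.
#' @export
symmetrize <- function(m, tol = 1e-6) {
  validate_count_matrix(m)
  scale <- max(abs(m), 1)
  asym <- max(abs(m - t(m))) / scale
  if (asym > tol)
    stop("matrix asymmetry ", format(asym), " exceeds tolerance ", tol)
  (m + t(m)) / 2
}

#' Zero the main diagonal
#'
#' Self-connections are not meaningful in a region-to-region network.
#'
#' @param m square matrix.
#' @return `m` with a zero diagonal, off-diagonal entries unchanged.
#' @export
zero_diagonal <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("m must be a square matrix")
  diag(m) <- 0
  m
}

#' Suppress noise edges below a streamline-count threshold
#'
#' Connections carried by fewer than `min_streamlines` streamlines are
#' treated as tractography noise and set to zero; entries at or above the
#' threshold are unchanged. The threshold is in raw streamline units and is
#' therefore applied before any normalization.
#'
#' @param m nonnegative count matrix.
#' @param min_streamlines smallest count retained as a real connection.
#' @return thresholded matrix.
#' @export
apply_noise_threshold <- function(m, min_streamlines = 10) {
  validate_count_matrix(m)
  m[m < min_streamlines] <- 0
  m
}

#' Normalize a count matrix by its total fiber count
#'
#' Divides every entry by the sum of the upper triangle (each anatomical
#' connection counted once), so the upper-triangle weights of the result sum
#' to 1. The normalizer is retained so raw counts can be recovered.
#'
#' @param m thresholded, diagonal-zero, symmetric count matrix.
#' @param labels optional character vector of region labels.
#' @return a `weighted_network` object: list with elements `weights`
#'   (normalized adjacency), `labels`, and `total_fibers` (the normalizer).
#' @export
normalize_total_fibers <- function(m, labels = NULL) {
  validate_count_matrix(m)
  total <- sum(m[upper.tri(m)])
  if (total <= 0)
    stop("degenerate network: no connections survive (total fiber count is 0)")
  new_weighted_network(m / total, labels = labels, total_fibers = total)
}

new_weighted_network <- function(weights, labels = NULL, total_fibers = NA_real_) {
  n <- nrow(weights)
  if (is.null(labels)) labels <- colnames(weights)
  if (is.null(labels)) labels <- sprintf("node_%03d", seq_len(n))
  if (length(labels) != n) stop("labels length must equal the number of nodes")
  dimnames(weights) <- list(labels, labels)
  structure(list(weights = weights, labels = labels, total_fibers = total_fibers),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  n <- nrow(x$weights)
  ne <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat("Weighted structural network:", n, "nodes,", ne, "edges\n")
  cat("  total fibers (normalizer):", format(x$total_fibers), "\n")
  cat("  edge density:", format(round(ne / choose(n, 2), 3)), "\n")
  invisible(x)
}

#' Build an analysis-ready weighted network
#'
#' Composition of the construction steps: validate, symmetrize (averaging
#' tiny asymmetries), zero the diagonal, apply the streamline-count noise
#' threshold, and normalize by the total fiber count.
#'
#' @param m raw streamline-count matrix.
#' @param min_streamlines noise threshold in raw streamline units.
#' @param labels optional region labels.
#' @param asym_tol relative asymmetry tolerance passed to [symmetrize()].
#' @return a `weighted_network`.
#' @export
build_network <- function(m, min_streamlines = 10, labels = NULL,
                          asym_tol = 1e-6) {
  m <- symmetrize(m, tol = asym_tol)
  m <- zero_diagonal(m)
  m <- apply_noise_threshold(m, min_streamlines = min_streamlines)
  normalize_total_fibers(m, labels = labels)
}

#' Recover the raw (pre-normalization) count matrix of a network
#'
#' @param net a `weighted_network`.
#' @return matrix of thresholded streamline counts (`weights * total_fibers`).
#' @export
raw_counts <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  net$weights * net$total_fibers
}

#' Classify injury severity from the Glasgow Coma Scale
#'
#' GCS at hospital admission, 3--15: scores 14--15 are classified mild
#' (`mTBI`), scores 3--13 moderate-severe (`msTBI`).
#'
#' @param gcs integer vector of GCS scores.
#' @return character vector, `"mTBI"` or `"msTBI"`.
#' @export
classify_severity <- function(gcs) {
  if (anyNA(gcs) || any(!is.finite(gcs))) stop("gcs must be finite")
  if (any(gcs != round(gcs))) stop("gcs must be integer-valued")
  if (any(gcs < 3 | gcs > 15))
    stop("gcs out of range: the Glasgow Coma Scale is 3-15")
  ifelse(gcs >= 14, "mTBI", "msTBI")
}

#' Cognitive change score
#'
#' Post-injury minus pre-injury score. A missing input yields `NA` (a
#' flagged-missing result), never zero.
#'
#' @param pre,post numeric scores.
#' @return `post - pre`, with `NA` where either input is missing.
#' @export
change_score <- function(pre, post) {
  out <- post - pre
  out[is.na(pre) | is.na(post)] <- NA_real_
  out
}
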