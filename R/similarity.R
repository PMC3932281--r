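# Medium-truth-degree similarity between gray levels, and the per-pixel
# neighborhood mean-similarity map used to weight the membership blend.

.mmtdfcm_cache <- new.env(parent = emptyenv())

.check_gray <- function(x, arg = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) == 0 || anyNA(x)) {
    stop(sprintf("'%s' must be numeric gray levels with no missing values", arg),
         call. = FALSE)
  }
  if (any(x < 0 | x > 255)) {
    stop(sprintf("'%s' contains gray levels outside [0, 255]", arg), call. = FALSE)
  }
  invisible(x)
}

#' Directed medium truth-degree similarity ratio between two gray levels
#'
#' Scores how strongly gray level `f` resembles gray level `x` by a ratio of
#' distances to the opposing anchor points of the gray axis.  The "similar"
#' predicate is anchored just below the gray range at -1 and just above it at
#' 256, so the ratio is `(f + 1) / (x + 1)` when `f < x`,
#' `(256 - f) / (256 - x)` when `f > x`, and exactly 1 when the levels are
#' equal.  The score lies in `(0, 1]` but is *not* symmetric in its arguments;
#' [medium_similarity()] is the symmetrized measure used throughout the
#' segmentation pipeline.
#'
#' @param f,x Numeric vectors of gray levels in `[0, 255]`; recycled to a
#'   common length.
#' @return Numeric vector of ratios in `(0, 1]`.
#' @seealso [medium_similarity()], [neighborhood_similarity_map()]
#' @examples
#' medium_ratio(50, 100)   # 51/101
#' medium_ratio(200, 100)  # 56/156
#' @export
medium_ratio <- function(f, x) {
  .check_gray(f, "f")
  .check_gray(x, "x")
  n <- max(length(f), length(x))
  f <- rep_len(as.numeric(f), n)
  x <- rep_len(as.numeric(x), n)
  out <- rep_len(1, n)
  lo <- f < x
  hi <- f > x
  out[lo] <- (f[lo] + 1) / (x[lo] + 1)
  out[hi] <- (256 - f[hi]) / (256 - x[hi])
  out
}

#' Medium similarity measure of two gray levels
#'
#' The symmetrized medium truth-degree similarity: the average of the two
#' directed ratios [medium_ratio()] `(f, x)` and `(x, f)`.  Equals 1 exactly
#' when the two gray levels coincide, decays strictly as they move apart, and
#' attains its minimum `1/256` at the extreme pair `(0, 255)`.
#'
#' @inheritParams medium_ratio
#' @return Numeric vector of similarities in `(0, 1]`.
#' @examples
#' medium_similarity(160, 160)  # 1
#' medium_similarity(0, 255)    # 1/256
#' @export
medium_similarity <- function(f, x) {
  (medium_ratio(f, x) + medium_ratio(x, f)) / 2
}

# 256 x 256 lookup table of medium_similarity over all gray pairs; element
# [f + 1, x + 1] is hh(f, x).  Computed once per session.
.hh_lut <- function() {
  if (is.null(.mmtdfcm_cache$hh_lut)) {
    g <- 0:255
    .mmtdfcm_cache$hh_lut <- outer(g, g, medium_similarity)
  }
  .mmtdfcm_cache$hh_lut
}

# Offsets of the eight 3x3 neighbors, (row, col), center excluded.
.offsets8 <- cbind(
  di = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
  dj = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
)

.validate_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop(sprintf("'%s' must be a numeric matrix of gray levels", arg), call. = FALSE)
  }
  .check_gray(as.vector(image), arg)
  if (any(image != round(image))) {
    stop(sprintf("'%s' must hold integer gray levels in [0, 255]", arg), call. = FALSE)
  }
  invisible(image)
}

# Image shifted by (di, dj) so that entry (i, j) holds pixel (i + di, j + dj).
# border = "replicate" clamps indices to the image; "valid" yields NA outside.
.shifted <- function(mat, di, dj, border) {
  M <- nrow(mat)
  N <- ncol(mat)
  ri <- seq_len(M) + di
  ci <- seq_len(N) + dj
  if (border == "replicate") {
    return(mat[pmin(pmax(ri, 1L), M), pmin(pmax(ci, 1L), N), drop = FALSE])
  }
  out <- matrix(NA_real_, M, N)
  ok_r <- ri >= 1L & ri <= M
  ok_c <- ci >= 1L & ci <= N
  if (any(ok_r) && any(ok_c)) {
    out[ok_r, ok_c] <- mat[ri[ok_r], ci[ok_c]]
  }
  out
}

#' Per-pixel mean medium similarity to the 3x3 neighborhood
#'
#' For every pixel, averages [medium_similarity()] between the pixel and each
#' of its eight neighbors in the 3x3 window.  The map is high (1 in the
#' limit) inside homogeneous regions and low at impulse-noise pixels and
#' region boundaries; the segmentation engine computes it once per image and
#' uses it as the fixed spatial blend weight for the medium membership.
#'
#' @param image Integer matrix of gray levels in `[0, 255]`.
#' @param border Border policy for the 3x3 window: `"replicate"` (default)
#'   pads by edge replication so every pixel has eight neighbors; `"valid"`
#'   averages only the in-bounds neighbors (5 at edges, 3 at corners).
#' @return Numeric matrix, same shape as `image`, entries in `(0, 1]`.
#' @examples
#' img <- matrix(160L, 3, 3)
#' img[2, 2] <- 0L
#' neighborhood_similarity_map(img)[2, 2]  # about 0.19: impulse pixel
#' @export
neighborhood_similarity_map <- function(image, border = c("replicate", "valid")) {
  border <- match.arg(border)
  .validate_image(image)
  lut <- .hh_lut()
  M <- nrow(image)
  N <- ncol(image)
  acc <- matrix(0, M, N)
  cnt <- matrix(0, M, N)
  center <- as.vector(image)
  for (k in seq_len(nrow(.offsets8))) {
    nb <- as.vector(.shifted(image, .offsets8[k, 1L], .offsets8[k, 2L], border))
    ok <- !is.na(nb)
    s <- numeric(length(nb))
    s[ok] <- lut[cbind(center[ok] + 1L, nb[ok] + 1L)]
    acc <- acc + s
    cnt <- cnt + as.numeric(ok)
  }
  acc / cnt
}
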