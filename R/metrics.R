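# Evaluation criteria: PSNR, Bezdek's partition coefficient / entropy, and a
# permutation-minimizing misclassification rate for phantoms with known truth.

#' Peak signal-to-noise ratio between two gray images
#'
#' `10 * log10(peak^2 / MSE)` in decibels, where MSE is the mean squared
#' gray-level difference.  The peak defaults to the maximum gray level of the
#' reference image; `peak = 255` forces the full 8-bit scale for
#' comparability across images.  Identical images give `Inf`; an all-zero
#' reference compared against a different image gives `-Inf`.
#'
#' @param original Reference image (integer gray matrix).
#' @param processed Image under evaluation, same shape.
#' @param peak `"image"` (maximum of `original`, default) or a positive
#'   number such as `255`.
#' @return PSNR in dB (possibly infinite).
#' @export
psnr <- function(original, processed, peak = c("image", "255")) {
  .validate_image(original, "original")
  .validate_image(processed, "processed")
  if (!all(dim(original) == dim(processed))) {
    stop("'original' and 'processed' must have the same shape", call. = FALSE)
  }
  if (is.numeric(peak)) {
    pk <- peak
  } else {
    peak <- match.arg(peak)
    pk <- if (peak == "255") 255 else max(original)
  }
  mse <- mean((as.numeric(original) - as.numeric(processed))^2)
  if (mse == 0) return(Inf)
  10 * log10(pk^2 / mse)
}

#' Partition coefficient of a fuzzy membership matrix
#'
#' Mean squared membership `(1/n) sum_ik u_ik^2`: 1 for a crisp partition,
#' `1/c` for the maximally fuzzy (uniform) one.  Higher means crisper.
#'
#' @param memberships Clusters x pixels membership matrix (columns sum to 1).
#' @return Value in `[1/c, 1]`.
#' @export
partition_coefficient <- function(memberships) {
  .validate_membership(memberships)
  sum(memberships^2) / ncol(memberships)
}

#' Partition entropy of a fuzzy membership matrix
#'
#' Mean membership entropy `-(1/n) sum_ik u_ik log u_ik`, with
#' `0 log 0 = 0`: 0 for a crisp partition, `log c` for the uniform one.
#' Lower means crisper.
#'
#' @inheritParams partition_coefficient
#' @param base Logarithm base; natural log by default.
#' @return Value in `[0, log(c, base)]`.
#' @export
partition_entropy <- function(memberships, base = exp(1)) {
  .validate_membership(memberships)
  u <- memberships[memberships > 0]
  -sum(u * log(u, base = base)) / ncol(memberships)
}

# All permutations of 1..k as a list (k <= 8).
.permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- vector("list", factorial(k))
  idx <- 1L
  for (i in seq_len(k)) {
    for (p in .permutations(k - 1L)) {
      rest <- seq_len(k)[-i]
      out[[idx]] <- c(i, rest[p])
      idx <- idx + 1L
    }
  }
  out
}

#' Misclassification rate against a ground-truth label map
#'
#' Fraction of disagreeing pixels, minimized over all relabelings of the
#' `clusters` cluster indices (exhaustive search over the `clusters!`
#' permutations, so segmentations that differ only in label order score 0).
#'
#' @param labels Integer label matrix from a segmentation (1-based).
#' @param truth Ground-truth label matrix, same shape.
#' @param clusters Number of clusters; at most 8.
#' @return Misclassification rate in `[0, 1]`.
#' @export
misclassification_rate <- function(labels, truth, clusters) {
  if (!all(dim(labels) == dim(truth))) {
    stop("'labels' and 'truth' must have the same shape", call. = FALSE)
  }
  clusters <- as.integer(clusters)
  if (clusters > 8L) {
    stop("permutation search supports at most 8 clusters", call. = FALSE)
  }
  lv <- factor(as.vector(labels), levels = seq_len(clusters))
  tv <- factor(as.vector(truth), levels = seq_len(clusters))
  if (anyNA(lv) || anyNA(tv)) {
    stop("labels must lie in 1..clusters", call. = FALSE)
  }
  conf <- table(lv, tv)
  n <- length(lv)
  best <- 0
  for (p in .permutations(clusters)) {
    hits <- sum(conf[cbind(seq_len(clusters), p)])
    if (hits > best) best <- hits
  }
  (n - best) / n
}

#' Piecewise-constant reconstruction of a segmentation
#'
#' Replaces every pixel by its assigned cluster center, rounded and clipped
#' to the integer gray range; this is the `processed` image the segmentation
#' PSNR is computed against.
#'
#' @param labels Integer label matrix (1-based).
#' @param centers Numeric vector of cluster centers on the gray scale.
#' @return Integer gray matrix, same shape as `labels`.
#' @export
reconstruct_image <- function(labels, centers) {
  gray <- pmin(pmax(round(centers), 0), 255)
  matrix(as.integer(gray[as.vector(labels)]), nrow(labels), ncol(labels))
}

#' Metrics report for a segmentation result
#'
#' Bundles the reconstruction PSNR against a reference image, the partition
#' coefficient and entropy of the final memberships, and (when ground truth
#' is supplied) the permutation-minimized misclassification rate.
#'
#' @param result An `"fcm_result"` from [fcm_segment()].
#' @param original Reference image the PSNR is computed against (typically
#'   the clean image, so the PSNR measures how well segmentation suppresses
#'   noise).
#' @param truth Optional ground-truth label matrix.
#' @param peak PSNR peak convention, see [psnr()].
#' @return A list of class `"metrics_report"` with elements `psnr`, `vpc`,
#'   `vpe` and optionally `misclassification`.
#' @export
metrics_report <- function(result, original, truth = NULL,
                           peak = c("image", "255")) {
  stopifnot(inherits(result, "fcm_result"))
  recon <- reconstruct_image(result$labels, result$centers)
  rep <- list(
    psnr = psnr(original, recon, peak = peak),
    vpc = partition_coefficient(result$memberships),
    vpe = partition_entropy(result$memberships)
  )
  if (!is.null(truth)) {
    rep$misclassification <-
      misclassification_rate(result$labels, truth, result$config$clusters)
  }
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("psnr: %.4f dB\nvpc:  %.4f\nvpe:  %.4f\n", x$psnr, x$vpc, x$vpe))
  if (!is.null(x$misclassification)) {
    cat(sprintf("misclassification: %.4f\n", x$misclassification))
  }
  invisible(x)
}
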