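# Synthetic phantoms and noise models: the package's self-contained test
# surface for the segmentation algorithms.

#' Synthetic gray-level phantom with ground-truth labels
#'
#' Builds a piecewise-constant test image from a short ascending list of gray
#' levels.  `"bands"` lays the levels out as equal-width vertical bands
#' (widths differ by at most one column when the width does not divide
#' evenly).  `"disk_square"` needs exactly three levels: a background, a
#' centered disk, and a square block in the top-left corner.  The default
#' emulates the common benchmark of a 128 x 128 image with the three gray
#' levels 0, 160 and 255.
#'
#' @param height,width Image size in pixels (default 128 x 128).
#' @param levels Strictly ascending integer gray levels, between 2 and 8 of
#'   them (default `c(0, 160, 255)`).
#' @param geometry `"bands"` (default) or `"disk_square"`.
#' @return A list with `image` (integer gray matrix) and `labels` (integer
#'   matrix of ground-truth region indices, `1..length(levels)`, where label
#'   `i` marks the pixels drawn at `levels[i]`).
#' @examples
#' ph <- make_phantom()
#' table(ph$image)
#' @export
make_phantom <- function(height = 128, width = 128, levels = c(0, 160, 255),
                         geometry = c("bands", "disk_square")) {
  geometry <- match.arg(geometry)
  height <- as.integer(height)
  width <- as.integer(width)
  if (height < 1L || width < 1L) stop("image size must be positive", call. = FALSE)
  levels <- as.integer(levels)
  k <- length(levels)
  if (k < 2L || k > 8L) {
    stop("'levels' must contain between 2 and 8 gray levels", call. = FALSE)
  }
  if (any(diff(levels) <= 0)) {
    stop("'levels' must be strictly ascending", call. = FALSE)
  }
  .check_gray(levels, "levels")

  if (geometry == "bands") {
    if (width < k) stop("image too narrow to host one band per level", call. = FALSE)
    widths <- rep(width %/% k, k)
    extra <- width %% k
    if (extra > 0L) widths[seq_len(extra)] <- widths[seq_len(extra)] + 1L
    band <- rep(seq_len(k), times = widths)
    labels <- matrix(rep(band, each = height), height, width)
  } else {
    if (k != 3L) stop("'disk_square' needs exactly 3 levels", call. = FALSE)
    side <- min(height, width)
    if (side < 8L) stop("image too small for the disk_square geometry", call. = FALSE)
    labels <- matrix(1L, height, width)
    radius <- side / 4
    ci <- (height + 1) / 2
    cj <- (width + 1) / 2
    rows <- matrix(seq_len(height), height, width)
    cols <- matrix(seq_len(width), height, width, byrow = TRUE)
    labels[(rows - ci)^2 + (cols - cj)^2 <= radius^2] <- 2L
    sq <- max(2L, side %/% 4L)
    labels[seq_len(sq), seq_len(sq)] <- 3L
  }
  image <- matrix(levels[labels], height, width)
  list(image = image, labels = labels)
}

#' Corrupt an image with salt-and-pepper (impulse) noise
#'
#' Each pixel is independently replaced by 0 ("pepper") with probability
#' `density/2` and by 255 ("salt") with probability `density/2`, so the
#' expected corrupted fraction equals `density`.
#'
#' @param image Integer gray matrix.
#' @param density Corruption probability per pixel, in `[0, 1]`
#'   (default 0.05).
#' @param seed Optional integer seed; runs with the same seed are
#'   bit-identical and the caller's RNG state is left untouched.
#' @return Noisy image, same shape.
#' @export
add_salt_pepper <- function(image, density = 0.05, seed = NULL) {
  .validate_image(image)
  if (density < 0 || density > 1) {
    stop("'density' must lie in [0, 1]", call. = FALSE)
  }
  .with_seed(seed, {
    r <- matrix(stats::runif(length(image)), nrow(image), ncol(image))
    out <- image
    out[r < density / 2] <- 0L
    out[r >= density / 2 & r < density] <- 255L
    out
  })
}

#' Corrupt an image with additive Gaussian noise
#'
#' Gray levels are scaled to `[0, 1]`, independent zero-mean normal noise of
#' the given variance is added, and the result is clipped back to `[0, 1]`,
#' rescaled to `[0, 255]` and rounded — the convention under which "Gaussian
#' noise of variance 0.01" corresponds to a standard deviation of about 25.5
#' gray levels.
#'
#' @param image Integer gray matrix.
#' @param variance Noise variance on the unit gray scale (default 0.01).
#' @param seed Optional integer seed, as in [add_salt_pepper()].
#' @return Noisy image, same shape.
#' @export
add_gaussian <- function(image, variance = 0.01, seed = NULL) {
  .validate_image(image)
  if (variance < 0) stop("'variance' must be non-negative", call. = FALSE)
  if (variance == 0) return(image)
  .with_seed(seed, {
    g <- image / 255 + stats::rnorm(length(image), mean = 0, sd = sqrt(variance))
    g <- pmin(pmax(g, 0), 1)
    matrix(as.integer(round(g * 255)), nrow(image), ncol(image))
  })
}
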