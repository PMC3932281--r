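# PNG/TIFF input and output and the paired-comparison experiment driver.

#' Read an 8-bit grayscale image
#'
#' Reads a PNG or TIFF file into an integer gray matrix in `[0, 255]`.
#' Multi-channel images are converted to luminance
#' (`0.299 R + 0.587 G + 0.114 B`) with a warning; an alpha channel is
#' dropped.  Bit depths above 8 are rejected.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Integer matrix of gray levels in `[0, 255]`.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read image: no such file '%s'", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path, info = TRUE)
    info <- attr(a, "info")
    if (!is.null(info$bit.depth) && info$bit.depth > 8) {
      stop(sprintf("unsupported bit depth %d in '%s' (only 8-bit supported)",
                   info$bit.depth, path), call. = FALSE)
    }
  } else if (ext %in% c("tif", "tiff")) {
    a <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(a, "bits.per.sample")
    if (!is.null(bits) && bits > 8) {
      stop(sprintf("unsupported bit depth %d in '%s' (only 8-bit supported)",
                   bits, path), call. = FALSE)
    }
  } else {
    stop(sprintf("unsupported image format '%s' (PNG or TIFF expected)", ext),
         call. = FALSE)
  }
  if (length(dim(a)) == 3L) {
    ch <- dim(a)[3]
    if (ch >= 3L) {
      warning(sprintf("'%s' is multi-channel; converting to luminance", path),
              call. = FALSE)
      a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    } else {
      a <- a[, , 1]
    }
  }
  matrix(as.integer(round(a * 255)), nrow(a), ncol(a))
}

#' Write an 8-bit grayscale image
#'
#' Writes an integer gray matrix to PNG or TIFF (chosen by extension).  A
#' write followed by [read_gray_image()] returns the identical matrix.
#'
#' @param image Integer gray matrix in `[0, 255]`.
#' @param path Destination `.png`, `.tif` or `.tiff` path.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path) {
  .validate_image(image)
  ext <- tolower(tools::file_ext(path))
  g <- image / 255
  if (ext == "png") {
    png::writePNG(g, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(g, path, bits.per.sample = 8L)
  } else {
    stop(sprintf("unsupported image format '%s' (PNG or TIFF expected)", ext),
         call. = FALSE)
  }
  invisible(path)
}

# Map 1-based labels to evenly spaced display grays (0 .. 255).
.labels_to_gray <- function(labels, clusters) {
  if (clusters < 2L) return(matrix(0L, nrow(labels), ncol(labels)))
  gray <- as.integer(round((seq_len(clusters) - 1) * 255 / (clusters - 1)))
  matrix(gray[as.vector(labels)], nrow(labels), ncol(labels))
}

#' Write the artifacts of a segmentation run
#'
#' Writes, under `out_dir`: `labels.png` (cluster labels mapped to evenly
#' spaced display grays), `reconstruction.png` (pixels replaced by their
#' cluster center), `metrics.txt` (key/value lines), and `manifest.yaml`
#' recording the resolved configuration for provenance.
#'
#' @param result An `"fcm_result"` from [fcm_segment()].
#' @param report A `"metrics_report"` from [metrics_report()], or `NULL`.
#' @param out_dir Output directory, created if missing.
#' @param manifest Named list of extra provenance fields (input path, noise
#'   settings, ...) merged into the written manifest.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_outputs <- function(result, report = NULL, out_dir, manifest = list()) {
  stopifnot(inherits(result, "fcm_result"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop(sprintf("cannot create output directory '%s'", out_dir), call. = FALSE)
  }
  paths <- c(
    labels = file.path(out_dir, "labels.png"),
    reconstruction = file.path(out_dir, "reconstruction.png"),
    metrics = file.path(out_dir, "metrics.txt"),
    manifest = file.path(out_dir, "manifest.yaml")
  )
  write_gray_image(.labels_to_gray(result$labels, result$config$clusters),
                   paths[["labels"]])
  write_gray_image(reconstruct_image(result$labels, result$centers),
                   paths[["reconstruction"]])

  lines <- c(
    sprintf("n_iter: %d", result$n_iter),
    sprintf("converged: %s", tolower(as.character(result$converged))),
    sprintf("centers: %s", paste(format(result$centers, digits = 10),
                                 collapse = " "))
  )
  if (!is.null(report)) {
    lines <- c(lines,
               sprintf("psnr: %.6f", report$psnr),
               sprintf("vpc: %.6f", report$vpc),
               sprintf("vpe: %.6f", report$vpe))
    if (!is.null(report$misclassification)) {
      lines <- c(lines, sprintf("misclassification: %.6f",
                                report$misclassification))
    }
  }
  writeLines(lines, paths[["metrics"]])
  yaml::write_yaml(c(result$config, manifest), paths[["manifest"]])
  invisible(paths)
}

#' Paired FCM versus MMTDFCM comparison over noise conditions
#'
#' Runs both algorithm variants, from one shared initialization per
#' condition, on the clean image and on noisy versions of it, and tabulates
#' the evaluation metrics — one row per (condition, algorithm).  PSNR is
#' computed between the *clean* image and each run's piecewise-constant
#' reconstruction, so it measures how well the segmentation recovers the
#' underlying structure despite the noise.
#'
#' @param image Clean integer gray matrix.
#' @param truth Optional ground-truth label matrix (adds a
#'   `misclassification` column).
#' @param clusters Number of clusters.
#' @param conditions Named list of noise conditions.  Each element is `NULL`
#'   (clean) or a list with `kind` (`"salt_pepper"` or `"gaussian"`) and
#'   `level` (density, respectively variance).  The default reproduces the
#'   usual benchmark: clean, 5% salt-and-pepper, Gaussian variance 0.01.
#' @param m,eps,max_iter,border Passed to [fcm_segment()].
#' @param init Initialization method for the shared starting centers,
#'   computed once per condition from the (noisy) input.
#' @param seed Base seed; condition `i` corrupts the image with seed
#'   `seed + i - 1`.
#' @param peak PSNR peak convention, see [psnr()].
#' @return A data frame with columns `condition`, `algorithm`, `psnr`,
#'   `vpc`, `vpe`, `misclassification` (if `truth` given), `n_iter`,
#'   `converged`.
#' @examples
#' ph <- make_phantom(48, 48)
#' compare_experiment(ph$image, ph$labels, clusters = 3, seed = 1)
#' @export
compare_experiment <- function(image, truth = NULL, clusters,
                               conditions = list(
                                 clean = NULL,
                                 salt_pepper = list(kind = "salt_pepper",
                                                    level = 0.05),
                                 gaussian = list(kind = "gaussian",
                                                 level = 0.01)
                               ),
                               m = 2, eps = 1e-5, max_iter = 100,
                               init = "quantile", seed = 0,
                               border = "replicate",
                               peak = c("image", "255")) {
  .validate_image(image)
  rows <- list()
  for (i in seq_along(conditions)) {
    cond <- conditions[[i]]
    cond_name <- names(conditions)[i]
    noisy <- if (is.null(cond)) {
      image
    } else if (cond$kind == "salt_pepper") {
      add_salt_pepper(image, density = cond$level, seed = seed + i - 1)
    } else if (cond$kind == "gaussian") {
      add_gaussian(image, variance = cond$level, seed = seed + i - 1)
    } else {
      stop(sprintf("unknown noise kind '%s'", cond$kind), call. = FALSE)
    }
    start <- init_centers(noisy, clusters, method = init, seed = seed + i - 1)
    for (variant in c("fcm", "mmtdfcm")) {
      res <- fcm_segment(noisy, clusters, variant = variant, m = m, eps = eps,
                         max_iter = max_iter, centers = start, border = border)
      rep <- metrics_report(res, image, truth = truth, peak = peak)
      row <- data.frame(condition = cond_name, algorithm = variant,
                        psnr = rep$psnr, vpc = rep$vpc, vpe = rep$vpe,
                        stringsAsFactors = FALSE)
      if (!is.null(truth)) row$misclassification <- rep$misclassification
      row$n_iter <- res$n_iter
      row$converged <- res$converged
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
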