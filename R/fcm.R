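# Fuzzy c-means on rasterized gray levels, plus the MMTDFCM variant that
# iterates on the medium membership (spatial blend of own and neighborhood
# memberships weighted by the similarity map).

.validate_membership <- function(u, arg = "memberships") {
  if (!is.matrix(u) || !is.numeric(u)) {
    stop(sprintf("'%s' must be a numeric clusters x pixels matrix", arg),
         call. = FALSE)
  }
  if (any(u < -1e-12 | u > 1 + 1e-12)) {
    stop(sprintf("'%s' has entries outside [0, 1]", arg), call. = FALSE)
  }
  if (max(abs(colSums(u) - 1)) > 1e-6) {
    stop(sprintf("'%s' columns must sum to 1", arg), call. = FALSE)
  }
  invisible(u)
}

# Run code with a private RNG stream: the caller's .Random.seed is untouched,
# and a NULL seed leaves the global stream in charge.
.with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Initial cluster centers for gray-level clustering
#'
#' `"quantile"` places the `clusters` centers at the `(i - 1/2)/clusters`
#' quantiles of the image's gray values: deterministic, spread across the
#' occupied gray range, and for well-separated gray masses it lands one center
#' in each mass.  `"random"` samples `clusters` pixel values (distinct values
#' when the image has that many) under the given seed.
#'
#' @param image Integer matrix of gray levels in `[0, 255]`.
#' @param clusters Number of clusters `c >= 2`.
#' @param method `"quantile"` (default) or `"random"`.
#' @param seed Integer seed for `"random"`; ignored for `"quantile"`.
#' @return Numeric vector of `clusters` centers on the gray scale.
#' @export
init_centers <- function(image, clusters, method = c("quantile", "random"),
                         seed = NULL) {
  method <- match.arg(method)
  .validate_image(image)
  clusters <- as.integer(clusters)
  if (clusters < 2L) stop("'clusters' must be at least 2", call. = FALSE)
  px <- as.numeric(image)
  if (clusters > length(px)) {
    stop("'clusters' exceeds the number of pixels", call. = FALSE)
  }
  if (method == "quantile") {
    probs <- (seq_len(clusters) - 0.5) / clusters
    return(unname(stats::quantile(px, probs = probs, names = FALSE)))
  }
  .with_seed(seed, {
    vals <- unique(px)
    if (length(vals) >= clusters) sort(sample(vals, clusters))
    else sort(sample(px, clusters))
  })
}

#' Fuzzy membership of pixels to cluster centers
#'
#' Classical fuzzy c-means membership from absolute gray distances
#' `d_ik = |x_k - v_i|`:
#' `u_ik = 1 / sum_j (d_ik / d_jk)^(2/(m-1))`.
#' A pixel coinciding with a center gets a crisp column: membership 1 for the
#' (lowest-indexed) zero-distance cluster, 0 elsewhere.
#'
#' @param pixels Numeric vector of gray levels.
#' @param centers Numeric vector of cluster centers.
#' @param m Fuzzifier exponent, `> 1`.
#' @return `length(centers) x length(pixels)` matrix; columns sum to 1.
#' @export
fuzzy_membership <- function(pixels, centers, m = 2) {
  if (!is.numeric(centers) || any(!is.finite(centers))) {
    stop("'centers' must be finite numeric", call. = FALSE)
  }
  if (m <= 1) stop("fuzzifier 'm' must exceed 1", call. = FALSE)
  d <- abs(outer(centers, as.numeric(pixels), "-"))
  u <- matrix(0, nrow(d), ncol(d))
  zero_cols <- which(colSums(d == 0) > 0L)
  if (length(zero_cols)) {
    first_zero <- apply(d[, zero_cols, drop = FALSE] == 0, 2, which.max)
    u[cbind(first_zero, zero_cols)] <- 1
  }
  reg_cols <- setdiff(seq_len(ncol(d)), zero_cols)
  if (length(reg_cols)) {
    w <- d[, reg_cols, drop = FALSE]^(-2 / (m - 1))
    u[, reg_cols] <- sweep(w, 2, colSums(w), "/")
  }
  u
}

# Neighborhood mean of one per-pixel field laid out as an M x N matrix.
.neighbor_mean_field <- function(mat, border, include_center = FALSE) {
  M <- nrow(mat)
  N <- ncol(mat)
  acc <- matrix(0, M, N)
  cnt <- matrix(0, M, N)
  for (k in seq_len(nrow(.offsets8))) {
    nb <- .shifted(mat, .offsets8[k, 1L], .offsets8[k, 2L], border)
    ok <- !is.na(nb)
    nb[!ok] <- 0
    acc <- acc + nb
    cnt <- cnt + ok
  }
  if (include_center) {
    acc <- acc + mat
    cnt <- cnt + 1
  }
  acc / cnt
}

#' Mean membership over each pixel's 3x3 neighborhood
#'
#' Averages each cluster's membership field over the eight 3x3 neighbors of
#' every pixel (the center pixel itself is excluded by default).  Averaging,
#' rather than summing, keeps every column of the result on the probability
#' simplex, which the medium-membership blend and the defuzzification step
#' rely on.
#'
#' @param memberships Clusters x pixels membership matrix (columns sum to 1).
#' @param image_dim Integer vector `c(M, N)`; `M * N` must equal the pixel
#'   count.  Pixels are rasterized in column-major order, matching
#'   `as.vector()` on the image matrix.
#' @param border Border policy, as in [neighborhood_similarity_map()].
#' @param include_center Also average in the center pixel's own membership
#'   (9-term mean instead of 8).
#' @return Membership matrix of the same shape; columns sum to 1.
#' @export
mean_neighbor_membership <- function(memberships, image_dim,
                                     border = c("replicate", "valid"),
                                     include_center = FALSE) {
  border <- match.arg(border)
  .validate_membership(memberships)
  M <- as.integer(image_dim[1])
  N <- as.integer(image_dim[2])
  if (M * N != ncol(memberships)) {
    stop("'image_dim' does not match the membership pixel count", call. = FALSE)
  }
  out <- memberships
  for (i in seq_len(nrow(memberships))) {
    field <- matrix(memberships[i, ], M, N)
    out[i, ] <- as.vector(.neighbor_mean_field(field, border, include_center))
  }
  out
}

#' Medium membership: similarity-weighted blend of own and neighborhood
#' membership
#'
#' Per-pixel convex combination
#' `u'_ik = hbar_k * ubar_ik + (1 - hbar_k) * u_ik`:
#' where a pixel resembles its neighborhood (`hbar` near 1) the blended
#' membership follows the neighborhood mean, and where it does not (`hbar`
#' near 0) the pixel keeps its own fuzzy membership.
#'
#' @param u Own fuzzy membership matrix (clusters x pixels).
#' @param u_bar Neighborhood-mean membership matrix, same shape.
#' @param h_bar Similarity map as a matrix or vector with one entry in
#'   `(0, 1]` per pixel.
#' @return Blended membership matrix; columns sum to 1.
#' @export
medium_membership <- function(u, u_bar, h_bar) {
  .validate_membership(u, "u")
  .validate_membership(u_bar, "u_bar")
  h <- as.numeric(h_bar)
  if (length(h) != ncol(u) || ncol(u) != ncol(u_bar) || nrow(u) != nrow(u_bar)) {
    stop("'u', 'u_bar' and 'h_bar' must share the pixel count", call. = FALSE)
  }
  if (any(h <= 0 | h > 1)) {
    stop("'h_bar' entries must lie in (0, 1]", call. = FALSE)
  }
  hm <- matrix(h, nrow(u), ncol(u), byrow = TRUE)
  hm * u_bar + (1 - hm) * u
}

#' Membership-weighted cluster center update
#'
#' Each center becomes the `membership^m`-weighted mean of the pixel gray
#' values: `v_i = sum_k u_ik^m x_k / sum_k u_ik^m`.  A cluster whose total
#' weight vanishes (possible when `clusters` exceeds the number of distinct
#' grays) keeps its previous center, with a warning.
#'
#' @param memberships Clusters x pixels membership matrix.
#' @param pixels Numeric vector of gray levels.
#' @param m Fuzzifier exponent, `> 1`.
#' @param prev Previous centers, used for degenerate (zero-weight) clusters.
#' @return Numeric vector of updated centers.
#' @export
update_centers <- function(memberships, pixels, m = 2, prev = NULL) {
  .validate_membership(memberships)
  if (m <= 1) stop("fuzzifier 'm' must exceed 1", call. = FALSE)
  w <- memberships^m
  den <- rowSums(w)
  num <- as.numeric(w %*% as.numeric(pixels))
  v <- num / den
  dead <- den == 0
  if (any(dead)) {
    if (is.null(prev)) {
      stop("cluster with zero total membership weight and no previous center",
           call. = FALSE)
    }
    warning("degenerate cluster: zero membership weight; keeping previous center",
            call. = FALSE)
    v[dead] <- prev[dead]
  }
  v
}

#' Hard labels from a membership matrix
#'
#' Maximum-membership rule: each pixel takes the cluster index of its largest
#' membership, ties going to the lowest cluster index.  Labels are 1-based.
#'
#' @param memberships Clusters x pixels membership matrix.
#' @param image_dim Integer vector `c(M, N)` giving the label-map shape.
#' @return Integer `M x N` matrix of labels in `1..clusters`.
#' @export
defuzzify <- function(memberships, image_dim) {
  .validate_membership(memberships)
  lab <- max.col(t(memberships), ties.method = "first")
  matrix(as.integer(lab), as.integer(image_dim[1]), as.integer(image_dim[2]))
}

# Fuzzy c-means objective sum_i sum_k u_ik^m d_ik^2 for gray-level clustering.
#' @rdname run_fcm
#' @param memberships,pixels Membership matrix and gray vector for
#'   `fcm_objective()`.
#' @export
fcm_objective <- function(memberships, pixels, centers, m = 2) {
  d2 <- outer(centers, as.numeric(pixels), "-")^2
  sum(memberships^m * d2)
}

#' Segment a grayscale image by fuzzy c-means or MMTDFCM
#'
#' Alternating optimization on the rasterized gray values.  Every iteration
#' computes the fuzzy memberships from the current centers, for the
#' `"mmtdfcm"` variant replaces them by the medium membership (the
#' similarity-weighted blend with the 3x3 neighborhood mean,
#' [medium_membership()]), and updates the centers with the resulting matrix.
#' The similarity map is computed once, before the loop, and held fixed.
#' Iteration stops when the largest absolute center change drops below `eps`
#' (Chebyshev norm) or after `max_iter` sweeps; the final memberships and
#' labels are recomputed from the converged centers.
#'
#' @param image Integer matrix of gray levels in `[0, 255]`.
#' @param clusters Number of clusters `c >= 2`.
#' @param variant `"mmtdfcm"` (spatially regularized) or `"fcm"` (classical
#'   baseline).
#' @param m Fuzzifier exponent `> 1` (default 2).
#' @param eps Convergence threshold on the center change (default `1e-5`).
#' @param max_iter Iteration cap (default 100).
#' @param init Center initialization method, see [init_centers()].
#' @param centers Optional explicit initial centers (overrides `init`); used
#'   to give paired runs of both variants an identical start.
#' @param seed Seed for `init = "random"`.
#' @param border Border policy for all 3x3 windows.
#' @param include_center Include the center pixel in the neighborhood mean.
#' @return An object of class `"fcm_result"`: a list with `labels` (integer
#'   matrix, 1-based), `memberships` (final clusters x pixels matrix — the
#'   blended matrix for `"mmtdfcm"`), `centers`, `n_iter`, `converged`,
#'   `center_history`, `objective` (per-iteration value of the weighted
#'   within-cluster objective), `h_bar` (similarity map, `"mmtdfcm"` only)
#'   and the resolved configuration.
#' @examples
#' ph <- make_phantom(32, 32)
#' res <- fcm_segment(ph$image, clusters = 3)
#' res$centers
#' @export
fcm_segment <- function(image, clusters, variant = c("mmtdfcm", "fcm"),
                        m = 2, eps = 1e-5, max_iter = 100,
                        init = c("quantile", "random"), centers = NULL,
                        seed = NULL, border = c("replicate", "valid"),
                        include_center = FALSE) {
  variant <- match.arg(variant)
  init <- match.arg(init)
  border <- match.arg(border)
  .validate_image(image)
  clusters <- as.integer(clusters)
  if (clusters < 2L) stop("'clusters' must be at least 2", call. = FALSE)
  if (m <= 1) stop("fuzzifier 'm' must exceed 1", call. = FALSE)
  if (eps <= 0) stop("'eps' must be positive", call. = FALSE)
  max_iter <- as.integer(max_iter)
  if (max_iter < 1L) stop("'max_iter' must be at least 1", call. = FALSE)

  dims <- dim(image)
  px <- as.numeric(image)
  if (is.null(centers)) {
    centers <- init_centers(image, clusters, method = init, seed = seed)
  } else {
    centers <- as.numeric(centers)
    if (length(centers) != clusters || any(!is.finite(centers))) {
      stop("'centers' must supply one finite value per cluster", call. = FALSE)
    }
  }

  h_bar <- NULL
  if (variant == "mmtdfcm") {
    h_bar <- neighborhood_similarity_map(image, border = border)
  }

  history <- list(centers)
  objective <- numeric(0)
  converged <- FALSE
  n_iter <- 0L
  up <- NULL
  blend <- function(v) {
    u <- fuzzy_membership(px, v, m)
    if (variant == "mmtdfcm") {
      ub <- mean_neighbor_membership(u, dims, border = border,
                                     include_center = include_center)
      medium_membership(u, ub, as.numeric(h_bar))
    } else {
      u
    }
  }
  for (l in seq_len(max_iter)) {
    up <- blend(centers)
    new_centers <- update_centers(up, px, m = m, prev = centers)
    history[[l + 1L]] <- new_centers
    objective[l] <- fcm_objective(up, px, new_centers, m = m)
    delta <- max(abs(new_centers - centers))
    centers <- new_centers
    n_iter <- l
    if (delta < eps) {
      converged <- TRUE
      break
    }
  }
  up <- blend(centers)
  labels <- defuzzify(up, dims)

  structure(list(
    labels = labels,
    memberships = up,
    centers = centers,
    n_iter = n_iter,
    converged = converged,
    center_history = history,
    objective = objective,
    h_bar = h_bar,
    config = list(clusters = clusters, variant = variant, m = m, eps = eps,
                  max_iter = max_iter, init = init, seed = seed,
                  border = border, include_center = include_center)
  ), class = "fcm_result")
}

#' Run the classical FCM baseline or the MMTDFCM variant
#'
#' Thin wrappers around [fcm_segment()] fixing the `variant`.
#'
#' @inheritParams fcm_segment
#' @param ... Passed on to [fcm_segment()].
#' @param centers Cluster centers (for `fcm_objective()`, the centers the
#'   objective is evaluated at).
#' @return See [fcm_segment()].
#' @export
run_fcm <- function(image, clusters, ...) {
  fcm_segment(image, clusters, variant = "fcm", ...)
}

#' @rdname run_fcm
#' @export
run_mmtdfcm <- function(image, clusters, ...) {
  fcm_segment(image, clusters, variant = "mmtdfcm", ...)
}

#' @export
print.fcm_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("%s segmentation: %d clusters, m = %g, eps = %g\n",
              toupper(cfg$variant), cfg$clusters, cfg$m, cfg$eps))
  cat(sprintf("  image: %d x %d pixels\n", nrow(x$labels), ncol(x$labels)))
  cat(sprintf("  iterations: %d (%s)\n", x$n_iter,
              if (x$converged) "converged" else "max_iter reached"))
  cat("  centers:", paste(sprintf("%.3f", x$centers), collapse = ", "), "\n")
  invisible(x)
}
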