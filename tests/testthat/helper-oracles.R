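# Independent explicit-loop oracles the vectorized implementation is checked
# against, plus small fixture builders.  Deliberately naive: scalar branches
# and quadruple loops, no shared code with R/.

oracle_hh <- function(f, x) {
  h <- function(a, b) {
    if (a < b) (a + 1) / (b + 1) else if (a > b) (256 - a) / (256 - b) else 1
  }
  (h(f, x) + h(x, f)) / 2
}

oracle_similarity_map <- function(image, border = "replicate") {
  M <- nrow(image)
  N <- ncol(image)
  out <- matrix(0, M, N)
  for (i in seq_len(M)) {
    for (j in seq_len(N)) {
      s <- 0
      cnt <- 0
      for (di in -1:1) {
        for (dj in -1:1) {
          if (di == 0 && dj == 0) next
          ii <- i + di
          jj <- j + dj
          if (border == "replicate") {
            ii <- min(max(ii, 1), M)
            jj <- min(max(jj, 1), N)
          } else if (ii < 1 || ii > M || jj < 1 || jj > N) {
            next
          }
          s <- s + oracle_hh(image[i, j], image[ii, jj])
          cnt <- cnt + 1
        }
      }
      out[i, j] <- s / cnt
    }
  }
  out
}

# One full MMTDFCM sweep transliterated with explicit loops: similarity map,
# fuzzy membership with the zero-distance rule, 8-neighbor mean membership,
# medium blend, and the membership^m-weighted center update.  Pixels are
# indexed column-major, as in the package.
oracle_mmtd_iteration <- function(image, centers, m) {
  M <- nrow(image)
  N <- ncol(image)
  nc <- length(centers)
  n <- M * N
  px <- as.vector(image)
  h_bar <- oracle_similarity_map(image, "replicate")

  u <- matrix(0, nc, n)
  for (k in seq_len(n)) {
    d <- abs(px[k] - centers)
    if (any(d == 0)) {
      u[which(d == 0)[1], k] <- 1
    } else {
      for (i in seq_len(nc)) u[i, k] <- 1 / sum((d[i] / d)^(2 / (m - 1)))
    }
  }

  idx <- function(i, j) (j - 1) * M + i
  u_bar <- matrix(0, nc, n)
  for (i in seq_len(M)) {
    for (j in seq_len(N)) {
      for (cc in seq_len(nc)) {
        s <- 0
        for (di in -1:1) {
          for (dj in -1:1) {
            if (di == 0 && dj == 0) next
            ii <- min(max(i + di, 1), M)
            jj <- min(max(j + dj, 1), N)
            s <- s + u[cc, idx(ii, jj)]
          }
        }
        u_bar[cc, idx(i, j)] <- s / 8
      }
    }
  }

  hv <- as.vector(h_bar)
  u_prime <- matrix(0, nc, n)
  for (k in seq_len(n)) {
    for (cc in seq_len(nc)) {
      u_prime[cc, k] <- hv[k] * u_bar[cc, k] + (1 - hv[k]) * u[cc, k]
    }
  }

  v <- numeric(nc)
  for (cc in seq_len(nc)) {
    w <- u_prime[cc, ]^m
    v[cc] <- sum(w * px) / sum(w)
  }
  list(h_bar = h_bar, u = u, u_bar = u_bar, u_prime = u_prime, centers = v)
}

random_gray_image <- function(M, N) {
  matrix(sample.int(256L, M * N, replace = TRUE) - 1L, M, N)
}

# Random column-stochastic clusters x n matrix.
random_membership <- function(clusters, n) {
  u <- matrix(stats::runif(clusters * n), clusters, n)
  sweep(u, 2, colSums(u), "/")
}
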