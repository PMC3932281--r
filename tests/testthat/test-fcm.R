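test_that("quantile initialization lands one center per well-separated gray mass", {
  img <- matrix(rep(c(0L, 160L, 255L), each = 30), 10, 9)
  expect_equal(init_centers(img, 3), c(0, 160, 255))
  expect_equal(init_centers(matrix(77L, 4, 4), 2), c(77, 77))
  expect_error(init_centers(matrix(0L, 2, 2), 5), "exceeds the number of pixels")
})

test_that("random initialization is seeded and leaves the global RNG alone", {
  img <- random_gray_image(8, 8)
  a <- init_centers(img, 3, method = "random", seed = 7)
  set.seed(123)
  before <- .Random.seed
  b <- init_centers(img, 3, method = "random", seed = 7)
  expect_identical(.Random.seed, before)
  expect_identical(a, b)
})

test_that("fuzzy membership reproduces hand-computed grades and the crisp rule", {
  expect_equal(fuzzy_membership(50, c(0, 100), m = 2), cbind(c(0.5, 0.5)))
  expect_equal(fuzzy_membership(25, c(0, 100), m = 2), cbind(c(0.9, 0.1)))
  # pixel coinciding with a center is crisp, for any fuzzifier
  for (m in c(1.5, 2, 3)) {
    expect_equal(fuzzy_membership(100, c(100, 37), m = m), cbind(c(1, 0)))
  }
  # coincident centers: crisp mass goes to the lowest index
  expect_equal(fuzzy_membership(80, c(80, 80), m = 2), cbind(c(1, 0)))
  expect_error(fuzzy_membership(10, c(0, Inf)), "finite")
  expect_error(fuzzy_membership(10, c(0, 100), m = 1), "exceed 1")
})

test_that("membership stages all preserve column-stochasticity", {
  set.seed(5)
  for (rep in 1:10) {
    img <- random_gray_image(6, 7)
    clusters <- sample(2:4, 1)
    centers <- init_centers(img, clusters, method = "random", seed = rep)
    u <- fuzzy_membership(as.vector(img), centers, m = runif(1, 1.3, 3))
    expect_equal(colSums(u), rep(1, 42), tolerance = 1e-9)
    ub <- mean_neighbor_membership(u, dim(img))
    expect_equal(colSums(ub), rep(1, 42), tolerance = 1e-9)
    h <- as.vector(neighborhood_similarity_map(img))
    up <- medium_membership(u, ub, h)
    expect_equal(colSums(up), rep(1, 42), tolerance = 1e-9)
  }
})

test_that("neighborhood mean membership matches a brute-force neighbor loop", {
  set.seed(8)
  u <- random_membership(3, 16)
  got <- mean_neighbor_membership(u, c(4, 4))
  for (cc in 1:3) {
    field <- matrix(u[cc, ], 4, 4)
    brute <- matrix(0, 4, 4)
    for (i in 1:4) {
      for (j in 1:4) {
        s <- 0
        for (di in -1:1) {
          for (dj in -1:1) {
            if (di == 0 && dj == 0) next
            s <- s + field[min(max(i + di, 1), 4), min(max(j + dj, 1), 4)]
          }
        }
        brute[i, j] <- s / 8
      }
    }
    expect_equal(matrix(got[cc, ], 4, 4), brute, tolerance = 1e-12)
  }
  # spatially constant membership field is a fixed point
  uc <- matrix(c(0.3, 0.7), 2, 12)
  expect_equal(mean_neighbor_membership(uc, c(3, 4)), uc)
  # crisp pixel surrounded by 8 crisp opposites takes the neighbors' column
  field <- matrix(0, 2, 9)
  field[2, ] <- 1
  field[, 5] <- c(1, 0)
  ub <- mean_neighbor_membership(field, c(3, 3))
  expect_equal(ub[, 5], c(0, 1))
})

test_that("medium membership is the similarity-weighted convex blend", {
  u <- cbind(c(0.9, 0.1))
  ub <- cbind(c(0.5, 0.5))
  expect_equal(medium_membership(u, ub, 0.8), cbind(c(0.58, 0.42)))
  # h = 1 returns the neighborhood mean; equal inputs are a fixed point
  expect_equal(medium_membership(u, ub, 1), ub)
  expect_equal(medium_membership(u, u, 0.37), u)
  expect_error(medium_membership(u, ub, 0), "\\(0, 1\\]")
  expect_error(medium_membership(u, ub, 1.2), "\\(0, 1\\]")
  # convexity: blended grade lies between the two inputs, elementwise
  set.seed(3)
  ua <- random_membership(4, 20)
  ubb <- random_membership(4, 20)
  h <- runif(20, 0.01, 1)
  up <- medium_membership(ua, ubb, h)
  expect_true(all(up >= pmin(ua, ubb) - 1e-12))
  expect_true(all(up <= pmax(ua, ubb) + 1e-12))
})

test_that("center update is the membership^m weighted gray mean", {
  u <- rbind(c(1, 1, 0), c(0, 0, 1))
  expect_equal(update_centers(u, c(10, 20, 90), m = 2), c(15, 90))
  uu <- matrix(1 / 3, 3, 4)
  expect_equal(update_centers(uu, c(0, 10, 20, 30), m = 2.5), rep(15, 3))
  u2 <- rbind(c(0.9, 0.1), c(0.1, 0.9))
  expect_equal(update_centers(u2, c(0, 100), m = 2)[1],
               (0.81 * 0 + 0.01 * 100) / 0.82, tolerance = 1e-12)
  # degenerate all-zero row keeps the previous center, with a warning
  ud <- rbind(c(1, 1), c(0, 0))
  expect_warning(v <- update_centers(ud, c(4, 6), m = 2, prev = c(0, 42)),
                 "degenerate")
  expect_equal(v, c(5, 42))
})

test_that("defuzzification takes the maximal membership, ties to the lowest index", {
  u <- cbind(c(0.2, 0.7, 0.1), c(1, 0, 0), c(1 / 3, 1 / 3, 1 / 3))
  expect_equal(as.vector(defuzzify(u, c(1, 3))), c(2L, 1L, 1L))
  u2 <- cbind(c(0.5, 0.5))
  expect_equal(as.vector(defuzzify(u2, c(1, 1))), 1L)
})

test_that("both variants recover a clean three-level phantom exactly", {
  ph <- make_phantom(64, 64)
  for (variant in c("fcm", "mmtdfcm")) {
    res <- fcm_segment(ph$image, 3, variant = variant)
    expect_true(res$converged)
    expect_equal(misclassification_rate(res$labels, ph$labels, 3), 0)
    expect_equal(res$centers, c(0, 160, 255), tolerance = 1 / 160)
  }
})

test_that("a constant image collapses to one label and converges immediately", {
  res <- suppressWarnings(fcm_segment(matrix(90L, 8, 8), 2, variant = "fcm"))
  expect_true(res$converged)
  expect_lte(res$n_iter, 2L)
  expect_equal(unique(as.vector(res$labels)), 1L)
})

test_that("crisp-correct centers on separated data are a fixed point of FCM", {
  img <- matrix(rep(c(0L, 200L), each = 18), 6, 6)
  res <- fcm_segment(img, 2, variant = "fcm", centers = c(0, 200))
  expect_equal(res$center_history[[2]], c(0, 200))
  expect_true(res$converged)
})

test_that("the FCM objective is non-increasing across iterations", {
  set.seed(21)
  for (rep in 1:10) {
    res <- run_fcm(random_gray_image(16, 16), 3, init = "random", seed = rep)
    expect_true(all(diff(res$objective) <= 1e-8))
  }
})

test_that("permuting the initial centers permutes rows and relabels identically", {
  ph <- make_phantom(24, 24)
  noisy <- add_gaussian(ph$image, 0.01, seed = 2)
  a <- fcm_segment(noisy, 3, centers = c(0, 160, 255))
  b <- fcm_segment(noisy, 3, centers = c(255, 0, 160))
  perm <- c(3, 1, 2)  # row i of b started from a's init center perm[i]
  expect_equal(b$centers, a$centers[perm], tolerance = 1e-9)
  expect_equal(b$memberships, a$memberships[perm, ], tolerance = 1e-9)
  expect_equal(misclassification_rate(a$labels, b$labels, 3), 0)
})

test_that("seeded runs are bit-reproducible end to end", {
  ph <- make_phantom(32, 32)
  noisy <- add_salt_pepper(ph$image, 0.05, seed = 9)
  a <- fcm_segment(noisy, 3, init = "random", seed = 4)
  b <- fcm_segment(noisy, 3, init = "random", seed = 4)
  expect_identical(a, b)
})

test_that("one full MMTDFCM sweep matches the explicit-loop transliteration", {
  set.seed(77)
  img <- random_gray_image(5, 5)
  centers <- c(60, 190)
  oracle <- oracle_mmtd_iteration(img, centers, m = 2)
  h <- neighborhood_similarity_map(img)
  u <- fuzzy_membership(as.vector(img), centers, m = 2)
  ub <- mean_neighbor_membership(u, dim(img))
  up <- medium_membership(u, ub, as.vector(h))
  v <- update_centers(up, as.vector(img), m = 2)
  expect_equal(h, oracle$h_bar, tolerance = 1e-12)
  expect_equal(u, oracle$u, tolerance = 1e-12)
  expect_equal(ub, oracle$u_bar, tolerance = 1e-12)
  expect_equal(up, oracle$u_prime, tolerance = 1e-12)
  expect_equal(v, oracle$centers, tolerance = 1e-12)
  # and the engine's first recorded center update agrees too
  res <- fcm_segment(img, 2, centers = centers, max_iter = 1)
  expect_equal(res$center_history[[2]], oracle$centers, tolerance = 1e-12)
})
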