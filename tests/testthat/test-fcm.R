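test_that("two well-separated groups give crisp clusters at their means", {
  x <- c(0, 0, 0, 10, 10, 10)
  fit <- fcm_cluster(x, n_clusters = 2, fuzziness = 2)
  expect_equal(fit$centroids, c(0, 10), tolerance = 1e-6)
  u <- fit$memberships
  expect_true(all(u[x == 0, 1] > 0.99))
  expect_true(all(u[x == 10, 2] > 0.99))
})

test_that("memberships sum to one and samples at a centroid are crisp", {
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(50, sample(1:5, 1), runif(1, 0.5, 2))
    fit <- fcm_cluster(x, n_clusters = sample(2:4, 1), fuzziness = 2)
    expect_true(all(abs(rowSums(fit$memberships) - 1) < 1e-9))
    expect_true(!is.unsorted(fit$centroids, strictly = TRUE))
  }
  # a sample exactly at a centroid has membership 1 there, 0 elsewhere
  fit <- fcm_cluster(c(1, 2, 3, 7, 8, 9), 2)
  x2 <- c(fit$centroids[1], fit$centroids[2], 5)
  d2 <- outer(x2, fit$centroids, function(a, b) (a - b)^2)
  u <- bpequant:::fcm_memberships(d2, 2)
  expect_identical(u[1, ], c(1, 0))
  expect_identical(u[2, ], c(0, 1))
})

test_that("the fuzzy objective is non-increasing across iterations", {
  set.seed(21)
  for (i in 1:100) {
    x <- c(rnorm(30), rnorm(30, runif(1, 1, 8)))
    fit <- fcm_cluster(x, n_clusters = 2, fuzziness = runif(1, 1.5, 3))
    expect_true(all(diff(fit$objective) <= 1e-8 * (1 + abs(fit$objective[-1]))))
  }
})

test_that("fcm_cluster agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(5)
  for (i in 1:5) {
    x <- c(rnorm(80, 0, 1), rnorm(60, 6, 1.2), rnorm(40, 14, 1.5))
    fit <- fcm_cluster(x, n_clusters = 3, fuzziness = 2, tol = 1e-8)
    ref <- e1071::cmeans(matrix(x), centers = matrix(sort(fit$centroids)),
                         m = 2, iter.max = 500)
    expect_equal(sort(fit$centroids), unname(sort(drop(ref$centers))),
                 tolerance = 1e-3)
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(fcm_cluster(c(1, 1, 1, 1), 2), "distinct")
  expect_error(fcm_cluster(c(1, 2, 3), 2, fuzziness = 1), "fuzziness")
  expect_error(fcm_cluster(c(1, 2, 3), 2, tol = 0), "tol")
  expect_error(fcm_cluster(c(1, NA, 3), 2), "finite")
})
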