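test_that("curvature clipping enforces the printed bounds", {
  r <- clip_curvature_features(H = c(0, 20, -20), K = c(100, -3, 0.5))
  expect_equal(r$K, c(45, -3, 0.5))
  expect_equal(r$K2, c(45, 9, 0.25))
  expect_equal(r$H, c(0, 15, -15))
  expect_equal(r$H2, c(0, 15, 15))
})

test_that("NaN curvatures are replaced by the finite mean before clipping", {
  r <- clip_curvature_features(H = c(NaN, 2, 4), K = c(0, 0, 0))
  expect_equal(r$H, c(3, 2, 4))
  expect_error(clip_curvature_features(H = c(NaN, NaN), K = c(1, 2)),
               "no finite mean")
})

test_that("clipping is idempotent on adversarial inputs", {
  set.seed(99)
  H <- c(rnorm(200, 0, 40), Inf, -Inf, 1e6, -1e6)
  K <- c(rnorm(200, 0, 200), 1e9, -1e9, NaN, 0)
  r1 <- clip_curvature_features(H, K)
  r2 <- clip_curvature_features(r1$H, r1$K)
  expect_equal(r2$H, r1$H)
  expect_equal(r2$K, r1$K)
  expect_equal(r2$K2, r1$K2)
  expect_true(all(abs(r1$K) <= 45), all(r1$K2 >= 0 & r1$K2 <= 45))
  expect_true(all(abs(r1$H) <= 15), all(r1$H2 >= 0 & r1$H2 <= 15))
})

test_that("1-D k-means splits separable clusters exactly", {
  D <- c(rep(1, 100), rep(5, 100))
  r <- kmeans_region_labels(D, 2, seed = 3)
  expect_equal(r$centers, c(1, 5))
  expect_equal(r$labels, c(rep(0L, 100), rep(1L, 100)))
  expect_error(kmeans_region_labels(rep(2, 50), 2), "distinct")
})

test_that("seeded k-means attains the dynamic-programming optimum", {
  for (s in 1:20) {
    set.seed(s)
    D <- runif(80, 0, 3)
    k <- sample(2:4, 1)
    r <- kmeans_region_labels(D, k, seed = s)
    wcss <- sum(vapply(0:(k - 1), function(c0) {
      sum((D[r$labels == c0] - mean(D[r$labels == c0]))^2)
    }, 0))
    expect_equal(wcss, dp_kmeans_wcss(D, k), tolerance = 1e-8)
  }
})

test_that("region labels are canonical across seeds on separated data", {
  D <- c(runif(50, 0, 0.2), runif(50, 1, 1.2), runif(50, 3, 3.2))
  a <- kmeans_region_labels(D, 3, seed = 1)
  b <- kmeans_region_labels(D, 3, seed = 999)
  expect_equal(a$labels, b$labels)
  expect_true(all(diff(a$centers) > 0))
})

test_that("region label stack covers k = 2..10 with ordinal labels", {
  set.seed(8)
  D <- runif(300, 0, 2)
  rg <- region_label_set(D, seed = 4)
  expect_equal(dim(rg$S), c(300L, 9L))
  for (i in seq_along(rg$ks)) {
    expect_true(all(rg$S[, i] %in% 0:(rg$ks[i] - 1)))
  }
})

test_that("feature assembly follows the per-variant schema", {
  set.seed(2)
  n <- 50
  curv <- list(H = rnorm(n), K = rnorm(n))
  Z1 <- assemble_features("dnn1", curv)
  expect_equal(dim(Z1), c(n, 4L))
  expect_equal(colnames(Z1), c("H", "H2", "K", "K2"))

  D <- runif(n)
  Z2 <- assemble_features("dnn2", curv, D = D)
  expect_equal(dim(Z2), c(n, 5L))
  expect_equal(Z2[, "D"], D)

  rg <- region_label_set(D, seed = 1)
  Z3 <- assemble_features("dnn3", curv, regions = rg)
  expect_equal(dim(Z3), c(n, 11L))
  expect_equal(colnames(Z3), c("K", "K2", paste0("S", 2:10)))

  expect_error(assemble_features("dnn2", curv), "needs D")
  expect_error(assemble_features("dnn3", curv), "region")
  expect_true(all(is.finite(Z1)), all(is.finite(Z3)))
})

test_that("feature rows stay aligned with vertices", {
  n <- 30
  curv <- list(H = seq_len(n) * 0.1, K = -seq_len(n) * 0.1)
  Z <- assemble_features("dnn1", curv)
  expect_equal(unname(Z[17, "H"]), 1.7)
  expect_equal(unname(Z[17, "K2"]), min(1.7^2, 45))
})
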