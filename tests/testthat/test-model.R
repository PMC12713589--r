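test_that("weighted BCE matches analytic values", {
  # perfect prediction: ~0
  Y <- rbind(c(1, 0))
  expect_lt(weighted_bce_loss(Y, rbind(c(1 - 1e-7, 1e-7))), 1e-5)
  # uniform prediction on one vertex: 2 ln 2 over the two output units
  expect_equal(weighted_bce_loss(Y, rbind(c(0.5, 0.5))), 2 * log(2),
               tolerance = 1e-12)
  expect_error(weighted_bce_loss(Y, rbind(c(1.2, 0.5))),
               "outside \\(0,1\\)")
})

test_that("per-mesh weights enter squared", {
  set.seed(1)
  n <- 20
  Y <- label_onehot(sample(c("spine", "shaft"), n, TRUE))
  P <- matrix(runif(2 * n, 0.1, 0.9), ncol = 2)
  id <- rep(1:2, each = n / 2)
  base <- weighted_bce_loss(Y, P, w = c(1, 1), mesh_id = id)
  l1 <- weighted_bce_loss(Y, P, w = c(2, 1), mesh_id = id)
  per_mesh1 <- weighted_bce_loss(Y[id == 1, ], P[id == 1, ])
  # doubling w_1 quadruples mesh 1's contribution
  expect_equal(l1 - base, 3 * per_mesh1 / 2, tolerance = 1e-12)
})

test_that("loss is invariant to mesh ordering", {
  set.seed(2)
  Zs <- lapply(1:3, function(i) matrix(rnorm(40), ncol = 4))
  Ys <- lapply(1:3, function(i) sample(c("spine", "shaft"), 10, TRUE))
  m1 <- spine_mlp(Zs, Ys, variant = "dnn1", epochs = 0, seed = 5)
  P <- lapply(Zs, function(z) predict(m1, z))
  l_fwd <- weighted_bce_loss(do.call(rbind, lapply(Ys, label_onehot)),
                             do.call(rbind, P),
                             mesh_id = rep(1:3, each = 10))
  perm <- c(3, 1, 2)
  l_perm <- weighted_bce_loss(
    do.call(rbind, lapply(Ys[perm], label_onehot)),
    do.call(rbind, P[perm]),
    mesh_id = rep(1:3, each = 10))
  expect_equal(l_fwd, l_perm, tolerance = 1e-12)
})

test_that("training separates linearly separable curvature classes", {
  set.seed(11)
  n <- 600
  lab <- sample(c("spine", "shaft"), n, TRUE)
  K <- ifelse(lab == "spine", rnorm(n, 12, 1.5), rnorm(n, 0, 1.5))
  H <- rnorm(n, -1, 0.5)
  Z <- assemble_features("dnn1", list(H = H, K = K))
  m <- spine_mlp(Z, lab, epochs = 200, seed = 3)
  pred <- classify_vertices(predict(m, Z))
  expect_gte(mean(pred == lab), 0.98)
  expect_lte(tail(m$loss_history, 1), m$loss_history[1])
})

test_that("training is deterministic given the seed", {
  set.seed(4)
  Z <- matrix(rnorm(200), ncol = 4)
  y <- sample(c("spine", "shaft"), 50, TRUE)
  m1 <- spine_mlp(Z, y, variant = "dnn1", epochs = 50, seed = 42)
  m2 <- spine_mlp(Z, y, variant = "dnn1", epochs = 50, seed = 42)
  for (l in seq_along(m1$W)) {
    expect_equal(m1$W[[l]], m2$W[[l]], tolerance = 1e-6)
  }
  expect_equal(m1$loss_history, m2$loss_history, tolerance = 1e-10)
})

test_that("zero-epoch fit returns the initialized model", {
  Z <- matrix(rnorm(40), ncol = 4)
  y <- rep(c("spine", "shaft"), 5)
  m <- spine_mlp(Z, y, variant = "dnn1", epochs = 0)
  expect_length(m$loss_history, 0)
  expect_length(m$W, 5)              # 4 hidden + output
  expect_equal(dim(m$W[[1]]), c(4L, 50L))
  expect_equal(dim(m$W[[5]]), c(50L, 2L))
})

test_that("predictions are probabilities with pure-function semantics", {
  m <- spine_mlp(matrix(rnorm(80), ncol = 4),
                 rep(c("spine", "shaft"), 10), variant = "dnn1",
                 epochs = 5)
  P0 <- predict(m, matrix(numeric(0), 0, 4))
  expect_equal(dim(P0), c(0L, 2L))
  Z <- matrix(rnorm(40), ncol = 4)
  P <- predict(m, Z)
  expect_true(all(P > 0 & P < 1))
  Pdup <- predict(m, Z[c(1, 1, 2, 2), ])
  expect_equal(Pdup[1, ], Pdup[2, ])
  expect_equal(Pdup[3, ], Pdup[4, ])
  expect_error(predict(m, Z[, 1:3]), "schema")
})

test_that("classification follows the prose rule with shaft ties", {
  P <- rbind(c(0.8, 0.3), c(0.5, 0.5), c(0.2, 0.9))
  expect_equal(classify_vertices(P), c("spine", "shaft", "shaft"))
  # scale invariance in (a, b)
  expect_equal(classify_vertices(P, a = 2, b = 2), classify_vertices(P))
  # raising b never converts shaft calls to spine
  set.seed(6)
  Pr <- matrix(runif(60), ncol = 2)
  prev <- classify_vertices(Pr, 1, 0.25)
  for (b in c(0.5, 1, 2, 4)) {
    cur <- classify_vertices(Pr, 1, b)
    expect_true(all(!(prev == "shaft" & cur == "spine")))
    prev <- cur
  }
})

test_that("checkpoints round-trip model predictions", {
  m <- spine_mlp(matrix(rnorm(200), ncol = 4),
                 sample(c("spine", "shaft"), 50, TRUE),
                 variant = "dnn1", epochs = 20, seed = 8)
  p <- withr::local_tempfile(fileext = ".json")
  write_checkpoint(m, p)
  m2 <- read_checkpoint(p)
  Z <- matrix(rnorm(40), ncol = 4)
  expect_equal(predict(m2, Z), predict(m, Z), tolerance = 1e-12)
  expect_equal(m2$variant, m$variant)
})

test_that("balance weighting up-weights spine-poor meshes", {
  set.seed(13)
  Zs <- list(matrix(rnorm(400), ncol = 4), matrix(rnorm(400), ncol = 4))
  ys <- list(c(rep("spine", 50), rep("shaft", 50)),
             c(rep("spine", 5), rep("shaft", 95)))
  m <- spine_mlp(Zs, ys, variant = "dnn1", epochs = 0,
                 weights = "balance")
  w <- m$config$weights
  expect_gt(w[2], w[1])
})
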