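test_that("mean curvature matches analytic values and the sign convention", {
  # spheres: |H| = 1/r, convex => negative
  for (r in c(0.5, 1, 2)) {
    s <- icosphere(3, r)
    H <- mean_curvature(s)
    expect_equal(median(H), -1 / r, tolerance = 0.05)
  }
  # open cylinder: principal curvatures 1/r and 0 => |H| = 1/(2r)
  cyl <- open_cylinder(r = 0.5, len = 4)
  H <- mean_curvature(cyl)
  ii <- cylinder_interior(cyl, 4)
  expect_equal(median(H[ii]), -1, tolerance = 0.1)
  # flat sheet: H ~ 0 on interior vertices
  g <- flat_grid(15)
  Hg <- mean_curvature(g)
  expect_lt(max(abs(Hg[grid_interior(15)])), 1e-6)
})

test_that("Gaussian curvature matches analytic values", {
  s <- icosphere(3, 2)
  K <- gaussian_curvature(s)
  expect_equal(median(K), 0.25, tolerance = 0.05)
  cyl <- open_cylinder(r = 0.5, len = 4)
  K2 <- gaussian_curvature(cyl)
  ii <- cylinder_interior(cyl, 4)
  expect_lt(median(abs(K2[ii])), 0.02 * (1 / 0.5^2))
  # saddle z = x^2 - y^2: K(0,0) = -4
  sd <- flat_grid(21, fz = function(x, y) x^2 - y^2)
  Ks <- gaussian_curvature(sd)
  center <- which.min(rowSums(sd$vertices[, 1:2]^2))
  expect_equal(Ks[center], -4, tolerance = 0.15 * 4)
})

test_that("Gauss-Bonnet holds on closed meshes", {
  s <- icosphere(3)
  cf <- curvature_field(s)
  expect_equal(sum(cf$K * cf$A), 4 * pi, tolerance = 0.01)
  tor <- torus_mesh()
  cft <- curvature_field(tor)
  expect_lt(abs(sum(cft$K * cft$A)), 0.05)
  expect_equal(euler_characteristic(s), 2L)
  expect_equal(euler_characteristic(tor), 0L)
})

test_that("curvature operators are rigid-motion and scale covariant", {
  s <- icosphere(2, 1.3)
  H0 <- mean_curvature(s)
  K0 <- gaussian_curvature(s)
  # rotation + translation
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  s2 <- triangle_mesh(s$vertices %*% t(R) + 2.5, s$faces)
  expect_equal(mean_curvature(s2), H0, tolerance = 1e-9)
  expect_equal(gaussian_curvature(s2), K0, tolerance = 1e-9)
  # uniform scale by s: H -> H/s, K -> K/s^2
  sc <- 2.7
  s3 <- triangle_mesh(s$vertices * sc, s$faces)
  expect_equal(mean_curvature(s3), H0 / sc, tolerance = 1e-6)
  expect_equal(gaussian_curvature(s3), K0 / sc^2, tolerance = 1e-6)
})

test_that("Willmore energy is scale invariant and ~4pi on spheres", {
  for (r in c(0.7, 2)) {
    s <- icosphere(3, r)
    expect_equal(willmore_energy(s, k_bend = 2), 4 * pi, tolerance = 0.05)
  }
  expect_identical(willmore_energy(icosphere(1), k_bend = 0), 0)
  # refinement changes the energy by < 5%
  e_coarse <- willmore_energy(icosphere(2), 2)
  e_fine <- willmore_energy(icosphere(4), 2)
  expect_equal(e_coarse, e_fine, tolerance = 0.05)
})

test_that("analytic bending gradient passes the finite-difference check", {
  set.seed(12)
  m <- icosphere(1)                         # 42 vertices
  m$vertices <- m$vertices +
    matrix(rnorm(length(m$vertices), 0, 0.01), ncol = 3)
  eg <- spineseg:::.cpp_willmore_energy_grad(m$vertices, m$faces, 1, TRUE)
  h <- 1e-6
  fd <- eg$gradient * 0
  for (i in seq_len(nrow(m$vertices))) {
    for (d in 1:3) {
      vp <- m$vertices; vp[i, d] <- vp[i, d] + h
      vm <- m$vertices; vm[i, d] <- vm[i, d] - h
      ep <- spineseg:::.cpp_willmore_energy_grad(vp, m$faces, 1, FALSE)$energy
      em <- spineseg:::.cpp_willmore_energy_grad(vm, m$faces, 1, FALSE)$energy
      fd[i, d] <- (ep - em) / (2 * h)
    }
  }
  expect_lt(max(abs(eg$gradient - fd)) / max(abs(fd)), 1e-4)
})

test_that("bending flow reduces curvature noise monotonically", {
  set.seed(7)
  s <- icosphere(3)
  noisy <- triangle_mesh(
    s$vertices + matrix(rnorm(length(s$vertices), 0, 0.02), ncol = 3),
    s$faces)
  err0 <- median(abs(gaussian_curvature(noisy) - 1))
  fl <- smooth_mesh(noisy, n_iters = 200)
  expect_true(all(diff(fl$energy) <= 1e-9))
  err1 <- median(abs(gaussian_curvature(fl$mesh) - 1))
  expect_lt(err1, err0 / 2)
  # volume preserved by renormalization
  expect_equal(mesh_volume(fl$mesh), mesh_volume(noisy), tolerance = 1e-6)
})

test_that("flow is near a fixed point on an already-smooth sphere", {
  s <- icosphere(3)
  fl <- smooth_mesh(s, n_iters = 20)
  disp <- sqrt(rowSums((fl$mesh$vertices - s$vertices)^2))
  expect_lt(max(disp) / 20, 1e-3)
})

test_that("flow with zero iterations returns the input unchanged", {
  s <- icosphere(2)
  fl <- smooth_mesh(s, n_iters = 0)
  expect_identical(fl$mesh$vertices, s$vertices)
  expect_length(fl$energy, 1)
})

test_that("willmore_energy reports NaN-curvature vertices", {
  m <- tetrahedron()
  m2 <- triangle_mesh(rbind(m$vertices, c(9, 9, 9)), m$faces,
                      validate = FALSE)  # isolated vertex
  expect_error(willmore_energy(m2), "NaN curvature")
})

test_that("curvature CSV export has the documented schema", {
  cf <- curvature_field(icosphere(1))
  p <- withr::local_tempfile(fileext = ".csv")
  write_curvature_csv(cf, p)
  d <- read.csv(p)
  expect_named(d, c("vertex_index", "H", "K", "area"))
  expect_equal(d$vertex_index[1], 0)
  expect_equal(nrow(d), length(cf$H))
})
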