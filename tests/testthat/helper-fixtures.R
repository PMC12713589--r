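# Analytic test meshes and independent oracles, built in code.

icosphere <- function(subdiv = 3, r = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11),
             c(1, 11, 12), c(2, 6, 10), c(6, 12, 5), c(12, 11, 3),
             c(11, 8, 7), c(8, 2, 9), c(4, 10, 5), c(4, 5, 3),
             c(4, 3, 7), c(4, 7, 9), c(4, 9, 10), c(5, 10, 6),
             c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    key <- new.env(parent = emptyenv())
    mid <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      if (!is.null(key[[k]])) return(key[[k]])
      p <- v[a, ] + v[b, ]
      p <- p / sqrt(sum(p^2))
      v <<- rbind(v, p)
      key[[k]] <- nrow(v)
      nrow(v)
    }
    nf <- vector("list", nrow(f))
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- mid(a, b); bc <- mid(b, c); ca <- mid(c, a)
      nf[[i]] <- rbind(c(a, ab, ca), c(b, bc, ab), c(c, ca, bc),
                       c(ab, bc, ca))
    }
    f <- do.call(rbind, nf)
  }
  triangle_mesh(v * r, f)
}

# open tube along z (no caps); outward orientation
open_cylinder <- function(r = 0.5, len = 4, nu = 48, nv = 40) {
  th <- seq(0, 2 * pi, length.out = nu + 1)[-(nu + 1)]
  zs <- seq(-len / 2, len / 2, length.out = nv)
  v <- cbind(r * cos(rep(th, nv)), r * sin(rep(th, nv)),
             rep(zs, each = nu))
  f <- NULL
  idx <- function(i, j) (j - 1) * nu + i
  fl <- vector("list", (nv - 1) * nu)
  k <- 0
  for (j in seq_len(nv - 1)) {
    for (i in seq_len(nu)) {
      i2 <- i %% nu + 1
      k <- k + 1
      fl[[k]] <- rbind(c(idx(i, j), idx(i2, j), idx(i2, j + 1)),
                       c(idx(i, j), idx(i2, j + 1), idx(i, j + 1)))
    }
  }
  triangle_mesh(v, do.call(rbind, fl))
}

# interior vertices of the open cylinder (away from the rim)
cylinder_interior <- function(mesh, len, frac = 0.25) {
  which(abs(mesh$vertices[, 3]) < len / 2 * (1 - frac))
}

# flat unit square grid in the z = 0 plane
flat_grid <- function(n = 15, fz = function(x, y) 0 * x) {
  xs <- seq(-1, 1, length.out = n)
  g <- expand.grid(x = xs, y = xs)
  v <- cbind(g$x, g$y, fz(g$x, g$y))
  idx <- function(i, j) (j - 1) * n + i
  fl <- vector("list", (n - 1)^2)
  k <- 0
  for (j in seq_len(n - 1)) {
    for (i in seq_len(n - 1)) {
      k <- k + 1
      fl[[k]] <- rbind(c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
                       c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
    }
  }
  triangle_mesh(v, do.call(rbind, fl))
}

grid_interior <- function(n = 15, margin = 3) {
  g <- expand.grid(i = seq_len(n), j = seq_len(n))
  which(g$i > margin & g$i <= n - margin & g$j > margin & g$j <= n - margin)
}

torus_mesh <- function(R = 1, r = 0.35, nu = 48, nv = 24) {
  us <- seq(0, 2 * pi, length.out = nu + 1)[-(nu + 1)]
  vs <- seq(0, 2 * pi, length.out = nv + 1)[-(nv + 1)]
  g <- expand.grid(u = us, v = vs)
  v3 <- cbind((R + r * cos(g$v)) * cos(g$u),
              (R + r * cos(g$v)) * sin(g$u),
              r * sin(g$v))
  idx <- function(i, j) (j - 1) * nu + i
  fl <- vector("list", nu * nv)
  k <- 0
  for (j in seq_len(nv)) {
    j2 <- j %% nv + 1
    for (i in seq_len(nu)) {
      i2 <- i %% nu + 1
      k <- k + 1
      fl[[k]] <- rbind(c(idx(i, j), idx(i2, j), idx(i2, j2)),
                       c(idx(i, j), idx(i2, j2), idx(i, j2)))
    }
  }
  triangle_mesh(v3, do.call(rbind, fl))
}

tetrahedron <- function() {
  triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
}

# axis-aligned unit cube as 12 triangles (outward orientation)
cube_mesh <- function(side = 1) {
  v <- as.matrix(expand.grid(x = c(0, side), y = c(0, side),
                             z = c(0, side)))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),      # z = 0
    c(5, 6, 7), c(6, 8, 7),      # z = side
    c(1, 2, 5), c(2, 6, 5),      # y = 0
    c(3, 7, 4), c(4, 7, 8),      # y = side
    c(1, 5, 3), c(3, 5, 7),      # x = 0
    c(2, 4, 6), c(4, 8, 6))      # x = side
  triangle_mesh(v, f)
}

# --- independent oracles -------------------------------------------------

# brute-force 1-ring adjacency by scanning every face
bf_adjacency <- function(mesh) {
  n <- nrow(mesh$vertices)
  nb <- vector("list", n)
  for (r in seq_len(nrow(mesh$faces))) {
    tri <- mesh$faces[r, ]
    for (a in 1:3) for (b in 1:3) {
      if (a != b) nb[[tri[a]]] <- c(nb[[tri[a]]], tri[b])
    }
  }
  lapply(nb, function(x) sort(unique(x)))
}

# plain-R BFS connected components restricted to a subset
bf_components <- function(neighbors, subset) {
  insub <- logical(length(neighbors))
  insub[subset] <- TRUE
  seen <- logical(length(neighbors))
  comps <- list()
  for (s in sort(subset)) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    comp <- integer(0)
    while (length(queue)) {
      u <- queue[1]
      queue <- queue[-1]
      comp <- c(comp, u)
      for (w in neighbors[[u]]) {
        if (insub[w] && !seen[w]) {
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

bf_min_dist <- function(A, B) {
  apply(A, 1, function(p) {
    min(sqrt(colSums((t(B) - p)^2)))
  })
}

# exact 1-D k-means by dynamic programming over sorted partitions
dp_kmeans_wcss <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  seg_cost <- function(i, j) {
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, k, n)
  for (j in seq_len(n)) D[1, j] <- seg_cost(1, j)
  if (k > 1) {
    for (q in 2:k) {
      for (j in q:n) {
        best <- Inf
        for (i in q:j) {
          c0 <- D[q - 1, i - 1] + seg_cost(i, j)
          if (c0 < best) best <- c0
        }
        D[q, j] <- best
      }
    }
  }
  D[k, n]
}

# --- memoized heavy fixtures --------------------------------------------

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- expr
  .fixture_env[[key]]
}

# a small spiny dendrite shared across test files
small_dendrite <- function() {
  fixture("small_dendrite", {
    generate_dendrite(dendrite_spec(shaft_length = 5, n_spines = 3,
                                    min_separation = 1.0,
                                    resolution = 0.06, seed = 400L))
  })
}

small_dendrite_skeleton <- function(voxel = 0.04) {
  fixture("small_dendrite_skel", {
    skeletonize_mesh(small_dendrite()$mesh, voxel)
  })
}
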