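#' Weighted binary cross-entropy loss over a set of meshes
#'
#' `L = (1/m) * sum_j w_j^2 * (1/n_j) * sum_i BCE(Y_ij, Yhat_ij)` where the
#' per-vertex BCE is summed over the two one-hot output units and the
#' predictions are clamped to `[eps, 1 - eps]`. The squared per-mesh weights
#' `w_j^2` let under-represented meshes be emphasized for a more balanced
#' optimization.
#'
#' @param Y `n x 2` one-hot label matrix (column 1 = spine).
#' @param Yhat `n x 2` prediction matrix in (0,1).
#' @param w per-mesh weights (default all 1).
#' @param mesh_id integer vector assigning each row to a mesh (default: one
#'   single mesh).
#' @param eps clamp tolerance.
#' @return scalar loss.
#' @export
weighted_bce_loss <- function(Y, Yhat, w = NULL, mesh_id = NULL,
                              eps = 1e-7) {
  Y <- as.matrix(Y)
  Yhat <- as.matrix(Yhat)
  stopifnot(all(dim(Y) == dim(Yhat)), ncol(Y) == 2L)
  if (any(Yhat < -1e-9 | Yhat > 1 + 1e-9))
    stop("predictions outside (0,1) beyond clamp tolerance")
  if (is.null(mesh_id)) mesh_id <- rep(1L, nrow(Y))
  meshes <- sort(unique(mesh_id))
  m <- length(meshes)
  if (is.null(w)) w <- rep(1, m)
  stopifnot(length(w) == m, all(w > 0))
  P <- pmin(pmax(Yhat, eps), 1 - eps)
  bce <- -rowSums(Y * log(P) + (1 - Y) * log(1 - P))
  total <- 0
  for (j in seq_len(m)) {
    rows <- mesh_id == meshes[j]
    total <- total + mean(bce[rows]) * w[j]^2
  }
  total / m
}

# Glorot-uniform initialization of the fixed architecture
mlp_init <- function(d_in, hidden, d_out, seed) {
  sizes <- c(d_in, hidden, d_out)
  with_seed(seed, {
    W <- vector("list", length(sizes) - 1)
    b <- vector("list", length(sizes) - 1)
    for (l in seq_along(W)) {
      lim <- sqrt(6 / (sizes[l] + sizes[l + 1]))
      W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -lim, lim),
                       sizes[l], sizes[l + 1])
      b[[l]] <- numeric(sizes[l + 1])
    }
    list(W = W, b = b)
  })
}

mlp_forward <- function(par, Z) {
  L <- length(par$W)
  acts <- vector("list", L + 1)
  acts[[1]] <- Z
  A <- Z
  for (l in seq_len(L - 1)) {
    A <- sweep(A %*% par$W[[l]], 2, par$b[[l]], "+")
    A[A < 0] <- 0                       # ReLU
    acts[[l + 1]] <- A
  }
  O <- sweep(A %*% par$W[[L]], 2, par$b[[L]], "+")
  P <- 1 / (1 + exp(-O))                # independent sigmoid outputs
  acts[[L + 1]] <- P
  acts
}

#' Fit an MLP vertex classifier
#'
#' Fits the fixed architecture used for dendritic spine-shaft vertex
#' classification: an input layer matching the feature schema of the chosen
#' variant, four hidden layers of fifty ReLU units, and two independent
#' sigmoid outputs (spine, shaft) trained against one-hot labels with the
#' weighted binary cross-entropy of [weighted_bce_loss()]. Optimization is
#' full-batch Adam with L1 and L2 penalties on the hidden-layer weights;
#' features are standardized per column over the training set and the
#' scaler is stored with the model. Training is deterministic given `seed`.
#'
#' @param x feature matrix from [assemble_features()], or a list of such
#'   matrices (one per mesh).
#' @param y label vector in `{spine, shaft}`, or a list of vectors matching
#'   `x`.
#' @param variant `"dnn1"`, `"dnn2"` or `"dnn3"`; default taken from the
#'   `"variant"` attribute of the features.
#' @param epochs training epochs (~1500 for a full fit; 0 returns the
#'   initialized, untrained model with an empty loss history).
#' @param lr Adam learning rate.
#' @param l1,l2 penalty coefficients on hidden-layer weights.
#' @param weights per-mesh weights `w_j` (default 1), or
#'   `"balance"` for `w_j^2` proportional to `n_j / spine count`.
#' @param hidden hidden layer widths.
#' @param max_rows_per_mesh optional cap on training vertices per mesh;
#'   a seeded random subsample is used for the gradient (prediction always
#'   covers every vertex). Dense EM meshes carry far more vertices than the
#'   classifier needs to converge.
#' @param seed RNG seed for the Glorot initialization (and subsampling).
#' @return an object of class `spine_mlp`.
#' @export
spine_mlp <- function(x, y, variant = NULL, epochs = 1500, lr = 1e-3,
                      l1 = 1e-5, l2 = 1e-5, weights = NULL,
                      hidden = c(50, 50, 50, 50),
                      max_rows_per_mesh = NULL, seed = 1L) {
  if (is.matrix(x)) {
    x <- list(x)
    y <- list(y)
  }
  stopifnot(length(x) == length(y), length(x) >= 1)
  if (!is.null(max_rows_per_mesh)) {
    att <- attr(x[[1]], "variant")
    for (j in seq_along(x)) {
      nj <- nrow(x[[j]])
      if (nj > max_rows_per_mesh) {
        keep <- with_seed(seed + 131L * j,
                          sort(sample.int(nj, max_rows_per_mesh)))
        x[[j]] <- x[[j]][keep, , drop = FALSE]
        y[[j]] <- y[[j]][keep]
      }
    }
    attr(x[[1]], "variant") <- att
  }
  if (is.null(variant)) variant <- attr(x[[1]], "variant")
  variant <- match.arg(variant, c("dnn1", "dnn2", "dnn3"))
  schema <- variant_schema(variant)
  for (Zi in x) {
    if (ncol(Zi) != length(schema))
      stop("feature matrix does not match the ", variant, " schema (",
           paste(schema, collapse = ", "), ")")
  }
  m <- length(x)
  n_j <- vapply(x, nrow, 0L)
  Z <- do.call(rbind, x)
  lab <- unlist(y, use.names = FALSE)
  stopifnot(length(lab) == nrow(Z))
  Y <- label_onehot(lab)
  mesh_id <- rep(seq_len(m), n_j)

  if (identical(weights, "balance")) {
    spine_n <- vapply(seq_len(m), function(j) {
      max(1L, sum(y[[j]] == "spine"))
    }, 0L)
    w <- sqrt(n_j / spine_n)
    w <- w / mean(w)
  } else if (is.null(weights)) {
    w <- rep(1, m)
  } else {
    stopifnot(length(weights) == m, all(weights > 0))
    w <- weights
  }

  mu <- colMeans(Z)
  sdv <- apply(Z, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  Zs <- sweep(sweep(Z, 2, mu), 2, sdv, "/")

  par <- mlp_init(ncol(Z), hidden, 2L, seed)
  L <- length(par$W)
  nh <- L - 1L                                 # hidden layers
  rho <- (w[mesh_id]^2) / (m * n_j[mesh_id])   # per-row loss weight

  # Adam state
  mW <- lapply(par$W, function(w_) w_ * 0)
  vW <- mW
  mb <- lapply(par$b, function(b_) b_ * 0)
  vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; aeps <- 1e-8
  eps <- 1e-7
  loss_history <- numeric(0)

  data_loss <- function(P) {
    Pc <- pmin(pmax(P, eps), 1 - eps)
    bce <- -rowSums(Y * log(Pc) + (1 - Y) * log(1 - Pc))
    sum(rho * bce)
  }
  reg_loss <- function() {
    s <- 0
    for (l in seq_len(nh)) s <- s + l1 * sum(abs(par$W[[l]])) +
        l2 * sum(par$W[[l]]^2)
    s
  }

  for (ep in seq_len(epochs)) {
    acts <- mlp_forward(par, Zs)
    P <- acts[[L + 1]]
    loss <- data_loss(P) + reg_loss()
    if (!is.finite(loss))
      stop("non-finite loss at epoch ", ep)
    loss_history <- c(loss_history, loss)

    # backward
    gW <- vector("list", L)
    gb <- vector("list", L)
    delta <- (P - Y) * rho                     # d loss / d pre-sigmoid
    for (l in L:1) {
      A <- acts[[l]]
      gW[[l]] <- crossprod(A, delta)
      gb[[l]] <- colSums(delta)
      if (l > 1) {
        delta <- delta %*% t(par$W[[l]])
        delta[acts[[l]] <= 0] <- 0             # ReLU derivative
      }
    }
    for (l in seq_len(nh)) {
      gW[[l]] <- gW[[l]] + l1 * sign(par$W[[l]]) + 2 * l2 * par$W[[l]]
    }
    # Adam update
    bc1 <- 1 - beta1^ep
    bc2 <- 1 - beta2^ep
    for (l in seq_len(L)) {
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
      par$W[[l]] <- par$W[[l]] -
        lr * (mW[[l]] / bc1) / (sqrt(vW[[l]] / bc2) + aeps)
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
      par$b[[l]] <- par$b[[l]] -
        lr * (mb[[l]] / bc1) / (sqrt(vb[[l]] / bc2) + aeps)
    }
  }

  structure(list(
    variant = variant, schema = schema, W = par$W, b = par$b,
    scaler = list(mean = mu, sd = sdv), hidden = hidden,
    loss_history = loss_history, epochs = epochs,
    config = list(lr = lr, l1 = l1, l2 = l2, seed = seed, weights = w),
    stage1 = NULL
  ), class = "spine_mlp")
}

#' Predict spine/shaft probabilities
#'
#' @param object a fitted `spine_mlp`.
#' @param newdata feature matrix matching the model's schema.
#' @param ... unused.
#' @return `n x 2` probability matrix with columns `spine`, `shaft`
#'   (independent sigmoid outputs; rows need not sum to 1).
#' @export
predict.spine_mlp <- function(object, newdata, ...) {
  Z <- as.matrix(newdata)
  if (ncol(Z) != length(object$schema))
    stop("feature matrix does not match the ", object$variant,
         " schema (", paste(object$schema, collapse = ", "), ")")
  if (nrow(Z) == 0)
    return(matrix(numeric(0), 0, 2,
                  dimnames = list(NULL, c("spine", "shaft"))))
  Zs <- sweep(sweep(Z, 2, object$scaler$mean), 2, object$scaler$sd, "/")
  acts <- mlp_forward(list(W = object$W, b = object$b), Zs)
  P <- acts[[length(object$W) + 1]]
  colnames(P) <- c("spine", "shaft")
  P
}

#' Threshold class probabilities into labels
#'
#' Vertex i is called spine iff `a * p_spine > b * p_shaft`; ties go to
#' shaft. The decision is scale-invariant in (a, b).
#'
#' @param prob `n x 2` probability matrix (column 1 = spine).
#' @param a,b positive class weights.
#' @return character vector in `{spine, shaft}`.
#' @export
classify_vertices <- function(prob, a = 1, b = 1) {
  stopifnot(a > 0, b > 0)
  ifelse(a * prob[, 1] > b * prob[, 2], "spine", "shaft")
}

#' @export
print.spine_mlp <- function(x, ...) {
  cat("spine_mlp vertex classifier (", x$variant, ")\n", sep = "")
  cat("  features:", paste(x$schema, collapse = ", "), "\n")
  cat("  architecture:", length(x$schema), "->",
      paste(x$hidden, collapse = " -> "), "-> 2 (sigmoid)\n")
  if (length(x$loss_history)) {
    cat(sprintf("  trained %d epochs, loss %.4f -> %.4f\n", x$epochs,
                x$loss_history[1], x$loss_history[length(x$loss_history)]))
  } else cat("  untrained (0 epochs)\n")
  if (!is.null(x$stage1))
    cat("  two-stage: carries a", x$stage1$variant, "stage-1 model\n")
  invisible(x)
}

#' @export
summary.spine_mlp <- function(object, ...) {
  np <- sum(vapply(object$W, length, 0)) + sum(vapply(object$b, length, 0))
  cat("spine_mlp (", object$variant, "), ", np, " parameters\n", sep = "")
  print(object)
  if (length(object$loss_history) > 1) {
    cat("  loss quartiles:",
        paste(sprintf("%.4f", stats::quantile(object$loss_history)),
              collapse = " "), "\n")
  }
  invisible(object)
}

#' @export
coef.spine_mlp <- function(object, ...) {
  list(W = object$W, b = object$b)
}

#' @export
plot.spine_mlp <- function(x, ...) {
  if (!length(x$loss_history)) {
    warning("untrained model: nothing to plot")
    return(invisible(x))
  }
  graphics::plot(seq_along(x$loss_history), x$loss_history, type = "l",
                 xlab = "epoch", ylab = "weighted BCE loss",
                 main = paste("training loss -", x$variant), ...)
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Portable JSON checkpoint: layer shapes, flat weight arrays, feature
#' schema and the standardization scaler.
#'
#' @param model a `spine_mlp`.
#' @param path output `.json` path.
#' @export
write_checkpoint <- function(model, path) {
  jsonlite::write_json(checkpoint_list(model), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

checkpoint_list <- function(model) {
  list(variant = model$variant, schema = model$schema,
       hidden = model$hidden,
       W = model$W, b = model$b,
       scaler = model$scaler,
       config = model$config[c("lr", "l1", "l2", "seed")],
       loss_history = model$loss_history, epochs = model$epochs,
       stage1 = if (!is.null(model$stage1)) checkpoint_list(model$stage1))
}

#' @rdname write_checkpoint
#' @param path checkpoint path.
#' @export
read_checkpoint <- function(path) {
  ck <- jsonlite::read_json(path, simplifyVector = TRUE)
  model_from_checkpoint(ck)
}

model_from_checkpoint <- function(ck) {
  m <- structure(list(
    variant = ck$variant, schema = unlist(ck$schema),
    W = lapply(ck$W, function(w) as.matrix(w)),
    b = lapply(ck$b, as.numeric),
    scaler = list(mean = as.numeric(ck$scaler$mean),
                  sd = as.numeric(ck$scaler$sd)),
    hidden = unlist(ck$hidden),
    loss_history = as.numeric(ck$loss_history),
    epochs = ck$epochs, config = ck$config, stage1 = NULL
  ), class = "spine_mlp")
  if (!is.null(ck$stage1) && length(ck$stage1))
    m$stage1 <- model_from_checkpoint(ck$stage1)
  m
}
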