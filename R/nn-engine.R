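# Minimal feed-forward engine: dense / ReLU / dropout / valid 3x3 conv
# (im2col) / 2x2 max-pool layers with hand-derived backward passes and an
# Adam optimizer. Activations are plain matrices, one row per example;
# conv/pool activations are stored flat as position-major blocks of
# `filters` channels, so the flatten step is a no-op.

lay_dense <- function(n_in, n_out) {
  list(type = "dense", n_in = n_in, n_out = n_out, W = NULL, b = NULL)
}

lay_relu <- function() list(type = "relu")

lay_dropout <- function(rate) {
  stopifnot(rate >= 0, rate < 1)
  list(type = "dropout", rate = rate)
}

# Valid convolution on a G x G single-channel grid, flattened row-major
# with x fastest (cell (x, y) -> column y*G + x + 1).
lay_conv <- function(extent, filters, kernel = 3L) {
  if (extent < kernel)
    stop("grid extent smaller than convolution kernel", call. = FALSE)
  oh <- extent - kernel + 1L
  P <- oh * oh
  pidx <- matrix(0L, nrow = P, ncol = kernel * kernel)
  for (py in 0:(oh - 1L)) for (px in 0:(oh - 1L)) {
    p <- py * oh + px + 1L
    k <- 1L
    for (dy in 0:(kernel - 1L)) for (dx in 0:(kernel - 1L)) {
      pidx[p, k] <- (py + dy) * extent + (px + dx) + 1L
      k <- k + 1L
    }
  }
  list(type = "conv", extent = extent, filters = filters, kernel = kernel,
       oh = oh, P = P, pidx = pidx,
       n_in = kernel * kernel, n_out = filters, W = NULL, b = NULL)
}

# 2x2/stride-2 max pool over the conv position grid; identity when the
# spatial map is already 1x1 (the worked 3x3-grid architecture).
lay_pool <- function(in_oh, filters) {
  if (in_oh < 2) {
    return(list(type = "pool", identity = TRUE, in_oh = in_oh,
                out_oh = in_oh, filters = filters))
  }
  out_oh <- in_oh %/% 2L
  groups <- vector("list", out_oh * out_oh)
  for (qy in 0:(out_oh - 1L)) for (qx in 0:(out_oh - 1L)) {
    q <- qy * out_oh + qx + 1L
    members <- integer(4)
    k <- 1L
    for (dy in 0:1) for (dx in 0:1) {
      members[k] <- (2L * qy + dy) * in_oh + (2L * qx + dx) + 1L
      k <- k + 1L
    }
    groups[[q]] <- members
  }
  list(type = "pool", identity = FALSE, in_oh = in_oh, out_oh = out_oh,
       filters = filters, groups = groups)
}

.blk <- function(p, f) ((p - 1L) * f + 1L):(p * f)

init_layer_params <- function(layers) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type %in% c("dense", "conv")) {
      sd <- sqrt(2 / l$n_in)
      layers[[i]]$W <- matrix(stats::rnorm(l$n_in * l$n_out, sd = sd),
                              l$n_in, l$n_out)
      layers[[i]]$b <- numeric(l$n_out)
    }
  }
  layers
}

stack_forward <- function(layers, X, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "dense") {
      caches[[i]] <- X
      X <- X %*% l$W
      X <- X + rep(l$b, each = nrow(X))
    } else if (l$type == "relu") {
      X <- X * (X > 0)
      caches[[i]] <- X
    } else if (l$type == "dropout") {
      if (training && l$rate > 0) {
        mask <- (matrix(stats::runif(length(X)), nrow(X)) >= l$rate) /
          (1 - l$rate)
        X <- X * mask
        caches[[i]] <- mask
      }
    } else if (l$type == "conv") {
      caches[[i]] <- X
      f <- l$filters
      n <- nrow(X)
      # im2col: one (n*P) x k^2 patch matrix, a single GEMM, then
      # reshape back to position-major channel blocks
      A <- X[, as.vector(t(l$pidx)), drop = FALSE]
      dim(A) <- c(n, l$n_in, l$P)
      patches <- matrix(aperm(A, c(3, 1, 2)), n * l$P, l$n_in)
      Zp <- patches %*% l$W
      Zp <- Zp + rep(l$b, each = nrow(Zp))  # rows: position fastest
      Z <- matrix(0, n, l$P * f)
      for (p in seq_len(l$P))
        Z[, .blk(p, f)] <- Zp[seq.int(p, n * l$P, by = l$P), , drop = FALSE]
      X <- Z
    } else if (l$type == "pool") {
      if (l$identity) next
      f <- l$filters
      nq <- length(l$groups)
      Z <- matrix(0, nrow(X), nq * f)
      pick <- matrix(1L, nrow(X), nq * f)
      for (q in seq_len(nq)) {
        mem <- l$groups[[q]]
        best <- X[, .blk(mem[1], f), drop = FALSE]
        which_m <- matrix(1L, nrow(X), f)
        for (k in 2:4) {
          cand <- X[, .blk(mem[k], f), drop = FALSE]
          upd <- cand > best
          best[upd] <- cand[upd]
          which_m[upd] <- k
        }
        Z[, .blk(q, f)] <- best
        pick[, .blk(q, f)] <- which_m
      }
      caches[[i]] <- pick
      X <- Z
    } else stop("unknown layer type: ", l$type)
  }
  list(out = X, caches = caches)
}

stack_backward <- function(layers, caches, dY) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    if (l$type == "dense") {
      X <- caches[[i]]
      grads[[i]] <- list(W = crossprod(X, dY), b = colSums(dY))
      dY <- tcrossprod(dY, l$W)
    } else if (l$type == "relu") {
      dY <- dY * (caches[[i]] > 0)
    } else if (l$type == "dropout") {
      if (!is.null(caches[[i]])) dY <- dY * caches[[i]]
    } else if (l$type == "conv") {
      X <- caches[[i]]
      f <- l$filters
      n <- nrow(X)
      A <- X[, as.vector(t(l$pidx)), drop = FALSE]
      dim(A) <- c(n, l$n_in, l$P)
      patches <- matrix(aperm(A, c(3, 1, 2)), n * l$P, l$n_in)
      dZ <- matrix(0, n * l$P, f)  # rows: position fastest within example
      for (p in seq_len(l$P))
        dZ[seq.int(p, n * l$P, by = l$P), ] <- dY[, .blk(p, f), drop = FALSE]
      grads[[i]] <- list(W = crossprod(patches, dZ), b = colSums(dZ))
      dP <- tcrossprod(dZ, l$W)  # (n*P) x k^2
      dX <- matrix(0, n, ncol(X))
      for (k in seq_len(l$n_in)) {
        # for fixed in-patch offset k the P target cells are distinct
        m <- t(matrix(dP[, k], l$P, n))
        cols <- l$pidx[, k]
        dX[, cols] <- dX[, cols] + m
      }
      dY <- dX
    } else if (l$type == "pool") {
      if (l$identity) next
      f <- l$filters
      pick <- caches[[i]]
      nq <- length(l$groups)
      dX <- matrix(0, nrow(dY), l$in_oh * l$in_oh * f)
      for (q in seq_len(nq)) {
        mem <- l$groups[[q]]
        dq <- dY[, .blk(q, f), drop = FALSE]
        wq <- pick[, .blk(q, f), drop = FALSE]
        for (k in 1:4) {
          sel <- (wq == k)
          if (any(sel)) {
            tgt <- dX[, .blk(mem[k], f), drop = FALSE]
            tgt[sel] <- tgt[sel] + dq[sel]
            dX[, .blk(mem[k], f)] <- tgt
          }
        }
      }
      dY <- dX
    }
  }
  list(grads = grads, dX = dY)
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(l) {
    if (is.null(l$W)) return(NULL)
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    layers[[i]]$W <- layers[[i]]$W - lr * (s$mW / bc1) /
      (sqrt(s$vW / bc2) + eps)
    layers[[i]]$b <- layers[[i]]$b - lr * (s$mb / bc1) /
      (sqrt(s$vb / bc2) + eps)
    state[[i]] <- s
  }
  list(layers = layers, state = state)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}
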