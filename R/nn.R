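# Internal neural-network engine.
#
# Networks are lists of layers operating on flat row-major batches
# (one sample per row). Image feature vectors are column-major per channel:
# index = (c-1)*H*W + (col-1)*H + row. Convolutions run as im2col matrix
# products with index maps precomputed at build time; gradients mirror the
# forward gathers exactly. The softmax/cross-entropy gradient is assembled
# cancellation-free (true-class entry = -sum of off-class probabilities) so
# small but consistent gradients are not lost to rounding.

nn_dense <- function(d_in, d_out) {
  bnd <- 1 / sqrt(d_in)
  list(type = "dense",
       W = matrix(runif(d_in * d_out, -bnd, bnd), d_in, d_out),
       b = runif(d_out, -bnd, bnd))
}

nn_relu <- function() list(type = "relu")

nn_conv <- function(in_shape, filters, k = 3L) {
  H <- in_shape[1]; W <- in_shape[2]; C <- in_shape[3]
  OH <- H - k + 1L; OW <- W - k + 1L
  K <- k * k * C; P <- OH * OW
  idx <- matrix(0L, K, P)
  p <- 0L
  for (oc in seq_len(OW)) for (or in seq_len(OH)) {
    p <- p + 1L
    kk <- 0L
    for (cc in seq_len(C)) for (kc in seq_len(k)) for (kr in seq_len(k)) {
      kk <- kk + 1L
      idx[kk, p] <- (cc - 1L) * H * W + (oc + kc - 2L) * H + (or + kr - 1L)
    }
  }
  bnd <- 1 / sqrt(K)
  list(type = "conv",
       W = matrix(runif(K * filters, -bnd, bnd), K, filters),
       b = runif(filters, -bnd, bnd),
       idx = idx, K = K, P = P, filters = filters,
       out_shape = c(OH, OW, filters))
}

nn_maxpool <- function(in_shape) {
  H <- in_shape[1]; W <- in_shape[2]; C <- in_shape[3]
  H2 <- H %/% 2L; W2 <- W %/% 2L
  # input indices of the four pool quadrants, in output-vector order
  base <- integer(H2 * W2 * C)
  p <- 0L
  for (cc in seq_len(C)) for (oc in seq_len(W2)) for (or in seq_len(H2)) {
    p <- p + 1L
    base[p] <- (cc - 1L) * H * W + (2L * oc - 2L) * H + (2L * or - 1L)
  }
  quads <- list(base, base + 1L, base + H, base + H + 1L)
  list(type = "maxpool", quads = quads, out_shape = c(H2, W2, C))
}

nn_dropout <- function(rate) list(type = "dropout", rate = rate)

nn_batchnorm <- function(d) {
  list(type = "batchnorm", gamma = rep(1, d), beta = rep(0, d),
       run_mean = rep(0, d), run_var = rep(1, d), momentum = 0.1,
       eps = 1e-5)
}

# forward pass; returns final activations plus per-layer caches for backprop
nn_forward <- function(layers, X, training = FALSE) {
  caches <- vector("list", length(layers))
  H <- X
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "dense") {
      caches[[i]] <- list(input = H)
      H <- H %*% l$W
      H <- H + rep(l$b, each = nrow(H))
    } else if (l$type == "relu") {
      H <- H * (H > 0)
      caches[[i]] <- list(out = H)
    } else if (l$type == "conv") {
      n <- nrow(H)
      cols <- H[, as.vector(l$idx), drop = FALSE]
      dim(cols) <- c(n, l$K, l$P)
      cols <- aperm(cols, c(1, 3, 2))
      dim(cols) <- c(n * l$P, l$K)
      out <- cols %*% l$W
      out <- out + rep(l$b, each = nrow(out))
      caches[[i]] <- list(cols = cols, n = n, d_in = ncol(H))
      dim(out) <- c(n, l$P * l$filters)
      H <- out
    } else if (l$type == "maxpool") {
      q <- l$quads
      m1 <- H[, q[[1]], drop = FALSE]; m2 <- H[, q[[2]], drop = FALSE]
      m3 <- H[, q[[3]], drop = FALSE]; m4 <- H[, q[[4]], drop = FALSE]
      M <- pmax(m1, m2, m3, m4)
      # argmax = first quadrant attaining the max (deterministic tie-break)
      arg <- matrix(4L, nrow(M), ncol(M))
      arg[M == m3] <- 3L; arg[M == m2] <- 2L; arg[M == m1] <- 1L
      caches[[i]] <- list(arg = arg, d_in = ncol(H))
      H <- M
    } else if (l$type == "dropout") {
      if (training && l$rate > 0) {
        mask <- matrix(runif(length(H)) >= l$rate, nrow(H), ncol(H))
        H <- H * mask / (1 - l$rate)
        caches[[i]] <- list(mask = mask)
      }
    } else if (l$type == "batchnorm") {
      if (training) {
        mu <- colMeans(H)
        cen <- H - rep(mu, each = nrow(H))
        v <- colMeans(cen^2)
        invstd <- 1 / sqrt(v + l$eps)
        xhat <- cen * rep(invstd, each = nrow(H))
        caches[[i]] <- list(xhat = xhat, invstd = invstd, mu = mu, v = v)
        H <- xhat * rep(l$gamma, each = nrow(H)) +
          rep(l$beta, each = nrow(H))
      } else {
        invstd <- 1 / sqrt(l$run_var + l$eps)
        H <- (H - rep(l$run_mean, each = nrow(H))) *
          rep(l$gamma * invstd, each = nrow(H)) +
          rep(l$beta, each = nrow(H))
      }
    } else {
      abort(paste0("unknown layer type: ", l$type))
    }
  }
  list(out = H, caches = caches)
}

# backward pass from dLoss/dlogits; returns per-layer parameter gradients
# and (optionally) updates batchnorm running stats on the side
nn_backward <- function(layers, caches, D) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    if (l$type == "dense") {
      inp <- caches[[i]]$input
      grads[[i]] <- list(W = crossprod(inp, D), b = colSums(D))
      D <- tcrossprod(D, l$W)
    } else if (l$type == "relu") {
      D <- D * (caches[[i]]$out > 0)
    } else if (l$type == "conv") {
      cc <- caches[[i]]
      n <- cc$n
      Dm <- D
      dim(Dm) <- c(n * l$P, l$filters)
      grads[[i]] <- list(W = crossprod(cc$cols, Dm), b = colSums(Dm))
      dcols <- tcrossprod(Dm, l$W)          # (n*P) x K
      dim(dcols) <- c(n, l$P, l$K)
      DX <- matrix(0, n, cc$d_in)
      for (k in seq_len(l$K)) {
        tgt <- l$idx[k, ]
        DX[, tgt] <- DX[, tgt] + dcols[, , k]
      }
      D <- DX
    } else if (l$type == "maxpool") {
      cc <- caches[[i]]
      DX <- matrix(0, nrow(D), cc$d_in)
      for (q in 1:4) {
        tgt <- l$quads[[q]]
        DX[, tgt] <- DX[, tgt] + D * (cc$arg == q)
      }
      D <- DX
    } else if (l$type == "dropout") {
      if (!is.null(caches[[i]])) {
        D <- D * caches[[i]]$mask / (1 - l$rate)
      }
    } else if (l$type == "batchnorm") {
      cc <- caches[[i]]
      nb <- nrow(D)
      dgamma <- colSums(D * cc$xhat)
      dbeta <- colSums(D)
      grads[[i]] <- list(gamma = dgamma, beta = dbeta)
      gi <- rep(l$gamma * cc$invstd, each = nb)
      D <- gi * (D - rep(dbeta / nb, each = nb) -
                   cc$xhat * rep(dgamma / nb, each = nb))
    }
  }
  grads
}

nn_update_bn_stats <- function(layers, caches) {
  for (i in seq_along(layers)) {
    if (layers[[i]]$type == "batchnorm" && !is.null(caches[[i]]$mu)) {
      m <- layers[[i]]$momentum
      layers[[i]]$run_mean <- (1 - m) * layers[[i]]$run_mean +
        m * caches[[i]]$mu
      layers[[i]]$run_var <- (1 - m) * layers[[i]]$run_var +
        m * caches[[i]]$v
    }
  }
  layers
}

nn_param_names <- function(layer) {
  switch(layer$type,
         dense = c("W", "b"), conv = c("W", "b"),
         batchnorm = c("gamma", "beta"), character(0))
}

nn_softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# cancellation-free softmax + cross-entropy gradient (mean reduction)
nn_xent_grad <- function(P, y01) {
  nb <- nrow(P)
  ti <- cbind(seq_len(nb), y01 + 1L)
  D <- P
  D[ti] <- 0
  D[ti] <- -rowSums(D)
  D / nb
}

nn_xent_loss <- function(P, y01) {
  p <- P[cbind(seq_len(nrow(P)), y01 + 1L)]
  -mean(log(pmax(p, 1e-300)))
}

# Adam with optional coupled L2 weight decay on dense/conv weight matrices
nn_adam_init <- function(layers) {
  lapply(layers, function(l) {
    nm <- nn_param_names(l)
    if (length(nm) == 0) return(NULL)
    st <- lapply(nm, function(p) list(m = l[[p]] * 0, v = l[[p]] * 0))
    names(st) <- nm
    st
  })
}

nn_adam_step <- function(layers, grads, state, t, lr, weight_decay = 0,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  corr <- lr * sqrt(1 - beta2^t) / (1 - beta1^t)
  for (i in seq_along(layers)) {
    nm <- nn_param_names(layers[[i]])
    if (length(nm) == 0 || is.null(grads[[i]])) next
    for (p in nm) {
      g <- grads[[i]][[p]]
      if (weight_decay > 0 && p == "W") {
        g <- g + weight_decay * layers[[i]][[p]]
      }
      st <- state[[i]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      state[[i]][[p]] <- st
      layers[[i]][[p]] <- layers[[i]][[p]] - corr * st$m / (sqrt(st$v) + eps)
    }
  }
  list(layers = layers, state = state)
}

nn_snapshot_params <- function(layers) {
  lapply(layers, function(l) l[nn_param_names(l)])
}

nn_restore_params <- function(layers, snap) {
  for (i in seq_along(layers)) {
    for (p in names(snap[[i]])) layers[[i]][[p]] <- snap[[i]][[p]]
  }
  layers
}

# label-preserving image jitter: integer shifts up to `shift` px (edge
# replication) and optional horizontal flips, drawn per image
nn_augment_batch <- function(X, side, shift = 2L, flip = FALSE) {
  n <- nrow(X)
  dx <- sample.int(2L * shift + 1L, n, replace = TRUE) - shift - 1L
  dy <- sample.int(2L * shift + 1L, n, replace = TRUE) - shift - 1L
  fl <- if (flip) runif(n) < 0.5 else rep(FALSE, n)
  key <- paste(dx, dy, fl)
  for (k in unique(key)) {
    rows <- which(key == k)
    r <- pmin(pmax(seq_len(side) + dy[rows[1]], 1L), side)
    cl <- pmin(pmax(seq_len(side) + dx[rows[1]], 1L), side)
    if (fl[rows[1]]) cl <- rev(cl)
    remap <- as.vector(outer(r, (cl - 1L) * side, "+"))
    X[rows, ] <- X[rows, remap, drop = FALSE]
  }
  X
}
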