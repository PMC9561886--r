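# Minimal conv-net core. Tensors are numeric arrays with dim (C, X, Y, Z),
# channel fastest; convolutions are im2col + BLAS matmul; every layer has an
# exact backward pass (validated by finite differences in the test suite).
# 2D networks use the same machinery with a singleton third spatial axis.

.he_init <- function(nout, nin, seed_state = NULL) {
  matrix(stats::rnorm(nout * nin, 0, sqrt(2 / nin)), nout, nin)
}

.layer_conv <- function(cin, cout, k = c(3, 3, 3), stride = c(1, 1, 1),
                        pad = (k - 1) %/% 2) {
  list(kind = "conv", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad),
       W = .he_init(cout, cin * prod(k)), b = numeric(cout))
}

# Transpose convolution with stride = kernel (non-overlapping upsampling).
# W is stored as the weight of the adjoint convolution: (cin, cout * prod(k)).
.layer_tconv <- function(cin, cout, k = c(2, 2, 2)) {
  list(kind = "tconv", k = as.integer(k),
       W = .he_init(cin, cout * prod(k)), b = numeric(cout))
}

.layer_gn <- function(channels, groups) {
  groups <- min(groups, channels)
  while (channels %% groups != 0) groups <- groups - 1
  list(kind = "gn", groups = groups, gamma = rep(1, channels),
       beta = numeric(channels), eps = 1e-5)
}

.layer_act <- function(slope = 0.01) list(kind = "lrelu", slope = slope)
.layer_sigmoid <- function() list(kind = "sigmoid")
.layer_softmaxc <- function() list(kind = "softmaxc")
.layer_pool <- function(pool) list(kind = "pool", pool = as.integer(pool))

.layer_fwd <- function(layer, x) {
  switch(layer$kind,
    conv = {
      col <- cpp_im2col3d(x, layer$k, layer$stride, layer$pad)
      od <- attr(col, "outdim")
      y <- layer$W %*% col + layer$b
      dim(y) <- c(nrow(layer$W), od)
      list(y = y, cache = list(col = col, xdim = dim(x)))
    },
    tconv = {
      xd <- dim(x)
      ci <- nrow(layer$W)
      co <- ncol(layer$W) / prod(layer$k)
      xmat <- matrix(x, ci)
      cols <- crossprod(layer$W, xmat)
      ydim <- c(co, xd[2:4] * layer$k)
      y <- cpp_col2im3d(cols, ydim, layer$k, layer$k, c(0L, 0L, 0L))
      y <- y + layer$b
      list(y = y, cache = list(xmat = xmat, xdim = xd, ydim = ydim))
    },
    gn = {
      d <- dim(x)
      cpg <- d[1] %/% layer$groups
      xm <- matrix(x, d[1])
      xhat <- xm; sdinv <- numeric(layer$groups); mu <- numeric(layer$groups)
      for (g in seq_len(layer$groups)) {
        rows <- ((g - 1) * cpg + 1):(g * cpg)
        v <- xm[rows, , drop = FALSE]
        mu[g] <- mean(v)
        sdinv[g] <- 1 / sqrt(mean((v - mu[g])^2) + layer$eps)
        xhat[rows, ] <- (v - mu[g]) * sdinv[g]
      }
      y <- xhat * layer$gamma + layer$beta
      dim(y) <- d
      list(y = y, cache = list(xhat = xhat, sdinv = sdinv, d = d, cpg = cpg))
    },
    lrelu = {
      pos <- x > 0
      y <- x * (layer$slope + (1 - layer$slope) * pos)
      dim(y) <- dim(x)
      list(y = y, cache = pos)
    },
    sigmoid = {
      y <- 1 / (1 + exp(-x))
      list(y = y, cache = y)
    },
    softmaxc = {
      d <- dim(x)
      xm <- matrix(x, d[1])
      xm <- sweep(xm, 2, apply(xm, 2, max))
      e <- exp(xm)
      y <- sweep(e, 2, colSums(e), `/`)
      dim(y) <- d
      list(y = y, cache = y)
    },
    pool = {
      r <- cpp_maxpool3d(x, layer$pool)
      list(y = r$out, cache = list(argmax = r$argmax, xdim = dim(x)))
    },
    stop("unknown layer kind: ", layer$kind))
}

.layer_bwd <- function(layer, cache, dy) {
  switch(layer$kind,
    conv = {
      dym <- matrix(dy, nrow(layer$W))
      dW <- tcrossprod(dym, cache$col)
      db <- rowSums(dym)
      dcol <- crossprod(layer$W, dym)
      dx <- cpp_col2im3d(dcol, cache$xdim, layer$k, layer$stride, layer$pad)
      list(dx = dx, grads = list(W = dW, b = db))
    },
    tconv = {
      colsG <- cpp_im2col3d(dy, layer$k, layer$k, c(0L, 0L, 0L))
      dxm <- layer$W %*% colsG
      dx <- array(dxm, cache$xdim)
      dW <- tcrossprod(cache$xmat, colsG)
      db <- rowSums(matrix(dy, cache$ydim[1]))
      list(dx = dx, grads = list(W = dW, b = db))
    },
    gn = {
      d <- cache$d; cpg <- cache$cpg
      dym <- matrix(dy, d[1])
      dgamma <- rowSums(dym * cache$xhat)
      dbeta <- rowSums(dym)
      dxh <- dym * .lg_gamma_col(layer$gamma)
      dx <- dxh
      for (g in seq_along(cache$sdinv)) {
        rows <- ((g - 1) * cpg + 1):(g * cpg)
        dh <- dxh[rows, , drop = FALSE]
        xh <- cache$xhat[rows, , drop = FALSE]
        dx[rows, ] <- cache$sdinv[g] *
          (dh - mean(dh) - xh * mean(dh * xh))
      }
      dim(dx) <- d
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    lrelu = {
      dx <- dy * (layer$slope + (1 - layer$slope) * cache)
      dim(dx) <- dim(dy)
      list(dx = dx, grads = NULL)
    },
    sigmoid = {
      list(dx = dy * cache * (1 - cache), grads = NULL)
    },
    softmaxc = {
      d <- dim(cache)
      p <- matrix(cache, d[1]); g <- matrix(dy, d[1])
      dx <- p * sweep(g, 2, colSums(g * p))
      dim(dx) <- d
      list(dx = dx, grads = NULL)
    },
    pool = {
      dx <- cpp_maxpool3d_grad(dy, cache$argmax, cache$xdim)
      list(dx = dx, grads = NULL)
    })
}

.lg_gamma_col <- function(gamma) gamma  # recycles down matrix columns

# sequential helpers over a vector of layer indices into model$layers
.seq_fwd <- function(layers, idx, x) {
  caches <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    r <- .layer_fwd(layers[[idx[j]]], x)
    x <- r$y
    caches[[j]] <- r$cache
  }
  list(y = x, caches = caches)
}

.seq_bwd <- function(layers, idx, caches, dy, grads) {
  for (j in rev(seq_along(idx))) {
    r <- .layer_bwd(layers[[idx[j]]], caches[[j]], dy)
    dy <- r$dx
    if (!is.null(r$grads)) grads[[idx[j]]] <- .grad_add(grads[[idx[j]]], r$grads)
  }
  list(dx = dy, grads = grads)
}

.grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

.n_params_layer <- function(l)
  length(l$W) + length(l$b) + length(l$gamma) + length(l$beta)

#' Number of trainable parameters in a model
#'
#' @param model a model from [build_heatmap_net()], [build_seg_net()],
#'   [build_slice_net()] or [build_detector()].
#' @return integer parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(model$layers, .n_params_layer, numeric(1)))
}
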