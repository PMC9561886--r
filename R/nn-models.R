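# Network builders. All models share the flat-layer representation:
# model$layers is a list of layer objects; the topology fields hold index
# vectors into it. Desk-scale defaults (depth 3, 8 base channels) train in
# minutes on one CPU; capacity is configurable, architecture is fixed.

#' Network configuration
#'
#' @param depth number of resolution levels (>= 1).
#' @param base_channels channels at the finest level (doubled per level).
#' @param norm `"group"` for group normalization or `"batch"`; with the
#'   batch-of-one training used here, batch statistics reduce to per-channel
#'   (instance) statistics, i.e. group norm with one channel per group.
#' @param groups group count for group norm.
#' @param in_channels input channels.
#' @param n_outputs output channels (classes for segmentation, 1 for heatmap).
#' @param convs_per_block convolutions per resolution block.
#' @param input_shape expected spatial input shape (used by the 2D nets; the
#'   3D U-Nets accept any shape divisible by `2^(depth-1)`).
#' @param channel_cap upper bound on channel growth (slice net).
#' @param box_size fixed detector box size in pixels (keypoint-as-box-centre).
#' @return list of class `acl_net_config`.
#' @export
net_config <- function(depth = 3, base_channels = 8, norm = c("group", "batch"),
                       groups = 4, in_channels = 1, n_outputs = 1,
                       convs_per_block = 2, input_shape = NULL,
                       channel_cap = 32, box_size = 11) {
  norm <- match.arg(norm)
  stopifnot(depth >= 1, base_channels >= 1, convs_per_block >= 1)
  structure(list(depth = depth, base_channels = base_channels, norm = norm,
                 groups = if (norm == "group") groups else 1L,
                 in_channels = in_channels, n_outputs = n_outputs,
                 convs_per_block = convs_per_block, input_shape = input_shape,
                 channel_cap = channel_cap, box_size = box_size),
            class = "acl_net_config")
}

.norm_groups <- function(config, channels) {
  if (config$norm == "batch") channels else min(config$groups, channels)
}

# Shared encoder-decoder skeleton: strided-conv downsampling, transpose-conv
# upsampling, skip concatenation at equal resolution, group norm + leaky ReLU
# after every convolution.
.build_unet <- function(config, final_act, seed) {
  set.seed(seed)
  ch <- config$base_channels * 2^(seq_len(config$depth) - 1)
  layers <- list()
  add <- function(l) { layers[[length(layers) + 1]] <<- l; length(layers) }
  block <- function(cin, cout) {
    idx <- c()
    for (i in seq_len(config$convs_per_block)) {
      idx <- c(idx, add(.layer_conv(if (i == 1) cin else cout, cout)),
               add(.layer_gn(cout, .norm_groups(config, cout))),
               add(.layer_act()))
    }
    idx
  }
  enc <- list(); down <- list(); up <- list(); dec <- list()
  enc[[1]] <- block(config$in_channels, ch[1])
  if (config$depth > 1) {
    for (l in 2:config$depth) {
      down[[l]] <- c(add(.layer_conv(ch[l - 1], ch[l], stride = c(2, 2, 2))),
                     add(.layer_gn(ch[l], .norm_groups(config, ch[l]))),
                     add(.layer_act()))
      enc[[l]] <- block(ch[l], ch[l])
    }
    for (l in (config$depth - 1):1) {
      up[[l]] <- add(.layer_tconv(ch[l + 1], ch[l]))
      dec[[l]] <- block(2 * ch[l], ch[l])
    }
  }
  final <- c(add(.layer_conv(ch[1], config$n_outputs, k = c(1, 1, 1),
                             pad = c(0, 0, 0))),
             add(final_act))
  list(kind = "unet", config = config, layers = layers, enc = enc, down = down,
       up = up, dec = dec, final = final)
}

#' Build the 3D segmentation network
#'
#' Encoder-decoder with skip connections producing per-voxel class scores
#' (softmax over `n_outputs` channels) at full input resolution.
#'
#' @param config a [net_config()]; `n_outputs` should be the class count.
#' @param seed seed for weight initialization.
#' @return a model usable with [net_forward()] and [train()].
#' @export
build_seg_net <- function(config = net_config(n_outputs = 4), seed = 1) {
  m <- .build_unet(config, .layer_softmaxc(), seed)
  m$loss_kind <- "dice_focal"
  m
}

#' Build the 3D heatmap regression network
#'
#' Same encoder-decoder skeleton with a single sigmoid output channel in
#' \[0, 1\] at full resolution; trained against [gaussian_heatmap()] targets
#' with [dice_focal_loss()], honouring the suppression band.
#'
#' @inheritParams build_seg_net
#' @export
build_heatmap_net <- function(config = net_config(n_outputs = 1), seed = 1) {
  m <- .build_unet(config, .layer_sigmoid(), seed)
  m$loss_kind <- "dice_focal"
  m
}

.unet_fwd <- function(model, x, keep = FALSE) {
  cfg <- model$config
  d <- dim(x)[2:4]
  if (any(d %% 2^(cfg$depth - 1) != 0))
    stop("input shape not divisible by 2^(depth-1)")
  L <- cfg$depth
  C <- list(enc = vector("list", L), down = vector("list", L),
            up = vector("list", L), dec = vector("list", L))
  skips <- vector("list", L)
  e <- .seq_fwd(model$layers, model$enc[[1]], x)
  C$enc[[1]] <- e$caches; skips[[1]] <- e$y
  h <- e$y
  if (L > 1) {
    for (l in 2:L) {
      dn <- .seq_fwd(model$layers, model$down[[l]], h)
      C$down[[l]] <- dn$caches
      e <- .seq_fwd(model$layers, model$enc[[l]], dn$y)
      C$enc[[l]] <- e$caches; skips[[l]] <- e$y
      h <- e$y
    }
    for (l in (L - 1):1) {
      u <- .layer_fwd(model$layers[[model$up[[l]]]], h)
      C$up[[l]] <- u$cache
      cat_in <- .cat_channels(skips[[l]], u$y)
      dcb <- .seq_fwd(model$layers, model$dec[[l]], cat_in)
      C$dec[[l]] <- dcb$caches
      h <- dcb$y
    }
  }
  fin <- .seq_fwd(model$layers, model$final, h)
  C$final <- fin$caches
  C$skip_ch <- vapply(skips, function(s) dim(s)[1], numeric(1))
  if (keep) list(y = fin$y, cache = C) else list(y = fin$y)
}

.cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1] + db[1], da[2:4]))
  out[seq_len(da[1]), , , ] <- a
  out[da[1] + seq_len(db[1]), , , ] <- b
  out
}

.unet_bwd <- function(model, cache, dy) {
  L <- model$config$depth
  grads <- vector("list", length(model$layers))
  r <- .seq_bwd(model$layers, model$final, cache$final, dy, grads)
  grads <- r$grads; dh <- r$dx
  dskips <- vector("list", L)
  if (L > 1) {
    for (l in 1:(L - 1)) {
      r <- .seq_bwd(model$layers, model$dec[[l]], cache$dec[[l]], dh, grads)
      grads <- r$grads
      nska <- cache$skip_ch[l]
      dskips[[l]] <- r$dx[seq_len(nska), , , , drop = FALSE]
      dup <- r$dx[-seq_len(nska), , , , drop = FALSE]
      ub <- .layer_bwd(model$layers[[model$up[[l]]]], cache$up[[l]], dup)
      if (!is.null(ub$grads))
        grads[[model$up[[l]]]] <- .grad_add(grads[[model$up[[l]]]], ub$grads)
      dh <- ub$dx
    }
    for (l in L:2) {
      if (l < L) dh <- dh + dskips[[l]]
      r <- .seq_bwd(model$layers, model$enc[[l]], cache$enc[[l]], dh, grads)
      grads <- r$grads
      r <- .seq_bwd(model$layers, model$down[[l]], cache$down[[l]], r$dx, grads)
      grads <- r$grads
      dh <- r$dx
    }
    dh <- dh + dskips[[1]]
  }
  r <- .seq_bwd(model$layers, model$enc[[1]], cache$enc[[1]], dh, grads)
  list(dx = r$dx, grads = r$grads)
}

#' Build the 2D slice-selection network
#'
#' Takes a single-channel slab of `n` slices (input `(1, nx, ny, n)`, default
#' 256 x 256 x 6) and scores each slice for containing the rupture point. Each
#' of the `log2(nx)` pooling stages is preceded by a set of two 1x3x3
#' convolutions (in-plane only, so slices never mix and the slice axis is
#' preserved); max pooling acts only on the in-plane dimensions. A final 1x1
#' convolution reduces to one channel, the in-plane size having collapsed to
#' 1x1, and a softmax over the slice axis yields the score vector. For the
#' default 256x256 input this is nine convolution sets and eight pools.
#'
#' @param config a [net_config()]; `input_shape` must be `c(nx, ny, n_slices)`
#'   with `nx == ny` a power of two.
#' @param seed seed for weight initialization.
#' @export
build_slice_net <- function(config = net_config(base_channels = 4,
                                                input_shape = c(256, 256, 6)),
                            seed = 1) {
  shp <- config$input_shape
  stopifnot(length(shp) == 3, shp[1] == shp[2])
  npool <- as.integer(round(log2(shp[1])))
  if (2^npool != shp[1]) stop("in-plane size must be a power of two")
  set.seed(seed)
  layers <- list()
  add <- function(l) { layers[[length(layers) + 1]] <<- l; length(layers) }
  idx <- c()
  cin <- config$in_channels
  for (s in seq_len(npool)) {
    cout <- min(config$base_channels * 2^((s - 1) %/% 2), config$channel_cap)
    for (i in 1:2) {
      idx <- c(idx, add(.layer_conv(if (i == 1) cin else cout, cout,
                                    k = c(3, 3, 1), pad = c(1, 1, 0))),
               add(.layer_act()))
      cin <- cout
    }
    idx <- c(idx, add(.layer_pool(c(2, 2, 1))))
  }
  idx <- c(idx, add(.layer_conv(cin, 1, k = c(1, 1, 1), pad = c(0, 0, 0))))
  list(kind = "slice", config = config, layers = layers, seq = idx,
       n_slices = shp[3], loss_kind = "ce_slices")
}

.slice_fwd <- function(model, x, keep = FALSE) {
  r <- .seq_fwd(model$layers, model$seq, x)
  z <- as.vector(r$y)                       # (1,1,1,n) -> n logits
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  if (keep) list(y = p, cache = list(seq = r$caches, p = p, ydim = dim(r$y)))
  else list(y = p)
}

.slice_bwd <- function(model, cache, dp) {
  p <- cache$p
  dz <- p * (dp - sum(dp * p))
  dy <- array(dz, cache$ydim)
  grads <- vector("list", length(model$layers))
  r <- .seq_bwd(model$layers, model$seq, cache$seq, dy, grads)
  list(dx = r$dx, grads = r$grads)
}

#' Build the 2D single-level keypoint detector
#'
#' A small strided convolutional backbone reduces the image to its deepest
#' feature map (stride 8); a 1x1 head predicts, per cell, an objectness logit
#' and sub-cell x/y offsets plus log-size corrections. Decoding picks the best
#' cell and reads the keypoint off the box centre; the box size defaults to the
#' ACL width equivalent in pixels.
#'
#' @param config a [net_config()]; `input_shape` is the in-plane image shape.
#' @param seed seed for weight initialization.
#' @export
build_detector <- function(config = net_config(base_channels = 8,
                                               input_shape = c(64, 64)),
                           seed = 1) {
  set.seed(seed)
  layers <- list()
  add <- function(l) { layers[[length(layers) + 1]] <<- l; length(layers) }
  cb <- config$base_channels
  idx <- c()
  cin <- config$in_channels
  for (s in 1:3) {
    cout <- cb * 2^(s - 1)
    idx <- c(idx,
             add(.layer_conv(cin, cout, k = c(3, 3, 1), stride = c(2, 2, 1),
                             pad = c(1, 1, 0))),
             add(.layer_gn(cout, .norm_groups(config, cout))),
             add(.layer_act()),
             add(.layer_conv(cout, cout, k = c(3, 3, 1), pad = c(1, 1, 0))),
             add(.layer_gn(cout, .norm_groups(config, cout))),
             add(.layer_act()))
    cin <- cout
  }
  idx <- c(idx, add(.layer_conv(cin, 5, k = c(1, 1, 1), pad = c(0, 0, 0))))
  list(kind = "detector", config = config, layers = layers, seq = idx,
       stride = 8L, loss_kind = "detector")
}

.detector_fwd <- function(model, x, keep = FALSE) {
  r <- .seq_fwd(model$layers, model$seq, x)
  if (keep) list(y = r$y, cache = r$caches) else list(y = r$y)
}

.detector_bwd <- function(model, cache, dy) {
  grads <- vector("list", length(model$layers))
  .seq_bwd(model$layers, model$seq, cache, dy, grads)
}

#' Decode a detector output map into one box and keypoint
#'
#' Picks the cell with the highest objectness score (first in scan order on
#' ties), applies the sigmoid sub-cell offsets and exponential size correction,
#' and clamps the centre to the image bounds.
#'
#' @param out detector output map `(5, nx/8, ny/8, 1)`.
#' @param model the detector model (for stride and box size).
#' @return list `center` (in-plane pixel pair, 0-based), `size` (pixels),
#'   `score` (objectness probability in \[0, 1\]).
#' @export
decode_detection <- function(out, model) {
  d <- dim(out)
  obj <- matrix(out[1, , , 1], d[2])
  best <- which(obj == max(obj), arr.ind = TRUE)[1, ]
  v <- out[, best[1], best[2], 1]
  s <- model$stride
  sig <- function(z) 1 / (1 + exp(-z))
  cx <- (best[1] - 1 + sig(v[2])) * s
  cy <- (best[2] - 1 + sig(v[3])) * s
  shp <- model$config$input_shape
  list(center = c(min(max(cx, 0), shp[1] - 1), min(max(cy, 0), shp[2] - 1)),
       size = model$config$box_size * exp(c(v[4], v[5])),
       score = sig(v[1]))
}

#' Run a model forward
#'
#' @param model any built model.
#' @param x input array: `(C, X, Y, Z)` for 3D nets; 2D nets accept
#'   `(C, nx, ny)` or `(C, nx, ny, 1)`.
#' @return the model output (array, or probability vector for the slice net).
#' @export
net_forward <- function(model, x) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  switch(model$kind,
         unet = .unet_fwd(model, x)$y,
         slice = .slice_fwd(model, x)$y,
         detector = .detector_fwd(model, x)$y)
}

.model_fwd_keep <- function(model, x) {
  switch(model$kind,
         unet = .unet_fwd(model, x, keep = TRUE),
         slice = .slice_fwd(model, x, keep = TRUE),
         detector = .detector_fwd(model, x, keep = TRUE))
}

.model_bwd <- function(model, cache, dy) {
  switch(model$kind,
         unet = .unet_bwd(model, cache, dy),
         slice = .slice_bwd(model, cache, dy),
         detector = .detector_bwd(model, cache, dy))
}
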