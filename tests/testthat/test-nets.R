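test_that("U-Net builders honour shape contracts across configurations", {
  set.seed(5)
  for (i in 1:4) {
    depth <- sample(1:3, 1)
    bc <- sample(2:4, 1)
    nout <- sample(1:4, 1)
    cfg <- net_config(depth = depth, base_channels = bc, n_outputs = nout,
                      groups = 2)
    net <- build_seg_net(cfg, seed = i)
    shp <- c(8, 8, 4) * 2^(depth - 1)
    x <- array(rnorm(prod(shp)), c(1, shp))
    y <- net_forward(net, x)
    expect_equal(dim(y), c(nout, shp))
    # softmax: class scores sum to one per voxel
    expect_equal(range(apply(y, 2:4, sum)), c(1, 1), tolerance = 1e-9)
  }
  # indivisible input is rejected
  net <- build_seg_net(net_config(depth = 3, base_channels = 2), seed = 1)
  expect_error(net_forward(net, array(0, c(1, 10, 8, 4))), "divisible")
})

test_that("heatmap net outputs probabilities and uses group norm only", {
  cfg <- net_config(depth = 2, base_channels = 4, norm = "group", groups = 4)
  net <- build_heatmap_net(cfg, seed = 2)
  x <- array(rnorm(1 * 16 * 16 * 8), c(1, 16, 16, 8))
  y <- net_forward(net, x)
  expect_equal(dim(y), c(1, 16, 16, 8))
  expect_gte(min(y), 0)
  expect_lte(max(y), 1)
  kinds <- vapply(net$layers, `[[`, "", "kind")
  expect_true(any(kinds == "gn"))
  norm_groups <- vapply(net$layers[kinds == "gn"], `[[`, 1, "groups")
  expect_true(all(norm_groups <= 4))
  # eval-mode determinism
  expect_identical(net_forward(net, x), net_forward(net, x))
})

test_that("parameter count scales quadratically with width", {
  n1 <- n_params(build_heatmap_net(net_config(depth = 3, base_channels = 8),
                                   seed = 1))
  n2 <- n_params(build_heatmap_net(net_config(depth = 3, base_channels = 16),
                                   seed = 1))
  expect_lt(abs(n2 / n1 - 4), 0.8)  # conv-dominated: ~4x within +/-20%
})

test_that("slice net collapses the plane and is slice-equivariant", {
  cfg <- net_config(base_channels = 2, channel_cap = 4,
                    input_shape = c(32, 32, 6))
  sn <- build_slice_net(cfg, seed = 3)
  x <- array(rnorm(32 * 32 * 6), c(1, 32, 32, 6))
  p <- net_forward(sn, x)
  expect_length(p, 6)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p > 0))

  # permuting input slices permutes the scores identically (1x3x3 convs and
  # in-plane pooling never mix slices)
  perm <- c(3, 1, 6, 2, 5, 4)
  p2 <- net_forward(sn, x[, , , perm, drop = FALSE])
  expect_equal(p2, p[perm], tolerance = 1e-9)

  # the reference geometry: 256 -> 1 after eight halvings, 6 slices out
  expect_equal(256 / 2^8, 1)
  sn256 <- build_slice_net(net_config(base_channels = 1, channel_cap = 2,
                                      input_shape = c(256, 256, 6)), seed = 4)
  npools <- sum(vapply(sn256$layers, `[[`, "", "kind") == "pool")
  nconvsets <- sum(vapply(sn256$layers, function(l)
    l$kind == "conv" && l$k[1] == 3, logical(1))) / 2
  expect_equal(npools, 8)
  expect_equal(nconvsets + 1, 9)  # eight double-conv sets + the 1x1 reducer
  p256 <- net_forward(sn256, array(rnorm(256 * 256 * 6), c(1, 256, 256, 6)))
  expect_length(p256, 6)
  expect_error(build_slice_net(net_config(input_shape = c(48, 48, 6))),
               "power of two")
})

test_that("detector decoding stays inside the image and is deterministic", {
  dn <- build_detector(net_config(base_channels = 4, input_shape = c(64, 64)),
                       seed = 6)
  x <- array(rnorm(64 * 64) * 10, c(1, 64, 64, 1))
  out <- net_forward(dn, x)
  expect_equal(dim(out), c(5, 8, 8, 1))
  dec <- decode_detection(out, dn)
  expect_true(all(dec$center >= 0 & dec$center <= 63))
  expect_true(dec$score >= 0 && dec$score <= 1)
  expect_identical(dec, decode_detection(net_forward(dn, x), dn))
})

test_that("backpropagation matches finite differences", {
  set.seed(42)
  cfg <- net_config(depth = 2, base_channels = 2, groups = 2, n_outputs = 1)
  net <- build_heatmap_net(cfg, seed = 3)
  x <- array(rnorm(1 * 8 * 8 * 4), c(1, 8, 8, 4))
  tgt <- structure(list(values = array(runif(8 * 8 * 4), c(8, 8, 4)),
                        invalid_mask = array(FALSE, c(8, 8, 4)),
                        landmark_index = c(1, 1, 1)),
                   class = "acl_heatmap_target")
  lc <- loss_config()
  fw <- aclloc:::.model_fwd_keep(net, x)
  lg <- aclloc:::.loss_and_grad(net, fw$y, tgt, lc)
  bw <- aclloc:::.model_bwd(net, fw$cache, lg$grad)
  lossfun <- function(m) {
    f <- aclloc:::.model_fwd_keep(m, x)
    aclloc:::.loss_and_grad(m, f$y, tgt, lc)$loss
  }
  eps <- 1e-5
  worst <- 0
  for (li in seq_along(net$layers)) {
    gl <- bw$grads[[li]]
    if (is.null(gl)) next
    for (nm in names(gl)) {
      n <- length(net$layers[[li]][[nm]])
      for (j in sample(n, min(2, n))) {
        m2 <- net; m2$layers[[li]][[nm]][j] <- m2$layers[[li]][[nm]][j] + eps
        m3 <- net; m3$layers[[li]][[nm]][j] <- m3$layers[[li]][[nm]][j] - eps
        fd <- (lossfun(m2) - lossfun(m3)) / (2 * eps)
        an <- gl[[nm]][j]
        worst <- max(worst, abs(fd - an) / max(abs(fd), abs(an), 1e-8))
      }
    }
  }
  expect_lt(worst, 1e-4)

  # per-class Dice + focal through the softmax segmentation head
  seg <- build_seg_net(net_config(depth = 2, base_channels = 2, groups = 2,
                                  n_outputs = 3), seed = 4)
  lab <- label_map(array(sample(0:2, 8 * 8 * 4, TRUE), c(8, 8, 4)),
                   geometry(c(1, 1, 1)), c("bg", "a", "b"))
  tgt2 <- seg_target(lab)
  fw <- aclloc:::.model_fwd_keep(seg, x)
  lg <- aclloc:::.loss_and_grad(seg, fw$y, tgt2, lc)
  bw <- aclloc:::.model_bwd(seg, fw$cache, lg$grad)
  lossfun2 <- function(m) {
    f <- aclloc:::.model_fwd_keep(m, x)
    aclloc:::.loss_and_grad(m, f$y, tgt2, lc)$loss
  }
  worst2 <- 0
  for (li in seq_along(seg$layers)) {
    gl <- bw$grads[[li]]
    if (is.null(gl)) next
    for (nm in names(gl)) {
      n <- length(seg$layers[[li]][[nm]])
      for (j in sample(n, min(1, n))) {
        m2 <- seg; m2$layers[[li]][[nm]][j] <- m2$layers[[li]][[nm]][j] + eps
        m3 <- seg; m3$layers[[li]][[nm]][j] <- m3$layers[[li]][[nm]][j] - eps
        fd <- (lossfun2(m2) - lossfun2(m3)) / (2 * eps)
        an <- gl[[nm]][j]
        worst2 <- max(worst2, abs(fd - an) / max(abs(fd), abs(an), 1e-8))
      }
    }
  }
  expect_lt(worst2, 5e-3)  # leaky-ReLU kinks limit finite-difference accuracy
})

test_that("dice+focal loss honours its analytic identities and the mask", {
  d <- c(6, 6, 4)
  set.seed(8)
  tval <- array(0, d); tval[3, 3, 2] <- 1; tval[4, 3, 2] <- 1
  invalid <- array(FALSE, d); invalid[1, 1, 1] <- TRUE; invalid[6, 6, 4] <- TRUE
  tgt <- structure(list(values = tval, invalid_mask = invalid,
                        landmark_index = c(2, 2, 1)),
                   class = "acl_heatmap_target")

  # near-perfect prediction: loss below 1e-3
  perfect <- pmin(pmax(tval, 1e-6), 1 - 1e-6)
  expect_lt(dice_focal_loss(perfect, tgt), 1e-3)

  # gamma 0, alpha 0.5, no dice: exactly half the binary cross-entropy
  p <- array(runif(prod(d), 0.05, 0.95), d)
  cfg0 <- loss_config(dice_weight = 0, focal_weight = 1, focal_gamma = 0,
                      focal_alpha = 0.5)
  got <- dice_focal_loss(p, tgt, cfg0)
  v <- !invalid
  bce <- mean(-(tval[v] * log(p[v]) + (1 - tval[v]) * log(1 - p[v])))
  expect_equal(got, bce / 2, tolerance = 1e-9)

  # perturbing invalid voxels changes nothing, to machine precision
  p2 <- p
  p2[1, 1, 1] <- 0.999; p2[6, 6, 4] <- 0.001
  expect_equal(dice_focal_loss(p2, tgt, cfg0), got, tolerance = 1e-12)
  expect_equal(dice_focal_loss(p2, tgt), dice_focal_loss(p, tgt),
               tolerance = 1e-12)

  expect_error(dice_focal_loss(array(0.5, c(2, 2, 2)), tgt), "mismatch")
  expect_error(loss_config(dice_weight = 0, focal_weight = 0), "> 0")
})

test_that("training contracts: identity at lr 0, determinism, descent", {
  cases <- make_dataset(6, tiny_spec(), seed = 91)
  ds <- heatmap_training_set(cases, tiny_loc_config())
  net <- build_heatmap_net(net_config(depth = 3, base_channels = 4), seed = 7)

  # one epoch at lr 0: history of length 1, weights untouched
  tr0 <- train(net, ds, train_config(epochs = 1, lr = 0, seed = 1))
  expect_length(tr0$history, 1)
  expect_identical(tr0$model$layers, net$layers)

  # seeded reruns agree exactly
  trA <- train(net, ds, train_config(epochs = 2, lr = 0.02, seed = 5))
  trB <- train(net, ds, train_config(epochs = 2, lr = 0.02, seed = 5))
  expect_identical(trA$history, trB$history)

  # loss drops by at least 20% over a short run on the phantom fixture
  tr <- train(net, ds, train_config(epochs = 8, lr = 0.03, seed = 5))
  expect_lt(tr$history[length(tr$history)], 0.8 * tr$history[1])
})

test_that("the detector learns to centre bright blobs", {
  set.seed(77)
  mk_img <- function() {
    ctr <- runif(2, 8, 55)
    xs <- matrix(0:63, 64, 64); ys <- t(xs)
    img <- exp(-((xs - ctr[1])^2 + (ys - ctr[2])^2) / (2 * 3^2))
    img <- img + matrix(rnorm(64 * 64, 0, 0.05), 64, 64)
    list(input = array(img, c(1, 64, 64, 1)),
         target = box_target(ctr, c(11, 11), c(64, 64)),
         center = ctr)
  }
  all80 <- lapply(1:80, function(i) mk_img())
  dn <- build_detector(net_config(base_channels = 8, input_shape = c(64, 64)),
                       seed = 9)
  tr <- train(dn, all80[1:64], train_config(epochs = 30, lr = 0.01, seed = 9))
  errs <- vapply(all80[65:80], function(cs) {
    dec <- decode_detection(net_forward(tr$model, cs$input), tr$model)
    sqrt(sum((dec$center - cs$center)^2))
  }, numeric(1))
  expect_lt(mean(errs), 2)
})
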