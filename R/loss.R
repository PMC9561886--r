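# Combined Dice + focal loss with exact exclusion of invalid voxels (the
# false-positive suppression band contributes nothing, not even epsilon).

#' Loss configuration for Dice + focal training
#'
#' @param dice_weight,focal_weight non-negative weights; their sum must be > 0.
#' @param focal_gamma focusing exponent (>= 0); 0 reduces the focal term to
#'   (alpha-weighted) cross-entropy.
#' @param focal_alpha positive-class weight in (0, 1).
#' @return list of class `acl_loss_config`.
#' @export
loss_config <- function(dice_weight = 1, focal_weight = 1, focal_gamma = 2,
                        focal_alpha = 0.25) {
  stopifnot(dice_weight >= 0, focal_weight >= 0, focal_gamma >= 0,
            focal_alpha > 0, focal_alpha < 1)
  if (dice_weight + focal_weight <= 0) stop("at least one weight must be > 0")
  structure(list(dice_weight = dice_weight, focal_weight = focal_weight,
                 focal_gamma = focal_gamma, focal_alpha = focal_alpha),
            class = "acl_loss_config")
}

.dice_focal_core <- function(p, t, valid, config, eps = 1e-5) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  pv <- p[valid]; tv <- t[valid]
  # soft Dice (sum-of-squares denominator)
  num <- 2 * sum(pv * tv) + eps
  den <- sum(pv^2) + sum(tv^2) + eps
  dice <- num / den
  g <- config$focal_gamma; a <- config$focal_alpha
  fpos <- -a * tv * (1 - pv)^g * log(pv)
  fneg <- -(1 - a) * (1 - tv) * pv^g * log(1 - pv)
  m <- length(pv)
  loss <- config$dice_weight * (1 - dice) +
    config$focal_weight * sum(fpos + fneg) / m
  # gradient wrt p on valid voxels
  ddice <- (2 * tv * den - num * 2 * pv) / den^2
  dfpos <- -a * tv * (-g * (1 - pv)^(pmax(g - 1, 0)) * log(pv) + (1 - pv)^g / pv)
  if (g == 0) dfpos <- -a * tv / pv
  dfneg <- -(1 - a) * (1 - tv) *
    (g * pv^(pmax(g - 1, 0)) * log(1 - pv) - pv^g / (1 - pv))
  if (g == 0) dfneg <- (1 - a) * (1 - tv) / (1 - pv)
  gv <- -config$dice_weight * ddice + config$focal_weight * (dfpos + dfneg) / m
  grad <- array(0, dim(p))
  grad[valid] <- gv
  list(loss = loss, grad = grad)
}

#' Combined Dice and focal loss
#'
#' `loss = dice_weight * (1 - softDice) + focal_weight * mean(focal)`, both
#' terms computed over valid voxels only: voxels flagged in the target's
#' `invalid_mask` (the false-positive suppression band) contribute exactly
#' nothing, so perturbing predictions there cannot change the loss.
#'
#' @param pred per-voxel probabilities: array shaped like the target values,
#'   or `(C, ...)` against a one-hot target.
#' @param target an `acl_heatmap_target`, or a one-hot array from
#'   [seg_target()], or a plain array (no mask).
#' @param config a [loss_config()].
#' @return scalar loss (>= 0).
#' @export
dice_focal_loss <- function(pred, target, config = loss_config()) {
  .dice_focal_dispatch(pred, target, config)$loss
}

# multi-class one-hot targets: Dice per class averaged over classes (so small
# foreground classes are not swamped by background), focal over all entries
.dice_focal_multiclass <- function(p, t, config, eps = 1e-5) {
  k <- dim(p)[1]
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  pm <- matrix(p, k); tm <- matrix(t, k)
  grad <- 0 * pm
  dice_loss <- 0
  for (c in seq_len(k)) {
    pv <- pm[c, ]; tv <- tm[c, ]
    num <- 2 * sum(pv * tv) + eps
    den <- sum(pv^2) + sum(tv^2) + eps
    dice_loss <- dice_loss + (1 - num / den)
    grad[c, ] <- grad[c, ] -
      config$dice_weight * (2 * tv * den - num * 2 * pv) / den^2 / k
  }
  g <- config$focal_gamma; a <- config$focal_alpha
  m <- length(pm)
  fpos <- -a * tm * (1 - pm)^g * log(pm)
  fneg <- -(1 - a) * (1 - tm) * pm^g * log(1 - pm)
  dfpos <- if (g == 0) -a * tm / pm else
    -a * tm * (-g * (1 - pm)^(g - 1) * log(pm) + (1 - pm)^g / pm)
  dfneg <- if (g == 0) (1 - a) * (1 - tm) / (1 - pm) else
    -(1 - a) * (1 - tm) * (g * pm^(g - 1) * log(1 - pm) - pm^g / (1 - pm))
  loss <- config$dice_weight * dice_loss / k + config$focal_weight *
    sum(fpos + fneg) / m
  grad <- grad + config$focal_weight * (dfpos + dfneg) / m
  list(loss = loss, grad = array(grad, dim(p)))
}

.dice_focal_dispatch <- function(pred, target, config) {
  if (inherits(target, "acl_heatmap_target")) {
    tval <- target$values
    if (length(dim(pred)) == 4 && dim(pred)[1] == 1)
      tval <- array(tval, dim(pred))
    if (!identical(dim(pred), dim(tval))) stop("pred/target shape mismatch")
    invalid <- array(target$invalid_mask, dim(pred))
    .dice_focal_core(pred, tval, !invalid, config)
  } else {
    if (!identical(dim(pred), dim(target))) stop("pred/target shape mismatch")
    if (length(dim(pred)) == 4 && dim(pred)[1] > 1)
      .dice_focal_multiclass(pred, target, config)
    else
      .dice_focal_core(pred, target, array(TRUE, dim(pred)), config)
  }
}

# cross-entropy against a straddle-slice probability vector
.ce_slices <- function(p, tv) {
  p <- pmin(pmax(p, 1e-9), 1)
  list(loss = -sum(tv * log(p)), grad = -tv / p)
}

# detector loss: softmax cross-entropy over cells for objectness (exactly one
# object per image) + L2 on sub-cell offsets and log-size at the true cell
.detector_loss <- function(out, target, model) {
  d <- dim(out)
  s <- model$stride
  cell <- pmin(floor(target$center / s), c(d[2], d[3]) - 1)
  frac <- target$center / s - cell
  logits <- as.vector(out[1, , , 1])
  z <- logits - max(logits)
  p <- exp(z) / sum(exp(z))
  k <- cell[1] + 1 + d[2] * cell[2]
  grad <- array(0, d)
  gobj <- p; gobj[k] <- gobj[k] - 1
  grad[1, , , 1] <- gobj
  v <- out[, cell[1] + 1, cell[2] + 1, 1]
  sig <- function(z) 1 / (1 + exp(-z))
  so <- sig(v[2:3])
  lsz <- v[4:5] - log(target$size / model$config$box_size)
  grad[2:3, cell[1] + 1, cell[2] + 1, 1] <-
    2 * (so - frac) * so * (1 - so)
  grad[4:5, cell[1] + 1, cell[2] + 1, 1] <- 2 * lsz
  loss <- -log(max(p[k], 1e-12)) + sum((so - frac)^2) + sum(lsz^2)
  list(loss = loss, grad = grad)
}

.loss_and_grad <- function(model, out, target, config) {
  switch(model$loss_kind,
         dice_focal = .dice_focal_dispatch(out, target, config),
         ce_slices = .ce_slices(out, target$target_vector),
         detector = .detector_loss(out, target, model),
         stop("no loss for model kind ", model$kind))
}
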