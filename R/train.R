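# Plain momentum-SGD training, batch of one, deterministic for a fixed seed
# on a single thread.

#' Training configuration
#'
#' @param epochs passes over the dataset.
#' @param lr learning rate.
#' @param momentum momentum coefficient.
#' @param seed integer seed controlling shuffling (and nothing else).
#' @param loss a [loss_config()] (used by Dice+focal models).
#' @param shuffle reshuffle case order every epoch.
#' @param verbose print per-epoch loss.
#' @return list of class `acl_train_config`.
#' @export
train_config <- function(epochs = 10, lr = 0.01, momentum = 0.9, seed = 1,
                         loss = loss_config(), shuffle = TRUE,
                         verbose = FALSE) {
  structure(list(epochs = epochs, lr = lr, momentum = momentum, seed = seed,
                 loss = loss, shuffle = shuffle, verbose = verbose),
            class = "acl_train_config")
}

.sgd_step <- function(model, grads, state, lr, momentum) {
  for (i in seq_along(model$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      v <- state[[i]][[nm]]
      if (is.null(v)) v <- 0 * g[[nm]]
      v <- momentum * v + g[[nm]]
      state[[i]][[nm]] <- v
      model$layers[[i]][[nm]] <- model$layers[[i]][[nm]] - lr * v
    }
  }
  list(model = model, state = state)
}

#' Train a model on a list of (input, target) pairs
#'
#' Stochastic gradient descent with momentum, one case per step. Aborts with a
#' diagnostic if the loss turns non-finite (divergence). Deterministic given
#' the seed and single-threaded execution; with `lr = 0` the weights are
#' returned unchanged.
#'
#' @param model a built model ([build_heatmap_net()] and friends).
#' @param dataset non-empty list; each element is a list with `input` (array)
#'   and `target` (matching the model's loss: an `acl_heatmap_target` or
#'   one-hot array for Dice+focal models, an `acl_slice_target` for the slice
#'   net, a [box_target()] for the detector).
#' @param config a [train_config()].
#' @return list with `model` (trained) and `history` (per-epoch mean loss).
#' @export
train <- function(model, dataset, config = train_config()) {
  if (length(dataset) == 0) stop("empty dataset")
  set.seed(config$seed)
  state <- vector("list", length(model$layers))
  history <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- if (config$shuffle) sample.int(length(dataset))
           else seq_along(dataset)
    tot <- 0
    for (i in ord) {
      x <- dataset[[i]]$input
      if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
      fw <- .model_fwd_keep(model, x)
      lg <- .loss_and_grad(model, fw$y, dataset[[i]]$target, config$loss)
      if (!is.finite(lg$loss))
        stop("training diverged: non-finite loss at epoch ", ep,
             ", case ", i)
      tot <- tot + lg$loss
      if (config$lr > 0) {
        bw <- .model_bwd(model, fw$cache, lg$grad)
        st <- .sgd_step(model, bw$grads, state, config$lr, config$momentum)
        model <- st$model; state <- st$state
      }
    }
    history[ep] <- tot / length(dataset)
    if (config$verbose)
      message(sprintf("epoch %d/%d  loss %.5f", ep, config$epochs, history[ep]))
  }
  list(model = model, history = history)
}

#' Save / load a model checkpoint
#'
#' Single-file serialized checkpoint embedding the model's `net_config`.
#'
#' @param model a built (possibly trained) model.
#' @param path checkpoint file path.
#' @return `path` (save) or the model (load).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
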