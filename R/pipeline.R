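# End-to-end orchestration: training-set construction, the demo pipeline and
# its artifacts. Training-set builders and localize_case() share the same ROI
# and patch code paths, so what the network sees in training is exactly what
# it sees at inference.

#' Build heatmap-regression training pairs from phantom cases
#'
#' For each case: ROI from the ground-truth labels, a fixed-shape normalized
#' patch around the ROI centre, and a [gaussian_heatmap()] target on the patch
#' geometry centred at the true rupture point.
#'
#' @param cases list of phantom cases.
#' @param config a [localize_config()] (patch shape and margin).
#' @param sigma,support_radius,suppression_band heatmap parameters in mm.
#' @return list of `list(input, target)` pairs for [train()].
#' @export
heatmap_training_set <- function(cases, config = localize_config(), sigma = 3,
                                 support_radius = 3 * sigma,
                                 suppression_band = 2) {
  lapply(cases, function(cs) {
    roi <- roi_from_labels(cs$labels, config$margin_mm)
    patch <- .loc_patch(cs$volume, roi$center, config)
    x <- .normalize_patch(patch$data)
    dim(x) <- c(1, dim(patch$data))
    tgt <- gaussian_heatmap(patch$geometry, cs$gt$rupture_point,
                            dim(patch$data), sigma = sigma,
                            support_radius = support_radius,
                            suppression_band = suppression_band)
    list(input = x, target = tgt)
  })
}

#' Build segmentation training pairs from phantom cases
#'
#' Normalized full volumes paired with one-hot label targets.
#'
#' @param cases list of phantom cases.
#' @return list of `list(input, target)` pairs for [train()].
#' @export
seg_training_set <- function(cases) {
  lapply(cases, function(cs) {
    x <- .normalize_patch(cs$volume$data)
    dim(x) <- c(1, dim(cs$volume$data))
    list(input = x, target = seg_target(cs$labels))
  })
}

#' Oracle heatmap localizer for a phantom case
#'
#' Returns a function that, given a normalized patch array with geometry
#' attached via closure, emits the ground-truth Gaussian heatmap — used to
#' validate decoding and classification independently of any training.
#'
#' @param cs a phantom case.
#' @param config a [localize_config()].
#' @param sigma heatmap width in mm.
#' @return function(patch array) -> probability array.
#' @export
oracle_heatmap_model <- function(cs, config = localize_config(), sigma = 3) {
  function(x) {
    roi <- roi_from_labels(cs$labels, config$margin_mm)
    patch <- .loc_patch(cs$volume, roi$center, config)
    gaussian_heatmap(patch$geometry, cs$gt$rupture_point, dim(patch$data),
                     sigma = sigma)$values
  }
}

#' Run the full phantom-to-metrics pipeline
#'
#' Generates a phantom dataset, trains the heatmap-regression network on the
#' training split (segmentation ROIs come from the ground-truth labels unless
#' `train_seg` is TRUE), localizes and classifies every held-out case, and
#' writes results (predictions TSV, metrics JSON-style TSV) under `out_dir`.
#' Every artifact records the seed; the whole run is deterministic given
#' (config, seed).
#'
#' @param n_train,n_test dataset sizes.
#' @param spec a [phantom_spec()].
#' @param seed master seed.
#' @param out_dir output directory (created).
#' @param train_cfg a [train_config()] for the heatmap net.
#' @param net_cfg a [net_config()] for the heatmap net.
#' @param loc_cfg a [localize_config()].
#' @param train_seg also train the segmentation net and use it for ROIs
#'   (slower; FALSE uses label-derived ROIs).
#' @param seg_train_cfg a [train_config()] for the segmentation net.
#' @return list with `stats` (held-out `acl_loc_stats`), `metrics`
#'   (`acl_metrics`), `confusion`, `history` (training loss), `results`
#'   (per-case data.frame), invisibly written under `out_dir`.
#' @export
run_pipeline <- function(n_train = 60, n_test = 20, spec = phantom_spec(),
                         seed = 7, out_dir = tempfile("aclloc_run_"),
                         train_cfg = train_config(epochs = 12, lr = 0.02,
                                                  seed = seed),
                         net_cfg = net_config(depth = 3, base_channels = 8),
                         loc_cfg = localize_config(),
                         train_seg = FALSE,
                         seg_train_cfg = train_config(epochs = 4, lr = 0.02,
                                                      seed = seed)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  all_cases <- make_dataset(n_train + n_test, spec, seed = seed)
  train_cases <- all_cases[seq_len(n_train)]
  test_cases <- all_cases[n_train + seq_len(n_test)]
  ds <- heatmap_training_set(train_cases, loc_cfg)
  net <- build_heatmap_net(net_cfg, seed = seed)
  tr <- train(net, ds, train_cfg)
  seg_model <- NULL
  if (train_seg) {
    seg_net <- build_seg_net(net_config(depth = net_cfg$depth,
                                        base_channels = net_cfg$base_channels,
                                        n_outputs = 4), seed = seed + 1)
    seg_tr <- train(seg_net, seg_training_set(train_cases), seg_train_cfg)
    seg_model <- seg_tr$model
  }
  rows <- lapply(names(test_cases), function(id) {
    cs <- test_cases[[id]]
    seg_in <- if (train_seg) seg_model else cs$labels
    res <- localize_case(cs$volume, seg_in, tr$model, "heatmap3d", loc_cfg)
    roi <- attr(res, "roi")
    axis <- acl_axis(roi$femoral_center, roi$tibial_center)
    side <- classify_case(res, axis)
    data.frame(case = id, x = res$point[1], y = res$point[2], z = res$point[3],
               method = res$method, fallback = res$fallback_used,
               error_mm = euclidean_error(res$point, cs$gt$rupture_point),
               pred_side = as.character(side$value),
               true_side = as.character(cs$gt$side))
  })
  results <- do.call(rbind, rows)
  stats <- localization_stats(results$error_mm)
  cm <- confusion(results$pred_side, results$true_side)
  metrics <- class_metrics(cm)
  utils::write.table(results, file.path(out_dir, "predictions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  summary_df <- data.frame(seed = seed, n_train = n_train, n_test = n_test,
                           mean_error_mm = stats$mean, sd_error_mm = stats$sd,
                           failures = stats$failures,
                           error_rate = stats$error_rate,
                           side_accuracy = metrics$overall_accuracy)
  utils::write.table(summary_df, file.path(out_dir, "metrics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(list(stats = stats, metrics = metrics, confusion = cm,
                 history = tr$history, results = results, out_dir = out_dir))
}
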