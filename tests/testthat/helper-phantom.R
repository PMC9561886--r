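# Shared fixtures: a small fast phantom spec for unit tests (the acceptance
# tests use the full default geometry).

tiny_spec <- function(...) {
  phantom_spec(grid_shape = c(32, 32, 16), spacing = c(1, 1, 3),
               acl_length = 24, acl_width = 8, footprint_radius = 4,
               gap_halfwidth = 2.5, ...)
}

tiny_loc_config <- function(...) {
  localize_config(patch_shape = c(24, 24, 16), patch_spacing = c(1.5, 1.5),
                  margin_mm = 4, ...)
}

# random proper-rotation matrix (det +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# oracle localizer: feeds the ground-truth heatmap through the real decoding
oracle_localize <- function(cs, config = localize_config()) {
  localize_case(cs$volume, cs$labels, oracle_heatmap_model(cs, config),
                mode = "heatmap3d", config = config)
}
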