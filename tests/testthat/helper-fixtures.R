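# Shared fixtures: tiny models and phantom batches, built in code.

tiny_config <- function(in_channels = 1L, depth = 2L, base_filters = 4L,
                        groups = 2L, seed = 1L) {
  unet_config(in_channels = in_channels, depth = depth,
              base_filters = base_filters, groupnorm_groups = groups,
              seed = seed)
}

tiny_images <- function(n = 4, size = 64, seed = 1, modality = "mri") {
  spec <- phantom_spec(size, size, modality = modality, seed = seed)
  lapply(seq_len(n) - 1L, function(i) {
    s <- generate_sample(spec, i)
    if (modality == "ct")
      normalize_image(stack_ct_channels(s$image), "per_channel")$data
    else normalize_image(s$image, "per_volume")$data
  })
}

tiny_labeled <- function(n = 4, size = 64, seed = 1) {
  spec <- phantom_spec(size, size, seed = seed)
  lapply(seq_len(n) - 1L, function(i) {
    s <- generate_sample(spec, i)
    list(x = normalize_image(s$image, "per_volume")$data, y = s$label_map)
  })
}

# brute-force oracle: check that all K x K patch rectangles are pairwise
# disjoint by direct interval intersection
patches_pairwise_disjoint <- function(anchors, K) {
  n <- nrow(anchors)
  if (n < 2) return(TRUE)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    overlap_r <- anchors[i, 1] < anchors[j, 1] + K &&
      anchors[j, 1] < anchors[i, 1] + K
    overlap_c <- anchors[i, 2] < anchors[j, 2] + K &&
      anchors[j, 2] < anchors[i, 2] + K
    if (overlap_r && overlap_c) return(FALSE)
  }
  TRUE
}

min_center_distance <- function(anchors, K) {
  ctr <- anchors + K / 2
  d <- as.matrix(stats::dist(ctr))
  diag(d) <- Inf
  min(d)
}
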