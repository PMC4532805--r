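# Shared fixture builders: small phantoms kept fast on one CPU.

tiny_config <- function(seed = 7L, n_hc = 4L, n_patients = 2L,
                        lesion_spec = default_lesion_spec(
                          count_per_patient = 1L, voxel_range = c(12L, 20L)),
                        ...) {
  phantom_config(grid_shape = c(24L, 16L, 12L), n_hc = n_hc,
                 n_patients = n_patients, lesion_spec = lesion_spec,
                 seed = seed, ...)
}

tiny_atlas <- function(config = tiny_config()) generate_atlas(config)

# A one-compartment world: single label, handy for hand-computed z oracles.
flat_atlas <- function(dims = c(6L, 6L, 6L), voxel_volume = 1) {
  lab <- array(1L, dims)
  tissue_atlas(lab, data.frame(label = 1L, lobe = "frontal", tissue = "WM"),
               voxel_volume = voxel_volume)
}

flat_reference <- function(mu = 100, sigma = 10) {
  out <- expand.grid(lobe = "frontal", tissue = "WM",
                     contrast = qmri_contrasts(), KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  out$mu <- mu
  out$sigma <- sigma
  out$n_voxels <- 1000L
  class(out) <- c("reference_stats", "data.frame")
  out
}

# Brute-force mask union voxel set, the set-oracle for merge_lesion_masks.
union_voxels_oracle <- function(masks) {
  sort(unique(unlist(lapply(masks, function(m) which(m != 0)))))
}
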