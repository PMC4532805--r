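blob <- function(dims, idx) {
  m <- array(0L, dims)
  m[idx] <- 1L
  m
}

test_that("mask union merging matches the set oracle and connectivity rules", {
  dims <- c(8L, 8L, 4L)
  a <- blob(dims, c(10L, 11L))
  b <- blob(dims, 200L)
  lab <- merge_lesion_masks(list(a, b))
  expect_equal(max(lab), 2L) # disjoint blobs -> 2 components

  # overlapping/touching blobs fuse into one component
  c1 <- blob(dims, c(10L, 11L, 12L))
  c2 <- blob(dims, c(12L, 13L))
  expect_equal(max(merge_lesion_masks(list(c1, c2))), 1L)

  # union voxel set equals the brute-force set union
  set.seed(3)
  masks <- replicate(3, blob(dims, sample(prod(dims), 40L)), simplify = FALSE)
  lab <- merge_lesion_masks(masks)
  expect_identical(sort(which(lab != 0L)), union_voxels_oracle(masks))

  # idempotence: merging the union with itself changes nothing
  u <- (lab != 0L) * 1L
  expect_identical(merge_lesion_masks(list(u, u)), merge_lesion_masks(list(u)))

  expect_error(merge_lesion_masks(list(a, blob(c(4L, 4L, 4L), 1L))),
               class = "qmri_input_error")
})

test_that("size filter is strict at the 10-voxel boundary", {
  dims <- c(30L, 4L, 4L)
  # three bars of 10, 11 and 5 voxels along x, well separated
  m <- array(0L, dims)
  m[1:10, 2, 2] <- 1L
  m[13:23, 2, 2] <- 1L # 11 voxels
  m[26:30, 2, 2] <- 1L
  lab <- merge_lesion_masks(list(m))
  kept <- filter_lesions(lab, min_voxels = 10L)
  expect_length(kept, 1L) # 10 excluded, 11 included, 5 excluded
  expect_length(kept[[1L]]$voxels, 11L)

  expect_identical(filter_lesions(array(0L, dims)), list())
})

test_that("localization and typing follow the GM/WM composition rules", {
  cfg <- tiny_config()
  atlas <- tiny_atlas(cfg)
  wm_front <- which(atlas$labels == 1L) # frontal WM
  gm_front <- which(atlas$labels == 2L) # frontal GM

  hom <- localize_and_type(wm_front[1:8], atlas)
  expect_equal(hom$lobe, "frontal")
  expect_equal(hom$type, "WM")

  mixed <- localize_and_type(c(gm_front[1:5], wm_front[1:6]), atlas)
  expect_equal(mixed$type, "cortical-I") # 5 GM + 6 WM voxels

  pure_gm <- localize_and_type(gm_front[1:4], atlas)
  expect_equal(pure_gm$type, "cortical-II")

  # lobe tie: equal voxels in frontal and parietal -> first in fixed order
  par_wm <- which(atlas$labels == 3L)
  tie <- localize_and_type(c(wm_front[1:3], par_wm[1:3]), atlas)
  expect_equal(tie$lobe, "frontal")

  # background-only lesion is an orphan
  bg <- which(atlas$labels == 0L)
  expect_error(localize_and_type(bg[1:5], atlas),
               class = "qmri_orphan_lesion_error")
})

test_that("volume normalization arithmetic, scaling and conservation", {
  expect_equal(normalize_volume(100L, 1, 1e6), 1e-4)
  expect_equal(normalize_volume(50L, 2, 1e6), 2 * normalize_volume(50L, 2, 2e6))
  n <- c(12L, 40L, 7L)
  tiv <- 5e5
  expect_equal(sum(normalize_volume(n, 1.5, tiv)) * tiv, sum(n * 1.5))
  expect_error(normalize_volume(10L, 1, 0), class = "qmri_input_error")
})

test_that("lesion z-scores: centering, hand oracle and affine invariance", {
  atlas <- flat_atlas(c(6L, 6L, 6L))
  ref <- flat_reference(mu = 100, sigma = 10)
  vox <- 1:3
  m <- array(100, c(6L, 6L, 6L))
  expect_equal(lesion_zscore(m, vox, "T1", ref, atlas), 0)

  # values mu + sigma, mu + 2 sigma, mu + 3 sigma -> z = 2
  m[vox] <- c(110, 120, 130)
  expect_equal(lesion_zscore(m, vox, "T1", ref, atlas), 2)

  # affine rescale of map, mu, sigma jointly cancels
  a <- 3.7
  b <- -12
  ref2 <- ref
  ref2$mu <- a * ref$mu + b
  ref2$sigma <- a * ref$sigma
  expect_equal(lesion_zscore(a * m + b, vox, "T1", ref2, atlas),
               lesion_zscore(m, vox, "T1", ref, atlas))

  # missing reference entry
  ref3 <- ref[ref$contrast != "MTR", ]
  expect_error(lesion_zscore(m, vox, "MTR", ref3, atlas),
               class = "qmri_missing_compartment_error")
})

test_that("voxelwise and majority compartment modes agree on homogeneous lesions", {
  cfg <- tiny_config()
  atlas <- tiny_atlas(cfg)
  hc <- generate_hc_maps(tiny_config(n_hc = 4L), atlas)
  ref <- compute_reference_stats(hc, atlas)
  vox <- which(atlas$labels == 1L)[1:12]
  m <- hc[[1L]]$T1
  expect_equal(
    lesion_zscore(m, vox, "T1", ref, atlas, compartment = "voxel"),
    lesion_zscore(m, vox, "T1", ref, atlas, compartment = "majority"))
})

test_that("reference-distributed lesions have z ~ Normal(0, 1/N)", {
  atlas <- flat_atlas(c(10L, 10L, 10L))
  ref <- flat_reference(mu = 50, sigma = 5)
  set.seed(99)
  n_vox <- 25L
  z <- replicate(300, {
    m <- array(rnorm(1000, 50, 5), c(10L, 10L, 10L))
    lesion_zscore(m, sample(1000L, n_vox), "T2", ref, atlas)
  })
  expect_lt(abs(mean(z)), 4 / sqrt(300 * n_vox))
  expect_lt(abs(sd(z) - 1 / sqrt(n_vox)), 0.25 / sqrt(n_vox))
})

test_that("quantify_lesions produces a complete per-lesion table", {
  cfg <- tiny_config(seed = 13L)
  atlas <- tiny_atlas(cfg)
  ref <- compute_reference_stats(generate_hc_maps(cfg, atlas), atlas)
  pat <- generate_patient(cfg, atlas, index = 1L)
  q <- quantify_lesions(pat$maps, pat$masks, atlas, ref)
  expect_true(all(q$n_voxels > 10L))
  expect_true(all(q$norm_volume > 0 & q$norm_volume < 1))
  expect_true(all(is.finite(as.matrix(q[c("z_T1", "z_T2", "z_T2star", "z_MTR")]))))
  expect_equal(q$volume_mm3, q$n_voxels * atlas$voxel_volume)
  expect_length(attr(q, "voxels"), nrow(q))
  # matched truth rows are found for every quantified lesion
  hit <- match_lesions_to_truth(q, pat$truth)
  expect_false(anyNA(hit))
})
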