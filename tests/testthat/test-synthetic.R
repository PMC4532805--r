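test_that("generated atlas partitions non-background voxels over all labels", {
  cfg <- tiny_config()
  atlas <- generate_atlas(cfg)
  labs <- atlas$labels
  present <- sort(unique(as.vector(labs[labs != 0L])))
  expect_identical(present, sort(atlas$table$label)) # all 10 labels present
  counts <- table(factor(as.vector(labs), levels = 0:max(atlas$table$label)))
  expect_equal(sum(counts), prod(cfg$grid_shape)) # conservation
  expect_true(all(counts[-1L] >= 1L))
  # determinism (the layout is seed-free by construction)
  expect_identical(generate_atlas(cfg)$labels, labs)
  # too-small grid is a configuration error
  expect_error(generate_atlas(phantom_config(grid_shape = c(4L, 4L, 4L))),
               class = "qmri_config_error")
})

test_that("HC maps follow the configured compartment distributions", {
  cfg <- tiny_config(n_hc = 10L)
  atlas <- tiny_atlas(cfg)
  hc <- generate_hc_maps(cfg, atlas)
  expect_length(hc, 10L)

  # Monte-Carlo: pooled sample mean of one compartment within 5 SE of truth
  sel <- atlas$labels == atlas$table$label[atlas$table$lobe == "frontal" &
                                             atlas$table$tissue == "WM"]
  cp <- cfg$contrast_params
  truth <- cp[cp$lobe == "frontal" & cp$tissue == "WM" & cp$contrast == "T1", ]
  vals <- unlist(lapply(hc, function(s) s$T1[sel]))
  se <- truth$sd / sqrt(length(vals))
  expect_lt(abs(mean(vals) - truth$mean), 5 * se)

  # fixed seed -> bit-identical cohort
  expect_identical(generate_hc_maps(cfg, atlas), hc)

  # degenerate noise: SD 0 everywhere reproduces the mean map exactly
  cp0 <- cfg$contrast_params
  cp0$sd <- 0
  cfg0 <- tiny_config(contrast_params = cp0)
  hc0 <- generate_hc_maps(tiny_config(contrast_params = cp0), generate_atlas(cfg0))
  m1 <- hc0[[1L]]$T1[sel]
  expect_true(all(m1 == truth$mean))
  expect_identical(hc0[[1L]]$T1, hc0[[2L]]$T1)
})

test_that("missing contrast parameters for a present label error out", {
  cfg <- tiny_config()
  atlas <- tiny_atlas(cfg)
  cfg$contrast_params <- cfg$contrast_params[cfg$contrast_params$lobe != "temporal", ]
  expect_error(generate_hc_maps(cfg, atlas), class = "qmri_config_error")
})

test_that("patient lesions respect bookkeeping, placement and mask invariants", {
  spec <- default_lesion_spec(count_per_patient = 2L, voxel_range = c(12L, 18L))
  cfg <- tiny_config(lesion_spec = spec)
  atlas <- tiny_atlas(cfg)
  pat <- generate_patient(cfg, atlas, index = 1L)

  expect_equal(nrow(pat$truth), sum(spec$count)) # lesion count bookkeeping
  expect_setequal(names(pat$masks), c("FLAIR", "DIR", "MP2RAGE"))

  # masks are subsets of non-background atlas voxels
  for (m in pat$masks) {
    expect_true(all(atlas$labels[m] != 0L))
  }

  # non-overlap and non-adjacency: union components = number of lesions
  lab <- merge_lesion_masks(pat$masks)
  expect_equal(max(lab), nrow(pat$truth))

  # same seed -> identical patient
  pat2 <- generate_patient(cfg, atlas, index = 1L)
  expect_identical(pat2$maps, pat$maps)
  expect_identical(pat2$truth, pat$truth)

  # WM-restricted groups (2-4) stay entirely in WM tissue
  wm_labels <- atlas$table$label[atlas$table$tissue == "WM"]
  lesions <- filter_lesions(lab, 0L)
  for (l in lesions) {
    tr <- pat$truth[pat$truth$seed_voxel %in% l$voxels, ]
    if (tr$group %in% 2:4) {
      expect_true(all(atlas$labels[l$voxels] %in% wm_labels))
    }
  }
})

test_that("mask_fraction < 1 yields connected subsets covering >= the fraction", {
  cfg <- tiny_config(mask_fraction = 0.7,
                     lesion_spec = default_lesion_spec(
                       count_per_patient = 1L, voxel_range = c(20L, 20L)))
  atlas <- tiny_atlas(cfg)
  pat <- generate_patient(cfg, atlas, index = 3L)
  full <- 20L
  for (m in pat$masks) {
    per_lesion <- table(label_components(m * 1L)[m])
    expect_true(all(per_lesion >= ceiling(0.7 * full)))
    expect_true(all(per_lesion <= full))
  }
  # union of the three masks may still undercover the lesion, but every mask
  # voxel must belong to some generated lesion's bounding extent
  expect_equal(nrow(pat$truth), 4L)
})

test_that("effect-size fidelity: mean shift per reference SD matches the spec", {
  # one big lesion per group; empirical shift close to the configured effect
  spec <- default_lesion_spec(count_per_patient = 1L,
                              voxel_range = c(120L, 120L))
  cfg <- phantom_config(grid_shape = c(40L, 24L, 16L), n_hc = 2L,
                        n_patients = 1L, lesion_spec = spec, seed = 5L)
  atlas <- generate_atlas(cfg)
  pat <- generate_patient(cfg, atlas, index = 1L)
  lab <- merge_lesion_masks(pat$masks)
  lesions <- filter_lesions(lab, 10L)
  match <- vapply(lesions, function(l) {
    which(pat$truth$seed_voxel %in% l$voxels)
  }, integer(1L))
  cp <- cfg$contrast_params
  for (i in seq_along(lesions)) {
    tr <- pat$truth[match[i], ]
    vox <- lesions[[i]]$voxels
    row <- atlas$table[match(atlas$labels[vox], atlas$table$label), ]
    for (ct in qmri_contrasts()) {
      p <- cp[cp$contrast == ct, ]
      key <- match(paste(row$lobe, row$tissue), paste(p$lobe, p$tissue))
      shift <- (pat$maps[[ct]][vox] - p$mean[key]) / p$sd[key]
      eff <- tr[[paste0("eff_", ct)]]
      # SE of the mean shift is 1/sqrt(120) ~ 0.09
      expect_lt(abs(mean(shift) - eff), 3 / sqrt(120))
    }
  }
})

test_that("impossible placements raise a placement error", {
  spec <- default_lesion_spec(count_per_patient = 50L,
                              voxel_range = c(30L, 30L))
  cfg <- tiny_config(lesion_spec = spec)
  atlas <- tiny_atlas(cfg)
  expect_error(generate_patient(cfg, atlas, index = 1L),
               class = "qmri_placement_error")
})
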