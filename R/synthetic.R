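# Synthetic multicontrast phantom generator.
#
# Emulates the statistical structure the analysis assumes, not MR physics:
# healthy-control (HC) maps with per-(lobe, tissue) Gaussian contrast
# distributions, and patient maps with inserted connected lesions whose
# per-contrast means are shifted by a configured number of reference SDs
# (effect-direction patterns of the four pathology groups). Ground truth is
# recorded for every lesion so downstream recovery is testable.

#' Default per-compartment contrast distributions
#'
#' Typical 3 T values: T1/T2/T2* relaxation times in ms, MTR dimensionless.
#' Small deterministic lobe offsets make compartments distinguishable.
#'
#' @return Data frame with columns lobe, tissue, contrast, mean, sd.
#' @export
default_contrast_params <- function() {
  base <- data.frame(
    tissue = rep(c("WM", "GM"), times = 4L),
    contrast = rep(qmri_contrasts(), each = 2L),
    mean = c(850, 1400, 75, 90, 50, 60, 0.45, 0.35),
    sd = c(50, 80, 5, 8, 5, 6, 0.02, 0.02),
    stringsAsFactors = FALSE
  )
  lobe_scale <- c(frontal = 1.00, parietal = 1.01, occipital = 0.99,
                  temporal = 1.02, cerebellum = 0.97)
  out <- do.call(rbind, lapply(names(lobe_scale), function(lb) {
    d <- base
    d$lobe <- lb
    d$mean <- d$mean * lobe_scale[[lb]]
    d
  }))
  rownames(out) <- NULL
  out[c("lobe", "tissue", "contrast", "mean", "sd")]
}

#' Default lesion specification
#'
#' One row per (pathology group x patient) lesion batch. Effects are mean
#' shifts in units of the compartment reference SD; directions follow the four
#' group patterns (1: none; 2: T2/T2* up; 3: T1 up with/without T2/T2* up;
#' 4: T1 up and MTR down). Magnitude 4 SD for "significant" contrasts is a
#' design default (the source patterns state directions, not magnitudes).
#'
#' @param effect Absolute effect size in SD units for non-null contrasts.
#' @param count_per_patient Lesions per group per patient.
#' @param voxel_range Length-2 integer range of lesion sizes (voxels).
#' @return Data frame with columns group, count, min_vox, max_vox, tissue and
#'   eff_T1, eff_T2, eff_T2star, eff_MTR.
#' @export
default_lesion_spec <- function(effect = 4, count_per_patient = 2,
                                voxel_range = c(15L, 40L)) {
  data.frame(
    group = 1:4,
    count = count_per_patient,
    min_vox = voxel_range[1L],
    max_vox = voxel_range[2L],
    tissue = c("any", "WM", "WM", "WM"),
    eff_T1 = c(0, 0, effect, effect),
    eff_T2 = c(0, effect, effect, 0),
    eff_T2star = c(0, effect, 0, 0),
    eff_MTR = c(0, 0, 0, -effect),
    stringsAsFactors = FALSE
  )
}

#' Phantom configuration
#'
#' Bundles every knob of the synthetic cohort: grid geometry, cohort sizes,
#' per-compartment contrast distributions, lesion specification, the clinical
#' score model and the global seed (expanded into independent per-subject
#' streams by fixed offsets).
#'
#' @param grid_shape 3 positive integers, voxels per axis.
#' @param voxel_volume Voxel volume in mm^3.
#' @param n_hc,n_patients Cohort sizes (defaults mirror an 18 HC / 36 patient
#'   study design).
#' @param contrast_params See [default_contrast_params()].
#' @param lesion_spec See [default_lesion_spec()].
#' @param mask_fraction Fraction (0.6..1) of each lesion covered by each of
#'   the three per-contrast pseudo-masks; 1 means identical masks.
#' @param connectivity Lesion connectivity (6, 18 or 26).
#' @param score_model See [default_score_model()]; may be NULL when clinical
#'   scores are not needed.
#' @param seed Global integer seed.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(48L, 48L, 48L), voxel_volume = 1,
                           n_hc = 18L, n_patients = 36L,
                           contrast_params = default_contrast_params(),
                           lesion_spec = default_lesion_spec(),
                           mask_fraction = 1.0, connectivity = 26L,
                           score_model = NULL, seed = 42L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L)) {
    config_error("grid_shape must be 3 positive integers")
  }
  if (voxel_volume <= 0) config_error("voxel_volume must be > 0")
  if (n_hc < 0L || n_patients < 0L) config_error("cohort sizes must be >= 0")
  # SD 0 is allowed at generation (degenerate-noise phantoms); a zero-variance
  # compartment only becomes an error when reference statistics are computed.
  if (any(contrast_params$sd < 0)) {
    config_error("contrast SDs must be >= 0")
  }
  if (nrow(lesion_spec)) {
    if (!all(lesion_spec$group %in% 1:4)) {
      config_error("lesion_spec groups must be in {1,2,3,4}")
    }
    if (any(lesion_spec$min_vox < 1L)) {
      config_error("lesion voxel_count_range minimum must be >= 1")
    }
    if (any(lesion_spec$max_vox < lesion_spec$min_vox)) {
      config_error("lesion max_vox must be >= min_vox")
    }
  }
  if (mask_fraction < 0.6 || mask_fraction > 1) {
    config_error("mask_fraction must be in [0.6, 1]")
  }
  structure(
    list(grid_shape = grid_shape, voxel_volume = as.double(voxel_volume),
         n_hc = as.integer(n_hc), n_patients = as.integer(n_patients),
         contrast_params = contrast_params, lesion_spec = lesion_spec,
         mask_fraction = mask_fraction,
         connectivity = as.integer(connectivity),
         score_model = score_model, seed = as.integer(seed)),
    class = "phantom_config"
  )
}

#' Generate a block-layout lobar atlas
#'
#' Realism is not the goal, label coverage is: the interior of the grid (one
#' voxel of background border) is split into five slabs along x (frontal,
#' parietal, occipital, temporal, cerebellum), each split along z into WM
#' (lower half) and GM (upper half). Deterministic.
#'
#' @param config A [phantom_config()].
#' @return A [tissue_atlas()].
#' @export
generate_atlas <- function(config) {
  gs <- config$grid_shape
  lobes <- qmri_lobes()
  if (gs[1L] < length(lobes) + 2L || gs[2L] < 3L || gs[3L] < 4L) {
    config_error(sprintf(
      "grid %s too small to host %d lobes x 2 tissues with a background border",
      paste(gs, collapse = "x"), length(lobes)))
  }
  lab <- array(0L, gs)
  xs <- 2:(gs[1L] - 1L)
  ys <- 2:(gs[2L] - 1L)
  zs <- 2:(gs[3L] - 1L)
  slab <- split(xs, cut(seq_along(xs), length(lobes), labels = FALSE))
  zmid <- zs[ceiling(length(zs) / 2)]
  tab <- expand.grid(tissue = qmri_tissues(), lobe = lobes,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$label <- seq_len(nrow(tab))
  for (i in seq_along(lobes)) {
    wm <- tab$label[tab$lobe == lobes[i] & tab$tissue == "WM"]
    gm <- tab$label[tab$lobe == lobes[i] & tab$tissue == "GM"]
    lab[slab[[i]], ys, zs[zs <= zmid]] <- wm
    lab[slab[[i]], ys, zs[zs > zmid]] <- gm
  }
  tissue_atlas(lab, tab[c("label", "lobe", "tissue")],
               voxel_volume = config$voxel_volume)
}

# Per-label (mean, sd) vectors for one contrast; errors if a label present in
# the atlas has no configured parameters.
label_params <- function(config, atlas, contrast) {
  cp <- config$contrast_params[config$contrast_params$contrast == contrast, ]
  key <- paste(cp$lobe, cp$tissue)
  akey <- paste(atlas$table$lobe, atlas$table$tissue)
  hit <- match(akey, key)
  if (anyNA(hit)) {
    config_error(sprintf("missing contrast parameters for %s (%s)",
                         paste(akey[is.na(hit)], collapse = ", "), contrast))
  }
  list(mean = cp$mean[hit], sd = cp$sd[hit], label = atlas$table$label)
}

# One subject's 4 maps: Gaussian per-compartment values, background 0.
simulate_maps <- function(config, atlas) {
  labvec <- as.vector(atlas$labels)
  fg <- labvec != 0L
  lut <- atlas_lookup(atlas)
  row <- lut[labvec[fg]]
  maps <- lapply(qmri_contrasts(), function(ct) {
    p <- label_params(config, atlas, ct)
    m <- array(0, config$grid_shape)
    m[fg] <- stats::rnorm(sum(fg), mean = p$mean[row], sd = p$sd[row])
    m
  })
  names(maps) <- qmri_contrasts()
  maps
}

#' Generate the healthy-control cohort maps
#'
#' @param config A [phantom_config()].
#' @param atlas The atlas the maps are defined on.
#' @return List of `n_hc` subjects; each a named list of 4 contrast arrays.
#' @export
generate_hc_maps <- function(config, atlas) {
  lapply(seq_len(config$n_hc), function(i) {
    set.seed(subject_seed(config$seed, i, offset = 0L))
    simulate_maps(config, atlas)
  })
}

#' Generate one synthetic patient
#'
#' Starts from an HC-like subject, then inserts the configured lesions:
#' non-overlapping (and non-touching, so union components stay separate)
#' connected blobs grown best-first inside tissue compatible with their spec.
#' Within a lesion, each contrast's voxel values are redrawn from
#' N(local mean + effect x local SD, local SD). Three binary pseudo-contrast
#' masks are emitted (full lesion, or a random connected subset covering at
#' least `mask_fraction` of it).
#'
#' @param config A [phantom_config()].
#' @param atlas The atlas.
#' @param index Patient index (selects the RNG stream).
#' @return List with elements `maps` (4 contrast arrays), `masks` (3 binary
#'   arrays named FLAIR, DIR, MP2RAGE) and `truth` (data frame: one row per
#'   inserted lesion with group, size, seed voxel and the applied effects).
#' @export
generate_patient <- function(config, atlas, index = 1L) {
  set.seed(subject_seed(config$seed, index, offset = 500000L))
  maps <- simulate_maps(config, atlas)
  gs <- config$grid_shape
  spec <- config$lesion_spec
  lut <- atlas_lookup(atlas)
  params <- lapply(qmri_contrasts(), function(ct) label_params(config, atlas, ct))
  names(params) <- qmri_contrasts()

  blocked <- array(FALSE, gs) # lesions + 1-voxel margin
  masks <- replicate(3L, array(FALSE, gs), simplify = FALSE)
  names(masks) <- c("FLAIR", "DIR", "MP2RAGE")
  truth <- list()
  lesion_id <- 0L

  tissue_allowed <- function(tissue) {
    keep <- if (identical(tissue, "any")) {
      atlas$table$label
    } else {
      atlas$table$label[atlas$table$tissue == tissue]
    }
    array(atlas$labels %in% keep, gs)
  }

  for (r in seq_len(nrow(spec))) {
    base_allowed <- tissue_allowed(spec$tissue[r])
    for (k in seq_len(spec$count[r])) {
      # sample.int avoids sample()'s scalar expansion when min == max
      size <- spec$min_vox[r] +
        sample.int(spec$max_vox[r] - spec$min_vox[r] + 1L, 1L) - 1L
      allowed <- base_allowed & !blocked
      pool <- which(allowed)
      region <- NULL
      for (try in seq_len(100L)) {
        if (!length(pool)) break
        seedvox <- pool[sample.int(length(pool), 1L)]
        region <- grow_region(allowed, seedvox, size,
                              connectivity = config$connectivity)
        if (!is.null(region)) break
      }
      if (is.null(region)) {
        placement_error(sprintf(
          "could not place a %d-voxel group-%d lesion after bounded retries",
          size, spec$group[r]))
      }
      lesion_id <- lesion_id + 1L
      labrow <- lut[atlas$labels[region]]
      effects <- c(T1 = spec$eff_T1[r], T2 = spec$eff_T2[r],
                   T2star = spec$eff_T2star[r], MTR = spec$eff_MTR[r])
      for (ct in qmri_contrasts()) {
        p <- params[[ct]]
        maps[[ct]][region] <- stats::rnorm(
          length(region),
          mean = p$mean[labrow] + effects[[ct]] * p$sd[labrow],
          sd = p$sd[labrow])
      }
      for (m in names(masks)) {
        sub <- region
        if (config$mask_fraction < 1) {
          inles <- array(FALSE, gs)
          inles[region] <- TRUE
          target <- max(1L, ceiling(config$mask_fraction * length(region)))
          sub <- grow_region(inles, region[sample.int(length(region), 1L)],
                             target, connectivity = config$connectivity)
        }
        masks[[m]][sub] <- TRUE
      }
      blocked <- block_with_margin(blocked, region)
      truth[[lesion_id]] <- data.frame(
        lesion = lesion_id, group = spec$group[r], n_voxels = length(region),
        seed_voxel = region[1L], eff_T1 = effects[["T1"]],
        eff_T2 = effects[["T2"]], eff_T2star = effects[["T2star"]],
        eff_MTR = effects[["MTR"]])
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(lesion = integer(0), group = integer(0), n_voxels = integer(0),
               seed_voxel = integer(0), eff_T1 = double(0), eff_T2 = double(0),
               eff_T2star = double(0), eff_MTR = double(0))
  list(maps = maps, masks = masks, truth = truth)
}

#' Generate a full synthetic cohort
#'
#' Convenience wrapper: atlas + HC maps + patients.
#'
#' @param config A [phantom_config()].
#' @return List with `atlas`, `hc` (list of map sets) and `patients` (list of
#'   [generate_patient()] results).
#' @export
generate_cohort <- function(config) {
  atlas <- generate_atlas(config)
  list(atlas = atlas,
       hc = generate_hc_maps(config, atlas),
       patients = lapply(seq_len(config$n_patients), function(i) {
         generate_patient(config, atlas, index = i)
       }))
}

#' Match quantified lesions to generator ground truth
#'
#' Component labelling renumbers lesions, so quantified rows are matched back
#' to `truth` rows by locating each truth seed voxel inside the quantified
#' voxel sets.
#'
#' @param lesions [quantify_lesions()] output (needs the `"voxels"`
#'   attribute).
#' @param truth A `truth` data frame from [generate_patient()].
#' @return Integer vector over quantified lesions: matching `truth` row index
#'   (NA when a lesion contains no truth seed, e.g. after mask subsetting).
#' @export
match_lesions_to_truth <- function(lesions, truth) {
  voxsets <- attr(lesions, "voxels")
  vapply(seq_len(nrow(lesions)), function(i) {
    hit <- which(truth$seed_voxel %in% voxsets[[i]])
    if (length(hit) == 1L) hit else NA_integer_
  }, integer(1L))
}
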