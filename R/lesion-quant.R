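# Lesion quantification: union-merge of per-contrast masks, size filtering,
# localization/typing against the atlas, TIV normalization, and per-lesion
# z-scores (mean over lesion voxels of the standardized deviation from the
# healthy-control compartment statistics).

#' Merge per-contrast lesion masks into a labelled union volume
#'
#' Voxelwise logical union of the input masks followed by connected-component
#' labelling; each component is one candidate lesion.
#'
#' @param masks List of binary 3D arrays on a shared grid.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return 3D integer array of lesion labels (0 = background).
#' @export
merge_lesion_masks <- function(masks, connectivity = 26) {
  if (!length(masks)) input_error("no masks given")
  dims <- dim(masks[[1L]])
  if (is.null(dims) || length(dims) != 3L) {
    input_error("masks must be 3D arrays")
  }
  for (m in masks) {
    if (!identical(dim(m), dims)) input_error("mask grids do not match")
  }
  union <- Reduce(`|`, lapply(masks, function(m) m != 0))
  label_components(array(union, dims), connectivity = connectivity)
}

#' Filter lesions by size
#'
#' Keeps components with strictly more than `min_voxels` voxels.
#'
#' @param labeled 3D integer label volume from [merge_lesion_masks()].
#' @param min_voxels Size threshold; a component of exactly `min_voxels`
#'   voxels is excluded (default 10).
#' @return List of lesions, each a list with `id` (renumbered 1..n) and
#'   `voxels` (sorted linear indices into the grid).
#' @export
filter_lesions <- function(labeled, min_voxels = 10L) {
  fg <- which(labeled != 0L)
  if (!length(fg)) return(list())
  comp <- split(fg, labeled[fg])
  comp <- comp[lengths(comp) > min_voxels]
  comp <- comp[order(as.integer(names(comp)))]
  lapply(seq_along(comp), function(i) {
    list(id = i, voxels = sort(comp[[i]]))
  })
}

#' Localize and type a lesion against the atlas
#'
#' Tissue type: `cortical-II` if all non-background lesion voxels are GM,
#' `WM` if all are WM, `cortical-I` (mixed GM/WM) otherwise. Lobe: majority
#' lobe over non-background lesion voxels, ties broken deterministically by
#' the fixed lobe order of [qmri_lobes()]. Voxels on background atlas labels
#' carry no compartment and are reported via `background_fraction`.
#'
#' @param voxels Linear voxel indices of one lesion.
#' @param atlas A [tissue_atlas()].
#' @return List with `lobe`, `type`, `compartment` (data frame lobe/tissue
#'   per non-background voxel, with `voxel` index) and `background_fraction`.
#' @export
localize_and_type <- function(voxels, atlas) {
  labs <- atlas$labels[voxels]
  keep <- labs != 0L
  if (!any(keep)) {
    orphan_lesion_error("lesion lies entirely on background atlas labels")
  }
  lut <- atlas_lookup(atlas)
  row <- lut[labs[keep]]
  lobe_v <- atlas$table$lobe[row]
  tissue_v <- atlas$table$tissue[row]
  type <- if (all(tissue_v == "GM")) {
    "cortical-II"
  } else if (all(tissue_v == "WM")) {
    "WM"
  } else {
    "cortical-I"
  }
  counts <- table(factor(lobe_v, levels = qmri_lobes()))
  lobe <- names(counts)[which.max(counts)] # which.max: first max = fixed order
  list(lobe = lobe, type = type,
       compartment = data.frame(voxel = voxels[keep], lobe = lobe_v,
                                tissue = tissue_v, stringsAsFactors = FALSE),
       background_fraction = 1 - sum(keep) / length(voxels))
}

#' Normalize a lesion volume by total intracranial volume
#'
#' @param n_voxels Lesion voxel count.
#' @param voxel_volume Voxel volume in mm^3.
#' @param tiv Total intracranial volume in mm^3; must be > 0.
#' @return Dimensionless normalized volume `n_voxels * voxel_volume / tiv`.
#' @export
normalize_volume <- function(n_voxels, voxel_volume, tiv) {
  if (!is.numeric(tiv) || any(tiv <= 0)) input_error("tiv must be > 0")
  n_voxels * voxel_volume / tiv
}

#' Per-lesion z-score for one contrast
#'
#' Mean over lesion voxels of the standardized residual against the
#' healthy-control reference of the voxel's own (lobe, tissue) compartment:
#' z = (1/N) * sum_v (I(v) - mu(L_v, T_v)) / sigma(L_v, T_v). For a lesion
#' confined to one compartment this reduces to
#' (mean lesion intensity - mu) / sigma. `compartment = "majority"` instead
#' standardizes every voxel by the lesion's majority compartment (the strict
#' per-lesion reading). Voxels on background atlas labels are excluded.
#'
#' @param map 3D contrast array.
#' @param voxels Linear voxel indices of the lesion.
#' @param contrast Contrast id (one of [qmri_contrasts()]).
#' @param ref A `reference_stats` data frame.
#' @param atlas A [tissue_atlas()].
#' @param compartment `"voxel"` (default) or `"majority"`.
#' @return Dimensionless z-score.
#' @export
lesion_zscore <- function(map, voxels, contrast, ref, atlas,
                          compartment = c("voxel", "majority")) {
  compartment <- match.arg(compartment)
  loc <- localize_and_type(voxels, atlas)
  comp <- loc$compartment
  if (compartment == "majority") {
    maj <- names(sort(table(paste(comp$lobe, comp$tissue, sep = "|")),
                      decreasing = TRUE))[1L]
    parts <- strsplit(maj, "|", fixed = TRUE)[[1L]]
    comp$lobe <- parts[1L]
    comp$tissue <- parts[2L]
  }
  lk <- reference_lookup(ref)
  key <- paste(comp$lobe, comp$tissue, contrast, sep = "|")
  if (anyNA(match(key, names(lk$mu)))) {
    missing_compartment_error(sprintf(
      "no reference entry for %s", paste(unique(key[!key %in% names(lk$mu)]),
                                         collapse = ", ")))
  }
  vals <- map[comp$voxel]
  mean((vals - lk$mu[key]) / lk$sigma[key])
}

#' Quantify all lesions of one subject
#'
#' Full per-subject lesion stage: union-merge the masks, label components,
#' apply the size filter (> `min_voxels`), localize and type each lesion,
#' drop lesions with more than half their voxels on background atlas labels,
#' normalize volumes by TIV and compute the four contrast z-scores.
#'
#' @param maps Named list of contrast arrays (names [qmri_contrasts()]).
#' @param masks List of binary lesion masks (e.g. FLAIR/DIR/MP2RAGE derived).
#' @param atlas A [tissue_atlas()].
#' @param ref A `reference_stats` data frame.
#' @param min_voxels Size filter threshold (default 10, strict).
#' @param connectivity Component connectivity (default 26).
#' @param tiv Total intracranial volume in mm^3; defaults to [atlas_tiv()].
#' @param compartment z-score compartment mode, see [lesion_zscore()].
#' @return Data frame with one row per retained lesion: id, lobe, type,
#'   n_voxels, volume_mm3, norm_volume, z_T1, z_T2, z_T2star, z_MTR. The
#'   voxel index sets are attached as attribute `"voxels"`.
#' @export
quantify_lesions <- function(maps, masks, atlas, ref, min_voxels = 10L,
                             connectivity = 26L, tiv = atlas_tiv(atlas),
                             compartment = "voxel") {
  if (!all(qmri_contrasts() %in% names(maps))) {
    input_error("maps must cover all four contrasts")
  }
  labeled <- merge_lesion_masks(masks, connectivity = connectivity)
  lesions <- filter_lesions(labeled, min_voxels = min_voxels)
  rows <- list()
  voxsets <- list()
  kept <- 0L
  for (les in lesions) {
    loc <- localize_and_type(les$voxels, atlas)
    if (loc$background_fraction > 0.5) next
    kept <- kept + 1L
    n <- length(les$voxels)
    z <- vapply(qmri_contrasts(), function(ct) {
      lesion_zscore(maps[[ct]], les$voxels, ct, ref, atlas,
                    compartment = compartment)
    }, double(1L))
    rows[[kept]] <- data.frame(
      id = kept, lobe = loc$lobe, type = loc$type, n_voxels = n,
      volume_mm3 = n * atlas$voxel_volume,
      norm_volume = normalize_volume(n, atlas$voxel_volume, tiv),
      z_T1 = z[["T1"]], z_T2 = z[["T2"]], z_T2star = z[["T2star"]],
      z_MTR = z[["MTR"]], stringsAsFactors = FALSE)
    voxsets[[kept]] <- les$voxels
  }
  out <- if (kept) do.call(rbind, rows) else
    data.frame(id = integer(0), lobe = character(0), type = character(0),
               n_voxels = integer(0), volume_mm3 = double(0),
               norm_volume = double(0), z_T1 = double(0), z_T2 = double(0),
               z_T2star = double(0), z_MTR = double(0))
  attr(out, "voxels") <- voxsets
  out
}
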