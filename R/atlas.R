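# Lobar tissue atlas: integer label volume + label table mapping each label
# to one (lobe, tissue) compartment. Label 0 is background.

#' Construct a tissue atlas
#'
#' @param labels 3D integer array of label ids (0 = background).
#' @param table Data frame with columns `label`, `lobe`, `tissue`; one row per
#'   non-background label, no duplicated (lobe, tissue) pair.
#' @param voxel_volume Voxel volume in mm^3.
#' @return An object of class `tissue_atlas`.
#' @export
tissue_atlas <- function(labels, table, voxel_volume = 1) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    input_error("atlas labels must be a 3D array")
  }
  needed <- c("label", "lobe", "tissue")
  if (!all(needed %in% names(table))) {
    input_error("atlas table needs columns label, lobe, tissue")
  }
  if (anyDuplicated(table$label)) input_error("duplicate atlas label ids")
  if (anyDuplicated(table[c("lobe", "tissue")])) {
    input_error("duplicate (lobe, tissue) pair in atlas table")
  }
  bad <- setdiff(unique(as.vector(labels)), c(0L, table$label))
  if (length(bad)) {
    input_error(sprintf("label volume contains ids missing from table: %s",
                        paste(bad, collapse = ", ")))
  }
  if (!is.numeric(voxel_volume) || voxel_volume <= 0) {
    input_error("voxel_volume must be positive")
  }
  structure(
    list(labels = labels,
         table = data.frame(label = as.integer(table$label),
                            lobe = as.character(table$lobe),
                            tissue = as.character(table$tissue),
                            stringsAsFactors = FALSE),
         voxel_volume = as.double(voxel_volume)),
    class = "tissue_atlas"
  )
}

#' @export
print.tissue_atlas <- function(x, ...) {
  cat(sprintf("<tissue_atlas> %s voxels (%s), %d labels, voxel %.3g mm^3\n",
              paste(dim(x$labels), collapse = "x"),
              format(sum(x$labels != 0L), big.mark = ","),
              nrow(x$table), x$voxel_volume))
  invisible(x)
}

# (lobe, tissue) for each label id, as a data.frame row lookup vector.
atlas_lookup <- function(atlas) {
  idx <- integer(max(atlas$table$label))
  idx[atlas$table$label] <- seq_len(nrow(atlas$table))
  idx
}

#' Total intracranial volume of an atlas
#'
#' Number of non-background voxels times the voxel volume.
#'
#' @param atlas A `tissue_atlas`.
#' @return TIV in mm^3.
#' @export
atlas_tiv <- function(atlas) {
  sum(atlas$labels != 0L) * atlas$voxel_volume
}

#' Write / read an atlas as NIfTI + label-table TSV
#'
#' The label volume goes to `<path>.nii` and the label table to
#' `<path>_labels.tsv`.
#'
#' @param atlas A `tissue_atlas`.
#' @param path Path stem (no extension).
#' @return `write_atlas`: the path stem, invisibly. `read_atlas`: a
#'   `tissue_atlas`.
#' @export
write_atlas <- function(atlas, path) {
  side <- atlas$voxel_volume^(1 / 3)
  write_nifti(atlas$labels, paste0(path, ".nii"), pixdim = rep(side, 3L),
              datatype = "int32")
  utils::write.table(atlas$table, paste0(path, "_labels.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  vol <- read_nifti(paste0(path, ".nii"))
  tab <- utils::read.delim(paste0(path, "_labels.tsv"),
                           stringsAsFactors = FALSE)
  vv <- attr(vol, "voxel_volume")
  storage.mode(vol) <- "integer"
  attributes(vol) <- list(dim = dim(vol))
  tissue_atlas(vol, tab, voxel_volume = vv)
}
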