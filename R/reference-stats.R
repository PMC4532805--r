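# Healthy-control reference statistics: mean and SD of each contrast within
# each (lobe, tissue) compartment, i.e. the mu and sigma that standardize
# lesion values into z-scores.

#' Compute healthy-control reference statistics
#'
#' For every (lobe, tissue) compartment present in the atlas and every
#' contrast, the compartment mean and SD over the HC cohort. By default
#' voxels are pooled across subjects into one sample per compartment
#' (`pooling = "voxel"`); `pooling = "subject"` instead computes per-subject
#' compartment means and SDs and averages them across subjects. SD uses the
#' n - 1 denominator throughout; background voxels never contribute.
#'
#' @param hc_cohort List of HC subjects; each a named list of contrast arrays
#'   (names from [qmri_contrasts()]), co-registered to the atlas grid.
#' @param atlas A [tissue_atlas()].
#' @param pooling `"voxel"` (default) or `"subject"`.
#' @return Object of class `reference_stats`: a data frame with columns
#'   lobe, tissue, contrast, mu, sigma, n_voxels.
#' @export
compute_reference_stats <- function(hc_cohort, atlas,
                                    pooling = c("voxel", "subject")) {
  pooling <- match.arg(pooling)
  if (length(hc_cohort) < 2L) {
    input_error("need at least 2 HC subjects for reference statistics")
  }
  for (s in hc_cohort) {
    if (!all(qmri_contrasts() %in% names(s))) {
      input_error("every HC subject needs maps for all four contrasts")
    }
    if (!all(vapply(s, function(m) identical(dim(m), dim(atlas$labels)),
                    logical(1L)))) {
      input_error("HC map grid does not match the atlas grid")
    }
  }
  labvec <- as.vector(atlas$labels)
  rows <- list()
  for (i in seq_len(nrow(atlas$table))) {
    sel <- labvec == atlas$table$label[i]
    if (!any(sel)) {
      missing_compartment_error(sprintf(
        "compartment (%s, %s) has zero voxels in the atlas",
        atlas$table$lobe[i], atlas$table$tissue[i]))
    }
    for (ct in qmri_contrasts()) {
      per_subj <- lapply(hc_cohort, function(s) as.vector(s[[ct]])[sel])
      if (pooling == "voxel") {
        pooled <- unlist(per_subj, use.names = FALSE)
        mu <- mean(pooled)
        sigma <- stats::sd(pooled)
        n <- length(pooled)
      } else {
        mu <- mean(vapply(per_subj, mean, double(1L)))
        sigma <- mean(vapply(per_subj, stats::sd, double(1L)))
        n <- sum(lengths(per_subj))
      }
      if (!is.finite(sigma) || sigma <= 0) {
        degenerate_reference_error(sprintf(
          "compartment (%s, %s) has zero %s variance; cannot normalize",
          atlas$table$lobe[i], atlas$table$tissue[i], ct))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        lobe = atlas$table$lobe[i], tissue = atlas$table$tissue[i],
        contrast = ct, mu = mu, sigma = sigma, n_voxels = n)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("reference_stats", "data.frame")
  out
}

# Fast (mu, sigma) lookup: named vectors keyed by "lobe|tissue|contrast".
reference_lookup <- function(ref) {
  key <- paste(ref$lobe, ref$tissue, ref$contrast, sep = "|")
  list(mu = stats::setNames(ref$mu, key),
       sigma = stats::setNames(ref$sigma, key))
}

#' Write / read reference statistics as TSV
#'
#' @param ref A `reference_stats` data frame.
#' @param path Output file.
#' @return `write_reference_stats`: `path` invisibly; `read_reference_stats`:
#'   a `reference_stats` data frame.
#' @export
write_reference_stats <- function(ref, path) {
  utils::write.table(ref, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_reference_stats
#' @export
read_reference_stats <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("reference_stats", "data.frame")
  out
}
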