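# Shared constants and classed error conditions.

#' Contrast identifiers used throughout the package
#'
#' The four quantitative/semi-quantitative contrasts: T1, T2 and T2*
#' relaxation times (ms) and the magnetization transfer ratio (dimensionless).
#' `"T2star"` is the programmatic spelling of T2*.
#'
#' @return Character vector of contrast ids, in canonical order.
#' @export
qmri_contrasts <- function() c("T1", "T2", "T2star", "MTR")

#' Lobe and tissue vocabularies
#'
#' Lobes follow the lobar parcellation used for reference statistics;
#' `cerebellum` is its own lobe with separate WM/GM compartments.
#'
#' @return Character vector of lobe (resp. tissue) labels.
#' @export
qmri_lobes <- function() {
  c("frontal", "parietal", "occipital", "temporal", "cerebellum")
}

#' @rdname qmri_lobes
#' @export
qmri_tissues <- function() c("WM", "GM")

# Tri-state z-score states, in the fixed sort order used for table layout.
qmri_states <- function() c("LOW", "NORMAL", "HIGH")

# Classed conditions so callers/tests can distinguish failure modes.
qmri_stop <- function(subclass, msg, call. = sys.call(-1)) {
  stop(structure(
    class = c(subclass, "qmri_error", "error", "condition"),
    list(message = msg, call = call.)
  ))
}

config_error <- function(msg) qmri_stop("qmri_config_error", msg)
input_error <- function(msg) qmri_stop("qmri_input_error", msg)
placement_error <- function(msg) qmri_stop("qmri_placement_error", msg)
missing_compartment_error <- function(msg) {
  qmri_stop("qmri_missing_compartment_error", msg)
}
degenerate_reference_error <- function(msg) {
  qmri_stop("qmri_degenerate_reference_error", msg)
}
orphan_lesion_error <- function(msg) qmri_stop("qmri_orphan_lesion_error", msg)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive an independent per-subject RNG seed from one global seed.
# Offsets keep HC and patient streams disjoint; result stays < 2^31.
subject_seed <- function(seed, index, offset = 0L) {
  (as.integer(seed) + 1009L * as.integer(index) + as.integer(offset)) %% 2147483629L
}
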