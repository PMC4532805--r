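# Tri-state signatures and pathology-group assignment.
#
# Each lesion's four z-scores are discretized into LOW (z < -2), NORMAL
# (-2 <= z <= 2, closed interval) and HIGH (z > 2), giving 3^4 = 81 possible
# combination signatures. Signatures map onto four pathology groups:
#   Group 1 - no significant change in any contrast;
#   Group 2 - isolated T2 and/or T2* increase (prevalent inflammatory edema);
#   Group 3 - T1 increase with or without T2/T2* increase (microdegeneration
#             with/without inflammation);
#   Group 4 - T1 increase plus MTR decrease, with or without T2/T2* increase
#             (prevalent tissue loss);
# every other signature (any T1/T2/T2* decrease, MTR increase, ...) -> OTHER.

# A signature is encoded as a 4-character key over {L, N, H} in the fixed
# contrast order T1, T2, T2*, MTR, e.g. "HNNL".

state_letter <- c(LOW = "L", NORMAL = "N", HIGH = "H")

#' Discretize z-scores into a tri-state signature
#'
#' HIGH iff z > threshold, LOW iff z < -threshold, NORMAL otherwise
#' (boundary values exactly at the threshold are NORMAL: the reference
#' interval is closed). The default threshold 2 captures more than 95% of a
#' standard normal distribution.
#'
#' @param z Numeric vector of 4 z-scores in contrast order (T1, T2, T2*,
#'   MTR), or a matrix / data frame with one such row per lesion.
#' @param threshold Positive threshold (default 2).
#' @return Character vector of 4-letter signature keys over `{L, N, H}`.
#' @export
zscore_signature <- function(z, threshold = 2) {
  if (is.data.frame(z)) z <- as.matrix(z)
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  if (ncol(z) != 4L) input_error("need 4 z-scores per lesion")
  if (any(!is.finite(z))) input_error("z-scores must be finite")
  letters <- matrix("N", nrow(z), 4L)
  letters[z > threshold] <- "H"
  letters[z < -threshold] <- "L"
  apply(letters, 1L, paste, collapse = "")
}

#' Expand a signature key into named states
#'
#' @param key 4-letter signature key(s).
#' @return Character matrix (rows = keys) with columns T1, T2, T2star, MTR
#'   and values in LOW/NORMAL/HIGH.
#' @export
signature_states <- function(key) {
  if (any(nchar(key) != 4L) ||
      any(!strsplit(paste(key, collapse = ""), "")[[1L]] %in% c("L", "N", "H"))) {
    input_error("signature keys must be 4 characters over {L, N, H}")
  }
  m <- do.call(rbind, strsplit(key, ""))
  m[] <- names(state_letter)[match(m, state_letter)]
  colnames(m) <- qmri_contrasts()
  rownames(m) <- key
  m
}

#' All 81 tri-state signatures
#'
#' @return Character vector of the 81 signature keys in lexicographic order
#'   (L < N < H per contrast, T1 varying slowest).
#' @export
all_signatures <- function() {
  g <- expand.grid(MTR = c("L", "N", "H"), T2star = c("L", "N", "H"),
                   T2 = c("L", "N", "H"), T1 = c("L", "N", "H"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  paste0(g$T1, g$T2, g$T2star, g$MTR)
}

#' Assign a pathology group to a signature
#'
#' Rules applied in order: Group 4 (T1 HIGH, MTR LOW, T2/T2* NORMAL or HIGH),
#' Group 3 (T1 HIGH, MTR NORMAL, T2/T2* NORMAL or HIGH), Group 2 (T1 NORMAL,
#' MTR NORMAL, T2/T2* NORMAL or HIGH with at least one HIGH), Group 1 (all
#' NORMAL); anything else is OTHER. The five labels partition all 81
#' signatures.
#'
#' @param key Signature key(s), see [zscore_signature()].
#' @return Character vector over `{"1", "2", "3", "4", "OTHER"}`.
#' @export
assign_group <- function(key) {
  s <- signature_states(key)
  t1 <- s[, "T1"]
  t2 <- s[, "T2"]
  t2s <- s[, "T2star"]
  mtr <- s[, "MTR"]
  no_low_t2 <- t2 != "LOW" & t2s != "LOW"
  out <- rep("OTHER", length(key))
  out[t1 == "HIGH" & mtr == "LOW" & no_low_t2] <- "4"
  out[t1 == "HIGH" & mtr == "NORMAL" & no_low_t2] <- "3"
  out[t1 == "NORMAL" & mtr == "NORMAL" & no_low_t2 &
        (t2 == "HIGH" | t2s == "HIGH")] <- "2"
  out[t1 == "NORMAL" & t2 == "NORMAL" & t2s == "NORMAL" & mtr == "NORMAL"] <- "1"
  unname(out)
}

# Deterministic signature ordering: group ascending (1,2,3,4,OTHER), then
# lexicographic on states T1,T2,T2*,MTR with LOW < NORMAL < HIGH.
signature_order <- function(key) {
  grp <- match(assign_group(key), c("1", "2", "3", "4", "OTHER"))
  rank <- chartr("LNH", "abc", key)
  order(grp, rank)
}

#' Mean lesion volume of a combination row
#'
#' @param total_norm_volume Total TIV-normalized lesion volume in the row.
#' @param count Number of lesions in the row; must be >= 1.
#' @return MLV = total normalized volume / count (dimensionless).
#' @export
mlv <- function(total_norm_volume, count) {
  if (any(count < 1L)) input_error("MLV is undefined for count < 1")
  total_norm_volume / count
}

# Map (lobe, type) to the six layout columns of the combination table.
layout_column <- function(lobe, type) {
  region <- ifelse(lobe == "cerebellum", "cereb", "brain")
  col <- ifelse(type == "WM", "wm",
                ifelse(type == "cortical-I", "cort1", "cort2"))
  paste(region, col, sep = "_")
}

layout_columns <- function() {
  c("brain_wm", "brain_cort1", "brain_cort2",
    "cereb_wm", "cereb_cort1", "cereb_cort2")
}

#' Enumerate observed z-score combinations
#'
#' One row per observed signature with lesion counts cross-tabulated by
#' region and tissue type (brain/cerebellum x WM / cortical-I / cortical-II),
#' total normalized lesion volume and MLV. Row order is deterministic: group
#' ascending, then a fixed lexicographic order on the states. A display
#' ordinal `combination` (1..n) is attached.
#'
#' @param lesions Data frame with columns `signature`, `lobe`, `type`,
#'   `norm_volume` (e.g. [quantify_lesions()] output plus a `signature`
#'   column from [zscore_signature()]).
#' @return Data frame of class `combination_table`.
#' @export
enumerate_combinations <- function(lesions) {
  need <- c("signature", "lobe", "type", "norm_volume")
  if (!all(need %in% names(lesions))) {
    input_error(sprintf("lesions must have columns %s",
                        paste(need, collapse = ", ")))
  }
  keys <- unique(lesions$signature)
  keys <- keys[signature_order(keys)]
  cols <- layout_columns()
  rows <- lapply(keys, function(k) {
    sub <- lesions[lesions$signature == k, , drop = FALSE]
    cnt <- table(factor(layout_column(sub$lobe, sub$type), levels = cols))
    out <- data.frame(signature = k, group = assign_group(k),
                      count = nrow(sub), stringsAsFactors = FALSE)
    out[cols] <- as.integer(cnt)
    out$total_norm_volume <- sum(sub$norm_volume)
    out$mlv <- mlv(out$total_norm_volume, out$count)
    out
  })
  out <- do.call(rbind, rows)
  out <- cbind(combination = seq_len(nrow(out)), out)
  class(out) <- c("combination_table", "data.frame")
  out
}

#' Per-subject MLV predictor matrix
#'
#' One column per signature observed anywhere in the cohort (pooled table
#' order), one row per subject; entries are the subject's MLV for that
#' combination, 0 when the subject has no such lesion.
#'
#' @param lesions Data frame as for [enumerate_combinations()], plus a
#'   `subject` column.
#' @return Data frame: `subject` plus `MLV_<signature>` columns.
#' @export
mlv_predictor_matrix <- function(lesions) {
  if (!"subject" %in% names(lesions)) {
    input_error("lesions must have a subject column")
  }
  pooled <- enumerate_combinations(lesions)
  subjects <- unique(lesions$subject)
  out <- data.frame(subject = subjects)
  for (k in pooled$signature) {
    v <- vapply(subjects, function(s) {
      sub <- lesions[lesions$subject == s & lesions$signature == k, ,
                     drop = FALSE]
      if (nrow(sub)) mlv(sum(sub$norm_volume), nrow(sub)) else 0
    }, double(1L))
    out[[paste0("MLV_", k)]] <- v
  }
  out
}

#' Summarize a combination table in the printed-table layout
#'
#' Given per-combination counts over the six region/type columns, computes
#' the column totals and percentage row, the cortical and pure-WM fractions,
#' and each combination's share of all lesions with its cortical/WM split.
#' Cortical lesions are cortical-I + cortical-II in brain and cerebellum;
#' pure-WM lesions are the brain and cerebellar WM columns.
#'
#' @param counts Data frame with the six [layout_columns()] count columns
#'   (extra columns are ignored), one row per combination.
#' @return List with `total`, `column_totals`, `column_percent`,
#'   `cortical_fraction`, `wm_fraction` and `rows` (per-combination share,
#'   cortical_share, wm_share).
#' @export
combination_summary <- function(counts) {
  cols <- layout_columns()
  if (!all(cols %in% names(counts))) {
    input_error(sprintf("counts must have columns %s",
                        paste(cols, collapse = ", ")))
  }
  m <- as.matrix(counts[cols])
  col_tot <- colSums(m)
  total <- sum(col_tot)
  if (total == 0) input_error("empty combination table")
  cortical_cols <- c("brain_cort1", "brain_cort2", "cereb_cort1", "cereb_cort2")
  wm_cols <- c("brain_wm", "cereb_wm")
  row_tot <- rowSums(m)
  row_cort <- rowSums(m[, cortical_cols, drop = FALSE])
  row_wm <- rowSums(m[, wm_cols, drop = FALSE])
  list(
    total = total,
    column_totals = col_tot,
    column_percent = 100 * col_tot / total,
    cortical_fraction = sum(col_tot[cortical_cols]) / total,
    wm_fraction = sum(col_tot[wm_cols]) / total,
    rows = data.frame(
      share = row_tot / total,
      cortical_share = ifelse(row_tot > 0, row_cort / row_tot, NA_real_),
      wm_share = ifelse(row_tot > 0, row_wm / row_tot, NA_real_))
  )
}
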