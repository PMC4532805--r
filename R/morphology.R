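# Small 3D binary morphology toolkit: neighbourhood offsets, connected
# component labelling and best-first region growing. Written against plain
# arrays; grids here are small (phantoms, lesion masks), so vectorized BFS in
# R is fast enough and avoids an image-processing dependency.

#' Neighbourhood offsets for 3D connectivity
#'
#' @param connectivity 6, 18 or 26.
#' @return Integer matrix (k x 3) of voxel offsets, excluding the origin.
#' @export
neighbor_offsets <- function(connectivity = 26) {
  if (!connectivity %in% c(6L, 18L, 26L)) {
    input_error("connectivity must be 6, 18 or 26")
  }
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
  keep <- switch(as.character(connectivity),
    `6` = rowSums(abs(g)) == 1L,
    `18` = rowSums(abs(g)) <= 2L,
    `26` = rep(TRUE, nrow(g))
  )
  storage.mode(g) <- "integer"
  unname(g[keep, , drop = FALSE])
}

# Linear indices of in-bounds neighbours of coordinate rows `coords` (n x 3).
neighbor_indices <- function(coords, offs, dims) {
  n <- nrow(coords)
  k <- nrow(offs)
  cand <- coords[rep(seq_len(n), each = k), , drop = FALSE] +
    offs[rep.int(seq_len(k), n), , drop = FALSE]
  ok <- cand[, 1L] >= 1L & cand[, 1L] <= dims[1L] &
    cand[, 2L] >= 1L & cand[, 2L] <= dims[2L] &
    cand[, 3L] >= 1L & cand[, 3L] <= dims[3L]
  cand <- cand[ok, , drop = FALSE]
  cand[, 1L] + (cand[, 2L] - 1L) * dims[1L] +
    (cand[, 3L] - 1L) * dims[1L] * dims[2L]
}

#' Label connected components of a 3D binary mask
#'
#' Breadth-first flood fill under the given connectivity. Components are
#' numbered 1..n in order of their first voxel in array (column-major) order,
#' which makes labelling deterministic.
#'
#' @param mask 3D array; non-zero voxels are foreground.
#' @param connectivity 6, 18 or 26 (default 26, the common volumetric choice).
#' @return 3D integer array of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 26) {
  if (!is.array(mask) || length(dim(mask)) != 3L) {
    input_error("mask must be a 3D array")
  }
  dims <- dim(mask)
  offs <- neighbor_offsets(connectivity)
  lab <- array(0L, dims)
  fg <- which(mask != 0)
  if (!length(fg)) return(lab)
  inmask <- array(FALSE, dims)
  inmask[fg] <- TRUE
  cur <- 0L
  for (s in fg) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    frontier <- arrayInd(s, dims)
    while (nrow(frontier)) {
      li <- neighbor_indices(frontier, offs, dims)
      li <- unique(li[inmask[li] & lab[li] == 0L])
      if (!length(li)) break
      lab[li] <- cur
      frontier <- arrayInd(li, dims)
    }
  }
  lab
}

# Grow a connected region of `target` voxels from `seed` (linear index),
# restricted to `allowed` (logical array), adding candidates in order of
# Euclidean distance from the seed => compact quasi-spherical blobs.
# Returns linear indices, or NULL if the region cannot reach `target`.
grow_region <- function(allowed, seed, target, connectivity = 26) {
  dims <- dim(allowed)
  offs <- neighbor_offsets(connectivity)
  if (!allowed[seed]) return(NULL)
  state <- array(0L, dims) # 0 unseen, 1 queued, 2 accepted
  state[seed] <- 1L
  seed_c <- arrayInd(seed, dims)
  cand_idx <- seed
  cand_d <- 0
  region <- integer(0)
  while (length(region) < target && length(cand_idx)) {
    i <- which.min(cand_d)
    v <- cand_idx[i]
    cand_idx <- cand_idx[-i]
    cand_d <- cand_d[-i]
    region <- c(region, v)
    state[v] <- 2L
    li <- neighbor_indices(arrayInd(v, dims), offs, dims)
    li <- unique(li[allowed[li] & state[li] == 0L])
    if (length(li)) {
      state[li] <- 1L
      cc <- arrayInd(li, dims)
      d <- sqrt((cc[, 1L] - seed_c[1L])^2 + (cc[, 2L] - seed_c[2L])^2 +
                  (cc[, 3L] - seed_c[3L])^2)
      cand_idx <- c(cand_idx, li)
      cand_d <- c(cand_d, d)
    }
  }
  if (length(region) < target) NULL else region
}

# Mark `idx` voxels and their 26-neighbourhood TRUE in `blocked`.
block_with_margin <- function(blocked, idx) {
  dims <- dim(blocked)
  offs <- neighbor_offsets(26L)
  blocked[idx] <- TRUE
  li <- neighbor_indices(arrayInd(idx, dims), offs, dims)
  blocked[li] <- TRUE
  blocked
}
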