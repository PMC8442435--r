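#' Render a nucleus as a 3-channel 3D intensity stack
#'
#' Renders each spot of one nucleus as an anisotropy-aware Gaussian blob at
#' its physical position, on a voxel grid covering the nucleus.  The
#' Gaussian sigma is chosen so the half-width at half maximum equals the
#' spot radius, making the rendered blob consistent with what
#' [detectSpots()] measures at its default threshold.  Channel order is
#' class I, class II, class III.
#'
#' @param pop a \linkS4class{FishPopulation}.
#' @param nucleusId nucleus to render (default: the first).
#' @param voxelSize voxel pitch (x, y, z) in \eqn{\mu m}.
#' @param margin extra space around the nucleus (\eqn{\mu m}).
#' @param gaussianNoiseSd additive Gaussian noise (fraction of peak).
#' @param poissonScale if > 0, intensities are Poisson-resampled with this
#'   expected peak count (photon-like noise).
#' @return a 4D array [x, y, z, channel] with attributes
#'   \code{"voxelSize"} and \code{"origin"} (physical position of the
#'   corner of voxel (0,0,0)).
#' @export
renderImage <- function(pop, nucleusId = NULL,
                        voxelSize = c(0.079, 0.079, 0.244),
                        margin = NULL, gaussianNoiseSd = 0,
                        poissonScale = 0) {
  nuc <- pop@nuclei
  if (is.null(nucleusId)) nucleusId <- nuc$nucleus_id[1]
  row <- nuc[nuc$nucleus_id == nucleusId, ]
  if (!nrow(row)) stop("unknown nucleus id: ", nucleusId)
  sp <- pop@spots[pop@spots$nucleus_id == nucleusId, ]
  R <- row$nucleus_radius_um
  if (is.null(margin))
    margin <- if (nrow(sp)) 3 * max(sp$spot_radius_um) else 0.5
  ctr <- c(row$nucleus_cx, row$nucleus_cy, row$nucleus_cz)
  half <- R + margin
  origin <- ctr - half
  dims <- pmax(ceiling(2 * half / voxelSize), 4L)
  if (nrow(sp)) {
    pos <- as.matrix(sp[, c("x_um", "y_um", "z_um")])
    rel <- sweep(pos, 2, origin)
    if (any(rel < 0) || any(sweep(rel, 2, dims * voxelSize) > 0))
      stop("rendered volume too small: a spot lies outside the stack")
  }
  stack <- array(0, dim = c(dims, 3L))
  ax <- lapply(1:3, function(k) ((seq_len(dims[k]) - 1) + 0.5) * voxelSize[k])
  for (s in seq_len(nrow(sp))) {
    chk <- match(sp$channel[s], CHANNELS)
    p <- c(sp$x_um[s], sp$y_um[s], sp$z_um[s]) - origin
    sigma <- sp$spot_radius_um[s] / sqrt(2 * log(2))
    win <- lapply(1:3, function(k) {
      which(abs(ax[[k]] - p[k]) <= 4 * sigma)
    })
    if (any(lengths(win) == 0)) next
    gx <- exp(-(ax[[1]][win[[1]]] - p[1])^2 / (2 * sigma^2))
    gy <- exp(-(ax[[2]][win[[2]]] - p[2])^2 / (2 * sigma^2))
    gz <- exp(-(ax[[3]][win[[3]]] - p[3])^2 / (2 * sigma^2))
    blob <- outer(outer(gx, gy), gz)
    stack[win[[1]], win[[2]], win[[3]], chk] <-
      stack[win[[1]], win[[2]], win[[3]], chk] + blob
  }
  if (poissonScale > 0)
    stack[] <- stats::rpois(length(stack), stack * poissonScale) / poissonScale
  if (gaussianNoiseSd > 0)
    stack[] <- pmax(stack + stats::rnorm(length(stack), 0, gaussianNoiseSd), 0)
  attr(stack, "voxelSize") <- voxelSize
  attr(stack, "origin") <- origin
  stack
}

#' Detect spots in a 3-channel 3D stack
#'
#' Per channel: threshold, label 26-connected components, and report the
#' intensity-weighted centroid (converted to \eqn{\mu m} with the
#' voxel-center convention) and an equivalent-sphere radius from the
#' component volume.  A channel with no voxel above threshold yields no
#' spots for that channel (with a warning).
#'
#' @param stack 4D array [x, y, z, channel] (or 3D for one channel), e.g.
#'   from [renderImage()].
#' @param voxelSize voxel pitch in \eqn{\mu m}; defaults to the stack
#'   attribute.
#' @param threshold absolute intensity threshold; default half the stack
#'   maximum.
#' @param minVoxels discard components smaller than this.
#' @return data.frame with columns \code{channel}, \code{x_um},
#'   \code{y_um}, \code{z_um}, \code{spot_radius_um}, \code{n_voxels},
#'   \code{peak}.
#' @export
detectSpots <- function(stack, voxelSize = attr(stack, "voxelSize"),
                        threshold = NULL, minVoxels = 2L) {
  if (is.null(voxelSize)) stop("voxelSize is required")
  if (length(dim(stack)) == 3L) dim(stack) <- c(dim(stack), 1L)
  nch <- dim(stack)[4]
  mx <- max(stack)
  if (is.null(threshold)) threshold <- mx / 2
  if (mx > 0 && (threshold <= 0 || threshold >= mx))
    stop("threshold must lie in (0, max intensity)")
  origin <- attr(stack, "origin") %||% c(0, 0, 0)
  res <- list()
  for (ch in seq_len(nch)) {
    vol <- stack[, , , ch, drop = FALSE]
    dim(vol) <- dim(stack)[1:3]
    comp <- .labelComponents3d(vol >= threshold)
    if (!length(comp)) {
      warning("no component above threshold in channel ",
              if (nch == 3L) CHANNELS[ch] else ch)
      next
    }
    for (vox in comp) {
      if (nrow(vox) < minVoxels) next
      w <- vol[vox]
      cen_idx <- colSums(vox * w) / sum(w) - 1  # 0-based fractional index
      cen <- voxelToPhysical(pmax(cen_idx, 0), voxelSize) + origin
      vol_um3 <- nrow(vox) * prod(voxelSize)
      res[[length(res) + 1L]] <- data.frame(
        channel = if (nch == 3L) CHANNELS[ch] else as.character(ch),
        x_um = cen[1], y_um = cen[2], z_um = cen[3],
        spot_radius_um = (3 * vol_um3 / (4 * pi))^(1 / 3),
        n_voxels = nrow(vox), peak = max(w),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(channel = character(), x_um = numeric(),
                      y_um = numeric(), z_um = numeric(),
                      spot_radius_um = numeric(), n_voxels = integer(),
                      peak = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, res)
}

## 26-connected component labeling of a logical 3D array; returns a list of
## voxel index matrices (1-based i, j, k rows per component)
.labelComponents3d <- function(mask) {
  dims <- dim(mask)
  idx <- which(mask)
  if (!length(idx)) return(list())
  lab <- array(0L, dims)
  nbr <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nbr <- nbr[rowSums(abs(nbr)) > 0, ]
  comps <- list()
  for (start in idx) {
    if (lab[start] != 0L) next
    id <- length(comps) + 1L
    queue <- arrayInd(start, dims)
    lab[start] <- id
    members <- queue
    while (nrow(queue)) {
      frontier <- NULL
      for (q in seq_len(nrow(queue))) {
        cand <- sweep(nbr, 2, queue[q, ], "+")
        ok <- cand[, 1] >= 1 & cand[, 1] <= dims[1] &
              cand[, 2] >= 1 & cand[, 2] <= dims[2] &
              cand[, 3] >= 1 & cand[, 3] <= dims[3]
        cand <- cand[ok, , drop = FALSE]
        if (!nrow(cand)) next
        lin <- cand[, 1] + (cand[, 2] - 1L) * dims[1] +
               (cand[, 3] - 1L) * dims[1] * dims[2]
        new <- mask[lin] & lab[lin] == 0L
        if (any(new)) {
          lab[lin[new]] <- id
          frontier <- rbind(frontier, cand[new, , drop = FALSE])
        }
      }
      if (is.null(frontier)) break
      members <- rbind(members, frontier)
      queue <- frontier
    }
    comps[[id]] <- members
  }
  comps
}

#' Write a rendered stack as multi-page TIFF
#'
#' Pages are channel-major (all z planes of channel 1, then channel 2, then
#' channel 3).  Intensities are rescaled to [0, 1].  Voxel size, dimensions
#' and origin are recorded in a JSON sidecar at \code{<path>.meta.json}.
#'
#' @param stack 4D array from [renderImage()].
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path) {
  dims <- dim(stack)
  mx <- max(stack)
  sc <- if (mx > 0) stack / mx else stack
  pages <- list()
  for (ch in seq_len(dims[4]))
    for (z in seq_len(dims[3]))
      pages[[length(pages) + 1L]] <- sc[, , z, ch]
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(voxel_size_um = attr(stack, "voxelSize"),
               origin_um = attr(stack, "origin"),
               dim = dims, channel_order = CHANNELS,
               page_order = "channel-major", scale = mx)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a stack written by [writeStack()]
#'
#' @param path TIFF path (the sidecar \code{<path>.meta.json} must exist).
#' @return a 4D array with voxel-size and origin attributes.
#' @export
readStack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  dims <- meta$dim
  stack <- array(0, dim = dims)
  k <- 1L
  for (ch in seq_len(dims[4]))
    for (z in seq_len(dims[3])) {
      stack[, , z, ch] <- pages[[k]] * meta$scale
      k <- k + 1L
    }
  attr(stack, "voxelSize") <- meta$voxel_size_um
  attr(stack, "origin") <- meta$origin_um
  stack
}
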