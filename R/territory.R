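# 3D chromosome-territory quantification: global iterative-intermeans
# (isodata) thresholding per channel, 26-connected component extraction with
# a strict > 30-voxel size filter, merging of surviving objects into one
# territory per channel, and volume / pairwise-overlap measurement.

#' Quantification parameters
#'
#' @param min_object_voxels objects are kept iff size is strictly greater
#'   than this (default 30).
#' @param connectivity 26 (faces + edges + corners; default) or 6 (faces).
#' @param threshold_method only `"isodata"` (iterative intermeans) is
#'   implemented.
#' @return a `QuantParams` list.
#' @export
quant_params <- function(min_object_voxels = 30L, connectivity = 26L,
                         threshold_method = "isodata") {
  if (min_object_voxels < 0)
    abort_np("min_object_voxels must be >= 0", "np_param_error")
  if (!connectivity %in% c(6L, 26L))
    abort_np("connectivity must be 6 or 26", "np_param_error")
  threshold_method <- match.arg(threshold_method, "isodata")
  structure(list(min_object_voxels = as.integer(min_object_voxels),
                 connectivity = as.integer(connectivity),
                 threshold_method = threshold_method),
            class = "QuantParams")
}

#' Iterative-intermeans (isodata) threshold of an intensity stack
#'
#' Computes the classic isodata threshold on the whole-stack histogram of
#' integer intensities: starting from the mean intensity, the threshold is
#' iterated to the rounded midpoint of the means of the two classes it
#' induces until it stabilizes.  The binary mask is `intensity > T`.
#'
#' @param stack numeric array of nonnegative integers (any dimensionality).
#' @param return_mask if TRUE (default) return the logical mask; otherwise
#'   return the threshold value T.
#' @return logical array (mask) or a single numeric threshold.
#' @export
threshold_stack <- function(stack, return_mask = TRUE) {
  v <- as.vector(stack)
  if (anyNA(v) || any(v < 0)) abort_np("intensities must be nonnegative",
                                       "np_param_error")
  if (min(v) == max(v))
    abort_np("constant image: histogram is degenerate, no threshold exists",
             "np_degenerate_histogram")
  counts <- tabulate(as.integer(v) + 1L)      # histogram over 0..max
  vals <- seq_along(counts) - 1L
  t_cur <- as.integer(round(sum(counts * vals) / sum(counts)))
  repeat {
    lo <- vals <= t_cur
    n_lo <- sum(counts[lo]); n_hi <- sum(counts[!lo])
    if (n_lo == 0 || n_hi == 0) break
    mu_lo <- sum(counts[lo] * vals[lo]) / n_lo
    mu_hi <- sum(counts[!lo] * vals[!lo]) / n_hi
    t_new <- as.integer(round((mu_lo + mu_hi) / 2))
    if (t_new == t_cur) break
    t_cur <- t_new
  }
  if (!return_mask) return(t_cur)
  mask <- stack > t_cur
  mask
}

#' Extract size-filtered 3D connected components
#'
#' Labels the mask under the requested connectivity and discards components
#' whose voxel count is `<= min_object_voxels` (strict "larger than" rule).
#'
#' @param mask logical 3D array (z, y, x).
#' @param params a `QuantParams`.
#' @return integer array of the same shape: 0 = background, 1..n surviving
#'   objects relabeled consecutively in discovery order; the attribute
#'   `sizes` holds their voxel counts.
#' @export
extract_objects <- function(mask, params = quant_params()) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  labels <- cpp_label3d(as.vector(mask), dim(mask), params$connectivity)
  if (max(labels) == 0) {
    attr(labels, "sizes") <- integer(0)
    return(labels)
  }
  sizes <- tabulate(labels[labels > 0])
  keep <- which(sizes > params$min_object_voxels)
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  out <- array(0L, dim(mask))
  nz <- labels > 0
  out[nz] <- remap[labels[nz]]
  attr(out, "sizes") <- sizes[keep]
  out
}

#' Measure territory volumes and pairwise overlaps
#'
#' Per channel: threshold (isodata) -> connected components -> size filter ->
#' union of surviving objects = territory mask.  Emits per-channel merged
#' volumes, the symmetric pairwise intersection-volume matrix, and the
#' row-normalized overlap fractions (intersection / row-channel volume).
#'
#' @param stacks named list of numeric 3D arrays with identical dims, one
#'   per channel.
#' @param params a `QuantParams`.
#' @param voxel_size optional numeric length-3 (z, y, x) voxel edge lengths
#'   in micrometers; adds volumes in cubic micrometers.
#' @return a `TerritoryStats` list: `volume` (named voxel counts),
#'   `volume_um3` (or NULL), `overlap` (matrix, diagonal = volumes),
#'   `overlap_fraction`, `masks` (list of logical arrays).
#' @export
measure_territories <- function(stacks, params = quant_params(),
                                voxel_size = NULL) {
  stopifnot(is.list(stacks), length(stacks) >= 1)
  if (is.null(names(stacks)))
    names(stacks) <- paste0("ch", seq_along(stacks))
  dims <- lapply(stacks, dim)
  if (!all(vapply(dims, function(d) identical(d, dims[[1]]), logical(1))))
    abort_np("channel stacks have mismatched dimensions", "np_dim_mismatch")
  masks <- lapply(stacks, function(st) {
    m <- threshold_stack(st)
    extract_objects(m, params) > 0L
  })
  vol <- vapply(masks, sum, numeric(1))
  nc <- length(masks)
  ov <- matrix(0, nc, nc, dimnames = list(names(masks), names(masks)))
  for (i in seq_len(nc)) for (j in i:nc)
    ov[i, j] <- ov[j, i] <- sum(masks[[i]] & masks[[j]])
  frac <- sweep(ov, 1, ifelse(vol > 0, vol, NA), "/")
  out <- list(volume = vol,
              volume_um3 = if (!is.null(voxel_size)) vol * prod(voxel_size)
                           else NULL,
              overlap = ov, overlap_fraction = frac, masks = masks)
  class(out) <- "TerritoryStats"
  out
}

#' @export
print.TerritoryStats <- function(x, ...) {
  cat("TerritoryStats:", length(x$volume), "channel(s)\n")
  print(data.frame(channel = names(x$volume), volume_voxels = x$volume,
                   row.names = NULL))
  if (length(x$volume) > 1) {
    cat("pairwise overlap (voxels):\n")
    print(x$overlap)
  }
  invisible(x)
}

#' Write territory statistics as CSV
#'
#' One row per channel: volume (voxels and, if known, um^3) followed by the
#' overlap volume and overlap fraction against every channel.
#'
#' @param stats a `TerritoryStats`.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_territory_csv <- function(stats, path) {
  chans <- names(stats$volume)
  df <- data.frame(channel = chans, volume_voxels = as.numeric(stats$volume))
  if (!is.null(stats$volume_um3)) df$volume_um3 <- as.numeric(stats$volume_um3)
  for (ch in chans) {
    df[[paste0("overlap_", ch)]] <- stats$overlap[, ch]
    df[[paste0("overlap_frac_", ch)]] <- stats$overlap_fraction[, ch]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
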