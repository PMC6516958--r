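# Synthetic genomes and synthetic 3D nucleus images with recorded ground
# truth, so the design and quantification pipelines are testable end to end
# without external data.

#' Synthetic genome parameters
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length length per chromosome in bp (recycled; >= 10 kb
#'   recommended for mining tests).
#' @param gc target GC fraction (default 0.36, roughly the nematode
#'   composition).
#' @param repeat_blocks optional list of `list(length =, copies =)` exact
#'   repeat blocks implanted per chromosome.
#' @param seed integer RNG seed (mandatory).
#' @return a `SimGenomeParams` list.
#' @export
sim_genome_params <- function(n_chrom = 2L, chrom_length = 1e6, gc = 0.36,
                              repeat_blocks = list(), seed) {
  if (missing(seed)) abort_np("seed is mandatory", "np_param_error")
  structure(list(n_chrom = as.integer(n_chrom),
                 chrom_length = rep_len(as.numeric(chrom_length), n_chrom),
                 gc = gc, repeat_blocks = repeat_blocks,
                 seed = as.integer(seed)),
            class = "SimGenomeParams")
}

#' Simulate a genome with implanted repeats
#'
#' Generates i.i.d. bases at the target GC, then implants exact repeat
#' copies at uniformly drawn non-overlapping positions.  Deterministic for a
#' fixed seed.
#'
#' @param params a `SimGenomeParams`.
#' @param fasta_path optional path; when given the genome is also written as
#'   FASTA.
#' @return list with `sequences` (named character vector) and `truth`
#'   (data.frame of implanted repeat coordinates: chrom, block, copy,
#'   start, end; 0-based half-open).
#' @export
simulate_genome <- function(params, fasta_path = NULL) {
  stopifnot(inherits(params, "SimGenomeParams"))
  set.seed(params$seed)
  seqs <- character(params$n_chrom)
  names(seqs) <- paste0("chr", seq_len(params$n_chrom))
  truth <- list()
  for (ci in seq_len(params$n_chrom)) {
    L <- params$chrom_length[ci]
    for (rb in params$repeat_blocks)
      if (rb$length * rb$copies > L)
        abort_np("repeat block does not fit in the chromosome",
                 "np_param_error")
    s <- strsplit(random_dna(1, L, params$gc), "", fixed = TRUE)[[1]]
    for (bi in seq_along(params$repeat_blocks)) {
      rb <- params$repeat_blocks[[bi]]
      unit <- random_dna(1, rb$length, params$gc)
      placed <- 0L
      guard <- 0L
      occupied <- matrix(numeric(0), ncol = 2)
      while (placed < rb$copies) {
        if ((guard <- guard + 1L) > 1000L * rb$copies)
          abort_np("could not place repeat copies without overlap",
                   "np_infeasible")
        st <- floor(runif(1, 0, L - rb$length))
        if (nrow(occupied) &&
            any(st < occupied[, 2] & st + rb$length > occupied[, 1])) next
        s[(st + 1):(st + rb$length)] <- strsplit(unit, "", fixed = TRUE)[[1]]
        occupied <- rbind(occupied, c(st, st + rb$length))
        placed <- placed + 1L
        truth[[length(truth) + 1]] <- data.frame(
          chrom = names(seqs)[ci], block = bi, copy = placed,
          start = st, end = st + rb$length)
      }
    }
    seqs[ci] <- paste(s, collapse = "")
  }
  truth <- if (length(truth)) do.call(rbind, truth)
           else data.frame(chrom = character(0), block = integer(0),
                           copy = integer(0), start = numeric(0),
                           end = numeric(0))
  if (!is.null(fasta_path)) {
    writeLines(unlist(lapply(names(seqs), function(nm)
      c(paste0(">", nm), seqs[[nm]]))), fasta_path)
  }
  list(sequences = seqs, truth = truth)
}

#' Synthetic nucleus-image parameters
#'
#' Emulates per-nucleus crops of territory-stained nuclei: each territory is
#' an ellipsoid rendered into its own channel at a uniform signal level over
#' background, optionally blurred and Poisson-degraded.
#'
#' @param dims grid size (z, y, x), default c(32, 64, 64).
#' @param n_territories number of territories/channels (default 3).
#' @param semiaxis_range range of ellipsoid semi-axes in voxels (default
#'   c(6, 12)).
#' @param placement `"disjoint"` (default) or `"overlapping"`.
#' @param target_overlap for overlapping placement: desired pairwise
#'   intersection fraction used to sample center distances; the realized
#'   overlap is recorded as truth (default 0.2).
#' @param blur_sigma Gaussian blur sigma in voxels (default 1).
#' @param background,signal intensity levels (defaults 10, 200).
#' @param noise logical: apply Poisson noise (default TRUE).
#' @param seed integer RNG seed (mandatory).
#' @return a `SimNucleusParams` list.
#' @export
sim_nucleus_params <- function(dims = c(32L, 64L, 64L), n_territories = 3L,
                               semiaxis_range = c(6, 12),
                               placement = c("disjoint", "overlapping"),
                               target_overlap = 0.2, blur_sigma = 1,
                               background = 10, signal = 200, noise = TRUE,
                               seed) {
  if (missing(seed)) abort_np("seed is mandatory", "np_param_error")
  placement <- match.arg(placement)
  structure(list(dims = as.integer(dims),
                 n_territories = as.integer(n_territories),
                 semiaxis_range = semiaxis_range, placement = placement,
                 target_overlap = target_overlap, blur_sigma = blur_sigma,
                 background = background, signal = signal, noise = noise,
                 seed = as.integer(seed)),
            class = "SimNucleusParams")
}

# voxelized ellipsoid mask centered at `center` (z, y, x), semi-axes `ax`
ellipsoid_mask <- function(dims, center, ax) {
  z <- slice.index(array(0, dims), 1)
  y <- slice.index(array(0, dims), 2)
  x <- slice.index(array(0, dims), 3)
  ((z - center[1]) / ax[1])^2 + ((y - center[2]) / ax[2])^2 +
    ((x - center[3]) / ax[3])^2 <= 1
}

#' Simulate a multi-channel nucleus image with ground truth
#'
#' Territories are voxelized ellipsoids; ground-truth volumes and pairwise
#' overlaps are recorded from the noiseless binary masks before blur and
#' noise are applied.
#'
#' @param params a `SimNucleusParams`.
#' @return list: `stacks` (named list of numeric (z, y, x) arrays, one per
#'   territory channel), `truth` (list with `volume`, `overlap` matrix,
#'   `masks`, `centers`, `semiaxes`).
#' @export
simulate_nucleus_image <- function(params) {
  stopifnot(inherits(params, "SimNucleusParams"))
  set.seed(params$seed)
  d <- params$dims
  n <- params$n_territories
  masks <- vector("list", n)
  centers <- matrix(NA_real_, n, 3)
  axes <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (attempt in seq_len(500L)) {
      ax <- runif(3, params$semiaxis_range[1], params$semiaxis_range[2])
      if (any(2 * ax + 1 >= d)) next  # this draw cannot fit; resample
      ctr <- vapply(1:3, function(a) runif(1, ax[a] + 1, d[a] - ax[a]),
                    numeric(1))
      m <- ellipsoid_mask(d, ctr, ax)
      ok <- TRUE
      if (i > 1) {
        for (j in seq_len(i - 1)) {
          inter <- sum(m & masks[[j]])
          if (params$placement == "disjoint" && inter > 0) { ok <- FALSE; break }
          if (params$placement == "overlapping") {
            # accept if intersection fraction is within a factor 2 of target
            fr <- inter / min(sum(m), sum(masks[[j]]))
            if (fr > 2 * params$target_overlap) { ok <- FALSE; break }
          }
        }
        if (ok && params$placement == "overlapping" && i == 2) {
          fr <- sum(m & masks[[1]]) / min(sum(m), sum(masks[[1]]))
          if (fr < params$target_overlap / 4) ok <- FALSE
        }
      }
      if (ok) {
        masks[[i]] <- m; centers[i, ] <- ctr; axes[i, ] <- ax
        placed <- TRUE
        break
      }
    }
    if (!placed)
      abort_np("could not place territories after bounded attempts",
               "np_infeasible")
  }
  names(masks) <- paste0("ch", seq_len(n))
  vol <- vapply(masks, sum, numeric(1))
  ov <- matrix(0, n, n, dimnames = list(names(masks), names(masks)))
  for (i in seq_len(n)) for (j in i:n)
    ov[i, j] <- ov[j, i] <- sum(masks[[i]] & masks[[j]])
  stacks <- lapply(masks, function(m) {
    img <- array(params$background, d) + m * (params$signal - params$background)
    if (params$blur_sigma > 0)
      img <- cpp_gaussian_blur3d(as.vector(img), d, params$blur_sigma)
    if (params$noise) img <- array(rpois(length(img), as.vector(img)), d)
    array(round(img), d)
  })
  list(stacks = stacks,
       truth = list(volume = vol, overlap = ov, masks = masks,
                    centers = centers, semiaxes = axes))
}

#' Write a simulated nucleus to disk (TIFF per channel + JSON ground truth)
#'
#' @param sim output of [simulate_nucleus_image()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default "nucleus").
#' @return character vector of written TIFF paths, invisibly.
#' @export
write_nucleus_files <- function(sim, dir, prefix = "nucleus") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(sim$stacks), function(ch) {
    p <- file.path(dir, sprintf("%s_%s.tif", prefix, ch))
    write_tiff_stack(sim$stacks[[ch]], p)
    p
  }, character(1))
  truth <- list(volume = as.list(sim$truth$volume),
                overlap = sim$truth$overlap)
  jsonlite::write_json(truth, file.path(dir, paste0(prefix, "_truth.json")),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(paths)
}
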