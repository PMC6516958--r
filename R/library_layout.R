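# Even-density subsampling ("every fifth oligo"), spacing statistics, and the
# per-chromosome summary table with sum-for-counts / unweighted-mean-for-
# ratios totals semantics.

#' Subsampling parameters
#'
#' Either a fixed decimation step (default every 5th candidate) or a target
#' density from which the step is derived as
#' `round(candidate_density / target_density)`.
#'
#' @param step keep every `step`-th candidate (default 5).
#' @param target_density probes per kb; mutually exclusive with `step`.
#' @param gap_threshold gap size in bp counted as a coverage gap
#'   (default 5000).
#' @return a `SelectionParams` list.
#' @export
selection_params <- function(step = 5L, target_density = NULL,
                             gap_threshold = 5000) {
  if (!is.null(target_density)) {
    if (!missing(step))
      abort_np("give either step or target_density, not both",
               "np_param_error")
    step <- NA_integer_
  }
  if (is.null(target_density) && (!is.numeric(step) || step < 1))
    abort_np("step must be >= 1", "np_param_error")
  if (gap_threshold <= 0)
    abort_np("gap_threshold must be positive", "np_param_error")
  structure(list(step = if (is.null(target_density)) as.integer(step) else NA_integer_,
                 target_density = target_density,
                 gap_threshold = gap_threshold),
            class = "SelectionParams")
}

# resolve the decimation step for a candidate set spanning `span_bp`
resolve_step <- function(params, n_candidates, span_bp) {
  if (!is.na(params$step)) return(params$step)
  dens <- n_candidates / (span_bp / 1000)
  max(1L, as.integer(round(dens / params$target_density)))
}

#' Subsample candidates to even density
#'
#' Keeps candidates at indices 0, N, 2N, ... computed independently within
#' each 500 kb segment, so every 500 kb sub-pool stays populated and the
#' selection is invariant to what happens in other segments.
#'
#' @param candidates data.frame of candidates sorted by start (columns chrom
#'   and start at minimum).
#' @param params a `SelectionParams`.
#' @return the selected subset, sorted by (chrom, start).
#' @export
subsample <- function(candidates, params = selection_params()) {
  stopifnot(is.data.frame(candidates))
  if (nrow(candidates) == 0) return(candidates)
  candidates <- candidates[order(candidates$chrom, candidates$start), ]
  seg <- segment_index_of(candidates$start, "kb500")
  key <- paste(candidates$chrom, seg, sep = "\r")
  picked <- unlist(lapply(split(seq_len(nrow(candidates)), key), function(ix) {
    n <- length(ix)
    step <- resolve_step(params, n,
                         max(candidates$start[ix]) - min(candidates$start[ix]) + 1)
    ix[seq(1, n, by = step)]
  }), use.names = FALSE)
  out <- candidates[sort(picked), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Spacing and gap statistics of a selected probe set
#'
#' `endpoint_mean` is `(last_coord - first_coord) / n` — division by n, not
#' n - 1 — and `density_per_kb` is `n / span_kb`, matching the semantics of
#' published per-chromosome probe tables.
#'
#' @param starts numeric vector of probe start coordinates (one chromosome),
#'   or a candidates data.frame with a `start` column.
#' @param gap_threshold gaps larger than this (bp) are counted (default 5000).
#' @return a `SpacingStats` list: n_selected, first_coord, last_coord,
#'   mean_adjacent, sd_adjacent, endpoint_mean, density_per_kb,
#'   gaps_over_threshold, max_gap.
#' @export
spacing_stats <- function(starts, gap_threshold = 5000) {
  if (is.data.frame(starts)) starts <- starts$start
  stopifnot(is.numeric(starts))
  if (length(starts) < 2)
    abort_np("spacing statistics need at least 2 selected probes",
             "np_too_few_probes")
  starts <- sort(starts)
  d <- diff(starts)
  n <- length(starts)
  span <- starts[n] - starts[1]
  structure(list(n_selected = n, first_coord = starts[1],
                 last_coord = starts[n],
                 mean_adjacent = mean(d), sd_adjacent = sd(d),
                 endpoint_mean = span / n,
                 density_per_kb = n / (span / 1000),
                 gaps_over_threshold = sum(d > gap_threshold),
                 max_gap = max(d)),
            class = "SpacingStats")
}

#' Spacing statistics from printed endpoints
#'
#' Recomputes the derived columns of a per-chromosome probe table from its
#' printed inputs: `endpoint_mean = (last_coord - first_coord) / n` and
#' `density_per_kb = n / ((last_coord - first_coord) / 1000)`.  Coordinate
#' convention (0- or 1-based) cancels in the difference.
#'
#' @param first_coord,last_coord first and last probe coordinates, bp.
#' @param n number of probes.
#' @return list with `endpoint_mean` (bp) and `density_per_kb`.
#' @export
spacing_from_endpoints <- function(first_coord, last_coord, n) {
  if (any(n < 1) || any(last_coord <= first_coord))
    abort_np("need last_coord > first_coord and n >= 1", "np_param_error")
  span <- last_coord - first_coord
  list(endpoint_mean = span / n, density_per_kb = n / (span / 1000))
}

#' Per-chromosome summary table with totals row
#'
#' Builds the summary from per-chromosome rows: first/last coordinate,
#' candidate count and density, chosen count and density, mean and sd of
#' adjacent distances.  The totals row SUMS the two count columns and takes
#' the UNWEIGHTED MEAN across chromosomes for the per-kb and distance
#' columns; coordinate columns are left empty.
#'
#' @param rows data.frame with columns chrom, first_coord, last_coord,
#'   n_candidates, candidates_per_kb, n_chosen, chosen_per_kb,
#'   mean_distance, sd_distance.
#' @return a `SummaryTable` data.frame: the input rows plus a totals row
#'   (chrom = "total").
#' @export
summarize_library <- function(rows) {
  need <- c("chrom", "first_coord", "last_coord", "n_candidates",
            "candidates_per_kb", "n_chosen", "chosen_per_kb",
            "mean_distance", "sd_distance")
  if (!is.data.frame(rows) || !all(need %in% names(rows)))
    abort_np(paste0("summary rows must have columns: ",
                    paste(need, collapse = ", ")), "np_param_error")
  if (nrow(rows) < 1) abort_np("need at least one chromosome row", "np_param_error")
  rows <- rows[, need]
  totals <- data.frame(chrom = "total", first_coord = NA_real_,
                       last_coord = NA_real_,
                       n_candidates = sum(rows$n_candidates),
                       candidates_per_kb = mean(rows$candidates_per_kb),
                       n_chosen = sum(rows$n_chosen),
                       chosen_per_kb = mean(rows$chosen_per_kb),
                       mean_distance = mean(rows$mean_distance),
                       sd_distance = mean(rows$sd_distance),
                       stringsAsFactors = FALSE)
  out <- rbind(rows, totals)
  rownames(out) <- NULL
  class(out) <- c("SummaryTable", "data.frame")
  out
}

#' Build the summary table directly from candidate and chosen probe sets
#'
#' @param candidates data.frame of all mined candidates (chrom, start).
#' @param chosen data.frame of selected probes (chrom, start).
#' @param gap_threshold bp, for spacing stats (default 5000).
#' @return a `SummaryTable`.
#' @export
library_summary <- function(candidates, chosen, gap_threshold = 5000) {
  chroms <- unique(candidates$chrom)
  rows <- do.call(rbind, lapply(chroms, function(cm) {
    ca <- sort(candidates$start[candidates$chrom == cm])
    ch <- sort(chosen$start[chosen$chrom == cm])
    st <- spacing_stats(ch, gap_threshold)
    span_kb <- (max(ca) - min(ca)) / 1000
    data.frame(chrom = cm, first_coord = min(ca), last_coord = max(ca),
               n_candidates = length(ca),
               candidates_per_kb = length(ca) / span_kb,
               n_chosen = length(ch),
               chosen_per_kb = st$density_per_kb,
               mean_distance = st$endpoint_mean,
               sd_distance = st$sd_adjacent,
               stringsAsFactors = FALSE)
  }))
  summarize_library(rows)
}

#' Write / read a summary table as TSV
#'
#' Round-trips bit-identically (full double precision).
#'
#' @param x a `SummaryTable`.
#' @param path file path.
#' @return `write_summary_tsv`: the path, invisibly; `read_summary_tsv`: the
#'   `SummaryTable`.
#' @export
write_summary_tsv <- function(x, path) {
  stopifnot(inherits(x, "SummaryTable"))
  y <- as.data.frame(x)
  for (cn in names(y)) if (is.numeric(y[[cn]]))
    y[[cn]] <- sprintf("%.17g", y[[cn]])
  y[y == "NA"] <- ""
  write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_tsv
#' @export
read_summary_tsv <- function(path) {
  y <- read.delim(path, stringsAsFactors = FALSE)
  for (cn in setdiff(names(y), "chrom")) y[[cn]] <- as.numeric(y[[cn]])
  class(y) <- c("SummaryTable", "data.frame")
  y
}
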