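# Bridge / detection oligo design and combinatorial color coding.
#
# A bridge oligo is the reverse complement of its target primary-probe
# barcode followed by two tandem copies of a 20-nt detection docking site;
# both detections on one bridge therefore carry the same dye.  A detection
# oligo is the reverse complement of a dock, dye-labeled at both termini by
# default.  Pair color codes are routed through the 5' and 3' chromosome
# barcodes of the same primary oligo, one bridge (and dye) per barcode.

DOCK_LENGTH <- 20L

#' Multiplexing configuration
#'
#' @param bridges_per_primary bridges addressing one primary oligo (<= 2:
#'   its 5' and 3' barcodes; default 2).
#' @param detections_per_bridge docking sites per bridge (default 2).
#' @param dyes_per_detection dye molecules per detection oligo (default 2:
#'   both termini labeled).
#' @return a `MultiplexConfig` list.
#' @export
multiplex_config <- function(bridges_per_primary = 2L,
                             detections_per_bridge = 2L,
                             dyes_per_detection = 2L) {
  cfg <- list(bridges_per_primary = as.integer(bridges_per_primary),
              detections_per_bridge = as.integer(detections_per_bridge),
              dyes_per_detection = as.integer(dyes_per_detection))
  if (any(unlist(cfg) < 1)) abort_np("all multiplicities must be >= 1",
                                     "np_param_error")
  if (cfg$bridges_per_primary > 2)
    abort_np("a primary oligo exposes at most 2 addressable termini",
             "np_param_error")
  class(cfg) <- "MultiplexConfig"
  cfg
}

#' Fluorophores recognizing one primary oligo
#'
#' The product bridges_per_primary x detections_per_bridge x
#' dyes_per_detection; (2, 2, 2) gives the eight-fluorophore amplification
#' of the dual-bridge, dual-detection, dual-dye scheme.
#'
#' @param config a `MultiplexConfig`.
#' @return integer count.
#' @export
fluorophore_multiplicity <- function(config = multiplex_config()) {
  stopifnot(inherits(config, "MultiplexConfig"))
  config$bridges_per_primary * config$detections_per_bridge *
    config$dyes_per_detection
}

#' Number of distinguishable targets on K channels
#'
#' Sum of binomial(k, s) over code sizes s = 1..max_code_size: each target
#' is assigned a distinct nonempty channel subset of bounded size.
#'
#' @param k_channels number of imaging channels (>= 1).
#' @param max_code_size largest channel subset used per target (default 2).
#' @return integer capacity.
#' @export
color_capacity <- function(k_channels, max_code_size = 2L) {
  stopifnot(k_channels >= 1, max_code_size >= 1,
            max_code_size <= k_channels)
  sum(choose(k_channels, seq_len(max_code_size)))
}

#' Assign combinatorial color codes to targets
#'
#' Deterministic: singleton codes first in channel order, then pairs in
#' lexicographic order, then larger subsets.  Errors when the targets exceed
#' [color_capacity()], reporting the channel count that would suffice.
#'
#' @param targets character vector of target names.
#' @param channels character vector of dye/channel identifiers.
#' @param max_code_size largest subset size (default 2).
#' @return a `ColorScheme` list: `channels` and `code_per_target` (named
#'   list of channel subsets).
#' @export
assign_colors <- function(targets, channels, max_code_size = 2L) {
  stopifnot(is.character(targets), is.character(channels),
            !anyDuplicated(targets), !anyDuplicated(channels))
  cap <- color_capacity(length(channels), max_code_size)
  if (length(targets) > cap) {
    k_needed <- length(channels)
    while (color_capacity(k_needed, min(max_code_size, k_needed)) <
           length(targets)) k_needed <- k_needed + 1
    abort_np(sprintf(
      "%d targets exceed the capacity %d of %d channels (need >= %d channels)",
      length(targets), cap, length(channels), k_needed), "np_capacity")
  }
  codes <- list()
  for (s in seq_len(max_code_size)) {
    idx <- utils::combn(length(channels), s, simplify = FALSE)
    codes <- c(codes, lapply(idx, function(i) channels[i]))
  }
  structure(list(channels = channels,
                 code_per_target = setNames(codes[seq_along(targets)],
                                            targets)),
            class = "ColorScheme")
}

#' Compile the bridge and detection oligo order sheet
#'
#' For each target, one bridge per code channel: the first bridge targets
#' the 5' (chrom_fwd) barcode, the second the 3' (chrom_rev) barcode of the
#' same primary oligos.  Each dye owns exactly one docking site, so no dock
#' is shared between two dyes.  Every species is listed once.
#'
#' @param targets data.frame with columns target, barcode_5p, barcode_3p
#'   (barcode sequences addressable on the sub-pool; barcode_3p may be NA
#'   for single-channel codes).
#' @param scheme a `ColorScheme` covering every target.
#' @param config a `MultiplexConfig`.
#' @param seed integer seed for dock sequence generation (default 1).
#' @return an `OrderSheet` data.frame: species, role (bridge/detection),
#'   target, sequence, dye, dock_id.
#' @export
compile_hybridization <- function(targets, scheme,
                                  config = multiplex_config(), seed = 1) {
  stopifnot(is.data.frame(targets),
            all(c("target", "barcode_5p", "barcode_3p") %in% names(targets)),
            inherits(scheme, "ColorScheme"))
  missing_code <- setdiff(targets$target, names(scheme$code_per_target))
  if (length(missing_code))
    abort_np(paste0("no color code for target(s): ",
                    paste(missing_code, collapse = ", ")), "np_param_error")
  set.seed(seed)
  docks <- setNames(random_dna(length(scheme$channels), DOCK_LENGTH, 0.5),
                    scheme$channels)
  rows <- list()
  for (i in seq_len(nrow(targets))) {
    tg <- targets$target[i]
    code <- scheme$code_per_target[[tg]]
    bcs <- c(targets$barcode_5p[i], targets$barcode_3p[i])
    if (length(code) > sum(!is.na(bcs)))
      abort_np(sprintf(
        "target %s has a %d-channel code but only %d addressable barcode(s)",
        tg, length(code), sum(!is.na(bcs))), "np_unaddressable")
    for (ci in seq_along(code)) {
      dye <- code[ci]
      dock <- docks[[dye]]
      bridge_seq <- paste0(revcomp(bcs[ci]),
                           paste(rep(dock, config$detections_per_bridge),
                                 collapse = ""))
      rows[[length(rows) + 1]] <- data.frame(
        species = sprintf("bridge|%s|%s", tg, dye), role = "bridge",
        target = tg, sequence = bridge_seq, dye = dye,
        dock_id = paste0("dock_", dye), stringsAsFactors = FALSE)
    }
  }
  dyes_used <- unique(unlist(lapply(targets$target,
                                    function(t) scheme$code_per_target[[t]])))
  for (dye in dyes_used) {
    rows[[length(rows) + 1]] <- data.frame(
      species = sprintf("detection|%s", dye), role = "detection",
      target = NA_character_, sequence = revcomp(docks[[dye]]), dye = dye,
      dock_id = paste0("dock_", dye), stringsAsFactors = FALSE)
  }
  sheet <- do.call(rbind, rows)
  rownames(sheet) <- NULL
  attr(sheet, "docks") <- docks
  attr(sheet, "config") <- config
  class(sheet) <- c("OrderSheet", "data.frame")
  sheet
}

#' Write an order sheet as TSV / a color scheme as JSON
#'
#' @param sheet an `OrderSheet`.
#' @param scheme a `ColorScheme`.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_order_sheet <- function(sheet, path) {
  write.table(as.data.frame(sheet), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_order_sheet
#' @export
write_color_scheme <- function(scheme, path) {
  jsonlite::write_json(list(channels = scheme$channels,
                            code_per_target = scheme$code_per_target),
                       path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
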