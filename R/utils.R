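# Small sequence helpers shared across modules.

BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' @param x character vector of A/C/G/T/N sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    chartr("ACGTNacgtn", "TGCANtgcan",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' GC fraction of DNA strings
#'
#' @param x character vector of sequences.
#' @return numeric vector of GC fractions.
#' @export
gc_fraction <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    b <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    sum(b %in% c("G", "C")) / length(b)
  }, numeric(1), USE.NAMES = FALSE)
}

# random DNA string(s) with given GC probability; uses the current RNG stream
random_dna <- function(n, length, gc = 0.5) {
  vapply(seq_len(n), function(i) {
    is_gc <- runif(length) < gc
    strong <- sample(c("G", "C"), length, replace = TRUE)
    weak <- sample(c("A", "T"), length, replace = TRUE)
    paste(ifelse(is_gc, strong, weak), collapse = "")
  }, character(1))
}

# Hamming distance between two equal-length strings
hamming <- function(a, b) {
  va <- strsplit(a, "", fixed = TRUE)[[1]]
  vb <- strsplit(b, "", fixed = TRUE)[[1]]
  stopifnot(length(va) == length(vb))
  sum(va != vb)
}

# longest 3'-end cross-complementarity between two oligos: length of the
# longest suffix of `a` whose reverse complement is a suffix of `b`
# (primer-dimer style annealing at the 3' ends)
three_prime_complementarity <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  rb <- revcomp(b)
  best <- 0L
  for (len in seq_len(min(na, nb))) {
    if (substr(a, na - len + 1L, na) == substr(rb, 1L, len)) best <- len
  }
  best
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_np <- function(msg, class) {
  stop(structure(class = c(class, "nemapaint_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
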