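# Independent brute-force oracles and fixture builders.  Every oracle here
# is a from-scratch implementation kept deliberately naive; the package code
# under test never calls into this file.

rc1 <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# all k-length substrings of s (ACGT runs only are not enforced here; the
# caller filters)
substr_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1)
}

# dictionary scan over both strands: occurrence count of `kmer` among all
# k-length substrings of the sequences and of their reverse complements
oracle_kmer_count <- function(seqs, kmer) {
  k <- nchar(kmer)
  all_k <- unlist(lapply(c(seqs, vapply(seqs, rc1, "")), substr_kmers, k))
  sum(all_k == kmer)
}

# literal transcription of the unified nearest-neighbor calculation,
# written against a named lookup table (no rolling sums)
oracle_tm <- function(seq, na = 0.39, ct = 5e-8, formamide = 0,
                      fm_coef = 0.65) {
  nn <- list(AA = c(-7.6, -21.3), TT = c(-7.6, -21.3),
             AT = c(-7.2, -20.4), TA = c(-7.2, -21.3),
             CA = c(-8.5, -22.7), TG = c(-8.5, -22.7),
             GT = c(-8.4, -22.4), AC = c(-8.4, -22.4),
             CT = c(-7.8, -21.0), AG = c(-7.8, -21.0),
             GA = c(-8.2, -22.2), TC = c(-8.2, -22.2),
             CG = c(-10.6, -27.2), GC = c(-9.8, -24.4),
             GG = c(-8.0, -19.9), CC = c(-8.0, -19.9))
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  dh <- 0.2; ds <- -5.7
  for (i in seq_len(length(b) - 1)) {
    p <- nn[[paste0(b[i], b[i + 1])]]
    dh <- dh + p[1]; ds <- ds + p[2]
  }
  if (b[1] %in% c("A", "T")) { dh <- dh + 2.2; ds <- ds + 6.9 }
  if (b[length(b)] %in% c("A", "T")) { dh <- dh + 2.2; ds <- ds + 6.9 }
  ds <- ds + 0.368 * (length(b) - 1) * log(na)
  tm <- 1000 * dh / (ds + 1.987 * log(ct / 4)) - 273.15
  tm - fm_coef * formamide
}

# quadratic enumeration over all substring pairs: longest s with
# seq[b..b+s) == revcomp(seq[a..a+s)) and loop b - (a + s) >= min_loop
oracle_stem <- function(seq, min_loop = 3) {
  n <- nchar(seq)
  best <- 0
  for (len in seq_len(n %/% 2)) {
    found <- FALSE
    for (a in seq_len(n - len + 1)) {
      arc <- rc1(substr(seq, a, a + len - 1))
      b0 <- a + len + min_loop
      if (b0 + len - 1 > n) next
      for (b in b0:(n - len + 1)) {
        if (substr(seq, b, b + len - 1) == arc) { found <- TRUE; break }
      }
      if (found) break
    }
    if (found) best <- len else break
  }
  best
}

# 3D flood fill on an array mask; returns component sizes (sorted)
oracle_component_sizes <- function(mask, connectivity = 26) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  sizes <- integer(0)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  if (connectivity == 6)
    offs <- offs[abs(offs$dz) + abs(offs$dy) + abs(offs$dx) == 1, ]
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    if (!mask[z, y, x] || lab[z, y, x] != 0) next
    nxt <- nxt + 1L
    queue <- matrix(c(z, y, x), 1)
    lab[z, y, x] <- nxt
    size <- 0L
    while (nrow(queue) > 0) {
      cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      size <- size + 1L
      for (r in seq_len(nrow(offs))) {
        p <- cur + as.numeric(offs[r, ])
        if (any(p < 1) || any(p > d)) next
        if (mask[p[1], p[2], p[3]] && lab[p[1], p[2], p[3]] == 0) {
          lab[p[1], p[2], p[3]] <- nxt
          queue <- rbind(queue, p)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sort(sizes)
}

# literal iterative-intermeans loop over raw intensities
oracle_isodata <- function(v) {
  v <- as.integer(v)
  t_cur <- as.integer(round(mean(v)))
  repeat {
    lo <- v[v <= t_cur]; hi <- v[v > t_cur]
    if (length(lo) == 0 || length(hi) == 0) break
    t_new <- as.integer(round((mean(lo) + mean(hi)) / 2))
    if (t_new == t_cur) break
    t_cur <- t_new
  }
  t_cur
}

# all-pairs Hamming distance check
oracle_min_hamming <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  best <- Inf
  for (i in seq_len(nrow(m) - 1)) for (j in (i + 1):nrow(m))
    best <- min(best, sum(m[i, ] != m[j, ]))
  best
}

# write a FASTA file from a named character vector; returns the path
write_fasta_fixture <- function(seqs, path = tempfile(fileext = ".fa"),
                                width = NULL) {
  lines <- unlist(lapply(names(seqs), function(nm) {
    body <- seqs[[nm]]
    if (!is.null(width))
      body <- substring(body, seq(1, nchar(body), width),
                        pmin(seq(1, nchar(body), width) + width - 1,
                             nchar(body)))
    c(paste0(">", nm), body)
  }))
  writeLines(lines, path)
  path
}

# small genome + index fixture shared by several test files
make_test_genome <- function(len = 2e4, seed = 11, k = 18) {
  set.seed(seed)
  seqs <- c(chrA = random_seq(len, 0.45))
  genome_index(seqs, k = k)
}
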