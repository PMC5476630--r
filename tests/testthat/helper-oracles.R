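# Independent reference implementations used to cross-check the package.
# Each is deliberately naive (enumeration / all-pairs / position scan) and
# shares no code with the functions it verifies.

# upper-tail hypergeometric by direct enumeration over the support
enum_hypergeom_upper <- function(k, K, n, N) {
  js <- max(0, k):min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# longest ORF by scanning forward from every ATG position on both strands
brute_longest_orf <- function(seq) {
  seq <- toupper(seq)
  rc <- paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "")[[1]]),
              collapse = "")
  best <- 0L
  for (s in c(seq, rc)) {
    atg <- unlist(gregexpr("ATG", s, fixed = TRUE))
    atg <- atg[atg > 0]
    for (a in atg) {
      pos <- a + 3
      len <- 1L
      repeat {
        if (pos + 2 > nchar(s)) break  # ran off the end: no stop, no ORF
        codon <- substr(s, pos, pos + 2)
        if (codon %in% c("TAA", "TAG", "TGA")) {
          best <- max(best, len)
          break
        }
        len <- len + 1L
        pos <- pos + 3
      }
    }
  }
  best
}

# all-pairs interval overlap on locus/peak tibbles (0-based half-open)
naive_overlap_ids <- function(loci, peaks, min_overlap = 1L) {
  hits <- character()
  for (i in seq_len(nrow(loci))) {
    for (j in seq_len(nrow(peaks))) {
      if (loci$chrom[i] != peaks$chrom[j]) next
      ov <- min(loci$end[i], peaks$end[j]) - max(loci$start[i], peaks$start[j])
      if (ov >= min_overlap) {
        hits <- c(hits, loci$transcript_id[i])
        break
      }
    }
  }
  hits
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000L,
                             max_len = 500L) {
  start <- sample.int(max_pos, n, replace = TRUE)
  tibble::tibble(
    transcript_id = sprintf("iv%04d", seq_len(n)),
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample.int(max_len, n, replace = TRUE)
  )
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
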