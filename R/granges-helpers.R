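# Internal converters between the package's tibble representations (0-based
# half-open) and GenomicRanges objects (1-based closed). All overlap work is
# delegated to IRanges/GenomicRanges; these shims keep the conversion in one
# place.

exons_granges <- function(transcripts) {
  n_ex <- purrr::map_int(transcripts$exons, nrow)
  GenomicRanges::GRanges(
    seqnames = rep(transcripts$chrom, n_ex),
    ranges = IRanges::IRanges(
      start = unlist(purrr::map(transcripts$exons, ~ .x[, "start"])) + 1L,
      end = unlist(purrr::map(transcripts$exons, ~ .x[, "end"]))
    ),
    transcript_id = rep(transcripts$transcript_id, n_ex)
  )
}

span_granges <- function(transcripts) {
  starts <- purrr::map_int(transcripts$exons, ~ as.integer(min(.x[, "start"])))
  ends <- purrr::map_int(transcripts$exons, ~ as.integer(max(.x[, "end"])))
  GenomicRanges::GRanges(
    seqnames = transcripts$chrom,
    ranges = IRanges::IRanges(start = starts + 1L, end = ends),
    transcript_id = transcripts$transcript_id
  )
}

peaks_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  )
}

# Transcript genomic spans as a tibble (0-based half-open).
transcript_spans <- function(transcripts) {
  tibble::tibble(
    transcript_id = transcripts$transcript_id,
    chrom = transcripts$chrom,
    start = purrr::map_int(transcripts$exons, ~ as.integer(min(.x[, "start"]))),
    end = purrr::map_int(transcripts$exons, ~ as.integer(max(.x[, "end"])))
  )
}
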