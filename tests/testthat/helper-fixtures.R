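# Shared fixtures, built once per test run.

# tiny expression tibble from a named list of 9-vectors
make_expr <- function(rows) {
  m <- do.call(rbind, rows)
  colnames(m) <- sample_names()
  tibble::as_tibble(cbind(tibble::tibble(transcript_id = names(rows)),
                          tibble::as_tibble(m)))
}

# single-exon transcript tibble
make_tx <- function(ids, chrom, start, end, biotype = "novel",
                    sequence = NULL) {
  out <- tibble::tibble(
    transcript_id = ids, gene_id = ids, chrom = chrom, strand = ".",
    biotype = biotype,
    exons = purrr::map2(start, end, ~ cbind(start = .x, end = .y)),
    length = end - start
  )
  if (!is.null(sequence)) out$sequence <- sequence
  out
}

# noiseless mid-sized bundle shared by recovery tests
noiseless_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_bundle(simulation_config(
        seed = 4242, n_coding = 300, n_novel = 150, noise_sd = 0))
    }
    cache
  }
})
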