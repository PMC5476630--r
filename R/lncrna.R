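#' Thresholds for the lncRNA identification filter chain
#'
#' Defaults follow the study design: noncoding transcripts are retained when
#' some sample exceeds 0.1 FPKM, transcripts shorter than 200 nt are
#' discarded, and transcripts whose longest open reading frame reaches 100
#' amino acids are treated as coding. The coding-transcript expression floor
#' (1.0 FPKM) is used by the regulation caller, not by this chain.
#'
#' @param fpkm_noncoding_min Strict lower FPKM bound for noncoding
#'   transcripts (a transcript survives iff its maximum over the nine
#'   samples exceeds this).
#' @param fpkm_coding_min Expression floor for coding transcripts (FPKM).
#' @param min_length Minimum spliced length in nt (inclusive).
#' @param max_orf ORF length, in amino acids, at or above which a transcript
#'   is considered coding and removed.
#' @return A list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(fpkm_noncoding_min = 0.1, fpkm_coding_min = 1.0,
                              min_length = 200L, max_orf = 100L) {
  stopifnot(fpkm_noncoding_min > 0, fpkm_coding_min > 0,
            min_length > 0, max_orf > 0)
  structure(
    list(fpkm_noncoding_min = fpkm_noncoding_min,
         fpkm_coding_min = fpkm_coding_min,
         min_length = as.integer(min_length),
         max_orf = as.integer(max_orf)),
    class = "filter_thresholds"
  )
}

#' Expression filter for novel transcripts
#'
#' A novel transcript survives iff its maximum FPKM over the nine samples is
#' strictly greater than `thr$fpkm_noncoding_min`; a transcript never
#' exceeding 0.1 FPKM anywhere in the design is treated as a partial or
#' artefactual assembly.
#'
#' @param novel Transcript tibble of novel transcripts (see [read_gtf()]).
#' @param expr Expression tibble covering every novel transcript.
#' @param thr [filter_thresholds()].
#' @return Character vector of surviving transcript ids (input order).
#' @export
filter_expression <- function(novel, expr, thr = filter_thresholds()) {
  m <- expr_matrix(expr)
  missing <- setdiff(novel$transcript_id, rownames(m))
  if (length(missing) > 0) {
    abort(paste0("no expression row for transcript(s): ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  mx <- apply(m[novel$transcript_id, , drop = FALSE], 1, max)
  novel$transcript_id[mx > thr$fpkm_noncoding_min]
}

#' Annotation-overlap filter
#'
#' Removes any novel transcript sharing at least one base pair of exonic
#' overlap with an annotated protein-coding transcript, strand-agnostic;
#' such transcripts may be unannotated splice variants rather than
#' independent noncoding loci. A novel transcript wholly inside an intron of
#' a coding gene is kept.
#'
#' @param novel,annotated Transcript tibbles.
#' @return Character vector of surviving transcript ids.
#' @export
filter_annotation_overlap <- function(novel, annotated) {
  if (nrow(novel) == 0) return(character())
  if (nrow(annotated) == 0) return(novel$transcript_id)
  nov_ex <- exons_granges(novel)
  ann_ex <- exons_granges(annotated)
  hits <- GenomicRanges::findOverlaps(nov_ex, ann_ex, minoverlap = 1L,
                                      ignore.strand = TRUE)
  removed <- unique(nov_ex$transcript_id[S4Vectors::queryHits(hits)])
  setdiff(novel$transcript_id, removed)
}

#' Length filter
#'
#' Keeps transcripts whose spliced length (sum of exon lengths) is at least
#' `thr$min_length` nucleotides.
#'
#' @inheritParams filter_expression
#' @return Character vector of surviving transcript ids.
#' @export
filter_length <- function(novel, thr = filter_thresholds()) {
  novel$transcript_id[novel$length >= thr$min_length]
}

#' Longest open reading frame
#'
#' Scans all three frames of both strands for ORFs of the form
#' `ATG ... in-frame stop` (the stop is required) and returns the longest
#' ORF length in codons, excluding the stop, so `"ATGTAA"` scores 1. A codon
#' containing `N` matches neither `ATG` nor a stop. Returns 0 when no
#' complete ORF exists.
#'
#' @param sequence A nucleotide string over `A`,`C`,`G`,`T`,`N`.
#' @return Integer ORF length in amino acids.
#' @export
longest_orf <- function(sequence) {
  if (is.na(sequence) || nchar(sequence) < 6) return(0L)
  sequence <- toupper(sequence)
  rc <- revcomp(sequence)
  best <- 0L
  for (s in c(sequence, rc)) {
    for (frame in 0:2) {
      best <- max(best, longest_orf_frame(s, frame))
    }
  }
  best
}

revcomp <- function(sequence) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", sequence), "", fixed = TRUE)[[1]]),
        collapse = "")
}

longest_orf_frame <- function(sequence, frame) {
  n <- nchar(sequence)
  n_codon <- (n - frame) %/% 3
  if (n_codon < 2) return(0L)
  starts <- frame + 3 * (seq_len(n_codon) - 1) + 1
  codons <- substring(sequence, starts, starts + 2)
  is_start <- codons == "ATG"
  is_stop <- codons %in% c("TAA", "TAG", "TGA")
  best <- 0L
  open_at <- NA_integer_  # earliest ATG since the last stop
  for (i in seq_len(n_codon)) {
    if (is_stop[i]) {
      if (!is.na(open_at)) {
        best <- max(best, i - open_at)
        open_at <- NA_integer_
      }
    } else if (is_start[i] && is.na(open_at)) {
      open_at <- i
    }
  }
  as.integer(best)
}

#' Coding-potential filter
#'
#' Removes novel transcripts whose longest ORF reaches `thr$max_orf` amino
#' acids (default 100): the large majority of genuine protein-coding genes
#' carry ORFs of that size, so a long ORF marks a likely coding transcript.
#'
#' @param novel Transcript tibble with a `sequence` column.
#' @inheritParams filter_expression
#' @return Character vector of surviving transcript ids.
#' @export
filter_coding_potential <- function(novel, thr = filter_thresholds()) {
  if (is.null(novel$sequence)) abort("`novel` must carry a `sequence` column")
  orf <- purrr::map_int(novel$sequence, longest_orf)
  novel$transcript_id[orf < thr$max_orf]
}

#' Small-RNA-precursor / transposable-element blacklist filter
#'
#' Removes transcripts matching a blacklist of small-RNA precursors and
#' transposable elements, by either or both of two criteria:
#' * interval mode: at least `min_coverage` (default 50%) of the
#'   transcript's exonic length overlaps blacklist intervals;
#' * sequence mode: the transcript shares an exact substring of at least
#'   `min_kmer` nt (default 50) with some blacklist sequence.
#'
#' @param novel Transcript tibble (with a `sequence` column when
#'   `blacklist_seqs` is used).
#' @param blacklist_intervals Optional interval tibble (`chrom`, `start`,
#'   `end`; 0-based half-open).
#' @param blacklist_seqs Optional named character vector of blacklist
#'   sequences.
#' @param min_coverage Fraction of exonic length that must be covered in
#'   interval mode.
#' @param min_kmer Exact shared-substring length for sequence mode, nt.
#' @return Character vector of surviving transcript ids.
#' @export
filter_blacklist <- function(novel, blacklist_intervals = NULL,
                             blacklist_seqs = NULL,
                             min_coverage = 0.5, min_kmer = 50L) {
  if (nrow(novel) == 0) return(character())
  removed <- character()
  if (!is.null(blacklist_intervals) && nrow(blacklist_intervals) > 0) {
    ex <- exons_granges(novel)
    bl <- GenomicRanges::reduce(peaks_granges(blacklist_intervals))
    hits <- GenomicRanges::findOverlaps(ex, bl, ignore.strand = TRUE)
    if (length(hits) > 0) {
      ov <- IRanges::pintersect(ex[S4Vectors::queryHits(hits)],
                                bl[S4Vectors::subjectHits(hits)])
      cov <- tapply(GenomicRanges::width(ov),
                    ex$transcript_id[S4Vectors::queryHits(hits)], sum)
      lens <- setNames(novel$length, novel$transcript_id)
      frac <- cov / lens[names(cov)]
      removed <- c(removed, names(frac)[frac >= min_coverage])
    }
  }
  if (!is.null(blacklist_seqs) && length(blacklist_seqs) > 0) {
    if (is.null(novel$sequence)) {
      abort("sequence-mode blacklist matching needs a `sequence` column")
    }
    kmers <- blacklist_kmers(blacklist_seqs, min_kmer)
    if (length(kmers) > 0) {
      pd <- Biostrings::PDict(kmers)
      subj <- Biostrings::DNAStringSet(setNames(novel$sequence,
                                                novel$transcript_id))
      hit <- vapply(Biostrings::vwhichPDict(pd, subj), length, integer(1)) > 0
      removed <- c(removed, novel$transcript_id[hit])
    }
  }
  setdiff(novel$transcript_id, unique(removed))
}

# All distinct k-mers of the blacklist sequences (windows containing N or
# other ambiguity codes are dropped: exact matching only).
blacklist_kmers <- function(seqs, k) {
  kmers <- unlist(purrr::map(seqs, function(s) {
    s <- toupper(s)
    n <- nchar(s)
    if (n < k) return(character())
    substring(s, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1)
  }))
  kmers <- unique(kmers)
  Biostrings::DNAStringSet(kmers[!grepl("[^ACGT]", kmers)])
}

#' Run the full lncRNA identification filter chain
#'
#' Applies the five filter stages in order -- expression,
#' annotation-overlap, length, coding-potential, blacklist -- to the novel
#' transcripts of an annotation, and returns the surviving lncRNA set with a
#' per-stage audit of the funnel.
#'
#' @param transcripts Transcript tibble mixing `annotated_coding` and
#'   `novel` biotypes, with sequences attached for the novel set.
#' @param expr Expression tibble covering all novel transcripts.
#' @inheritParams filter_blacklist
#' @param thr [filter_thresholds()].
#' @return A list with `lncrna_ids` (character) and `audit`, a tibble with
#'   one row per stage: `stage`, `n_in`, `n_removed`, `n_out` and a
#'   `removed` list-column of removed ids. The audit telescopes:
#'   `n_out[i] == n_in[i + 1]`.
#' @export
run_lncrna_pipeline <- function(transcripts, expr,
                                blacklist_intervals = NULL,
                                blacklist_seqs = NULL,
                                thr = filter_thresholds(),
                                min_coverage = 0.5, min_kmer = 50L) {
  novel <- transcripts[transcripts$biotype == "novel", , drop = FALSE]
  annotated <- transcripts[transcripts$biotype == "annotated_coding", , drop = FALSE]
  stages <- list(
    expression = function(nv) filter_expression(nv, expr, thr),
    annotation_overlap = function(nv) filter_annotation_overlap(nv, annotated),
    length = function(nv) filter_length(nv, thr),
    coding_potential = function(nv) filter_coding_potential(nv, thr),
    blacklist = function(nv) filter_blacklist(nv, blacklist_intervals,
                                              blacklist_seqs,
                                              min_coverage, min_kmer)
  )
  audit <- vector("list", length(stages))
  current <- novel
  for (i in seq_along(stages)) {
    surviving <- if (nrow(current) == 0) character() else stages[[i]](current)
    removed <- setdiff(current$transcript_id, surviving)
    audit[[i]] <- tibble::tibble(
      stage = names(stages)[i],
      n_in = nrow(current),
      n_removed = length(removed),
      n_out = nrow(current) - length(removed),
      removed = list(removed)
    )
    current <- current[current$transcript_id %in% surviving, , drop = FALSE]
  }
  list(lncrna_ids = current$transcript_id, audit = purrr::list_rbind(audit))
}
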