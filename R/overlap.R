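# A "locus" here is a transcript's genomic span (leftmost exon start to
# rightmost exon end); exon-resolved overlap is the business of the
# annotation filter, while chromatin-domain questions are asked at span
# level.

loci_tibble <- function(loci) {
  if ("exons" %in% names(loci)) return(transcript_spans(loci))
  out <- tibble::as_tibble(loci)
  if (!"transcript_id" %in% names(out)) {
    out$transcript_id <- if ("name" %in% names(out)) out$name
                         else as.character(seq_len(nrow(out)))
  }
  out[, c("transcript_id", "chrom", "start", "end")]
}

#' Loci overlapping a peak set
#'
#' Returns the loci (transcript spans) having at least `min_overlap` bases
#' of overlap with any peak. Interval search is index-based and agrees
#' exactly with a naive all-pairs scan.
#'
#' @param loci A transcript tibble (spans are used) or an interval tibble
#'   (`transcript_id`/`name`, `chrom`, `start`, `end`, 0-based half-open).
#' @param peaks Peak tibble (see [read_bed()]).
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return Character vector of overlapping locus ids.
#' @export
overlap_loci <- function(loci, peaks, min_overlap = 1L) {
  lt <- loci_tibble(loci)
  if (nrow(lt) == 0 || nrow(peaks) == 0) return(character())
  gr <- GenomicRanges::GRanges(
    seqnames = lt$chrom,
    ranges = IRanges::IRanges(start = lt$start + 1L, end = lt$end)
  )
  hits <- GenomicRanges::findOverlaps(gr, peaks_granges(peaks),
                                      minoverlap = min_overlap,
                                      ignore.strand = TRUE)
  unique(lt$transcript_id[S4Vectors::queryHits(hits)])
}

#' Peak-overlap association between a locus group and its background
#'
#' Counts, for a group of loci and a background group, how many overlap the
#' peak set, and tests association with the Pearson chi-square on the 2x2
#' table (group membership x peak overlap).
#'
#' @param group_loci,background_loci Transcript or interval tibbles (both
#'   non-empty).
#' @param peaks Peak tibble.
#' @param min_overlap Minimum overlap in bp.
#' @return A list of class `overlap_report`: `groups` (tibble with `group`,
#'   `n_loci`, `n_overlapping`, `fraction`), `table` (2x2 matrix) and
#'   `test` (tibble from [chi_square_2x2()]).
#' @export
overlap_association <- function(group_loci, background_loci, peaks,
                                min_overlap = 1L) {
  if (nrow(group_loci) == 0 || nrow(background_loci) == 0) {
    abort("both locus groups must be non-empty")
  }
  g <- loci_tibble(group_loci)
  b <- loci_tibble(background_loci)
  g_ov <- length(overlap_loci(g, peaks, min_overlap))
  b_ov <- length(overlap_loci(b, peaks, min_overlap))
  tab <- matrix(c(g_ov, nrow(g) - g_ov, b_ov, nrow(b) - b_ov),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("group", "background"),
                                c("overlapping", "not_overlapping")))
  structure(
    list(
      groups = tibble::tibble(
        group = c("group", "background"),
        n_loci = c(nrow(g), nrow(b)),
        n_overlapping = c(g_ov, b_ov),
        fraction = c(g_ov / nrow(g), b_ov / nrow(b))
      ),
      table = tab,
      test = chi_square_2x2(tab)
    ),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  print(x$groups)
  cat("chi-square = ", format(x$test$statistic, digits = 4),
      ", df = 1, p = ", format(x$test$p, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Coding genes neighbouring lncRNA loci
#'
#' Pairs each lncRNA with every coding transcript whose genomic span lies
#' within `window` bp of the lncRNA span on the same chromosome
#' (strand-agnostic, edge-to-edge, boundary inclusive). The signed distance
#' is 0 for overlapping spans, positive when the coding gene lies downstream
#' (higher coordinates) and negative upstream.
#'
#' @param lncrnas,coding Transcript tibbles (or interval tibbles).
#' @param window Maximum gap in bp (default 10000).
#' @return A tibble with `lncrna_id`, `gene_id` (the partner's transcript
#'   id) and `distance`.
#' @export
neighbour_pairs <- function(lncrnas, coding, window = 10000L) {
  lt <- loci_tibble(lncrnas)
  ct <- loci_tibble(coding)
  if (nrow(lt) == 0 || nrow(ct) == 0) {
    return(tibble::tibble(lncrna_id = character(), gene_id = character(),
                          distance = integer()))
  }
  lg <- GenomicRanges::GRanges(lt$chrom, IRanges::IRanges(lt$start + 1L, lt$end))
  cg <- GenomicRanges::GRanges(ct$chrom, IRanges::IRanges(ct$start + 1L, ct$end))
  hits <- GenomicRanges::findOverlaps(lg, cg, maxgap = window,
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  gap_right <- ct$start[si] - lt$end[qi]   # gene downstream of lncRNA
  gap_left <- lt$start[qi] - ct$end[si]    # gene upstream of lncRNA
  dist <- ifelse(gap_right > 0, gap_right, ifelse(gap_left > 0, -gap_left, 0L))
  keep <- abs(dist) <= window
  tibble::tibble(
    lncrna_id = lt$transcript_id[qi][keep],
    gene_id = ct$transcript_id[si][keep],
    distance = as.integer(dist[keep])
  ) |> dplyr::arrange(.data$lncrna_id, .data$distance, .data$gene_id)
}

#' Expression correlation of lncRNA/neighbour pairs
#'
#' Pearson correlation of the two transcripts' normalized profiles
#' (z-scored log10(FPKM + pseudocount) across the nine samples). Pairs with
#' `r >= pos_threshold` are called `positive`, `r <= neg_threshold`
#' `negative`, the rest `none`; a pair in which either member has a flat
#' profile gets `r = NA` and call `none`.
#'
#' @param pairs Tibble from [neighbour_pairs()].
#' @param expr Expression tibble covering both pair members.
#' @param pos_threshold,neg_threshold Correlation call thresholds
#'   (defaults +0.8 / -0.8).
#' @param pseudocount FPKM pseudocount before the log.
#' @return `pairs` with columns `r` and `call` added.
#' @export
pair_correlation <- function(pairs, expr, pos_threshold = 0.8,
                             neg_threshold = -0.8, pseudocount = 0.1) {
  ids <- unique(c(pairs$lncrna_id, pairs$gene_id))
  prof <- normalize_profiles(expr, ids, pseudocount)
  m <- profiles_matrix(prof)
  flat <- rowSums(m != 0) == 0
  r <- purrr::map2_dbl(pairs$lncrna_id, pairs$gene_id, function(a, b) {
    if (flat[a] || flat[b]) return(NA_real_)
    cor(m[a, ], m[b, ])
  })
  pairs$r <- r
  pairs$call <- factor(
    dplyr::case_when(
      is.na(r) ~ "none",
      r >= pos_threshold ~ "positive",
      r <= neg_threshold ~ "negative",
      TRUE ~ "none"
    ),
    levels = c("positive", "negative", "none")
  )
  pairs
}

#' Median normalized profile per cluster
#'
#' The per-sample median of the normalized profiles of a set of
#' transcripts, one row per cluster -- the summary used to draw
#' cluster-level expression shapes.
#'
#' @param expr Expression tibble.
#' @param assignment Tibble with `transcript_id` and `cluster`.
#' @param pseudocount FPKM pseudocount before the log.
#' @return A tibble: `cluster` plus nine median z-score columns.
#' @export
cluster_median_profiles <- function(expr, assignment, pseudocount = 0.1) {
  prof <- normalize_profiles(expr, unique(assignment$transcript_id), pseudocount)
  prof |>
    dplyr::inner_join(assignment[, c("transcript_id", "cluster")],
                      by = "transcript_id") |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(sample_names()), median),
                     .groups = "drop")
}
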