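#' Read a GTF transcript annotation
#'
#' Parses an Ensembl-dialect GTF and returns one row per transcript with its
#' exon structure. GTF's 1-based closed coordinates are converted at this
#' boundary to the 0-based half-open convention used everywhere inside the
#' package, so a GTF exon `1..100` becomes the interval `[0, 100)` of length
#' 100.
#'
#' The annotated-coding vs novel status of each transcript is taken from the
#' attribute named by `biotype_attr`; transcripts lacking the attribute are
#' classified `"novel"` (assembled transcripts typically carry no biotype).
#'
#' @param path Path to a GTF file.
#' @param biotype_attr Name of the GTF attribute carrying the biotype
#'   (default `"biotype"`). Values other than `"annotated_coding"` map to
#'   `"novel"`.
#' @return A tibble with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand` (`+`, `-` or `.`), `biotype` (`annotated_coding` or `novel`),
#'   `exons` (list column of two-column integer matrices `start`,`end` in
#'   0-based half-open coordinates, sorted, non-overlapping) and `length`
#'   (spliced length in nt).
#' @export
read_gtf <- function(path, biotype_attr = "biotype") {
  if (!validate_gtf_lines(path)) return(empty_transcripts())
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  df <- df[df$type == "exon", , drop = FALSE]
  if (nrow(df) == 0) return(empty_transcripts())
  if (anyNA(df$transcript_id)) {
    abort("GTF exon feature without a transcript_id attribute")
  }
  biotype <- if (biotype_attr %in% names(df)) as.character(df[[biotype_attr]]) else NA_character_
  df$`.biotype` <- ifelse(!is.na(biotype) & biotype == "annotated_coding",
                          "annotated_coding", "novel")
  # GRanges is 1-based closed; internal convention is 0-based half-open
  df$start0 <- df$start - 1L
  df$end0 <- df$end
  ord <- order(df$transcript_id, df$start0)
  df <- df[ord, , drop = FALSE]
  split_idx <- split(seq_len(nrow(df)), df$transcript_id)
  tx <- purrr::imap(split_idx, function(idx, tid) {
    d <- df[idx, , drop = FALSE]
    ex <- cbind(start = as.integer(d$start0), end = as.integer(d$end0))
    check_exons(ex, tid)
    tibble::tibble(
      transcript_id = tid,
      gene_id = as.character(d$gene_id[1]),
      chrom = as.character(d$seqnames[1]),
      strand = as.character(d$strand[1]),
      biotype = d$`.biotype`[1],
      exons = list(ex),
      length = sum(ex[, "end"] - ex[, "start"])
    )
  })
  out <- purrr::list_rbind(tx)
  out$strand[out$strand == "*"] <- "."
  out
}

empty_transcripts <- function() {
  tibble::tibble(
    transcript_id = character(), gene_id = character(), chrom = character(),
    strand = character(), biotype = character(), exons = list(),
    length = integer()
  )
}

check_exons <- function(ex, tid) {
  if (any(ex[, "end"] <= ex[, "start"])) {
    abort(paste0("transcript ", tid, ": exon with end <= start"))
  }
  if (nrow(ex) > 1 && any(ex[-1, "start"] < ex[-nrow(ex), "end"])) {
    abort(paste0("transcript ", tid, ": overlapping exons"))
  }
  invisible(ex)
}

# Fast structural scan so malformed lines are reported with their number;
# the real parse is delegated to rtracklayer. Returns FALSE for a file with
# no feature lines.
validate_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  if (length(body) == 0) return(FALSE)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- body[nfield < 9]
  if (length(bad) > 0) {
    abort(paste0("malformed GTF line ", bad[1], ": expected 9 tab-separated fields"))
  }
  TRUE
}

#' Write transcripts to GTF
#'
#' Inverse of [read_gtf()]: internal 0-based half-open exons are written as
#' 1-based closed GTF coordinates with `transcript_id`, `gene_id` and
#' `biotype` attributes. `read_gtf(write_gtf(x)) == x` up to row order.
#'
#' @param transcripts A transcript tibble as returned by [read_gtf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path) {
  lines <- purrr::pmap(
    list(transcripts$transcript_id, transcripts$gene_id, transcripts$chrom,
         transcripts$strand, transcripts$biotype, transcripts$exons),
    function(tid, gid, chrom, strand, biotype, ex) {
      sprintf(
        '%s\tendosclust\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; biotype "%s";',
        chrom, ex[, "start"] + 1L, ex[, "end"],
        if (strand == ".") "." else strand, gid, tid, biotype
      )
    }
  )
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Read and write BED interval files
#'
#' BED3/BED6 files are read into a peak tibble keeping BED's native 0-based
#' half-open coordinates, sorted by chromosome then start.
#' `read_bed(write_bed(x))` reproduces `x` exactly.
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `chrom`, `start`, `end` and, when present
#'   in the file, `name` and `score`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  gr <- rtracklayer::import(path, format = "bed")
  out <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if ("name" %in% names(mc) && !all(is.na(mc$name))) out$name <- as.character(mc$name)
  if ("score" %in% names(mc) && !all(is.na(mc$score))) out$score <- as.numeric(mc$score)
  if (any(out$start >= out$end)) abort("BED interval with start >= end")
  dplyr::arrange(out, .data$chrom, .data$start, .data$end)
}

#' @param peaks A peak tibble (`chrom`, `start`, `end`, optional `name`,
#'   `score`).
#' @rdname read_bed
#' @export
write_bed <- function(peaks, path) {
  if (any(peaks$start >= peaks$end)) abort("BED interval with start >= end")
  if ("name" %in% names(peaks)) {
    score <- if ("score" %in% names(peaks)) peaks$score else rep(0, nrow(peaks))
    lines <- sprintf("%s\t%d\t%d\t%s\t%g\t.", peaks$chrom, peaks$start,
                     peaks$end, peaks$name, score)
  } else {
    lines <- sprintf("%s\t%d\t%d", peaks$chrom, peaks$start, peaks$end)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an FPKM expression table
#'
#' Reads a TSV whose first column is `transcript_id` and whose remaining
#' header names are exactly the nine samples of the design (see
#' [sample_keys()]); columns are reordered to canonical order. Duplicate
#' transcript ids, missing or extra sample columns, and negative values are
#' errors.
#'
#' @param path Path to a tab-separated table.
#' @return An expression tibble: `transcript_id` plus nine FPKM columns.
#' @export
read_expression <- function(path) {
  expr <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(expr)[1] <- "transcript_id"
  expr$transcript_id <- as.character(expr$transcript_id)
  check_expression(expr)
  expr[, c("transcript_id", sample_names())]
}

#' @rdname read_expression
#' @param expr An expression tibble.
#' @export
write_expression <- function(expr, path) {
  check_expression(expr)
  readr::write_tsv(expr[, c("transcript_id", sample_names())], path, progress = FALSE)
  invisible(path)
}

#' Read gene catalogues and GO maps
#'
#' `read_catalog()` reads a one-column list of gene/transcript ids (TF, MEG
#' or PEG catalogues) into a unique character vector. `read_go_map()` reads
#' a two-column TSV (`term`, `gene`) mapping GO terms to genes; a gene
#' annotated to several terms appears once per term.
#'
#' @param path Path to the file.
#' @return `read_catalog()`: a character vector of unique ids.
#'   `read_go_map()`: a tibble with columns `term` and `gene`, distinct rows.
#' @export
read_catalog <- function(path) {
  ids <- readLines(path, warn = FALSE)
  ids <- ids[nzchar(ids) & !grepl("^#", ids)]
  unique(ids)
}

#' @rdname read_catalog
#' @export
read_go_map <- function(path) {
  map <- readr::read_tsv(path, col_names = c("term", "gene"),
                         col_types = "cc", comment = "#", progress = FALSE)
  if (nrow(map) > 0 && map$term[1] == "term" && map$gene[1] == "gene") {
    map <- map[-1, ]
  }
  dplyr::distinct(map)
}

#' Read a FASTA file of transcript sequences
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return A named character vector, one spliced sense-strand sequence per
#'   transcript id.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  setNames(as.character(seqs), names(seqs))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 70)
  invisible(path)
}

#' Cross-validate a pipeline input bundle
#'
#' Checks that the files of an input bundle exist and cross-reference: every
#' novel transcript has an expression row and (if a FASTA is given) a
#' sequence of matching spliced length.
#'
#' @param gtf,expr Paths to the annotation GTF and the expression TSV
#'   (required).
#' @param fasta,peaks Optional paths to transcript FASTA and H3K27me3 BED.
#' @return A tibble of check results (`check`, `ok`, `detail`), invisibly;
#'   any failed check raises an error.
#' @export
validate_bundle <- function(gtf, expr, fasta = NULL, peaks = NULL) {
  checks <- list()
  tx <- read_gtf(gtf)
  em <- read_expression(expr)
  novel <- tx$transcript_id[tx$biotype == "novel"]
  missing_expr <- setdiff(novel, em$transcript_id)
  checks$expression_rows <- c(
    ok = length(missing_expr) == 0,
    detail = paste0(length(missing_expr), " novel transcripts without expression row")
  )
  if (!is.null(fasta)) {
    seqs <- read_fasta(fasta)
    with_seq <- intersect(tx$transcript_id, names(seqs))
    lens <- tx$length[match(with_seq, tx$transcript_id)]
    bad <- sum(nchar(seqs[with_seq]) != lens)
    checks$sequence_lengths <- c(
      ok = bad == 0,
      detail = paste0(bad, " sequences with length != spliced exon length")
    )
  }
  if (!is.null(peaks)) {
    pk <- read_bed(peaks)
    checks$peaks_on_known_chroms <- c(
      ok = all(pk$chrom %in% tx$chrom),
      detail = "peak chromosomes present in annotation"
    )
  }
  out <- tibble::tibble(
    check = names(checks),
    ok = purrr::map_lgl(checks, ~ as.logical(.x[["ok"]])),
    detail = purrr::map_chr(checks, ~ .x[["detail"]])
  )
  if (!all(out$ok)) {
    abort(paste0("bundle validation failed: ",
                 paste(out$check[!out$ok], collapse = ", ")))
  }
  invisible(out)
}
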