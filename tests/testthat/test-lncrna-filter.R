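test_that("expression filter is a strict > 0.1 on the per-transcript maximum", {
  tx <- make_tx(c("a", "b", "c"), "chr1", c(0L, 1000L, 2000L),
                c(300L, 1300L, 2300L))
  expr <- make_expr(list(
    a = rep(0, 9),
    b = c(0.1, rep(0, 8)),
    c = c(0.11, rep(0, 8))
  ))
  expect_equal(filter_expression(tx, expr), "c")
  expect_error(filter_expression(make_tx("zz", "chr1", 0L, 100L), expr),
               "no expression row")
})

test_that("annotation overlap is exonic, >= 1 bp, half-open; intronic containment survives", {
  coding <- tibble::tibble(
    transcript_id = "cod1", gene_id = "cod1", chrom = "chr1", strand = "+",
    biotype = "annotated_coding",
    exons = list(cbind(start = c(100L, 500L), end = c(200L, 700L))),
    length = 300L
  )
  novel <- make_tx(c("hit", "abut", "intronic", "far"), "chr1",
                   c(150L, 200L, 250L, 5000L), c(160L, 300L, 400L, 5300L))
  surv <- filter_annotation_overlap(novel, coding)
  expect_setequal(surv, c("abut", "intronic", "far"))

  # random instances agree with an all-pairs oracle
  set.seed(41)
  nov <- random_intervals(60)
  ann <- random_intervals(40)
  nov_tx <- make_tx(nov$transcript_id, nov$chrom, nov$start, nov$end)
  ann_tx <- make_tx(paste0("a", ann$transcript_id), ann$chrom, ann$start,
                    ann$end, biotype = "annotated_coding")
  removed_oracle <- naive_overlap_ids(nov, ann)
  expect_setequal(filter_annotation_overlap(nov_tx, ann_tx),
                  setdiff(nov$transcript_id, removed_oracle))
})

test_that("length filter keeps >= 200 nt of spliced length", {
  tx <- tibble::tibble(
    transcript_id = c("l199", "l200", "multi"),
    gene_id = c("l199", "l200", "multi"), chrom = "chr1", strand = ".",
    biotype = "novel",
    exons = list(cbind(start = 0L, end = 199L),
                 cbind(start = 0L, end = 200L),
                 cbind(start = c(0L, 400L), end = c(150L, 460L))),
    length = c(199L, 200L, 210L)
  )
  expect_setequal(filter_length(tx), c("l200", "multi"))
})

test_that("longest_orf matches its definition on constructed cases", {
  expect_equal(longest_orf("ATGTAA"), 1)
  expect_equal(longest_orf("CCCCCCCCC"), 0)     # no ATG
  expect_equal(longest_orf("ATGAAACCC"), 0)     # ATG without a stop
  expect_equal(longest_orf("ATGNNNTAA"), 2)     # N codon is a plain residue
  expect_equal(longest_orf("NATGTAA"), 1)       # frame shift still found
  expect_equal(longest_orf(""), 0)
  # reverse strand: revcomp of ATG AAA TAA
  expect_equal(longest_orf("TTATTTCAT"), 2)
})

test_that("longest_orf equals the brute-force ATG scan on random sequences", {
  set.seed(97)
  for (i in 1:6) {
    s <- random_seq(3000)
    expect_equal(longest_orf(s), brute_longest_orf(s), label = paste("seq", i))
  }
})

test_that("coding-potential filter removes ORFs of >= 100 aa, boundary inclusive", {
  make_orf_seq <- function(aa) {
    body <- paste(rep("GCT", aa - 1), collapse = "")
    paste0("CC", "ATG", body, "TAA", "CC")
  }
  tx <- make_tx(c("aa99", "aa100"), "chr1", c(0L, 1000L),
                c(400L, 1400L),
                sequence = c(make_orf_seq(99), make_orf_seq(100)))
  expect_equal(longest_orf(tx$sequence[1]), 99)
  expect_equal(longest_orf(tx$sequence[2]), 100)
  expect_equal(filter_coding_potential(tx), "aa99")
})

test_that("blacklist filter removes by interval coverage and by shared 50-mer", {
  set.seed(13)
  te_seq <- random_seq(300)
  inside <- make_tx("inside", "chr1", 1000L, 1400L,
                    sequence = random_seq(400))
  clean <- make_tx("clean", "chr2", 0L, 400L, sequence = random_seq(400))
  shares60 <- make_tx("shares60", "chr3", 0L, 400L,
                      sequence = paste0(substr(te_seq, 1, 60), random_seq(340)))
  shares49 <- make_tx("shares49", "chr3", 1000L, 1400L,
                      sequence = paste0(substr(te_seq, 100, 148), random_seq(351)))
  novel <- dplyr::bind_rows(inside, clean, shares60, shares49)
  intervals <- tibble::tibble(chrom = "chr1", start = 900L, end = 1500L)
  surv <- filter_blacklist(novel, blacklist_intervals = intervals,
                           blacklist_seqs = c(te1 = te_seq))
  expect_setequal(surv, c("clean", "shares49"))
})

test_that("the filter chain recovers the planted lncRNA set and audits the funnel", {
  b <- noiseless_bundle()
  res <- run_lncrna_pipeline(b$transcripts, b$expr,
                             blacklist_intervals = b$blacklist_intervals,
                             blacklist_seqs = b$blacklist_seqs)
  truth_lnc <- b$truth$transcript_id[b$truth$is_true_lncrna]
  expect_setequal(res$lncrna_ids, truth_lnc)

  a <- res$audit
  expect_equal(a$n_out, a$n_in - a$n_removed)
  expect_equal(a$n_in[-1], a$n_out[-nrow(a)])       # stages telescope
  expect_equal(a$n_in[1], sum(b$transcripts$biotype == "novel"))
  expect_equal(a$n_out[nrow(a)], length(truth_lnc))

  # each stage removes exactly its designated confounder class
  class_of <- setNames(b$truth$class, b$truth$transcript_id)
  expected_class <- c(expression = "low_expression",
                      annotation_overlap = "annot_overlap",
                      length = "short", coding_potential = "long_orf",
                      blacklist = "blacklist")
  for (i in seq_len(nrow(a))) {
    removed <- a$removed[[i]]
    expect_true(all(class_of[removed] == expected_class[[a$stage[i]]]),
                label = a$stage[i])
  }
})

test_that("the filter chain is monotone and invariant to input order", {
  b <- noiseless_bundle()
  res <- run_lncrna_pipeline(b$transcripts, b$expr,
                             blacklist_intervals = b$blacklist_intervals,
                             blacklist_seqs = b$blacklist_seqs)
  novel_ids <- b$transcripts$transcript_id[b$transcripts$biotype == "novel"]
  expect_true(all(res$lncrna_ids %in% novel_ids))

  set.seed(5)
  shuffled <- b$transcripts[sample.int(nrow(b$transcripts)), ]
  res2 <- run_lncrna_pipeline(shuffled, b$expr,
                              blacklist_intervals = b$blacklist_intervals,
                              blacklist_seqs = b$blacklist_seqs)
  expect_setequal(res2$lncrna_ids, res$lncrna_ids)

  empty <- run_lncrna_pipeline(
    b$transcripts[b$transcripts$biotype == "annotated_coding", ], b$expr)
  expect_equal(empty$lncrna_ids, character())
  expect_true(all(empty$audit$n_in == 0))
})
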