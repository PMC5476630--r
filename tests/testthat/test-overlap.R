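test_that("locus/peak overlap is half-open and agrees with the all-pairs oracle", {
  loci <- tibble::tibble(transcript_id = c("in", "abut"),
                         chrom = "chr1", start = c(100L, 100L),
                         end = c(500L, 200L))
  peaks <- tibble::tibble(chrom = "chr1", start = c(200L), end = c(300L))
  expect_equal(overlap_loci(loci, peaks), "in")

  set.seed(23)
  loci_r <- random_intervals(1000, chroms = paste0("chr", 1:3))
  peaks_r <- random_intervals(1000, chroms = paste0("chr", 1:3))
  expect_setequal(
    overlap_loci(loci_r, peaks_r[, c("chrom", "start", "end")]),
    naive_overlap_ids(loci_r, peaks_r)
  )
})

test_that("peak association finds planted preferential overlap and not its absence", {
  b <- generate_bundle(simulation_config(seed = 61, n_coding = 300,
                                         n_novel = 200,
                                         peak_assoc_prob = 0.8,
                                         peak_background_prob = 0.1))
  reg_lnc <- b$truth$transcript_id[b$truth$is_true_lncrna & b$truth$regulated]
  group <- b$transcripts[b$transcripts$transcript_id %in% reg_lnc, ]
  background <- b$transcripts[!b$transcripts$transcript_id %in% reg_lnc, ]
  rep <- overlap_association(group, background, b$peaks)
  expect_lt(rep$test$p, 0.01)
  expect_gt(rep$groups$fraction[1], rep$groups$fraction[2])

  # two groups drawn from the same loci: no association signal
  same <- overlap_association(background[1:150, ], background[151:300, ],
                              b$peaks)
  expect_gt(same$test$p, 0.01)
  expect_error(overlap_association(group[0, ], background, b$peaks),
               "non-empty")
})

test_that("neighbour pairing is window-inclusive, signed, and mirror-symmetric", {
  lnc <- make_tx("lnc1", "chr1", 20000L, 21000L)
  genes <- make_tx(c("gUp", "gDownBoundary", "gTooFar", "gOverlap", "gOtherChr"),
                   c("chr1", "chr1", "chr1", "chr1", "chr2"),
                   c(5000L, 31000L, 31001L, 20500L, 20000L),
                   c(10000L, 32000L, 32001L, 22000L, 21000L),
                   biotype = "annotated_coding")
  pairs <- neighbour_pairs(lnc, genes, window = 10000L)
  expect_setequal(pairs$gene_id, c("gUp", "gDownBoundary", "gOverlap"))
  expect_equal(pairs$distance[pairs$gene_id == "gUp"], -10000L)
  expect_equal(pairs$distance[pairs$gene_id == "gDownBoundary"], 10000L)
  expect_equal(pairs$distance[pairs$gene_id == "gOverlap"], 0L)

  # mirror the chromosome: same pairs, distances negated
  L <- 50000L
  mirror <- function(tx) {
    tx$exons <- purrr::map(tx$exons, function(ex) {
      cbind(start = L - rev(ex[, "end"]), end = L - rev(ex[, "start"]))
    })
    tx
  }
  mp <- neighbour_pairs(mirror(lnc), mirror(genes), window = 10000L)
  expect_setequal(mp$gene_id, pairs$gene_id)
  expect_equal(mp$distance[match(pairs$gene_id, mp$gene_id)], -pairs$distance)
})

test_that("planted neighbour geometry is recovered from the bundle", {
  b <- noiseless_bundle()
  lnc_ids <- b$truth$transcript_id[b$truth$is_true_lncrna]
  pairs <- neighbour_pairs(
    b$transcripts[b$transcripts$transcript_id %in% lnc_ids, ],
    b$transcripts[b$transcripts$biotype == "annotated_coding", ])
  planted <- b$truth[!is.na(b$truth$neighbour_gene), ]
  found <- dplyr::inner_join(planted, pairs,
                             by = c(transcript_id = "lncrna_id",
                                    neighbour_gene = "gene_id"))
  expect_equal(nrow(found), nrow(planted))
  expect_equal(abs(found$distance), found$neighbour_distance)
})

test_that("pair correlation calls follow the thresholds and sampling behaviour", {
  v <- c(1, 5, 2, 8, 3, 9, 4, 7, 6)
  # b = 3v: identical shape after the log (scaling is exact on log scale);
  # c = 1/v: exact negation of the log profile
  expr <- make_expr(list(a = v, b = v * 3, c = 1 / v, flat = rep(2, 9)))
  pairs <- tibble::tibble(lncrna_id = c("a", "a", "a"),
                          gene_id = c("b", "c", "flat"),
                          distance = 0L)
  got <- pair_correlation(pairs, expr, pseudocount = 1e-12)
  expect_equal(got$r[1], 1)
  expect_equal(got$r[2], -1, tolerance = 1e-6)
  expect_equal(as.character(got$call), c("positive", "negative", "none"))
  expect_true(is.na(got$r[3]))

  set.seed(3)
  n <- 1000
  ids <- sprintf("r%04d", 1:(2 * n))
  prof <- purrr::map(ids, ~ 10^rnorm(9))
  names(prof) <- ids
  expr_big <- make_expr(prof)
  pairs_big <- tibble::tibble(lncrna_id = ids[1:n],
                              gene_id = ids[(n + 1):(2 * n)], distance = 0L)
  rs <- pair_correlation(pairs_big, expr_big)$r
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("cluster median profiles summarise member shapes", {
  b <- noiseless_bundle()
  reg <- b$truth[b$truth$regulated & b$truth$class == "coding", ]
  asn <- tibble::tibble(transcript_id = reg$transcript_id,
                        cluster = reg$cluster)
  med <- cluster_median_profiles(b$expr, asn)
  expect_equal(nrow(med), length(unique(reg$cluster)))
  betl_cl <- b$patterns$cluster[b$patterns$name == "BETL_up"]
  row <- med[med$cluster == betl_cl, sample_names()]
  betl_cols <- sample_keys()$sample[sample_keys()$tissue == "BETL"]
  expect_true(min(row[, betl_cols]) > max(row[, setdiff(sample_names(), betl_cols)]))
})
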