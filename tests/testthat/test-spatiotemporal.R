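test_that("tissue and stage profiles average FPKM + pseudocount per group", {
  expr <- make_expr(list(
    const = rep(5, 9),
    onehot = c(9, rep(0, 8))  # expressed in BETL08 only
  ))
  tp <- tissue_profile(expr, pseudocount = 0.1)
  expect_equal(unlist(tp[tp$transcript_id == "const", c("BETL", "AL", "SE")]),
               c(BETL = 5.1, AL = 5.1, SE = 5.1))
  # one-hot: BETL mean = (9 + 0.1*3)/3, others = 0.1
  expect_equal(tp$BETL[tp$transcript_id == "onehot"], (9 + 0.3) / 3)
  expect_equal(tp$AL[tp$transcript_id == "onehot"], 0.1)

  sp <- stage_profile(expr, pseudocount = 0.1)
  expect_equal(sp$dap8[sp$transcript_id == "onehot"], (9 + 0.3) / 3)
  expect_equal(sp$dap12[sp$transcript_id == "onehot"], 0.1)
})

test_that("profiles are invariant to sample-column reordering", {
  b <- noiseless_bundle()
  expr <- b$expr[1:20, ]
  perm <- expr[, c("transcript_id", sample(sample_names()))]
  expect_equal(tissue_profile(perm), tissue_profile(expr))
  expect_equal(stage_profile(perm), stage_profile(expr))
})

test_that("spatial calls apply the one-vs-rest 4-fold rule with inclusive boundary", {
  eps <- 1e-6
  mk <- function(betl, al, se) {
    make_expr(list(x = rep(c(betl, al, se), each = 3)))
  }
  p <- fold_params(pseudocount = eps, expression_floor = 1.0)
  up <- call_spatial(mk(8.1, 2, 2), p)
  expect_equal(up$spatial_up[[1]], "BETL")
  expect_equal(up$spatial_down[[1]], character())

  none <- call_spatial(mk(5, 5, 5), p)
  expect_false(none$spatial)

  # FPKM chosen so the pseudocount-shifted means are exactly (4, 1, 1)
  boundary <- call_spatial(mk(4 - eps, 1 - eps, 1 - eps), p)
  expect_equal(boundary$spatial_up[[1]], "BETL")
  strict <- call_spatial(mk(4 - eps, 1 - eps, 1 - eps),
                         fold_params(pseudocount = eps, expression_floor = 1.0,
                                     inclusive = FALSE))
  expect_false(strict$spatial)

  dn <- call_spatial(mk(1, 8.1, 8.1), p)
  expect_equal(dn$spatial_down[[1]], "BETL")

  floor_block <- call_spatial(mk(0.8, 0.1, 0.1), p)  # max FPKM below 1.0
  expect_false(floor_block$spatial)
})

test_that("temporal calls mirror spatial calls under the tissue/stage exchange", {
  eps <- 1e-6
  # 8-DAP-up: samples at DAP 8 high in all tissues
  v <- ifelse(sample_keys()$dap == 8, 8.1, 2)
  expr <- make_expr(list(x = v))
  p <- fold_params(pseudocount = eps, expression_floor = 1.0)
  tm <- call_temporal(expr, p)
  expect_equal(tm$temporal_up[[1]], "8")
  sp <- call_spatial(expr, p)
  expect_false(sp$spatial)

  zero <- call_temporal(make_expr(list(x = rep(0, 9))), p)
  expect_false(zero$temporal)
})

test_that("calls are invariant to global rescaling and row order", {
  b <- noiseless_bundle()
  coding_ids <- b$transcripts$transcript_id[b$transcripts$biotype == "annotated_coding"]
  expr <- b$expr[b$expr$transcript_id %in% coding_ids[1:60], ]
  p <- fold_params()
  base <- regulation_calls(expr, p)

  scaled <- expr
  scaled[sample_names()] <- scaled[sample_names()] * 7
  p_scaled <- fold_params(pseudocount = p$pseudocount * 7,
                          expression_floor = p$expression_floor * 7)
  expect_equal(regulation_calls(scaled, p_scaled), base)

  set.seed(2)
  shuf <- expr[sample.int(nrow(expr)), ]
  reshuffled <- regulation_calls(shuf, p)
  expect_equal(reshuffled[match(base$transcript_id,
                                reshuffled$transcript_id), ], base)
})

test_that("noise-free planted transcripts are called exactly as planted", {
  b <- noiseless_bundle()
  coding_ids <- b$transcripts$transcript_id[b$transcripts$biotype == "annotated_coding"]
  calls <- regulation_calls(b$expr[b$expr$transcript_id %in% coding_ids, ],
                            fold_params(expression_floor = 1.0))
  tr <- b$truth[match(calls$transcript_id, b$truth$transcript_id), ]
  expect_true(all(purrr::map2_lgl(calls$spatial_up, tr$spatial_up, setequal)))
  expect_true(all(purrr::map2_lgl(calls$temporal_up, tr$temporal_up, setequal)))
  expect_true(all(lengths(calls$spatial_down) == 0))
  expect_true(all(lengths(calls$temporal_down) == 0))
  expect_equal(calls$venn == "both", lengths(tr$spatial_up) > 0 &
                 lengths(tr$temporal_up) > 0)
})

test_that("venn partition obeys set algebra and percentage bookkeeping", {
  d <- venn_partition(c("a", "b"), c("c", "d"))
  expect_equal(d$n, c(0, 2, 2))
  s_in_t <- venn_partition(c("a", "b"), c("a", "b", "c"))
  expect_equal(s_in_t$n[s_in_t$category == "spatial_only"], 0)

  vc <- venn_counts(10, 8, 14)
  expect_equal(vc$n, c(4, 6, 4))
  expect_equal(sum(vc$n), 14)
  expect_error(venn_counts(10, 8, 20), "inconsistent")
})
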