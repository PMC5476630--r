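test_that("profile normalization z-scores log10 FPKM and zeroes flat rows", {
  expr <- make_expr(list(
    flat = rep(3, 9),
    spike = c(10, rep(1, 8))
  ))
  z <- normalize_profiles(expr)
  m <- as.matrix(z[, sample_names()])
  expect_equal(unname(m[1, ]), rep(0, 9))
  expect_equal(mean(m[2, ]), 0, tolerance = 1e-12)
  expect_equal(sd(m[2, ]), 1, tolerance = 1e-12)

  # the z-score step is idempotent: re-standardizing changes nothing
  z2 <- t(apply(m[2, , drop = FALSE], 1, function(r) (r - mean(r)) / sd(r)))
  expect_equal(unname(z2[1, ]), unname(m[2, ]), tolerance = 1e-12)
})

test_that("degenerate input collapses to one unit with zero quantization error", {
  profs <- matrix(rep(c(rep(1, 5), rep(-1, 4)), 10), nrow = 10, ncol = 9,
                  byrow = TRUE)  # every profile identical
  rownames(profs) <- paste0("t", 1:10)
  m <- train_som(profs, som_config(2, 1, iterations = 500, n_restarts = 2,
                                   seed = 3))
  expect_equal(length(unique(m$assignment$cluster)), 1)
  expect_lt(m$quantization_error, 1e-6)
})

test_that("two well-separated planted prototypes are recovered exactly on a 2x1 grid", {
  set.seed(8)
  a <- matrix(rnorm(40 * 9, mean = 2, sd = 0.05), 40, 9)
  b <- matrix(rnorm(40 * 9, mean = -2, sd = 0.05), 40, 9)
  profs <- rbind(a, b)
  rownames(profs) <- paste0("t", 1:80)
  truth <- rep(1:2, each = 40)
  m <- train_som(profs, som_config(2, 1, iterations = 2000, seed = 17))
  expect_equal(mclust::adjustedRandIndex(m$assignment$cluster, truth), 1)
})

test_that("training is deterministic and keeps the best of its restarts", {
  b <- noiseless_bundle()
  prof <- normalize_profiles(
    b$expr, b$truth$transcript_id[b$truth$regulated & b$truth$class == "coding"])
  cfg <- som_config(2, 3, iterations = 2000, n_restarts = 3, seed = 21)
  m1 <- train_som(prof, cfg)
  m2 <- train_som(prof, cfg)
  expect_identical(m1$prototypes, m2$prototypes)
  expect_identical(m1$assignment, m2$assignment)
  expect_true(all(m1$quantization_error <= m1$restart_errors + 1e-12))

  expect_error(train_som(prof[1:4, ], som_config(2, 3)), "at least 6")
})

test_that("planted partitions are recovered under noise (ARI >= 0.8)", {
  bb <- generate_bundle(simulation_config(seed = 31, n_coding = 600,
                                          n_novel = 0, noise_sd = 0.3,
                                          frac_regulated_coding = 1))
  prof <- normalize_profiles(bb$expr)
  m <- train_som(prof, som_config(2, 3, iterations = 20000, n_restarts = 5,
                                  seed = 5))
  truth_cl <- bb$truth$cluster[match(m$assignment$transcript_id,
                                     bb$truth$transcript_id)]
  expect_gte(mclust::adjustedRandIndex(m$assignment$cluster, truth_cl), 0.8)
})

test_that("specificity labels read tissue, stage and direction off the prototype", {
  onehot <- rep(0, 9)
  onehot[1] <- 1
  z <- (onehot - mean(onehot)) / sd(onehot)
  protos <- rbind(z, rep(0, 9), -z)
  model <- structure(list(
    prototypes = matrix(protos, 3, 9,
                        dimnames = list(1:3, sample_names())),
    grid = tibble::tibble(cluster = 1:3, row = 1:3, col = 1L),
    assignment = tibble::tibble(transcript_id = c("a", "b", "c"),
                                cluster = c(1L, 2L, 3L), dist = 0)
  ), class = "endo_som")
  lab <- label_specificity(model, margin = 1)
  expect_equal(lab$tissue, c("BETL", NA, "BETL"))
  expect_equal(lab$tissue_direction, c("up", NA, "down"))
  expect_equal(lab$dap, c("8", NA, "8"))
  expect_equal(lab$dap_direction, c("up", NA, "down"))

  # empty clusters are skipped
  model$assignment <- model$assignment[1:2, ]
  expect_equal(label_specificity(model, margin = 1)$cluster, 1:2)
})

test_that("planted tissue patterns yield the planted count of tissue-specific clusters", {
  b <- noiseless_bundle()
  reg <- b$truth$transcript_id[b$truth$regulated & b$truth$class == "coding"]
  prof <- normalize_profiles(b$expr, reg)
  m <- train_som(prof, som_config(2, 3, iterations = 8000, n_restarts = 3,
                                  seed = 33))
  lab <- label_specificity(m)
  # planted patterns: BETL/AL/SE tissue-up plus one BETL point pattern
  expect_setequal(unique(stats::na.omit(lab$tissue)), c("BETL", "AL", "SE"))
})

test_that("heatmap leaf order places identical rows adjacent and matches hand linkage", {
  base <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  profs <- rbind(A = base, B = base + 0.001, C = rev(base))
  ord <- order_for_heatmap(profs)
  expect_equal(abs(diff(match(c("A", "B"), ord))), 1)

  # hand linkage: d(A,B) ~ 0 merges first, C joins last -> C at an end
  expect_true(match("C", ord) %in% c(1, 3))
  expect_equal(order_for_heatmap(profs[1:1, , drop = FALSE]), "A")
})
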