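#' Parameters for 4-fold regulation calling
#'
#' A transcript is called spatially regulated when one tissue's mean
#' expression differs at least `fold`-fold from the other tissues, and
#' temporally regulated symmetrically over developmental stages. Means are
#' computed on FPKM + `pseudocount` so unexpressed transcripts never divide
#' by zero; only transcripts whose maximum raw FPKM exceeds
#' `expression_floor` are eligible (1.0 for coding transcripts, 0.1 for
#' noncoding ones).
#'
#' @param fold Fold-change threshold (ratio, > 1); default 4.
#' @param pseudocount FPKM added to every value before ratios; default 0.1.
#' @param expression_floor Strict minimum of the per-transcript maximum raw
#'   FPKM for eligibility.
#' @param inclusive Whether the fold threshold is inclusive (`>=`, default)
#'   or strict (`>`).
#' @return A list of class `fold_params`.
#' @export
fold_params <- function(fold = 4, pseudocount = 0.1, expression_floor = 1.0,
                        inclusive = TRUE) {
  stopifnot(fold > 1, pseudocount > 0, expression_floor >= 0)
  structure(
    list(fold = fold, pseudocount = pseudocount,
         expression_floor = expression_floor, inclusive = inclusive),
    class = "fold_params"
  )
}

#' Per-tissue and per-stage mean expression profiles
#'
#' Collapses the nine samples to the three tissue means (`tissue_profile`)
#' or the three stage means (`stage_profile`), each the mean of the three
#' samples sharing the tissue (resp. DAP), computed on FPKM + `pseudocount`.
#'
#' @param expr Expression tibble.
#' @param pseudocount FPKM pseudocount added before averaging.
#' @return A tibble with `transcript_id` plus one mean column per tissue
#'   (`BETL`, `AL`, `SE`) or per stage (`dap8`, `dap12`, `dap16`).
#' @export
tissue_profile <- function(expr, pseudocount = 0.1) {
  m <- expr_matrix(expr) + pseudocount
  keys <- sample_keys()
  out <- tibble::tibble(transcript_id = rownames(m))
  for (t in tissue_levels()) {
    out[[t]] <- unname(rowMeans(m[, keys$sample[keys$tissue == t], drop = FALSE]))
  }
  out
}

#' @rdname tissue_profile
#' @export
stage_profile <- function(expr, pseudocount = 0.1) {
  m <- expr_matrix(expr) + pseudocount
  keys <- sample_keys()
  out <- tibble::tibble(transcript_id = rownames(m))
  for (d in dap_levels()) {
    out[[paste0("dap", d)]] <-
      unname(rowMeans(m[, keys$sample[keys$dap == d], drop = FALSE]))
  }
  out
}

# One-vs-rest 4-fold calling on a matrix of group means (rows = transcripts,
# 3 columns). Returns list(up = , down = ) of list-columns of group names.
call_one_vs_rest <- function(means, eligible, params) {
  cmp_up <- if (params$inclusive) `>=` else `>`
  cmp_dn <- if (params$inclusive) `<=` else `<`
  groups <- colnames(means)
  up <- vector("list", nrow(means))
  down <- vector("list", nrow(means))
  for (j in seq_along(groups)) {
    others <- means[, -j, drop = FALSE]
    max_other <- apply(others, 1, max)
    min_other <- apply(others, 1, min)
    is_up <- eligible & cmp_up(means[, j], params$fold * max_other)
    is_dn <- eligible & cmp_dn(means[, j], min_other / params$fold)
    for (i in which(is_up)) up[[i]] <- c(up[[i]], groups[j])
    for (i in which(is_dn)) down[[i]] <- c(down[[i]], groups[j])
  }
  up <- purrr::map(up, ~ .x %||% character())
  down <- purrr::map(down, ~ .x %||% character())
  list(up = up, down = down)
}

#' Call spatially regulated transcripts
#'
#' A tissue `t` is called up for a transcript when the transcript's mean
#' expression in `t` is at least `fold` times the larger of the other two
#' tissue means (and the transcript passes the expression floor); down when
#' it is at most `1/fold` of the smaller of the other two. At most one
#' tissue can be up and one down.
#'
#' @param expr Expression tibble.
#' @param params [fold_params()].
#' @return A tibble with `transcript_id`, list-columns `spatial_up` /
#'   `spatial_down` (tissue names) and logical `spatial`.
#' @export
call_spatial <- function(expr, params = fold_params()) {
  m <- expr_matrix(expr)
  eligible <- apply(m, 1, max) > params$expression_floor
  prof <- tissue_profile(expr, params$pseudocount)
  means <- as.matrix(prof[, tissue_levels()])
  calls <- call_one_vs_rest(means, eligible, params)
  tibble::tibble(
    transcript_id = prof$transcript_id,
    spatial_up = calls$up,
    spatial_down = calls$down,
    spatial = lengths(calls$up) + lengths(calls$down) > 0
  )
}

#' Call temporally regulated transcripts
#'
#' Symmetric to [call_spatial()] over developmental stages: stage means pool
#' the three tissues at each DAP, so a temporal call marks regulation at a
#' particular stage regardless of tissue.
#'
#' @inheritParams call_spatial
#' @return A tibble with `transcript_id`, list-columns `temporal_up` /
#'   `temporal_down` (DAP values as characters) and logical `temporal`.
#' @export
call_temporal <- function(expr, params = fold_params()) {
  m <- expr_matrix(expr)
  eligible <- apply(m, 1, max) > params$expression_floor
  prof <- stage_profile(expr, params$pseudocount)
  means <- as.matrix(prof[, paste0("dap", dap_levels())])
  colnames(means) <- as.character(dap_levels())
  calls <- call_one_vs_rest(means, eligible, params)
  tibble::tibble(
    transcript_id = prof$transcript_id,
    temporal_up = calls$up,
    temporal_down = calls$down,
    temporal = lengths(calls$up) + lengths(calls$down) > 0
  )
}

#' Combined spatio-temporal regulation calls with Venn category
#'
#' Runs [call_spatial()] and [call_temporal()] and assigns each transcript a
#' Venn category: `both` when it is spatially and temporally regulated,
#' `spatial_only`, `temporal_only`, or `none`.
#'
#' @inheritParams call_spatial
#' @return A tibble with one row per transcript: the columns of both
#'   callers plus a factor `venn`.
#' @export
regulation_calls <- function(expr, params = fold_params()) {
  sp <- call_spatial(expr, params)
  tm <- call_temporal(expr, params)
  out <- dplyr::inner_join(sp, tm, by = "transcript_id")
  out$venn <- factor(
    dplyr::case_when(
      out$spatial & out$temporal ~ "both",
      out$spatial ~ "spatial_only",
      out$temporal ~ "temporal_only",
      TRUE ~ "none"
    ),
    levels = c("both", "spatial_only", "temporal_only", "none")
  )
  out
}

#' Venn partition of spatially and temporally regulated sets
#'
#' Splits the union of the spatially and temporally regulated transcript
#' sets into `both`, `spatial_only` and `temporal_only`, with each
#' category's share of the union as a percentage.
#'
#' @param spatial_ids,temporal_ids Character vectors of transcript ids.
#' @return A tibble with columns `category`, `n`, `percent` (share of the
#'   union, rounded half away from zero) and a list-column `ids`.
#' @export
venn_partition <- function(spatial_ids, temporal_ids) {
  spatial_ids <- unique(spatial_ids)
  temporal_ids <- unique(temporal_ids)
  both <- intersect(spatial_ids, temporal_ids)
  s_only <- setdiff(spatial_ids, temporal_ids)
  t_only <- setdiff(temporal_ids, spatial_ids)
  n_union <- length(both) + length(s_only) + length(t_only)
  tibble::tibble(
    category = factor(c("both", "spatial_only", "temporal_only"),
                      levels = c("both", "spatial_only", "temporal_only")),
    n = c(length(both), length(s_only), length(t_only)),
    percent = if (n_union > 0) round_half_away(100 * .data$n / n_union) else rep(0, 3),
    ids = list(both, s_only, t_only)
  )
}

#' Venn arithmetic from printed set sizes
#'
#' Computes the `both` / `spatial_only` / `temporal_only` partition directly
#' from the sizes of the spatial set, the temporal set and their union,
#' using `|both| = |S| + |T| - |S U T|`.
#'
#' @param n_spatial,n_temporal,n_union Set sizes.
#' @return A tibble with `category`, `n` and `percent` of the union.
#' @export
venn_counts <- function(n_spatial, n_temporal, n_union) {
  if (n_union > n_spatial + n_temporal || n_union < max(n_spatial, n_temporal)) {
    abort("inconsistent set sizes: need max(|S|,|T|) <= |S U T| <= |S| + |T|")
  }
  both <- n_spatial + n_temporal - n_union
  tibble::tibble(
    category = factor(c("both", "spatial_only", "temporal_only"),
                      levels = c("both", "spatial_only", "temporal_only")),
    n = c(both, n_spatial - both, n_temporal - both),
    percent = round_half_away(100 * .data$n / n_union)
  )
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
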