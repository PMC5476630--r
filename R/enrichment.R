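#' Upper-tail hypergeometric p-value
#'
#' Probability of observing `k` or more category members in a cluster of
#' size `n` drawn without replacement from a universe of `N` transcripts of
#' which `K` belong to the category: `P(X >= k)` with
#' `X ~ Hypergeometric(N, K, n)`. Evaluated through the distribution's
#' log-space tail so small p-values keep full precision.
#'
#' @param k Observed hits in the cluster.
#' @param K Category size in the universe.
#' @param n Cluster size.
#' @param N Universe size.
#' @return The upper-tail p-value; `k = 0` gives exactly 1.
#' @export
hypergeom_upper <- function(k, K, n, N) {
  if (any(k < 0 | K < 0 | n < 0 | N < 0)) abort("negative counts")
  if (any(K > N | n > N)) abort("K and n must not exceed N")
  if (any(k > pmin(K, n))) abort("k must not exceed min(K, n)")
  exp(phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values; a thin,
#' named wrapper so the multiple-testing family used throughout the package
#' is explicit and swappable.
#'
#' @param pvals Numeric vector of p-values.
#' @return Adjusted q-values in the input order.
#' @export
bh_adjust <- function(pvals) p.adjust(pvals, method = "BH")

#' Category enrichment of co-expression clusters
#'
#' Tests every (cluster, category) pair for over-representation with the
#' upper-tail hypergeometric test, adjusting p-values by Benjamini-Hochberg
#' within each cluster (one BH family per cluster, across its categories).
#' Counts are taken within `universe`: `N = |universe|`, `K` the category
#' size in the universe, `n` the cluster size in the universe, `k` their
#' intersection.
#'
#' @param assignment Tibble with columns `transcript_id` and `cluster`
#'   (e.g. `tidy()` of an `endo_som` fit).
#' @param category_map Tibble with columns `term` and `gene`
#'   (see [read_go_map()]); a catalogue can be passed as a single term.
#' @param universe Character vector of background transcript ids.
#' @param k_min Minimum category size in the universe for a test
#'   (default 2).
#' @param alpha Significance level on q (default 0.05).
#' @return A tibble with one row per tested pair: `cluster`, `term`, `k`,
#'   `K`, `n`, `N`, `p`, `q`, `significant`.
#' @export
enrich_clusters <- function(assignment, category_map, universe,
                            k_min = 2L, alpha = 0.05) {
  universe <- unique(universe)
  N <- length(universe)
  if (N == 0) abort("empty universe")
  cat_sets <- split(category_map$gene, category_map$term)
  cat_sets <- purrr::map(cat_sets, ~ intersect(unique(.x), universe))
  cat_sets <- cat_sets[lengths(cat_sets) >= k_min]
  if (length(cat_sets) == 0) {
    return(tibble::tibble(cluster = integer(), term = character(),
                          k = integer(), K = integer(), n = integer(),
                          N = integer(), p = double(), q = double(),
                          significant = logical()))
  }
  asn <- assignment[assignment$transcript_id %in% universe, , drop = FALSE]
  clusters <- split(asn$transcript_id, asn$cluster)
  rows <- purrr::imap(clusters, function(members, cl) {
    n <- length(members)
    k <- purrr::map_int(cat_sets, ~ length(intersect(.x, members)))
    K <- lengths(cat_sets)
    p <- hypergeom_upper(k, K, n, N)
    tibble::tibble(cluster = cl, term = names(cat_sets),
                   k = unname(k), K = unname(K), n = n, N = N,
                   p = unname(p), q = bh_adjust(unname(p)))
  })
  out <- purrr::list_rbind(rows)
  out$cluster <- utils::type.convert(out$cluster, as.is = TRUE)
  out$significant <- out$q < alpha
  dplyr::arrange(out, .data$cluster, .data$q, .data$term)
}

#' Pearson chi-square test of a 2x2 contingency table
#'
#' Pearson's chi-square statistic without continuity correction on the
#' table `[a b; c d]`, via the margin closed form
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, df = 1.
#'
#' @param a,b,c,d Non-negative cell counts (row 1: a, b; row 2: c, d), or a
#'   2x2 matrix passed as `a`.
#' @return A tibble with `statistic`, `df` and `p`.
#' @export
chi_square_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0)) abort("negative cell count")
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) abort("zero margin in 2x2 table")
  total <- sum(cells)
  stat <- total * (a * d - b * c)^2 / prod(margins)
  tibble::tibble(statistic = stat, df = 1L,
                 p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Representation of a gene catalogue in a detected set
#'
#' How much of a reference catalogue (e.g. known maternally expressed
#' imprinted genes) is present in a detected transcript set, as a count and
#' a percentage rounded half away from zero (so 247 of 370 reports 67).
#'
#' @param catalog Character vector of catalogue ids.
#' @param detected Character vector of detected ids.
#' @return A tibble with `count`, `total` and `percent`.
#' @export
catalog_representation <- function(catalog, detected) {
  catalog <- unique(catalog)
  count <- length(intersect(catalog, detected))
  total <- length(catalog)
  tibble::tibble(
    count = count, total = total,
    percent = if (total > 0) round_half_away(100 * count / total) else 0
  )
}
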