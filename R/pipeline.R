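#' Run the full spatio-temporal endosperm analysis
#'
#' Orchestrates every stage on an input bundle: lncRNA filter chain,
#' 4-fold spatial/temporal calls for coding transcripts (expression floor
#' 1.0 FPKM) and lncRNAs (floor 0.1), Venn partitions, SOM clustering of
#' both transcript classes with specificity labels, GO and catalogue
#' enrichment, H3K27me3 peak overlap with chi-square association
#' (spatio-temporally regulated lncRNA loci against all other loci), and
#' lncRNA/neighbour-gene correlation. Coding and noncoding transcripts run
#' through the same caller and SOM code paths with different floors and
#' grids.
#'
#' @param bundle An `endo_bundle` (see [generate_bundle()]) or a list with
#'   the same elements assembled from files via the `read_*` functions;
#'   `go_map`, `peaks` and the catalogue elements may be `NULL`, in which
#'   case the dependent stage is skipped with a warning.
#' @param thr [filter_thresholds()] for the lncRNA filter chain.
#' @param coding_som,lnc_som [som_config()]s for the two transcript
#'   classes; defaults are a 3x7 grid (coding) and a 2x7 grid (lncRNA).
#' @param fold,pseudocount 4-fold calling parameters shared by both
#'   classes (floors differ; see above).
#' @param window Neighbour window in bp.
#' @param out_dir Optional directory where the result tables are written
#'   as TSV.
#' @return A list of class `endo_report`; see Details. `summary` is a
#'   tibble of per-stage counts.
#' @export
run_endosperm_pipeline <- function(bundle,
                                   thr = filter_thresholds(),
                                   coding_som = som_config(3, 7, seed = 11L),
                                   lnc_som = som_config(2, 7, seed = 12L),
                                   fold = 4, pseudocount = 0.1,
                                   window = 10000L,
                                   out_dir = NULL) {
  tx <- bundle$transcripts
  expr <- bundle$expr
  if (is.null(tx) || is.null(expr)) {
    abort("stage load: bundle must provide `transcripts` and `expr`")
  }
  coding <- tx[tx$biotype == "annotated_coding", , drop = FALSE]

  # -- lncRNA discovery -------------------------------------------------
  lnc <- run_lncrna_pipeline(tx, expr,
                             blacklist_intervals = bundle$blacklist_intervals,
                             blacklist_seqs = bundle$blacklist_seqs,
                             thr = thr)
  lnc_tx <- tx[tx$transcript_id %in% lnc$lncrna_ids, , drop = FALSE]

  # -- 4-fold regulation calls ------------------------------------------
  params_coding <- fold_params(fold = fold, pseudocount = pseudocount,
                               expression_floor = thr$fpkm_coding_min)
  params_lnc <- fold_params(fold = fold, pseudocount = pseudocount,
                            expression_floor = thr$fpkm_noncoding_min)
  expr_coding <- expr[expr$transcript_id %in% coding$transcript_id, ]
  expr_lnc <- expr[expr$transcript_id %in% lnc$lncrna_ids, ]
  calls_coding <- regulation_calls(expr_coding, params_coding)
  calls_lnc <- regulation_calls(expr_lnc, params_lnc)
  venn_coding <- venn_partition(
    calls_coding$transcript_id[calls_coding$spatial],
    calls_coding$transcript_id[calls_coding$temporal])
  venn_lnc <- venn_partition(
    calls_lnc$transcript_id[calls_lnc$spatial],
    calls_lnc$transcript_id[calls_lnc$temporal])

  # -- SOM clustering ----------------------------------------------------
  som_for <- function(calls, e, config, label) {
    ids <- calls$transcript_id[calls$venn != "none"]
    if (length(ids) < config$grid_rows * config$grid_cols) {
      warn(paste0("stage som_", label, ": fewer regulated transcripts (",
                  length(ids), ") than grid cells; skipped"))
      return(NULL)
    }
    train_som(normalize_profiles(e, ids), config)
  }
  som_coding <- som_for(calls_coding, expr_coding, coding_som, "coding")
  som_lnc <- som_for(calls_lnc, expr_lnc, lnc_som, "lncrna")
  labels_coding <- if (!is.null(som_coding)) label_specificity(som_coding)
  labels_lnc <- if (!is.null(som_lnc)) label_specificity(som_lnc)

  # -- enrichment --------------------------------------------------------
  expressed_coding <- {
    m <- expr_matrix(expr_coding)
    rownames(m)[apply(m, 1, max) > thr$fpkm_coding_min]
  }
  enrichment_go <- NULL
  if (!is.null(bundle$go_map) && !is.null(som_coding)) {
    enrichment_go <- enrich_clusters(som_coding$assignment, bundle$go_map,
                                     universe = expressed_coding)
  } else if (is.null(bundle$go_map)) {
    warn("stage enrichment: no GO map supplied; GO enrichment skipped")
  }
  catalogs <- purrr::compact(list(TF = bundle$tf_ids, MEG = bundle$meg_ids,
                                  PEG = bundle$peg_ids))
  catalog_repr <- purrr::imap(catalogs, function(ids, nm) {
    dplyr::mutate(catalog_representation(ids, expressed_coding),
                  catalog = nm, .before = 1)
  }) |> purrr::list_rbind()
  catalog_enrichment <- NULL
  if (length(catalogs) > 0 && !is.null(som_coding)) {
    cat_map <- purrr::imap(catalogs, ~ tibble::tibble(term = .y, gene = .x)) |>
      purrr::list_rbind()
    catalog_enrichment <- enrich_clusters(som_coding$assignment, cat_map,
                                          universe = expressed_coding)
  }

  # -- H3K27me3 overlap --------------------------------------------------
  overlap <- NULL
  if (!is.null(bundle$peaks) && nrow(bundle$peaks) > 0) {
    reg_lnc_ids <- calls_lnc$transcript_id[calls_lnc$venn != "none"]
    group <- tx[tx$transcript_id %in% reg_lnc_ids, , drop = FALSE]
    background <- tx[!tx$transcript_id %in% reg_lnc_ids, , drop = FALSE]
    if (nrow(group) > 0) {
      overlap <- overlap_association(group, background, bundle$peaks)
    } else {
      warn("stage overlap: no regulated lncRNA loci; association skipped")
    }
  } else {
    warn("stage overlap: no peaks supplied; overlap skipped")
  }

  # -- neighbour correlation --------------------------------------------
  neighbours <- neighbour_pairs(lnc_tx, coding, window = window)
  if (nrow(neighbours) > 0) {
    neighbours <- pair_correlation(neighbours, expr, pseudocount = pseudocount)
  }

  summary <- tibble::tibble(
    stage = c("transcripts", "annotated_coding", "novel", "lncrna",
              "coding_spatial", "coding_temporal", "coding_regulated",
              "lncrna_regulated", "neighbour_pairs"),
    n = c(nrow(tx), nrow(coding), sum(tx$biotype == "novel"),
          length(lnc$lncrna_ids),
          sum(calls_coding$spatial), sum(calls_coding$temporal),
          sum(calls_coding$venn != "none"), sum(calls_lnc$venn != "none"),
          nrow(neighbours))
  )

  report <- structure(
    list(
      audit = lnc$audit, lncrna_ids = lnc$lncrna_ids,
      calls_coding = calls_coding, calls_lnc = calls_lnc,
      venn_coding = venn_coding, venn_lnc = venn_lnc,
      som_coding = som_coding, som_lnc = som_lnc,
      labels_coding = labels_coding, labels_lnc = labels_lnc,
      enrichment_go = enrichment_go, catalog_representation = catalog_repr,
      catalog_enrichment = catalog_enrichment,
      overlap = overlap, neighbours = neighbours,
      summary = summary
    ),
    class = "endo_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

flatten_calls <- function(calls) {
  dplyr::mutate(
    calls,
    dplyr::across(dplyr::where(is.list),
                  ~ purrr::map_chr(.x, paste, collapse = ","))
  )
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  readr::write_tsv(dplyr::select(report$audit, -"removed"), p("lncrna_audit.tsv"),
                   progress = FALSE)
  writeLines(report$lncrna_ids, p("lncrna_ids.txt"))
  readr::write_tsv(flatten_calls(report$calls_coding), p("calls_coding.tsv"),
                   progress = FALSE)
  readr::write_tsv(flatten_calls(report$calls_lnc), p("calls_lncrna.tsv"),
                   progress = FALSE)
  if (!is.null(report$som_coding)) {
    readr::write_tsv(report$som_coding$assignment, p("clusters_coding.tsv"),
                     progress = FALSE)
  }
  if (!is.null(report$som_lnc)) {
    readr::write_tsv(report$som_lnc$assignment, p("clusters_lncrna.tsv"),
                     progress = FALSE)
  }
  if (!is.null(report$enrichment_go)) {
    readr::write_tsv(report$enrichment_go, p("enrichment_go.tsv"),
                     progress = FALSE)
  }
  if (nrow(report$neighbours) > 0) {
    readr::write_tsv(report$neighbours, p("neighbours.tsv"), progress = FALSE)
  }
  readr::write_tsv(report$summary, p("summary.tsv"), progress = FALSE)
  invisible(out_dir)
}

#' @export
print.endo_report <- function(x, ...) {
  cat("Spatio-temporal endosperm analysis\n")
  print(x$summary, n = nrow(x$summary))
  invisible(x)
}
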