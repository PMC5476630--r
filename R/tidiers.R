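#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted self-organizing map
#'
#' `tidy()` returns the per-transcript assignment (one row per profile,
#' with its best-matching cluster and the Euclidean distance to it);
#' `glance()` returns a one-row model summary.
#'
#' @param x An `endo_som` fit.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy endo_som
#' @export
tidy.endo_som <- function(x, ...) {
  dplyr::left_join(x$assignment, x$grid, by = "cluster")
}

#' @rdname tidy.endo_som
#' @method glance endo_som
#' @export
glance.endo_som <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$assignment),
    n_clusters = nrow(x$grid),
    n_empty = sum(!x$grid$cluster %in% x$assignment$cluster),
    grid_rows = x$config$grid_rows,
    grid_cols = x$config$grid_cols,
    iterations = x$config$iterations,
    n_restarts = x$config$n_restarts,
    quantization_error = x$quantization_error
  )
}

#' Tidy the prototype curves of a self-organizing map
#'
#' One row per (cluster, sample): the prototype's normalized expression,
#' with tissue and stage decoded from the sample key -- the long format
#' [autoplot.endo_som()] draws.
#'
#' @param model An `endo_som` fit.
#' @return A tibble with `cluster`, `sample`, `tissue`, `dap`, `value`.
#' @export
som_prototypes <- function(model) {
  tibble::as_tibble(model$prototypes) |>
    dplyr::mutate(cluster = model$grid$cluster) |>
    tidyr::pivot_longer(dplyr::all_of(sample_names()),
                        names_to = "sample", values_to = "value") |>
    dplyr::left_join(sample_keys(), by = "sample") |>
    dplyr::mutate(sample = factor(.data$sample, levels = sample_names()))
}
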