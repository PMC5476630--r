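#' The nine-sample endosperm design
#'
#' The experimental design crossed three endosperm cell types -- the basal
#' endosperm transfer layer (BETL), the aleurone (AL) and the starchy
#' endosperm (SE) -- with three developmental stages (8, 12 and 16 days
#' after pollination, DAP), one RNA-Seq library per combination. All
#' expression tables in this package carry exactly these nine sample
#' columns, in the canonical order BETL08, BETL12, BETL16, AL08, AL12,
#' AL16, SE08, SE12, SE16.
#'
#' @return A tibble with columns `sample`, `tissue` (factor BETL/AL/SE) and
#'   `dap` (integer 8/12/16), one row per library in canonical order.
#' @examples
#' sample_keys()
#' @export
sample_keys <- function() {
  tibble::tibble(
    sample = c("BETL08", "BETL12", "BETL16",
               "AL08", "AL12", "AL16",
               "SE08", "SE12", "SE16"),
    tissue = factor(rep(c("BETL", "AL", "SE"), each = 3),
                    levels = c("BETL", "AL", "SE")),
    dap    = rep(c(8L, 12L, 16L), times = 3)
  )
}

#' @rdname sample_keys
#' @export
sample_names <- function() sample_keys()$sample

tissue_levels <- function() c("BETL", "AL", "SE")
dap_levels <- function() c(8L, 12L, 16L)

# Extract the 9-column FPKM matrix (rows = transcripts) from an expression
# tibble, with columns coerced to canonical order.
expr_matrix <- function(expr) {
  check_expression(expr)
  m <- as.matrix(expr[, sample_names()])
  rownames(m) <- expr$transcript_id
  storage.mode(m) <- "double"
  m
}

check_expression <- function(expr) {
  if (!is.data.frame(expr) || !"transcript_id" %in% names(expr)) {
    abort("`expr` must be a data frame with a `transcript_id` column.")
  }
  missing <- setdiff(sample_names(), names(expr))
  extra <- setdiff(names(expr), c("transcript_id", sample_names()))
  if (length(missing) > 0) {
    abort(paste0("expression table is missing sample column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (length(extra) > 0) {
    abort(paste0("expression table has unexpected column(s): ",
                 paste(extra, collapse = ", ")))
  }
  if (anyDuplicated(expr$transcript_id)) {
    abort("duplicate transcript_id in expression table")
  }
  vals <- as.matrix(expr[, sample_names()])
  if (anyNA(vals) || any(vals < 0)) {
    abort("FPKM values must be non-negative and non-missing")
  }
  invisible(expr)
}
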