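#' Tidy a paired automated-vs-manual comparison
#'
#' @param x A [compare_to_manual()] result.
#' @param ... Unused.
#' @return One-row tibble with `estimate` (mean difference), `statistic`,
#'   `p.value`, `parameter` (df), `n` and `significant`.
#' @export
tidy.cyto_paired_test <- function(x, ...) {
  tibble(
    estimate = x$mean_difference,
    statistic = x$statistic,
    p.value = x$p_value,
    parameter = x$df,
    n = x$n,
    significant = x$significant,
    method = "paired t-test",
    alternative = "two.sided"
  )
}

#' @rdname tidy.cyto_paired_test
#' @export
glance.cyto_paired_test <- function(x, ...) tidy(x, ...)

#' Tidy per-object measurements of a pipeline result
#'
#' @param x A [run_pipeline()] result.
#' @param ... Unused.
#' @return The per-nucleus measurement tibble.
#' @export
tidy.cyto_result <- function(x, ...) x$objects

#' One-row summary of a pipeline result
#'
#' @param x A [run_pipeline()] result.
#' @param ... Unused.
#' @return The counts-report tibble (one row).
#' @export
glance.cyto_result <- function(x, ...) x$counts
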