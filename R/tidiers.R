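# broom-style tidiers.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an association result
#'
#' @param x A `cpacor_result` tibble.
#' @param ... Unused.
#' @return A tibble with one row per marker and broom-style column names
#'   (`term`, `estimate`, `std.error`, `p.value`, ...).
#' @method tidy cpacor_result
#' @export
tidy.cpacor_result <- function(x, ...) {
  out <- tibble::as_tibble(x)
  dplyr::rename(out, term = "marker_id", estimate = "coef",
                std.error = "se", p.value = "p")
}

#' One-line summary of an association result
#'
#' @param x A `cpacor_result` tibble.
#' @param sig_threshold Significance threshold for the hit count (default
#'   the epigenome-wide 1e-7).
#' @param ... Unused.
#' @return A one-row tibble: marker counts, genomic inflation `lambda`,
#'   minimum P and number of hits.
#' @method glance cpacor_result
#' @export
glance.cpacor_result <- function(x, sig_threshold = 1e-7, ...) {
  p <- x$p[!is.na(x$p)]
  tibble::tibble(n_markers = nrow(x),
                 n_tested = length(p),
                 lambda = if (length(p) >= 10) genomic_inflation(p) else NA_real_,
                 min_p = if (length(p)) min(p) else NA_real_,
                 n_significant = sum(p < sig_threshold))
}

#' Tidy a permutation-null summary
#'
#' @param x A `cpacor_null` object.
#' @param ... Unused.
#' @return The per-permutation lambda tibble.
#' @method tidy cpacor_null
#' @export
tidy.cpacor_null <- function(x, ...) x$lambda

#' One-line summary of a permutation null
#'
#' @param x A `cpacor_null` object.
#' @param ... Unused.
#' @return A one-row tibble with the lambda median and percentile interval.
#' @method glance cpacor_null
#' @export
glance.cpacor_null <- function(x, ...) {
  s <- x$lambda_summary
  tibble::tibble(n_perm = x$n_perm, lambda_median = s[["median"]],
                 lambda_q2.5 = s[["q2.5"]], lambda_q97.5 = s[["q97.5"]])
}

#' Tidy control-probe or residual PCs
#'
#' @param x A `control_pcs` or `residual_pcs` object.
#' @param ... Unused.
#' @return A long tibble `sample_id`, `pc`, `score`.
#' @method tidy control_pcs
#' @export
tidy.control_pcs <- function(x, ...) {
  tibble::as_tibble(x$scores, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "pc", values_to = "score")
}

#' @rdname tidy.control_pcs
#' @method tidy residual_pcs
#' @export
tidy.residual_pcs <- tidy.control_pcs

#' @method glance cpacor_fit
#' @export
glance.cpacor_fit <- function(x, ...) glance(x$result, ...)

#' @method tidy cpacor_fit
#' @export
tidy.cpacor_fit <- function(x, ...) tidy(x$result, ...)
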