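# broom-style tidiers for fitted result objects.

#' Tidy a correlation result
#'
#' @param x A `bg_cor` from [pearson_with_ci()].
#' @param ... Unused.
#' @return One-row tibble with term-level estimates (`r`, `slope`,
#'   `intercept`) and their intervals.
#' @export
tidy.bg_cor <- function(x, ...) {
  tibble::tibble(
    term = c("r", "slope", "intercept"),
    estimate = c(x$r, x$slope, x$intercept),
    conf.low = c(x$ci_lo, x$slope_lo, NA_real_),
    conf.high = c(x$ci_hi, x$slope_hi, NA_real_)
  )
}

#' @rdname tidy.bg_cor
#' @export
glance.bg_cor <- function(x, ...) {
  tibble::tibble(r = x$r, p.value = x$p_value, nobs = x$n)
}

#' Tidy a composite-score PCA
#'
#' @param x A `bg_pca` from [pca_composite()].
#' @param ... Unused.
#' @return `tidy()`: the PC1 loadings; `glance()`: variance explained and
#'   number of metrics.
#' @export
tidy.bg_pca <- function(x, ...) x$loadings

#' @rdname tidy.bg_pca
#' @export
glance.bg_pca <- function(x, ...) {
  tibble::tibble(variance_explained = x$variance_explained,
                 n_metrics = nrow(x$loadings),
                 n_subjects = nrow(x$scores))
}

#' Tidy a group comparison
#'
#' @param x A `bg_comparison` from [group_compare()].
#' @param ... Unused.
#' @return One-row tibble with the branch taken, statistic and p value.
#' @export
tidy.bg_comparison <- function(x, ...) {
  tibble::tibble(method = x$test, statistic = x$statistic,
                 p.value = x$p_value, normal = x$normal)
}
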