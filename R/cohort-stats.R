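# Cohort-level statistics: percent changes and restoration ratios,
# afferent-function correlations, PCA composite functionality, and
# normality-gated group comparisons with Holm-Sidak correction.

#' Percent increase of one mean over another
#'
#' `100 * (a - b) / b`, reported raw and rounded half-away-from-zero to
#' integer percent (the reporting convention that reproduces printed
#' percentages from their printed inputs, e.g. 186.8 -> 187).
#'
#' @param a,b Numeric values (vectorized); `b` must be nonzero.
#' @return Tibble with `percent_raw` and `percent`.
#' @export
#' @examples
#' percent_increase(1.78, 1.26)  # 41 %
percent_increase <- function(a, b) {
  if (any(b == 0)) stop("percent increase undefined for b = 0", call. = FALSE)
  raw <- 100 * (a - b) / b
  tibble::tibble(percent_raw = raw, percent = round_half_away(raw))
}

#' Restoration ratio against a biologically intact reference
#'
#' `100 * value / intact_ref`, raw and integer-rounded.
#'
#' @param value Observed value (vectorized).
#' @param intact_ref Positive biologically intact reference value.
#' @return Tibble with `percent_raw` and `percent`.
#' @export
#' @examples
#' restoration_ratio(1.95, 3.0)  # 65 %
restoration_ratio <- function(value, intact_ref) {
  if (any(intact_ref <= 0)) {
    stop("intact reference must be positive", call. = FALSE)
  }
  raw <- 100 * value / intact_ref
  tibble::tibble(percent_raw = raw, percent = round_half_away(raw))
}

#' Pearson correlation with confidence interval and slope
#'
#' Sample Pearson `r` with a Fisher-z 95 % confidence interval and two-sided
#' p value, plus the ordinary least-squares slope `m` (and its t-based 95 %
#' interval) of `y` on `x`.
#'
#' @param data Data frame.
#' @param x,y Column names (unquoted or strings).
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble of class `bg_cor`: `r`, `ci_lo`, `ci_hi`, `slope`,
#'   `slope_lo`, `slope_hi`, `intercept`, `p_value`, `n`.
#' @export
pearson_with_ci <- function(data, x, y, conf_level = 0.95) {
  xv <- rlang::eval_tidy(rlang::enquo(x), data)
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]; yv <- yv[keep]
  n <- length(xv)
  if (n < 3) stop("need at least 3 complete observations", call. = FALSE)
  if (sd(xv) == 0 || sd(yv) == 0) {
    stop("correlation undefined: zero variance in x or y", call. = FALSE)
  }
  ct <- cor.test(xv, yv, conf.level = conf_level)
  fit <- lm(yv ~ xv)
  ci_slope <- confint(fit, "xv", level = conf_level)
  out <- tibble::tibble(
    r = unname(ct$estimate),
    ci_lo = if (!is.null(ct$conf.int)) ct$conf.int[1] else NA_real_,
    ci_hi = if (!is.null(ct$conf.int)) ct$conf.int[2] else NA_real_,
    slope = unname(coef(fit)[2]),
    slope_lo = ci_slope[1], slope_hi = ci_slope[2],
    intercept = unname(coef(fit)[1]),
    p_value = ct$p.value, n = n
  )
  class(out) <- c("bg_cor", class(out))
  out
}

#' Composite bionic-functionality score by principal component analysis
#'
#' Z-scores every metric column, reverses the sign of the columns listed in
#' `flip` (so that biomimetic features carry a consistent positive sign,
#' e.g. stair-descent negative peak power and net work), extracts the first
#' principal component from the eigen-decomposition of the correlation
#' matrix, and orients it so the loading on `orient_on` (default the first
#' column) is positive. Missing cells are refused, not imputed.
#'
#' @param data Data frame; non-numeric columns (e.g. subject, group) are
#'   carried through to the score table.
#' @param flip Character vector of columns whose sign is reversed.
#' @param orient_on Column whose PC1 loading is forced positive.
#' @return A `bg_pca` list: `loadings` (tibble metric/loading, unit norm),
#'   `scores` (id columns + `pc1`), `variance_explained` in `[0, 1]`.
#' @export
pca_composite <- function(data, flip = character(), orient_on = NULL) {
  is_num <- vapply(data, is.numeric, logical(1))
  X <- as.matrix(data[, is_num, drop = FALSE])
  ids <- data[, !is_num, drop = FALSE]
  if (ncol(X) < 2) stop("need at least 2 metric columns", call. = FALSE)
  if (anyNA(X)) stop("missing cells are refused; complete the table first",
                     call. = FALSE)
  bad_flip <- setdiff(flip, colnames(X))
  if (length(bad_flip)) {
    stop("flip columns not found: ", paste(bad_flip, collapse = ", "),
         call. = FALSE)
  }
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    stop("constant column(s): ", paste(colnames(X)[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  X[, flip] <- -X[, flip, drop = FALSE]
  Z <- scale(X)
  eg <- eigen(cor(Z), symmetric = TRUE)
  v1 <- eg$vectors[, 1]
  if (is.null(orient_on)) orient_on <- colnames(X)[1]
  j <- match(orient_on, colnames(X))
  if (is.na(j)) stop("orient_on column not found: ", orient_on, call. = FALSE)
  if (v1[j] < 0) v1 <- -v1
  scores <- as.numeric(Z %*% v1)
  structure(
    list(loadings = tibble::tibble(metric = colnames(X), loading = v1),
         scores = dplyr::bind_cols(tibble::as_tibble(ids),
                                   tibble::tibble(pc1 = scores)),
         variance_explained = eg$values[1] / sum(eg$values)),
    class = "bg_pca")
}

#' Holm-Sidak step-down adjusted p values
#'
#' Step-down Sidak procedure: for ascending p values
#' `p_(1) <= ... <= p_(m)`, the i-th adjusted value is
#' `1 - (1 - p_(i))^(m - i + 1)`, enforced monotone nondecreasing. A family
#' of one returns the unadjusted p value.
#'
#' @param p Numeric vector of p values in one comparison family.
#' @return Adjusted p values in the original order.
#' @export
holm_sidak <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

#' Normality-gated two-group comparison
#'
#' Shapiro-Wilk normality gate (alpha = 0.05 on each group, or on the
#' paired differences): normally distributed data take a two-sided paired or
#' unpaired t-test, data violating normality take a Mann-Whitney U-test
#' (Wilcoxon signed-rank when paired). The report records which branch
#' fired.
#'
#' @param x,y Numeric vectors (each group at least 3 values).
#' @param paired Paired comparison? Requires equal lengths.
#' @param alpha Normality gate level (default 0.05).
#' @return Tibble of class `bg_comparison`: `test`, `statistic`, `p_value`,
#'   `normal`, `shapiro_p_x`, `shapiro_p_y`, `paired`, `n_x`, `n_y`.
#' @export
group_compare <- function(x, y, paired = FALSE, alpha = 0.05) {
  stopifnot(length(x) >= 3, length(y) >= 3)
  if (paired && length(x) != length(y)) {
    stop("paired comparison requires equal group lengths", call. = FALSE)
  }
  safe_shapiro <- function(v) {
    if (sd(v) == 0) 0 else shapiro.test(v)$p.value
  }
  if (paired) {
    sp_x <- safe_shapiro(x - y)
    sp_y <- NA_real_
    normal <- sp_x > alpha
  } else {
    sp_x <- safe_shapiro(x)
    sp_y <- safe_shapiro(y)
    normal <- sp_x > alpha && sp_y > alpha
  }
  if (normal) {
    ht <- t.test(x, y, paired = paired)
    test <- if (paired) "paired t-test" else "unpaired t-test"
  } else {
    ht <- suppressWarnings(wilcox.test(x, y, paired = paired, exact = FALSE))
    test <- if (paired) "Wilcoxon signed-rank" else "Mann-Whitney U"
  }
  out <- tibble::tibble(
    test = test, statistic = unname(ht$statistic), p_value = ht$p.value,
    normal = normal, shapiro_p_x = sp_x, shapiro_p_y = sp_y,
    paired = paired, n_x = length(x), n_y = length(y)
  )
  class(out) <- c("bg_comparison", class(out))
  out
}
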