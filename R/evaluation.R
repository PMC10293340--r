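#' Bland-Altman agreement analysis
#'
#' Paired-method agreement summarized as the mean difference (bias), the
#' sample SD of the differences (n-1 denominator), and the conventional 95%
#' limits of agreement `bias +/- 1.96 sd`. Percent statistics use the
#' per-pair mean of the two methods as denominator (standard ratio
#' practice); when any pairwise mean is zero the percent statistics are
#' reported as `NA` while the absolute statistics remain valid.
#'
#' @param a,b Paired measurements from the two methods (equal length,
#'   `n >= 2`, finite). Alternatively `a` may be a two-column matrix or
#'   data frame of pairs with `b` omitted.
#' @return An `agreement_report`: list with `n`, `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, and percent counterparts `bias_pct`, `sd_pct`,
#'   `loa_pct_low`, `loa_pct_high`.
#' @export
#' @examples
#' bland_altman(c(10, 20), c(12, 18))
bland_altman <- function(a, b = NULL) {
  if (is.null(b)) {
    a <- as.matrix(a)
    stopifnot(ncol(a) == 2)
    b <- a[, 2]
    a <- a[, 1]
  }
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("`a` and `b` must have equal length")
  n <- length(a)
  if (n < 2) stop("Bland-Altman analysis needs at least 2 pairs")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("paired values must be finite")
  d <- a - b
  bias <- mean(d)
  sdd <- sd(d)
  means <- (a + b) / 2
  if (any(means == 0)) {
    warning("a pairwise mean is zero; percent statistics are undefined",
            call. = FALSE)
    bias_pct <- sd_pct <- NA_real_
  } else {
    pct <- 100 * d / means
    bias_pct <- mean(pct)
    sd_pct <- sd(pct)
  }
  structure(list(n = n, bias = bias, sd_diff = sdd,
                 loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
                 bias_pct = bias_pct, sd_pct = sd_pct,
                 loa_pct_low = bias_pct - 1.96 * sd_pct,
                 loa_pct_high = bias_pct + 1.96 * sd_pct),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (n = %d)\n", x$n))
  cat(sprintf("  bias %.4g, SD %.4g, 95%% LoA [%.4g, %.4g]\n",
              x$bias, x$sd_diff, x$loa_low, x$loa_high))
  if (!is.na(x$bias_pct))
    cat(sprintf("  bias %.3g%%, SD %.3g%%, 95%% LoA [%.3g%%, %.3g%%]\n",
                x$bias_pct, x$sd_pct, x$loa_pct_low, x$loa_pct_high))
  invisible(x)
}

#' Per-case agreement table with a Bland-Altman footer
#'
#' Renders the per-case comparison between automatic and manual (or any two)
#' measurements: one row per case with both values, their difference and
#' percent difference, ordered deterministically by case label, plus the
#' overall [bland_altman()] report attached as attribute `report`.
#'
#' @param auto,manual Per-case values from the two methods (equal length).
#' @param labels Case identifiers (same length; default `1..n`).
#' @return A `data.frame` with columns `id`, `a`, `b`, `diff`, `pct_diff`
#'   and attribute `report`.
#' @export
agreement_table <- function(auto, manual, labels = seq_along(auto)) {
  if (length(auto) != length(manual))
    stop("`auto` and `manual` must have equal length")
  if (length(labels) != length(auto))
    stop("`labels` must match the number of cases")
  if (length(auto) == 0) stop("no cases supplied")
  ord <- order(labels)
  a <- as.numeric(auto)[ord]
  b <- as.numeric(manual)[ord]
  d <- a - b
  m <- (a + b) / 2
  tab <- data.frame(id = labels[ord], a = a, b = b, diff = d,
                    pct_diff = ifelse(m == 0, NA_real_, 100 * d / m))
  attr(tab, "report") <- bland_altman(a, b)
  tab
}

#' Write / read an agreement table as CSV
#'
#' @param tab Result of [agreement_table()].
#' @param path Output CSV path.
#' @return `read_agreement_csv` returns the table (without the report
#'   attribute); `write_agreement_csv` returns `path` invisibly.
#' @export
write_agreement_csv <- function(tab, path) {
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_agreement_csv
#' @export
read_agreement_csv <- function(path) {
  read.csv(path)
}
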