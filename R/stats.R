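#' Statistical battery
#'
#' The tests used on the sample-level summaries: Shapiro-Wilk normality
#' check, unpaired two-group t-tests (Welch by default) with significance at
#' p <= 0.05, two-sample Kolmogorov-Smirnov comparison of CSA
#' distributions, and families of Spearman rank correlations with Bonferroni
#' correction.
#'
#' @name statistics
NULL

#' Shapiro-Wilk normality check
#'
#' @param values Numeric vector, `n >= 3`. A constant vector has no defined
#'   statistic and is an error.
#' @return List with `W` and `p`.
#' @export
normality_check <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3L) stop("normality check needs n >= 3", call. = FALSE)
  if (length(unique(values)) == 1L) {
    stop("all values identical; normality is undefined for a constant sample",
         call. = FALSE)
  }
  s <- stats::shapiro.test(values)
  list(W = unname(s$statistic), p = s$p.value)
}

#' Unpaired two-group comparison
#'
#' Two-sided unpaired t-test; Welch's unequal-variance form by default, the
#' pooled-variance (Student) form with `var_equal = TRUE`. Significance is
#' declared at `p <= alpha` (inclusive).
#'
#' @param a,b Numeric vectors, each `n >= 2`.
#' @param var_equal Use the pooled-variance t-test.
#' @param alpha Significance level.
#' @return List with `t`, `df`, `p`, `significant`.
#' @export
compare_groups <- function(a, b, var_equal = FALSE, alpha = 0.05) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       significant = tt$p.value <= alpha)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' `D = sup |ECDF_a - ECDF_b|` with the asymptotic two-sided p-value (ties
#' permitted; the tie warning of the exact method does not apply).
#'
#' @param a,b Non-empty numeric vectors (e.g. pooled CSA lists).
#' @return List with `D` and `p`.
#' @export
ks_compare <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("empty input sample", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(kt$statistic), p = min(1, kt$p.value))
}

#' Spearman correlation family with Bonferroni correction
#'
#' Spearman's rank correlation (average ranks for ties) for each declared
#' pair of summary quantities, two-sided p-values, and the Bonferroni
#' adjustment `p_adj = min(1, m * p)` with `m` the number of pairs in the
#' family. P-values are exact (enumeration for n < 10, Edgeworth series
#' above) when there are no ties and `n <= exact_n_max`, asymptotic
#' otherwise; the method used is recorded per pair. Pairs with fewer than 4
#' complete observations are skipped with a warning.
#'
#' @param table Data.frame of sample summaries, one row per sample.
#' @param pairs List of length-2 character vectors naming column pairs; the
#'   family size `m` is the number of pairs.
#' @param exact_n_max Largest n for which the exact/Edgeworth p is used.
#' @return Data.frame: `quantity_a`, `quantity_b`, `n`, `r`, `p`, `p_adj`,
#'   `m`, `method`.
#' @export
spearman_family <- function(table, pairs, exact_n_max = 12L) {
  stopifnot(length(pairs) >= 1L)
  m <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    stopifnot(length(pr) == 2L)
    x <- table[[pr[1L]]]; y <- table[[pr[2L]]]
    if (is.null(x) || is.null(y)) {
      stop("unknown quantity in pair: ", paste(pr, collapse = " ~ "),
           call. = FALSE)
    }
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 4L) {
      warning("pair ", pr[1L], " ~ ", pr[2L], " skipped: fewer than 4 ",
              "complete observations", call. = FALSE)
      return(NULL)
    }
    x <- x[ok]; y <- y[ok]
    ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
    exact <- !ties && sum(ok) <= exact_n_max
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = exact))
    data.frame(quantity_a = pr[1L], quantity_b = pr[2L], n = sum(ok),
               r = unname(ct$estimate), p = min(1, ct$p.value),
               method = if (exact) "exact" else "asymptotic",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no pair had enough complete observations",
                         call. = FALSE)
  out$p_adj <- pmin(1, m * out$p)
  out$m <- m
  out[c("quantity_a", "quantity_b", "n", "r", "p", "p_adj", "m", "method")]
}
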