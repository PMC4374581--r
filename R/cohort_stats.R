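# Exact small-sample statistics for on-treatment percentage changes.
#
# With cohorts of n <= 8 the null distribution of the one-sample Wilcoxon
# signed-rank statistic is computed exactly by enumerating the 2^n
# equiprobable sign assignments (via the equivalent generating-function
# recursion), never by normal approximation. For a sample in which every
# change has the same sign the two-sided p is exactly 2 / 2^n: 0.0078125 at
# n = 8 and 0.015625 at n = 7.

TIMEPOINT_LEVELS <- c("baseline", "fx11", "fx21")
COHORT_PARAMETERS <- c("gtv_ct", "gtv_mr", "gtv_dw", "gtv_pet", "suvmax",
                       "adc", "pf", "pv", "ve", "ps", "ef", "ktrans")
COHORT_INTERVALS <- c("baseline-fx11", "baseline-fx21", "fx11-fx21")

#' Percentage change between two measurements
#'
#' `100 * (x2 - x1) / x1`, vectorized. A zero baseline has no defined
#' percentage change and returns `NA` with a warning (excluded downstream,
#' never imputed).
#'
#' @param x1 Baseline value(s), non-zero.
#' @param x2 Follow-up value(s).
#' @return Percentage change(s).
#' @export
percent_change <- function(x1, x2) {
  out <- 100 * (x2 - x1) / x1
  bad <- !is.na(x1) & x1 == 0
  if (any(bad)) {
    warning("percentage change undefined for zero baseline; returning NA",
            call. = FALSE)
    out[bad] <- NA_real_
  }
  out
}

# Exact distribution of 2*W (W = positive-rank sum, midranks doubled to make
# integers) over all 2^n sign assignments: counts[w + 1] = number of
# assignments with statistic w. Generating-function (shift-and-add) form of
# the full enumeration.
signed_rank_counts <- function(ranks2) {
  total <- sum(ranks2)
  counts <- c(1, numeric(total))
  for (r in ranks2) {
    shifted <- c(numeric(r), counts[seq_len(total + 1 - r)])
    counts <- counts + shifted
  }
  counts
}

#' Exact one-sample Wilcoxon signed-rank test
#'
#' Tests the null hypothesis that the median change is zero. Zeros are
#' dropped before ranking (standard convention); absolute changes are ranked
#' with midranks for ties; the null distribution of the positive-rank sum W
#' is exact over all `2^n` sign assignments. The two-sided p-value doubles
#' the smaller tail (capped at 1), which reproduces `2 / 2^n` for
#' same-signed samples; a minimum-likelihood convention (summing the
#' probability of all outcomes no more probable than the observed one) is
#' available via `two_sided = "min_likelihood"`.
#'
#' @param changes Numeric changes (typically percentages); n <= 20 after
#'   dropping exact zeros.
#' @param two_sided `"double_tail"` (default) or `"min_likelihood"`.
#' @return A list of class `signed_rank_exact`: `p.value`, `statistic` (W),
#'   `n` (non-zero changes used), `degenerate` (all changes zero).
#' @export
signed_rank_exact <- function(changes, two_sided = c("double_tail",
                                                     "min_likelihood")) {
  two_sided <- match.arg(two_sided)
  changes <- changes[!is.na(changes)]
  nonzero <- changes[changes != 0]
  n <- length(nonzero)
  if (n == 0L) {
    return(structure(list(p.value = 1, statistic = 0, n = 0L,
                          degenerate = TRUE), class = "signed_rank_exact"))
  }
  if (n > 20L)
    stop("exact enumeration supported for n <= 20 only", call. = FALSE)
  r <- rank(abs(nonzero))
  r2 <- as.integer(round(2 * r))        # midranks doubled -> integers
  w2 <- sum(r2[nonzero > 0])
  counts <- signed_rank_counts(r2)
  tot <- 2^n
  if (two_sided == "double_tail") {
    lo <- sum(counts[seq_len(w2 + 1)]) / tot
    hi <- sum(counts[(w2 + 1):length(counts)]) / tot
    p <- min(1, 2 * min(lo, hi))
  } else {
    pw <- counts[w2 + 1]
    p <- sum(counts[counts <= pw]) / tot
  }
  structure(list(p.value = p, statistic = w2 / 2, n = n, degenerate = FALSE),
            class = "signed_rank_exact")
}

#' @export
print.signed_rank_exact <- function(x, ...) {
  cat(sprintf("Exact one-sample signed-rank test: W = %.4g, n = %d, p = %.6g%s\n",
              x$statistic, x$n, x$p.value,
              if (x$degenerate) " (degenerate: all changes zero)" else ""))
  invisible(x)
}

#' Pearson correlation with a two-sided p-value
#'
#' Product-moment correlation on complete pairs; p from
#' `t = r sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom. A perfect
#' correlation (|r| = 1) gives p = 0. Zero variance in either variable makes
#' r undefined (`NA`).
#'
#' @param x,y Paired numeric vectors (>= 3 complete pairs).
#' @return A list: `r`, `p.value`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  sx <- x - mean(x); sy <- y - mean(y)
  vx <- sum(sx^2);   vy <- sum(sy^2)
  if (vx == 0 || vy == 0) {
    warning("zero variance: correlation undefined", call. = FALSE)
    return(list(r = NA_real_, p.value = NA_real_, n = n))
  }
  r <- sum(sx * sy) / sqrt(vx * vy)
  r <- max(-1, min(1, r))
  if (abs(r) >= 1 - 1e-15) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p.value = p, n = n)
}

interval_endpoints <- function(interval) {
  strsplit(interval, "-", fixed = TRUE)[[1]]
}

# records -> per-patient percentage changes of `param` over `interval`
interval_changes <- function(records, param, interval) {
  ep <- interval_endpoints(interval)
  wide <- records |>
    dplyr::select(dplyr::all_of(c("patient", "timepoint", param))) |>
    tidyr::pivot_wider(names_from = "timepoint",
                       values_from = dplyr::all_of(param))
  if (!all(ep %in% names(wide))) return(tibble::tibble(patient = character(0),
                                                       change = numeric(0)))
  x1 <- wide[[ep[1]]]; x2 <- wide[[ep[2]]]
  keep <- !is.na(x1) & !is.na(x2) & x1 != 0
  tibble::tibble(patient = wide$patient[keep],
                 change = 100 * (x2[keep] - x1[keep]) / x1[keep])
}

#' Summarize percentage changes across the cohort
#'
#' For each parameter and each timepoint interval: per-patient percentage
#' changes on complete pairs, their median / min / max, the number of
#' patients contributing, and the exact signed-rank p-value. Missing
#' modalities reduce n; nothing is imputed. Parameters absent for every
#' patient are omitted (with a message); single-patient parameters report
#' `NA` for p.
#'
#' @param records Tibble of patient-timepoint records: columns `patient`,
#'   `timepoint` (`baseline`, `fx11`, `fx21`) and one column per parameter.
#' @param parameters Parameter columns to summarize; defaults to the twelve
#'   standard imaging parameters present in `records`.
#' @param intervals Intervals to summarize (default all three).
#' @return Tibble: `parameter`, `interval`, `n`, `median_pct`, `min_pct`,
#'   `max_pct`, `p_value`.
#' @export
change_summary <- function(records,
                           parameters = intersect(COHORT_PARAMETERS,
                                                  names(records)),
                           intervals = COHORT_INTERVALS) {
  stopifnot(all(c("patient", "timepoint") %in% names(records)))
  records <- tibble::as_tibble(records)
  rows <- list()
  for (param in parameters) {
    if (all(is.na(records[[param]]))) {
      message("parameter '", param, "' missing for all patients; row omitted")
      next
    }
    for (interval in intervals) {
      ch <- interval_changes(records, param, interval)
      n <- nrow(ch)
      if (n == 0) next
      p <- if (n >= 2) signed_rank_exact(ch$change)$p.value else NA_real_
      rows[[length(rows) + 1]] <- tibble::tibble(
        parameter = param, interval = interval, n = n,
        median_pct = median(ch$change), min_pct = min(ch$change),
        max_pct = max(ch$change), p_value = p)
    }
  }
  dplyr::bind_rows(rows)
}

#' Screen all parameter pairs for correlated percentage changes
#'
#' Computes Pearson correlations between the percentage changes of every
#' unordered pair of parameters (66 pairs for the twelve standard ones),
#' per interval, and reports the pairs with `p < alpha`. No multiplicity
#' correction is applied by default (each pair is tested at `alpha`);
#' Holm correction over each interval's pair family is available with
#' `holm = TRUE`.
#'
#' @inheritParams change_summary
#' @param alpha Significance level (default 0.05).
#' @param holm Apply Holm correction within each interval (default `FALSE`).
#' @return Tibble: `interval`, `parameter1`, `parameter2`, `n`, `r`,
#'   `p_value` for the significant pairs, ordered as computed.
#' @export
correlation_screen <- function(records,
                               parameters = intersect(COHORT_PARAMETERS,
                                                      names(records)),
                               intervals = COHORT_INTERVALS,
                               alpha = 0.05, holm = FALSE) {
  records <- tibble::as_tibble(records)
  out <- list()
  for (interval in intervals) {
    ch <- lapply(parameters, function(p)
      interval_changes(records, p, interval))
    names(ch) <- parameters
    rows <- list()
    for (i in seq_along(parameters)) {
      for (j in seq_along(parameters)) {
        if (j <= i) next
        a <- ch[[i]]; b <- ch[[j]]
        merged <- dplyr::inner_join(a, b, by = "patient",
                                    suffix = c("_1", "_2"))
        if (nrow(merged) < 3) next
        res <- tryCatch(
          suppressWarnings(pearson_with_p(merged$change_1, merged$change_2)),
          error = function(e) NULL)
        if (is.null(res) || is.na(res$r)) next
        rows[[length(rows) + 1]] <- tibble::tibble(
          interval = interval,
          parameter1 = parameters[i], parameter2 = parameters[j],
          n = res$n, r = res$r, p_value = res$p.value)
      }
    }
    tab <- dplyr::bind_rows(rows)
    if (nrow(tab) == 0) next
    if (holm) tab$p_value <- stats::p.adjust(tab$p_value, method = "holm")
    out[[interval]] <- dplyr::filter(tab, .data$p_value < alpha)
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0)
    res <- tibble::tibble(interval = character(0), parameter1 = character(0),
                          parameter2 = character(0), n = integer(0),
                          r = numeric(0), p_value = numeric(0))
  res
}
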