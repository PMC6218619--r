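# Paired rest-vs-stress statistics: Wilcoxon signed-rank implemented
# directly (zero differences dropped, ties mid-ranked, tie-corrected normal
# approximation without continuity correction, or exact enumeration over all
# sign assignments), plus cohort summary tables.

# Exact null distribution of the positive-rank sum W for the observed rank
# vector (ties allowed): dynamic program over sign assignments on doubled
# ranks (so mid-ranks become integers).
.wilcoxon_exact_p <- function(ranks, W) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  # prob[w + 1] = P(2W = w), built by convolving each rank's two signs
  prob <- numeric(total + 1L)
  prob[1L] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), prob[seq_len(total + 1L - r)])
    prob <- (prob + shifted) / 2
  }
  w2 <- round(2 * W)
  p_low <- sum(prob[seq_len(w2 + 1L)])
  p_high <- sum(prob[(w2 + 1L):(total + 1L)])
  min(1, 2 * min(p_low, p_high))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired observations. Zero differences are
#' dropped before ranking and ties are mid-ranked. The asymptotic method
#' uses the normal approximation
#' \deqn{z = \frac{W - n(n+1)/4}{\sqrt{n(n+1)(2n+1)/24 - \sum(t^3-t)/48}}}
#' without continuity correction (with the tie term only when ties are
#' present); the exact method enumerates the full null distribution of the
#' positive-rank sum over all 2^n sign assignments.
#'
#' @param x_rest,x_stress paired numeric vectors (same subjects, same
#'   order); alternatively pass the differences as `x_rest` and omit
#'   `x_stress`.
#' @param method `"asymptotic"` or `"exact"`.
#' @param variable optional variable name carried into the result.
#' @param tie_correction apply the tie correction to the asymptotic
#'   variance.
#' @return An object of class `paired_comparison`: `variable`, `n` (pairs
#'   after dropping zero differences), `W` (positive-rank sum), `z`
#'   (asymptotic only), `p`, `method`, `significant` (at 0.05).
#' @export
wilcoxon_signed_rank <- function(x_rest, x_stress = NULL,
                                 method = c("asymptotic", "exact"),
                                 variable = NA_character_,
                                 tie_correction = TRUE) {
  method <- match.arg(method)
  d <- if (is.null(x_stress)) x_rest else x_stress - x_rest
  if (!is.null(x_stress) && length(x_rest) != length(x_stress))
    stop("wilcoxon_signed_rank: vectors must be paired (equal length)")
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n < 2L)
    stop("wilcoxon_signed_rank: fewer than 2 non-zero differences - ",
         "test undefined")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (method == "asymptotic") {
    mu <- n * (n + 1) / 4
    sig2 <- n * (n + 1) * (2 * n + 1) / 24
    if (tie_correction) {
      ties <- table(r)
      sig2 <- sig2 - sum(ties^3 - ties) / 48
    }
    if (sig2 <= 0)
      stop("wilcoxon_signed_rank: zero variance (all ranks tied)")
    z <- (W - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
  } else {
    z <- NA_real_
    p <- .wilcoxon_exact_p(r, W)
  }
  structure(list(variable = variable, n = n, W = W, z = z, p = p,
                 method = method, significant = p < 0.05),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank (%s)%s: n = %d, W = %.1f, p = %.4g%s\n",
              x$method,
              if (!is.na(x$variable)) paste0(" [", x$variable, "]") else "",
              x$n, x$W, x$p, if (x$significant) " *" else ""))
  invisible(x)
}

#' Cohort summary table with paired rest-vs-stress tests
#'
#' One row per variable: rest and stress mean, SD and range over the paired
#' cohort, plus the two-sided Wilcoxon signed-rank p-value and a
#' significance flag at p < 0.05.
#'
#' @param data data frame in long-by-state layout: one row per subject and
#'   state.
#' @param variables character vector of numeric columns to summarize.
#' @param subject_col,state_col column names identifying the subject and the
#'   state; states must be exactly `rest` and `stress` for every subject.
#' @param method Wilcoxon method (see [wilcoxon_signed_rank()]).
#' @return A data frame with columns `variable`, `rest_mean`, `rest_sd`,
#'   `rest_min`, `rest_max`, `stress_mean`, `stress_sd`, `stress_min`,
#'   `stress_max`, `p`, `significant`.
#' @export
summarize_cohort <- function(data, variables, subject_col = "subject",
                             state_col = "state",
                             method = c("asymptotic", "exact")) {
  method <- match.arg(method)
  stopifnot(all(c(subject_col, state_col, variables) %in% names(data)))
  subjects <- unique(data[[subject_col]])
  for (s in subjects) {
    st <- data[[state_col]][data[[subject_col]] == s]
    if (!setequal(st, c("rest", "stress")) || length(st) != 2L)
      stop("summarize_cohort: subject '", s,
           "' is not paired (needs exactly one rest and one stress row)")
  }
  rest <- data[data[[state_col]] == "rest", ]
  stress <- data[data[[state_col]] == "stress", ]
  rest <- rest[match(subjects, rest[[subject_col]]), ]
  stress <- stress[match(subjects, stress[[subject_col]]), ]
  rows <- lapply(variables, function(v) {
    xr <- rest[[v]]; xs <- stress[[v]]
    p <- if (all(xs - xr == 0, na.rm = TRUE)) NA_real_ else
      wilcoxon_signed_rank(xr, xs, method = method, variable = v)$p
    data.frame(variable = v,
               rest_mean = mean(xr, na.rm = TRUE),
               rest_sd = stats::sd(xr),
               rest_min = min(xr, na.rm = TRUE),
               rest_max = max(xr, na.rm = TRUE),
               stress_mean = mean(xs, na.rm = TRUE),
               stress_sd = stats::sd(xs),
               stress_min = min(xs, na.rm = TRUE),
               stress_max = max(xs, na.rm = TRUE),
               p = p,
               significant = !is.na(p) && p < 0.05)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
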