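# Contingency statistics for the simulated clinical validation: counts of
# changed vs. unchanged planning decisions by respondent group, Fisher's
# exact test by hypergeometric enumeration, the 2x2 chi-square closed form,
# and display-rounded change rates.

#' Construct a 2x2 contingency table
#'
#' Rows are respondent groups, columns changed/unchanged decisions:
#' \preformatted{        changed  unchanged
#'  group1    a         b
#'  group2    c         d}
#'
#' @param a,b,c,d nonnegative integer counts; total > 0.
#' @return An object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (sum(counts) == 0) stop("table must have a positive total", call. = FALSE)
  structure(as.list(as.integer(counts)), names = names(counts),
            class = "contingency_2x2")
}

#' Fisher's exact test on a 2x2 table
#'
#' Enumerates the hypergeometric distribution of the top-left count over all
#' tables with the observed margins. One-sided: upper tail from the observed
#' `a`. Two-sided: sum of the probabilities of all tables no more probable
#' than the observed one.
#'
#' @param table a [contingency_2x2()].
#' @param sided `"one"` or `"two"`.
#' @return A `test_result` list: `p_value`, `method`, and the enumerated
#'   support probabilities as attribute `support`.
#' @export
fisher_exact <- function(table, sided = c("one", "two")) {
  stopifnot(inherits(table, "contingency_2x2"))
  sided <- match.arg(sided)
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  m <- a + b          # row 1 total
  n2 <- c + d         # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0L, k - n2); hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  p <- if (sided == "one") {
    sum(probs[support >= a])
  } else {
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  res <- list(statistic = NA_real_, p_value = min(max(p, 0), 1),
              method = paste0("fisher_", sided, "_sided"))
  attr(res, "support") <- stats::setNames(probs, support)
  class(res) <- "test_result"
  res
}

#' Chi-square test on a 2x2 table
#'
#' Closed form `N (|ad - bc| - yates * N/2)^2 / (r1 r2 c1 c2)` with the
#' p-value from the chi-square distribution with 1 degree of freedom.
#'
#' @param table a [contingency_2x2()].
#' @param yates apply the continuity correction.
#' @return A `test_result` list: `statistic`, `p_value`, `method`.
#' @export
chi_square <- function(table, yates = FALSE) {
  stopifnot(inherits(table, "contingency_2x2"))
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  N <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (any(c(r1, r2, c1, c2) == 0))
    stop("zero margin: expected counts must all be positive", call. = FALSE)
  delta <- abs(a * d - b * c) - if (yates) N / 2 else 0
  delta <- max(delta, 0)
  stat <- N * delta^2 / (r1 * r2 * c1 * c2)
  res <- list(statistic = stat,
              p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
              method = if (yates) "chi_square_yates" else "chi_square")
  class(res) <- "test_result"
  res
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: p = %.4g", x$method, x$p_value))
  if (!is.na(x$statistic)) cat(sprintf(" (statistic = %.4g)", x$statistic))
  cat("\n")
  invisible(x)
}

#' Change rate as a display percentage
#'
#' `100 * changed / total`, rounded half-up to one decimal (display step
#' only; keep full precision internally for further computation).
#'
#' @param changed,total counts with `0 <= changed <= total`, `total > 0`.
#' @return Percentage with one decimal.
#' @export
change_rate <- function(changed, total) {
  if (total <= 0) stop("total must be > 0", call. = FALSE)
  if (changed < 0 || changed > total)
    stop("require 0 <= changed <= total", call. = FALSE)
  floor(1000 * changed / total + 0.5) / 10
}

#' Per-question mean of Likert responses
#'
#' Plain summarizer of 5-point usefulness scores per question and modality;
#' no inferential comparison is attempted.
#'
#' @param responses `data.frame` with columns `question`, `modality`,
#'   `score` (1-5).
#' @return `data.frame` of means by question and modality.
#' @export
likert_means <- function(responses) {
  stopifnot(all(c("question", "modality", "score") %in% names(responses)))
  if (any(responses$score < 1 | responses$score > 5))
    stop("scores must lie in 1..5", call. = FALSE)
  agg <- stats::aggregate(score ~ question + modality, data = responses, FUN = mean)
  names(agg)[names(agg) == "score"] <- "mean_score"
  agg[order(agg$question, agg$modality), ]
}
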