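# Reliability statistics: ICC(3,k) (two-way mixed, consistency, average of
# k measurements) and one-way repeated-measures ANOVA.

#' Reliability band for an ICC value
#'
#' Interpretation bands: poor below 0.5, moderate in [0.5, 0.75), good in
#' [0.75, 0.9], excellent above 0.9. The value 0.9 itself is classed as
#' good (the customary wording "0.75-0.9 good, above 0.9 excellent" is
#' closed at 0.9).
#'
#' @param icc numeric ICC value(s).
#' @return Character vector of band labels.
#' @export
icc_band <- function(icc) {
  b <- as.character(cut(icc, breaks = c(-Inf, 0.5, 0.75, 0.9, Inf),
                        labels = c("poor", "moderate", "good", "excellent"),
                        right = FALSE))
  b[icc == 0.9] <- "good"  # band [0.75, 0.9] is closed at 0.9
  b
}

#' Average-measures consistency intraclass correlation, ICC(3,k)
#'
#' Two-way mixed-effects, consistency-definition ICC for the average of the
#' k measurements of each of n subjects (Shrout--Fleiss case 3,k). From the
#' subjects x measurements mean squares, `icc = (MS_rows - MS_err) / MS_rows`
#' with `F = MS_rows / MS_err` on (n-1, (n-1)(k-1)) degrees of freedom; the
#' 95% confidence interval follows from the F distribution
#' (`lower = 1 - 1/(F / qf(0.975, df1, df2))`,
#' `upper = 1 - 1/(F * qf(0.975, df2, df1))`).
#'
#' @param x numeric matrix, subjects in rows, measurements in columns; no
#'   missing cells.
#' @param alpha confidence level is `1 - alpha`.
#' @return An object of class `icc3k`: `icc`, `ci` (length 2), `f`, `df1`,
#'   `df2`, `ms_rows`, `ms_error`, `n`, `k`, `band`, `alpha`.
#' @examples
#' set.seed(1)
#' subj <- rnorm(12, 10, 2)
#' x <- sapply(1:5, function(j) subj + rnorm(12, 0, 0.5))
#' icc3k(x)
#' @export
icc3k <- function(x, alpha = 0.05) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing cells are not allowed", call. = FALSE)
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) {
    stop("need at least 2 subjects and 2 measurements", call. = FALSE)
  }
  gm <- mean(x)
  ss_rows <- k * sum((rowMeans(x) - gm)^2)
  ss_cols <- n * sum((colMeans(x) - gm)^2)
  ss_tot <- sum((x - gm)^2)
  ss_err <- max(ss_tot - ss_rows - ss_cols, 0)
  df1 <- n - 1L
  df2 <- (n - 1L) * (k - 1L)
  ms_rows <- ss_rows / df1
  ms_err <- ss_err / df2
  if (ms_rows <= 0) {
    stop("degenerate input: no between-subject variance", call. = FALSE)
  }
  icc <- (ms_rows - ms_err) / ms_rows
  f <- if (ms_err > 0) ms_rows / ms_err else Inf
  fl <- f / qf(1 - alpha / 2, df1, df2)
  fu <- f * qf(1 - alpha / 2, df2, df1)
  ci <- c(1 - 1 / fl, 1 - 1 / fu)
  structure(list(icc = icc, ci = ci, f = f, df1 = df1, df2 = df2,
                 ms_rows = ms_rows, ms_error = ms_err, n = n, k = k,
                 band = icc_band(icc), alpha = alpha),
            class = "icc3k")
}

#' @export
print.icc3k <- function(x, digits = 3, ...) {
  cat(sprintf("ICC(3,k): %.*f  %d%% CI (%.*f, %.*f)  [%s]\n", digits, x$icc,
              round(100 * (1 - x$alpha)), digits, x$ci[1], digits, x$ci[2],
              x$band))
  cat(sprintf("  F(%d, %d) = %.4g, n = %d subjects, k = %d measurements\n",
              x$df1, x$df2, x$f, x$n, x$k))
  invisible(x)
}

#' @export
coef.icc3k <- function(object, ...) {
  c(icc = object$icc, ci_low = object$ci[1], ci_high = object$ci[2])
}

#' One-way repeated-measures ANOVA across sessions
#'
#' Within-subject one-way ANOVA with subjects as blocks:
#' `F = MS_session / MS_residual` on `(s-1, (s-1)(n-1))` degrees of
#' freedom, where the residual is the subject x session interaction. No
#' sphericity correction is applied to the headline p-value; a
#' Greenhouse--Geisser corrected p is reported alongside, clearly labelled.
#'
#' @param x numeric matrix of per-subject session means: subjects in rows,
#'   sessions in columns, complete.
#' @return An object of class `rm_anova`: `f`, `df1`, `df2`, `p`,
#'   `ms_session`, `ms_error`, `session_means`, `session_sds`, `n`, `s`,
#'   `gg_epsilon`, `p_gg`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(36, 10), 12, 3) + rnorm(12, 0, 2)  # subject blocks
#' rm_anova(x)
#' @export
rm_anova <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("incomplete matrix: missing cells", call. = FALSE)
  n <- nrow(x); s <- ncol(x)
  if (n < 2 || s < 2) {
    stop("need at least 2 subjects and 2 sessions", call. = FALSE)
  }
  gm <- mean(x)
  ss_subj <- s * sum((rowMeans(x) - gm)^2)
  ss_sess <- n * sum((colMeans(x) - gm)^2)
  ss_tot <- sum((x - gm)^2)
  ss_res <- max(ss_tot - ss_subj - ss_sess, 0)
  df1 <- s - 1L
  df2 <- (n - 1L) * (s - 1L)
  ms_sess <- ss_sess / df1
  ms_res <- ss_res / df2
  if (ms_res <= 0) {
    stop("degenerate input: zero residual variance", call. = FALSE)
  }
  f <- ms_sess / ms_res
  p <- pf(f, df1, df2, lower.tail = FALSE)
  # Greenhouse-Geisser epsilon from the double-centred covariance matrix
  S <- stats::cov(x)
  Sc <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
  eps <- sum(diag(Sc))^2 / ((s - 1) * sum(Sc^2))
  eps <- min(1, max(1 / (s - 1), eps))
  p_gg <- pf(f, df1 * eps, df2 * eps, lower.tail = FALSE)
  structure(list(f = f, df1 = df1, df2 = df2, p = p,
                 ms_session = ms_sess, ms_error = ms_res,
                 session_means = colMeans(x),
                 session_sds = apply(x, 2, sd),
                 n = n, s = s, gg_epsilon = eps, p_gg = p_gg),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, digits = 4, ...) {
  cat(sprintf("Repeated-measures ANOVA: F(%d, %d) = %.4g, p = %.*g\n",
              x$df1, x$df2, x$f, digits, x$p))
  cat(sprintf("  Greenhouse-Geisser corrected: eps = %.3f, p = %.*g\n",
              x$gg_epsilon, digits, x$p_gg))
  ms <- paste(sprintf("%.3g (%.3g)", x$session_means, x$session_sds),
              collapse = ", ")
  cat("  session mean (SD):", ms, "\n")
  invisible(x)
}
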