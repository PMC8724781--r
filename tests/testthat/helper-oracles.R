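# Independent sums-of-squares oracles computed with explicit double loops,
# kept deliberately naive and separate from the package implementation.

oracle_icc3k <- function(x) {
  n <- nrow(x); k <- ncol(x)
  gm <- 0
  for (i in 1:n) for (j in 1:k) gm <- gm + x[i, j]
  gm <- gm / (n * k)
  row_means <- numeric(n); col_means <- numeric(k)
  for (i in 1:n) {
    s <- 0
    for (j in 1:k) s <- s + x[i, j]
    row_means[i] <- s / k
  }
  for (j in 1:k) {
    s <- 0
    for (i in 1:n) s <- s + x[i, j]
    col_means[j] <- s / n
  }
  ss_rows <- 0; ss_cols <- 0; ss_tot <- 0
  for (i in 1:n) ss_rows <- ss_rows + k * (row_means[i] - gm)^2
  for (j in 1:k) ss_cols <- ss_cols + n * (col_means[j] - gm)^2
  for (i in 1:n) for (j in 1:k) ss_tot <- ss_tot + (x[i, j] - gm)^2
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  list(icc = (ms_rows - ms_err) / ms_rows, f = ms_rows / ms_err,
       ms_rows = ms_rows, ms_err = ms_err)
}

oracle_rm_anova <- function(x) {
  n <- nrow(x); s <- ncol(x)
  gm <- 0
  for (i in 1:n) for (j in 1:s) gm <- gm + x[i, j]
  gm <- gm / (n * s)
  subj <- numeric(n); sess <- numeric(s)
  for (i in 1:n) {
    acc <- 0
    for (j in 1:s) acc <- acc + x[i, j]
    subj[i] <- acc / s
  }
  for (j in 1:s) {
    acc <- 0
    for (i in 1:n) acc <- acc + x[i, j]
    sess[j] <- acc / n
  }
  ss_subj <- 0; ss_sess <- 0; ss_tot <- 0
  for (i in 1:n) ss_subj <- ss_subj + s * (subj[i] - gm)^2
  for (j in 1:s) ss_sess <- ss_sess + n * (sess[j] - gm)^2
  for (i in 1:n) for (j in 1:s) ss_tot <- ss_tot + (x[i, j] - gm)^2
  ss_res <- ss_tot - ss_subj - ss_sess
  f <- (ss_sess / (s - 1)) / (ss_res / ((n - 1) * (s - 1)))
  list(f = f, p = pf(f, s - 1, (n - 1) * (s - 1), lower.tail = FALSE),
       ss = c(subject = ss_subj, session = ss_sess, residual = ss_res,
              total = ss_tot))
}
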