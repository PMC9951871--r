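# Independent oracles used by several test files.

# dense grid search over the exponent with the linear parameters profiled
# out: an exhaustive reference for the power-law fit
grid_oracle <- function(x, y, ks = seq(0.01, 1, by = 0.01)) {
  best <- NULL
  for (k in ks) {
    xk <- x^k
    f <- stats::lm(y ~ xk)
    rss <- sum(stats::residuals(f)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(a = unname(stats::coef(f)[2]), k = k,
                   c = unname(stats::coef(f)[1]), rss = rss)
  }
  best
}

# brute-force enumeration of the signed-rank null over all 2^n sign
# assignments
wilcoxon_enum_oracle <- function(d, alternative = "greater") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- signs %*% r
  if (alternative == "greater") mean(ws >= w - 1e-9) else mean(ws <= w + 1e-9)
}
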