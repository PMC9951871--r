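#' Fit a power law to Dice versus pretraining-data amount
#'
#' Fits `y = a * x^k + c` by nonlinear least squares, with `k` constrained
#' positive so that `x = 0` (the fully-supervised baseline) maps to `c`.
#' The fit profiles out the linear parameters: for fixed `k` the model is
#' linear in `(a, c)`, so a 1-D multi-start search over `k` (starts at
#' 0.1, 0.3, 0.5, 0.7, 1.0, each refined by local optimization) provides
#' robust initial values that are polished with Levenberg-Marquardt; the
#' best residual sum of squares wins.
#'
#' Goodness of fit is summarized by the residual standard error
#' `S = sqrt(sum((y - yhat)^2) / (n - 2))`.
#'
#' @param x Pretraining-data amounts (percent of the standard training
#'   set; non-negative, at least 4 distinct values).
#' @param y Mean test Dice at each `x`.
#' @param k_starts Multi-start values for the exponent.
#' @param k_max Upper bound for the exponent search.
#' @return Object of class `scaling_fit` with `a`, `k`, `c`, `S`, fitted
#'   values and the data points.
#' @export
fit_power_law <- function(x, y, k_starts = c(0.1, 0.3, 0.5, 0.7, 1.0),
                          k_max = 5) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(unique(x)) < 4L)
    stop("fitting a three-parameter power law needs at least 4 distinct x values")
  if (any(x < 0)) stop("x must be non-negative")

  # profile RSS: for fixed k, solve the linear least squares in (a, c)
  profile_fit <- function(k) {
    xk <- x^k
    f <- stats::lm(y ~ xk)
    list(k = k, a = unname(coef(f)[2]), c = unname(coef(f)[1]),
         rss = sum(stats::residuals(f)^2))
  }
  cands <- list()
  for (k0 in k_starts) {
    lo <- max(1e-6, k0 / 4); hi <- min(k_max, k0 * 4)
    op <- stats::optimize(function(k) profile_fit(k)$rss, c(lo, hi))
    cands[[length(cands) + 1L]] <- profile_fit(op$minimum)
    cands[[length(cands) + 1L]] <- profile_fit(k0)
  }
  best <- cands[[which.min(vapply(cands, `[[`, numeric(1), "rss"))]]

  # Levenberg-Marquardt polish from the profiled optimum
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * x^k + c,
                      start = list(a = best$a, k = best$k, c = best$c),
                      lower = c(a = -Inf, k = 1e-6, c = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    co <- coef(fit)
    rss <- sum(stats::residuals(fit)^2)
    if (rss <= best$rss + 1e-12)
      best <- list(k = co[["k"]], a = co[["a"]], c = co[["c"]], rss = rss)
  }
  n <- length(x)
  yhat <- best$a * x^best$k + best$c
  S <- sqrt(sum((y - yhat)^2) / (n - 2))
  structure(list(a = best$a, k = best$k, c = best$c, S = S,
                 fitted = yhat, points = data.frame(x = x, y = y),
                 rss = best$rss),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("power-law fit: y = %.4g * x^%.4g + %.4g  (S = %.4g, n = %d)\n",
              x$a, x$k, x$c, x$S, nrow(x$points)))
  invisible(x)
}

#' @export
coef.scaling_fit <- function(object, ...) {
  c(a = object$a, k = object$k, c = object$c)
}

#' @export
predict.scaling_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$points$x
  else if (is.data.frame(newdata)) newdata$x else newdata
  object$a * x^object$k + object$c
}

#' @export
residuals.scaling_fit <- function(object, ...) {
  object$points$y - object$fitted
}

#' @export
plot.scaling_fit <- function(x, ...) {
  pts <- x$points
  plot(pts$x, pts$y, xlab = "pretraining data (% of training set)",
       ylab = "mean test Dice", ...)
  xs <- seq(min(pts$x), max(pts$x), length.out = 200)
  graphics::lines(xs, predict(x, xs))
  invisible(x)
}

#' One-sided Wilcoxon signed-rank test
#'
#' Paired test on `a - b`. Zero differences are dropped (at least 5
#' non-zero pairs required); ties among the absolute differences receive
#' midranks. For n <= 12 the null distribution is computed by exhaustive
#' enumeration of all 2^n sign assignments (exact even under ties);
#' for larger n a normal approximation with tie-corrected variance is
#' used.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @param alternative `"greater"` (a > b) or `"less"`.
#' @param exact_max Largest n for exhaustive enumeration.
#' @return An object of class `htest` with the signed-rank statistic (sum
#'   of ranks of positive differences) and one-sided p-value.
#' @export
wilcoxon_one_sided <- function(a, b, alternative = c("greater", "less"),
                               exact_max = 12L) {
  alternative <- match.arg(alternative)
  if (length(a) != length(b)) stop("paired samples must have equal length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("degenerate sample: all differences are zero")
  if (n < 5L) stop("need at least 5 non-zero differences")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    # distribution of W over all sign assignments, by convolution over ranks
    stats_all <- c(0)
    for (ri in r) stats_all <- c(stats_all, stats_all + ri)
    p <- if (alternative == "greater") mean(stats_all >= w - 1e-9)
    else mean(stats_all <= w + 1e-9)
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w - mu) / sqrt(sig2)
    p <- if (alternative == "greater") pnorm(z, lower.tail = FALSE)
    else pnorm(z)
    method <- "normal approximation with tie correction"
  }
  structure(list(statistic = c(W = w), p.value = p,
                 alternative = alternative,
                 method = paste("One-sided Wilcoxon signed-rank test,", method),
                 data.name = sprintf("%d non-zero paired differences", n),
                 n = n),
            class = "htest")
}

#' Rank pretraining strategies by benefit over supervised learning
#'
#' For each strategy and dataset, pools the class-averaged per-image Dice
#' scores of its SSL models across the label-limited regimes, tests
#' whether they exceed the paired fully-supervised scores with a
#' one-sided Wilcoxon signed-rank test, sorts strategies by ascending
#' p-value, and selects the strategy present in the top `top_n` of every
#' dataset. An empty intersection yields a no-consensus result (with the
#' full rankings still reported).
#'
#' @param scores Data frame with columns `strategy`, `dataset`, `id`,
#'   `regime`, `dice_ssl`, `dice_supervised`.
#' @param top_n Size of each dataset's head-of-ranking set.
#' @param pool_regimes Pool scores across regimes into one test per
#'   strategy (the default); otherwise the minimum per-regime p-value is
#'   used.
#' @return Object of class `strategy_ranking`: per-dataset ranking tables,
#'   the consensus `selected` strategy (or `NULL`), and `no_consensus`.
#' @export
rank_strategies <- function(scores, top_n = 3L, pool_regimes = TRUE) {
  needed <- c("strategy", "dataset", "id", "regime", "dice_ssl",
              "dice_supervised")
  if (!all(needed %in% names(scores)))
    stop("scores must have columns ", paste(needed, collapse = ", "))
  rankings <- list()
  for (ds in unique(scores$dataset)) {
    sub <- scores[scores$dataset == ds, ]
    ps <- vapply(unique(sub$strategy), function(st) {
      s2 <- sub[sub$strategy == st, ]
      if (pool_regimes) {
        wilcoxon_one_sided(s2$dice_ssl, s2$dice_supervised)$p.value
      } else {
        min(vapply(unique(s2$regime), function(rg) {
          s3 <- s2[s2$regime == rg, ]
          wilcoxon_one_sided(s3$dice_ssl, s3$dice_supervised)$p.value
        }, numeric(1)))
      }
    }, numeric(1))
    rankings[[ds]] <- data.frame(strategy = names(ps), p_value = unname(ps),
                                 stringsAsFactors = FALSE)
    rankings[[ds]] <- rankings[[ds]][order(rankings[[ds]]$p_value), ]
    rankings[[ds]]$rank <- seq_len(nrow(rankings[[ds]]))
  }
  tops <- lapply(rankings, function(r) head(r$strategy, top_n))
  consensus <- Reduce(intersect, tops)
  selected <- if (length(consensus)) {
    # among consensus strategies, prefer the best mean rank
    mean_rank <- vapply(consensus, function(st)
      mean(vapply(rankings, function(r) r$rank[r$strategy == st], numeric(1))),
      numeric(1))
    consensus[which.min(mean_rank)]
  } else NULL
  structure(list(rankings = rankings, selected = selected,
                 no_consensus = is.null(selected), top_n = top_n),
            class = "strategy_ranking")
}

#' @export
print.strategy_ranking <- function(x, ...) {
  for (ds in names(x$rankings)) {
    cat(sprintf("dataset %s:\n", ds))
    print(head(x$rankings[[ds]], 5), row.names = FALSE)
  }
  if (x$no_consensus)
    cat(sprintf("no strategy appears in the top %d for every dataset\n", x$top_n))
  else cat("selected strategy:", x$selected, "\n")
  invisible(x)
}
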