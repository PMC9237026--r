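#' Two-sample Anderson-Darling test
#'
#' The k-sample Anderson-Darling rank statistic (k = 2) in its midrank
#' version for ties, standardised by its exact finite-sample variance, with
#' the p-value obtained from the published interpolation of the statistic's
#' critical values. The interpolation is valid between p = 0.25 and
#' p = 0.001; values outside are reported at those bounds, with the
#' `p_capped`/`p_floored` flags set.
#'
#' @param x,y numeric samples, each of size >= 5.
#' @return a list of class `ad_test`: `statistic` (the standardised
#'   statistic), `a2` (the raw rank statistic), `p` (capped/floored),
#'   `p_capped`, `p_floored`, `n_x`, `n_y`.
#' @export
anderson_darling_2sample <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample", call. = FALSE)
  if (length(x) < 5 || length(y) < 5) {
    stop("each sample must have at least 5 values", call. = FALSE)
  }
  samples <- list(as.numeric(x), as.numeric(y))
  k <- 2L
  n <- lengths(samples)
  Z <- sort(c(x, y))
  N <- length(Z)
  Zstar <- unique(Z)
  if (length(Zstar) < 2) stop("all values tied; test undefined", call. = FALSE)

  # midrank version of the rank statistic
  left <- findInterval(Zstar, Z, left.open = TRUE)       # count of Z <  Zstar
  right <- findInterval(Zstar, Z)                        # count of Z <= Zstar
  lj <- right - left
  Bj <- left + lj / 2
  A2 <- 0
  for (i in 1:k) {
    s <- sort(samples[[i]])
    s_right <- findInterval(Zstar, s)
    fij <- s_right - findInterval(Zstar, s, left.open = TRUE)
    Mij <- s_right - fij / 2
    inner <- lj / N * (N * Mij - Bj * n[i])^2 / (Bj * (N - Bj) - N * lj / 4)
    A2 <- A2 + sum(inner) / n[i]
  }
  A2 <- A2 * (N - 1) / N

  # exact variance of the statistic under H0 (Scholz-Stephens)
  H <- sum(1 / n)
  hs_cs <- cumsum(1 / seq(N - 1, 2))
  h <- hs_cs[length(hs_cs)] + 1
  g <- sum(hs_cs / seq(2, N - 1))
  a <- (4 * g - 6) * (k - 1) + (10 - 6 * g) * H
  b <- (2 * g - 4) * k^2 + 8 * h * k + (2 * g - 14 * h - 4) * H - 8 * h + 4 * g - 6
  cc <- (6 * h + 2 * g - 2) * k^2 + (4 * h - 4 * g + 6) * k + (2 * h - 6) * H + 4 * h
  d <- (2 * h + 6) * k^2 - 4 * h * k
  sigmasq <- (a * N^3 + b * N^2 + cc * N + d) / ((N - 1) * (N - 2) * (N - 3))
  m <- k - 1
  Tkn <- (A2 - m) / sqrt(sigmasq)

  # published critical-value surface t_m(alpha) = b0 + b1/sqrt(m) + b2/m,
  # inverted by a quadratic fit of log(alpha) against t_m
  b0 <- c(0.675, 1.281, 1.645, 1.960, 2.326, 2.573, 3.085)
  b1 <- c(-0.245, 0.250, 0.678, 1.149, 1.822, 2.364, 3.615)
  b2 <- c(-0.105, -0.305, -0.362, -0.391, -0.396, -0.345, -0.154)
  sig <- c(0.25, 0.1, 0.05, 0.025, 0.01, 0.005, 0.001)
  tm <- b0 + b1 / sqrt(m) + b2 / m
  p_capped <- Tkn < min(tm)
  p_floored <- Tkn > max(tm)
  if (p_capped) {
    p <- 0.25
  } else if (p_floored) {
    p <- 0.001
  } else {
    fit <- stats::lm(log(sig) ~ poly(tm, 2, raw = TRUE))
    p <- exp(sum(stats::coef(fit) * c(1, Tkn, Tkn^2)))
    p <- min(max(p, 0.001), 0.25)
  }
  structure(list(statistic = Tkn, a2 = A2, p = p,
                 p_capped = p_capped, p_floored = p_floored,
                 n_x = length(x), n_y = length(y)),
            class = "ad_test")
}

#' @exportS3Method base::print
print.ad_test <- function(x, ...) {
  ptxt <- if (x$p_floored) "< 0.001" else if (x$p_capped) ">= 0.25" else
    sprintf("= %.4g", x$p)
  cat(sprintf("Anderson-Darling 2-sample: T = %.4f, p %s (n = %d, %d)\n",
              x$statistic, ptxt, x$n_x, x$n_y))
  invisible(x)
}

#' Median-difference effect size
#'
#' `median(x) - median(y)` divided by the pooled standard deviation
#' `sqrt((sd(x)^2 + sd(y)^2) / 2)` (equal-n root-mean-square pooling, sample
#' n-1 standard deviations). An effect with zero pooled sd and nonzero
#' difference is reported infinite with a warning.
#'
#' @param x,y numeric ensembles (intended equal-sized).
#' @param pooling `"rms"` (default) or `"variance_weighted"`
#'   (`sqrt(((n_x-1) sd_x^2 + (n_y-1) sd_y^2) / (n_x + n_y - 2))`).
#' @return list with `median_difference`, `pooled_sd`, `effect`.
#' @export
effect_size <- function(x, y, pooling = c("rms", "variance_weighted")) {
  pooling <- match.arg(pooling)
  md <- stats::median(x) - stats::median(y)
  sx <- stats::sd(x); sy <- stats::sd(y)
  ps <- if (pooling == "rms") {
    sqrt((sx^2 + sy^2) / 2)
  } else {
    nx <- length(x); ny <- length(y)
    sqrt(((nx - 1) * sx^2 + (ny - 1) * sy^2) / (nx + ny - 2))
  }
  eff <- if (ps == 0) {
    if (md == 0) 0 else {
      warning("pooled sd is 0 with a nonzero median difference; effect is infinite")
      sign(md) * Inf
    }
  } else md / ps
  list(median_difference = md, pooled_sd = ps, effect = eff)
}

#' Chi-squared comparison of two QSS results
#'
#' Pearson chi-squared (no continuity correction) on the 2x2 table of
#' stable/unstable counts by web. If any expected count falls below 5 a
#' warning is issued and Fisher's exact test is used instead.
#'
#' @param a,b `qss_result` objects, see [qss()].
#' @return list with `chi2` (`NA` for the exact fallback), `p`, `method`.
#' @export
chi_squared_qss <- function(a, b) {
  tab <- rbind(c(a$n_stable, a$n_samples - a$n_stable),
               c(b$n_stable, b$n_samples - b$n_stable))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    warning("expected count below 5; falling back to Fisher's exact test")
    ft <- stats::fisher.test(tab)
    return(list(chi2 = NA_real_, p = ft$p.value, method = "fisher_exact"))
  }
  if (identical(tab[1, ], tab[2, ])) {
    # guard: chisq.test warns on zero margins; identical rows are trivially p = 1
    return(list(chi2 = 0, p = 1, method = "pearson_chi_squared"))
  }
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(chi2 = unname(ct$statistic), p = ct$p.value,
       method = "pearson_chi_squared")
}

#' Trim IQR outliers (display only)
#'
#' Removes points below `Q1 - 1.5 IQR` or above `Q3 + 1.5 IQR`, with
#' quartiles by linear interpolation (quantile type 7). Intended only for
#' plotting; never applied before statistics.
#'
#' @param values numeric vector of length >= 4.
#' @return list with `values` (trimmed) and `n_removed`.
#' @export
iqr_trim <- function(values) {
  if (length(values) < 4) stop("need at least 4 values", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  keep <- values >= q[1] - 1.5 * iqr & values <= q[2] + 1.5 * iqr
  list(values = values[keep], n_removed = sum(!keep))
}

#' Compare two webs' null ensembles metric by metric
#'
#' Builds the per-metric comparison rows (medians, median difference,
#' pooled sd, effect size, Anderson-Darling statistic and p) from already
#' computed ensembles, plus the QSS chi-squared row. The report mirrors the
#' conventional metric-table layout of fishing vs non-fishing analyses.
#'
#' @param ensembles_a,ensembles_b named lists of `null_ensemble` objects
#'   for the two scenarios (matching names).
#' @param qss_a,qss_b optional `qss_result` objects for the two scenarios.
#' @return a list of class `comparison_report` with `metrics` (data.frame)
#'   and `qss` (list or `NULL`).
#' @export
comparison_report <- function(ensembles_a, ensembles_b,
                              qss_a = NULL, qss_b = NULL) {
  stopifnot(identical(names(ensembles_a), names(ensembles_b)))
  rows <- lapply(names(ensembles_a), function(nm) {
    ea <- ensembles_a[[nm]]; eb <- ensembles_b[[nm]]
    es <- effect_size(ea$values, eb$values)
    ad <- anderson_darling_2sample(ea$values, eb$values)
    data.frame(metric = ea$metric,
               weighted = isTRUE(ea$recipe$weighted),
               median_a = stats::median(ea$values),
               median_b = stats::median(eb$values),
               median_difference = es$median_difference,
               pooled_sd = es$pooled_sd,
               effect_size = es$effect,
               ad_statistic = ad$statistic,
               ad_p = ad$p,
               ad_p_floored = ad$p_floored)
  })
  qrow <- NULL
  if (!is.null(qss_a) && !is.null(qss_b)) {
    ch <- chi_squared_qss(qss_a, qss_b)
    qrow <- list(prop_a = qss_a$proportion_stable,
                 prop_b = qss_b$proportion_stable,
                 se_a = qss_a$se, se_b = qss_b$se,
                 n = qss_a$n_samples,
                 chi2 = ch$chi2, p = ch$p, method = ch$method)
  }
  structure(list(metrics = do.call(rbind, rows), qss = qrow),
            class = "comparison_report")
}

#' @exportS3Method base::print
print.comparison_report <- function(x, ...) {
  cat("comparison_report\n")
  df <- x$metrics
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 4)
  print(df, row.names = FALSE)
  if (!is.null(x$qss)) {
    cat(sprintf("QSS: %.4f vs %.4f, chi2 = %s, p = %.3g (%s)\n",
                x$qss$prop_a, x$qss$prop_b,
                ifelse(is.na(x$qss$chi2), "NA", sprintf("%.1f", x$qss$chi2)),
                x$qss$p, x$qss$method))
  }
  invisible(x)
}
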