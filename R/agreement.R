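# Method-agreement statistics between contactless estimates and a
# contact reference, computed per feature across subjects: Spearman rank
# correlation, range-normalized RMSE, and Bland-Altman limits of
# agreement.

#' Paired per-subject feature values
#'
#' Pairs estimate and reference values by subject; pairs with a missing
#' member are dropped (with a recorded count).
#'
#' @param x_est per-subject estimated values (e.g. video-derived).
#' @param x_ref per-subject reference values (e.g. finger PPG).
#' @param feature feature name label.
#' @return list of class `paired_features`: `feature`, `x_est`, `x_ref`,
#'   `n`, `n_dropped`.
#' @export
paired_features <- function(x_est, x_ref, feature = "feature") {
  if (length(x_est) != length(x_ref))
    stop("paired_features: estimate and reference must have equal length")
  ok <- is.finite(x_est) & is.finite(x_ref)
  dropped <- sum(!ok)
  if (dropped)
    message("paired_features(", feature, "): dropped ", dropped,
            " incomplete pair(s)")
  if (sum(ok) < 3L)
    stop("paired_features: need at least 3 complete pairs")
  structure(list(feature = feature, x_est = x_est[ok], x_ref = x_ref[ok],
                 n = sum(ok), n_dropped = dropped),
            class = "paired_features")
}

#' Spearman rank correlation of paired features
#'
#' Monotonic association between estimate and reference, with average
#' ranks for ties and a two-sided p-value.
#'
#' @param paired a [paired_features].
#' @return list: `rho`, `pval`.
#' @export
spearman_corr <- function(paired) {
  stopifnot(inherits(paired, "paired_features"))
  if (stats::sd(rank(paired$x_est)) == 0 ||
      stats::sd(rank(paired$x_ref)) == 0)
    stop("spearman_corr: zero rank variance")
  ct <- suppressWarnings(
    stats::cor.test(paired$x_est, paired$x_ref, method = "spearman",
                    alternative = "two.sided", exact = FALSE))
  list(rho = unname(ct$estimate), pval = ct$p.value)
}

#' Range-normalized root mean square error
#'
#' `RMSE = sqrt(mean((x_est - x_ref)^2))`, normalized by the reference
#' range: `NRMSE = RMSE / (max(x_ref) - min(x_ref))`.
#'
#' @param paired a [paired_features].
#' @return list: `nrmse`, `rmse`.
#' @export
nrmse <- function(paired) {
  stopifnot(inherits(paired, "paired_features"))
  rng <- diff(range(paired$x_ref))
  if (rng == 0)
    stop("nrmse: constant reference (zero range)")
  rmse <- sqrt(mean((paired$x_est - paired$x_ref)^2))
  list(nrmse = rmse / rng, rmse = rmse)
}

#' Bland-Altman bias and 95% limits of agreement
#'
#' Differences `d_i = x_est_i - x_ref_i`: bias is their mean, the limits
#' of agreement are `bias +/- 1.96 SD` (N-1 standard deviation, the 1.96
#' constant used exactly).  Per-point plot coordinates (pair mean on x,
#' difference on y) are returned for plotting.
#'
#' @param paired a [paired_features].
#' @return list: `bias`, `sd_diff`, `loa_low`, `loa_high`, `points`
#'   (data.frame with `mean` and `diff`), `n`.
#' @export
bland_altman <- function(paired) {
  stopifnot(inherits(paired, "paired_features"))
  d <- paired$x_est - paired$x_ref
  bias <- mean(d)
  sdd <- stats::sd(d)
  list(bias = bias, sd_diff = sdd,
       loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
       points = data.frame(mean = (paired$x_est + paired$x_ref) / 2,
                           diff = d),
       n = paired$n)
}

#' Kolmogorov-Smirnov check of Gaussianity
#'
#' One-sample KS statistic against a normal distribution with the sample
#' mean and SD; used to justify the nonparametric correlation choice in
#' reports, not as a formal test (parameters are estimated from the same
#' sample, which makes the p-value conservative).
#'
#' @param values numeric vector, n >= 5.
#' @return list: `statistic`, `pval`.
#' @export
gaussianity_check <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 5L) stop("gaussianity_check: need n >= 5")
  s <- stats::sd(values)
  if (s == 0) stop("gaussianity_check: degenerate (zero SD) input")
  kt <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), s))
  list(statistic = unname(kt$statistic), pval = kt$p.value)
}

#' Full agreement report for one feature
#'
#' @param paired a [paired_features].
#' @return object of class `agreement_report` combining [spearman_corr],
#'   [nrmse] and [bland_altman] fields, plus `n` and `n_dropped`.
#' @export
agreement_report <- function(paired) {
  sp <- spearman_corr(paired)
  er <- nrmse(paired)
  ba <- bland_altman(paired)
  structure(list(feature = paired$feature, rho = sp$rho, pval = sp$pval,
                 nrmse = er$nrmse, rmse = er$rmse, bias = ba$bias,
                 sd_diff = ba$sd_diff, loa_low = ba$loa_low,
                 loa_high = ba$loa_high, points = ba$points,
                 n = paired$n, n_dropped = paired$n_dropped),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(paste0("<agreement_report> %s (n=%d): rho=%.3f (p=%.3g), ",
                     "NRMSE=%.3g, bias=%.3g [%.3g, %.3g]\n"),
              x$feature, x$n, x$rho, x$pval, x$nrmse, x$bias,
              x$loa_low, x$loa_high))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Pair means on the x-axis, differences on the y-axis, with the bias and
#' the 95% limits of agreement drawn as horizontal lines.
#'
#' @param report an [agreement_report] (or the list from [bland_altman]).
#' @param file optional PNG or SVG path; plots to the active device when
#'   `NULL`.
#' @param ... passed to [graphics::plot].
#' @export
plot_bland_altman <- function(report, file = NULL, ...) {
  if (!is.null(file)) {
    if (grepl("\\.svg$", file)) grDevices::svg(file, width = 6, height = 4.5)
    else grDevices::png(file, width = 720, height = 540)
    on.exit(grDevices::dev.off())
  }
  p <- report$points
  ttl <- if (!is.null(report$feature)) report$feature else ""
  graphics::plot(p$mean, p$diff, pch = 19,
                 xlab = "Mean of estimate and reference",
                 ylab = "Difference (estimate - reference)",
                 main = ttl, ...)
  graphics::abline(h = report$bias, lty = 1)
  graphics::abline(h = c(report$loa_low, report$loa_high), lty = 2)
  invisible(report)
}
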