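# Diagnostic accuracy: ROC curve construction, AUC with Hanley-McNeil CI
# and test against chance, Youden-index optimal cutoff with Wilson score
# CIs for sensitivity/specificity, and the positive likelihood ratio.

#' Construct a ROC curve
#'
#' Builds the ROC curve of a continuous score for discriminating the
#' positive class (high resilience). Thresholds are placed at midpoints
#' between consecutive distinct scores plus sentinels beyond the extremes.
#' With `direction = "auto"` the orientation (whether larger or smaller
#' scores indicate the positive class) is chosen so the AUC is at least
#' 0.5, and is recorded: `">"` means score above the cutoff calls the
#' positive class, `"<"` the reverse.
#'
#' @param data Data frame with scores and class labels.
#' @param score,label Column names (tidy-eval).
#' @param positive Label of the positive class (default `"high"`).
#' @param direction `"auto"`, `">"` (greater is positive) or `"<"`.
#' @return Object of class `ev_roc`: list with `points` (tibble:
#'   `threshold`, `sensitivity`, `specificity`, `fpr`, `j`), `direction`,
#'   `auc`, `n_pos`, `n_neg`, `positive`.
#' @export
roc_curve <- function(data, score, label, positive = "high",
                      direction = c("auto", ">", "<")) {
  direction <- match.arg(direction)
  s <- dplyr::pull(data, {{ score }})
  l <- dplyr::pull(data, {{ label }})
  ok <- !is.na(s) & !is.na(l)
  s <- s[ok]
  l <- l[ok]
  is_pos <- l == positive
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  auc_greater <- function(sp, sn) {
    # P(score_pos > score_neg) + 0.5 P(equal), via mid-ranks
    r <- rank(c(sp, sn))
    (sum(r[seq_along(sp)]) - length(sp) * (length(sp) + 1) / 2) /
      (length(sp) * length(sn))
  }
  a_gt <- auc_greater(s[is_pos], s[!is_pos])
  if (direction == "auto") direction <- if (a_gt >= 0.5) ">" else "<"
  auc <- if (direction == ">") a_gt else 1 - a_gt
  uq <- sort(unique(s))
  thr <- c(
    uq[1] - 1,
    if (length(uq) > 1) (uq[-length(uq)] + uq[-1]) / 2,
    uq[length(uq)] + 1
  )
  sens <- spec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    call_pos <- if (direction == ">") s > thr[i] else s < thr[i]
    sens[i] <- sum(call_pos & is_pos) / n_pos
    spec[i] <- sum(!call_pos & !is_pos) / n_neg
  }
  points <- tibble::tibble(
    threshold = thr, sensitivity = sens, specificity = spec,
    fpr = 1 - spec, j = sens + spec - 1
  )
  points <- dplyr::arrange(points, .data$fpr, .data$sensitivity)
  structure(
    list(
      points = points, direction = direction, auc = auc,
      n_pos = n_pos, n_neg = n_neg, positive = positive
    ),
    class = "ev_roc"
  )
}

#' AUC with Hanley-McNeil CI and test against chance
#'
#' The AUC equals the trapezoidal area of the curve and the Mann-Whitney
#' rank statistic `U / (n_pos * n_neg)` under the chosen orientation. The
#' CI uses the Hanley-McNeil standard error and the p-value the z-test of
#' `AUC = 0.5` against the same SE. A degenerate score (single distinct
#' value) yields AUC 0.5 with a collapsed CI, flagged.
#'
#' @param roc An `ev_roc`.
#' @param conf_level Confidence level.
#' @return One-row tibble: `auc`, `ci_low`, `ci_high`, `se`, `p`, `flag`.
#' @export
auc_ci <- function(roc, conf_level = 0.95) {
  a <- roc$auc
  n1 <- roc$n_pos
  n2 <- roc$n_neg
  if (nrow(roc$points) <= 2) {
    return(tibble::tibble(
      auc = 0.5, ci_low = 0.5, ci_high = 0.5, se = 0, p = 1,
      flag = "degenerate: single distinct score"
    ))
  }
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  se <- sqrt(
    (a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n2 - 1) * (q2 - a^2)) /
      (n1 * n2)
  )
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- if (se > 0) min(1, 2 * stats::pnorm(-abs((a - 0.5) / se))) else 0
  tibble::tibble(
    auc = a,
    ci_low = max(0, a - zq * se), ci_high = min(1, a + zq * se),
    se = se, p = p, flag = NA_character_
  )
}

#' Wilson score confidence interval for a proportion
#'
#' @param k Successes; `n` trials.
#' @param n Number of trials.
#' @param conf_level Confidence level.
#' @return Named numeric `c(low, high)`, always within `[0, 1]` and
#'   containing `k/n`.
#' @export
wilson_ci <- function(k, n, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, centre - half), high = min(1, centre + half))
}

#' Youden-index optimal operating point
#'
#' Finds the threshold maximising `J = sensitivity + specificity - 1`.
#' Ties are broken towards higher sensitivity, then towards the lower
#' cutoff. Sensitivity and specificity carry Wilson score CIs.
#'
#' @param roc An `ev_roc`.
#' @param conf_level Confidence level for the Wilson intervals.
#' @return One-row tibble: `cutoff`, `direction`, `sensitivity`,
#'   `sens_ci_low`, `sens_ci_high`, `specificity`, `spec_ci_low`,
#'   `spec_ci_high`, `j`.
#' @export
youden_optimal <- function(roc, conf_level = 0.95) {
  pts <- roc$points
  ord <- order(-pts$j, -pts$sensitivity, pts$threshold)
  best <- pts[ord[1], ]
  sci <- wilson_ci(round(best$sensitivity * roc$n_pos), roc$n_pos, conf_level)
  pci <- wilson_ci(round(best$specificity * roc$n_neg), roc$n_neg, conf_level)
  tibble::tibble(
    cutoff = best$threshold, direction = roc$direction,
    sensitivity = best$sensitivity,
    sens_ci_low = sci[["low"]], sens_ci_high = sci[["high"]],
    specificity = best$specificity,
    spec_ci_low = pci[["low"]], spec_ci_high = pci[["high"]],
    j = best$j
  )
}

#' Positive likelihood ratio
#'
#' `LR+ = sensitivity / (1 - specificity)`: how many times more likely a
#' positive call is in a truly positive subject than in a truly negative
#' one. Perfect specificity gives an infinite ratio, returned as `Inf`
#' with a warning.
#'
#' @param sensitivity,specificity Proportions in `[0, 1]`.
#' @return Numeric scalar.
#' @examples
#' likelihood_ratio(0.80, 0.90) # 8
#' likelihood_ratio(0.90, 0.60) # 2.25
#' @export
likelihood_ratio <- function(sensitivity, specificity) {
  stopifnot(
    sensitivity >= 0, sensitivity <= 1,
    specificity >= 0, specificity <= 1
  )
  if (specificity == 1) {
    warning("specificity = 1: infinite likelihood ratio", call. = FALSE)
    return(Inf)
  }
  sensitivity / (1 - specificity)
}

#' Full ROC analysis of one variable
#'
#' Curve, AUC with CI and p, Youden-optimal operating point and positive
#' likelihood ratio, in one row.
#'
#' @inheritParams roc_curve
#' @param conf_level Confidence level.
#' @return One-row tibble combining [auc_ci()] and [youden_optimal()]
#'   output plus `lr_positive`, `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(data, score, label, positive = "high",
                         direction = "auto", conf_level = 0.95) {
  roc <- roc_curve(data, {{ score }}, {{ label }},
    positive = positive, direction = direction
  )
  a <- auc_ci(roc, conf_level)
  yj <- youden_optimal(roc, conf_level)
  lr <- if (yj$specificity == 1) {
    Inf
  } else {
    likelihood_ratio(yj$sensitivity, yj$specificity)
  }
  dplyr::bind_cols(
    dplyr::rename(a,
      auc_ci_low = "ci_low", auc_ci_high = "ci_high",
      auc_se = "se", auc_p = "p"
    ),
    yj,
    tibble::tibble(lr_positive = lr, n_pos = roc$n_pos, n_neg = roc$n_neg)
  )
}

#' @export
print.ev_roc <- function(x, ...) {
  cat(
    "<ev_roc> AUC ", format(x$auc, digits = 3), ", direction ", x$direction,
    ", ", x$n_pos, " positive / ", x$n_neg, " negative\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a ROC curve
#'
#' @param x An `ev_roc`.
#' @param ... Unused.
#' @return The points tibble (threshold, sensitivity, specificity, fpr, J).
#' @export
tidy.ev_roc <- function(x, ...) x$points

#' One-row ROC summary
#'
#' @param x An `ev_roc`.
#' @param ... Unused.
#' @return Tibble: AUC with CI/p plus the Youden operating point.
#' @export
glance.ev_roc <- function(x, ...) {
  dplyr::bind_cols(
    dplyr::select(auc_ci(x), -"flag"),
    dplyr::select(youden_optimal(x), -"direction")
  )
}

#' Plot a ROC curve
#'
#' Standard ROC plot (sensitivity against 1 - specificity) with the chance
#' diagonal and the Youden-optimal operating point marked.
#'
#' @param object An `ev_roc`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ev_roc <- function(object, ...) {
  yj <- youden_optimal(object)
  ggplot2::ggplot(
    object$points,
    ggplot2::aes(x = .data$fpr, y = .data$sensitivity)
  ) +
    ggplot2::geom_abline(
      intercept = 0, slope = 1,
      linetype = "dashed", colour = "grey60"
    ) +
    ggplot2::geom_step(direction = "vh", linewidth = 0.7) +
    ggplot2::geom_point(
      data = tibble::tibble(
        fpr = 1 - yj$specificity, sensitivity = yj$sensitivity
      ),
      colour = "red", size = 2
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf(
        "AUC = %.2f (cutoff %s %.3g, J = %.2f)",
        object$auc, yj$direction, yj$cutoff, yj$j
      )
    ) +
    ggplot2::theme_minimal()
}
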