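# Resource-split multiplier model: does dividing attention between two
# colors halve the SSVEP attentional modulation of each?
#
# For each target color the divided-attention amplitude is modelled as
#   Amp_div = p * (Amp_attended + Amp_unattended)
# where the two right-hand amplitudes come from the focused conditions.
# p = 0.5 is the strict resource-halving prediction, equivalent to the
# divided amplitude equalling the mean of the two focused amplitudes.

#' Resource-split multiplier
#'
#' `p = amp_div / (amp_att + amp_unatt)` (vectorised).
#'
#' @param amp_div Amplitude of the color under divided attention, microvolts.
#' @param amp_att Amplitude when the color is attended alone.
#' @param amp_unatt Amplitude when the other target color is attended.
#' @return The multiplier p (dimensionless).
#' @examples
#' multiplier_p(0.8, 1.0, 0.6)  # exact halving: 0.5
#' @export
multiplier_p <- function(amp_div, amp_att, amp_unatt) {
  denom <- amp_att + amp_unatt
  if (any(denom <= 0)) stop("amp_att + amp_unatt must be positive")
  amp_div / denom
}

#' Mean-amplitude prediction for divided attention
#'
#' The divided-attention amplitude predicted by strict resource halving:
#' the average of the two focused-attention amplitudes. Algebraically the
#' same statement as `p = 0.5` in [multiplier_p()].
#'
#' @inheritParams multiplier_p
#' @return Predicted divided-attention amplitude, microvolts.
#' @examples
#' mean_amplitude_prediction(1.0, 0.6)  # 0.8
#' @export
mean_amplitude_prediction <- function(amp_att, amp_unatt) {
  (amp_att + amp_unatt) / 2
}

#' One-sample t-test of multiplier values against a null
#'
#' Two-sided one-sample t-test with a `qt`-based 95% confidence interval.
#' When the values are constant the test is degenerate: t is reported as 0
#' (if the mean equals the null) or signed infinity, with `degenerate = TRUE`.
#'
#' @param p Numeric vector of per-participant multiplier estimates.
#' @param null Null value, default 0.5 (resource halving).
#' @param conf_level Confidence level for the interval.
#' @return One-row data frame: `mean_p`, `ci_low`, `ci_high`, `t`, `df`,
#'   `p_value`, `degenerate`.
#' @export
multiplier_test <- function(p, null = 0.5, conf_level = 0.95) {
  stopifnot(length(p) >= 2, is.numeric(p))
  n <- length(p)
  m <- mean(p)
  se <- stats::sd(p) / sqrt(n)
  df <- n - 1
  tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  if (se == 0) {
    tval <- if (m == null) 0 else sign(m - null) * Inf
    return(data.frame(mean_p = m, ci_low = m, ci_high = m, t = tval, df = df,
                      p_value = if (m == null) 1 else 0, degenerate = TRUE))
  }
  tval <- (m - null) / se
  data.frame(mean_p = m, ci_low = m - tq * se, ci_high = m + tq * se,
             t = tval, df = df,
             p_value = 2 * stats::pt(-abs(tval), df), degenerate = FALSE)
}

#' Fit the resource-split model to per-participant amplitudes
#'
#' Computes the multiplier p per participant, target color and context from
#' an attentional-effects table, then tests the group of per-participant
#' values against `null = 0.5` separately for each color x context cell
#' (no pooling across cells), plus a pooled test on each participant's mean
#' p across cells.
#'
#' @param effects Data frame from [attentional_effects()] with a
#'   `participant` column (columns `amp_focused`, `amp_unattended`,
#'   `amp_divided`, `color`, `context`).
#' @param null Null multiplier, default 0.5.
#' @return An object of class `resource_split`: list with `p`
#'   (per-participant table including the `p` column), `table` (per
#'   color x context test results), `overall` (test on per-participant mean
#'   p) and `null`.
#' @examples
#' \donttest{
#' amps <- simulate_ssvep_study(n_participants = 4, seed = 1)
#' fit <- fit_resource_split(attentional_effects(amps))
#' coef(fit)
#' }
#' @export
fit_resource_split <- function(effects, null = 0.5) {
  needed <- c("participant", "color", "context", "amp_focused",
              "amp_unattended", "amp_divided")
  stopifnot(all(needed %in% names(effects)))
  effects$p <- multiplier_p(effects$amp_divided, effects$amp_focused,
                            effects$amp_unattended)
  cells <- unique(effects[c("color", "context")])
  tab <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- effects[effects$color == cells$color[i] &
                     effects$context == cells$context[i], ]
    cbind(cells[i, , drop = FALSE], multiplier_test(sub$p, null))
  }))
  rownames(tab) <- NULL
  per_part <- stats::aggregate(list(p = effects$p),
                               by = effects["participant"], FUN = mean)
  structure(list(p = effects, table = tab,
                 overall = multiplier_test(per_part$p, null), null = null),
            class = "resource_split")
}

#' @export
print.resource_split <- function(x, ...) {
  cat(sprintf("Resource-split multiplier model (null p = %.2f)\n", x$null))
  cat(sprintf("  %d participants, %d color x context cells\n",
              length(unique(x$p$participant)), nrow(x$table)))
  cat(sprintf("  overall mean p = %.3f [%.3f, %.3f], t(%d) = %.2f, p = %.3g\n",
              x$overall$mean_p, x$overall$ci_low, x$overall$ci_high,
              x$overall$df, x$overall$t, x$overall$p_value))
  invisible(x)
}

#' @export
summary.resource_split <- function(object, ...) {
  cat(sprintf("Resource-split multiplier model (null p = %.2f)\n\n",
              object$null))
  df <- object$table
  df$label <- sprintf("%s, %s context", df$color, df$context)
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-22s p = %.3f, 95%% CI %.3f-%.3f, t(%d) = %.3f, p = %.3g\n",
                df$label[i], df$mean_p[i], df$ci_low[i], df$ci_high[i],
                df$df[i], df$t[i], df$p_value[i]))
  }
  cat(sprintf("\n  overall: p = %.3f, 95%% CI %.3f-%.3f, t(%d) = %.3f, p = %.3g\n",
              object$overall$mean_p, object$overall$ci_low,
              object$overall$ci_high, object$overall$df, object$overall$t,
              object$overall$p_value))
  invisible(object$table)
}

#' @export
coef.resource_split <- function(object, ...) {
  stats::setNames(object$table$mean_p,
                  paste(object$table$color, object$table$context, sep = "."))
}

#' @export
confint.resource_split <- function(object, parm, level = 0.95, ...) {
  tab <- do.call(rbind, lapply(seq_len(nrow(object$table)), function(i) {
    sub <- object$p[object$p$color == object$table$color[i] &
                      object$p$context == object$table$context[i], ]
    multiplier_test(sub$p, object$null, conf_level = level)[, c("ci_low", "ci_high")]
  }))
  rownames(tab) <- paste(object$table$color, object$table$context, sep = ".")
  as.matrix(tab)
}

#' Write the resource-split summary table as CSV
#'
#' @param fit A `resource_split` object.
#' @param path File path.
#' @export
write_resource_split <- function(fit, path) {
  utils::write.csv(fit$table, path, row.names = FALSE)
  invisible(path)
}
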