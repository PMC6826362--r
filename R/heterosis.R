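# Mid-parent heterosis percentage and its significance test.
#
# H% = 100 * (F1bar - MP) / MP with MP = (P1bar + P2bar) / 2.
# The t statistic treats the parental means as fixed and tests the F1 mean
# against the mid-parent constant:
#   t = H%(fraction) * (P1bar + P2bar) * sqrt(n1) / (2 * s_F1)
#     = (F1bar - MP) * sqrt(n1) / s_F1,   df = n1 - 1.

#' Mid-parent heterosis percentage
#'
#' @param f1_mean Mean trait value of the hybrid group.
#' @param p1_mean,p2_mean Mean trait values of the two parental lines.
#' @return Heterosis as a percentage of the mid-parent value.
#' @export
heterosis_percent <- function(f1_mean, p1_mean, p2_mean) {
  midparent <- (p1_mean + p2_mean) / 2
  if (any(midparent == 0))
    stop("mid-parent value is zero; heterosis percentage undefined",
         call. = FALSE)
  100 * (f1_mean - midparent) / midparent
}

#' Heterosis t-test from F1 summary statistics
#'
#' The default `t_variant = "delta"` reading is equivalent to the
#' one-sample Student t-test of the F1 mean against the mid-parent value
#' treated as a constant; `"sqrt2"` inflates the SE by sqrt(2) (an
#' alternative reading of the garbled published formula) and is uniformly
#' more conservative.
#'
#' @param f1_mean,s_f1,n1 F1 sample mean, sample SD (divisor n1 - 1) and
#'   size.
#' @param p1_mean,p2_mean Parental group means.
#' @param t_variant `"delta"` (default) or `"sqrt2"`.
#' @param cross Label stored in the result (`"F1A"` or `"F1B"`).
#' @return List of class `heterosis_result`: `cross`, `f1_mean`,
#'   `midparent`, `heterosis_pct`, `t_value`, `df`, `p_value`, `n1`,
#'   `s_f1`, `degenerate` (TRUE when s_f1 = 0).
#' @export
heterosis_t_summary <- function(f1_mean, s_f1, n1, p1_mean, p2_mean,
                                t_variant = c("delta", "sqrt2"),
                                cross = "F1A") {
  t_variant <- match.arg(t_variant)
  if (n1 < 2) stop("need n1 >= 2 F1 observations", call. = FALSE)
  if (s_f1 < 0) stop("s_f1 must be >= 0", call. = FALSE)
  midparent <- (p1_mean + p2_mean) / 2
  hpct <- heterosis_percent(f1_mean, p1_mean, p2_mean)
  df <- n1 - 1
  degenerate <- s_f1 == 0
  if (degenerate) {
    # all F1 identical: off mid-parent is infinitely significant, on it is null
    t_value <- if (hpct == 0) 0 else sign(hpct) * Inf
    p_value <- if (hpct == 0) 1 else 0
  } else {
    t_value <- (hpct / 100) * (p1_mean + p2_mean) * sqrt(n1) / (2 * s_f1)
    if (t_variant == "sqrt2") t_value <- t_value / sqrt(2)
    p_value <- 2 * stats::pt(-abs(t_value), df)
  }
  structure(list(cross = cross, f1_mean = f1_mean, midparent = midparent,
                 heterosis_pct = hpct, t_value = t_value, df = df,
                 p_value = p_value, n1 = n1, s_f1 = s_f1,
                 degenerate = degenerate),
            class = "heterosis_result")
}

#' Heterosis t-test from individual F1 trait values
#'
#' @param f1_values Numeric vector of F1 trait values (length >= 2).
#' @inheritParams heterosis_t_summary
#' @return A `heterosis_result` (see [heterosis_t_summary()]).
#' @export
heterosis_t_test <- function(f1_values, p1_mean, p2_mean,
                             t_variant = c("delta", "sqrt2"),
                             cross = "F1A") {
  if (length(f1_values) < 2)
    stop("need n1 >= 2 F1 observations", call. = FALSE)
  heterosis_t_summary(mean(f1_values), stats::sd(f1_values),
                      length(f1_values), p1_mean, p2_mean,
                      t_variant = t_variant, cross = cross)
}

#' @export
print.heterosis_result <- function(x, ...) {
  star <- if (x$p_value < 0.01) "**" else if (x$p_value < 0.05) "*" else ""
  cat(sprintf(
    "%s: H%% = %.2f%%%s (F1 mean %.3f vs mid-parent %.3f; t = %.3f, df = %d, p = %.3g)\n",
    x$cross, x$heterosis_pct, star, x$f1_mean, x$midparent, x$t_value,
    x$df, x$p_value))
  invisible(x)
}

#' Heterosis report for every cross present in a phenotype table
#'
#' @param pheno A [phenotype_table()].
#' @param sex Which sex to analyse, `"F"` or `"M"`.
#' @inheritParams heterosis_t_summary
#' @return data.frame with one row per cross: `cross`, `n1`, `f1_mean`,
#'   `s_f1`, `midparent`, `heterosis_pct`, `t_value`, `df`, `p_value`.
#' @export
heterosis_report <- function(pheno, sex = c("F", "M"),
                             t_variant = c("delta", "sqrt2")) {
  sex <- match.arg(sex)
  t_variant <- match.arg(t_variant)
  tab <- pheno[pheno$sex == sex, , drop = FALSE]
  for (p in c("P1", "P2")) {
    if (!any(tab$group == p))
      stop("missing parent group ", p, " for sex ", sex, call. = FALSE)
  }
  crosses <- intersect(c("F1A", "F1B"), unique(as.character(tab$group)))
  if (length(crosses) == 0)
    stop("no cross (F1A/F1B) present for sex ", sex, call. = FALSE)
  p1_mean <- mean(tab$trait[tab$group == "P1"])
  p2_mean <- mean(tab$trait[tab$group == "P2"])
  rows <- lapply(crosses, function(cr) {
    r <- heterosis_t_test(tab$trait[tab$group == cr], p1_mean, p2_mean,
                          t_variant = t_variant, cross = cr)
    data.frame(cross = cr, n1 = r$n1, f1_mean = r$f1_mean, s_f1 = r$s_f1,
               midparent = r$midparent, heterosis_pct = r$heterosis_pct,
               t_value = r$t_value, df = r$df, p_value = r$p_value)
  })
  do.call(rbind, rows)
}
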