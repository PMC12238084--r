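# Summary-statistic comparisons computed from published group summaries
# (mean +/- SD, n): two-sample t statistics and mean ratios, as used to
# compare a colchicine-doubled octoploid line with its tetraploid parent.

#' Group summary (mean, SD, n)
#'
#' @param mean Group mean, trait units.
#' @param sd Group standard deviation, trait units (>= 0).
#' @param n Group size (>= 2).
#' @return An object of class `group_summary`.
#' @export
#' @examples
#' group_summary(95.68, 1.36, 10)
group_summary <- function(mean, sd, n) {
  stopifnot(length(mean) == 1, length(sd) == 1, length(n) == 1)
  if (n < 2) stop("n must be at least 2", call. = FALSE)
  if (sd < 0) stop("sd must be non-negative", call. = FALSE)
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "group_summary")
}

#' Two-sample t statistic from group summaries
#'
#' Pooled-variance two-sample t (default):
#' `sp2 = ((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2)`,
#' `t = (mean1 - mean2) / sqrt(sp2 (1/n1 + 1/n2))` — the sign convention
#' is `mean1 - mean2`. With `welch = TRUE` the unpooled (Welch) statistic
#' and Welch-Satterthwaite degrees of freedom are used instead. If both
#' SDs are zero and the means are equal, t is defined as 0.
#'
#' @param g1,g2 [group_summary()] objects.
#' @param welch Use the Welch (unpooled) statistic.
#' @return A list with `statistic` (full precision), `rounded` (two
#'   decimals, half away from zero), `df` and `method`.
#' @export
#' @examples
#' pooled_t_from_summary(group_summary(95.68, 1.36, 10),
#'                       group_summary(55.23, 8.27, 10))$rounded  # 15.26
pooled_t_from_summary <- function(g1, g2, welch = FALSE) {
  stopifnot(inherits(g1, "group_summary"), inherits(g2, "group_summary"))
  delta <- g1$mean - g2$mean
  if (g1$sd == 0 && g2$sd == 0) {
    if (delta == 0)
      return(list(statistic = 0, rounded = 0, df = g1$n + g2$n - 2L,
                  method = if (welch) "welch" else "pooled"))
    stop("both SDs are zero with unequal means: t is unbounded",
         call. = FALSE)
  }
  if (welch) {
    v1 <- g1$sd^2 / g1$n
    v2 <- g2$sd^2 / g2$n
    tstat <- delta / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
    method <- "welch"
  } else {
    sp2 <- ((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / (g1$n + g2$n - 2)
    tstat <- delta / sqrt(sp2 * (1 / g1$n + 1 / g2$n))
    df <- g1$n + g2$n - 2
    method <- "pooled"
  }
  list(statistic = tstat, rounded = .round_half_up(tstat, 2L), df = df,
       method = method)
}

#' Ratio of group means
#'
#' @param g1,g2 [group_summary()] objects (or bare numeric means).
#' @return A list with `ratio` (mean1 / mean2, full precision) and
#'   `rounded` (one decimal, half away from zero).
#' @export
#' @examples
#' ratio_of_means(group_summary(4.23, 0.57, 10),
#'                group_summary(2.40, 0.43, 10))$rounded   # 1.8
ratio_of_means <- function(g1, g2) {
  m1 <- if (inherits(g1, "group_summary")) g1$mean else as.numeric(g1)
  m2 <- if (inherits(g2, "group_summary")) g2$mean else as.numeric(g2)
  if (m2 == 0) stop("denominator mean is zero", call. = FALSE)
  r <- m1 / m2
  list(ratio = r, rounded = .round_half_up(r, 1L))
}
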