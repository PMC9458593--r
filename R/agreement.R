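# Frozen-vs-paraffin method agreement statistics.

#' Bland-Altman analysis of paired measurements
#'
#' Differences are frozen minus paraffin.  Limits of agreement are
#' `mean +/- 1.96 * SD` with the sample (n-1) standard deviation; 1.96 is
#' used exactly, not a t-quantile.  Proportional bias is tested by ordinary
#' least-squares regression of the difference on the pair mean, with a
#' two-sided t-test on the slope.
#'
#' @param frozen,paraffin Numeric vectors of paired measurements (e.g. SRIA
#'   in percent), length >= 3.
#' @return Object of class `"srq_bland_altman"` with `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `bias_slope_beta`, `bias_p`, `n_pairs`.
#' @export
bland_altman <- function(frozen, paraffin) {
  if (length(frozen) != length(paraffin))
    stop("frozen and paraffin must have equal length", call. = FALSE)
  n <- length(frozen)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (!all(is.finite(frozen)) || !all(is.finite(paraffin)))
    stop("measurements must be finite", call. = FALSE)
  d <- frozen - paraffin
  m <- (frozen + paraffin) / 2
  mean_diff <- mean(d)
  sd_diff <- stats::sd(d)
  if (stats::var(m) > 0 && sd_diff > 0) {
    fit <- stats::lm(d ~ m)
    sl <- summary(fit)$coefficients
    beta <- sl["m", "Estimate"]; bias_p <- sl["m", "Pr(>|t|)"]
    degenerate <- FALSE
  } else if (stats::var(m) > 0) {
    beta <- 0; bias_p <- 1; degenerate <- FALSE   # constant offset: slope 0
  } else {
    beta <- NA_real_; bias_p <- NA_real_; degenerate <- TRUE
  }
  structure(list(mean_diff = mean_diff, sd_diff = sd_diff,
                 loa_low = mean_diff - 1.96 * sd_diff,
                 loa_high = mean_diff + 1.96 * sd_diff,
                 bias_slope_beta = beta, bias_p = bias_p,
                 slope_degenerate = degenerate, n_pairs = n),
            class = "srq_bland_altman")
}

#' @export
print.srq_bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): mean difference %.2f pp, LoA [%.2f, %.2f]\n",
              x$n_pairs, x$mean_diff, x$loa_low, x$loa_high))
  if (isTRUE(x$slope_degenerate))
    cat("  proportional-bias slope undefined (no spread in pair means)\n")
  else
    cat(sprintf("  proportional-bias slope %.4f (p = %.3g)\n",
                x$bias_slope_beta, x$bias_p))
  invisible(x)
}

#' Two-way consistency, average-measures intraclass correlation
#'
#' ICC(C,k) for two raters from the two-way ANOVA decomposition over
#' n subjects x 2 measurements: `ICC = (MS_subjects - MS_error)/MS_subjects
#' = 1 - 1/F` with `F = MS_subjects / MS_error` on (n-1, n-1) degrees of
#' freedom.  The confidence interval uses F-quantiles:
#' `ci_low = 1 - F*_(1-alpha/2)/F`, `ci_high = 1 - 1/(F F*_(1-alpha/2))`.
#' Consistency ignores a constant shift between the raters.
#'
#' @param x,y Paired measurement vectors, length n >= 3.
#' @param alpha Two-sided confidence level is `1 - alpha`.
#' @return Object of class `"srq_icc"` with `icc`, `f_value`, `df1`, `df2`,
#'   `ci_low`, `ci_high`, `p`, `model`.
#' @export
icc_consistency_average <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 subjects", call. = FALSE)
  dat <- cbind(x, y)
  grand <- mean(dat)
  subj_means <- rowMeans(dat)
  rater_means <- colMeans(dat)
  ss_subj <- 2 * sum((subj_means - grand)^2)
  ss_rater <- n * sum((rater_means - grand)^2)
  ss_tot <- sum((dat - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_rater
  ms_subj <- ss_subj / (n - 1)
  ms_err <- ss_err / (n - 1)
  degenerate <- ms_err <= .Machine$double.eps * ms_subj
  if (degenerate) {
    f <- Inf; icc <- 1; ci <- c(1, 1); p <- 0
  } else {
    f <- ms_subj / ms_err
    icc <- 1 - 1 / f
    fq <- stats::qf(1 - alpha / 2, n - 1, n - 1)
    ci <- c(1 - fq / f, 1 - 1 / (f * fq))
    p <- stats::pf(f, n - 1, n - 1, lower.tail = FALSE)
  }
  structure(list(icc = icc, f_value = f, df1 = n - 1L, df2 = n - 1L,
                 ci_low = ci[1L], ci_high = ci[2L], p = p,
                 degenerate = degenerate,
                 model = "two-way consistency, average measures"),
            class = "srq_icc")
}

#' Reconstruct the average-measures consistency ICC from a printed F value
#'
#' Applies the identity `ICC = 1 - 1/F` and the F-quantile interval without
#' access to the raw data, for checking reported statistics.
#'
#' @param f_value F statistic `MS_subjects / MS_error`.
#' @param df1,df2 Its degrees of freedom (both n-1 for two raters).
#' @param alpha Two-sided confidence level is `1 - alpha`.
#' @return An `srq_icc`.
#' @export
icc_from_f <- function(f_value, df1, df2, alpha = 0.05) {
  stopifnot_scalar_number(f_value, "f_value", lo = .Machine$double.xmin)
  fq <- stats::qf(1 - alpha / 2, df1, df2)
  structure(list(icc = 1 - 1 / f_value, f_value = f_value,
                 df1 = df1, df2 = df2,
                 ci_low = 1 - fq / f_value, ci_high = 1 - 1 / (f_value * fq),
                 p = stats::pf(f_value, df1, df2, lower.tail = FALSE),
                 degenerate = FALSE,
                 model = "two-way consistency, average measures"),
            class = "srq_icc")
}

#' @export
print.srq_icc <- function(x, ...) {
  cat(sprintf("ICC (%s): %.3f, 95%% CI [%.3f, %.3f], F(%d,%d) = %.3f, p = %.3g\n",
              x$model, x$icc, x$ci_low, x$ci_high, x$df1, x$df2, x$f_value, x$p))
  invisible(x)
}

#' Quadratic-weighted Cohen's kappa for ordered grades
#'
#' `kappa = 1 - sum(w O) / sum(w E)` with disagreement weights
#' `w_ij = ((i - j)/(K - 1))^2`, observed cell proportions O, and expected
#' proportions E from the outer product of the marginals.  With two
#' categories the quadratic weights coincide with the unweighted kappa.
#'
#' @param a,b Integer grade vectors on the same scale.
#' @param levels Grade levels defining the K x K table (default: all values
#'   observed in either rater).
#' @return Object of class `"srq_kappa"` with `kappa`, `confusion`, `n`.
#' @export
weighted_kappa <- function(a, b, levels = NULL) {
  if (length(a) != length(b)) stop("a and b must have equal length", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("grades must not be missing", call. = FALSE)
  if (is.null(levels)) levels <- sort(unique(c(a, b)))
  K <- length(levels)
  if (K < 2L)
    stop("a single category is present in both raters; kappa is undefined",
         call. = FALSE)
  if (!all(a %in% levels) || !all(b %in% levels))
    stop("grades outside the stated levels", call. = FALSE)
  fa <- factor(a, levels = levels); fb <- factor(b, levels = levels)
  confusion <- table(fa, fb)
  n <- length(a)
  O <- confusion / n
  E <- outer(rowSums(O), colSums(O))
  idx <- seq_len(K) - 1L
  W <- outer(idx, idx, function(i, j) ((i - j) / (K - 1))^2)
  we <- sum(W * E)
  if (we == 0)
    stop("expected disagreement is zero (degenerate marginals); kappa undefined",
         call. = FALSE)
  structure(list(kappa = 1 - sum(W * O) / we, weight_scheme = "quadratic",
                 confusion = unclass(confusion), levels = levels, n = n),
            class = "srq_kappa")
}

#' @export
print.srq_kappa <- function(x, ...) {
  cat(sprintf("Quadratic-weighted Cohen's kappa: %.3f (n = %d, %d categories)\n",
              x$kappa, x$n, length(x$levels)))
  invisible(x)
}

#' Compare frozen-paraffin differences between two subgroups
#'
#' Splits the per-pair differences by a dichotomous factor and compares the
#' groups with an unpaired t-test when both pass a Shapiro-Wilk normality
#' gate (alpha = 0.05), otherwise a Mann-Whitney U test (exact for combined
#' n <= 12 without ties, normal approximation with tie correction
#' otherwise).
#'
#' @param diffs Numeric vector of frozen-paraffin differences.
#' @param group Logical/two-level vector assigning each pair to a subgroup.
#' @param factor_name Label for reporting.
#' @param test `"auto"` (the normality gate, default) or a forced choice of
#'   `"t_test"` / `"mann_whitney"`.
#' @return Object of class `"srq_subgroup"` with `group_means`, `test_used`,
#'   `statistic`, `p`.
#' @export
subgroup_difference <- function(diffs, group, factor_name = "factor",
                                test = c("auto", "t_test", "mann_whitney")) {
  test <- match.arg(test)
  if (length(diffs) != length(group))
    stop("diffs and group must have equal length", call. = FALSE)
  keep <- !is.na(diffs) & !is.na(group)
  diffs <- diffs[keep]; group <- group[keep]
  g <- as.factor(group)
  if (nlevels(g) != 2L || any(table(g) == 0))
    stop(sprintf("factor '%s' must split the pairs into two non-empty groups",
                 factor_name), call. = FALSE)
  x1 <- diffs[g == levels(g)[1L]]
  x2 <- diffs[g == levels(g)[2L]]
  if (length(x1) < 3L || length(x2) < 3L)
    stop(sprintf("factor '%s': need >= 3 pairs per subgroup", factor_name),
         call. = FALSE)
  normal_ok <- function(v)
    stats::var(v) > 0 && stats::shapiro.test(v)$p.value >= 0.05
  use_t <- switch(test, auto = normal_ok(x1) && normal_ok(x2),
                  t_test = TRUE, mann_whitney = FALSE)
  if (use_t) {
    tt <- stats::t.test(x1, x2)
    test_used <- "t_test"; statistic <- unname(tt$statistic); p <- tt$p.value
  } else {
    exact <- (length(x1) + length(x2)) <= 12L && !any(duplicated(c(x1, x2)))
    wt <- suppressWarnings(stats::wilcox.test(x1, x2, exact = exact,
                                              correct = TRUE))
    test_used <- "mann_whitney"; statistic <- unname(wt$statistic); p <- wt$p.value
  }
  structure(list(factor = factor_name,
                 group_levels = levels(g),
                 group_ns = c(length(x1), length(x2)),
                 group_means = c(mean(x1), mean(x2)),
                 test_used = test_used, statistic = statistic, p = p),
            class = "srq_subgroup")
}

#' @export
print.srq_subgroup <- function(x, ...) {
  cat(sprintf("Subgroup '%s' (%s: n=%d, mean %.2f | %s: n=%d, mean %.2f): %s, p = %.3g\n",
              x$factor, x$group_levels[1L], x$group_ns[1L], x$group_means[1L],
              x$group_levels[2L], x$group_ns[2L], x$group_means[2L],
              x$test_used, x$p))
  invisible(x)
}

#' Flag relevant frozen-vs-paraffin disagreement for one pair
#'
#' A pair is flagged when the two SRIA values differ by at least 10
#' percentage points, or when the two IF grades (if both are given)
#' disagree at all.
#'
#' @param sria_frozen,sria_paraffin SRIA percentages.
#' @param if_frozen,if_paraffin Optional IF grades.
#' @param sria_threshold_pp Flagging threshold in percentage points.
#' @return List with logical `sria_flag` and `score_flag` (`NA` when grades
#'   are absent).
#' @export
relevant_difference_flags <- function(sria_frozen, sria_paraffin,
                                      if_frozen = NA_integer_,
                                      if_paraffin = NA_integer_,
                                      sria_threshold_pp = 10) {
  list(sria_flag = abs(sria_frozen - sria_paraffin) >= sria_threshold_pp,
       score_flag = if (is.na(if_frozen) || is.na(if_paraffin)) NA
                    else if_frozen != if_paraffin)
}

#' Agreement report for a table of included pairs
#'
#' Runs Bland-Altman, the average-measures consistency ICC, the
#' quadratic-weighted kappa on the SRIA-derived IF grades, per-pair
#' relevant-difference flags, and the requested subgroup comparisons.
#'
#' @param pairs Data frame as produced by the pipeline (columns
#'   `sria_frozen`, `sria_paraffin`, `if_frozen`, `if_paraffin`, and the
#'   donor covariates for subgroup rules).
#' @param subgroups Character vector of built-in subgroup rules among
#'   `"donor_age_gt60"`, `"male_donor"`, `"cit_gt20"`, `"nhbd"`.
#' @return Object of class `"srq_agreement"`.
#' @export
agreement_report <- function(pairs, subgroups = character()) {
  inc <- pairs[isTRUE_vec(pairs$included), , drop = FALSE]
  if (nrow(inc) == 0L)
    return(structure(list(n_included = 0L, bland_altman = NULL, icc = NULL,
                          kappa = NULL, flags = NULL, subgroups = list()),
                     class = "srq_agreement"))
  ba <- if (nrow(inc) >= 3L) bland_altman(inc$sria_frozen, inc$sria_paraffin)
  icc <- if (nrow(inc) >= 3L)
    icc_consistency_average(inc$sria_frozen, inc$sria_paraffin)
  kap <- tryCatch(weighted_kappa(inc$if_frozen, inc$if_paraffin, levels = 0:3),
                  error = function(e) NULL)
  flags <- data.frame(
    biopsy_id = inc$biopsy_id,
    sria_flag = abs(inc$sria_frozen - inc$sria_paraffin) >= 10,
    score_flag = inc$if_frozen != inc$if_paraffin)
  rules <- list(
    donor_age_gt60 = function(d) d$donor_age > 60,
    male_donor     = function(d) d$donor_male,
    cit_gt20       = function(d) d$cit_hours > 20,
    nhbd           = function(d) d$donor_type == "NHBD")
  sub <- list()
  for (s in subgroups) {
    if (is.null(rules[[s]])) stop("unknown subgroup rule: ", s, call. = FALSE)
    sub[[s]] <- tryCatch(
      subgroup_difference(inc$diff, rules[[s]](inc), factor_name = s),
      error = function(e) list(factor = s, error = conditionMessage(e)))
  }
  structure(list(n_included = nrow(inc), bland_altman = ba, icc = icc,
                 kappa = kap, flags = flags, subgroups = sub),
            class = "srq_agreement")
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.srq_agreement <- function(x, ...) {
  cat(sprintf("Agreement report over %d included pairs\n", x$n_included))
  if (!is.null(x$bland_altman)) print(x$bland_altman)
  if (!is.null(x$icc)) print(x$icc)
  if (!is.null(x$kappa)) print(x$kappa)
  for (s in x$subgroups)
    if (inherits(s, "srq_subgroup")) print(s)
    else cat(sprintf("Subgroup '%s': %s\n", s$factor, s$error))
  invisible(x)
}
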