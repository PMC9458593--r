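# Delayed-graft-function outcome modelling: univariate logistic screens,
# a p < 0.1 candidate rule, a multivariate logistic model with Wald
# odds-ratio confidence intervals, and VIF collinearity checks.

#' Fit a logistic regression for a binary outcome
#'
#' Maximum likelihood via iteratively reweighted least squares
#' (`stats::glm`, binomial family, relative-convergence 1e-8, at most 100
#' iterations).  Reported per term: coefficient, standard error, Wald z
#' p-value, odds ratio `exp(coef)` and 95% CI `exp(coef +/- 1.96 se)`.
#' With two or more covariates, VIFs are computed on the design matrix
#' excluding the intercept.  (Quasi-)complete separation is detected from
#' boundary fitted probabilities and flagged as non-convergence.
#'
#' @param data Data frame of records.
#' @param outcome Name of the logical/0-1 outcome column (default `"dgf"`).
#' @param covariates Character vector of covariate column names; empty for
#'   an intercept-only model.
#' @return Object of class `"srq_logit"`: `terms` data frame (name,
#'   coefficient, se, odds_ratio, ci_low, ci_high, p, vif), `intercept`,
#'   `n`, `converged`, `diagnostic`, and the underlying `glm` fit.
#' @export
fit_logistic <- function(data, outcome = "dgf", covariates = character()) {
  if (!outcome %in% names(data)) stop("outcome column not found: ", outcome,
                                      call. = FALSE)
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov))
    stop("covariate column not found: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  cols <- c(outcome, covariates)
  dat <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  y <- as.integer(dat[[outcome]])
  if (length(unique(y)) < 2L)
    stop("outcome has a single class; logistic model is undefined", call. = FALSE)
  if (nrow(dat) <= length(covariates) + 1L)
    stop("more terms than observations", call. = FALSE)
  fml <- stats::reformulate(if (length(covariates)) covariates else "1",
                            response = outcome)
  fit <- suppressWarnings(stats::glm(
    fml, data = dat, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 100L)))
  probs <- stats::fitted(fit)
  separated <- any(probs > 1 - 1e-8) || any(probs < 1e-8)
  converged <- isTRUE(fit$converged) && !separated
  diagnostic <- if (separated)
    "boundary fitted probabilities: (quasi-)complete separation suspected"
  else if (!fit$converged) "IRLS did not converge" else NA_character_
  cf <- summary(fit)$coefficients
  term_names <- setdiff(rownames(cf), "(Intercept)")
  vifs <- if (length(covariates) >= 2L)
    vif(dat[covariates])$vif else rep(NA_real_, length(term_names))
  terms <- data.frame(
    name = term_names,
    coefficient = cf[term_names, "Estimate"],
    se = cf[term_names, "Std. Error"],
    odds_ratio = exp(cf[term_names, "Estimate"]),
    ci_low = exp(cf[term_names, "Estimate"] - 1.96 * cf[term_names, "Std. Error"]),
    ci_high = exp(cf[term_names, "Estimate"] + 1.96 * cf[term_names, "Std. Error"]),
    p = cf[term_names, "Pr(>|z|)"],
    vif = vifs,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(terms = terms, intercept = unname(cf["(Intercept)", "Estimate"]),
                 n = nrow(dat), converged = converged, diagnostic = diagnostic,
                 outcome = outcome, fit = fit),
            class = "srq_logit")
}

#' @export
print.srq_logit <- function(x, digits = 3, ...) {
  cat(sprintf("Logistic model for %s (n = %d%s): intercept = %.2f\n",
              x$outcome, x$n,
              if (x$converged) "" else "; NOT CONVERGED", x$intercept))
  if (!is.na(x$diagnostic)) cat("  ", x$diagnostic, "\n", sep = "")
  if (nrow(x$terms)) {
    tab <- x$terms
    tab$odds_ratio <- round(tab$odds_ratio, digits)
    tab$ci <- sprintf("%.3f-%.3f", tab$ci_low, tab$ci_high)
    tab$p <- signif(tab$p, 2)
    print(tab[, c("name", "odds_ratio", "ci", "p", "vif")], row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.srq_logit <- function(object, ...) {
  c("(Intercept)" = object$intercept,
    stats::setNames(object$terms$coefficient, object$terms$name))
}

#' Univariate logistic screen with a p-value entry rule
#'
#' Fits one single-covariate logistic model per candidate and retains the
#' candidates whose Wald p-value is below `alpha_in` (default 0.1), the
#' entry rule for the subsequent multivariate model.  A failing fit is
#' recorded per covariate and does not abort the screen.
#'
#' @param data Data frame of records.
#' @param candidates Character vector of covariate names.
#' @param outcome Outcome column name.
#' @param alpha_in Retention threshold on the Wald p-value.
#' @return Object of class `"srq_screen"`: `fits` (named list of
#'   `srq_logit` or error message), `table` (name, odds_ratio, ci, p,
#'   retained), `retained` (character vector).
#' @export
univariate_screen <- function(data, candidates, outcome = "dgf", alpha_in = 0.1) {
  if (length(candidates) < 1L) stop("need at least one candidate", call. = FALSE)
  fits <- stats::setNames(lapply(candidates, function(cv)
    tryCatch(fit_logistic(data, outcome, cv),
             error = function(e) conditionMessage(e))), candidates)
  rows <- lapply(candidates, function(cv) {
    f <- fits[[cv]]
    if (inherits(f, "srq_logit")) {
      t1 <- f$terms[1L, ]
      data.frame(name = cv, odds_ratio = t1$odds_ratio, ci_low = t1$ci_low,
                 ci_high = t1$ci_high, p = t1$p, intercept = f$intercept,
                 n = f$n, retained = is.finite(t1$p) && t1$p < alpha_in,
                 error = NA_character_, stringsAsFactors = FALSE)
    } else {
      data.frame(name = cv, odds_ratio = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, p = NA_real_, intercept = NA_real_,
                 n = NA_integer_, retained = FALSE, error = f,
                 stringsAsFactors = FALSE)
    }
  })
  tab <- do.call(rbind, rows)
  structure(list(fits = fits, table = tab,
                 retained = tab$name[tab$retained], alpha_in = alpha_in,
                 outcome = outcome),
            class = "srq_screen")
}

#' @export
print.srq_screen <- function(x, ...) {
  cat(sprintf("Univariate screen for %s (entry rule p < %g):\n",
              x$outcome, x$alpha_in))
  tab <- x$table
  tab$odds_ratio <- round(tab$odds_ratio, 3)
  tab$ci <- ifelse(is.na(tab$ci_low), NA,
                   sprintf("%.3f-%.3f", tab$ci_low, tab$ci_high))
  tab$p <- signif(tab$p, 2)
  print(tab[, c("name", "odds_ratio", "ci", "p", "retained")], row.names = FALSE)
  invisible(x)
}

#' Screen-then-fit delayed-graft-function model
#'
#' Runs the univariate screen, then fits the multivariate logistic model on
#' the retained candidates (an intercept-only model when none is retained).
#'
#' @inheritParams univariate_screen
#' @return List with `screen` (`srq_screen`) and `multivariate`
#'   (`srq_logit`).
#' @export
dgf_model <- function(data, candidates, outcome = "dgf", alpha_in = 0.1) {
  scr <- univariate_screen(data, candidates, outcome, alpha_in)
  multi <- fit_logistic(data, outcome, scr$retained)
  list(screen = scr, multivariate = multi)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from the ordinary
#' least-squares regression of covariate j on the remaining covariates.
#' Exact collinearity is reported as an infinite VIF.
#'
#' @param covariates Data frame or numeric matrix of >= 2 non-constant
#'   columns (logicals are coerced to 0/1).
#' @return Data frame with columns `name` and `vif`.
#' @export
vif <- function(covariates) {
  X <- as.data.frame(covariates)
  X[] <- lapply(X, function(col) as.numeric(col))
  if (ncol(X) < 2L) stop("need at least 2 covariates", call. = FALSE)
  if (any(vapply(X, function(col) stats::var(col) == 0, logical(1L))))
    stop("constant covariate column", call. = FALSE)
  out <- vapply(seq_len(ncol(X)), function(j) {
    r2 <- suppressWarnings(summary(stats::lm(X[[j]] ~ ., data = X[-j]))$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1L))
  data.frame(name = names(X), vif = out, row.names = NULL,
             stringsAsFactors = FALSE)
}
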