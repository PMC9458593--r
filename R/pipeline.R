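# End-to-end orchestration: quantify -> pair/include -> agreement ->
# Remuzzi translation -> outcome models, with machine-readable artefacts
# and a reproducible run manifest.

#' Cross-tabulate two gradings of the same biopsies
#'
#' @param grades_a,grades_b Equal-length integer grade vectors in 0..K-1.
#' @param K Number of grade categories (4 for the Remuzzi IF grade).
#' @return Object of class `"srq_score_matrix"` (a K x K count matrix).
#' @export
build_score_matrix <- function(grades_a, grades_b, K = 4L) {
  if (length(grades_a) != length(grades_b))
    stop("grade vectors must have equal length", call. = FALSE)
  lev <- 0:(K - 1L)
  if (!all(grades_a %in% lev) || !all(grades_b %in% lev))
    stop("grades must lie in 0..", K - 1L, call. = FALSE)
  m <- table(factor(grades_a, levels = lev), factor(grades_b, levels = lev))
  structure(unclass(m), class = "srq_score_matrix")
}

#' @export
print.srq_score_matrix <- function(x, ...) {
  cat("Score matrix (rows: method A, cols: method B)\n")
  print(unclass(x))
  invisible(x)
}

#' Plot a score matrix as a heat-map-style grid
#'
#' @param x An `srq_score_matrix`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.srq_score_matrix <- function(x, ...) {
  K <- nrow(x)
  graphics::image(0:(K - 1L), 0:(K - 1L), t(unclass(x))[, K:1, drop = FALSE],
                  xlab = "method B grade", ylab = "method A grade",
                  axes = FALSE, ...)
  graphics::axis(1, at = 0:(K - 1L)); graphics::axis(2, at = 0:(K - 1L),
                                                     labels = (K - 1L):0)
  for (i in seq_len(K)) for (j in seq_len(K))
    graphics::text(j - 1L, K - i, x[i, j])
  invisible(x)
}

#' Pipeline configuration
#'
#' @param output_dir Directory for artefacts (created if needed).
#' @param n_pairs Number of simulated section pairs (ignored when
#'   `image_stems` is given).
#' @param true_fraction_range Range of ground-truth paraffin fractions the
#'   simulated pairs sweep, percent.
#' @param frozen_delta_pct Mean additive frozen artefact, percentage points.
#' @param frozen_delta_sd_pct Between-pair SD of the artefact; the default
#'   7.9 pp is the spread implied by the published limits of agreement.
#'   Set to 0 for an exactly constant artefact.
#' @param width_px,height_px,microns_per_pixel Simulated image geometry.
#' @param image_stems Optional list of `c(frozen = stem, paraffin = stem)`
#'   pairs for file-based runs (see [read_section_image()]).
#' @param cohort_csv Optional path to a clinical cohort CSV; when `NULL` a
#'   synthetic cohort of `n_patients` is generated.
#' @param n_patients Synthetic cohort size.
#' @param channel_method,threshold Quantification options (see
#'   [quantify_pair()]).
#' @param cutpoints Remuzzi IF cutpoints, percent.
#' @param min_area_mm2 Pair-inclusion rule.
#' @param subgroups Subgroup comparison rules (see [agreement_report()]).
#' @param screen_alpha Univariate entry rule for the DGF model.
#' @param seed Integer master seed; all randomness derives from it.
#' @return Object of class `"srq_pipeline_config"`.
#' @export
pipeline_config <- function(output_dir,
                            n_pairs = 10L,
                            true_fraction_range = c(15, 50),
                            frozen_delta_pct = 7.8,
                            frozen_delta_sd_pct = 7.9,
                            width_px = 768L, height_px = 768L,
                            microns_per_pixel = 2,
                            image_stems = NULL,
                            cohort_csv = NULL, n_patients = 200L,
                            channel_method = "deconvolution",
                            threshold = "otsu",
                            cutpoints = c(5, 20, 50),
                            min_area_mm2 = 1.0,
                            subgroups = c("donor_age_gt60", "male_donor",
                                          "cit_gt20", "nhbd"),
                            screen_alpha = 0.1,
                            seed = 1L) {
  structure(as.list(environment()), class = "srq_pipeline_config")
}

# per-pair donor covariates for simulated runs (invented distributions,
# matching the cohort generator's defaults)
.sim_pair_covariates <- function() {
  list(donor_age = round(clamp(stats::rnorm(1, 64, 14), 18, 88)),
       donor_male = stats::runif(1) < 0.644,
       donor_type = if (stats::runif(1) < 0.822) "BDD" else "NHBD",
       cit_hours = clamp(stats::rlnorm(1, log(17), 0.35), 2, 48))
}

#' Run the full analysis pipeline
#'
#' Simulated mode generates `n_pairs` frozen/paraffin section pairs and a
#' synthetic cohort; file mode reads section images and a cohort CSV.
#' Stages: quantification, pair inclusion, agreement statistics, Remuzzi
#' translation with a frozen-vs-paraffin score matrix, and the DGF
#' screen-then-fit logistic model.  Artefacts (`pairs.csv`,
#' `agreement.json`, `score_matrix.csv`, `dgf_models.json`,
#' `manifest.json`, `run.log`) are written to `config$output_dir`; the
#' manifest carries the seed, parameters, versions and artefact checksums,
#' and together with the seed fully determines all outputs.  Per-biopsy
#' stage errors are logged and skipped; global errors abort.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `"srq_run"`, invisibly: the pair table,
#'   agreement report, score matrix, DGF models and manifest.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "srq_pipeline_config"))
    stop("`config` must come from pipeline_config()", call. = FALSE)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$output_dir, "run.log")
  log_con <- file(log_path, "w"); on.exit(close(log_con))
  logmsg <- function(...) {
    line <- sprintf(...)
    message(line); writeLines(line, log_con)
  }

  # --- stage 1: section pairs -------------------------------------------
  pairs <- list()
  if (is.null(config$image_stems)) {
    fr <- config$true_fraction_range
    truths <- if (config$n_pairs == 1L) mean(fr) else
      seq(fr[1L], fr[2L], length.out = config$n_pairs)
    deltas <- with_local_seed(config$seed * 1000L + 999L, {
      d <- stats::rnorm(config$n_pairs, config$frozen_delta_pct,
                        config$frozen_delta_sd_pct)
      clamp(d, 0.5 - truths, 99.5 - truths)   # keep frozen truth in (0, 100)
    })
    for (i in seq_len(config$n_pairs)) {
      id <- sprintf("sim-%03d", i)
      res <- tryCatch({
        sc <- section_sim_config(width_px = config$width_px,
                                 height_px = config$height_px,
                                 microns_per_pixel = config$microns_per_pixel,
                                 true_fraction_pct = truths[i],
                                 frozen_delta_pct = deltas[i],
                                 seed = config$seed * 1000L + i)
        pair_imgs <- simulate_section_pair(sc, biopsy_id = id)
        cov <- with_local_seed(config$seed * 1000L + 500L + i,
                               .sim_pair_covariates())
        quantify_pair(pair_imgs$frozen, pair_imgs$paraffin,
                      method = config$channel_method,
                      threshold = config$threshold, covariates = cov)
      }, error = function(e) e)
      if (inherits(res, "error")) logmsg("[%s] stage error: %s", id,
                                         conditionMessage(res))
      else pairs[[id]] <- res
    }
  } else {
    for (id in names(config$image_stems)) {
      res <- tryCatch({
        st <- config$image_stems[[id]]
        quantify_pair(read_section_image(st[["frozen"]]),
                      read_section_image(st[["paraffin"]]),
                      method = config$channel_method,
                      threshold = config$threshold)
      }, error = function(e) e)
      if (inherits(res, "error")) logmsg("[%s] stage error: %s", id,
                                         conditionMessage(res))
      else pairs[[id]] <- res
    }
  }
  pairs <- lapply(pairs, check_pair_inclusion,
                  min_area_mm2 = config$min_area_mm2)
  ptab <- if (length(pairs)) pairs_table(pairs, config$cutpoints) else NULL
  if (!is.null(ptab)) {
    n_exc <- sum(!ptab$included)
    if (n_exc) logmsg("%d pair(s) excluded by the %g mm2 rule", n_exc,
                      config$min_area_mm2)
    utils::write.csv(ptab, file.path(config$output_dir, "pairs.csv"),
                     row.names = FALSE)
  }

  # --- stage 2: agreement ------------------------------------------------
  agreement <- if (!is.null(ptab))
    agreement_report(ptab, subgroups = config$subgroups) else NULL
  if (!is.null(agreement)) {
    if (agreement$n_included < 3L)
      logmsg("fewer than 3 included pairs: no ICC / Bland-Altman emitted")
    jsonlite::write_json(agreement_as_list(agreement),
                         file.path(config$output_dir, "agreement.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  score_matrix <- NULL
  if (!is.null(ptab) && any(isTRUE_vec(ptab$included))) {
    inc <- ptab[isTRUE_vec(ptab$included), ]
    score_matrix <- build_score_matrix(inc$if_frozen, inc$if_paraffin)
    utils::write.csv(as.data.frame(unclass(score_matrix)),
                     file.path(config$output_dir, "score_matrix.csv"))
  }

  # --- stage 3: outcome modelling ---------------------------------------
  cohort <- if (is.null(config$cohort_csv))
    generate_cohort(cohort_sim_config(n_patients = config$n_patients,
                                      seed = config$seed))
  else utils::read.csv(config$cohort_csv, stringsAsFactors = FALSE)
  candidates <- intersect(c("sria_paraffin_pct", "sria_frozen_pct",
                            "if_grade_original", "remuzzi_final_grade",
                            "cit_hours", "donor_age", "donor_male",
                            "recipient_age", "recipient_male", "dsa_present"),
                          names(cohort))
  dgf <- tryCatch(dgf_model(cohort, candidates, alpha_in = config$screen_alpha),
                  error = function(e) { logmsg("DGF stage error: %s",
                                               conditionMessage(e)); NULL })
  if (!is.null(dgf))
    jsonlite::write_json(dgf_as_list(dgf),
                         file.path(config$output_dir, "dgf_models.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")

  # --- manifest ----------------------------------------------------------
  artefacts <- intersect(c("pairs.csv", "agreement.json", "score_matrix.csv",
                           "dgf_models.json"),
                         list.files(config$output_dir))
  cfg <- unclass(config); cfg$output_dir <- NULL
  manifest <- list(
    tool = "sriaquant",
    version = as.character(utils::packageVersion("sriaquant")),
    r_version = R.version.string,
    seed = config$seed,
    parameters = cfg,
    artefacts = lapply(stats::setNames(artefacts, artefacts), function(f)
      unname(tools::md5sum(file.path(config$output_dir, f)))))
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  logmsg("run complete: %d pairs analysed, artefacts in %s",
         length(pairs), config$output_dir)
  invisible(structure(list(pairs = ptab, agreement = agreement,
                           score_matrix = score_matrix, dgf = dgf,
                           cohort = cohort, manifest = manifest),
                      class = "srq_run"))
}

#' @export
print.srq_run <- function(x, ...) {
  cat(sprintf("<srq_run> %d pairs, cohort n = %d\n",
              if (is.null(x$pairs)) 0L else nrow(x$pairs),
              if (is.null(x$cohort)) 0L else nrow(x$cohort)))
  if (!is.null(x$agreement)) print(x$agreement)
  if (!is.null(x$dgf)) print(x$dgf$multivariate)
  invisible(x)
}

# ---- plain-list serialisers (every reported number reaches JSON) --------

agreement_as_list <- function(x) {
  list(n_included = x$n_included,
       bland_altman = if (!is.null(x$bland_altman)) unclass(x$bland_altman),
       icc = if (!is.null(x$icc)) unclass(x$icc),
       kappa = if (!is.null(x$kappa)) {
         k <- unclass(x$kappa); k$confusion <- as.data.frame.matrix(k$confusion); k
       },
       flags = x$flags,
       subgroups = lapply(x$subgroups, function(s)
         if (inherits(s, "srq_subgroup")) unclass(s) else s))
}

dgf_as_list <- function(x) {
  list(screen = list(alpha_in = x$screen$alpha_in, table = x$screen$table,
                     retained = x$screen$retained),
       multivariate = list(terms = x$multivariate$terms,
                           intercept = x$multivariate$intercept,
                           n = x$multivariate$n,
                           converged = x$multivariate$converged))
}
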