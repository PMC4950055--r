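# End-to-end chart-construction analysis: record selection, summaries,
# secular-trend and missingness regressions, reference comparison.

#' Select analysable records
#'
#' Applies, in order: outcome is a live birth; karyotype is free trisomy
#' 21; birth weight and gestation both recorded; gestation within the
#' fit window. The order fixes how each exclusion is charged, so the
#' per-stage counts are well defined.
#'
#' @param records data.frame of birth records.
#' @param week_range integer pair: gestational fit window.
#' @return A list with `records` (the retained data.frame) and `report`
#'   (class `selection_report`: per-stage entered/excluded/retained
#'   counts).
#' @export
select_records <- function(records, week_range = c(28L, 43L)) {
  records <- as.data.frame(records)
  stages <- list(
    live_birth = function(d) !is.na(d$outcome) & d$outcome == "live_birth",
    free_trisomy_21 = function(d) !is.na(d$karyotype) &
      d$karyotype == "free_trisomy_21",
    complete_weight_and_gestation = function(d) !is.na(d$weight_g) &
      !is.na(d$gest_weeks),
    gestation_in_window = function(d) d$gest_weeks >= week_range[1] &
      d$gest_weeks <= week_range[2]
  )
  total <- nrow(records)
  rep_df <- data.frame(stage = names(stages), entered = NA_integer_,
                       excluded = NA_integer_, retained = NA_integer_)
  d <- records
  for (i in seq_along(stages)) {
    keep <- stages[[i]](d)
    rep_df$entered[i] <- nrow(d)
    rep_df$excluded[i] <- sum(!keep)
    d <- d[keep, , drop = FALSE]
    rep_df$retained[i] <- nrow(d)
  }
  rownames(d) <- NULL
  report <- structure(list(total = total, stages = rep_df,
                           retained = nrow(d)),
                      class = "selection_report")
  list(records = d, report = report)
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Record selection:", x$total, "records in,", x$retained,
      "retained\n")
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' Modal gestational age
#'
#' The completed week with the largest number of births; ties are broken
#' toward the lower week. Optionally scales an external week histogram
#' (e.g. for all births in the population) to the same total for
#' side-by-side display.
#'
#' @param records data.frame of birth records (uses `gest_weeks`).
#' @param reference optional data.frame `week`, `n`: an external
#'   gestation distribution to rescale against the records' total.
#' @return A list with `mode` (integer week), `histogram` (data.frame
#'   `week`, `n`) and, when supplied, `reference_scaled`.
#' @export
modal_gestation <- function(records, reference = NULL) {
  w <- records$gest_weeks
  w <- w[!is.na(w)]
  if (length(w) == 0L) stop_("no gestational ages present")
  tab <- table(w)
  weeks <- as.integer(names(tab))
  n <- as.integer(tab)
  hist <- data.frame(week = weeks, n = n)
  out <- list(mode = weeks[which.max(n)], histogram = hist)
  if (!is.null(reference)) {
    reference <- as.data.frame(reference)
    sc <- reference$n * sum(n) / sum(reference$n)
    out$reference_scaled <- data.frame(week = reference$week, n = sc)
  }
  out
}

#' Secular trend in birth weight
#'
#' Ordinary least squares regression of the records' birth-weight SD
#' scores (z-scores under the fitted model or a supplied LMS table) on
#' calendar year of birth, with a normal-theory 95% confidence interval.
#' The slope is also converted to grams per year by multiplying by
#' `M * S` at the records' modal week, averaged over the sexes (an
#' approximate SD in grams at that week).
#'
#' @param records data.frame of birth records (needs `year`).
#' @param model an [fit_lms()] result or an [lms_table()] used to
#'   compute z-scores.
#' @return An object of class `trend_result`: `slope_sd`, `ci_sd`
#'   (SD-score units per year), `slope_g`, `ci_g` (grams per year),
#'   `modal_week`, `n`.
#' @export
secular_trend <- function(records, model) {
  records <- as.data.frame(records)
  z <- zscore_records(records, model)
  ok <- !is.na(z) & !is.na(records$year)
  if (sum(ok) < 3L) stop_("need >= 3 records with z-score and year")
  year <- as.numeric(records$year[ok])
  if (length(unique(year)) < 2L) {
    stop_("degenerate design: all records share one birth year")
  }
  fit <- stats::lm(z[ok] ~ year)
  slope <- unname(stats::coef(fit)[2])
  se <- sqrt(diag(stats::vcov(fit)))[2]
  ci <- slope + c(-1.96, 1.96) * se
  mw <- modal_gestation(records[ok, , drop = FALSE])$mode
  if (inherits(model, "lms_fit")) {
    cv <- eval_curves(model, mw)
    sd_g <- mean(c(cv$M_male, cv$M_female)) * cv$S
  } else {
    tab <- if (inherits(model, "lms_table")) model else lms_table(model)
    tri_m <- lms_lookup(tab, "male", mw)
    tri_f <- lms_lookup(tab, "female", mw)
    sd_g <- mean(c(tri_m$M, tri_f$M)) * mean(c(tri_m$S, tri_f$S))
  }
  structure(list(slope_sd = slope, ci_sd = ci,
                 slope_g = slope * sd_g, ci_g = ci * sd_g,
                 sd_g_per_unit = sd_g, modal_week = mw, n = sum(ok)),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("Secular trend: %.4f SD/year (95%%CI %.4f to %.4f), n = %d\n",
              x$slope_sd, x$ci_sd[1], x$ci_sd[2], x$n))
  cat(sprintf("  = %.2f g/year (95%%CI %.2f to %.2f) at week %d\n",
              x$slope_g, x$ci_g[1], x$ci_g[2], x$modal_week))
  invisible(x)
}

#' Association between gestational age and missing birth weight
#'
#' Logistic regression of the missing-weight indicator on gestational
#' week, among records with gestation recorded. Reports the log-odds
#' slope per week, its standard error and the two-sided Wald p-value.
#'
#' @param records data.frame of birth records.
#' @return A list with `slope`, `se`, `p`, `n`.
#' @export
missingness_association <- function(records) {
  records <- as.data.frame(records)
  ok <- !is.na(records$gest_weeks)
  miss <- is.na(records$weight_g[ok])
  week <- as.numeric(records$gest_weeks[ok])
  if (length(unique(miss)) < 2L) {
    stop_("degenerate outcome: weight is ",
          if (all(miss)) "always" else "never", " missing")
  }
  fit <- stats::glm(miss ~ week, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-12,
                                                 maxit = 100))
  slope <- unname(stats::coef(fit)[2])
  se <- sqrt(diag(stats::vcov(fit)))[2]
  p <- 2 * stats::pnorm(-abs(slope / se))
  list(slope = slope, se = unname(se), p = unname(p), n = sum(ok))
}

#' Compare two LMS charts centile by centile
#'
#' Per (sex, week) over the overlapping week range, the difference
#' (reference minus study) at every centile line of the specification.
#' Swapping the charts negates every difference.
#'
#' @param study,reference [lms_table()] objects with overlapping weeks.
#' @param spec a [centile_spec()].
#' @return An object of class `comparison_result`: a data.frame `sex`,
#'   `week`, `label`, `z`, `study`, `reference`, `difference` (grams,
#'   unrounded).
#' @export
compare_to_reference <- function(study, reference,
                                 spec = default_centile_spec()) {
  study <- if (inherits(study, "lms_table")) study else lms_table(study)
  reference <- if (inherits(reference, "lms_table")) reference else
    lms_table(reference)
  weeks <- intersect(unique(study$week), unique(reference$week))
  if (length(weeks) == 0L) stop_("charts have no overlapping weeks")
  weeks <- sort(weeks)
  rows <- list()
  for (s in SEXES) {
    tri_s <- lms_lookup(study, s, weeks)
    tri_r <- lms_lookup(reference, s, weeks)
    for (j in seq_len(nrow(spec))) {
      a <- centile_value(tri_s, spec$z[j])
      b <- centile_value(tri_r, spec$z[j])
      rows[[length(rows) + 1L]] <- data.frame(
        sex = s, week = weeks, label = spec$label[j], z = spec$z[j],
        study = a, reference = b, difference = b - a,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$sex, SEXES), out$week, out$z), ]
  rownames(out) <- NULL
  structure(out, class = c("comparison_result", "data.frame"))
}

#' Run the full chart-construction pipeline
#'
#' Selection -> LMS fit -> parameter table -> centile tables ->
#' sex-difference, modal-gestation, secular-trend and (when weights are
#' missing) missingness summaries -> optional comparison against an
#' external reference chart. Deterministic given the simulation seed.
#'
#' @param input a data.frame of birth records, or a
#'   [simulation_config()] from which a register is simulated first.
#' @param config a [fit_config()].
#' @param reference optional external [lms_table()] to compare against.
#' @param spec a [centile_spec()] for the centile tables.
#' @param out_dir optional directory: when given, the LMS table, the two
#'   centile tables, the selection report and diagnostics, and any
#'   comparison are written there.
#' @return An object of class `pipeline_report`: a list with
#'   `selection`, `model`, `lms_table`, `centiles`, `sex_difference`,
#'   `modal_gestation`, `trend`, `missingness` (NULL when no weights are
#'   missing) and `comparison` (NULL when no reference is given).
#' @export
run_pipeline <- function(input, config = fit_config(), reference = NULL,
                         spec = default_centile_spec(), out_dir = NULL) {
  records <- if (inherits(input, "sim_config")) {
    simulate_register(input)
  } else {
    as.data.frame(input)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop_("pipeline stage '", stage, "' failed: ", conditionMessage(e))
    })
  }
  sel <- run_stage("selection",
                   select_records(records, config$week_range_fit))
  model <- run_stage("fit", fit_lms(sel$records, config))
  tab <- run_stage("evaluate", evaluate_model(model))
  ct <- run_stage("centiles", make_centile_table(tab, spec))
  sexdiff <- if (config$sex_offset) sex_difference_percent(model) else NULL
  mg <- run_stage("modal_gestation", modal_gestation(sel$records))
  trend <- run_stage("secular_trend", secular_trend(sel$records, model))
  missp <- NULL
  assessed <- records[!is.na(records$gest_weeks), , drop = FALSE]
  if (nrow(assessed) && anyNA(assessed$weight_g) &&
      !all(is.na(assessed$weight_g))) {
    missp <- run_stage("missingness", missingness_association(records))
  }
  cmp <- if (!is.null(reference)) {
    run_stage("comparison", compare_to_reference(tab, reference, spec))
  } else NULL

  out <- structure(list(
    selection = sel$report, model = model, lms_table = tab, centiles = ct,
    sex_difference = sexdiff, modal_gestation = mg, trend = trend,
    missingness = missp, comparison = cmp
  ), class = "pipeline_report")
  if (!is.null(out_dir)) write_pipeline_report(out, out_dir)
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  print(x$selection)
  print(x$model)
  cat("Modal gestation:", x$modal_gestation$mode, "weeks\n")
  print(x$trend)
  if (!is.null(x$missingness)) {
    cat(sprintf("Missing-weight ~ gestation: slope %.4f (SE %.4f), p = %.3f\n",
                x$missingness$slope, x$missingness$se, x$missingness$p))
  }
  invisible(x)
}
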