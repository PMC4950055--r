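# Seeded synthetic birth-register generator.
#
# Emulates a national cytogenetic register of Down syndrome births: a
# fixed number of clean live-birth free-trisomy-21 records per (sex,
# week) cell whose weights follow the configured BCCG distributions,
# plus optional secular trend, missingness and contaminating records
# (non-live outcomes, non-free-trisomy karyotypes) that the selection
# stage must remove.

OUTCOMES <- c("live_birth", "stillbirth", "termination")
KARYOTYPES <- c("free_trisomy_21", "translocation", "mosaic", "other")

#' Configuration of a synthetic birth register
#'
#' Defaults reproduce the study conditions of the England & Wales Down
#' syndrome reference: the published per-(sex, week) counts and LMS
#' parameters ([ds_reference()]), birth years uniform over 1989-2011, no
#' secular trend, no missingness and no contamination.
#'
#' @param count_table data.frame `week`, `sex`, `n`: clean live-birth
#'   records to emit per cell.
#' @param lms_table generating [lms_table()] covering every week in
#'   `count_table`.
#' @param year_range integer pair of birth years (inclusive).
#' @param trend_g_per_year additive secular trend in grams per calendar
#'   year, applied relative to the midpoint of `year_range`.
#' @param missing_weight_rate probability a clean record's weight is
#'   missing at the reference week (38).
#' @param missing_gestation_rate probability a clean record's gestation
#'   is missing (completely at random).
#' @param missingness_gestation_slope log-odds change per week of
#'   gestation in the weight-missingness probability (around week 38;
#'   only effective when `missing_weight_rate > 0`).
#' @param non_live_fraction,non_free_trisomy_fraction fractions (of the
#'   clean count) of extra contaminating records appended with non-live
#'   outcomes / non-free-trisomy karyotypes.
#' @param stillbirth_offset_g additive weight offset for simulated
#'   stillbirths (an exploration knob; the true deficit is unpublished).
#' @param seed integer seed; the register is byte-identical for a fixed
#'   seed.
#' @return An object of class `sim_config` (a named list, validated).
#' @export
simulation_config <- function(count_table = NULL,
                              lms_table = NULL,
                              year_range = c(1989L, 2011L),
                              trend_g_per_year = 0,
                              missing_weight_rate = 0,
                              missing_gestation_rate = 0,
                              missingness_gestation_slope = 0,
                              non_live_fraction = 0,
                              non_free_trisomy_fraction = 0,
                              stillbirth_offset_g = -150,
                              seed = NULL) {
  ref <- NULL
  if (is.null(count_table) || is.null(lms_table)) ref <- ds_reference()
  if (is.null(count_table)) count_table <- ref$counts
  if (is.null(lms_table)) lms_table <- ref$lms
  if (!inherits(lms_table, "lms_table")) lms_table <- lms_table(lms_table)
  if (!is.data.frame(count_table) ||
      !all(c("week", "sex", "n") %in% names(count_table))) {
    stop_("count_table needs columns week, sex, n")
  }
  count_table <- as.data.frame(count_table)[c("week", "sex", "n")]
  count_table$week <- as.integer(count_table$week)
  count_table$n <- as.integer(count_table$n)
  if (any(count_table$n < 0)) stop_("counts must be non-negative")
  if (!all(count_table$sex %in% SEXES)) {
    stop_("count_table sex must be one of ", paste(SEXES, collapse = ", "))
  }
  present <- paste(lms_table$week, lms_table$sex)
  need <- paste(count_table$week, count_table$sex)
  if (!all(need %in% present)) {
    stop_("lms_table does not cover every (week, sex) in count_table")
  }
  year_range <- as.integer(year_range)
  if (length(year_range) != 2L || year_range[1] > year_range[2]) {
    stop_("year_range must be an increasing integer pair")
  }
  probs <- c(missing_weight_rate = missing_weight_rate,
             missing_gestation_rate = missing_gestation_rate,
             non_live_fraction = non_live_fraction,
             non_free_trisomy_fraction = non_free_trisomy_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop_(paste(names(probs)[probs < 0 | probs > 1], collapse = ", "),
          " must be in [0, 1]")
  }
  structure(list(
    count_table = count_table, lms_table = lms_table,
    year_range = year_range, trend_g_per_year = trend_g_per_year,
    missing_weight_rate = missing_weight_rate,
    missing_gestation_rate = missing_gestation_rate,
    missingness_gestation_slope = missingness_gestation_slope,
    non_live_fraction = non_live_fraction,
    non_free_trisomy_fraction = non_free_trisomy_fraction,
    stillbirth_offset_g = stillbirth_offset_g,
    seed = seed
  ), class = "sim_config")
}

# Draw standard normal z truncated to 1 + L*S*z > 0 by rejection; the
# rejection probability is negligible at chart-scale parameters but the
# redraw preserves the BCCG shape exactly.
draw_truncated_z <- function(L, S) {
  n <- length(L)
  z <- stats::rnorm(n)
  bad <- abs(L) >= .L_EPS & (1 + L * S * z) <= 0
  while (any(bad)) {
    z[bad] <- stats::rnorm(sum(bad))
    bad <- bad & (1 + L * S * z) <= 0
  }
  z
}

# Expand (sex, week) cells into per-record weights and years.
draw_records <- function(cells, lms, config) {
  idx <- rep(seq_len(nrow(cells)), cells$n)
  week <- cells$week[idx]
  sex <- cells$sex[idx]
  key <- match(paste(week, sex), paste(lms$week, lms$sex))
  tri <- lms_triple(lms$L[key], lms$M[key], lms$S[key])
  z <- draw_truncated_z(tri$L, tri$S)
  weight <- centile_value(tri, z)
  yr <- config$year_range
  year <- sample.int(yr[2] - yr[1] + 1L, length(idx), replace = TRUE) +
    yr[1] - 1L
  weight <- weight + config$trend_g_per_year * (year - mean(yr))
  data.frame(sex = sex, gest_weeks = week, weight_g = weight, year = year,
             stringsAsFactors = FALSE)
}

#' Simulate a synthetic birth register
#'
#' Emits exactly the configured number of clean live-birth
#' free-trisomy-21 records per (sex, week), each weight drawn from the
#' generating BCCG distribution for that cell (standard-normal z,
#' redrawn on the negligible event `1 + L*S*z <= 0`), plus the secular
#' trend in grams per year, then applies missingness and appends any
#' contaminating records. Fully reproducible for a fixed seed.
#'
#' @param config a [simulation_config()].
#' @return A data.frame of birth records with columns `sex`,
#'   `gest_weeks`, `weight_g`, `year`, `outcome`, `karyotype`; missing
#'   values are `NA`.
#' @export
simulate_register <- function(config = simulation_config()) {
  if (!inherits(config, "sim_config")) stop_("config must be a sim_config")
  with_seed(config$seed, {
    cells <- config$count_table
    cells <- cells[order(cells$week, match(cells$sex, SEXES)), ]
    clean <- draw_records(cells, config$lms_table, config)
    clean$outcome <- "live_birth"
    clean$karyotype <- "free_trisomy_21"

    # weight missingness: logistic in gestation around the modal week 38
    if (config$missing_weight_rate > 0) {
      p <- stats::plogis(stats::qlogis(config$missing_weight_rate) +
                           config$missingness_gestation_slope *
                             (clean$gest_weeks - 38))
      clean$weight_g[stats::runif(nrow(clean)) < p] <- NA_real_
    }
    if (config$missing_gestation_rate > 0) {
      drop <- stats::runif(nrow(clean)) < config$missing_gestation_rate
      clean$gest_weeks[drop] <- NA_integer_
    }

    extras <- list()
    n_clean <- sum(cells$n)
    sample_cells <- function(k) {
      i <- sample.int(nrow(cells), k, replace = TRUE, prob = cells$n)
      data.frame(week = cells$week[i], sex = cells$sex[i], n = 1L)
    }
    k_live <- round(config$non_live_fraction * n_clean)
    if (k_live > 0) {
      e <- draw_records(sample_cells(k_live), config$lms_table, config)
      e$outcome <- sample(c("stillbirth", "termination"), k_live,
                          replace = TRUE)
      still <- e$outcome == "stillbirth"
      e$weight_g[still] <- pmax(e$weight_g[still] +
                                  config$stillbirth_offset_g, 1)
      e$karyotype <- "free_trisomy_21"
      extras <- c(extras, list(e))
    }
    k_kar <- round(config$non_free_trisomy_fraction * n_clean)
    if (k_kar > 0) {
      e <- draw_records(sample_cells(k_kar), config$lms_table, config)
      e$outcome <- "live_birth"
      e$karyotype <- sample(c("translocation", "mosaic", "other"), k_kar,
                            replace = TRUE)
      extras <- c(extras, list(e))
    }
    out <- do.call(rbind, c(list(clean), extras))
    rownames(out) <- NULL
    out
  })
}
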