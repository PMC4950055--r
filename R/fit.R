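# Penalized maximum-likelihood LMS fitting.
#
# The model: for a record with weight y at gestation t and sex s,
#   z = ((y/mu)^L(t) - 1) / (L(t) * S(t)) ~ N(0, 1)   (BCCG),
#   log mu = log M(t) + delta * [s == female]          (log link),
# with L(t), log M(t), log S(t) smooth curves (cubic B-splines with a
# second-difference curvature penalty) shared across sexes except for
# the constant log-scale offset delta on the median. The penalty weight
# of each curve is chosen by root-finding so that the trace of its hat
# matrix equals the configured effective degrees of freedom (edf).
# Estimation is by backfitting: each curve takes one penalized Fisher-
# scoring step holding the others fixed, then delta is updated in closed
# form from the median-score; a step-halving safeguard keeps the
# penalized log-likelihood monotone.

#' Fitting configuration
#'
#' @param week_range_fit integer pair: gestational window (completed
#'   weeks) of records used for fitting; records outside are excluded,
#'   not clamped.
#' @param week_range_report integer pair: default tabulation window of
#'   [evaluate_model()]; must lie within `week_range_fit`.
#' @param edf_L,edf_M,edf_S effective degrees of freedom of the three
#'   smooth curves. `1` fits an exact constant; values in (1, 2] are
#'   effectively linear (the curvature penalty cannot shrink below a
#'   straight line); larger values buy curvature up to the basis size.
#' @param max_iterations cap on backfitting sweeps per cycle.
#' @param tolerance relative change in penalized log-likelihood at which
#'   the backfitting loop stops.
#' @param sex_offset fit the constant log-scale sex offset on the median
#'   (requires both sexes in the data).
#' @param nbasis number of cubic B-spline basis functions (upper bound;
#'   reduced automatically for narrow week spans).
#' @return An object of class `fit_config` (a named list, validated).
#' @export
fit_config <- function(week_range_fit = c(28L, 43L),
                       week_range_report = c(30L, 42L),
                       edf_L = 4, edf_M = 6, edf_S = 4,
                       max_iterations = 200L,
                       tolerance = 1e-7,
                       sex_offset = TRUE,
                       nbasis = 10L) {
  week_range_fit <- as.integer(week_range_fit)
  week_range_report <- as.integer(week_range_report)
  if (length(week_range_fit) != 2L || week_range_fit[1] >= week_range_fit[2]) {
    stop_("week_range_fit must be an increasing integer pair")
  }
  if (week_range_report[1] < week_range_fit[1] ||
      week_range_report[2] > week_range_fit[2] ||
      week_range_report[1] > week_range_report[2]) {
    stop_("week_range_report must lie within week_range_fit")
  }
  edf <- c(L = edf_L, M = edf_M, S = edf_S)
  if (any(edf < 1)) stop_("edf values must be >= 1 (1 = constant curve)")
  if (tolerance <= 0) stop_("tolerance must be > 0")
  assert_scalar_flag(sex_offset, "sex_offset")
  structure(list(
    week_range_fit = week_range_fit, week_range_report = week_range_report,
    edf = edf, max_iterations = as.integer(max_iterations),
    tolerance = tolerance, sex_offset = sex_offset,
    nbasis = as.integer(nbasis)
  ), class = "fit_config")
}

# Equally spaced cubic B-spline knots over [lo, hi]; nbasis >= 4.
bspline_knots <- function(lo, hi, nbasis) {
  dx <- (hi - lo) / (nbasis - 3)
  seq(lo - 3 * dx, hi + 3 * dx, by = dx)
}

bspline_eval <- function(knots, t) {
  splines::splineDesign(knots, t, ord = 4)
}

second_diff_penalty <- function(nb) {
  if (nb < 3L) return(matrix(0, nb, nb))
  D <- diff(diag(nb), differences = 2)
  crossprod(D)
}

quadform <- function(a, P) as.numeric(t(a) %*% P %*% a)

# Eigenvalues of the penalty whitened by chol(B'WB): with B'WB = R'R
# and e_k = eig(R^-T P R^-1), tr((B'WB + lam P)^-1 B'WB) equals
# sum_k 1/(1 + lam * e_k), stable for any lambda (unlike a direct solve,
# which degenerates once lam*P swamps B'WB).
penalty_spectrum <- function(B, w, P) {
  BtWB <- crossprod(B, w * B)
  R <- chol(BtWB + diag(1e-9 * mean(diag(BtWB)), ncol(B)))
  Rinv <- backsolve(R, diag(ncol(B)))
  pmax(eigen(t(Rinv) %*% P %*% Rinv, symmetric = TRUE,
             only.values = TRUE)$values, 0)
}

# Penalty weight lambda such that the curve's edf hits the target
# (monotone decreasing in lambda; searched on log scale).
match_lambda <- function(B, w, P, target) {
  e <- penalty_spectrum(B, w, P)
  f <- function(loglam) sum(1 / (1 + exp(loglam) * e)) - target
  lo <- -20; hi <- 40
  if (f(lo) <= 0) return(exp(lo))
  if (f(hi) >= 0) return(exp(hi))
  exp(stats::uniroot(f, c(lo, hi), tol = 1e-4)$root)
}

curve_edf <- function(B, w, P, lam) {
  sum(1 / (1 + lam * penalty_spectrum(B, w, P)))
}

#' Fit smooth LMS curves to birth records
#'
#' Maximizes the BCCG log-likelihood of the records, penalized by
#' curvature penalties on L(t), log M(t) and log S(t), with a log-link
#' median and (optionally) a constant log-scale sex offset `delta` such
#' that `M_female(t) = M_male(t) * exp(delta)`. L and S are pooled
#' across sexes. See the package vignette for the estimation scheme.
#'
#' @param records data.frame of birth records (columns `sex`,
#'   `gest_weeks`, `weight_g`; other columns ignored). Records with
#'   missing fields or gestation outside `week_range_fit` are dropped.
#' @param config a [fit_config()].
#' @return An object of class `lms_fit`: curves (basis knots and
#'   coefficients), `delta` and its standard error, per-record fitted
#'   z-scores, the penalized log-likelihood trace of the final cycle,
#'   convergence diagnostics, and the realized edf and penalty weights.
#' @export
fit_lms <- function(records, config = fit_config()) {
  if (!inherits(config, "fit_config")) stop_("config must be a fit_config")
  records <- as.data.frame(records)
  req <- c("sex", "gest_weeks", "weight_g")
  if (!all(req %in% names(records))) {
    stop_("records need columns ", paste(req, collapse = ", "))
  }
  wr <- config$week_range_fit
  keep <- !is.na(records$sex) & !is.na(records$gest_weeks) &
    !is.na(records$weight_g) &
    records$gest_weeks >= wr[1] & records$gest_weeks <= wr[2]
  d <- records[keep, req]
  if (nrow(d) < 50L) {
    stop_("insufficient data: need >= 50 complete records in the fit window")
  }
  if (any(d$weight_g <= 0)) stop_("weights must be positive")
  if (config$sex_offset && length(unique(d$sex)) < 2L) {
    stop_("sex_offset requires records of both sexes")
  }
  x <- as.numeric(d$gest_weeks)
  y <- as.numeric(d$weight_g)
  fem <- as.numeric(d$sex == "female")
  n <- length(y)
  uw <- sort(unique(x))

  constant <- config$edf <= 1
  nbasis <- min(config$nbasis, length(uw) + 2L)
  if (!all(constant)) {
    if (nbasis < 4L) {
      stop_("singular basis: week span too narrow for a smooth curve; ",
            "use edf = 1 (constant)")
    }
    bad <- !constant & (config$edf > pmin(nbasis - 0.5, length(uw)))
    if (any(bad)) {
      stop_("singular basis: requested edf (",
            paste(names(config$edf)[bad], collapse = ", "),
            ") exceeds what ", length(uw), " distinct weeks / ", nbasis,
            " basis functions support")
    }
  }
  knots <- if (all(constant)) NULL else bspline_knots(wr[1], wr[2], nbasis)
  Bfull <- if (is.null(knots)) NULL else bspline_eval(knots, x)
  Bones <- matrix(1, n, 1L)
  B <- list(L = if (constant["L"]) Bones else Bfull,
            M = if (constant["M"]) Bones else Bfull,
            S = if (constant["S"]) Bones else Bfull)
  P <- lapply(B, function(b) second_diff_penalty(ncol(b)))

  # --- starting values -------------------------------------------------
  delta <- 0
  if (config$sex_offset) {
    delta <- log(stats::median(y[fem == 1]) / stats::median(y[fem == 0]))
  }
  ym <- y / exp(delta * fem)  # girls rescaled to the male median scale
  med_w <- tapply(ym, x, stats::median)
  n_w <- tapply(ym, x, length)
  iqr_w <- tapply(ym, x, stats::IQR)
  init_curve <- function(Bc, Pc, weeks, vals, wts) {
    if (ncol(Bc) == 1L) return(sum(wts * vals) / sum(wts))
    Bl <- bspline_eval(knots, weeks)
    as.vector(solve(crossprod(Bl, wts * Bl) + 1 * second_diff_penalty(nbasis) +
                      1e-8 * diag(nbasis),
                    crossprod(Bl, wts * vals)))
  }
  aM <- init_curve(B$M, P$M, uw, log(as.numeric(med_w)), as.numeric(n_w))
  s_ok <- n_w >= 5 & iqr_w > 0
  if (sum(s_ok) >= 2) {
    s_init <- pmin(pmax((iqr_w[s_ok] / 1.349) / med_w[s_ok], 0.01), 1)
    aS <- init_curve(B$S, P$S, uw[s_ok], log(as.numeric(s_init)),
                     as.numeric(n_w[s_ok]))
  } else {
    s_glob <- max((stats::IQR(ym) / 1.349) / stats::median(ym), 0.01)
    aS <- if (ncol(B$S) == 1L) log(s_glob) else rep(log(s_glob), nbasis)
  }
  aL <- rep(1, ncol(B$L))  # B-splines sum to one, so this is L(t) = 1

  # --- state / objective ----------------------------------------------
  lam <- list(L = 0, M = 0, S = 0)
  state <- function(aL, aM, aS, delta) {
    L <- as.vector(B$L %*% aL)
    etaMc <- as.vector(B$M %*% aM)
    etaS <- as.vector(B$S %*% aS)
    u <- log(y) - etaMc - delta * fem
    S <- exp(etaS)
    v <- exp(L * u)
    z <- ifelse(abs(L) < .L_EPS, u / S, (v - 1) / (L * S))
    ll <- sum(-z^2 / 2 + L * u - etaS) - n * 0.5 * log(2 * pi) - sum(log(y))
    pen <- 0.5 * (lam$L * quadform(aL, P$L) + lam$M * quadform(aM, P$M) +
                    lam$S * quadform(aS, P$S))
    list(L = L, S = S, u = u, v = v, z = z, etaMc = etaMc,
         ll = ll, pll = ll - pen)
  }
  scores <- function(st) {
    sM <- st$z * st$v / st$S - st$L
    sS <- st$z^2 - 1
    dzdL <- ifelse(abs(st$L) < .L_EPS,
                   st$u^2 / (2 * st$S),
                   (st$u * st$v - st$S * st$z) / (st$L * st$S))
    sL <- -st$z * dzdL + st$u
    list(L = sL, M = sM, S = sS,
         wL = 7 * st$S^2 / 4, wM = 1 / st$S^2 + 2 * st$L^2,
         wS = rep(2, length(st$z)))
  }

  coefs <- list(L = aL, M = aM, S = aS, delta = delta)
  st <- state(coefs$L, coefs$M, coefs$S, coefs$delta)
  pll_of <- function(cf) state(cf$L, cf$M, cf$S, cf$delta)$pll

  # accept a proposed coefficient set with step-halving toward `coefs`
  try_step <- function(coefs, proposal, cur_pll) {
    step <- 1
    for (h in 0:14) {
      cand <- coefs
      for (nm in names(proposal)) {
        cand[[nm]] <- coefs[[nm]] + step * (proposal[[nm]] - coefs[[nm]])
      }
      p <- pll_of(cand)
      if (is.finite(p) && p >= cur_pll) return(list(coefs = cand, pll = p))
      step <- step / 2
    }
    list(coefs = coefs, pll = cur_pll)
  }

  iterations <- 0L
  converged <- FALSE
  trace <- numeric(0)
  for (cycle in 1:2) {
    sc <- scores(st)
    for (nm in c("L", "M", "S")) {
      lam[[nm]] <- if (ncol(B[[nm]]) == 1L) 0 else {
        match_lambda(B[[nm]], sc[[paste0("w", nm)]], P[[nm]],
                     min(config$edf[[nm]], ncol(B[[nm]]) - 0.2))
      }
    }
    st <- state(coefs$L, coefs$M, coefs$S, coefs$delta)
    trace <- st$pll
    converged <- FALSE
    for (it in seq_len(config$max_iterations)) {
      pll0 <- st$pll
      for (nm in c("L", "M", "S")) {
        sc <- scores(st)
        s <- sc[[nm]]; w <- sc[[paste0("w", nm)]]
        eta <- as.vector(B[[nm]] %*% coefs[[nm]])
        a_new <- tryCatch(
          as.vector(solve(crossprod(B[[nm]], w * B[[nm]]) + lam[[nm]] * P[[nm]],
                          crossprod(B[[nm]], w * eta + s))),
          error = function(e) coefs[[nm]])
        upd <- try_step(coefs, stats::setNames(list(a_new), nm), st$pll)
        coefs <- upd$coefs
        st <- state(coefs$L, coefs$M, coefs$S, coefs$delta)
        if (nm == "M" && config$sex_offset) {
          sc <- scores(st)
          d_new <- coefs$delta + sum(sc$M[fem == 1]) / sum(sc$wM[fem == 1])
          upd <- try_step(coefs, list(delta = d_new), st$pll)
          coefs <- upd$coefs
          st <- state(coefs$L, coefs$M, coefs$S, coefs$delta)
        }
      }
      iterations <- iterations + 1L
      trace <- c(trace, st$pll)
      if (abs(st$pll - pll0) < config$tolerance * (abs(pll0) + 0.1)) {
        converged <- TRUE
        break
      }
    }
  }

  # --- delta standard error (joint information with the M curve) ------
  delta_se <- NA_real_
  if (config$sex_offset) {
    sc <- scores(st)
    w <- sc$wM
    Bm <- B$M
    XtWX <- rbind(
      cbind(crossprod(Bm, w * Bm) + lam$M * P$M, crossprod(Bm, w * fem)),
      cbind(t(crossprod(Bm, w * fem)), sum(w * fem))
    )
    delta_se <- sqrt(solve(XtWX)[ncol(Bm) + 1L, ncol(Bm) + 1L])
  }

  sc <- scores(st)
  edf_actual <- vapply(c("L", "M", "S"), function(nm) {
    if (ncol(B[[nm]]) == 1L) 1 else {
      curve_edf(B[[nm]], sc[[paste0("w", nm)]], P[[nm]], lam[[nm]])
    }
  }, numeric(1))

  structure(list(
    coef = coefs[c("L", "M", "S")],
    delta = coefs$delta, delta_se = delta_se,
    knots = knots, nbasis = nbasis, constant = constant,
    week_range_fit = wr, week_range_report = config$week_range_report,
    sex_offset = config$sex_offset,
    edf_target = config$edf, edf_actual = edf_actual,
    lambda = unlist(lam),
    iterations = iterations, converged = converged,
    loglik = st$ll, pll = st$pll, pll_trace = trace,
    zscores = st$z, n = n
  ), class = "lms_fit")
}

# Evaluate the fitted curves at arbitrary gestations within the window.
eval_curves <- function(model, t) {
  t <- as.numeric(t)
  wr <- model$week_range_fit
  if (any(t < wr[1] | t > wr[2])) {
    stop_("gestation outside the fitted window [", wr[1], ", ", wr[2], "]")
  }
  Bfull <- if (is.null(model$knots)) NULL else bspline_eval(model$knots, t)
  col1 <- matrix(1, length(t), 1L)
  get <- function(nm) {
    b <- if (model$constant[[nm]]) col1 else Bfull
    as.vector(b %*% model$coef[[nm]])
  }
  list(L = get("L"), M_male = exp(get("M")),
       M_female = exp(get("M") + model$delta), S = exp(get("S")))
}

#' Tabulate a fitted model as an LMS table
#'
#' Evaluates the smooth curves at integer weeks for both sexes. By
#' default `M` is rounded to integer grams, `L` to two decimals and `S`
#' to three, matching the precision of published chart parameter tables;
#' pass `digits = NULL` for full precision.
#'
#' @param model an [fit_lms()] result.
#' @param weeks integer weeks to tabulate (default: the configured
#'   reporting window); must lie within the fitted window.
#' @param digits named vector `c(L = , S = )` of rounding digits, or
#'   `NULL` for no rounding.
#' @param round_M round medians to integer grams.
#' @return An [lms_table()].
#' @export
evaluate_model <- function(model, weeks = NULL, digits = c(L = 2, S = 3),
                           round_M = TRUE) {
  if (!inherits(model, "lms_fit")) stop_("model must be an lms_fit")
  if (is.null(weeks)) {
    weeks <- seq(model$week_range_report[1], model$week_range_report[2])
  }
  weeks <- as.integer(weeks)
  cv <- eval_curves(model, weeks)
  Lv <- cv$L; Sv <- cv$S; Mm <- cv$M_male; Mf <- cv$M_female
  if (!is.null(digits)) {
    Lv <- round(Lv, digits[["L"]])
    Sv <- round(Sv, digits[["S"]])
  }
  if (round_M) {
    Mm <- round_half_out(Mm)
    Mf <- round_half_out(Mf)
  }
  lms_table(data.frame(
    week = rep(weeks, 2L),
    sex = rep(SEXES, each = length(weeks)),
    L = rep(Lv, 2L), M = c(Mm, Mf), S = rep(Sv, 2L)
  ))
}

#' Constant percentage sex difference in median birth weight
#'
#' Transforms the fitted log-scale offset to the percentage by which the
#' female median lies below the male median, `100 * (1 - exp(delta))`,
#' with a normal-theory 95% confidence interval from
#' `delta +/- 1.96 * SE(delta)`.
#'
#' @param model an [fit_lms()] result fitted with `sex_offset = TRUE`.
#' @return A list with `estimate` (percent), `ci` (length-2 percent
#'   interval), `delta` and `delta_se`.
#' @export
sex_difference_percent <- function(model) {
  if (!inherits(model, "lms_fit")) stop_("model must be an lms_fit")
  if (!model$sex_offset) {
    stop_("model was fitted without a sex offset")
  }
  est <- 100 * (1 - exp(model$delta))
  ci <- sort(100 * (1 - exp(model$delta + c(-1.96, 1.96) * model$delta_se)))
  list(estimate = est, ci = ci, delta = model$delta,
       delta_se = model$delta_se)
}

#' z-scores of records under a fitted model or LMS table
#'
#' @param records data.frame of birth records.
#' @param ref an [fit_lms()] result or an [lms_table()].
#' @return Numeric vector aligned with `records`; `NA` where sex,
#'   gestation or weight is missing.
#' @export
zscore_records <- function(records, ref) {
  records <- as.data.frame(records)
  ok <- !is.na(records$sex) & !is.na(records$gest_weeks) &
    !is.na(records$weight_g)
  z <- rep(NA_real_, nrow(records))
  if (!any(ok)) return(z)
  t <- as.numeric(records$gest_weeks[ok])
  y <- as.numeric(records$weight_g[ok])
  sex <- records$sex[ok]
  if (inherits(ref, "lms_fit")) {
    cv <- eval_curves(ref, t)
    M <- ifelse(sex == "female", cv$M_female, cv$M_male)
    tri <- lms_triple(cv$L, M, cv$S)
    z[ok] <- zscore_value(y, tri)
  } else {
    ref <- if (inherits(ref, "lms_table")) ref else lms_table(ref)
    for (s in SEXES) {
      i <- sex == s
      if (any(i)) {
        tri <- interpolate_lms(ref, s, t[i])
        z[which(ok)[i]] <- zscore_value(y[i], tri)
      }
    }
  }
  z
}

#' @export
print.lms_fit <- function(x, ...) {
  cat("Penalized-likelihood LMS fit\n")
  cat("  records:", x$n, " window:", x$week_range_fit[1], "-",
      x$week_range_fit[2], "weeks\n")
  cat("  edf (L, M, S): target", paste(round(x$edf_target, 1),
                                       collapse = "/"),
      " realized", paste(round(x$edf_actual, 2), collapse = "/"), "\n")
  if (x$sex_offset) {
    sd <- sex_difference_percent(x)
    cat(sprintf("  sex offset: delta = %.4f (SE %.4f); girls %.1f%% (95%%CI %.1f-%.1f) below boys\n",
                x$delta, x$delta_se, sd$estimate, sd$ci[1], sd$ci[2]))
  }
  cat(sprintf("  log-likelihood %.2f after %d iterations (%s)\n",
              x$loglik, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
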