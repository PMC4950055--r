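# LMS tables (per sex and gestational week) and centile tables.

SEXES <- c("male", "female")

#' LMS table: parameters per sex and gestational week
#'
#' A long-format table with one row per (sex, completed gestational
#' week), columns `week`, `sex`, `L`, `M`, `S`. Both sexes must cover
#' the identical, gap-free week range.
#'
#' @param x a data.frame with columns `week`, `sex` (`"male"`/`"female"`),
#'   `L`, `M`, `S`.
#' @return An object of class `lms_table` (a data.frame), sorted by week
#'   with male before female within each week.
#' @export
lms_table <- function(x) {
  req <- c("week", "sex", "L", "M", "S")
  if (!is.data.frame(x) || !all(req %in% names(x))) {
    stop_("an LMS table needs columns ", paste(req, collapse = ", "))
  }
  x <- as.data.frame(x)[req]
  x$week <- as.integer(x$week)
  x$sex <- as.character(x$sex)
  if (!all(x$sex %in% SEXES)) {
    stop_("sex must be one of ", paste(SEXES, collapse = ", "))
  }
  if (any(x$M <= 0) || any(x$S <= 0)) {
    stop_("invalid LMS parameters: M and S must be > 0")
  }
  if (anyDuplicated(x[c("week", "sex")])) {
    stop_("duplicate (week, sex) rows in LMS table")
  }
  ranges <- lapply(SEXES, function(s) sort(x$week[x$sex == s]))
  names(ranges) <- SEXES
  if (any(lengths(ranges) == 0L)) stop_("LMS table must cover both sexes")
  gaps <- character(0)
  for (s in SEXES) {
    w <- ranges[[s]]
    miss <- setdiff(seq(min(w), max(w)), w)
    if (length(miss)) {
      gaps <- c(gaps, paste0(s, " week ", miss))
    }
  }
  if (!identical(range(ranges$male), range(ranges$female))) {
    stop_("both sexes must cover the identical week range")
  }
  if (length(gaps)) {
    stop_("LMS table has gaps: missing ", paste(gaps, collapse = ", "))
  }
  x <- x[order(x$week, match(x$sex, SEXES)), ]
  rownames(x) <- NULL
  structure(x, class = c("lms_table", "data.frame"))
}

#' @rdname lms_table
#' @param table an `lms_table`.
#' @export
week_range <- function(table) range(table$week)

# Extract the triple(s) for one sex at integer weeks (exact lookup).
lms_lookup <- function(table, sex, weeks) {
  sub <- table[table$sex == sex, ]
  idx <- match(weeks, sub$week)
  if (anyNA(idx)) {
    stop_("week(s) ", paste(unique(weeks[is.na(idx)]), collapse = ", "),
          " not present in LMS table for ", sex)
  }
  lms_triple(sub$L[idx], sub$M[idx], sub$S[idx])
}

#' Interpolate LMS parameters at non-integer gestations
#'
#' Linear interpolation in exact gestational age of `L`, `log M` and
#' `log S` between adjacent integer weeks; exact at the tabulated weeks.
#' Interpolating the logs keeps `M` and `S` positive and is consistent
#' with the log link used for the median during fitting.
#'
#' @param table an [lms_table()].
#' @param sex `"male"` or `"female"`.
#' @param t gestational age(s) in exact weeks (real), within the table's
#'   week range.
#' @return An [lms_triple()] of the same length as `t`.
#' @export
interpolate_lms <- function(table, sex, t) {
  if (!inherits(table, "lms_table")) table <- lms_table(table)
  sex <- match.arg(sex, SEXES)
  t <- as.numeric(t)
  rng <- week_range(table)
  if (any(t < rng[1] | t > rng[2])) {
    stop_("gestation outside the table's week range [", rng[1], ", ",
          rng[2], "]")
  }
  w0 <- pmin(floor(t), rng[2] - 1L)
  w1 <- w0 + 1L
  a <- lms_lookup(table, sex, w0)
  b <- lms_lookup(table, sex, w1)
  f <- t - w0
  lms_triple(
    L = (1 - f) * a$L + f * b$L,
    M = exp((1 - f) * log(a$M) + f * log(b$M)),
    S = exp((1 - f) * log(a$S) + f * log(b$S))
  )
}

#' Build a centile table from an LMS table
#'
#' Applies the centile formula cell-wise over every (sex, week) in the
#' table and every line of the centile specification, rounding half away
#' from zero to integer grams (the convention of printed chart tables).
#'
#' @param table an [lms_table()].
#' @param spec a [centile_spec()]; default the seven-line two-thirds-SD
#'   spacing.
#' @return An object of class `centile_table`: a list with one
#'   weeks-by-labels integer matrix per sex and the spec used.
#' @export
make_centile_table <- function(table, spec = default_centile_spec()) {
  if (!inherits(table, "lms_table")) table <- lms_table(table)
  if (!inherits(spec, "centile_spec")) stop_("spec must be a centile_spec")
  weeks <- sort(unique(table$week))
  out <- list()
  for (s in SEXES) {
    tri <- lms_lookup(table, s, weeks)
    m <- matrix(NA_real_, nrow = length(weeks), ncol = nrow(spec),
                dimnames = list(weeks, spec$label))
    for (j in seq_len(nrow(spec))) {
      bad <- abs(tri$L) >= .L_EPS & (1 + tri$L * tri$S * spec$z[j]) <= 0
      if (any(bad)) {
        stop_("centile undefined at (", s, ", week ",
              weeks[which(bad)[1]], ", ", spec$label[j], ")")
      }
      m[, j] <- round_half_out(centile_value(tri, spec$z[j]))
    }
    out[[s]] <- m
  }
  structure(list(male = out$male, female = out$female, spec = spec),
            class = "centile_table")
}

#' @export
print.centile_table <- function(x, ...) {
  for (s in SEXES) {
    cat("Birth weight (g) centiles,", s, "\n")
    print(x[[s]])
    cat("\n")
  }
  invisible(x)
}
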