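# Box-Cox-Cole-Green (BCCG) distribution and LMS centile arithmetic.
#
# An LMS triple (L, M, S) describes a positive measurement y through the
# Box-Cox transform: z = ((y/M)^L - 1) / (L*S) is standard normal
# (z = log(y/M)/S in the limit L -> 0). Centiles follow from
# C = M * (1 + L*S*z)^(1/L). The positive-support truncation factor of
# the BCCG density is deliberately omitted: for coefficients of variation
# S <= 0.27 (as in weight-for-gestation charts) the correction is below
# 1e-8 and the classical LMS method ignores it.

#' LMS parameter triple
#'
#' Bundle the three LMS parameters: Box-Cox power `L` (dimensionless, may
#' be negative or zero), median `M` (measurement units, > 0) and
#' coefficient of variation `S` (dimensionless, > 0). Vectors are
#' accepted and recycled against each other.
#'
#' @param L Box-Cox power(s).
#' @param M median(s), strictly positive.
#' @param S coefficient(s) of variation, strictly positive.
#' @return An object of class `lms_triple`: a list with components
#'   `L`, `M`, `S` of common length.
#' @examples
#' lms_triple(L = 0.69, M = 3019, S = 0.162)
#' @export
lms_triple <- function(L, M, S) {
  n <- max(length(L), length(M), length(S))
  L <- rep_len(as.numeric(L), n)
  M <- rep_len(as.numeric(M), n)
  S <- rep_len(as.numeric(S), n)
  if (anyNA(L) || anyNA(M) || anyNA(S)) stop_("L, M, S must be non-missing")
  if (any(M <= 0)) stop_("invalid LMS parameters: M must be > 0")
  if (any(S <= 0)) stop_("invalid LMS parameters: S must be > 0")
  structure(list(L = L, M = M, S = S), class = "lms_triple")
}

as_lms_triple <- function(lms) {
  if (inherits(lms, "lms_triple")) return(lms)
  if (is.list(lms) && all(c("L", "M", "S") %in% names(lms))) {
    return(lms_triple(lms$L, lms$M, lms$S))
  }
  stop_("expected an lms_triple or a list with components L, M, S")
}

# Switch point to the L -> 0 (lognormal) analytic limit.
.L_EPS <- 1e-8

#' Centile (quantile at a given z) of an LMS distribution
#'
#' Evaluates `M * (1 + L*S*z)^(1/L)`, the measurement value lying `z`
#' standard-deviation-equivalents from the median; for `|L| < 1e-8` the
#' analytic limit `M * exp(S*z)` is used. This is the LMS centile
#' formula: the 2nd/9th/25th/50th/75th/91st/98th chart centiles
#' correspond to z = 0, +/-2/3, +/-4/3, +/-2 (see
#' [default_centile_spec()]).
#'
#' @param lms an [lms_triple()] (vector components recycled against `z`).
#' @param z z-score(s) at which to evaluate.
#' @return Numeric vector of (unrounded) measurement values.
#' @seealso [zscore_value()] for the inverse.
#' @examples
#' centile_value(lms_triple(0.83, 3251, 0.150), z = -2)
#' @export
centile_value <- function(lms, z) {
  lms <- as_lms_triple(lms)
  n <- max(length(lms$L), length(z))
  L <- rep_len(lms$L, n); M <- rep_len(lms$M, n); S <- rep_len(lms$S, n)
  z <- rep_len(as.numeric(z), n)
  small <- abs(L) < .L_EPS
  a <- 1 + L * S * z
  if (any(!small & a <= 0)) {
    stop_("centile undefined: 1 + L*S*z <= 0 for the given triple and z")
  }
  out <- numeric(n)
  out[small] <- M[small] * exp(S[small] * z[small])
  ns <- !small
  out[ns] <- M[ns] * a[ns]^(1 / L[ns])
  out
}

#' z-score (SD score) of a measurement under an LMS distribution
#'
#' Evaluates `((x/M)^L - 1) / (L*S)` (`log(x/M)/S` for `|L| < 1e-8`),
#' the exact inverse of [centile_value()] on its domain.
#'
#' @param x measurement value(s), strictly positive.
#' @param lms an [lms_triple()].
#' @return Numeric vector of z-scores.
#' @examples
#' zscore_value(2302, lms_triple(0.83, 3251, 0.150))
#' @export
zscore_value <- function(x, lms) {
  lms <- as_lms_triple(lms)
  n <- max(length(lms$L), length(x))
  L <- rep_len(lms$L, n); M <- rep_len(lms$M, n); S <- rep_len(lms$S, n)
  x <- rep_len(as.numeric(x), n)
  if (any(!is.finite(x) | x <= 0)) stop_("invalid measurement: x must be > 0")
  small <- abs(L) < .L_EPS
  out <- numeric(n)
  out[small] <- log(x[small] / M[small]) / S[small]
  ns <- !small
  out[ns] <- ((x[ns] / M[ns])^L[ns] - 1) / (L[ns] * S[ns])
  out
}

#' BCCG log-density, CDF and quantile function
#'
#' The distribution in which the Box-Cox transformed, scaled measurement
#' is standard normal. `bccg_cdf(x) = pnorm(zscore_value(x, lms))`,
#' `bccg_quantile(p) = centile_value(lms, qnorm(p))`, and
#' `bccg_logdensity` is the change-of-variables density of the Box-Cox
#' transform. The truncation correction for positive support is omitted
#' (negligible for S well below 1/|2L|).
#'
#' @param x measurement value(s), strictly positive.
#' @param p probability(ies) in (0, 1).
#' @param lms an [lms_triple()].
#' @return `bccg_logdensity`: log density values; `bccg_cdf`:
#'   probabilities; `bccg_quantile`: measurement values.
#' @examples
#' lms <- lms_triple(0.69, 3019, 0.162)
#' bccg_cdf(bccg_quantile(0.1, lms), lms)
#' @export
bccg_logdensity <- function(x, lms) {
  lms <- as_lms_triple(lms)
  z <- zscore_value(x, lms)
  n <- length(z)
  L <- rep_len(lms$L, n); M <- rep_len(lms$M, n); S <- rep_len(lms$S, n)
  x <- rep_len(as.numeric(x), n)
  -z^2 / 2 - 0.5 * log(2 * pi) + L * log(x / M) - log(x) - log(S)
}

#' @rdname bccg_logdensity
#' @export
bccg_cdf <- function(x, lms) stats::pnorm(zscore_value(x, lms))

#' @rdname bccg_logdensity
#' @export
bccg_quantile <- function(p, lms) {
  if (any(!is.finite(p) | p <= 0 | p >= 1)) {
    stop_("invalid probability: p must be in (0, 1)")
  }
  centile_value(as_lms_triple(lms), stats::qnorm(p))
}

#' Centile specification (labelled z values)
#'
#' An ordered set of chart centile lines, each a label plus the z value
#' that defines it. The default follows the two-thirds-of-an-SD spacing
#' convention: lines at z = 0, +/-2/3, +/-4/3, +/-2, labelled as the
#' approximate 50th, 25th/75th, 9th/91st and 2nd/98th centiles. Labels
#' map to exact z values, not to `qnorm(0.02)` etc.: the z spacing, not
#' the nominal tail area, defines the lines.
#'
#' @param labels character vector of unique line labels.
#' @param z numeric vector of strictly increasing z values.
#' @return An object of class `centile_spec`: a data.frame with columns
#'   `label` and `z`.
#' @export
centile_spec <- function(labels, z) {
  labels <- as.character(labels)
  z <- as.numeric(z)
  if (length(labels) != length(z) || length(z) == 0L) {
    stop_("labels and z must be non-empty and of equal length")
  }
  if (anyDuplicated(labels)) stop_("centile labels must be unique")
  if (any(diff(z) <= 0)) stop_("centile z values must be strictly increasing")
  structure(data.frame(label = labels, z = z, stringsAsFactors = FALSE),
            class = c("centile_spec", "data.frame"))
}

#' @rdname centile_spec
#' @export
default_centile_spec <- function() {
  centile_spec(
    labels = c("2nd", "9th", "25th", "50th", "75th", "91st", "98th"),
    z = c(-2, -4 / 3, -2 / 3, 0, 2 / 3, 4 / 3, 2)
  )
}
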