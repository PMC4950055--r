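# Published England & Wales Down syndrome birth-weight reference.

#' Down syndrome birth-weight reference: sample sizes and LMS parameters
#'
#' The published weekly sample sizes and smoothed LMS parameters for
#' birth weight in live-born infants with free trisomy 21 in England and
#' Wales (national register births, 1989-2011; n = 8,825), covering
#' 28-43 completed weeks of gestation. The Box-Cox power `L` and
#' coefficient of variation `S` are shared by the sexes; the median `M`
#' differs by a constant percentage (about 2.4% lower in girls). These
#' values serve both as the default generative truth for
#' [simulate_register()] and as the natural input to
#' [make_centile_table()].
#'
#' @return A list with components `counts` (data.frame `week`, `sex`,
#'   `n`) and `lms` (an [lms_table()]), both covering weeks 28-43 for
#'   both sexes.
#' @examples
#' ref <- ds_reference()
#' sum(ref$counts$n) # 8825
#' @export
ds_reference <- function() {
  week <- 28:43
  n_male <- c(11, 16, 26, 29, 73, 84, 117, 192, 414, 693, 1219, 822,
              797, 204, 55, 8)
  n_female <- c(10, 19, 23, 27, 41, 54, 85, 156, 298, 525, 921, 824,
                809, 207, 56, 10)
  M_male <- c(960, 1132, 1319, 1518, 1719, 1915, 2113, 2333, 2567, 2800,
              3019, 3164, 3251, 3304, 3318, 3300)
  M_female <- c(937, 1105, 1288, 1482, 1678, 1869, 2063, 2277, 2506,
                2733, 2947, 3088, 3174, 3225, 3239, 3221)
  L <- c(-0.12, -0.03, 0.06, 0.15, 0.23, 0.31, 0.39, 0.47, 0.55, 0.62,
         0.69, 0.76, 0.83, 0.89, 0.96, 1.02)
  S <- c(0.266, 0.253, 0.243, 0.237, 0.233, 0.228, 0.220, 0.206, 0.189,
         0.174, 0.162, 0.153, 0.150, 0.151, 0.152, 0.153)
  counts <- data.frame(
    week = rep(week, 2L),
    sex = rep(c("male", "female"), each = length(week)),
    n = c(n_male, n_female)
  )
  lms <- lms_table(data.frame(
    week = rep(week, 2L),
    sex = rep(c("male", "female"), each = length(week)),
    L = rep(L, 2L),
    M = c(M_male, M_female),
    S = rep(S, 2L)
  ))
  list(counts = counts, lms = lms)
}
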