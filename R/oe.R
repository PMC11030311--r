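#' Capped observed/expected ratio
#'
#' The unit of missense constraint: the count of rare variants observed in a
#' reference population divided by the count expected under the neutral
#' mutational model. Because the method looks for depletion, ratios are capped
#' at 1, and an expectation of exactly zero is floored at 1e-9 so the ratio
#' stays finite.
#'
#' @param obs Non-negative observed variant count(s).
#' @param exp Non-negative expected count(s) (may be fractional).
#' @param cap Upper cap on the ratio. Default 1.
#' @param exp_floor Replacement for an expectation of exactly zero.
#'
#' @return A numeric vector of ratios in `[0, cap]`.
#' @examples
#' oe_ratio(0, 10)   # 0
#' oe_ratio(30, 20)  # capped at 1
#' oe_ratio(3, 0)    # floored expectation -> 1
#' @export
oe_ratio <- function(obs, exp, cap = 1, exp_floor = 1e-9) {
  if (any(obs < 0, na.rm = TRUE) || any(exp < 0, na.rm = TRUE)) {
    stop("`obs` and `exp` must be non-negative", call. = FALSE)
  }
  pmin(cap, obs / pmax(exp, exp_floor))
}

#' Observed/expected summary as a tibble
#'
#' @param obs,exp Vectors of observed and expected counts.
#' @inheritParams oe_ratio
#' @return A tibble with columns `obs`, `exp`, `oe`.
#' @export
oe_tbl <- function(obs, exp, cap = 1, exp_floor = 1e-9) {
  tibble::tibble(obs = obs, exp = exp, oe = oe_ratio(obs, exp, cap, exp_floor))
}
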