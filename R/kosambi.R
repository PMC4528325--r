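#' Kosambi map function
#'
#' Convert between genetic map distance and recombination fraction under the
#' Kosambi map function, which allows for partial crossover interference.
#' For a distance \eqn{d} in Morgans, \eqn{r = \tanh(2d)/2}; inversely
#' \eqn{d = \log((1+2r)/(1-2r))/4}.  Distances are handled in centimorgans.
#'
#' @param d Genetic distance(s) in cM, non-negative.
#' @param r Recombination fraction(s) in [0, 0.5).
#' @return `kosambi_d_to_r` returns recombination fractions in [0, 0.5);
#'   `kosambi_r_to_d` returns distances in cM.
#' @examples
#' kosambi_d_to_r(27.465)   # ~0.25
#' kosambi_r_to_d(0.25)     # 25 * log(3) / 2 = 27.465 cM
#' @export
kosambi_d_to_r <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop_fmt("map distance must be >= 0 cM")
  0.5 * tanh(2 * d / 100)
}

#' @rdname kosambi_d_to_r
#' @export
kosambi_r_to_d <- function(r) {
  if (any(r < 0 | r >= 0.5, na.rm = TRUE))
    stop_fmt("recombination fraction must lie in [0, 0.5)")
  100 * 0.25 * log((1 + 2 * r) / (1 - 2 * r))
}
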