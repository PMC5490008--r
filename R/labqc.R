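#' @include peptidome.R
NULL

#' Drop-to-particle ratio of a droplet sorter
#'
#' Drops generated per sorted particle: the drop generation frequency
#' divided by the net particle rate (detected events minus electronic
#' noise). A large ratio means sorted particles are separated by many
#' empty drops, which is what makes single-particle deposition safe.
#'
#' @param params a [SorterParams] object. With the defaults (38,700
#'   drops/s, 50 events/s of which 20/s are noise) the ratio is 1,290,
#'   i.e. about 1 particle per 1,300 drops.
#' @return list with elements `raw` (exact ratio), `rounded` (nearest
#'   hundred) and `netParticleRate`.
#' @examples
#' dropParticleRatio(sorterParams())
#' @export
dropParticleRatio <- function(params = sorterParams()) {
  net <- params@eventRateHz - params@noiseRateHz
  if (net <= 0) stop("net particle rate must be > 0; ratio undefined")
  raw <- params@dropFrequencyHz / net
  list(raw = raw, rounded = round(raw / 100) * 100, netParticleRate = net)
}

#' Doublet probability of an occupied droplet
#'
#' Under Poisson droplet occupancy with rate lambda = net particle rate
#' / drop frequency, the probability that an occupied drop holds two or
#' more particles:
#' \deqn{P(N \ge 2 \mid N \ge 1) = \frac{1 - e^{-\lambda} -
#'   \lambda e^{-\lambda}}{1 - e^{-\lambda}}}
#' For small lambda this approaches lambda / 2.
#'
#' @param params a [SorterParams] object.
#' @return probability (numeric scalar).
#' @examples
#' doubletProbability(sorterParams())   # ~3.9e-4
#' @export
doubletProbability <- function(params = sorterParams()) {
  net <- params@eventRateHz - params@noiseRateHz
  if (net <= 0) stop("net particle rate must be > 0; occupancy undefined")
  lambda <- net / params@dropFrequencyHz
  if (lambda > 1)
    warning("droplet occupancy lambda > 1; sorter overloaded")
  (1 - exp(-lambda) - lambda * exp(-lambda)) / (1 - exp(-lambda))
}
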