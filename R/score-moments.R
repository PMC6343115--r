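# Population moments of the mean scale score under the latent-trait ordinal
# model, by quadrature over the person trait. Used to calibrate latent
# shifts against target standardized effects and as a simulation oracle.

# Category probabilities of one item conditional on the person trait t.
.item_pmf_given_trait <- function(t, loading, tau) {
  s <- sqrt(1 - loading^2)
  exceed <- if (s > 0) {
    1 - stats::pnorm((tau - loading * t) / s)
  } else {
    as.numeric(loading * t > tau)
  }
  c(1, exceed) - c(exceed, 0) # pmf over categories min..max
}

#' Population moments of a scale score under the latent-trait generator
#'
#' Computes the population mean and standard deviation of the mean-of-items
#' score, and (for scales with a cut-off) the caseness probability, for a
#' latent trait distributed N(`delta`, 1). Items are conditionally
#' independent given the trait, so all quantities reduce to one-dimensional
#' integrals over the trait, evaluated on a fine grid; the caseness
#' probability uses the exact conditional distribution of the item sum
#' (discrete convolution).
#'
#' @param delta Latent-trait mean shift (standardized units).
#' @param definition A [scale_definition()].
#' @param loading Item loading in (0, 1]; defaults to the generator default
#'   for the scale.
#' @param ngrid Number of quadrature nodes over the trait.
#' @return List with `mean`, `sd` and `p_case` (`NA` without a cut-off).
#' @export
score_moments <- function(delta, definition,
                          loading = .config_scalar(
                            synthetic_config()$item_loading, definition$name,
                            "item_loading"),
                          ngrid = 601L) {
  stopifnot(inherits(definition, "scale_definition"))
  tau <- .scale_thresholds(definition$name)
  cutoff <- definition$caseness_cutoff
  k <- definition$n_items
  cats <- seq.int(definition$response_min, definition$response_max)
  tg <- seq(delta - 6, delta + 6, length.out = ngrid)
  w <- stats::dnorm(tg, delta, 1)
  w <- w / sum(w)
  f <- numeric(ngrid); v <- numeric(ngrid); pc <- numeric(ngrid)
  sum_support <- seq.int(k * definition$response_min, k * definition$response_max)
  for (i in seq_len(ngrid)) {
    pmf <- .item_pmf_given_trait(tg[i], loading, tau)
    m1 <- sum(cats * pmf)
    f[i] <- m1
    v[i] <- sum(cats^2 * pmf) - m1^2
    if (!is.null(cutoff)) {
      conv <- 1
      for (j in seq_len(k)) conv <- stats::convolve(conv, rev(pmf), type = "open")
      pc[i] <- sum(pmax(conv, 0)[sum_support / k >= cutoff])
    }
  }
  mu <- sum(w * f)
  va <- sum(w * v) / k + sum(w * (f - mu)^2)
  list(mean = mu, sd = sqrt(va),
       p_case = if (is.null(cutoff)) NA_real_ else sum(w * pc))
}

#' Latent shift that produces a target standardized effect
#'
#' Inverts the generator's shift-to-effect map: finds the latent-trait shift
#' `delta` such that the population standardized effect on the observed
#' score scale,
#' \deqn{(\mu(\delta) - \mu(0)) / \sigma(\delta),}
#' equals `target_effect`, where \eqn{\mu} and \eqn{\sigma} come from
#' [score_moments()]. The denominator is the score SD of the *shifted*
#' population, matching an estimator that standardizes by the observed
#' (cohort) standard deviation.
#'
#' @param target_effect Target standardized effect (signed).
#' @param definition A [scale_definition()].
#' @param loading Item loading; defaults as in [score_moments()].
#' @param interval Search interval for the shift.
#' @return The latent shift (a single number).
#' @export
latent_shift_for_effect <- function(target_effect, definition,
                                    loading = .config_scalar(
                                      synthetic_config()$item_loading,
                                      definition$name, "item_loading"),
                                    interval = c(-3, 3)) {
  if (target_effect == 0) return(0)
  base_mean <- score_moments(0, definition, loading)$mean
  f <- function(d) {
    m <- score_moments(d, definition, loading)
    (m$mean - base_mean) / m$sd - target_effect
  }
  stats::uniroot(f, interval, tol = 1e-7)$root
}
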