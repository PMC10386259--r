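## The loop electrostatic crossover function Phi.
##
## Phi(y) interpolates the electrostatic self-energy of a freely jointed
## charged chain of y = kappa * l_ss * L screened backbone bonds between the
## small-y (rod-like, Phi ~ y (1 - ln(pi/2))) and large-y (fully screened,
## Phi -> 1) regimes.

#' @importFrom pracma expint_E1
NULL

## pFq power series for x >= 0.  All terms are positive, so plain forward
## summation is stable; the ratio of consecutive terms decays like
## x / k^(q-p+1) and the series terminates quickly for the arguments used
## here (q - p = 1).
genhyp_series <- function(a, b, x, rel_tol = 1e-16, max_terms = 10000L) {
  stopifnot(x >= 0)
  term <- 1
  total <- 1
  for (k in 0:(max_terms - 1L)) {
    term <- term * prod(a + k) / prod(b + k) * x / (k + 1)
    total <- total + term
    if (term < rel_tol * total) return(total)
  }
  stop("hypergeometric series did not converge", call. = FALSE)
}

## Beyond this the alternating y^2/y^3 hypergeometric terms (each growing
## like exp(y/pi)) exhaust double precision; the crossover form, whose error
## vanishes as y -> infinity, takes over.
PHI_SERIES_LIMIT <- 70

phi_exact_scalar <- function(y) {
  if (y == 0) return(0)
  if (y > PHI_SERIES_LIMIT) return(phi_approx(y))
  g <- physical_constants()$euler_mascheroni
  x <- y^2 / (4 * pi^2)
  f1 <- genhyp_series(0.5, c(1, 1.5), x)
  f2 <- genhyp_series(c(1, 1), c(1.5, 1.5, 2), x)
  y * log(y) + y * (g - log(pi / 2)) -
    y^2 / 2 * f1 + y^3 / (2 * pi^2) * f2 +
    1 - exp(-y) + y * pracma::expint_E1(y)
}

#' Loop electrostatic function Phi: exact hypergeometric evaluation
#'
#' Direct summation of the closed form in terms of the generalized
#' hypergeometric functions 1F2(1/2; 1, 3/2; y^2/4pi^2) and
#' 2F3(1, 1; 3/2, 3/2, 2; y^2/4pi^2) together with the incomplete gamma
#' function Gamma(0, y) = E1(y).  Phi(0) = 0 and Phi(y)/y -> 1 - ln(pi/2)
#' as y -> 0.  For y above ~70 the two hypergeometric terms cancel beyond
#' double precision and evaluation switches to the asymptotically exact
#' crossover form [phi_approx()].
#'
#' @param y Dimensionless argument, >= 0 (vectorized).
#' @return Phi(y), dimensionless.
#' @seealso [phi_approx()] for the fast crossover form used by default in
#'   energy evaluation.
#' @examples
#' phi_exact(0)        # 0
#' phi_exact(1.723)    # ~0.841
#' @export
phi_exact <- function(y) {
  stopifnot(is.numeric(y))
  if (any(!is.finite(y)) || any(y < 0)) stop("y must be >= 0", call. = FALSE)
  vapply(y, phi_exact_scalar, numeric(1))
}

#' Loop electrostatic function Phi: crossover approximation
#'
#' Rational-crossover approximation of [phi_exact()] that blends the small-y
#' polynomial expansion with the large-y asymptote through the switch factor
#' `(2 pi)^6 / (y^6 + (2 pi)^6)`.  This is the form used by production
#' implementations of the model and is the package default for energy
#' evaluation; it deviates from the exact hypergeometric evaluation by at
#' most ~0.21 (at y ~ 26) and agrees in both limits.
#'
#' @inheritParams phi_exact
#' @return Phi(y), dimensionless.
#' @examples
#' phi_approx(10.05)   # ~1.65
#' @export
phi_approx <- function(y) {
  stopifnot(is.numeric(y))
  if (any(!is.finite(y)) || any(y < 0)) stop("y must be >= 0", call. = FALSE)
  g <- physical_constants()$euler_mascheroni
  out <- numeric(length(y))
  pos <- y > 0
  yp <- y[pos]
  w <- (2 * pi)^6 / (yp^6 + (2 * pi)^6)
  out[pos] <- yp * log(yp) + yp * (g - log(pi / 2)) +
    yp * w * (yp^4 / (36 * pi^4) - yp^3 / (24 * pi^2) +
                yp^2 / (2 * pi^2) - yp / 2) +
    (1 - w) * (yp * (log(2 * pi) - 1.96351) - yp * log(yp)) +
    (1 - exp(-yp)) + yp * pracma::expint_E1(yp)
  out
}

## Dispatch helper used by the energy functions.
phi_eval <- function(y, phi = c("approx", "exact")) {
  phi <- match.arg(phi)
  if (phi == "approx") phi_approx(y) else phi_exact(y)
}
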