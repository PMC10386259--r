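## Deterministic fixture generators: random valid secondary structures and
## synthetic two-state melting tables.

## Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

## Random balanced dot-bracket of exactly `len` characters.  Innermost
## pairs always enclose >= 3 unpaired bases; bifurcations produce
## multiloops when nested under a pair.
random_db <- function(len) {
  if (len < 7) return(strrep(".", len))
  u <- stats::runif(1)
  if (u < 0.2) {
    paste0(".", random_db(len - 1L))
  } else if (u < 0.75 || len < 14) {
    paste0("(", random_db(len - 2L), ")")
  } else {
    k <- sample(7:(len - 7L), 1L)
    paste0(random_db(k), random_db(len - k))
  }
}

#' Deterministic random secondary-structure fixtures
#'
#' Generates `n` valid, non-crossing dot-bracket structures of the given
#' length with a mixture of helices, hairpin, interior and multibranch
#' loops.  The same seed always produces the same set, and every structure
#' parses with [parse_dot_bracket()].
#'
#' @param seed Integer seed.
#' @param n Number of structures.
#' @param length Structure length in nucleotides.
#' @return Character vector of dot-bracket strings.
#' @examples
#' make_structure_fixtures(1, 3, 40)
#' @export
make_structure_fixtures <- function(seed, n, length) {
  stopifnot(n >= 1, length >= 1)
  with_seed(seed, vapply(seq_len(n), function(i) random_db(length),
                         character(1)))
}

#' Synthetic two-state melting table
#'
#' Melting points generated from the closed form
#' `Tm = dH / (dS + R ln c)` of a temperature-independent two-state duplex,
#' optionally with Gaussian noise added on the 1/Tm scale (where the van 't
#' Hoff model is linear).
#'
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @param dH Enthalpy, kcal/mol (negative for a stabilizing duplex).
#' @param dS Entropy, kcal/(mol K) (negative).
#' @param c_grid Strand concentrations, mol/L, in (0, 1).
#' @param noise_sd Standard deviation of noise on 1/Tm, 1/K.
#' @return Data frame with columns `c` and `Tm` (Kelvin).
#' @examples
#' make_melting_fixtures(1, -60, -0.16, 10^seq(-6, -4, length.out = 5))
#' @export
make_melting_fixtures <- function(seed, dH = -60, dS = -0.16,
                                  c_grid = 10^seq(-6, -4, length.out = 8),
                                  noise_sd = 0) {
  stopifnot(all(c_grid > 0), all(c_grid < 1))
  tm <- two_state_tm(dH, dS, c_grid)
  if (noise_sd > 0) {
    inv <- with_seed(seed, 1 / tm + stats::rnorm(length(tm), 0, noise_sd))
    tm <- 1 / inv
  }
  data.frame(c = c_grid, Tm = tm)
}
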