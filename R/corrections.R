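## The four salt-correction terms: loop, stack, duplex initiation, and the
## linear multiloop fit.  All corrections are differences of electrostatic
## free energies between the requested concentration and the standard
## condition rho0 = 1.021 M, evaluated at the *same* temperature, so every
## correction vanishes identically at rho = rho0.

#' Standard (reference) monovalent salt concentration, mol/L
#'
#' Nearest-neighbor parameter sets are calibrated at 1.021 M Na+ (1 M plus
#' buffer sodium).  All salt corrections are taken relative to this
#' concentration.
#'
#' @return 1.021
#' @export
standard_salt <- function() 1.021

## Smallest supported concentration: the stack term diverges like -ln(rho),
## so "virtually no cations" is outside the model.
MIN_RHO <- 1e-6

check_rho <- function(rho) {
  if (any(!is.finite(rho)) || any(rho <= 0)) {
    stop("salt concentration must be > 0 (stack term diverges as rho -> 0)",
         call. = FALSE)
  }
  if (any(rho < MIN_RHO)) {
    stop(sprintf("salt concentration below the supported minimum of %g M",
                 MIN_RHO), call. = FALSE)
  }
  invisible(rho)
}

#' Electrostatic free energy of a loop
#'
#' Debye-Hueckel energy of a freely jointed charged chain of `L` backbone
#' bonds: `G_u(L) = R T l_B kappa^-1 tau_ss^2 Phi(kappa l_ss L)`, with the
#' Manning-condensed single-strand charge density [tau_ss()].  Strictly
#' positive for any rho > 0, increasing in L, and approaching `L` times a
#' constant in the low-salt limit.
#'
#' @param L Loop size in backbone bonds (positive integer; vectorized).
#' @param temperature Temperature in Kelvin.
#' @param rho Monovalent salt concentration, mol/L (> 0).
#' @param geom [na_geometry()] or `"RNA"`/`"DNA"`.
#' @param phi Phi evaluation: `"approx"` (crossover form, default, mirrors
#'   production folding implementations) or `"exact"` (hypergeometric
#'   series).
#' @return Energy in kcal/mol.
#' @examples
#' loop_energy(5, 310.15, 0.03)  # ~1.24 kcal/mol
#' @export
loop_energy <- function(L, temperature, rho, geom = na_geometry("RNA"),
                        phi = c("approx", "exact")) {
  geom <- as_geometry(geom)
  check_rho(rho)
  if (any(L < 1) || any(L != round(L))) {
    stop("loop size L must be a positive integer", call. = FALSE)
  }
  R  <- physical_constants()$gas_constant_kcal
  lB <- bjerrum_length(temperature)
  kappa <- inverse_debye_length(temperature, rho)
  tau <- tau_ss(temperature, geom)
  R * temperature * lB * (1 / kappa) * tau^2 *
    phi_eval(kappa * geom$l_ss * L, phi)
}

#' Salt correction for a loop
#'
#' `g_u(L, rho) = G_u(L; rho) - G_u(L; rho0)` at the same temperature;
#' identically zero at `rho = rho0` and increasing as rho decreases.
#'
#' @inheritParams loop_energy
#' @param rho0 Reference concentration, mol/L (default [standard_salt()]).
#' @return Correction in kcal/mol.
#' @examples
#' loop_salt_correction(10, 1.021, 310.15)   # 0
#' loop_salt_correction(5, 0.03, 310.15)     # ~0.83 kcal/mol
#' @export
loop_salt_correction <- function(L, rho, temperature = 310.15,
                                 geom = na_geometry("RNA"),
                                 rho0 = standard_salt(),
                                 phi = c("approx", "exact")) {
  loop_energy(L, temperature, rho, geom, phi) -
    loop_energy(L, temperature, rho0, geom, phi)
}

#' Electrostatic free energy per stacked base pair
#'
#' Debye-Hueckel interaction energy of a nucleotide with the opposite strand
#' when the two backbones are modelled as parallel charged rods at distance
#' `d`: `G_p = 2 R T tau_ds^2 l_ds l_B K0(kappa d)` with the zeroth-order
#' modified Bessel function of the second kind.  K0 is evaluated directly
#' (base R `besselK`), never through a difference approximation, so the
#' correction vanishes exactly at the reference concentration.  Since
#' `K0(z) ~ -ln z` for small z, the energy diverges logarithmically as
#' rho -> 0.
#'
#' @inheritParams loop_energy
#' @return Energy in kcal/mol per stacking interface.
#' @examples
#' stack_energy(310.15, 0.03)  # ~0.162 kcal/mol
#' @export
stack_energy <- function(temperature, rho, geom = na_geometry("RNA")) {
  geom <- as_geometry(geom)
  check_rho(rho)
  R  <- physical_constants()$gas_constant_kcal
  lB <- bjerrum_length(temperature)
  kappa <- inverse_debye_length(temperature, rho)
  tau <- tau_ds(temperature, geom)
  2 * R * temperature * tau^2 * geom$l_ds * lB * besselK(kappa * geom$d, 0)
}

#' Salt correction per stacked base pair
#'
#' `g_p(rho) = G_p(rho) - G_p(rho0)` at the same temperature.
#'
#' @inheritParams loop_salt_correction
#' @return Correction in kcal/mol per stacking interface.
#' @examples
#' stack_salt_correction(0.03, 310.15)  # ~0.162 kcal/mol
#' @export
stack_salt_correction <- function(rho, temperature = 310.15,
                                  geom = na_geometry("RNA"),
                                  rho0 = standard_salt()) {
  stack_energy(temperature, rho, geom) - stack_energy(temperature, rho0, geom)
}

#' Salt correction for duplex initiation
#'
#' Bimolecular duplex formation carries an initiation penalty whose salt
#' dependence is not captured by the rod/chain electrostatics; an empirical
#' logarithmic term `g_init(rho) = a ln(rho / rho0)` is used instead, with
#' the slope `a` fitted per polymer type (RNA: -0.45324, DNA: -0.58389
#' kcal/mol) and assumed temperature-independent.
#'
#' @inheritParams loop_salt_correction
#' @param slope Optional user override of the slope `a` in kcal/mol; `0`
#'   disables the correction.
#' @param enabled If `FALSE` the correction is switched off (returns 0).
#' @return Correction in kcal/mol per duplex.
#' @examples
#' duplex_init_correction(0.121)            # ~0.967 kcal/mol (RNA)
#' duplex_init_correction(0.121, "DNA")     # larger magnitude slope
#' @export
duplex_init_correction <- function(rho, geom = na_geometry("RNA"),
                                   rho0 = standard_salt(), slope = NULL,
                                   enabled = TRUE) {
  geom <- as_geometry(geom)
  check_rho(rho)
  if (!enabled) return(rep(0, length(rho)))
  a <- if (is.null(slope)) geom$init_slope_a else slope
  a * log(rho / rho0)
}

#' Linear fit of the loop salt correction for multibranch loops
#'
#' Cubic-time folding recursions require multiloop energies linear in the
#' number of branches q and unpaired bases m.  Since the loop size is
#' `L = m + q + 1`, the loop salt correction is approximated as
#' `g_u(L, rho) ~ a0(rho) + a1(rho) L` by unweighted ordinary least squares
#' over the integer loop sizes `L1:L2` (default 6:24; shorter multiloops are
#' rare and conformationally constrained anyway).  At `rho = rho0` the fit
#' is exactly (0, 0).
#'
#' @inheritParams loop_salt_correction
#' @param L1,L2 Integer fit range bounds, `1 <= L1 < L2`.
#' @return List with `a0`, `a1` (kcal/mol), `max_residual` (kcal/mol over
#'   the fit range) and `fit_range`.
#' @examples
#' multiloop_fit(0.021, 310.15)
#' @export
multiloop_fit <- function(rho, temperature = 310.15,
                          geom = na_geometry("RNA"), L1 = 6, L2 = 24,
                          rho0 = standard_salt(),
                          phi = c("approx", "exact")) {
  if (L1 < 1 || L1 != round(L1) || L2 != round(L2)) {
    stop("fit range bounds must be positive integers", call. = FALSE)
  }
  if (L2 - L1 < 1) stop("fit range must contain at least 2 loop sizes",
                        call. = FALSE)
  L <- L1:L2
  g <- loop_salt_correction(L, rho, temperature, geom, rho0, phi)
  fit <- stats::lm(g ~ L)
  a <- unname(stats::coef(fit))
  list(a0 = a[1], a1 = a[2],
       max_residual = max(abs(stats::residuals(fit))),
       fit_range = c(L1, L2))
}

#' All salt-correction terms at one condition
#'
#' Precomputes the per-stack correction, the loop correction array over
#' `L = 1:L_max`, the linear multiloop coefficients and the duplex-initiation
#' correction at a given `(rho, temperature)`.
#'
#' @inheritParams loop_salt_correction
#' @param L_max Largest loop size tabulated (default 31); corrections for
#'   larger loops are computed on demand by [loop_salt_correction()].
#' @param fit_range Integer vector `c(L1, L2)` for the multiloop fit.
#' @param init `"model"` (fitted slope), `"off"`, or a numeric user-supplied
#'   correction value in kcal/mol used verbatim.
#' @return List of class `salt_correction_set` with elements `g_stack`,
#'   `g_loop` (named vector over L), `a0`, `a1`, `g_init`, and the condition
#'   metadata.
#' @examples
#' sc <- salt_correction_set(0.121, 310.15)
#' sc$g_stack
#' sc$g_loop[["5"]]
#' @export
salt_correction_set <- function(rho, temperature = 310.15,
                                geom = na_geometry("RNA"), L_max = 31,
                                fit_range = c(6, 24),
                                rho0 = standard_salt(),
                                init = "model",
                                phi = c("approx", "exact")) {
  geom <- as_geometry(geom)
  phi <- match.arg(phi)
  check_rho(rho)
  L <- seq_len(L_max)
  g_loop <- loop_salt_correction(L, rho, temperature, geom, rho0, phi)
  names(g_loop) <- L
  ml <- multiloop_fit(rho, temperature, geom, fit_range[1], fit_range[2],
                      rho0, phi)
  g_init <-
    if (identical(init, "off")) 0
    else if (is.numeric(init)) init
    else duplex_init_correction(rho, geom, rho0)
  structure(list(
    rho = rho, temperature = temperature, geom_kind = geom$kind,
    g_stack = stack_salt_correction(rho, temperature, geom, rho0),
    g_loop = g_loop, a0 = ml$a0, a1 = ml$a1,
    g_init = g_init, fit_range = ml$fit_range, rho0 = rho0, phi = phi
  ), class = "salt_correction_set")
}

#' @export
print.salt_correction_set <- function(x, ...) {
  cat(sprintf("Salt corrections (%s) at rho = %g M, T = %g K (reference %g M):\n",
              x$geom_kind, x$rho, x$temperature, x$rho0))
  cat(sprintf("  stack   g_p    = %+.4f kcal/mol\n", x$g_stack))
  cat(sprintf("  init    g_init = %+.4f kcal/mol\n", x$g_init))
  cat(sprintf("  multiloop fit [%d,%d]: a0 = %+.4f, a1 = %+.4f kcal/mol\n",
              x$fit_range[1], x$fit_range[2], x$a0, x$a1))
  cat(sprintf("  loop    g_u(L) over L = 1..%d, e.g. g_u(5) = %+.4f kcal/mol\n",
              length(x$g_loop), x$g_loop[["5"]]))
  invisible(x)
}

#' @export
as.data.frame.salt_correction_set <- function(x, ...) {
  data.frame(
    term = c("g_stack", "g_init", "a0", "a1",
             paste0("g_loop_", names(x$g_loop))),
    kcal_mol = c(x$g_stack, x$g_init, x$a0, x$a1, unname(x$g_loop)),
    stringsAsFactors = FALSE
  )
}

#' Serialize a salt-correction set
#'
#' @param x A `salt_correction_set`.
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_salt_corrections <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    writeLines(jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA),
               path)
  }
  invisible(path)
}
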