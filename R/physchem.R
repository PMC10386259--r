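## Physical constants, permittivity, Bjerrum/Debye lengths, Manning charge
## densities.  Energies are kcal/mol, lengths Angstrom, concentrations mol/L,
## temperatures Kelvin throughout the package.

#' Physical constants (CODATA 2018)
#'
#' Returns the fundamental constants used by all electrostatic computations.
#' Derived quantities such as the Bjerrum-length prefactor are always computed
#' from these values, never hard-coded.
#'
#' @return A named list of class `phys_constants` with elements
#'   `elementary_charge` (C), `boltzmann` (J/K), `vacuum_permittivity` (F/m),
#'   `avogadro` (1/mol), `gas_constant_kcal` (kcal/(mol K)) and
#'   `euler_mascheroni` (dimensionless).
#' @examples
#' physical_constants()$gas_constant_kcal  # ~0.0019872
#' @export
physical_constants <- function() {
  e    <- 1.602176634e-19    # elementary charge, exact since 2019 SI
  kB   <- 1.380649e-23       # Boltzmann constant, exact since 2019 SI
  eps0 <- 8.8541878128e-12   # vacuum permittivity
  NA_  <- 6.02214076e23      # Avogadro constant, exact since 2019 SI
  structure(list(
    elementary_charge   = e,
    boltzmann           = kB,
    vacuum_permittivity = eps0,
    avogadro            = NA_,
    gas_constant_kcal   = kB * NA_ / 4184,
    euler_mascheroni    = 0.577215664901532861
  ), class = "phys_constants")
}

#' @export
print.phys_constants <- function(x, ...) {
  cat("Physical constants (CODATA 2018):\n")
  for (nm in names(x)) cat(sprintf("  %-20s %.12g\n", nm, x[[nm]]))
  invisible(x)
}

#' Dump the physical constants and derived prefactors as JSON
#'
#' For auditability: the raw constants together with the two derived
#' prefactors entering the Bjerrum and Debye lengths.
#'
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, if written to `path`).
#' @export
constants_json <- function(path = NULL) {
  k <- physical_constants()
  obj <- c(unclass(k), list(
    bjerrum_prefactor_AK = bjerrum_prefactor(),
    debye_prefactor      = debye_prefactor()
  ))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Bjerrum-length prefactor e^2/(4 pi k_B eps0) in Angstrom Kelvin
#'
#' The Bjerrum length is `bjerrum_prefactor() / (T * relative_permittivity(T))`.
#' Computed from [physical_constants()]; CODATA 2018 gives 167100.95 A K
#' (the value 167092.53 A K quoted in parts of the literature differs by
#' 5e-5 relative, which is physically inconsequential).
#'
#' @return Scalar, Angstrom Kelvin.
#' @export
bjerrum_prefactor <- function() {
  k <- physical_constants()
  k$elementary_charge^2 /
    (4 * pi * k$boltzmann * k$vacuum_permittivity) * 1e10
}

#' Debye-length prefactor 1/sqrt(8 pi N_A) in A^(3/2) mol^(1/2) L^(-1/2)
#'
#' The inverse Debye length is `sqrt(bjerrum_length(T) * I) / debye_prefactor()`
#' with the ionic strength I in mol/L and lengths in Angstrom; the litre-to-
#' cubic-Angstrom conversion (1 L = 1e27 A^3) is absorbed here.
#'
#' @return Scalar, ~8.1284 in the mixed Angstrom/litre units.
#' @export
debye_prefactor <- function() {
  k <- physical_constants()
  1 / sqrt(8 * pi * k$avogadro / 1e27)
}

#' Relative permittivity of water as a function of temperature
#'
#' Empirical cubic-polynomial-plus-1/T fit, valid over liquid-water
#' temperatures.  Its temperature dependence keeps the Bjerrum length above
#' the single-strand bond length over the whole range, so the Manning charge
#' densities are continuous in T (a constant eps_r = 80 would introduce a
#' spurious discontinuity near 53 C; see [tau_ss()]).
#'
#' @param temperature Temperature in Kelvin, in (0, 500].
#' @return Dimensionless relative permittivity (vectorized over `temperature`).
#' @examples
#' relative_permittivity(310.15)  # ~74.14
#' @export
relative_permittivity <- function(temperature) {
  stopifnot(is.numeric(temperature))
  if (any(!is.finite(temperature)) || any(temperature <= 0) ||
      any(temperature > 500)) {
    stop("temperature must be in (0, 500] K", call. = FALSE)
  }
  T <- temperature
  5321 / T + 233.76 - 0.9297 * T + 1.417e-3 * T^2 - 0.8292e-6 * T^3
}

#' Bjerrum length in Angstrom
#'
#' Distance at which the Coulomb energy of two unit charges in water equals
#' the thermal energy k_B T.
#'
#' @inheritParams relative_permittivity
#' @return Length in Angstrom (vectorized).
#' @examples
#' bjerrum_length(310.15)  # ~7.27 A
#' @export
bjerrum_length <- function(temperature) {
  bjerrum_prefactor() / (temperature * relative_permittivity(temperature))
}

#' Ionic strength of a solution, mol/L
#'
#' `I = 1/2 sum_i rho_i z_i^2` over all ionic species.  For a single fully
#' dissociated monovalent salt at concentration rho (both ions counted) this
#' reduces to rho.
#'
#' @param species A data frame or list with components `concentration`
#'   (mol/L, >= 0) and `charge` (integer).
#' @return Ionic strength in mol/L.
#' @examples
#' ionic_strength(data.frame(concentration = c(1.021, 1.021), charge = c(1, -1)))
#' @export
ionic_strength <- function(species) {
  conc <- species$concentration
  z    <- species$charge
  if (is.null(conc) || is.null(z) || length(conc) == 0L) {
    stop("species must be non-empty with 'concentration' and 'charge'",
         call. = FALSE)
  }
  if (length(conc) != length(z)) {
    stop("concentration and charge must have equal length", call. = FALSE)
  }
  if (any(conc < 0)) stop("concentrations must be >= 0", call. = FALSE)
  sum(conc * z^2) / 2
}

#' Inverse Debye screening length, 1/Angstrom
#'
#' `kappa = sqrt(bjerrum_length(T) * I) / debye_prefactor()`.  The screening
#' length `1/kappa` shrinks with the square root of the ionic strength.
#'
#' @inheritParams relative_permittivity
#' @param ionic_strength Ionic strength in mol/L, > 0.
#' @return kappa in 1/Angstrom.
#' @examples
#' 1 / inverse_debye_length(310.15, 1.0)  # screening length ~3.0 A
#' @export
inverse_debye_length <- function(temperature, ionic_strength) {
  if (any(!is.finite(ionic_strength)) || any(ionic_strength <= 0)) {
    stop("ionic strength must be > 0 (screening length undefined otherwise)",
         call. = FALSE)
  }
  sqrt(bjerrum_length(temperature) * ionic_strength) / debye_prefactor()
}

#' Nucleic-acid geometry
#'
#' Per-polymer geometric constants of the charged-chain/charged-rod model:
#' single-strand backbone bond length `l_ss` (phosphate-to-phosphate),
#' double-strand helical rise `l_ds`, inter-strand rod distance `d`, cation
#' charge `z_c` (the model supports `z_c = 1` only) and the empirical slope
#' `init_slope_a` of the duplex-initiation salt correction.
#'
#' @param kind `"RNA"` or `"DNA"`.
#' @param l_ss,l_ds Optional overrides, Angstrom.
#' @param init_slope_a Optional override of the duplex-initiation slope,
#'   kcal/mol.
#' @return List of class `na_geometry`.
#' @examples
#' na_geometry("RNA")
#' na_geometry("DNA", l_ds = 3.3)
#' @export
na_geometry <- function(kind = c("RNA", "DNA"), l_ss = NULL, l_ds = NULL,
                        init_slope_a = NULL) {
  kind <- match.arg(kind)
  g <- switch(kind,
    RNA = list(kind = "RNA", l_ss = 6,    l_ds = 2.8, d = 20, z_c = 1,
               init_slope_a = -0.45324),
    DNA = list(kind = "DNA", l_ss = 6.76, l_ds = 3.4, d = 20, z_c = 1,
               init_slope_a = -0.58389))
  if (!is.null(l_ss)) g$l_ss <- l_ss
  if (!is.null(l_ds)) g$l_ds <- l_ds
  if (!is.null(init_slope_a)) g$init_slope_a <- init_slope_a
  if (!(g$l_ss > g$l_ds) || g$l_ds <= 0 || g$d <= 0) {
    stop("geometry requires l_ss > l_ds > 0 and d > 0", call. = FALSE)
  }
  structure(g, class = "na_geometry")
}

#' @export
print.na_geometry <- function(x, ...) {
  cat(sprintf("%s geometry: l_ss = %g A, l_ds = %g A, d = %g A, z_c = %d, init slope a = %g kcal/mol\n",
              x$kind, x$l_ss, x$l_ds, x$d, x$z_c, x$init_slope_a))
  invisible(x)
}

as_geometry <- function(geom) {
  if (inherits(geom, "na_geometry")) return(geom)
  if (is.character(geom) && length(geom) == 1L) return(na_geometry(geom))
  stop("geom must be an na_geometry object or \"RNA\"/\"DNA\"", call. = FALSE)
}

#' Manning charge densities for single and double strands
#'
#' The effective line-charge density is capped by counter-ion condensation:
#' `tau = min(1/l, 1/(l_B z_c))` with `l` the bare charge spacing.  With the
#' temperature-dependent permittivity the Bjerrum length exceeds both `l_ss`
#' and `l_ds` over liquid-water temperatures, so both densities reduce to
#' `1/l_B` and vary smoothly with T.
#'
#' @inheritParams relative_permittivity
#' @param geom An [na_geometry()] object (or `"RNA"`/`"DNA"`).
#' @return Charge density in 1/Angstrom.
#' @export
tau_ss <- function(temperature, geom = na_geometry("RNA")) {
  geom <- as_geometry(geom)
  pmin(1 / geom$l_ss, 1 / (bjerrum_length(temperature) * geom$z_c))
}

#' @rdname tau_ss
#' @export
tau_ds <- function(temperature, geom = na_geometry("RNA")) {
  geom <- as_geometry(geom)
  pmin(1 / geom$l_ds, 1 / (bjerrum_length(temperature) * geom$z_c))
}

#' Celsius to Kelvin
#'
#' @param celsius Temperature in degrees Celsius.
#' @return Temperature in Kelvin.
#' @export
celsius_to_kelvin <- function(celsius) celsius + 273.15
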