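## Two-state dimerization equilibrium, melting temperature, van 't Hoff
## regression, self-complementarity.

#' Dimerization equilibrium constant from ensemble free energies
#'
#' For the reaction 2A = AA, `[AA]/[A]^2 = exp((2 G_A - G_AA) / RT)` with
#' `G_A`, `G_AA` the ensemble free energies of monomer and dimer.
#'
#' @param G_A,G_AA Free energies, kcal/mol.
#' @param temperature Temperature in Kelvin (> 0).
#' @param log Return the natural log of the ratio instead (overflow-safe).
#' @return Equilibrium ratio (L/mol scale), or its log.
#' @examples
#' equilibrium_ratio(0, -1.42, 310.15)
#' @export
equilibrium_ratio <- function(G_A, G_AA, temperature, log = FALSE) {
  stopifnot(temperature > 0)
  R <- physical_constants()$gas_constant_kcal
  lr <- (2 * G_A - G_AA) / (R * temperature)
  if (log) lr else exp(lr)
}

#' Two-state melting temperature by bisection
#'
#' The melting temperature is defined as the temperature at which half of
#' the strands are dimerized, which gives the fixed-point condition
#' `T_m = (2 G_A(T_m) - G_AA(T_m)) / (-R ln c)` for total strand
#' concentration `c`.  Solved by bisection of
#' `f(T) = T (-R ln c) - (2 G_A(T) - G_AA(T))` on `bracket` to within
#' `tol` Kelvin; errors (rather than returning NaN) if `f` does not change
#' sign on the bracket or the provider returns non-finite energies.
#'
#' @param provider Function of temperature (K) returning a numeric vector
#'   `c(G_A, G_AA)` in kcal/mol.
#' @param c Total strand concentration, mol/L, in (0, 1).
#' @param bracket Search interval in Kelvin.
#' @param tol Temperature tolerance in Kelvin.
#' @return Melting temperature in Kelvin.
#' @examples
#' # temperature-independent two-state duplex: dH = -60, dS = -0.16
#' prov <- function(T) c(0, -60 - T * -0.16)
#' melting_temperature(prov, 1e-5)          # = dH / (dS + R ln c)
#' @export
melting_temperature <- function(provider, c, bracket = c(273.15, 423.15),
                                tol = 1e-3) {
  if (!is.function(provider)) stop("provider must be a function", call. = FALSE)
  if (!(c > 0 && c < 1)) stop("strand concentration must be in (0, 1) mol/L",
                              call. = FALSE)
  R <- physical_constants()$gas_constant_kcal
  f <- function(T) {
    g <- provider(T)
    if (length(g) != 2 || any(!is.finite(g))) {
      stop("provider must return two finite free energies", call. = FALSE)
    }
    T * (-R * log(c)) - (2 * g[1] - g[2])
  }
  lo <- bracket[1]; hi <- bracket[2]
  flo <- f(lo); fhi <- f(hi)
  if (sign(flo) == sign(fhi)) {
    stop("no sign change on the bracket: melting temperature not bracketed",
         call. = FALSE)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fmid <- f(mid)
    if (sign(fmid) == sign(flo)) {
      lo <- mid; flo <- fmid
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

#' Closed-form two-state melting temperature
#'
#' For temperature-independent `dH`, `dS` (monomer free energy zero) the
#' fixed point has the closed form `T_m = dH / (dS + R ln c)`.
#'
#' @param dH Enthalpy, kcal/mol.
#' @param dS Entropy, kcal/(mol K).
#' @param c Total strand concentration, mol/L.
#' @return Melting temperature in Kelvin.
#' @export
two_state_tm <- function(dH, dS, c) {
  R <- physical_constants()$gas_constant_kcal
  dH / (dS + R * log(c))
}

#' Van 't Hoff regression of melting points
#'
#' Fits `1/T_m = (R / dH) ln c + dS / dH` by ordinary least squares and
#' inverts slope and intercept to `(dH, dS)`.  Standard errors are
#' propagated from the regression coefficients (delta method).
#'
#' @param points Data frame with columns `c` (strand concentration, mol/L)
#'   and `Tm` (Kelvin); at least two distinct concentrations.
#' @return List with `dH` (kcal/mol), `dS` (kcal/(mol K)), `se_dH`, `se_dS`,
#'   and the underlying `fit`.
#' @examples
#' pts <- make_melting_fixtures(1, dH = -60, dS = -0.16,
#'                              c_grid = 10^seq(-6, -4, length.out = 6))
#' vant_hoff_fit(pts)[c("dH", "dS")]
#' @export
vant_hoff_fit <- function(points) {
  if (!all(c("c", "Tm") %in% names(points))) {
    stop("points must have columns 'c' and 'Tm'", call. = FALSE)
  }
  if (length(unique(points$c)) < 2) {
    stop("need at least two distinct strand concentrations", call. = FALSE)
  }
  stopifnot(all(points$c > 0), all(points$Tm > 0))
  R <- physical_constants()$gas_constant_kcal
  inv_tm <- 1 / points$Tm
  ln_c <- log(points$c)
  fit <- stats::lm(inv_tm ~ ln_c)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (slope == 0) stop("zero slope: enthalpy not identifiable", call. = FALSE)
  dH <- R / slope
  dS <- intercept * dH
  ## vcov on a numerically perfect fit triggers a harmless summary warning
  V <- suppressWarnings(stats::vcov(fit))
  se_slope <- sqrt(V[2, 2])
  se_dH <- abs(R / slope^2) * se_slope
  ## dS = R b0 / b1: gradient (R/b1, -R b0/b1^2)
  grad <- c(R / slope, -R * intercept / slope^2)
  se_dS <- sqrt(drop(t(grad) %*% V[c(1, 2), c(1, 2)] %*% grad))
  list(dH = dH, dS = dS, se_dH = se_dH, se_dS = se_dS, fit = fit)
}

RNA_COMPLEMENT <- c(A = "U", U = "A", G = "C", C = "G")
DNA_COMPLEMENT <- c(A = "T", T = "A", G = "C", C = "G")

#' Self-complementarity test and symmetry correction
#'
#' A strand identical to its reverse complement dimerizes with itself; the
#' two-state free energy then carries a symmetry correction of `RT ln 2`.
#' Complement rules are strict Watson-Crick (G.U wobbles do not count).
#'
#' @param sequence Nucleotide sequence (RNA letters AUGC, or ATGC for DNA).
#' @param kind `"RNA"` or `"DNA"`.
#' @return Logical.
#' @examples
#' is_self_complementary("AUGCAU")   # TRUE
#' is_self_complementary("AAAA")     # FALSE
#' @export
is_self_complementary <- function(sequence, kind = c("RNA", "DNA")) {
  kind <- match.arg(kind)
  comp <- if (kind == "RNA") RNA_COMPLEMENT else DNA_COMPLEMENT
  s <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  if (!all(s %in% names(comp))) {
    stop(sprintf("sequence contains non-%s letters", kind), call. = FALSE)
  }
  rc <- rev(unname(comp[s]))
  identical(paste(s, collapse = ""), paste(rc, collapse = ""))
}

#' @rdname is_self_complementary
#' @param temperature Temperature in Kelvin (> 0).
#' @return `self_complementary_correction`: `R T ln 2` in kcal/mol.
#' @export
self_complementary_correction <- function(temperature) {
  stopifnot(temperature > 0)
  physical_constants()$gas_constant_kcal * temperature * log(2)
}

#' Read and write melting-point tables
#'
#' TSV with columns `c` (mol/L) and `Tm` (Kelvin).
#'
#' @param path File path.
#' @return `read_melting_table`: data frame with columns `c`, `Tm`.
#' @export
read_melting_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("c", "Tm") %in% names(df))) {
    stop("melting table must have columns 'c' and 'Tm'", call. = FALSE)
  }
  df
}

#' @rdname read_melting_table
#' @param points Data frame with columns `c` and `Tm`.
#' @export
write_melting_table <- function(points, path) {
  utils::write.table(points[, c("c", "Tm")], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
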