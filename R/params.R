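## Nearest-neighbor parameter sets and the salt-corrected parameter update.
##
## The update is purely additive and context-independent: every stack key is
## shifted by the same g_p, hairpin/interior length entries by the loop
## correction at their bond count, the multiloop affine coefficients by the
## linear-fit coefficients, and the duplex initiation by g_init.  Dangling
## ends and coaxial stacking pass through untouched.

#' Construct a nearest-neighbor parameter set
#'
#' A minimal container for the parameters that a salt correction touches.
#' Stack keys are opaque: the electrostatic shift is sequence-independent,
#' so any naming convention works.  Length-indexed arrays carry the number
#' of unpaired nucleotides `m` as names (hairpins start at m = 3).
#'
#' @param stacks Named numeric vector of stacking free energies, kcal/mol.
#' @param hairpin Named numeric vector of hairpin-loop energies by m (>= 3).
#' @param interior Named numeric vector of interior-loop energies by m (>= 1).
#' @param ml_closing,ml_branch,ml_unpaired Multiloop affine coefficients
#'   alpha, beta, gamma in `E_ml = alpha + beta q + gamma m`, kcal/mol.
#' @param duplex_init Duplex initiation energy, kcal/mol.
#' @param passthrough Named numeric vector of terms (dangles, coaxial
#'   stacks, ...) that salt correction leaves untouched.
#' @return List of class `nn_params`.
#' @export
nn_params <- function(stacks, hairpin, interior, ml_closing, ml_branch,
                      ml_unpaired, duplex_init, passthrough = numeric(0)) {
  for (v in list(stacks, hairpin, interior)) {
    if (length(v) > 0 && is.null(names(v))) {
      stop("stacks, hairpin and interior must be named vectors", call. = FALSE)
    }
  }
  m_h <- as.integer(names(hairpin))
  if (length(m_h) && (any(is.na(m_h)) || any(m_h < 3))) {
    stop("hairpin entries must be named by m >= 3", call. = FALSE)
  }
  m_i <- as.integer(names(interior))
  if (length(m_i) && (any(is.na(m_i)) || any(m_i < 1))) {
    stop("interior entries must be named by m >= 1", call. = FALSE)
  }
  structure(list(
    stacks = stacks, hairpin = hairpin, interior = interior,
    ml_closing = ml_closing, ml_branch = ml_branch,
    ml_unpaired = ml_unpaired, duplex_init = duplex_init,
    passthrough = passthrough
  ), class = "nn_params")
}

#' @export
print.nn_params <- function(x, ...) {
  cat(sprintf("Nearest-neighbor parameter set: %d stacks, hairpin m in [%s], interior m in [%s]\n",
              length(x$stacks),
              paste(range(as.integer(names(x$hairpin))), collapse = ", "),
              paste(range(as.integer(names(x$interior))), collapse = ", ")))
  cat(sprintf("  multiloop: alpha = %g, beta = %g, gamma = %g kcal/mol\n",
              x$ml_closing, x$ml_branch, x$ml_unpaired))
  cat(sprintf("  duplex init = %g kcal/mol; %d pass-through terms\n",
              x$duplex_init, length(x$passthrough)))
  invisible(x)
}

#' Deterministic toy nearest-neighbor parameter fixture
#'
#' A reproducible, physically plausible stand-in parameter set (synthetic;
#' not a published table): stacking energies around -3..-1 kcal/mol,
#' positive loop penalties growing slowly with length, standard-looking
#' multiloop and initiation terms, and a few pass-through dangle entries.
#'
#' @param seed Integer seed; the same seed always yields the same set.
#' @return An [nn_params()] object.
#' @export
toy_param_fixture <- function(seed = 1L) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pairs <- c("CG", "GC", "AU", "UA", "GU", "UG")
  keys <- as.vector(outer(pairs, pairs, paste, sep = "/"))
  stacks <- stats::setNames(round(stats::runif(length(keys), -3, -1), 2), keys)
  hairpin <- stats::setNames(round(4 + 1.75 * log(3:30 / 3) +
                                     stats::runif(28, 0, 0.5), 2), 3:30)
  interior <- stats::setNames(round(1.5 + 1.75 * log(1:29) +
                                      stats::runif(29, 0, 0.5), 2), 1:29)
  dangles <- stats::setNames(round(stats::runif(4, -0.5, -0.1), 2),
                             paste0("dangle5_", c("A", "C", "G", "U")))
  nn_params(
    stacks = stacks, hairpin = hairpin, interior = interior,
    ml_closing = 3.4, ml_branch = 0.4, ml_unpaired = 0.0, duplex_init = 4.09,
    passthrough = c(dangles, coax_flush = -2.1)
  )
}

#' Apply salt corrections to a nearest-neighbor parameter set
#'
#' Shifts every parameter by its salt correction at `(rho, temperature)`:
#' stacks by `g_p`; hairpin entries of length m by `g_u(m+1)` and interior
#' entries by `g_u(m+2)` (their backbone bond counts); the multiloop
#' coefficients by `(a0 + a1, a1, a1)` from the linear fit; the duplex
#' initiation by `g_init`.  Pass-through terms are returned unchanged.
#' Corrections are absolute relative to `rho0`, never cumulative: applying
#' at rho1 and then re-applying the *uncorrected* set at rho2 equals a
#' direct application at rho2.
#'
#' @param params An [nn_params()] object.
#' @inheritParams salt_correction_set
#' @return A corrected [nn_params()] object.
#' @examples
#' p <- toy_param_fixture(1)
#' p37 <- apply_salt_corrections(p, rho = 0.1)
#' p37$stacks[1] - p$stacks[1]  # = stack_salt_correction(0.1, 310.15)
#' @export
apply_salt_corrections <- function(params, rho, temperature = 310.15,
                                   geom = na_geometry("RNA"),
                                   fit_range = c(6, 24),
                                   rho0 = standard_salt(),
                                   init = "model",
                                   phi = c("approx", "exact")) {
  stopifnot(inherits(params, "nn_params"))
  geom <- as_geometry(geom)
  phi <- match.arg(phi)
  out <- params
  g_p <- stack_salt_correction(rho, temperature, geom, rho0)
  out$stacks <- params$stacks + g_p
  if (length(params$hairpin)) {
    m <- as.integer(names(params$hairpin))
    out$hairpin <- params$hairpin +
      loop_salt_correction(m + 1L, rho, temperature, geom, rho0, phi)
  }
  if (length(params$interior)) {
    m <- as.integer(names(params$interior))
    out$interior <- params$interior +
      loop_salt_correction(m + 2L, rho, temperature, geom, rho0, phi)
  }
  ml <- multiloop_fit(rho, temperature, geom, fit_range[1], fit_range[2],
                      rho0, phi)
  out$ml_closing  <- params$ml_closing + ml$a0 + ml$a1
  out$ml_branch   <- params$ml_branch + ml$a1
  out$ml_unpaired <- params$ml_unpaired + ml$a1
  g_init <-
    if (identical(init, "off")) 0
    else if (is.numeric(init)) init
    else duplex_init_correction(rho, geom, rho0)
  out$duplex_init <- params$duplex_init + g_init
  out
}

#' Multiloop energy from a parameter set
#'
#' `E_ml = alpha + beta q + gamma m` for a multiloop with `q` enclosed
#' branches and `m` unpaired bases.
#'
#' @param params An [nn_params()] object.
#' @param m Unpaired bases in the multiloop.
#' @param q Enclosed branches.
#' @return Energy in kcal/mol.
#' @export
multiloop_energy <- function(params, m, q) {
  stopifnot(inherits(params, "nn_params"))
  params$ml_closing + params$ml_branch * q + params$ml_unpaired * m
}

## ---------------------------------------------------------------------------
## TSV dialect: '#' comments, blank lines ignored, a section is opened by a
## bare keyword line (STACK, HAIRPIN_LEN, INTERIOR_LEN, MULTILOOP, INIT,
## PASSTHROUGH), followed by "key<TAB>value" rows.

PARAM_SECTIONS <- c("STACK", "HAIRPIN_LEN", "INTERIOR_LEN", "MULTILOOP",
                    "INIT", "PASSTHROUGH")

#' Read a nearest-neighbor parameter table (TSV dialect)
#'
#' The dialect is UTF-8, tab-separated, `#`-comments, with sections
#' `STACK`, `HAIRPIN_LEN`, `INTERIOR_LEN`, `MULTILOOP` (keys `alpha`,
#' `beta`, `gamma`), `INIT` (key `init`) and `PASSTHROUGH`.  Parse errors
#' report the offending line number.  `read_param_table` and
#' [write_param_table()] are mutually inverse on valid tables.
#'
#' @param path Path to a parameter TSV file.
#' @return An [nn_params()] object.
#' @export
read_param_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  section <- NA_character_
  acc <- list(STACK = c(), HAIRPIN_LEN = c(), INTERIOR_LEN = c(),
              MULTILOOP = c(), INIT = c(), PASSTHROUGH = c())
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (ln == "") next
    if (!grepl("\t", ln)) {
      if (!ln %in% PARAM_SECTIONS) {
        stop(sprintf("line %d: unknown section '%s'", i, ln), call. = FALSE)
      }
      section <- ln
      next
    }
    if (is.na(section)) {
      stop(sprintf("line %d: data row before any section header", i),
           call. = FALSE)
    }
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2) {
      stop(sprintf("line %d: expected 'key<TAB>value'", i), call. = FALSE)
    }
    key <- parts[1]
    val <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(val)) {
      stop(sprintf("line %d: non-numeric value '%s'", i, parts[2]),
           call. = FALSE)
    }
    if (key %in% names(acc[[section]])) {
      stop(sprintf("line %d: duplicate key '%s' in section %s", i, key,
                   section), call. = FALSE)
    }
    acc[[section]] <- c(acc[[section]], stats::setNames(val, key))
  }
  missing_ml <- setdiff(c("alpha", "beta", "gamma"), names(acc$MULTILOOP))
  if (length(missing_ml)) {
    stop(sprintf("MULTILOOP section missing keys: %s",
                 paste(missing_ml, collapse = ", ")), call. = FALSE)
  }
  if (!"init" %in% names(acc$INIT)) {
    stop("INIT section missing key 'init'", call. = FALSE)
  }
  nn_params(
    stacks = acc$STACK, hairpin = acc$HAIRPIN_LEN,
    interior = acc$INTERIOR_LEN,
    ml_closing = unname(acc$MULTILOOP[["alpha"]]),
    ml_branch = unname(acc$MULTILOOP[["beta"]]),
    ml_unpaired = unname(acc$MULTILOOP[["gamma"]]),
    duplex_init = unname(acc$INIT[["init"]]),
    passthrough = acc$PASSTHROUGH
  )
}

#' Write a nearest-neighbor parameter table (TSV dialect)
#'
#' @param params An [nn_params()] object.
#' @param path Output file path.
#' @param digits Serialized precision (significant digits).
#' @return `path`, invisibly.
#' @rdname read_param_table
#' @export
write_param_table <- function(params, path, digits = 10) {
  stopifnot(inherits(params, "nn_params"))
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  rows <- function(v) paste0(names(v), "\t", fmt(unname(v)))
  out <- c(
    "# nearest-neighbor parameter table (kcal/mol)",
    "STACK", rows(params$stacks),
    "HAIRPIN_LEN", rows(params$hairpin),
    "INTERIOR_LEN", rows(params$interior),
    "MULTILOOP", rows(c(alpha = params$ml_closing, beta = params$ml_branch,
                        gamma = params$ml_unpaired)),
    "INIT", rows(c(init = params$duplex_init)),
    "PASSTHROUGH", rows(params$passthrough)
  )
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}
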