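## Dot-bracket parsing, loop decomposition and structure-level salt
## correction.
##
## Loop sizes are counted in backbone bonds: a loop with m unpaired
## nucleotides and q enclosed branches has L = m + q + 1 bonds (hairpin
## q = 0 gives L = m + 1, interior q = 1 gives L = m + 2).  An interior
## "loop" with m = 0 is a stacking interface, not a loop.

#' Parse a secondary structure in dot-bracket notation
#'
#' Accepts `(`, `)`, `.`, and a single `&` separating the two strands of a
#' duplex.  If a sequence is supplied it must match in length (with `&` at
#' the same position, or absent).
#'
#' @param db Dot-bracket string.
#' @param sequence Optional nucleotide sequence.
#' @return List of class `pair_table` with `length` (nucleotides), `pairs`
#'   (1-based partner index per position, 0 if unpaired), `strand_break`
#'   (position of the last nucleotide of strand 1, or `NA` for a single
#'   strand) and `sequence` (possibly `NA`).
#' @examples
#' parse_dot_bracket("((...))")
#' parse_dot_bracket("((((&))))")    # two-strand duplex
#' @export
parse_dot_bracket <- function(db, sequence = NULL) {
  stopifnot(is.character(db), length(db) == 1L)
  chars <- strsplit(db, "", fixed = TRUE)[[1]]
  amp <- which(chars == "&")
  if (length(amp) > 1L) {
    stop("at most one '&' strand separator is supported", call. = FALSE)
  }
  strand_break <- if (length(amp)) amp - 1L else NA_integer_
  chars <- chars[chars != "&"]
  n <- length(chars)
  if (!is.na(strand_break) && (strand_break < 1L || strand_break >= n)) {
    stop("'&' must separate two non-empty strands", call. = FALSE)
  }
  bad <- which(!chars %in% c("(", ")", "."))
  if (length(bad)) {
    stop(sprintf("invalid character '%s' at position %d", chars[bad[1]],
                 bad[1]), call. = FALSE)
  }
  pairs <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack)) {
        stop(sprintf("unmatched ')' at position %d", i), call. = FALSE)
      }
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs[i] <- j
      pairs[j] <- i
    }
  }
  if (length(stack)) {
    stop(sprintf("unmatched '(' at position %d", stack[length(stack)]),
         call. = FALSE)
  }
  seq_chars <- NA_character_
  if (!is.null(sequence)) {
    s <- gsub("&", "", sequence, fixed = TRUE)
    if (nchar(s) != n) {
      stop(sprintf("sequence length (%d) does not match structure length (%d)",
                   nchar(s), n), call. = FALSE)
    }
    seq_chars <- toupper(s)
  }
  structure(list(length = n, pairs = pairs, strand_break = strand_break,
                 sequence = seq_chars), class = "pair_table")
}

#' @export
print.pair_table <- function(x, ...) {
  n_bp <- sum(x$pairs > 0) / 2
  cat(sprintf("Pair table: %d nt, %d base pairs%s\n", x$length, n_bp,
              if (!is.na(x$strand_break))
                sprintf(", strand break after position %d", x$strand_break)
              else ""))
  invisible(x)
}

## TRUE if the backbone between loop positions a < b (consecutive around a
## loop) crosses the strand nick.
crosses_nick <- function(a, b, brk) !is.na(brk) && a <= brk && b > brk

#' Decompose a structure into stacks and loop records
#'
#' Walks every closing pair of a [parse_dot_bracket()] table and classifies
#' the enclosed face: stacking interface (interior face with m = 0),
#' hairpin, interior loop, or multiloop.  Exterior (unpaired, outside all
#' pairs) bases are counted but carry no salt term.  A face containing the
#' strand nick of a duplex is exterior-like and is skipped, so a fully
#' helical duplex of l pairs decomposes into l - 1 stacks and no loops.
#' Lone pairs contribute no stacking interface.
#'
#' @param pt A `pair_table`.
#' @return List of class `loop_decomposition` with `stacks` (count),
#'   `loops` (data frame: kind, m, q, L, closing_i, closing_j),
#'   `exterior_unpaired` (count) and `strand_count`.
#' @examples
#' decompose_structure(parse_dot_bracket("((((....))))"))
#' @export
decompose_structure <- function(pt) {
  stopifnot(inherits(pt, "pair_table"))
  pairs <- pt$pairs
  brk <- pt$strand_break
  n <- pt$length
  stacks <- 0L
  loops <- list()
  opens <- which(pairs > seq_len(n))  # i of each pair (i, j), i < j
  for (i in opens) {
    j <- pairs[i]
    ## walk the face enclosed by (i, j)
    m <- 0L
    branches <- list()
    nicked <- FALSE
    k <- i
    while (TRUE) {
      nxt <- k + 1L
      if (crosses_nick(k, nxt, brk)) nicked <- TRUE
      if (nxt >= j) break
      if (pairs[nxt] == 0L) {
        m <- m + 1L
        k <- nxt
      } else {
        branches[[length(branches) + 1L]] <- c(nxt, pairs[nxt])
        k <- pairs[nxt]
      }
    }
    q <- length(branches)
    if (nicked) next  # face contains the duplex nick: exterior-like
    if (q == 1L && m == 0L) {
      stacks <- stacks + 1L
      next
    }
    kind <- if (q == 0L) "hairpin" else if (q == 1L) "interior" else "multiloop"
    loops[[length(loops) + 1L]] <- data.frame(
      kind = kind, m = m, q = q, L = m + q + 1L,
      closing_i = i, closing_j = j, stringsAsFactors = FALSE)
  }
  loop_df <- if (length(loops)) do.call(rbind, loops) else
    data.frame(kind = character(0), m = integer(0), q = integer(0),
               L = integer(0), closing_i = integer(0), closing_j = integer(0),
               stringsAsFactors = FALSE)
  enclosed <- logical(n)
  for (i in opens) enclosed[(i + 1L):(pairs[i] - 1L)] <- TRUE
  exterior_unpaired <- sum(pairs == 0L & !enclosed)
  structure(list(
    stacks = stacks, loops = loop_df,
    exterior_unpaired = exterior_unpaired,
    strand_count = if (is.na(brk)) 1L else 2L
  ), class = "loop_decomposition")
}

#' @export
print.loop_decomposition <- function(x, ...) {
  cat(sprintf("Loop decomposition: %d stacking interfaces, %d loops, %d exterior unpaired, %d strand(s)\n",
              x$stacks, nrow(x$loops), x$exterior_unpaired, x$strand_count))
  if (nrow(x$loops)) print(x$loops, row.names = FALSE)
  invisible(x)
}

#' Salt correction of a whole secondary structure
#'
#' Sum of the per-stack correction over all stacking interfaces, the loop
#' correction `g_u(L)` over all hairpin and interior loops, the multiloop
#' term (exact `g_u(L)` or the linear `a0 + a1 L` depending on
#' `multiloop_mode`), and, for two-strand structures, the duplex-initiation
#' correction.  Exterior bases carry no salt term.  Identically zero at the
#' reference concentration.
#'
#' @param pt A `pair_table` (or dot-bracket string, parsed on the fly).
#' @inheritParams loop_salt_correction
#' @param multiloop_mode `"exact"` (default for evaluation) or `"linear"`
#'   (the folding-parameter route).
#' @param fit_range Multiloop fit range for `multiloop_mode = "linear"`.
#' @param include_init Include the duplex-initiation term for two-strand
#'   structures.
#' @param mismatch `"loop"` (default: a 1x1 mismatch in a helix is an
#'   interior loop with m = 2, L = 4) or `"stack"` (treat it as two extra
#'   stacking interfaces; the slightly-distorted-helix reading).
#' @return Correction in kcal/mol.
#' @examples
#' hp <- parse_dot_bracket("((((((((....))))))))")
#' structure_salt_correction(hp, 0.03, 310.15) -
#'   structure_salt_correction(hp, 1.02, 310.15)   # ~1.96 kcal/mol
#' @export
structure_salt_correction <- function(pt, rho, temperature = 310.15,
                                      geom = na_geometry("RNA"),
                                      rho0 = standard_salt(),
                                      multiloop_mode = c("exact", "linear"),
                                      fit_range = c(6, 24),
                                      include_init = TRUE,
                                      phi = c("approx", "exact"),
                                      mismatch = c("loop", "stack")) {
  if (is.character(pt)) pt <- parse_dot_bracket(pt)
  multiloop_mode <- match.arg(multiloop_mode)
  mismatch <- match.arg(mismatch)
  phi <- match.arg(phi)
  geom <- as_geometry(geom)
  dec <- decompose_structure(pt)
  loops <- dec$loops
  n_stacks <- dec$stacks
  if (mismatch == "stack" && nrow(loops)) {
    mm <- loops$kind == "interior" & loops$m == 2
    ## only 1x1 internal mismatches (one unpaired base on each strand)
    if (any(mm)) {
      is_1x1 <- vapply(which(mm), function(r) {
        i <- loops$closing_i[r]; j <- loops$closing_j[r]
        pt$pairs[i + 1L] == 0L && pt$pairs[j - 1L] == 0L
      }, logical(1))
      drop <- which(mm)[is_1x1]
      if (length(drop)) {
        n_stacks <- n_stacks + 2L * length(drop)
        loops <- loops[-drop, , drop = FALSE]
      }
    }
  }
  total <- n_stacks * stack_salt_correction(rho, temperature, geom, rho0)
  if (nrow(loops)) {
    ml <- loops$kind == "multiloop"
    plain <- loops$L[!ml]
    if (length(plain)) {
      total <- total + sum(loop_salt_correction(plain, rho, temperature,
                                                geom, rho0, phi))
    }
    if (any(ml)) {
      if (multiloop_mode == "exact") {
        total <- total + sum(loop_salt_correction(loops$L[ml], rho,
                                                  temperature, geom, rho0,
                                                  phi))
      } else {
        f <- multiloop_fit(rho, temperature, geom, fit_range[1],
                           fit_range[2], rho0, phi)
        total <- total + sum(f$a0 + f$a1 * loops$L[ml])
      }
    }
  }
  if (dec$strand_count == 2L && include_init) {
    total <- total + duplex_init_correction(rho, geom, rho0)
  }
  total
}

#' Salt correction of a perfect duplex
#'
#' For a fully helical duplex of `length_bp` base pairs the structure-level
#' correction collapses to `(l_w - 1) g_p + g_init`.
#'
#' @param length_bp Duplex length in base pairs (>= 2).
#' @inheritParams stack_salt_correction
#' @param include_init Include the duplex-initiation term.
#' @return Correction in kcal/mol.
#' @examples
#' duplex_salt_correction(8, 0.121, 310.15)
#' @export
duplex_salt_correction <- function(length_bp, rho, temperature = 310.15,
                                   geom = na_geometry("RNA"),
                                   rho0 = standard_salt(),
                                   include_init = TRUE) {
  if (length_bp < 2 || length_bp != round(length_bp)) {
    stop("duplex length must be an integer >= 2", call. = FALSE)
  }
  geom <- as_geometry(geom)
  (length_bp - 1) * stack_salt_correction(rho, temperature, geom, rho0) +
    if (include_init) duplex_init_correction(rho, geom, rho0) else 0
}

#' Per-term salt-correction report for a structure
#'
#' A tidy table of every stacking interface (pooled) and loop with its
#' individual correction, suitable for TSV output.
#'
#' @inheritParams structure_salt_correction
#' @return A data frame with columns `term`, `kind`, `m`, `q`, `L`,
#'   `kcal_mol`.
#' @export
structure_salt_report <- function(pt, rho, temperature = 310.15,
                                  geom = na_geometry("RNA"),
                                  rho0 = standard_salt(),
                                  include_init = TRUE,
                                  phi = c("approx", "exact")) {
  if (is.character(pt)) pt <- parse_dot_bracket(pt)
  phi <- match.arg(phi)
  geom <- as_geometry(geom)
  dec <- decompose_structure(pt)
  rows <- list()
  if (dec$stacks > 0) {
    rows[[1]] <- data.frame(
      term = "stacks", kind = "stack", m = NA, q = NA, L = NA,
      kcal_mol = dec$stacks * stack_salt_correction(rho, temperature, geom,
                                                    rho0),
      stringsAsFactors = FALSE)
  }
  if (nrow(dec$loops)) {
    l <- dec$loops
    rows[[length(rows) + 1L]] <- data.frame(
      term = sprintf("loop_%d_%d", l$closing_i, l$closing_j),
      kind = l$kind, m = l$m, q = l$q, L = l$L,
      kcal_mol = loop_salt_correction(l$L, rho, temperature, geom, rho0,
                                      phi),
      stringsAsFactors = FALSE)
  }
  if (dec$strand_count == 2L && include_init) {
    rows[[length(rows) + 1L]] <- data.frame(
      term = "duplex_init", kind = "init", m = NA, q = NA, L = NA,
      kcal_mol = duplex_init_correction(rho, geom, rho0),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(term = character(0), kind = character(0), m = integer(0),
               q = integer(0), L = integer(0), kcal_mol = numeric(0),
               stringsAsFactors = FALSE)
  out
}
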