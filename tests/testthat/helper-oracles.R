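## Shared helpers: independent oracles kept deliberately separate from the
## package implementation paths they check.

## Ordinary least squares by explicit normal equations (oracle for the
## QR-based fit inside multiloop_fit).
ols_normal_equations <- function(x, y) {
  X <- cbind(1, x)
  as.vector(solve(t(X) %*% X, t(X) %*% y))
}

## Perfect two-strand duplex of l base pairs in dot-bracket notation.
perfect_duplex_db <- function(l) {
  paste0(strrep("(", l), "&", strrep(")", l))
}

## Temperature grid spanning liquid water used by the flatness/zero checks.
T_GRID <- c(283.15, 310.15, 333.15, 363.15)
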