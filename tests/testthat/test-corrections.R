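# Loop, stack, duplex-initiation and multiloop-fit salt corrections.
# Frozen values come from a 40-digit arbitrary-precision evaluation of the
# full physical chain (permittivity -> Bjerrum -> Debye -> energy).

test_that("loop electrostatic energy reproduces the oracle chain", {
  expect_equal(loop_energy(5, 310.15, 0.03), 1.24292266216, tolerance = 1e-9)
  expect_equal(loop_energy(5, 310.15, 0.03, phi = "exact"), 1.24228482078,
               tolerance = 1e-9)
  expect_error(loop_energy(5, 310.15, 0), "concentration")
  expect_error(loop_energy(0, 310.15, 0.1), "positive integer")
})

test_that("loop energy grows with loop size and with decreasing salt", {
  # monotone in L while the screening argument y = kappa l_ss L stays below
  # the Phi peak; at 0.011 M that covers the whole tabulated range
  g <- loop_energy(1:31, 310.15, 0.011)
  expect_true(all(diff(g) > 0))
  expect_gt(loop_energy(10, 310.15, 0.1), loop_energy(5, 310.15, 0.1))
  rhos <- c(0.005, 0.02, 0.1, 0.5, 1.021, 2)
  for (L1 in c(1, 5, 15, 31)) {
    gr <- vapply(rhos, function(r) loop_energy(L1, 310.15, r), numeric(1))
    expect_true(all(diff(gr) < 0))
  }
})

test_that("loop energy approaches L times a constant in the low-salt limit", {
  # y and kappa are both ~ sqrt(rho), so the rho dependence cancels
  per_L <- function(rho) loop_energy(c(5, 10, 20), 310.15, rho) / c(5, 10, 20)
  spread <- function(rho) diff(range(per_L(rho))) / mean(per_L(rho))
  expect_lt(spread(1e-6), spread(1e-3))
  expect_lt(spread(1e-6), 0.02)
})

test_that("every correction vanishes identically at the reference concentration", {
  for (T in T_GRID) {
    expect_identical(loop_salt_correction(1:31, 1.021, T), rep(0, 31))
    expect_identical(stack_salt_correction(1.021, T), 0)
    f <- multiloop_fit(1.021, T)
    expect_identical(c(f$a0, f$a1), c(0, 0))
  }
  expect_identical(duplex_init_correction(1.021), 0)
})

test_that("stack energy and correction reproduce the oracle and diverge like -ln(rho)", {
  expect_equal(stack_energy(310.15, 0.03), 0.16225754165, tolerance = 1e-9)
  expect_equal(stack_energy(310.15, 0.03) - stack_energy(310.15, 1.02),
               0.161979089052, tolerance = 1e-9)
  # K0(z) ~ -ln z: correction / (-ln rho) converges (slowly, through the
  # -ln(z/2) - gamma tail) to a positive constant as rho -> 0
  r <- c(1e-4, 1e-5, 1e-6)
  ratio <- stack_salt_correction(r, 310.15) / (-log(r))
  expect_true(all(ratio > 0))
  expect_lt(abs(ratio[3] - ratio[2]), abs(ratio[2] - ratio[1]))
  expect_error(stack_energy(310.15, -1), "concentration")
  expect_error(stack_salt_correction(1e-9), "minimum")
})

test_that("duplex initiation correction is a log law with per-polymer slope", {
  expect_identical(duplex_init_correction(1.021), 0)
  expect_equal(duplex_init_correction(0.121), 0.9666463738, tolerance = 1e-9)
  expect_gt(duplex_init_correction(0.121, "DNA"),
            duplex_init_correction(0.121, "RNA"))
  expect_equal(duplex_init_correction(0.121, slope = -1),
               -log(0.121 / 1.021), tolerance = 1e-12)
  expect_identical(duplex_init_correction(0.121, enabled = FALSE), 0)
  expect_identical(duplex_init_correction(0.5, slope = 0), 0)
  # temperature never enters
  expect_error(duplex_init_correction(0), "concentration")
})

test_that("multiloop linear fit equals a normal-equations oracle and stays within 1 kcal/mol", {
  for (rho in c(0.011, 0.051, 0.521)) {
    f <- multiloop_fit(rho, 310.15)
    L <- 6:24
    g <- loop_salt_correction(L, rho, 310.15)
    ab <- ols_normal_equations(L, g)
    expect_equal(c(f$a0, f$a1), ab, tolerance = 1e-10)
    expect_lte(f$max_residual, 1)
  }
  expect_error(multiloop_fit(0.1, 310.15, L1 = 6, L2 = 6), "at least 2")
  expect_error(multiloop_fit(0.1, 310.15, L1 = 0, L2 = 10), "positive integers")
})

test_that("corrections are nearly flat over the usual temperature range", {
  Tg <- seq(283.15, 363.15, by = 5)
  for (rho in c(0.021, 0.121)) {
    gl <- vapply(Tg, function(T) loop_salt_correction(10, rho, T), numeric(1))
    gs <- vapply(Tg, function(T) stack_salt_correction(rho, T), numeric(1))
    expect_lt(diff(range(gl)), loop_salt_correction(10, rho, 310.15))
    expect_lt(diff(range(gs)), stack_salt_correction(rho, 310.15))
  }
})

test_that("salt_correction_set bundles consistent terms and serializes", {
  sc <- salt_correction_set(0.121, 310.15)
  expect_s3_class(sc, "salt_correction_set")
  expect_length(sc$g_loop, 31)
  expect_equal(sc$g_stack, stack_salt_correction(0.121, 310.15))
  expect_equal(unname(sc$g_loop[5]), loop_salt_correction(5, 0.121, 310.15))
  expect_equal(sc$g_init, duplex_init_correction(0.121))
  sc0 <- salt_correction_set(1.021, 310.15)
  expect_true(all(unlist(sc0[c("g_stack", "g_loop", "a0", "a1", "g_init")]) == 0))
  expect_identical(salt_correction_set(0.2, init = "off")$g_init, 0)
  expect_identical(salt_correction_set(0.2, init = 1.5)$g_init, 1.5)
  tsv <- tempfile(fileext = ".tsv")
  write_salt_corrections(sc, tsv)
  df <- read.delim(tsv)
  expect_equal(df$kcal_mol[df$term == "g_stack"], sc$g_stack,
               tolerance = 1e-6)
})
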