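# Dot-bracket parsing, loop decomposition, and structure-level corrections.

test_that("dot-bracket parsing builds a valid involution and reports errors by position", {
  pt <- parse_dot_bracket("((...))")
  expect_equal(pt$pairs, c(7, 6, 0, 0, 0, 2, 1))
  idx <- which(pt$pairs > 0)
  expect_true(all(pt$pairs[pt$pairs[idx]] == idx))
  expect_error(parse_dot_bracket("((..)"), "unmatched '\\(' at position 1")
  expect_error(parse_dot_bracket("(..))"), "unmatched '\\)' at position 5")
  expect_error(parse_dot_bracket("((x))"), "invalid character 'x' at position 3")
  dup <- parse_dot_bracket("((((&))))")
  expect_equal(sum(dup$pairs > 0) / 2, 4)
  expect_equal(dup$strand_break, 4L)
  expect_error(parse_dot_bracket("(&)&"), "at most one")
  expect_error(parse_dot_bracket("((..))", sequence = "AAA"),
               "does not match")
  expect_equal(parse_dot_bracket("((..))", sequence = "gcaagc")$sequence,
               "GCAAGC")
})

test_that("decomposition follows the backbone-bond conventions", {
  d <- decompose_structure(parse_dot_bracket("((((....))))"))
  expect_equal(d$stacks, 3L)
  expect_equal(nrow(d$loops), 1L)
  expect_equal(d$loops$kind, "hairpin")
  expect_equal(d$loops$m, 4L)
  expect_equal(d$loops$L, 5L)

  # 8-bp helix interrupted by a 1-nt bulge, closing a 4-nt hairpin loop
  d2 <- decompose_structure(parse_dot_bracket("(((((.(((....))))))))"))
  expect_equal(d2$stacks, 6L)
  expect_equal(sort(d2$loops$kind), c("hairpin", "interior"))
  expect_equal(d2$loops$L[d2$loops$kind == "interior"], 3L)
  expect_equal(d2$loops$m[d2$loops$kind == "interior"], 1L)
  expect_equal(d2$loops$L[d2$loops$kind == "hairpin"], 5L)

  # junction of 3 enclosed helices: m = 6 unpaired, q = 3, L = 10
  h <- "((....))"
  ml <- paste0("((.", h, ".", h, ".", h, "...))")
  d3 <- decompose_structure(parse_dot_bracket(ml))
  mlrec <- d3$loops[d3$loops$kind == "multiloop", ]
  expect_equal(nrow(mlrec), 1L)
  expect_equal(c(mlrec$m, mlrec$q, mlrec$L), c(6L, 3L, 10L))
  expect_equal(d3$stacks, 4L)  # 1 in the outer helix + 1 in each arm
})

test_that("lone pairs contribute no stacking interface", {
  d <- decompose_structure(parse_dot_bracket(".(.....)."))
  expect_equal(d$stacks, 0L)
  expect_equal(d$loops$kind, "hairpin")
})

test_that("a fully helical duplex decomposes into l - 1 stacks and no loops", {
  for (l in c(2, 4, 8)) {
    d <- decompose_structure(parse_dot_bracket(perfect_duplex_db(l)))
    expect_equal(d$stacks, l - 1L)
    expect_equal(nrow(d$loops), 0L)
    expect_equal(d$strand_count, 2L)
  }
})

test_that("decomposition conserves every position on random structures", {
  dbs <- make_structure_fixtures(7, 20, 70)
  for (db in dbs) {
    pt <- parse_dot_bracket(db)
    d <- decompose_structure(pt)
    paired <- sum(pt$pairs > 0)
    unpaired_in_loops <- sum(d$loops$m)
    expect_equal(paired + unpaired_in_loops + d$exterior_unpaired, pt$length)
  }
})

test_that("structure correction is zero at reference and additive over independent parts", {
  dbs <- make_structure_fixtures(21, 5, 50)
  for (db in dbs) {
    expect_equal(structure_salt_correction(db, 1.021, 310.15), 0)
  }
  a <- "((((....))))"
  b <- "(((((.(((....))))))))"
  expect_equal(structure_salt_correction(paste0(a, "..", b), 0.05),
               structure_salt_correction(a, 0.05) +
                 structure_salt_correction(b, 0.05),
               tolerance = 1e-12)
})

test_that("perfect duplexes match the compositional (l-1) g_p + g_init form", {
  for (l in c(2, 5, 8)) {
    for (inc in c(TRUE, FALSE)) {
      expect_equal(
        structure_salt_correction(perfect_duplex_db(l), 0.121, 310.15,
                                  include_init = inc),
        duplex_salt_correction(l, 0.121, 310.15, include_init = inc),
        tolerance = 1e-14)
    }
  }
  # an imperfect duplex (internal bulge) deviates from the closed form
  bulged <- "(((.(((&))))))"
  expect_false(isTRUE(all.equal(
    structure_salt_correction(bulged, 0.121, 310.15),
    duplex_salt_correction(6, 0.121, 310.15))))
  expect_error(duplex_salt_correction(1, 0.1), ">= 2")
})

test_that("exact and linear multiloop modes differ by at most the fit residual", {
  h <- "((....))"
  ml <- paste0("((.", h, ".", h, ".", h, "...))")  # multiloop L = 10
  for (rho in c(0.021, 0.121)) {
    f <- multiloop_fit(rho, 310.15)
    d <- abs(structure_salt_correction(ml, rho, multiloop_mode = "exact") -
               structure_salt_correction(ml, rho, multiloop_mode = "linear"))
    expect_lte(d, f$max_residual + 1e-9)
  }
})

test_that("1x1 mismatches switch between interior-loop and two-stack treatment", {
  mm <- "(((.(((....))).)))"   # one unpaired base on each strand, m = 2
  as_loop <- structure_salt_correction(mm, 0.05, mismatch = "loop")
  as_stack <- structure_salt_correction(mm, 0.05, mismatch = "stack")
  expect_equal(as_stack - as_loop,
               2 * stack_salt_correction(0.05, 310.15) -
                 loop_salt_correction(4, 0.05, 310.15),
               tolerance = 1e-12)
  # a bulge (unpaired on one strand only) is never reclassified
  blg <- "(((.(((....))))))"
  expect_equal(structure_salt_correction(blg, 0.05, mismatch = "stack"),
               structure_salt_correction(blg, 0.05, mismatch = "loop"),
               tolerance = 1e-14)
})

test_that("the per-term report sums to the total correction", {
  db <- "(((((.(((....))))))))"
  rep <- structure_salt_report(db, 0.03, 310.15)
  expect_equal(sum(rep$kcal_mol),
               structure_salt_correction(db, 0.03, 310.15),
               tolerance = 1e-12)
  dup <- perfect_duplex_db(6)
  rep2 <- structure_salt_report(dup, 0.121)
  expect_true("duplex_init" %in% rep2$term)
})
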