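# network where one haplotype has replicated members: AA x3 at 10 +/- spread,
# AT x3 at 12, TT x1
delta_fixture <- function(vals_AA = c(9, 10, 11), vals_AT = c(12, 12, 12)) {
  strings <- c(a1 = "AA", a2 = "AA", a3 = "AA", b1 = "AT", b2 = "AT",
               b3 = "AT", c1 = "TT")
  phen <- stats::setNames(c(vals_AA, vals_AT, 14), names(strings))
  build_network(collapse_haplotypes(strings, phen))
}

test_that("delta is the mean coefficient of variation of qualifying vertices", {
  net <- delta_fixture()
  est <- estimate_delta(net)
  expect_true(est$available)
  cv_AA <- stats::sd(c(9, 10, 11)) / 10
  expect_equal(unname(est$cvs), c(cv_AA, 0))
  expect_equal(est$delta, mean(c(cv_AA, 0)))
  expect_equal(est$n_contributing, 2L)
  expect_equal(est$fraction_contributing, 2 / 3)
  # identical members give CV 0 and delta 0
  est0 <- estimate_delta(delta_fixture(vals_AA = c(10, 10, 10)))
  expect_equal(est0$delta, 0)
})

test_that("delta is unavailable when no vertex has three members", {
  strings <- c(a = "AA", b = "AA", c = "AT", d = "AT")
  net <- build_network(collapse_haplotypes(strings, c(a = 1, b = 2, c = 3, d = 4)))
  est <- estimate_delta(net)
  expect_false(est$available)
  expect_true(is.na(est$delta))
  summ <- summarize_epistasis(net, est)
  expect_equal(summ$status, "delta_unavailable")
})

test_that("zero-mean vertices are excluded from delta with a warning", {
  net <- delta_fixture(vals_AA = c(-1, 0, 1))
  expect_warning(est <- estimate_delta(net), "zero mean")
  expect_equal(est$n_excluded_zero_mean, 1L)
  expect_equal(est$delta, 0)  # only the AT vertex contributes
})

test_that("identical-neighbor fraction counts edges within delta", {
  net <- net_from_strings(c("AA", "AT", "TT"), phen = c(1.0, 1.05, 2.0))
  expect_equal(fraction_identical_neighbors(net, 0.1), 0.5)
  expect_equal(fraction_identical_neighbors(net, 0), 0)
  expect_equal(fraction_identical_neighbors(net, 10), 1)
  iso <- net_from_strings(c("AA", "TT"), phen = c(0, 1))
  expect_warning(f <- fraction_identical_neighbors(iso, 1), "no edges")
  expect_true(is.na(f))
})

test_that("square orientation finds AB, its diagonal wild type, and skips ties", {
  cyc <- c("AA", "TA", "TT", "AT")
  sq <- orient_square(cyc, c(0, 1, 2, 1))
  expect_equal(sq$haplotypes[["AB"]], "TT")
  expect_equal(sq$haplotypes[["ab"]], "AA")   # diagonal partner gets 0
  expect_equal(sort(sq$positions), c(1L, 2L))
  expect_null(orient_square(cyc, c(2, 1, 2, 1)))  # tied maximum
  # Ab/aB relabeling leaves epsilon and class unchanged
  sq2 <- orient_square(cyc[c(1, 4, 3, 2)], c(0, 1, 2, 1))
  expect_equal(classify_square(sq, 0.1)$epsilon, classify_square(sq2, 0.1)$epsilon)
  expect_equal(classify_square(sq, 0.1)$class, classify_square(sq2, 0.1)$class)
})

test_that("classification reproduces the canonical truth table", {
  cases <- list(
    list(v = c(0, 1, 1, 2), delta = 0.1, eps = 0, class = "none"),
    list(v = c(0, 1, 1, 3), delta = 0.5, eps = 1, class = "magnitude"),
    list(v = c(0, -1, 1, 2), delta = 0.5, eps = 2, class = "simple_sign"),
    list(v = c(1, 0, 0, 2), delta = 0.5, eps = 3, class = "reciprocal_sign")
  )
  for (cs in cases) {
    v <- cs$v  # (V_ab, V_Ab, V_aB, V_AB); cycle order ab, Ab, AB, aB
    sq <- orient_square(c("aa", "Aa", "AA", "aA"), v[c(1, 2, 4, 3)])
    call <- classify_square(sq, cs$delta)
    expect_equal(call$class, cs$class, label = cs$class)
    expect_equal(call$epsilon, cs$eps, label = cs$class)
  }
})

test_that("classifier agrees with the coarse-sign-pattern oracle", {
  set.seed(404)
  n <- 4000
  for (i in seq_len(n)) {
    vals <- round(stats::rnorm(4, sd = 2), 3)
    if (sum(vals == max(vals)) > 1L) next
    sq <- orient_square(c("aa", "Aa", "AA", "aA"), vals)
    delta <- stats::runif(1, 0, diff(range(vals)))
    call <- classify_square(sq, delta)
    expected <- oracle_classify(sq$values[["V_ab"]], sq$values[["V_Ab"]],
                                sq$values[["V_aB"]], sq$values[["V_AB"]], delta)
    if (call$class != expected) {
      fail(sprintf("mismatch at i=%d: %s vs %s", i, call$class, expected))
      break
    }
  }
  succeed()
})

test_that("epsilon is invariant under constant shifts and exact additivity gives none", {
  set.seed(7)
  for (i in 1:50) {
    vals <- stats::rnorm(4)
    if (sum(vals == max(vals)) > 1L) next
    sq <- orient_square(c("aa", "Aa", "AA", "aA"), vals)
    sq_shift <- orient_square(c("aa", "Aa", "AA", "aA"), vals + 100)
    expect_equal(classify_square(sq, 0)$epsilon,
                 classify_square(sq_shift, 0)$epsilon)
  }
  # exactly additive square: none for every delta >= 0
  for (delta in c(0, 0.01, 1)) {
    sq <- orient_square(c("aa", "Aa", "AA", "aA"), c(0.5, 1.5, 3.0, 2.0))
    expect_equal(classify_square(sq, delta)$class, "none")
  }
})

test_that("network-level tallies, flags and skip records are correct", {
  # one reciprocal-sign square
  net <- net_from_strings(c("AA", "TA", "AT", "TT"), phen = c(1, 0, 0.5, 2))
  summ <- summarize_epistasis(net, 0.1)
  expect_equal(summ$status, "ok")
  expect_equal(unname(summ$counts), c(0L, 0L, 0L, 1L))
  expect_true(summ$all_epistatic)
  expect_equal(summ$epistatic_fraction, 1)
  # mixed composition: 2 squares in a 3-cube slab
  strings <- c("AAA", "TAA", "ATA", "TTA", "AAT", "TAT", "ATT", "TTT")
  vals <- c(0, 1, 1, 2, 1, 2, 2, 10)  # last square strongly epistatic
  net3 <- net_from_strings(strings, phen = vals)
  summ3 <- summarize_epistasis(net3, 0.05)
  expect_equal(summ3$n_classified, 6L)
  expect_equal(sum(summ3$counts), 6L)
  expect_equal(summ3$fractions[["none"]],
               summ3$counts[["none"]] / summ3$n_classified)
  # no squares -> not analyzable
  path_net <- net_from_strings(c("AA", "AT", "TT"), phen = 1:3)
  expect_equal(summarize_epistasis(path_net, 0)$status, "no_squares")
  # all squares additive: epistatic fraction 0, all_epistatic FALSE
  add <- net_from_strings(c("AA", "TA", "AT", "TT"), phen = c(0, 1, 1, 2))
  sa <- summarize_epistasis(add, 0.2)
  expect_equal(sa$epistatic_fraction, 0)
  expect_false(sa$all_epistatic)
  # tied maxima are skipped and tallied
  tied <- net_from_strings(c("AA", "TA", "AT", "TT"), phen = c(2, 1, 1, 2))
  st <- summarize_epistasis(tied, 0)
  expect_equal(st$status, "all_squares_tied")
  expect_equal(st$n_skipped_tied_max, 1L)
})

test_that("scale_delta rescales by the network phenotype magnitude", {
  net <- net_from_strings(c("AA", "AT"), phen = c(8, 12))
  expect_equal(scale_delta(0.05, net, "raw"), 0.05)
  expect_equal(scale_delta(0.05, net, "mean_phenotype"), 0.05 * 10)
})
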