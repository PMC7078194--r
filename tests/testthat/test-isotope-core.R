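test_that("formula parsing recovers element counts and rejects garbage", {
  gln <- parse_formula("C5H10N2O3")
  expect_equal(unclass(gln)[c("C", "H", "N", "O")], c(C = 5L, H = 10L, N = 2L, O = 3L))
  fum <- parse_formula("C4H4O4")
  expect_equal(unclass(fum)[c("C", "H", "O")], c(C = 4L, H = 4L, O = 4L))
  expect_equal(parse_formula("CH4")[["C"]], 1L)
  expect_error(parse_formula("C5Xe2"), "unknown element")
  expect_error(parse_formula("c5h10"), "malformed")
})

test_that("isotopologue masses match the brute-force per-atom sum", {
  reg <- metabolite_registry()
  for (i in seq_len(nrow(reg))) {
    f <- parse_formula(reg$formula[i])
    for (c0 in 0:f[["C"]]) {
      for (n0 in 0:f[["N"]]) {
        got <- isotopologue_mz(f, c0, n0)$neutral_mass
        expect_equal(got, oracle_mass(f, c0, n0), tolerance = 1e-6 / got)
      }
    }
  }
  # frozen reference values
  gln <- parse_formula("C5H10N2O3")
  expect_equal(isotopologue_mz(gln, 0, 0)$neutral_mass, 146.069142, tolerance = 1e-6)
  expect_equal(isotopologue_mz(gln, 5, 2)$neutral_mass, 153.079986, tolerance = 1e-6)
})

test_that("the 13C-15N single-substitution mass gap is constant at 0.0063199 Da", {
  for (fstr in c("C5H10N2O3", "C10H13N4O8P", "C9H13N2O9P")) {
    f <- parse_formula(fstr)
    gap <- isotopologue_mz(f, 1, 0)$neutral_mass - isotopologue_mz(f, 0, 1)$neutral_mass
    expect_equal(gap, 0.0063199, tolerance = 1e-7 / 0.0063199)
  }
})

test_that("m/z follows the protonation convention", {
  glu <- parse_formula("C5H9NO4")
  m <- isotopologue_mz(glu, 0, 0)$neutral_mass
  expect_equal(isotopologue_mz(glu, 0, 0, charge = -1)$mz, m - 1.00727646)
  expect_equal(isotopologue_mz(glu, 0, 0, charge = 1)$mz, m + 1.00727646)
  expect_equal(isotopologue_mz(glu, 0, 0, charge = -2)$mz, (m - 2 * 1.00727646) / 2)
  expect_error(isotopologue_mz(glu, 6, 0), "bounds")
})

test_that("separability reproduces the instrument formula on the glutamate pair", {
  glu <- parse_formula("C5H9NO4")
  a <- isotopologue_mz(glu, 1, 0, charge = -1)$mz
  b <- isotopologue_mz(glu, 0, 1, charge = -1)$mz
  s <- separability(a, b, resolution_model(70000, 200, 0.5, 1))
  required_direct <- mean(c(a, b)) / abs(a - b)
  instrument_direct <- 70000 * sqrt(200 / mean(c(a, b)))
  expect_equal(s$required_rp, required_direct)
  expect_equal(s$instrument_rp, instrument_direct)
  expect_true(s$resolved)
  expect_equal(s$required_rp, 23100, tolerance = 0.01)
  expect_error(separability(100, 100), "differ")
})

test_that("separability boundary uses >= at exactly one FWHM", {
  # construct a pair whose gap equals the FWHM at their mean m/z
  model <- resolution_model(10000, 200, 0, 1) # flat resolving power
  mz <- 200
  gap <- mz / 10000
  s <- separability(mz - gap / 2, mz + gap / 2, model)
  expect_true(s$resolved)
  # a slightly narrower gap needs more resolving power than available
  s2 <- separability(mz - gap / 2 * 0.99, mz + gap / 2 * 0.99, model)
  expect_false(s2$resolved)
  s3 <- separability(mz - gap / 2 * 1.01, mz + gap / 2 * 1.01, model)
  expect_true(s3$resolved)
})

test_that("grid enumeration has the right size, order and bounds checks", {
  gln <- parse_formula("C5H10N2O3")
  g <- enumerate_grid(gln, 5, 2)
  expect_equal(nrow(g), 18)
  expect_false(is.unsorted(g$mz))
  fum <- parse_formula("C4H4O4")
  expect_equal(nrow(enumerate_grid(fum, 4, 0)), 5)
  expect_error(enumerate_grid(gln, 5, 3), "exceed")
})

test_that("peak assignment honors tolerance and normalizes", {
  gln <- parse_formula("C5H10N2O3")
  grid <- enumerate_grid(gln, 5, 2, charge = 1)
  m0 <- grid$mz[grid$n13C == 0 & grid$n15N == 0]
  res <- assign_peaks(tibble::tibble(mz = m0, intensity = 100), grid, 5)
  expect_equal(res$mid$fraction[res$mid$n13C == 0 & res$mid$n15N == 0], 1)
  expect_equal(sum(res$mid$fraction), 1)
  # peak 6 ppm away is unassigned
  res2 <- suppressWarnings(
    assign_peaks(tibble::tibble(mz = m0 * (1 + 6e-6), intensity = 100), grid, 5)
  )
  expect_equal(nrow(res2$unassigned), 1)
  expect_equal(sum(res2$mid$fraction), 0)
})

test_that("correction matrix columns are binomial convolutions", {
  # 1-carbon metabolite: column for true M0 is (0.9893, 0.0107)
  f <- parse_formula("CH4")
  M <- build_correction(f, maxC = 1, maxN = 0)
  expect_equal(unname(M[, 1]), c(0.9893, 0.0107))
  # all natural abundances zero -> identity
  tab0 <- isotope_table()
  for (el in names(tab0)) {
    tab0[[el]] <- tab0[[el]][1, ]
    tab0[[el]]$abundance <- 1
  }
  gln <- parse_formula("C5H10N2O3")
  M0 <- build_correction(gln, table = tab0)
  expect_lt(max(abs(M0 - diag(18))), 1e-12)
})

test_that("resolved C and N axes factorize as per-element binomials", {
  gln <- parse_formula("C5H10N2O3")
  tab <- isotope_table()
  aC <- tab$C$abundance[2]
  aN <- tab$N$abundance[2]
  M <- build_correction(gln, resolved = c("C", "N"))
  layout <- attr(M, "layout")
  for (c0 in c(0, 2, 5)) {
    for (n0 in c(0, 1, 2)) {
      col <- which(layout$n13C == c0 & layout$n15N == n0)
      for (r in seq_len(nrow(layout))) {
        expected <- oracle_conv_prob(
          5, 2, c0, n0, layout$n13C[r], layout$n15N[r], aC, aN
        )
        expect_lt(abs(M[r, col] - expected), 1e-12)
      }
    }
  }
})

test_that("tracer impurity enters the correction columns", {
  f <- parse_formula("CH4")
  M <- build_correction(f, maxC = 1, maxN = 0, purity = c(C = 0.99, N = 1))
  # true M1: retained with p 0.99, natural abundance cannot add to a labeled atom
  expect_equal(unname(M[, 2]), c(0.01, 0.99))
})

test_that("correction round trip is identity on random grids", {
  gln <- parse_formula("C5H10N2O3")
  M <- build_correction(gln)
  for (seed in 1:5) {
    true <- random_mid_grid(5, 2, seed)
    obs <- as.vector(M %*% mid_vector_for_test(true, attr(M, "layout")))
    obs_mid <- attr(M, "layout") |>
      dplyr::mutate(fraction = obs / sum(obs))
    rec <- correct_mid(obs_mid, M)
    j <- dplyr::inner_join(rec, true, by = c("n13C", "n15N"))
    expect_lt(max(abs(j$fraction.x - j$fraction.y)), 1e-8)
  }
  # identity matrix leaves the grid unchanged
  I <- diag(18)
  attr(I, "layout") <- attr(M, "layout")
  true <- random_mid_grid(5, 2, 42)
  rec <- correct_mid(true, I)
  j <- dplyr::inner_join(rec, true, by = c("n13C", "n15N"))
  expect_equal(j$fraction.x, j$fraction.y, tolerance = 1e-12)
})

test_that("percent labeled is the atom fraction and behaves linearly", {
  full <- tibble::tibble(n13C = 5, n15N = 2, fraction = 1)
  expect_equal(percent_labeled(full, "C", 5), 1)
  expect_equal(percent_labeled(full, "N", 2), 1)
  none <- tibble::tibble(n13C = 0, n15N = 0, fraction = 1)
  expect_equal(percent_labeled(none, "C", 5), 0)
  # IMP with half the pool at 2 15N: (2 * 0.5) / 4
  imp <- tibble::tibble(n13C = c(0, 0), n15N = c(0, 2), fraction = c(0.5, 0.5))
  expect_equal(percent_labeled(imp, "N", 4), 0.25)
  # renormalization invariance
  scaled <- dplyr::mutate(imp, fraction = fraction * 7)
  expect_equal(percent_labeled(scaled, "N", 4), 0.25)
  # linearity in mixtures
  a <- random_mid_grid(5, 2, 1)
  b <- random_mid_grid(5, 2, 2)
  alpha <- 0.3
  mix <- dplyr::mutate(a, fraction = alpha * a$fraction + (1 - alpha) * b$fraction)
  expect_equal(
    percent_labeled(mix, "C", 5),
    alpha * percent_labeled(a, "C", 5) + (1 - alpha) * percent_labeled(b, "C", 5)
  )
  # any-label molecule fraction
  expect_equal(frac_any_labeled(imp, "N"), 0.5)
  expect_equal(frac_any_labeled(full, "C"), 1)
})
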