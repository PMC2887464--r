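# grid shared by the property-style tests
alphas <- list(frac(0), frac(1, 7), frac(1, 6))

test_that("tetraploid gamete frequencies match the closed form's anchor cases", {
  # classical chromosomal segregation from a duplex parent: 1:4:1
  g <- gamete_frequencies(2, alpha = 0)
  expect_true(all(g$freq == frac(c(1, 4, 1), 6)))
  # maximal double reduction from a duplex parent
  g <- gamete_frequencies(2, alpha = frac(1, 6))
  expect_true(all(g$freq == frac(c(2, 5, 2), 9)))
  # triplex parent: homozygous-mutant gametes at 13/24 (about 54%)
  g <- gamete_frequencies(3, alpha = frac(1, 6))
  expect_true(g$freq[[3]] == frac(13, 24))
  # no mutant alleles, any alpha
  for (a in alphas) {
    g <- gamete_frequencies(0, alpha = a)
    expect_true(all(g$freq == frac(c(1, 0, 0))))
  }
})

test_that("diploid parents produce haploid gametes at dosage/2", {
  g <- gamete_frequencies(1, alpha = 0, ploidy = 2)
  expect_identical(g$label, c("A", "a"))
  expect_true(all(g$freq == frac(c(1, 1), 2)))
  expect_true(all(gamete_frequencies(2, alpha = 0, ploidy = 2)$freq ==
                    frac(c(0, 1))))
})

test_that("distributions sum to exactly one across the whole grid", {
  for (d in 0:4) {
    for (a in alphas) {
      expect_true(sum(gamete_frequencies(d, a)$freq) == frac(1))
    }
  }
  for (d in 0:2) {
    expect_true(sum(gamete_frequencies(d, 0, ploidy = 2)$freq) == frac(1))
  }
})

test_that("enumeration oracle agrees exactly with the closed form", {
  for (d in 0:4) {
    expect_true(all(gamete_frequencies(d, frac(0))$freq ==
                      enumerate_gametes(d, "chromosomal")$freq))
    expect_true(all(gamete_frequencies(d, frac(1, 7))$freq ==
                      enumerate_gametes(d, "random_chromatid")$freq))
  }
  # spot values from direct counting
  expect_true(all(enumerate_gametes(2, "random_chromatid")$freq ==
                    frac(c(3, 8, 3), 14)))
  expect_true(all(enumerate_gametes(4, "chromosomal")$freq ==
                    frac(c(0, 0, 1))))
})

test_that("relabelling gamete classes mirrors swapping the allele", {
  for (d in 0:4) {
    for (a in alphas) {
      expect_true(all(gamete_frequencies(d, a)$freq ==
                        rev(gamete_frequencies(4 - d, a)$freq)))
    }
  }
})

test_that("double reduction strictly converts heterozygous to homozygous gametes", {
  grid <- frac(0:6, 36)  # 0 to 1/6 in steps of 1/36
  for (d in 1:3) {
    probs <- vapply(seq_along(grid), function(i) {
      gamete_frequencies(d, grid[[i]])$prob
    }, double(3))
    expect_true(all(diff(probs[1, ]) > 0))  # AA increasing
    expect_true(all(diff(probs[2, ]) < 0))  # Aa decreasing
    expect_true(all(diff(probs[3, ]) > 0))  # aa increasing
  }
})

test_that("domain violations are rejected", {
  expect_error(gamete_frequencies(5, 0), "dosage")
  expect_error(gamete_frequencies(-1, 0), "dosage")
  expect_error(gamete_frequencies(2, frac(1, 5)), "1/6")
  expect_error(gamete_frequencies(2, -0.01), "1/6")
  expect_error(gamete_frequencies(1, frac(1, 6), ploidy = 2), "diploid")
  expect_error(gamete_frequencies(2, 0, ploidy = 6), "ploidy")
})

test_that("female selection aborts the right classes and renormalises", {
  rec <- selection_model("recessive")
  dom <- selection_model("dominant")
  g <- gamete_frequencies(2, frac(1, 6))
  fem <- apply_female_selection(g, rec)
  expect_true(fem$abort_fraction == frac(2, 9))
  expect_true(all(fem$viable$freq == frac(c(2, 5), 7)))
  # simplex under the dominant model: alpha/4 + (1 - alpha)/2 = 11/24
  g1 <- gamete_frequencies(1, frac(1, 6))
  expect_true(apply_female_selection(g1, dom)$abort_fraction == frac(11, 24))
  # nulliplex: nothing aborts
  g0 <- gamete_frequencies(0, frac(1, 6))
  fem0 <- apply_female_selection(g0, rec)
  expect_true(fem0$abort_fraction == frac(0))
  expect_true(sum(fem0$viable$freq) == frac(1))
  # quadruplex recessive: every female gamete aborts
  g4 <- gamete_frequencies(4, frac(1, 6))
  expect_error(apply_female_selection(g4, rec), "Degenerate female pool")
})

test_that("female selection conserves probability across the grid", {
  for (d in 0:3) {
    for (a in alphas) {
      for (mode in c("recessive", "dominant")) {
        sel <- selection_model(mode)
        g <- gamete_frequencies(d, a)
        fem <- tryCatch(apply_female_selection(g, sel), error = function(e) NULL)
        if (is.null(fem)) next  # degenerate all-abort case
        expect_true(fem$abort_fraction +
                      (frac(1) - fem$abort_fraction) * sum(fem$viable$freq) ==
                      frac(1))
      }
    }
  }
})

test_that("male selection weights, renormalises, and keeps exactness", {
  rec <- selection_model("recessive", male_te = 0.1)
  g <- gamete_frequencies(2, frac(1, 6))
  male <- apply_male_selection(g, rec)
  # (2/9, 5/9, 0.2/9) / (7.2/9) = (10/36, 25/36, 1/36)
  expect_true(all(male$freq == frac(c(10, 25, 1), 36)))
  expect_true(sum(male$freq) == frac(1))
  # all weights 1: identity
  neutral <- selection_model("recessive", male_weights = c(1, 1, 1))
  expect_true(all(apply_male_selection(g, neutral)$freq == g$freq))
  # dominant triplex: class-0 share 10/33
  g3 <- gamete_frequencies(3, frac(1, 6))
  male3 <- apply_male_selection(g3, selection_model("dominant", male_te = 0.1))
  expect_true(male3$freq[[1]] == frac(10, 33))
  # degenerate: all weighted frequencies zero
  g4 <- gamete_frequencies(4, frac(1, 6))
  dead <- selection_model("recessive", male_weights = c(1, 1, 0))
  expect_error(apply_male_selection(g4, dead), "Degenerate male pool")
})

test_that("selection model validates its weights", {
  expect_error(selection_model("recessive", male_te = 1.2), "0, 1")
  expect_error(selection_model("recessive", male_weights = c(1, 1)), "length 3")
  expect_error(selection_model("recessive", male_weights = c(1, 1, 2)), "0, 1")
  sel <- selection_model("dominant")
  expect_identical(sel$female_abort, 1:2)
  expect_true(all(sel$male_weights == frac(c(10, 1, 1), 10)))
})
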