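test_that("a well-formed file round-trips through read/write unchanged", {
  path <- writeTinyCsv()
  x <- readSampleTable(path)
  expect_s4_class(x, "SoilSamples")
  expect_equal(ncol(x), 3)
  expect_equal(landUse(x), rep("PA", 3))
  expect_equal(concMatrix(x), concMatrix(tinySamples()), tolerance = 1e-12)
  # second round trip is exact
  path2 <- file.path(dirname(path), "again.csv")
  writeSampleTable(x, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("land-use codes are validated and case-folded", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "bad.csv")
  writeLines(c("sample_id,land_use,As", "s1,XX,5.0"), path)
  expect_error(readSampleTable(path), "XX")
  path2 <- file.path(dir, "lower.csv")
  writeLines(c("sample_id,land_use,As", "s1,mw,5.0"), path2)
  expect_equal(landUse(readSampleTable(path2)), "MW")
})

test_that("validation rejects negative concentrations and missing columns", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "neg.csv")
  writeLines(c("sample_id,land_use,As", "s1,PA,-1"), path)
  expect_error(readSampleTable(path), "negative")
  path2 <- file.path(dir, "nolu.csv")
  writeLines(c("sample_id,As", "s1,5"), path2)
  expect_error(readSampleTable(path2), "land_use")
  expect_error(SoilSamples(matrix(-1, 1, 1, dimnames = list("As", "s1")), "PA"),
               "negative|non-finite")
})

test_that("below-detection sentinels apply the MDL/2 substitution policy", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "bd.csv")
  writeLines(c("sample_id,land_use,As,Cd",
               "s1,PA,5.0,<0.004",
               "s2,PA,6.0,0.5"), path)
  x <- readSampleTable(path)
  expect_true(belowDetection(x)["Cd", "s1"])
  expect_false(belowDetection(x)["Cd", "s2"])
  expect_equal(concMatrix(x)["Cd", "s1"], 0.002)      # MDL/2 default
  expect_equal(detectionLimits(x)[["Cd"]], 0.004)
  x2 <- readSampleTable(path, substitute = "mdl")
  expect_equal(concMatrix(x2)["Cd", "s1"], 0.004)
  # censoring survives a round trip
  path2 <- file.path(dir, "bd2.csv")
  writeSampleTable(x, path2)
  expect_true(belowDetection(readSampleTable(path2))["Cd", "s1"])
})

test_that("site summaries use the sample-sd convention and match hand values", {
  s <- summarizeBySite(tinySamples())
  as_row <- s[s$element == "As", ]
  expect_equal(as_row$land_use, "PA")
  expect_equal(as_row$n, 3)
  expect_equal(as_row$mean, 8.56, tolerance = 1e-9)
  expect_equal(as_row$min, 3.32)
  expect_equal(as_row$max, 13.90)
  expect_equal(as_row$sd, sd(c(3.32, 8.46, 13.90)))
  # degenerate single-sample site: sd is NA, min = mean = max
  one <- SoilSamples(matrix(5, 1, 1, dimnames = list("As", "s1")), "RA")
  s1 <- summarizeBySite(one)
  expect_true(is.na(s1$sd))
  expect_equal(s1$min, s1$mean)
  expect_equal(s1$max, s1$mean)
  # identical samples: sd 0
  same <- SoilSamples(matrix(4, 1, 3, dimnames = list("As", paste0("s", 1:3))),
                      rep("M", 3))
  expect_equal(summarizeBySite(same)$sd, 0)
})

test_that("exceedance fractions equal a brute-force count", {
  refs <- defaultReferences()
  conc <- matrix(c(2, 7, 8, 9), 1, dimnames = list("As", paste0("s", 1:4)))
  x <- SoilSamples(conc, rep("IA", 4))
  expect_equal(exceedanceFraction(x, refs, "TRV", "As"), 0.75)  # TRV(As) = 6
  low <- SoilSamples(matrix(c(1, 2), 1, 2,
                            dimnames = list("As", c("a", "b"))), c("PA", "PA"))
  expect_equal(exceedanceFraction(low, refs, "TRV", "As"), 0)
  # independent count on a larger synthetic table, against CSQS
  set.seed(3)
  n <- 20
  m <- matrix(runif(n, 0, 100), 1, dimnames = list("Cr", paste0("s", 1:n)))
  big <- SoilSamples(m, rep("M", n))
  expect_equal(exceedanceFraction(big, refs, "CSQS", "Cr"),
               sum(m > standards(refs)["CSQS", "Cr"]) / n)
  expect_error(exceedanceFraction(x, refs, "NOPE", "As"), "unknown standard")
  expect_error(exceedanceFraction(x, refs, "TRV", "Zn"), "Zn")
})

test_that("shipped references match the study-area table", {
  refs <- defaultReferences()
  expect_equal(background(refs),
               c(As = 4.90, Cd = 0.30, Pb = 20, Cr = 41, Ni = 22, Cu = 27))
  expect_equal(toxicResponse(refs),
               c(As = 10, Cd = 30, Pb = 5, Cr = 2, Ni = 6, Cu = 5))
  expect_equal(unname(standards(refs)["TRV", "Cu"]), 16)
  expect_true(is.na(feBackground(refs)))
})

test_that("generator output converges to the target means at large n", {
  spec <- defaultSiteSpecs()
  spec <- spec[spec$land_use == "MW", ]
  spec$n <- 10000
  x <- generateSiteSamples(spec, seed = 99)
  s <- summarizeBySite(x)
  for (i in seq_len(nrow(s))) {
    target <- spec$mean[spec$element == s$element[i]]
    se <- s$sd[i] / sqrt(s$n[i])
    expect_lt(abs(s$mean[i] - target), 3 * se)
  }
})
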