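test_that("chronic daily intakes match hand arithmetic at unit concentration", {
  child <- exposureProfile("child")
  adult <- exposureProfile("adult")
  expect_equal(cdiIngestion(1, child), 200 * 350 * 6 / (15 * 2190) * 1e-6)
  expect_equal(cdiIngestion(1, child), 1.2785e-5, tolerance = 1e-4)
  expect_equal(cdiDermal(1, child), 2100 * 0.2 * 0.1 * 350 * 6 /
                 (15 * 2190) * 1e-6)
  expect_equal(cdiDermal(1, child), 2.6849e-6, tolerance = 1e-4)
  expect_equal(cdiInhalation(1, child),
               10 * 350 * 6 / (1.3e9 * 15 * 2190))
  expect_equal(cdiInhalation(1, child), 4.918e-10, tolerance = 1e-3)
  expect_equal(cdiIngestion(0, adult), 0)
  expect_equal(cdiDermal(0, adult), 0)
  expect_equal(cdiInhalation(0, adult), 0)
})

test_that("child/adult intake ratios follow the exposure parameters", {
  child <- exposureProfile("child")
  adult <- exposureProfile("adult")
  for (cs in c(1, 7.3, 124.67)) {
    expect_equal(cdiInhalation(cs, child) / cdiInhalation(cs, adult),
                 (10 / 15) / (20 / 70))  # 2.3333, element-independent
    expect_equal(cdiIngestion(cs, child) / cdiIngestion(cs, adult),
                 (200 / 15) / (100 / 70))  # 9.3333
  }
})

test_that("non-carcinogenic intake is independent of exposure duration", {
  for (ed in c(2, 6, 30, 70)) {
    p <- exposureProfile("child", exposure_duration = ed)
    expect_equal(cdiIngestion(5, p), cdiIngestion(5, exposureProfile("child")))
    expect_equal(cdiDermal(5, p), cdiDermal(5, exposureProfile("child")))
    expect_equal(cdiInhalation(5, p),
                 cdiInhalation(5, exposureProfile("child")))
  }
  # ...but the carcinogenic intake scales with ED
  p2 <- exposureProfile("child", exposure_duration = 12)
  expect_equal(cdiIngestion(5, p2, carcinogenic = TRUE),
               2 * cdiIngestion(5, exposureProfile("child"),
                                carcinogenic = TRUE))
})

test_that("all doses are homogeneous of degree one in concentration", {
  child <- exposureProfile("child")
  tox <- defaultToxicity()
  for (f in list(cdiIngestion, cdiDermal, cdiInhalation)) {
    expect_equal(f(17 * 2.3, child), 17 * f(2.3, child))
  }
  hq1 <- hazardQuotient(cdiIngestion(1, child), rfd(tox)["As", "ingestion"])
  hq9 <- hazardQuotient(cdiIngestion(9, child), rfd(tox)["As", "ingestion"])
  expect_equal(hq9, 9 * hq1)
  cr1 <- cancerRisk(cdiIngestion(1, child, TRUE), csf(tox)["As", "ingestion"])
  cr9 <- cancerRisk(cdiIngestion(9, child, TRUE), csf(tox)["As", "ingestion"])
  expect_equal(cr9, 9 * cr1)
})

test_that("hazard quotients, indices and the not-assessed rule behave", {
  expect_equal(hazardQuotient(3e-4, 3e-4), 1)
  expect_equal(hazardQuotient(0, 1e-3), 0)
  expect_true(is.na(hazardQuotient(1e-5, NA)))
  expect_equal(hazardIndex(c(0.1, 0.02, 0.003)), 0.123)
  expect_equal(hazardIndex(c(0.4)), 0.4)
  expect_message(hazardIndex(c(0.1, NA, 0.02)), "not assessed")
  expect_equal(hazardIndex(c(0.1, NA, 0.02), quiet = TRUE), 0.12)
  expect_error(hazardIndex(c(NA_real_, NA_real_)), "no defined")
  m <- rbind(As = c(0.1, 0.02, 0.003), Cd = c(0.2, NA, 0.001))
  expect_equal(hazardIndex(m, quiet = TRUE), c(As = 0.123, Cd = 0.201))
  expect_equal(hazardIndex(m, across_elements = TRUE, quiet = TRUE), 0.324)
})

test_that("cancer risks multiply, sum over routes, and flag the window", {
  expect_equal(cancerRisk(0, 1.5), 0)
  expect_equal(lifetimeCancerRisk(c(1e-5, 2e-6, 3e-8)), 1.203e-5)
  expect_equal(lifetimeCancerRisk(c(1e-5, NA, 3e-8)), 1.003e-5)
  expect_true(is.na(lifetimeCancerRisk(c(NA_real_, NA_real_))))
  expect_equal(cancerRiskFlag(c(5e-7, 5e-5, 2e-4)),
               c("below", "within", "exceeds"))
  expect_equal(cancerRiskFlag(1e-4), "within")  # boundary: not an exceedance
})

test_that("the site-level report is coherent and children exceed adults", {
  hr <- suppressMessages(healthRiskReport(defaultSiteSpecs()))
  d <- hr$detail
  expect_true(all(d$cdi_nc >= 0 & d$cdi_car >= 0))
  expect_true(all(d$hq >= 0, na.rm = TRUE))
  expect_true(all(d$cr >= 0, na.rm = TRUE))
  # HI per element equals the route sum recomputed by brute force
  for (i in sample(nrow(hr$by_element), 8)) {
    row <- hr$by_element[i, ]
    sub <- d[d$receptor == row$receptor & d$land_use == row$land_use &
               d$element == row$element, ]
    expect_equal(row$hi, sum(sub$hq, na.rm = TRUE))
  }
  # site totals equal the element sums
  for (i in sample(nrow(hr$summary), 4)) {
    row <- hr$summary[i, ]
    sub <- hr$by_element[hr$by_element$receptor == row$receptor &
                           hr$by_element$land_use == row$land_use, ]
    expect_equal(row$hi_total, sum(sub$hi, na.rm = TRUE))
  }
  # children are the more exposed receptor at every site
  wide <- merge(hr$summary[hr$summary$receptor == "child", ],
                hr$summary[hr$summary$receptor == "adult", ],
                by = "land_use", suffixes = c("_child", "_adult"))
  expect_true(all(wide$hi_total_child > wide$hi_total_adult))
  # dermal RfD fallback is flagged only where the table lacks a dermal RfD
  expect_false(any(d$rfd_fallback[d$route == "ingestion"]))
})
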