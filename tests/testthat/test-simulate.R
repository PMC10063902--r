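smallParams <- function(seed = 5, ...) {
  simulationParams(nProteins = 150, nSites = 900, nGeneSets = 10,
                   ppiDensity = 2e-3, seed = seed, ...)
}

test_that("the generator is deterministic in the seed and varies across seeds", {
  a <- simulateStudy(smallParams())
  b <- simulateStudy(smallParams())
  expect_identical(intensities(a$experiment), intensities(b$experiment))
  expect_identical(siteData(a$experiment), siteData(b$experiment))
  expect_identical(a$truth$sites, b$truth$sites)
  expect_identical(a$edges, b$edges)
  c <- simulateStudy(smallParams(seed = 6))
  expect_false(identical(intensities(a$experiment),
                         intensities(c$experiment)))
})

test_that("missingRate = 0 produces a complete table", {
  sim <- simulateStudy(smallParams(missingRate = 0))
  expect_false(anyNA(intensities(sim$experiment)))
})

test_that("generated marginals match the requested composition and moments", {
  sim <- simulateStudy(simulationParams(seed = 3))
  sd <- siteData(sim$experiment)
  expect_equal(nrow(sd), 21239L)
  expect_equal(ncol(sim$experiment), 12L)
  frac <- table(sd$residue)[c("S", "T", "Y")] / nrow(sd)
  expect_equal(unname(as.numeric(frac)), c(0.8276, 0.1612, 0.0112),
               tolerance = 0.01 / 0.8276)  # within one percentage point
  # log2 intensity moments: mean near the protein baseline mean; the
  # variance decomposes into baseline + site + replicate components
  sim0 <- simulateStudy(simulationParams(seed = 3, missingRate = 0,
                                         fracDifferentialHC = 0))
  x <- log2(intensities(sim0$experiment))
  expect_equal(mean(x), 23, tolerance = 0.15)
  expect_equal(var(as.numeric(x)), 2^2 + 1^2 + 0.3^2, tolerance = 0.8)
})

test_that("missingness is biased toward low intensities when MNAR weight is positive", {
  full <- simulateStudy(smallParams(missingRate = 0))
  holey <- simulateStudy(smallParams(missingRate = 0.3, mnarWeight = 0.9))
  allVals <- log2(intensities(full$experiment))
  obs <- log2(intensities(holey$experiment))
  expect_identical(dim(allVals), dim(obs))
  expect_gt(mean(obs, na.rm = TRUE), mean(allVals))
  rate <- mean(is.na(obs))
  expect_equal(rate, 0.3, tolerance = 0.05)
})

test_that("ground-truth group means encode the spiked effect structure", {
  sim <- simulateStudy(smallParams())
  ts <- sim$truth$sites
  d <- ts[ts$diffHC, ]
  expect_true(all(abs(abs(d$meanH - d$meanC) - 1.5) < 1e-12))
  expect_true(all(ts$meanH[!ts$diffHC] == ts$meanC[!ts$diffHC]))
  r <- ts[ts$diffSH, ]
  expect_true(all(r$meanS - r$meanH == -(r$meanH - r$meanC)))
  expect_true(all(ts$meanS[!ts$diffSH] == ts$meanH[!ts$diffSH]))
  # per-protein classes are consistent with site-level truth
  tp <- sim$truth$proteins
  revGenes <- unique(ts$gene[ts$diffSH])
  expect_setequal(tp$gene[tp$classS != "none"], revGenes)
  mixed <- tp$gene[tp$classS == "mixed"]
  expect_true(length(mixed) >= 1)
  for (g in mixed) {
    dirs <- unique(ts$dirHC[ts$gene == g & ts$diffSH])
    expect_setequal(dirs, c("up", "down"))
  }
})

test_that("infeasible parameter combinations are rejected", {
  expect_error(simulationParams(residueProbs = c(S = 0.5, T = 0.4, Y = 0.2)),
               "sum to 1")
  expect_error(simulationParams(missingRate = 1), "missingRate")
  expect_error(simulateStudy(smallParams(fracDifferentialHC = 0.01,
                                         fracReversedByS = 1,
                                         fracReversedByE = 1,
                                         nMixedProteins = 0)),
               "infeasible")
})

test_that("truthReport recovers perfect and null calls as 1 and 0", {
  sim <- simulateStudy(smallParams())
  ts <- sim$truth$sites
  oracle <- data.frame(site_id = ts$site_id, protein = ts$protein,
                       gene = ts$gene, position = 1L, residue = "S",
                       multiplicity = "1", log2fc = 0, t = 0, p = 1,
                       call = ts$dirHC, stringsAsFactors = FALSE)
  oracle$call[oracle$call == "none"] <- "ns"
  r <- truthReport(sim$truth, list(`H/C` = oracle))
  expect_equal(r$differential$`H/C`$sensitivity, 1)
  expect_equal(r$differential$`H/C`$fdr, 0)
  allNull <- oracle; allNull$call <- "ns"
  r0 <- truthReport(sim$truth, list(`H/C` = allNull))
  expect_equal(r0$differential$`H/C`$sensitivity, 0)
  # foreign identifiers are refused
  foreign <- oracle; foreign$site_id <- paste0("X", foreign$site_id)
  expect_error(truthReport(sim$truth, list(`H/C` = foreign)), "mismatch")
})
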