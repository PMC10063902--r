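test_that("degenerate group patterns give the expected calls", {
  # identical groups: zero fold change, not significant
  mat <- matrix(rep(c(10, 10, 10, 10, 10, 10), 3), 3, 6, byrow = TRUE,
                dimnames = list(NULL, c("C1", "C2", "C3", "H1", "H2", "H3")))
  pe <- matExperiment(mat)
  dt <- computeContrast(pe, twoGroupDesign(), "H/C")
  expect_equal(dt$log2fc, rep(0, 3))
  expect_equal(dt$call, rep("ns", 3))
  # constructed two-unit shift with infinitesimal jitter
  set.seed(1)
  jit <- matrix(rnorm(6, 0, 1e-6), 1)
  mat2 <- matrix(c(8, 8, 8, 10, 10, 10), 1) + jit
  colnames(mat2) <- c("C1", "C2", "C3", "H1", "H2", "H3")
  dt2 <- computeContrast(matExperiment(mat2), twoGroupDesign(), "H/C")
  expect_equal(dt2$log2fc, 2, tolerance = 1e-4)
  expect_equal(dt2$call, "up")
})

test_that("t statistics and p-values match stats::t.test to 1e-10", {
  set.seed(42)
  n <- 200
  mat <- matrix(rnorm(n * 6, 20, 1), n,
                dimnames = list(NULL, c("C1", "C2", "C3", "H1", "H2", "H3")))
  mat[sample(length(mat), 40)] <- NA
  pe <- matExperiment(mat)
  d <- twoGroupDesign()
  for (test in c("student", "welch")) {
    dt <- computeContrast(pe, d, "H/C",
                          differentialParams(test = test))
    for (i in seq_len(n)) {
      h <- mat[i, 4:6]; c0 <- mat[i, 1:3]
      if (sum(!is.na(h)) < 2 || sum(!is.na(c0)) < 2) {
        expect_true(is.na(dt$p[i]))
        expect_equal(dt$call[i], "ns")
        next
      }
      tt <- t.test(h[!is.na(h)], c0[!is.na(c0)],
                   var.equal = (test == "student"))
      expect_equal(dt$t[i], unname(tt$statistic), tolerance = 1e-10)
      expect_equal(dt$p[i], tt$p.value, tolerance = 1e-10)
      expect_equal(dt$log2fc[i],
                   mean(h, na.rm = TRUE) - mean(c0, na.rm = TRUE),
                   tolerance = 1e-12)
    }
  }
})

test_that("swapping numerator and denominator negates fold changes and swaps calls", {
  pe <- makeExperiment(nSites = 80, seed = 3, missing = 0.2, scale = "log2")
  d <- StudyDesign(list(C = paste0("C", 1:3), H = paste0("H", 1:3)),
                   contrasts = c("H/C", "C/H"))
  a <- computeContrast(pe, d, "H/C")
  b <- computeContrast(pe, d, "C/H")
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  swap <- c(up = "down", down = "up", ns = "ns")
  expect_identical(unname(swap[a$call]), b$call)
})

test_that("BH adjustment is monotone in raw-p rank order and gates significance", {
  pe <- makeExperiment(nSites = 100, seed = 4, missing = 0, scale = "log2")
  dt <- computeContrast(pe, twoGroupDesign(), "H/C",
                        differentialParams(pAdjust = "BH"))
  ord <- order(dt$p)
  expect_true(all(diff(dt$padj[ord]) >= -1e-15))
  sig <- dt$call != "ns"
  expect_true(all(dt$padj[sig] < 0.05))
})

test_that("volcano tables carry the plot coordinates and drop untested sites", {
  dt <- handDiffTable(c("P1", "P2", "P3"), 1:3, c("up", "ns", "down"))
  dt$p <- c(0.01, NA, 0.001)
  v <- volcanoTable(dt)
  expect_equal(nrow(v), 2L)
  expect_equal(v$neg_log10_p[1], 2)
  expect_equal(unname(attr(v, "counts")[c("up", "down")]), c(1L, 1L))
  vns <- volcanoTable(handDiffTable("P1", 1, "ns"))
  expect_true(all(vns$call == "ns"))
})

test_that("contrast summaries are pure counts with up + down = significant", {
  t1 <- handDiffTable(sprintf("P%04d", 1:1200), 1:1200,
                      c(rep("up", 686), rep("down", 398), rep("ns", 116)))
  t2 <- handDiffTable(sprintf("Q%04d", 1:1600), 1:1600,
                      c(rep("up", 955), rep("down", 597), rep("ns", 48)))
  s <- summarizeContrasts(list(`S/H` = t1, `E/H` = t2))
  expect_equal(s$n_significant, c(1084L, 1552L))
  expect_equal(s$n_up + s$n_down, s$n_significant)
  empty <- handDiffTable(character(0), integer(0), character(0))
  s0 <- summarizeContrasts(list(x = empty))
  expect_equal(s0$n_significant, 0L)
})
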