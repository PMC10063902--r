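test_that("a disease-down site paired with a treatment-up site at another position reverses", {
  disease <- handDiffTable(c("CACNA1D", "OTHER"), c(802, 10),
                           c("down", "down"))
  treatment <- handDiffTable(c("CACNA1D", "OTHER"), c(869, 11),
                             c("up", "down"))
  pairs <- findReversedSites(disease, treatment)
  expect_equal(unique(pairs$protein), "CACNA1D")
  expect_equal(pairs$pattern, "down_up")
  expect_equal(pairs$disease_position, 802)
  expect_equal(pairs$treatment_position, 869)
  hits <- classifyReversalProteins(pairs)
  expect_equal(hits$class, "down_up")
  expect_equal(hits$disease_direction, "Down")
  expect_equal(hits$treatment_direction, "Up")
  # same direction in both contrasts is not a reversal (OTHER above)
  expect_false("OTHER" %in% pairs$protein)
})

test_that("same-site mode only pairs identical records", {
  disease <- handDiffTable("P1", c(10, 20), c("down", "ns"))
  treatment <- handDiffTable("P1", c(20, 10), c("up", "ns"))
  expect_equal(nrow(findReversedSites(disease, treatment, mode = "site")), 0L)
  treatment2 <- handDiffTable("P1", c(10, 20), c("up", "ns"))
  same <- findReversedSites(disease, treatment2, mode = "site")
  expect_equal(nrow(same), 1L)
  expect_equal(same$disease_position, same$treatment_position)
})

test_that("protein classification distinguishes pure and mixed patterns", {
  disease <- handDiffTable(c("GSK3A", "GSK3A", "CACNA1D"), c(1, 2, 3),
                           c("up", "down", "down"))
  treatment <- handDiffTable(c("GSK3A", "GSK3A", "CACNA1D"), c(5, 6, 7),
                             c("down", "up", "up"))
  hits <- classifyReversalProteins(findReversedSites(disease, treatment))
  expect_equal(hits$class[hits$gene == "GSK3A"], "mixed")
  expect_equal(hits$disease_direction[hits$gene == "GSK3A"], "Up/down")
  expect_equal(hits$class[hits$gene == "CACNA1D"], "down_up")
  # a single site pair can never be mixed
  one <- classifyReversalProteins(
    findReversedSites(handDiffTable("P1", 1, "down"),
                      handDiffTable("P1", 2, "up")))
  expect_equal(one$class, "down_up")
})

test_that("reversal matching equals the brute-force double loop on fuzzed tables", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(50:200, 1)
    prot <- sprintf("P%02d", sample.int(25, n, replace = TRUE))
    mk <- function() handDiffTable(prot, sample.int(5000, n),
                                   sample(c("up", "down", "ns"), n, TRUE,
                                          prob = c(0.2, 0.2, 0.6)))
    d <- mk(); t <- mk()
    got <- findReversedSites(d, t)
    want <- bruteReversalPairs(d, t)
    keyG <- sort(paste(got$protein, got$pattern, got$disease_position,
                       got$treatment_position))
    keyW <- sort(paste(want$protein, want$pattern, want$disease_position,
                       want$treatment_position))
    expect_identical(keyG, keyW)
    # reversed proteins are significant in BOTH contrasts
    expect_true(all(got$protein %in%
                      intersect(d$protein[d$call != "ns"],
                                t$protein[t$call != "ns"])))
  }
})

test_that("swapping the contrasts maps down_up to up_down and fixes mixed", {
  set.seed(22)
  prot <- sprintf("P%02d", sample.int(15, 80, replace = TRUE))
  d <- handDiffTable(prot, sample.int(999, 80),
                     sample(c("up", "down", "ns"), 80, TRUE))
  t <- handDiffTable(prot, 1000 + sample.int(999, 80),
                     sample(c("up", "down", "ns"), 80, TRUE))
  fwd <- classifyReversalProteins(findReversedSites(d, t))
  rev <- classifyReversalProteins(findReversedSites(t, d))
  expect_setequal(fwd$protein, rev$protein)
  m <- match(fwd$protein, rev$protein)
  swap <- c(down_up = "up_down", up_down = "down_up", mixed = "mixed")
  expect_identical(unname(swap[fwd$class]), rev$class[m])
})

test_that("pathway restriction keeps only annotated hits and attaches memberships", {
  hits <- classifyReversalProteins(
    findReversedSites(handDiffTable(c("A", "B"), c(1, 2), c("down", "up")),
                      handDiffTable(c("A", "B"), c(3, 4), c("up", "down"))))
  gsc <- GeneSetCollection(list(pw1 = c("A", "X"), pw2 = c("X", "Y")))
  kept <- restrictToPathways(hits, c("pw1", "pw2"), gsc)
  expect_equal(kept$gene, "A")
  expect_equal(kept$pathways, "pw1")
  # empty top-20 gives an empty result
  expect_equal(nrow(restrictToPathways(hits, character(0), gsc)), 0L)
})

test_that("tables from different processing runs are refused", {
  d <- handDiffTable("P1", 1, "down", provenance = "runA")
  t <- handDiffTable("P1", 2, "up", provenance = "runB")
  expect_error(findReversedSites(d, t), "provenance")
})

test_that("published direction columns regenerate their reversal counts", {
  df <- data.frame(gene = c("X1", "X2", "X3"),
                   disease = c("Down", "Up", "Up/down"),
                   treatment = c("Up", "Down", "Down/up"),
                   stringsAsFactors = FALSE)
  tabs <- directionFixtureTables(df)
  hits <- classifyReversalProteins(
    findReversedSites(tabs$disease, tabs$treatment))
  expect_equal(nrow(hits), 3L)
  expect_equal(hits$class[hits$gene == "X3"], "mixed")
  expect_equal(hits$class[hits$gene == "X1"], "down_up")
})
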