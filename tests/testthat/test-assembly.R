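# shorthand for PSM rows with full ladder support
psmRow <- function(chain, start, end, seq, score, mods = "",
                   shift = NA_real_, shiftPos = NA_integer_,
                   accepted = TRUE) {
  n <- nchar(seq)
  data.frame(spectrum = paste0("s", start), taxon = "t", chain = chain,
             start = start, end = end, seq = seq, mods = mods,
             shift = shift, shiftPos = shiftPos, k = 2L * (n - 1L),
             n = 2L * (n - 1L), score = score, accepted = accepted,
             bMatch = strrep("1", n - 1L), yMatch = strrep("1", n - 1L))
}

ML <- c(alpha1 = 600L, alpha2 = 600L)

test_that("PSMs map to site calls with score-based conflict resolution", {
  p <- psmRow("alpha2", 495, 509, strrep("G", 15), 80)
  calls <- mapPsmsToSites(p, ML)
  expect_equal(nrow(calls), 15L)
  expect_equal(calls$site, 495:509)

  # overlapping agreeing PSMs: one call per site, support = max score
  p2 <- rbind(p, psmRow("alpha2", 500, 514, strrep("G", 15), 95))
  calls <- mapPsmsToSites(p2, ML)
  expect_equal(nrow(calls), 20L)
  expect_equal(calls$score[calls$site == 505], 95)

  # conflicting overlap: higher score wins; exact tie -> '?' (dropped call)
  pa <- psmRow("alpha1", 10, 13, "GAGR", 90)
  pb <- psmRow("alpha1", 10, 13, "GSGR", 70)
  calls <- mapPsmsToSites(rbind(pa, pb), ML)
  expect_equal(calls$residue[calls$site == 11], "A")
  pc <- psmRow("alpha1", 10, 13, "GSGR", 90)
  calls <- mapPsmsToSites(rbind(pa, pc), ML)
  expect_equal(calls$residue[calls$site == 11], "?")

  expect_error(mapPsmsToSites(psmRow("alpha1", 590, 605, strrep("G", 16), 50),
                              ML), "outside")
})

test_that("error-tolerant shifts convert to residue calls only when unambiguous", {
  # A + 30.01057 = T
  p <- psmRow("alpha1", 1, 4, "GAGR", 85, shift = 30.01057, shiftPos = 2L)
  calls <- mapPsmsToSites(p, ML)
  expect_equal(calls$residue[calls$site == 2], "T")
  # A + 42.08 matches no residue: site stays uncalled
  p <- psmRow("alpha1", 1, 4, "GAGR", 85, shift = 42.08, shiftPos = 2L)
  calls <- mapPsmsToSites(p, ML)
  expect_false(2 %in% calls$site)
  # V + 14.01565 = I/L, resolved to L pending isobaric canonicalisation
  p <- psmRow("alpha1", 1, 4, "GVGR", 85, shift = 14.01565, shiftPos = 2L)
  calls <- mapPsmsToSites(p, ML)
  expect_equal(calls$residue[calls$site == 2], "L")
})

test_that("residues without flanking fragment support are not called", {
  # b ions all matched except b2/b3; y ions all unmatched:
  # residue 3 loses both its b-flanks and has no y support
  p <- psmRow("alpha1", 1, 6, "GAVGSR", 85)
  p$bMatch <- "10011"
  p$yMatch <- "00000"
  calls <- mapPsmsToSites(p, ML)
  expect_setequal(calls$site, c(1, 5, 6))
  # with requireLadder = FALSE every residue is called
  calls <- mapPsmsToSites(p, ML, requireLadder = FALSE)
  expect_equal(nrow(calls), 6L)
})

test_that("deamidated sites are unverifiable and left uncalled by default", {
  p <- psmRow("alpha1", 1, 4, "GNGR", 85, mods = "deam@2")
  expect_false(2 %in% mapPsmsToSites(p, ML)$site)
  calls <- mapPsmsToSites(p, ML, deamidatedAs = "database")
  expect_equal(calls$residue[calls$site == 2], "N")
})

test_that("consensus takes column majorities and leaves ties unknown", {
  refs <- c(a = "AAG", b = "AAG", c = "SSG")
  expect_equal(consensusSequence(refs), "AAG")
  refs <- c(a = "AG", b = "SG")
  expect_equal(consensusSequence(refs), "?G")
  expect_error(consensusSequence(character(0)), "empty")
})

test_that("taxon sequences fill unknowns per mode, never overwriting calls", {
  refs <- c(r1 = "AAGPK", r2 = "AAGPK", r3 = "SAGPR")
  calls <- data.frame(chain = "alpha1", site = c(2L, 4L),
                      residue = c("V", "W"), score = 50)
  sUnk <- buildTaxonSequence(calls, masterLength = 5L, fillMode = "unknown")
  expect_equal(sUnk, "?V?W?")
  sCon <- buildTaxonSequence(calls, refs, 5L, fillMode = "consensus")
  expect_equal(sCon, "AVGWK")
  expect_error(buildTaxonSequence(calls, NULL, 5L, fillMode = "consensus"),
               "reference")
})

test_that("isobaric canonicalisation rewrites columns and is idempotent", {
  aln <- alignmentFromStrings(c(a = "LGA", b = "LGA", c = "IGA", d = "AGA"))
  r <- resolveIsobaric(aln)
  expect_equal(siteMatrix(r)[, 1], c(a = "L", b = "L", c = "L", d = "A"))
  expect_equal(siteMatrix(r)[, 2:3], siteMatrix(aln)[, 2:3])  # untouched
  # tie -> alphabetically first ('I'), reported
  aln2 <- alignmentFromStrings(c(a = "I", b = "L"))
  expect_message(r2 <- resolveIsobaric(aln2), "tied")
  expect_equal(unname(siteMatrix(r2)[, 1]), c("I", "I"))
  # idempotence
  expect_equal(siteMatrix(resolveIsobaric(r)), siteMatrix(r))
})

test_that("concatenation pads missing chains and reports coverage", {
  a1 <- c(t1 = "GAP", t2 = "GAP", fossil = "G??")
  a2 <- c(t1 = "GPKR", t2 = "GPKR")
  aln <- concatenateChains(a1, a2)
  expect_equal(chainBoundary(aln), 3L)
  cv <- coverageFraction(aln)
  expect_equal(unname(cv[c("t1", "t2")]), c(1, 1))
  expect_equal(unname(cv["fossil"]), 1 / 7)   # alpha2 all-'?' block
  expect_error(concatenateChains(c(a = "G", a = "G"), c(a = "G")),
               "duplicate")
})

test_that("half-retained fossil peptides give about half coverage", {
  seqs <- list(alpha1 = simulateReference(1, 1014),
               alpha2 = simulateReference(2, 1014))
  d <- degradeToFossil(seqs, 0.5, seed = 11)
  aln <- concatenateChains(
    c(ref = seqs$alpha1, fossil = d$alpha1),
    c(ref = seqs$alpha2, fossil = d$alpha2))
  expect_equal(unname(coverageFraction(aln)["fossil"]), d$coverage,
               tolerance = 1e-12)
  expect_gt(coverageFraction(aln)["fossil"], 0.42)
  expect_lt(coverageFraction(aln)["fossil"], 0.58)
})

test_that("aligned FASTA round-trips with '?' encoded as X", {
  seqs <- c(a = "GA?PL", b = "GAXPL", fossil = "??GPL")
  f <- tempfile(fileext = ".fasta")
  writeAlignedFasta(seqs, f)
  txt <- readLines(f)
  expect_true(any(grepl("GAXPL", txt)))
  back <- readAlignedFasta(f)
  expect_equal(back[["a"]], "GA?PL")
  expect_equal(back[["fossil"]], "??GPL")
})
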