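test_that("reference chains follow the Gly-Xaa-Yaa template deterministically", {
  s <- simulateReference(1, 1014)
  chars <- strsplit(s, "")[[1]]
  expect_equal(nchar(s), 1014L)
  expect_true(all(chars[seq(1, 1014, by = 3)] == "G"))
  expect_identical(s, simulateReference(1, 1014))
  expect_false(identical(s, simulateReference(2, 1014)))
  expect_error(simulateReference(1, 1000), "divisible by 3")
})

test_that("Xaa/Yaa proline frequency matches the configured composition", {
  s <- simulateReference(2, 3000)
  chars <- strsplit(s, "")[[1]][-seq(1, 3000, by = 3)]  # Xaa/Yaa only
  p <- mean(chars == "P")
  se <- sqrt(0.3 * 0.7 / length(chars))
  expect_lt(abs(p - 0.3), 3 * se)
  kr <- mean(chars %in% c("K", "R"))
  expect_lt(abs(kr - 0.13), 3 * sqrt(0.13 * 0.87 / length(chars)))
})

test_that("evolution is the identity at zero time and rejects bad trees", {
  root <- list(alpha1 = simulateReference(1, 120),
               alpha2 = simulateReference(2, 120))
  tr <- ape::read.tree(text = "(a:0,b:0,c:0);")
  leaves <- evolveSequences(root, tr, seed = 1)
  for (lf in leaves) expect_identical(lf, root)
  bad <- ape::read.tree(text = "(a:0.1,b:-0.1,c:0.1);")
  expect_error(evolveSequences(root, bad, 1), "non-negative")
})

test_that("observed divergence matches the Dayhoff expectation", {
  root <- list(alpha1 = simulateReference(3, 1500),
               alpha2 = simulateReference(4, 1500))
  tr <- ape::read.tree(text = "(a:0.1,b:0);")
  leaves <- evolveSequences(root, tr, seed = 5, gInvariant = FALSE)
  a <- strsplit(leaves$a$alpha1, "")[[1]]
  b <- strsplit(leaves$b$alpha1, "")[[1]]
  # expectation from the transition matrix exponential (independent expm),
  # conditional on the realised root composition
  P <- oracleTransition(0.1)
  comp <- table(factor(b, levels = AA20)) / length(b)
  pExp <- sum(vapply(seq_along(AA20), function(i)
    comp[[i]] * (1 - P[i, i]), 1))
  pObs <- mean(a != b)
  expect_lt(abs(pObs - pExp), 3 * sqrt(pExp * (1 - pExp) / length(a)))
  # different seeds diverge, same alphabet
  l2 <- evolveSequences(root, tr, seed = 6, gInvariant = FALSE)
  expect_false(identical(l2$a$alpha1, leaves$a$alpha1))
})

test_that("site-rate multipliers scale realised divergence", {
  root <- list(alpha1 = simulateReference(7, 1200),
               alpha2 = simulateReference(8, 1200))
  tr <- ape::read.tree(text = "(a:0.3,b:0);")
  rates <- rep(c(0, 2), each = 1200)
  leaves <- evolveSequences(root, tr, seed = 9, gInvariant = FALSE,
                            siteRates = rates)
  a1 <- strsplit(leaves$a$alpha1, "")[[1]]
  b1 <- strsplit(leaves$b$alpha1, "")[[1]]
  expect_identical(a1, b1)                      # rate-0 sites frozen
  expect_gt(mean(strsplit(leaves$a$alpha2, "")[[1]] !=
                 strsplit(leaves$b$alpha2, "")[[1]]), 0.2)
})

test_that("fossil degradation removes whole tryptic blocks to target", {
  seqs <- list(alpha1 = simulateReference(1, 1014),
               alpha2 = simulateReference(2, 1014))
  d0 <- degradeToFossil(seqs, 0, seed = 1)
  expect_true(all(strsplit(d0$alpha1, "")[[1]] == "?"))
  d1 <- degradeToFossil(seqs, 1, seed = 1)
  expect_identical(d1$alpha1, seqs$alpha1)
  d5 <- degradeToFossil(seqs, 0.5, seed = 3)
  expect_gte(d5$coverage, 0.42)
  expect_lte(d5$coverage, 0.58)
  # coverage conservation: realised retention equals the non-'?' fraction
  obs <- mean(c(strsplit(d5$alpha1, "")[[1]],
                strsplit(d5$alpha2, "")[[1]]) != "?")
  expect_equal(obs, d5$coverage, tolerance = 1e-12)
  # lost regions are unions of tryptic blocks: every retained block is an
  # exact tryptic peptide of the parent
  dig <- rbind(cbind(chain = "alpha1", trypticDigest(seqs$alpha1, 0)),
               cbind(chain = "alpha2", trypticDigest(seqs$alpha2, 0)))
  key <- paste(dig$chain, dig$start, dig$end)
  expect_true(all(paste(d5$retained$chain, d5$retained$start,
                        d5$retained$end) %in% key))
})

test_that("PMF simulation jitters true peaks and appends decoys", {
  mh <- c(900.1, 1200.2, 2400.3)
  s0 <- simulatePmf(mh, jitterSd = 0, decoys = 0, seed = 1)
  expect_equal(peakMz(s0), mh, tolerance = 1e-12)
  s50 <- simulatePmf(mh, jitterSd = 0, decoys = 50, seed = 1)
  expect_equal(length(s50), 53L)
  expect_error(simulatePmf(mh, jitterSd = -1), ">= 0")
  expect_error(simulatePmf(c(-5, 900)), "> 0")
  # 0.05 Da jitter stays within the 0.5 Da tolerance (Gaussian tail)
  mh <- seq(800, 3400, length.out = 600)
  sj <- simulatePmf(mh, jitterSd = 0.05, decoys = 0, seed = 2)
  expect_gte(mean(abs(peakMz(sj) - mh) <= 0.5), 0.99)
})

test_that("MS/MS simulation reproduces the ladder and calibrated intensity", {
  pep <- "GPAGKDGEAGAQGPR"
  sp <- simulateMsms(pep, "ox@2", seed = 1, dropout = 0, noisePeaks = 0,
                     jitterSd = 0)
  lad <- fragmentIons(pep, "ox@2")
  expect_equal(peakMz(sp), sort(c(lad$b, lad$y)), tolerance = 1e-9)
  expect_equal(precursorMz(sp),
               unname(peptideMass(pep, "ox@2")[["mhplus"]]),
               tolerance = 1e-9)
  # default config: summed fragment intensity within the ion-count range
  for (i in 1:5) {
    spd <- simulateMsms(pep, seed = i)
    expect_gte(sum(peakIntensity(spd)), 3000)
    expect_lte(sum(peakIntensity(spd)), 5000)
  }
  expect_error(simulateMsms(""), "empty")
  # seeded determinism
  expect_identical(peakMz(simulateMsms(pep, seed = 4)),
                   peakMz(simulateMsms(pep, seed = 4)))
})

test_that("hydroxylation targets only Yaa-frame prolines", {
  # chain frame: start 4 -> peptide positions p with (4+p-1) %% 3 == 0
  pep <- "GPPGPPGPP"
  mods <- assignHydroxylations(pep, chainStart = 4, rate = 1, seed = 1)
  sites <- parseMods(mods)$site
  expect_setequal(sites, which((4 + seq_len(9) - 1) %% 3 == 0 &
                               strsplit(pep, "")[[1]] == "P"))
  expect_equal(assignHydroxylations(pep, 4, rate = 0, seed = 1), "")
})

test_that("simulation config enforces its invariants", {
  expect_error(simulationConfig(chainLengths = c(10L, 12L)), "divisible")
  expect_error(simulationConfig(targetCoverage = 1.2), "\\[0, 1\\]")
  expect_error(simulationConfig(fossilTaxon = "nope"), "not in tree")
  cfg <- simulationConfig(seed = 5)
  expect_s3_class(cfg, "SimulationConfig")
  expect_equal(ape::Ntip(cfg$tree), 11L)
})
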