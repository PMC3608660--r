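test_that("NJ is exact on additive matrices with the worked 4-taxon case", {
  m <- additiveMatrix4()
  tr <- njTree(m)
  # topology (A,B)|(C,D)
  expect_true(ape::is.monophyletic(ape::root(tr, "D"), c("A", "B")))
  # path lengths reproduce the additive input exactly
  expect_equal(ape::cophenetic.phylo(tr)[rownames(m), colnames(m)], m,
               tolerance = 1e-12)
  # edge lengths: pendants 1,2,3,4 and internal edge 1
  tip <- tr$edge[, 2] <= 4
  pend <- tr$edge.length[tip][order(tr$tip.label[tr$edge[tip, 2]])]
  expect_equal(pend, c(1, 2, 3, 4), tolerance = 1e-12)
  expect_equal(tr$edge.length[!tip], 1, tolerance = 1e-12)

  expect_error(njTree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("NJ reproduces random additive matrices exactly", {
  set.seed(17)
  for (i in 1:5) {
    tr0 <- ape::rtree(7, br = function(n) runif(n, 0.5, 2))
    m <- ape::cophenetic.phylo(tr0)
    tr <- njTree(m)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(m), colnames(m)], m,
                 tolerance = 1e-8)
  }
})

test_that("three-taxon NJ solves the three-point equations", {
  m <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- njTree(m)
  el <- tr$edge.length[order(tr$tip.label[tr$edge[, 2]])]
  expect_equal(el, c(1, 2, 4), tolerance = 1e-12)  # (ab+ac-bc)/2 etc.
})

test_that("ML distances: zero for identical, capped when saturated", {
  s <- simulateReference(1, 300)
  aln <- alignmentFromStrings(c(a = s, b = s))
  expect_equal(as.numeric(mlDistances(aln)), 0, tolerance = 1e-8)
  # maximally divergent pair saturates to the cap
  perm <- chartr("ARNDCQEGHILKMFPSTWYV", "RNDCQEGHILKMFPSTWYVA", s)
  expect_warning(d <- mlDistances(alignmentFromStrings(c(a = s, b = perm))),
                 "saturated")
  expect_equal(as.numeric(d), 5)
  # no shared observed site -> error naming the pair
  bad <- alignmentFromStrings(c(a = "AG??", b = "??GA", c = "AGGA"))
  expect_error(mlDistances(bad), "a and b")
})

test_that("pairwise ML distance agrees with a dense likelihood grid search", {
  root <- list(alpha1 = simulateReference(5, 501),
               alpha2 = simulateReference(6, 501))
  tr <- ape::read.tree(text = "(a:0.08,b:0.08);")
  lv <- evolveSequences(root, tr, seed = 7, gInvariant = FALSE)
  a <- paste0(lv$a$alpha1, lv$a$alpha2)
  b <- paste0(lv$b$alpha1, lv$b$alpha2)
  dHat <- pairwiseDistance(a, b)
  # independent two-sequence log-likelihood via an independent matrix exponential
  ia <- match(strsplit(a, "")[[1]], AA20)
  ib <- match(strsplit(b, "")[[1]], AA20)
  pi <- dayhoffFrequencies()
  ll <- function(t) {
    P <- oracleTransition(t)
    sum(log(pi[ia] * P[cbind(ia, ib)]))
  }
  grid <- seq(max(1e-4, dHat - 0.05), dHat + 0.05, by = 5e-4)
  tGrid <- grid[which.max(vapply(grid, ll, 1))]
  expect_lt(abs(dHat - tGrid), 1e-3)
})

test_that("pruning likelihood equals the exhaustive-state oracle", {
  set.seed(23)
  tlen <- c(0.12, 0.07, 0.2, 0.05, 0.09)  # a, b, c, d, internal
  seqs <- c(a = randomSequence(10), b = randomSequence(10),
            c = randomSequence(10), d = randomSequence(10))
  aln <- alignmentFromStrings(seqs)
  tr <- ape::read.tree(
    text = sprintf("((a:%g,b:%g):%g,c:%g,d:%g);",
                   tlen[1], tlen[2], tlen[5], tlen[3], tlen[4]))
  expect_equal(treeLogLik(aln, tr, k = 1),
               oracleLogLik4(seqs, tlen), tolerance = 1e-10)
  # gamma(4) averaging over equal-probability category rates
  rates <- phangorn::discrete.gamma(0.7, 4)
  expect_equal(treeLogLik(aln, tr, k = 4, shape = 0.7),
               oracleLogLik4(seqs, tlen, rates = rates), tolerance = 1e-10)
})

test_that("likelihood is invariant under re-rooting (pulley principle)", {
  root <- list(alpha1 = simulateReference(9, 120),
               alpha2 = simulateReference(10, 120))
  tr <- defaultStudyTree()
  lv <- evolveSequences(root, tr, seed = 11)
  seqs <- vapply(lv, function(x) paste0(x$alpha1, x$alpha2), "")
  aln <- alignmentFromStrings(seqs, boundary = 120)
  u <- ape::unroot(tr)
  l0 <- treeLogLik(aln, u, k = 1)
  for (og in c("aardvark", "pangolin", "outgroup")) {
    r <- ape::unroot(ape::root(u, og, resolve.root = TRUE))
    expect_equal(treeLogLik(aln, r, k = 1), l0, tolerance = 1e-8)
  }
  expect_error(treeLogLik(aln, ape::rtree(4), k = 1), "taxa")
  bad <- u; bad$edge.length[1] <- -0.1
  expect_error(treeLogLik(aln, bad, k = 1), "negative")
})

test_that("NeighborNet returns exactly the tree splits on a tree metric", {
  set.seed(29)
  tr0 <- ape::rtree(6, br = function(n) runif(n, 0.5, 2))
  ss <- splitNetwork(ape::cophenetic.phylo(tr0))
  treeSplits <- phangorn::as.splits(tr0)
  labs <- attr(treeSplits, "labels")
  canon <- function(idx, taxa) {
    side <- sort(taxa[idx])
    other <- sort(setdiff(labs, side))
    paste(if (paste(side, collapse = "|") < paste(other, collapse = "|"))
      side else other, collapse = "|")
  }
  # non-trivial tree splits with their weights
  tw <- attr(treeSplits, "weights")
  tkeys <- vapply(seq_along(treeSplits), function(i)
    canon(treeSplits[[i]], labs), "")
  nkeys <- vapply(ss@splits, function(i) canon(i, ss@taxa), "")
  nontriv <- function(keys) {
    sz <- lengths(strsplit(keys, "|", fixed = TRUE))
    keys[sz >= 2 & sz <= 4]
  }
  expect_setequal(nontriv(nkeys), unique(nontriv(tkeys)))
  # weights agree split-by-split
  for (k in nontriv(nkeys)) {
    expect_equal(ss@weights[nkeys == k][1],
                 sum(tw[tkeys == k]), tolerance = 1e-6)
  }
})

test_that("NeighborNet recovers both splits of a box metric", {
  # distance = sum of two incompatible weighted splits + pendant terms
  taxa <- c("A", "B", "C", "D")
  w1 <- 1; w2 <- 0.6   # AB|CD and AC|BD
  m <- matrix(0, 4, 4, dimnames = list(taxa, taxa))
  pend <- c(A = 0.5, B = 0.7, C = 0.4, D = 0.6)
  for (i in 1:3) for (j in (i + 1):4) {
    a <- taxa[i]; b <- taxa[j]
    d <- pend[a] + pend[b]
    if (!setequal(c(a, b), c("A", "B")) && !setequal(c(a, b), c("C", "D")))
      d <- d + w1
    if (!setequal(c(a, b), c("A", "C")) && !setequal(c(a, b), c("B", "D")))
      d <- d + w2
    m[a, b] <- m[b, a] <- d
  }
  ss <- splitNetwork(m)
  sides <- lapply(splitList(ss), sort)
  hasAB <- any(vapply(sides, function(s)
    setequal(s, c("A", "B")) || setequal(s, c("C", "D")), TRUE))
  hasAC <- any(vapply(sides, function(s)
    setequal(s, c("A", "C")) || setequal(s, c("B", "D")), TRUE))
  expect_true(hasAB && hasAC)
  expect_true(all(splitWeights(ss) > 0))
})

test_that("ML search recovers the generating 8-taxon topology", {
  tr <- ape::read.tree(text = paste0(
    "(((a:0.05,b:0.05):0.04,(c:0.05,d:0.05):0.04):0.03,",
    "((e:0.05,f:0.05):0.04,(g:0.05,h:0.05):0.04):0.03);"))
  hits <- 0L
  nrep <- 10L
  for (r in seq_len(nrep)) {
    root <- list(alpha1 = simulateReference(1000 + r, 999),
                 alpha2 = simulateReference(2000 + r, 999))
    lv <- evolveSequences(root, tr, seed = 3000 + r)
    seqs <- vapply(lv, function(x) paste0(x$alpha1, x$alpha2), "")
    fit <- mlTree(alignmentFromStrings(seqs, boundary = 999))
    same <- ape::dist.topo(ape::unroot(tr), fit$tree) == 0
    hits <- hits + as.integer(same)
  }
  expect_gte(hits / nrep, 0.9)
})

test_that("bootstrap supports are deterministic and saturate on congruent data", {
  # evolve on a well-separated 6-taxon tree: every resampled column set
  # supports the same topology
  tr <- ape::read.tree(text = paste0(
    "((a:0.04,b:0.04):0.1,((c:0.04,d:0.04):0.1,(e:0.04,f:0.04):0.1):0.05);"))
  root <- list(alpha1 = simulateReference(31, 600),
               alpha2 = simulateReference(32, 600))
  lv <- evolveSequences(root, tr, seed = 33)
  seqs <- vapply(lv, function(x) paste0(x$alpha1, x$alpha2), "")
  fit <- mlTree(alignmentFromStrings(seqs, boundary = 600))
  t1 <- bootstrapSupport(fit, nReplicates = 20, seed = 2)
  sup <- as.numeric(t1$node.label)
  expect_true(all(sup[!is.na(sup)] == 100))
  t2 <- bootstrapSupport(fit, nReplicates = 20, seed = 2)
  expect_identical(t1$node.label, t2$node.label)
})

test_that("degenerate alignments are flagged when bootstrapping", {
  # variable but parsimony-uninformative sites (singletons only)
  seqs <- c(a = "GGGGGGAGGG", b = "GGGGGGGSGG", c = "GGGGGGGGTG",
            d = "GGGGGGGGGW")
  fit <- mlTree(alignmentFromStrings(seqs))
  expect_warning(tb <- bootstrapSupport(fit, nReplicates = 5, seed = 1),
                 "degenerate")
  expect_true(attr(tb, "degenerate"))
})

test_that("monophyly queries root at the outgroup and find smallest clades", {
  tr <- defaultStudyTree()
  expect_true(checkMonophyly(tr, setdiff(tr$tip.label, "outgroup"),
                             "outgroup")$monophyletic)
  expect_true(checkMonophyly(tr, "tenrec", "outgroup")$monophyletic)
  r <- checkMonophyly(tr, c("fossil", "tenrec"), "outgroup")
  expect_true(r$monophyletic)
  r2 <- checkMonophyly(tr, c("fossil", "golden_mole"), "outgroup")
  expect_false(r2$monophyletic)
  expect_setequal(r2$clade, c("fossil", "tenrec", "golden_mole"))
  expect_error(checkMonophyly(tr, "unicorn", "outgroup"), "unknown")
})

test_that("gamma shape and branch lengths are recovered within 20%", {
  tr <- ape::read.tree(text = paste0(
    "((a:0.06,b:0.06):0.05,((c:0.06,d:0.06):0.05,(e:0.06,f:0.06):0.05):0.04);"))
  shape <- 0.6
  nsite <- 5001
  rates <- .withSeedTest(91, sample(phangorn::discrete.gamma(shape, 4),
                                    2 * nsite, replace = TRUE))
  root <- list(alpha1 = simulateReference(92, nsite),
               alpha2 = simulateReference(93, nsite))
  lv <- evolveSequences(root, tr, seed = 94, gInvariant = FALSE,
                        siteRates = rates)
  seqs <- vapply(lv, function(x) paste0(x$alpha1, x$alpha2), "")
  fit <- mlTree(alignmentFromStrings(seqs, boundary = nsite))
  expect_lt(abs(fit$shape - shape) / shape, 0.2)
  expect_lt(abs(sum(fit$tree$edge.length) - sum(tr$edge.length)) /
              sum(tr$edge.length), 0.2)
})

test_that("split systems and distances write to their exchange formats", {
  set.seed(37)
  tr0 <- ape::rtree(5, br = function(n) runif(n, 0.5, 1.5))
  m <- ape::cophenetic.phylo(tr0)
  ss <- splitNetwork(m)
  f <- tempfile(fileext = ".nex")
  writeSplitsNexus(ss, f)
  txt <- readLines(f)
  expect_true(any(grepl("BEGIN SPLITS", txt)))
  expect_true(any(grepl("CYCLE", txt)))
  back <- phangorn::read.nexus.splits(f)
  expect_equal(length(back), length(ss@splits))

  fp <- tempfile(fileext = ".phy")
  writeDistPhylip(m, fp)
  lines <- readLines(fp)
  expect_equal(as.integer(trimws(lines[1])), 5L)
  expect_equal(length(lines), 6L)
})
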