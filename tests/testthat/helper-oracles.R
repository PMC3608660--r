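# Independent oracles and fixture builders used across the suite.
# These deliberately avoid the package's own algorithms: digestion by
# exhaustive substring enumeration, likelihoods by brute-force summation
# over internal states with Matrix::expm.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.withSeedTest <- function(seed, expr) {
  set.seed(seed)
  expr
}

randomSequence <- function(n, letters = AA20) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# brute-force tryptic digestion: test every substring against the cleavage
# rule (cut after K/R unless followed by P), independent of the package's
# segment-based construction
oracleDigest <- function(seq, maxMissed) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  isCut <- function(i) i >= 1 && i < n && chars[i] %in% c("K", "R") &&
    chars[i + 1] != "P"
  out <- list()
  for (s in 1:n) for (e in s:n) {
    if (!(s == 1 || isCut(s - 1))) next
    if (!(e == n || isCut(e))) next
    internal <- if (e > s) sum(vapply(s:(e - 1), isCut, TRUE)) else 0L
    if (internal <= maxMissed)
      out[[length(out) + 1]] <- data.frame(
        seq = paste(chars[s:e], collapse = ""), start = s, end = e,
        missed = internal)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# random peptide with random valid modifications drawn from the shipped set
randomModifiedPeptide <- function(len = NULL) {
  if (is.null(len)) len <- sample(4:20, 1)
  seq <- randomSequence(len)
  v <- applyModifications(seq, maxVariable = 2L)
  i <- sample(nrow(v), 1)
  list(seq = seq, mods = v$mods[i])
}

alignmentFromStrings <- function(seqs, boundary = NULL) {
  m <- do.call(rbind, strsplit(unname(seqs), ""))
  rownames(m) <- names(seqs)
  if (is.null(boundary)) boundary <- ncol(m)
  new("ConcatAlignment", seqs = m, boundary = as.integer(boundary))
}

# Dayhoff transition matrix via Matrix::expm (Pade + scaling-squaring),
# independent of the package's spectral decomposition
oracleTransition <- function(t) {
  unname(as.matrix(Matrix::expm(dayhoffRateMatrix() * t)))
}

# Brute-force log-likelihood of a 4-taxon unrooted tree
# ((a:t1,b:t2):t5,c:t3,d:t4); summing over both internal node states.
# rates: per-category rate multipliers averaged with equal weight.
oracleLogLik4 <- function(seqs, tlen, rates = 1) {
  pi <- dayhoffFrequencies()
  idx <- lapply(seqs, function(s) match(strsplit(s, "")[[1]], AA20))
  nsite <- length(idx[[1]])
  total <- 0
  Ps <- lapply(rates, function(r) lapply(tlen, function(t)
    oracleTransition(t * r)))
  for (s in seq_len(nsite)) {
    a <- idx[[1]][s]; b <- idx[[2]][s]; cc <- idx[[3]][s]; d <- idx[[4]][s]
    lik <- 0
    for (P in Ps) {
      for (x in 1:20) for (y in 1:20) {
        lik <- lik + pi[x] * P[[1]][x, a] * P[[2]][x, b] *
          P[[5]][x, y] * P[[3]][y, cc] * P[[4]][y, d]
      }
    }
    total <- total + log(lik / length(Ps))
  }
  unname(total)
}

# additive 4-taxon matrix from the worked tree: (A,B)|(C,D), pendant edges
# 1,2,3,4 and internal edge 1
additiveMatrix4 <- function() {
  m <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  m["A", "B"] <- m["B", "A"] <- 3
  m["A", "C"] <- m["C", "A"] <- 5
  m["A", "D"] <- m["D", "A"] <- 6
  m["B", "C"] <- m["C", "B"] <- 6
  m["B", "D"] <- m["D", "B"] <- 7
  m["C", "D"] <- m["D", "C"] <- 7
  m
}
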