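# Assembly of accepted peptide-spectrum matches into partial chain
# sequences on the master coordinate system, consensus filling, isobaric
# canonicalisation and alpha1+alpha2 concatenation.

#' Convert accepted PSMs to per-site residue calls
#'
#' Each site covered by an accepted PSM receives the residue implied by its
#' best-scoring covering PSM, subject to two validation rules that mirror
#' manual spectrum interpretation:
#' \itemize{
#'   \item A residue is called only when it is delimited by matched fragment
#'     ions — both flanking b ions or both flanking y ions present (the
#'     peptide termini and the precursor count as matched boundaries). This
#'     stops mass-coincident but wrong peptides from injecting unsupported
#'     residues (\code{requireLadder = FALSE} disables it).
#'   \item Sites carrying a deamidation modification are left uncalled by
#'     default: deamidated N/Q is exactly isobaric with D/E, so the call
#'     would be unverifiable from the spectrum
#'     (\code{deamidatedAs = "database"} keeps the database residue
#'     instead).
#' }
#' An error-tolerant mass shift converts to a residue call only when the
#' shifted residue mass matches a standard residue within
#' \code{residueTol} (isoleucine/leucine ambiguity resolves to 'L'; the
#' isobaric canonicalisation step revisits this later); otherwise that site
#' stays uncalled. Equal-score conflicts at a site yield '?'.
#'
#' @param psms data.frame from \code{\link{searchSpectra}}; only rows with
#'   \code{accepted == TRUE} are used.
#' @param masterLengths Named integer vector, e.g.
#'   \code{c(alpha1 = 1014, alpha2 = 1014)}.
#' @param residueTol Tolerance (Da) for matching a shifted mass to a residue
#'   (default 0.01; smaller than the 0.036 Da K/Q gap).
#' @param requireLadder Require flanking fragment-ion support per residue
#'   (default TRUE; ignored for PSMs without \code{bMatch}/\code{yMatch}).
#' @param deamidatedAs \code{"unknown"} (default) or \code{"database"}.
#' @return data.frame with columns \code{chain}, \code{site}, \code{residue},
#'   \code{score} (support of the winning call).
#' @export
mapPsmsToSites <- function(psms, masterLengths, residueTol = 0.01,
                           requireLadder = TRUE,
                           deamidatedAs = c("unknown", "database")) {
  deamidatedAs <- match.arg(deamidatedAs)
  acc <- psms[psms$accepted, , drop = FALSE]
  if (!nrow(acc))
    return(data.frame(chain = character(), site = integer(),
                      residue = character(), score = numeric()))
  if (any(acc$start < 1L) ||
      any(acc$end > masterLengths[acc$chain]))
    stop("PSM coordinates outside the master chain lengths")
  hasFlags <- all(c("bMatch", "yMatch") %in% names(acc))
  long <- vector("list", nrow(acc))
  for (i in seq_len(nrow(acc))) {
    chars <- strsplit(acc$seq[i], "")[[1]]
    np <- length(chars)
    if (!is.na(acc$shift[i])) {
      pos <- acc$shiftPos[i]
      implied <- .RESIDUE_MASS[chars[pos]] + acc$shift[i]
      hit <- which(abs(.RESIDUE_MASS - implied) <= residueTol)
      chars[pos] <- if (length(hit) == 0L) "?"
        else if (setequal(names(.RESIDUE_MASS)[hit], c("I", "L"))) "L"
        else names(.RESIDUE_MASS)[hit[1]]
    }
    if (deamidatedAs == "unknown") {
      pm <- parseMods(acc$mods[i])
      chars[pm$site[pm$name == "deam"]] <- "?"
    }
    if (requireLadder && hasFlags && np >= 2L) {
      b <- strsplit(acc$bMatch[i], "")[[1]] == "1"   # b_1 .. b_{n-1}
      y <- strsplit(acc$yMatch[i], "")[[1]] == "1"   # y_1 .. y_{n-1}
      bOk <- c(TRUE, b) & c(b, TRUE)                 # residue i: b_{i-1}, b_i
      yOk <- rev(c(TRUE, y) & c(y, TRUE))            # residue i: y_{n-i+1}, y_{n-i}
      chars[!(bOk | yOk)] <- "?"
    }
    long[[i]] <- data.frame(chain = acc$chain[i],
                            site = acc$start[i]:acc$end[i],
                            residue = chars, score = acc$score[i])
  }
  long <- do.call(rbind, long)
  long <- long[long$residue != "?", , drop = FALSE]
  key <- paste(long$chain, long$site)
  calls <- lapply(split(long, key), function(g) {
    top <- g[g$score == max(g$score), , drop = FALSE]
    res <- unique(top$residue)
    data.frame(chain = top$chain[1], site = top$site[1],
               residue = if (length(res) > 1L) "?" else res,
               score = top$score[1])
  })
  out <- do.call(rbind, calls)
  out <- out[order(out$chain, out$site), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Column-majority consensus of aligned reference chains
#'
#' @param refs Named character vector of equal-length aligned sequences.
#' @return Single string; tied columns yield '?'.
#' @export
consensusSequence <- function(refs) {
  if (!length(refs)) stop("empty reference set")
  m <- do.call(rbind, strsplit(unname(refs), ""))
  cons <- apply(m, 2L, function(col) {
    col <- col[col != "?"]
    if (!length(col)) return("?")
    tab <- sort(table(col), decreasing = TRUE)
    if (length(tab) > 1L && tab[1] == tab[2]) "?" else names(tab)[1]
  })
  paste(cons, collapse = "")
}

#' Build a taxon's chain sequence from site calls
#'
#' Starts from an uncovered template — the reference consensus
#' (\code{fillMode = "consensus"}, used when constructing the search
#' database) or all-'?' (\code{fillMode = "unknown"}, used for
#' phylogenetics so fossil gaps enter as missing data) — and writes the
#' observed residue calls on top. Conflicted ('?') calls count as uncovered.
#'
#' @param calls data.frame from \code{\link{mapPsmsToSites}}, already
#'   restricted to one chain.
#' @param references Named character vector of aligned reference chains
#'   (required for consensus mode).
#' @param masterLength Chain length on the master coordinate system.
#' @param fillMode \code{"unknown"} or \code{"consensus"}.
#' @return Single string of length \code{masterLength}.
#' @export
buildTaxonSequence <- function(calls, references = NULL, masterLength,
                               fillMode = c("unknown", "consensus")) {
  fillMode <- match.arg(fillMode)
  if (fillMode == "consensus") {
    if (is.null(references) || !length(references))
      stop("consensus fill requires a non-empty reference set")
    base <- strsplit(consensusSequence(references), "")[[1]]
    if (length(base) != masterLength)
      stop("reference length does not match masterLength")
  } else {
    base <- rep("?", masterLength)
  }
  obs <- calls[calls$residue != "?", , drop = FALSE]
  if (nrow(obs)) {
    if (any(obs$site < 1L | obs$site > masterLength))
      stop("site calls outside the master chain length")
    base[obs$site] <- obs$residue
  }
  paste(base, collapse = "")
}

#' Canonicalise isobaric residues column-wise
#'
#' At every alignment column containing members of an isobaric set (by
#' default I/L, indistinguishable at 113.08406 Da), all members are
#' rewritten to the column's most frequent member; ties resolve to the
#' alphabetically first member and are reported via a message. Other
#' residues are untouched, so column mass content never changes.
#'
#' @param aln A \linkS4class{ConcatAlignment}.
#' @param sets List of character vectors of isobaric residues.
#' @return A \linkS4class{ConcatAlignment} with canonicalised columns; the
#'   indices of tie-broken columns are attached as attribute
#'   \code{"tieColumns"}.
#' @export
resolveIsobaric <- function(aln, sets = list(c("I", "L"))) {
  m <- siteMatrix(aln)
  ties <- integer(0)
  for (set in sets) {
    set <- sort(set)
    for (j in seq_len(ncol(m))) {
      members <- m[, j] %in% set
      if (!any(members)) next
      tab <- sort(table(factor(m[members, j], levels = set)),
                  decreasing = TRUE)
      tab <- tab[tab > 0]
      if (length(tab) > 1L && tab[1] == tab[2]) {
        winner <- sort(names(tab[tab == tab[1]]))[1]
        ties <- c(ties, j)
      } else winner <- names(tab)[1]
      m[members, j] <- winner
    }
  }
  if (length(ties))
    message("resolveIsobaric: ", length(ties),
            " tied column(s) resolved alphabetically")
  out <- new("ConcatAlignment", seqs = m, boundary = chainBoundary(aln))
  attr(out, "tieColumns") <- ties
  out
}

#' Concatenate alpha1 and alpha2 chains into a site matrix
#'
#' Builds the concatenated alignment (alpha1 columns first), padding a taxon
#' missing from one chain with an all-'?' block.
#'
#' @param a1,a2 Named character vectors of aligned chain sequences (equal
#'   lengths within each chain).
#' @return A \linkS4class{ConcatAlignment}; per-taxon coverage is available
#'   via \code{\link{coverageFraction}}.
#' @export
concatenateChains <- function(a1, a2) {
  if (anyDuplicated(names(a1)) || anyDuplicated(names(a2)))
    stop("duplicate taxon labels")
  stopifnot(length(unique(nchar(a1))) == 1L,
            length(unique(nchar(a2))) == 1L)
  l1 <- nchar(a1[1]); l2 <- nchar(a2[1])
  taxa <- union(names(a1), names(a2))
  m <- matrix("?", nrow = length(taxa), ncol = l1 + l2,
              dimnames = list(taxa, NULL))
  for (tx in taxa) {
    if (tx %in% names(a1)) m[tx, seq_len(l1)] <- strsplit(a1[[tx]], "")[[1]]
    if (tx %in% names(a2)) m[tx, l1 + seq_len(l2)] <- strsplit(a2[[tx]], "")[[1]]
  }
  new("ConcatAlignment", seqs = m, boundary = as.integer(l1))
}

#' Write aligned sequences as FASTA
#'
#' '?' (unobserved) is encoded as 'X' on disk; '-' gaps are preserved.
#'
#' @param seqs Named character vector of sequences, or a
#'   \linkS4class{ConcatAlignment}.
#' @param file Output path.
#' @export
writeAlignedFasta <- function(seqs, file) {
  if (is(seqs, "ConcatAlignment"))
    seqs <- apply(siteMatrix(seqs), 1L, paste, collapse = "")
  con <- file(file, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    writeLines(gsub("?", "X", seqs[[nm]], fixed = TRUE), con)
  }
  invisible(file)
}

#' Read aligned sequences from FASTA
#'
#' Inverse of \code{\link{writeAlignedFasta}}: 'X' is decoded to '?'.
#'
#' @param file FASTA path.
#' @return Named character vector of sequences.
#' @export
readAlignedFasta <- function(file) {
  aa <- ape::read.FASTA(file, type = "AA")
  seqs <- vapply(as.character(aa), function(x)
    paste(toupper(x), collapse = ""), "")
  gsub("X", "?", seqs, fixed = TRUE)
}

#' Per-taxon coverage report
#'
#' @param aln A \linkS4class{ConcatAlignment}.
#' @param file Optional TSV output path.
#' @return data.frame with columns \code{taxon}, \code{coverage}.
#' @export
coverageReport <- function(aln, file = NULL) {
  rep <- data.frame(taxon = alignmentTaxa(aln),
                    coverage = unname(coverageFraction(aln)))
  if (!is.null(file))
    utils::write.table(rep, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  rep
}
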