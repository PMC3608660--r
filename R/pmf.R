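# Peptide-mass-fingerprint construction, tolerance matching, cross-taxon
# similarity, and species-biomarker peptide discovery.

#' Theoretical peptide mass fingerprint
#'
#' Collapses a table of digested peptide variants to a deduplicated MH+ peak
#' list with unit intensities, restricted to the MALDI mass window.
#'
#' @param digest data.frame with an \code{mhplus} column (e.g. from
#'   \code{\link{digestVariants}}).
#' @param window MALDI m/z window, default \code{c(800, 3500)} Da.
#' @param label Spectrum label.
#' @return A \linkS4class{Spectrum} with unit intensities.
#' @export
theoreticalPmf <- function(digest, window = c(800, 3500), label = "") {
  stopifnot(nrow(digest) > 0)
  mz <- sort(digest$mhplus)
  mz <- mz[mz >= window[1] & mz <= window[2]]
  # deduplicate within 1e-6 Da
  if (length(mz) > 1L) mz <- mz[c(TRUE, diff(mz) > 1e-6)]
  if (!length(mz))
    warning("no peptides inside the MALDI window [", window[1], ", ",
            window[2], "]")
  Spectrum(mz = mz, label = label)
}

#' Match two peak lists at a mass tolerance
#'
#' Greedy nearest-neighbour matching: candidate pairs within \code{tol} are
#' accepted in order of increasing |delta m/z|, each peak used at most once.
#' This equals optimal matching whenever peak spacing exceeds twice the
#' tolerance (the collagen PMF regime).
#'
#' @param a,b \linkS4class{Spectrum} objects.
#' @param tol Match tolerance in Da (default 0.5).
#' @return data.frame with columns \code{ia}, \code{ib}, \code{mza},
#'   \code{mzb}, \code{delta}.
#' @export
matchPeakLists <- function(a, b, tol = 0.5) {
  stopifnot(tol > 0)
  mza <- peakMz(a); mzb <- peakMz(b)
  if (!length(mza) || !length(mzb))
    return(data.frame(ia = integer(), ib = integer(), mza = numeric(),
                      mzb = numeric(), delta = numeric()))
  # candidate pairs within tol
  lo <- findInterval(mza - tol, mzb)
  hi <- findInterval(mza + tol, mzb)
  cand <- do.call(rbind, lapply(seq_along(mza), function(i) {
    if (hi[i] > lo[i])
      cbind(ia = i, ib = (lo[i] + 1L):hi[i])
  }))
  if (is.null(cand) || !nrow(cand))
    return(data.frame(ia = integer(), ib = integer(), mza = numeric(),
                      mzb = numeric(), delta = numeric()))
  delta <- mza[cand[, 1]] - mzb[cand[, 2]]
  o <- order(abs(delta))
  usedA <- logical(length(mza)); usedB <- logical(length(mzb))
  keep <- logical(nrow(cand))
  for (r in o) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (!usedA[i] && !usedB[j]) {
      keep[r] <- TRUE
      usedA[i] <- TRUE
      usedB[j] <- TRUE
    }
  }
  res <- data.frame(ia = cand[keep, 1], ib = cand[keep, 2],
                    mza = mza[cand[keep, 1]], mzb = mzb[cand[keep, 2]],
                    delta = delta[keep])
  res <- res[order(res$ia), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' PMF similarity score
#'
#' Dice-type score on the number of matched peaks:
#' 2 |matches| / (|a| + |b|), symmetric and in [0, 1]. The published PMF
#' comparison was visual; this score is its quantitative stand-in.
#'
#' @inheritParams matchPeakLists
#' @return Score in [0, 1].
#' @export
pmfSimilarity <- function(a, b, tol = 0.5) {
  if (!length(peakMz(a)) || !length(peakMz(b)))
    stop("pmfSimilarity: empty spectrum")
  m <- nrow(matchPeakLists(a, b, tol))
  2 * m / (length(peakMz(a)) + length(peakMz(b)))
}

#' Species-biomarker table
#'
#' For each homologous peptide locus (peptides sharing reference coordinates
#' across taxa), partitions the taxa into groups whose MH+ values agree
#' within the tolerance; loci with more than one group discriminate taxa and
#' are flagged as biomarkers. Grouping is by sorted-gap binning: taxa fall in
#' the same group iff consecutive sorted masses differ by at most \code{tol}.
#'
#' @param masses data.frame with columns \code{taxon}, \code{locus} (a label
#'   shared by homologous peptides, e.g. "alpha2:495-509"), \code{mz}.
#' @param tol Mass tolerance in Da (default 0.5).
#' @return data.frame with one row per locus: \code{locus}, \code{nGroups},
#'   \code{biomarker} (logical) and \code{groups} (list column of character
#'   vectors of taxa, one per group).
#' @export
biomarkerTable <- function(masses, tol = 0.5) {
  stopifnot(all(c("taxon", "locus", "mz") %in% names(masses)),
            length(unique(masses$taxon)) >= 2)
  loci <- unique(masses$locus)
  rows <- lapply(loci, function(lc) {
    sub <- masses[masses$locus == lc, , drop = FALSE]
    o <- order(sub$mz)
    grp <- cumsum(c(1, diff(sub$mz[o]) > tol))
    groups <- split(sub$taxon[o], grp)
    names(groups) <- NULL
    data.frame(locus = lc, nGroups = max(grp),
               biomarker = max(grp) > 1L,
               groups = I(list(groups)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Indistinguishable taxon pairs at a biomarker locus
#'
#' Convenience accessor listing, per locus, the taxon pairs that fall in the
#' same mass group (i.e. that the locus cannot discriminate).
#'
#' @param bt Output of \code{\link{biomarkerTable}}.
#' @return data.frame with columns \code{locus}, \code{taxonA}, \code{taxonB}.
#' @export
indistinguishablePairs <- function(bt) {
  rows <- lapply(seq_len(nrow(bt)), function(i) {
    prs <- lapply(bt$groups[[i]], function(g) {
      if (length(g) >= 2) {
        cmb <- utils::combn(sort(g), 2)
        data.frame(locus = bt$locus[i], taxonA = cmb[1, ], taxonB = cmb[2, ])
      }
    })
    do.call(rbind, prs)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(locus = character(), taxonA = character(),
                      taxonB = character())
  rownames(out) <- NULL
  out
}
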