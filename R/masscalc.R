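# In-silico tryptic digestion, variable-modification enumeration, and
# monoisotopic mass arithmetic.
#
# Peptides are rows of plain data.frames. Modifications travel as compact
# strings "name@site[,name@site...]" with sites 1-based within the peptide;
# "" means unmodified.

.checkResidues <- function(sequence, allowUnknown = TRUE) {
  chars <- strsplit(sequence, "")[[1]]
  ok <- chars %in% .AA_ORDER | (allowUnknown & chars == "?")
  if (!all(ok)) {
    pos <- which(!ok)[1]
    stop("invalid residue letter '", chars[pos], "' at position ", pos)
  }
  chars
}

#' Parse a modification string
#'
#' @param mods Modification string, e.g. \code{"ox@3,deam@1"}; \code{""} or
#'   \code{NA} means unmodified.
#' @return data.frame with columns \code{name}, \code{site}, \code{delta}.
#' @export
parseMods <- function(mods) {
  if (is.na(mods) || !nzchar(mods))
    return(data.frame(name = character(), site = integer(),
                      delta = numeric()))
  parts <- strsplit(strsplit(mods, ",", fixed = TRUE)[[1]], "@", fixed = TRUE)
  tab <- collagenMods()
  name <- vapply(parts, `[`, "", 1L)
  site <- as.integer(vapply(parts, `[`, "", 2L))
  idx <- match(name, tab$name)
  if (anyNA(idx)) stop("unknown modification: ", name[which(is.na(idx))[1]])
  data.frame(name = name, site = site, delta = tab$delta[idx])
}

.formatMods <- function(name, site) {
  if (!length(name)) return("")
  o <- order(site)
  paste(paste0(name[o], "@", site[o]), collapse = ",")
}

#' Tryptic digestion with missed cleavages
#'
#' Cleaves C-terminal to K or R except when the next residue is P (Keil
#' rule), and returns every peptide with 0..\code{maxMissed} internal
#' cleavage sites together with its 1-based coordinates on the parent chain.
#' Peptides spanning any '?' (unobserved) site are flagged unobservable.
#'
#' @param sequence Chain sequence (single string; 20 amino-acid letters,
#'   optionally '?').
#' @param maxMissed Maximum internal missed cleavage sites (default 2).
#' @return data.frame with columns \code{seq}, \code{start}, \code{end},
#'   \code{missed}, \code{observable}.
#' @export
#' @examples
#' trypticDigest("AAKGGRPGGKAA", maxMissed = 0)$seq
trypticDigest <- function(sequence, maxMissed = 2L) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nzchar(sequence), maxMissed >= 0)
  chars <- .checkResidues(sequence)
  n <- length(chars)
  # cleavage after position i: K/R at i, not P at i+1
  cut <- which(chars[-n] %in% c("K", "R") & chars[-1] != "P")
  bounds <- c(0L, cut, n)                       # segment boundaries
  ns <- length(bounds) - 1L
  out <- vector("list", ns)
  for (i in seq_len(ns)) {
    jmax <- min(ns, i + maxMissed)
    j <- i:jmax
    start <- bounds[i] + 1L
    end <- bounds[j + 1L]
    out[[i]] <- data.frame(
      seq = vapply(end, function(e)
        paste(chars[start:e], collapse = ""), ""),
      start = start, end = end, missed = j - i)
  }
  res <- do.call(rbind, out)
  res$observable <- !grepl("?", res$seq, fixed = TRUE)
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Enumerate variable-modification variants of a peptide
#'
#' Enumerates every assignment of at most \code{maxVariable} modification
#' instances to their allowed sites (N-terminal pyroglutamate restricted to
#' position 1; no site carries two modifications), including the unmodified
#' form.
#'
#' @param seq Peptide sequence (string).
#' @param maxVariable Maximum number of modification instances (default 2).
#' @param mods Modification table as from \code{\link{collagenMods}}.
#' @param proOxSites Optional integer vector restricting oxidation of
#'   proline to these peptide positions (e.g. the Yaa positions of the
#'   collagen repeat, where prolyl 4-hydroxylase acts); \code{NULL} allows
#'   every proline.
#' @return data.frame with columns \code{seq}, \code{mods} (modification
#'   string), \code{nmods}, \code{deltaMass}.
#' @export
#' @examples
#' applyModifications("GPR")$mods   # "", "ox@2"
applyModifications <- function(seq, maxVariable = 2L, mods = collagenMods(),
                               proOxSites = NULL) {
  stopifnot(maxVariable >= 0)
  chars <- .checkResidues(seq, allowUnknown = FALSE)
  # candidate (site, mod) pairs, as parallel vectors
  candName <- character(); candSite <- integer(); candDelta <- numeric()
  for (m in seq_len(nrow(mods))) {
    allowed <- strsplit(mods$residues[m], "")[[1]]
    sites <- which(chars %in% allowed)
    if (mods$nterm[m]) sites <- sites[sites == 1L]
    if (mods$name[m] == "ox" && !is.null(proOxSites))
      sites <- sites[chars[sites] != "P" | sites %in% proOxSites]
    if (length(sites)) {
      candName <- c(candName, rep(mods$name[m], length(sites)))
      candSite <- c(candSite, sites)
      candDelta <- c(candDelta, rep(mods$delta[m], length(sites)))
    }
  }
  nc <- length(candName)
  pick <- list(integer(0))
  if (nc && maxVariable >= 1L) {
    for (k in seq_len(min(maxVariable, nc))) {
      combs <- utils::combn(nc, k, simplify = FALSE)
      keep <- Filter(function(ix) !anyDuplicated(candSite[ix]), combs)
      pick <- c(pick, keep)
    }
  }
  data.frame(
    seq = seq,
    mods = vapply(pick, function(ix)
      .formatMods(candName[ix], candSite[ix]), ""),
    nmods = lengths(pick),
    deltaMass = vapply(pick, function(ix) sum(candDelta[ix]), 1))
}

#' Peptide monoisotopic mass and MH+
#'
#' Neutral mass = sum of residue masses + water; MH+ = neutral mass + proton;
#' modification deltas are added on top.
#'
#' @param seq Peptide sequence.
#' @param mods Modification string (see \code{\link{parseMods}}).
#' @return Named numeric vector \code{c(neutral =, mhplus =)}.
#' @export
#' @examples
#' peptideMass("AG")[["mhplus"]]  # 147.07641
peptideMass <- function(seq, mods = "") {
  chars <- .checkResidues(seq, allowUnknown = FALSE)
  pm <- parseMods(mods)
  if (nrow(pm) && any(pm$site < 1L | pm$site > length(chars)))
    stop("modification site outside peptide")
  neutral <- sum(.RESIDUE_MASS[chars]) + .WATER + sum(pm$delta)
  c(neutral = neutral, mhplus = neutral + .PROTON)
}

#' Digest a chain and enumerate modified variants with masses
#'
#' Convenience wrapper: tryptic digestion, then per-peptide modification
#' enumeration and mass computation. Unobservable peptides (containing '?')
#' are digested but excluded from variant enumeration.
#'
#' @inheritParams trypticDigest
#' @inheritParams applyModifications
#' @param chain Chain label carried into the output (e.g. "alpha1").
#' @param proOxYaaOnly Restrict proline oxidation (hydroxyproline) to Yaa
#'   positions of the Gly-Xaa-Yaa frame, inferred from each peptide's start
#'   coordinate (default TRUE; K and M oxidation stay unrestricted). This
#'   keeps a +15.99 Da hydroxyproline variant from shadowing a genuine
#'   P -> I/L substitution (+16.03 Da) at Xaa sites under wide tolerances.
#' @return data.frame with columns \code{chain}, \code{start}, \code{end},
#'   \code{seq}, \code{missed}, \code{mods}, \code{nmods}, \code{neutral},
#'   \code{mhplus}.
#' @export
digestVariants <- function(sequence, chain = "alpha1", maxMissed = 2L,
                           maxVariable = 2L, mods = collagenMods(),
                           proOxYaaOnly = TRUE) {
  dig <- trypticDigest(sequence, maxMissed)
  dig <- dig[dig$observable, , drop = FALSE]
  if (!nrow(dig))
    return(data.frame(chain = character(), start = integer(),
                      end = integer(), seq = character(),
                      missed = integer(), mods = character(),
                      nmods = integer(), neutral = numeric(),
                      mhplus = numeric()))
  vs <- lapply(seq_len(nrow(dig)), function(i) {
    proOx <- if (proOxYaaOnly) {
      pos <- seq_len(nchar(dig$seq[i]))
      pos[(dig$start[i] + pos - 1L) %% 3L == 0L]   # Yaa frame positions
    }
    applyModifications(dig$seq[i], maxVariable = maxVariable, mods = mods,
                       proOxSites = proOx)
  })
  base <- vapply(dig$seq, function(s) peptideMass(s)[["neutral"]], 1)
  nv <- vapply(vs, nrow, 1L)
  delta <- unlist(lapply(vs, `[[`, "deltaMass"), use.names = FALSE)
  neutral <- rep(base, nv) + delta
  data.frame(chain = chain,
             start = rep(dig$start, nv), end = rep(dig$end, nv),
             seq = rep(dig$seq, nv), missed = rep(dig$missed, nv),
             mods = unlist(lapply(vs, `[[`, "mods"), use.names = FALSE),
             nmods = unlist(lapply(vs, `[[`, "nmods"), use.names = FALSE),
             neutral = neutral, mhplus = neutral + .PROTON)
}

#' Write a digest table as TSV
#'
#' @param digest data.frame as returned by \code{\link{digestVariants}}.
#' @param file Output path.
#' @export
writeDigestTable <- function(digest, file) {
  utils::write.table(digest, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
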