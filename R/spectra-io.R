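# Plain-text spectrum IO: two-column TSV peak lists (MALDI PMFs) and
# Mascot generic format (MGF) for tandem spectra. No installed R package
# reads MGF, so a minimal reader/writer for the BEGIN IONS / PEPMASS /
# CHARGE / TITLE dialect is provided here.

#' Read a two-column peak list (TSV)
#'
#' @param file Path to a TSV with columns m/z and intensity (header optional).
#' @param label Spectrum label (defaults to the file name).
#' @return A \linkS4class{Spectrum}.
#' @export
readPeakList <- function(file, label = basename(file)) {
  first <- readLines(file, n = 1L)
  header <- !grepl("^[0-9.]", trimws(first))
  tab <- utils::read.table(file, header = header, sep = "\t")
  Spectrum(mz = tab[[1]], intensity = tab[[2]], label = label)
}

#' Write a Spectrum as a two-column TSV peak list
#'
#' @param spectrum A \linkS4class{Spectrum}.
#' @param file Output path.
#' @export
writePeakList <- function(spectrum, file) {
  utils::write.table(
    data.frame(mz = peakMz(spectrum), intensity = peakIntensity(spectrum)),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read MS/MS spectra from an MGF file
#'
#' Parses BEGIN IONS/END IONS blocks with TITLE, PEPMASS and CHARGE headers;
#' PEPMASS is interpreted as the singly protonated precursor MH+ (MALDI
#' convention, charge 1+).
#'
#' @param file Path to an MGF file.
#' @return Named list of \linkS4class{Spectrum} objects.
#' @export
readMgf <- function(file) {
  lines <- readLines(file)
  begins <- grep("^BEGIN IONS", lines)
  ends <- grep("^END IONS", lines)
  if (length(begins) != length(ends))
    stop("malformed MGF: unbalanced BEGIN/END IONS in ", file)
  out <- vector("list", length(begins))
  nms <- character(length(begins))
  for (i in seq_along(begins)) {
    block <- lines[(begins[i] + 1L):(ends[i] - 1L)]
    kv <- grepl("=", block, fixed = TRUE)
    title <- sub("^TITLE=", "", grep("^TITLE=", block, value = TRUE))
    pepmass <- grep("^PEPMASS=", block, value = TRUE)
    pre <- if (length(pepmass))
      as.numeric(strsplit(sub("^PEPMASS=", "", pepmass[1]), "[ \t]")[[1]][1])
    else NA_real_
    peaks <- block[!kv & nzchar(trimws(block))]
    mzint <- do.call(rbind, lapply(strsplit(trimws(peaks), "[ \t]+"),
                                   function(x) as.numeric(x[1:2])))
    lab <- if (length(title)) title[1] else paste0("spectrum", i)
    out[[i]] <- Spectrum(mz = mzint[, 1], intensity = mzint[, 2],
                         precursorMz = pre, label = lab)
    nms[i] <- lab
  }
  names(out) <- nms
  out
}

#' Write MS/MS spectra to an MGF file
#'
#' @param spectra A \linkS4class{Spectrum} or list of them.
#' @param file Output path.
#' @export
writeMgf <- function(spectra, file) {
  if (is(spectra, "Spectrum")) spectra <- list(spectra)
  con <- file(file, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", spectrumLabel(s)), con)
    if (!is.na(precursorMz(s)))
      writeLines(paste0("PEPMASS=", format(precursorMz(s), digits = 12)), con)
    writeLines("CHARGE=1+", con)
    writeLines(paste(format(peakMz(s), digits = 12),
                     format(peakIntensity(s), digits = 8)), con)
    writeLines("END IONS", con)
  }
  invisible(file)
}
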