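#' Read an MS2 peak list
#'
#' Two supported plain-text forms: a two-column whitespace/comma-separated
#' `m/z intensity` table (precursor supplied via arguments, or on a header
#' line `# PEPMASS=<mz> CHARGE=<z>-`), and MGF-style blocks
#' (`BEGIN IONS` / `PEPMASS=` / `CHARGE=` / peak lines / `END IONS`;
#' negative polarity is assumed throughout).
#'
#' @param path File path.
#' @param precursorMz,precursorCharge Used when the file carries no
#'   precursor header.
#' @return A [GlycanSpectrum-class] (the first spectrum, for MGF files with
#'   several blocks use [readMgf()]).
#' @export
readPeakList <- function(path, precursorMz = NA_real_,
                         precursorCharge = 1L) {
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("^BEGIN IONS", lines)))
    return(readMgf(path)[[1L]])
  hdr <- grep("^#", lines, value = TRUE)
  for (h in hdr) {
    pm <- regmatches(h, regexpr("PEPMASS=([0-9.]+)", h))
    if (length(pm)) precursorMz <- as.numeric(sub("PEPMASS=", "", pm))
    cg <- regmatches(h, regexpr("CHARGE=([0-9]+)", h))
    if (length(cg)) precursorCharge <- as.integer(sub("CHARGE=", "", cg))
  }
  body <- lines[!grepl("^#|^[[:space:]]*$", lines)]
  if (length(body) == 0L)
    return(glycanSpectrum(precursorMz, precursorCharge))
  fields <- strsplit(trimws(body), "[,[:space:]]+")
  mz <- vapply(fields, function(f) as.numeric(f[1]), numeric(1))
  it <- vapply(fields, function(f)
    if (length(f) > 1L) as.numeric(f[2]) else 100, numeric(1))
  if (any(is.na(mz)))
    stop("malformed peak list line(s): ",
         paste(which(is.na(mz)), collapse = ", "))
  glycanSpectrum(precursorMz, precursorCharge, mz = mz, intensity = it)
}

#' Read MGF-style spectra
#'
#' @param path MGF file path.
#' @return List of [GlycanSpectrum-class] objects, named by TITLE when
#'   present.
#' @export
readMgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^BEGIN IONS", lines)
  ends <- grep("^END IONS", lines)
  if (length(starts) != length(ends) || any(ends < starts))
    stop("malformed MGF: unbalanced BEGIN/END IONS")
  out <- list()
  for (k in seq_along(starts)) {
    blk <- lines[(starts[k] + 1L):(ends[k] - 1L)]
    getv <- function(key) {
      h <- grep(paste0("^", key, "="), blk, value = TRUE)
      if (length(h)) sub(paste0("^", key, "="), "", h[1]) else NA_character_
    }
    pm <- as.numeric(strsplit(getv("PEPMASS"), "[[:space:]]+")[[1]][1])
    cg <- abs(as.integer(gsub("[^0-9]", "", getv("CHARGE"))))
    ttl <- getv("TITLE")
    pk <- blk[!grepl("=", blk) & nzchar(trimws(blk))]
    fields <- strsplit(trimws(pk), "[,[:space:]]+")
    mz <- vapply(fields, function(f) as.numeric(f[1]), numeric(1))
    it <- vapply(fields, function(f)
      if (length(f) > 1L) as.numeric(f[2]) else 100, numeric(1))
    sp <- glycanSpectrum(pm, if (is.na(cg)) 1L else cg, mz, it)
    out[[if (is.na(ttl)) paste0("spectrum", k) else ttl]] <- sp
  }
  out
}

#' Write a spectrum as an MGF-style block
#'
#' @param spec A [GlycanSpectrum-class].
#' @param path Output path.
#' @param title TITLE line content; negative polarity is noted.
#' @param append Append to an existing file.
#' @return `path`, invisibly.
#' @export
writeMgf <- function(spec, path, title = "glycan MS2 (negative mode)",
                     append = FALSE) {
  stopifnot(is(spec, "GlycanSpectrum"))
  pk <- peaks(spec)
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(c(
    "BEGIN IONS",
    paste0("TITLE=", title),
    paste0("PEPMASS=", sprintf("%.4f", spec@precursorMz)),
    paste0("CHARGE=", spec@precursorCharge, "-"),
    sprintf("%.4f %.1f", pk$mz, pk$intensity),
    "END IONS"
  ), con)
  invisible(path)
}
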