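# Minimal JCAMP-DX 5.00 reader/writer for 1-D NMR spectra: AFFN-encoded
# XYDATA=(X++(Y..Y)) tables with the standard FIRSTX/LASTX/XFACTOR/YFACTOR
# bookkeeping. Covers the subset this package writes plus plain AFFN files
# from other software; no compressed (SQZ/DIF/DUP) forms.

#' Write a spectrum as JCAMP-DX
#'
#' @param spectrum an \linkS4class{NMRSpectrum}.
#' @param path output file path.
#' @param title title record.
#' @return \code{path}, invisibly.
#' @export
writeJcampDx <- function(spectrum, path, title = "fluorspin spectrum") {
  x <- spectrum@axisPpm
  y <- spectrum@intensity
  n <- length(x)
  yfac <- max(abs(y)) / 32767
  if (yfac == 0) yfac <- 1
  yi <- round(y / yfac)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("##TITLE=%s", title)
  w("##JCAMP-DX=5.00")
  w("##DATA TYPE=NMR SPECTRUM")
  w("##XUNITS=PPM")
  w("##YUNITS=ARBITRARY UNITS")
  w("##.OBSERVE NUCLEUS=^%s", spectrum@params@detect)
  w("##NPOINTS=%d", n)
  w("##FIRSTX=%.10g", x[1])
  w("##LASTX=%.10g", x[n])
  w("##XFACTOR=1")
  w("##YFACTOR=%.10g", yfac)
  w("##XYDATA=(X++(Y..Y))")
  per <- 6
  for (i in seq(1, n, per)) {
    j <- min(i + per - 1, n)
    w("%s", paste(c(sprintf("%.8g", x[i]), sprintf("%d", yi[i:j])),
                  collapse = " "))
  }
  w("##END=")
  invisible(path)
}

#' Read a JCAMP-DX spectrum
#'
#' @param path file path.
#' @return an \linkS4class{NMRSpectrum} (absorption intensity only).
#' @export
readJcampDx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  field <- function(name, default = NA) {
    hit <- grep(paste0("^##", name, "="), lines, value = TRUE)
    if (!length(hit)) return(default)
    sub(paste0("^##", name, "="), "", hit[1])
  }
  npoints <- as.integer(field("NPOINTS"))
  firstx <- as.numeric(field("FIRSTX"))
  lastx <- as.numeric(field("LASTX"))
  yfac <- as.numeric(field("YFACTOR", "1"))
  xfac <- as.numeric(field("XFACTOR", "1"))
  nucleus <- sub("^\\^", "", field(".OBSERVE NUCLEUS", "1H"))
  start <- grep("^##XYDATA", lines)
  if (!length(start)) stop("no XYDATA table in ", path)
  stop_ <- grep("^##END", lines)
  stop_ <- min(stop_[stop_ > start])
  body <- lines[(start + 1):(stop_ - 1)]
  y <- numeric(0)
  for (ln in body) {
    vals <- as.numeric(strsplit(trimws(ln), "[ \t]+")[[1]])
    if (length(vals) < 2) next
    y <- c(y, vals[-1])
  }
  if (!is.na(npoints) && length(y) != npoints)
    stop("XYDATA length disagrees with NPOINTS in ", path)
  n <- length(y)
  x <- seq(firstx * xfac, lastx * xfac, length.out = n)
  params <- acquisitionParams(detect = nucleus, points = n, zerofill = n,
                              sweepPpm = abs(lastx - firstx),
                              centerPpm = (firstx + lastx) / 2)
  new("NMRSpectrum", axisPpm = x, intensity = y * yfac,
      complexIntensity = y * yfac + 0i, params = params)
}
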