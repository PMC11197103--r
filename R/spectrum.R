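# Frequency-domain processing: apodization, zero filling, Fourier transform
# and the ppm axis. The detection phase convention is that an isolated
# resonance comes out in pure absorption with zero zeroth-order phase (ideal
# pulse, zero dead time); no first-order phase is ever applied.

setValidity("NMRSpectrum", function(object) {
  if (length(object@axisPpm) != length(object@intensity))
    return("axis/intensity length mismatch")
  d <- diff(object@axisPpm)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    return("axis must be strictly monotone")
  TRUE
})

setMethod("show", "NMRSpectrum", function(object) {
  cat(sprintf("NMRSpectrum (%s): %d points, %.3f .. %.3f ppm\n",
              object@params@detect, length(object@axisPpm),
              min(object@axisPpm), max(object@axisPpm)))
})

#' Transform an FID into a spectrum
#'
#' Applies exponential apodization at the requested line broadening, zero
#' fills, discrete-Fourier transforms and attaches a ppm axis centred on the
#' carrier. The absorption intensity is the real part of the transform.
#'
#' @param fid a \linkS4class{Fid}.
#' @param params an \linkS4class{AcquisitionParams} consistent with the FID
#'   (\code{points == length(samples)}).
#' @return an \linkS4class{NMRSpectrum}.
#' @export
fidToSpectrum <- function(fid, params) {
  n <- length(fid@samples)
  if (params@points != n)
    stop("params inconsistent with fid: n_points != length(samples)")
  if (params@zerofill < n) stop("zerofill_to must be >= n_points")
  lb <- params@lineBroadening
  tgrid <- (seq_len(n) - 1) * fid@dwell
  x <- fid@samples * exp(-pi * lb * tgrid)
  xz <- c(x, complex(params@zerofill - n))
  S <- .fftshift(stats::fft(xz, inverse = TRUE))
  nz <- params@zerofill
  freqHz <- (seq_len(nz) - 1 - floor(nz / 2)) / (nz * fid@dwell)
  obs <- fid@obsMHz
  center <- fid@centerPpm
  if (is.na(obs)) obs <- 1
  if (is.na(center)) center <- 0
  axis <- center + freqHz / obs
  new("NMRSpectrum", axisPpm = axis, intensity = Re(S),
      complexIntensity = S, params = params)
}

#' Two-column text spectrum I/O
#'
#' Reads/writes a spectrum as delimited text with a ppm column and an
#' intensity column (header \code{ppm} and \code{intensity}). A leading
#' comment line preserves the acquisition metadata so the spectrum can be
#' fitted after a round trip through disk.
#'
#' @param spectrum an \linkS4class{NMRSpectrum}.
#' @param path file path.
#' @param params acquisition metadata overriding what the file carries
#'   (optional).
#' @return \code{readSpectrumText}: an \linkS4class{NMRSpectrum};
#'   \code{writeSpectrumText}: \code{path}, invisibly.
#' @export
writeSpectrumText <- function(spectrum, path) {
  p <- spectrum@params
  hdr <- sprintf(
    "# detect=%s points=%d zerofill=%d sweep_ppm=%.17g center_ppm=%.17g lb_hz=%.17g",
    p@detect, p@points, p@zerofill, p@sweepPpm, p@centerPpm,
    p@lineBroadening)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(
    data.frame(ppm = sprintf("%.17g", spectrum@axisPpm),
               intensity = sprintf("%.17g", spectrum@intensity)),
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSpectrumText
#' @export
readSpectrumText <- function(path, params = NULL) {
  first <- readLines(path, n = 1)
  tab <- utils::read.delim(path, comment.char = "#")
  if (!all(c("ppm", "intensity") %in% names(tab)))
    stop("expected columns 'ppm' and 'intensity' in ", path)
  if (is.null(params)) {
    if (startsWith(first, "#")) {
      kv <- regmatches(first, gregexpr("[a-z_]+=[^ ]+", first))[[1]]
      meta <- stats::setNames(
        lapply(kv, function(s) sub("^[a-z_]+=", "", s)),
        sub("=.*$", "", kv))
      params <- acquisitionParams(
        detect = meta$detect,
        points = as.integer(meta$points),
        zerofill = as.integer(meta$zerofill),
        sweepPpm = as.numeric(meta$sweep_ppm),
        centerPpm = as.numeric(meta$center_ppm),
        lineBroadening = as.numeric(meta$lb_hz))
    } else {
      params <- acquisitionParams(points = nrow(tab), zerofill = nrow(tab),
                                  sweepPpm = abs(diff(range(tab$ppm))),
                                  centerPpm = mean(range(tab$ppm)))
    }
  }
  new("NMRSpectrum", axisPpm = tab$ppm, intensity = tab$intensity,
      complexIntensity = tab$intensity + 0i, params = params)
}
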