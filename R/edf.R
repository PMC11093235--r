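# Minimal EDF (European Data Format) reader/writer.
#
# Supports the plain-EDF subset this package needs: 16-bit samples, 1-second
# data records, one physical-range calibration per signal. Annotations travel
# as sidecar CSVs (see io.R), not as EDF+ annotation channels.

.edfPad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop(sprintf("EDF header field too long: '%s'", x))
  formatC(x, width = -width, flag = " ")
}

# Format a number into an 8-char EDF header field and return the value that
# the field will parse back to, so digitization uses the on-disk calibration.
.edfNum <- function(x) {
  s <- NULL
  for (d in 7:1) {
    cand <- formatC(signif(x, d), format = "g", digits = d, width = -1)
    if (nchar(cand) <= 8) { s <- cand; break }
  }
  if (is.null(s)) {
    for (d in 2:0) {
      cand <- formatC(x, format = "e", digits = d, width = -1)
      if (nchar(cand) <= 8) { s <- cand; break }
    }
  }
  if (is.null(s)) stop(sprintf("cannot represent %g in an 8-char EDF field", x))
  list(text = .edfPad(s, 8), value = as.numeric(s))
}

#' Write signals to an EDF file
#'
#' Low-level writer: each signal is digitized to 16 bits over a physical range
#' covering its extrema, in 1-second data records. All signals must span an
#' integer number of seconds and share the same total duration.
#'
#' @param path output file path.
#' @param signals named list of numeric vectors.
#' @param rates numeric vector of per-signal sampling rates (Hz, integer).
#' @param units character vector of physical dimension labels (e.g. `"uV"`).
#' @param patientID,recordingID free-text EDF header fields.
#' @return `path`, invisibly.
#' @seealso [writePSG()] for the PSGRecord-level interface.
#' @export
writeEDF <- function(path, signals, rates, units = NULL,
                     patientID = "X", recordingID = "Startdate X") {
  ns <- length(signals)
  stopifnot(ns > 0, length(rates) == ns, !is.null(names(signals)))
  units <- units %||% rep("", ns)
  if (any(rates <= 0 | rates != round(rates))) {
    stop("sampling rates must be positive integers (1-s records)")
  }
  durs <- vapply(seq_len(ns), function(i) length(signals[[i]]) / rates[i], numeric(1))
  if (max(durs) - min(durs) > 1e-9 || abs(durs[1] - round(durs[1])) > 1e-9) {
    stop("all signals must span the same integer number of seconds")
  }
  nrec <- as.integer(round(durs[1]))

  # symmetric physical range +/- c*10^k with two significant digits: always
  # representable in the 8-char header fields and always covers the extrema
  phys <- lapply(seq_len(ns), function(i) {
    x <- signals[[i]]
    if (any(!is.finite(x))) {
      stop(sprintf("signal '%s' contains non-finite values", names(signals)[i]))
    }
    m <- max(abs(x), 1e-9)
    k <- floor(log10(m)) - 1
    top <- ceiling(m / 10^k) * 10^k
    pmax <- .edfNum(top); pmin <- .edfNum(-top)
    if (pmin$value > min(x) || pmax$value < max(x)) {
      stop(sprintf("signal '%s' exceeds representable physical range", names(signals)[i]))
    }
    list(pmin = pmin, pmax = pmax)
  })

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wr(.edfPad("0", 8))
  wr(.edfPad(patientID, 80))
  wr(.edfPad(recordingID, 80))
  wr(.edfPad("01.01.00", 8))
  wr(.edfPad("00.00.00", 8))
  wr(.edfPad(256 * (ns + 1), 8))
  wr(.edfPad("", 44))
  wr(.edfPad(nrec, 8))
  wr(.edfPad("1", 8))
  wr(.edfPad(ns, 4))
  for (i in seq_len(ns)) wr(.edfPad(names(signals)[i], 16))
  for (i in seq_len(ns)) wr(.edfPad("", 80))
  for (i in seq_len(ns)) wr(.edfPad(units[i], 8))
  for (i in seq_len(ns)) wr(phys[[i]]$pmin$text)
  for (i in seq_len(ns)) wr(phys[[i]]$pmax$text)
  for (i in seq_len(ns)) wr(.edfPad(-32768, 8))
  for (i in seq_len(ns)) wr(.edfPad(32767, 8))
  for (i in seq_len(ns)) wr(.edfPad("", 80))
  for (i in seq_len(ns)) wr(.edfPad(rates[i], 8))
  for (i in seq_len(ns)) wr(.edfPad("", 32))

  dig <- lapply(seq_len(ns), function(i) {
    pmin <- phys[[i]]$pmin$value; pmax <- phys[[i]]$pmax$value
    d <- round((signals[[i]] - pmin) / (pmax - pmin) * 65535 - 32768)
    as.integer(.clamp(d, -32768, 32767))
  })
  # interleave per 1-s record
  idx <- lapply(rates, function(r) seq_len(r))
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      off <- (r - 1) * rates[i]
      writeBin(dig[[i]][off + idx[[i]]], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @return list with `signals` (named list of numeric vectors), `rates` (Hz),
#'   `units`, and `header` (patient/recording fields, record count).
#' @export
readEDF <- function(path) {
  if (!file.exists(path)) stop(sprintf("EDF file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  version <- rd(8)
  patientID <- rd(80); recordingID <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  nrec <- as.integer(rd(8))
  recdur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns <= 0) stop("malformed EDF header (signal count)")
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  units <- vapply(seq_len(ns), function(i) rd(8), character(1))
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)

  total_per_rec <- sum(spr)
  raw <- readBin(con, integer(), n = total_per_rec * nrec, size = 2,
                 signed = TRUE, endian = "little")
  if (length(raw) < total_per_rec * nrec) stop("EDF data section truncated")
  signals <- vector("list", ns)
  offs <- cumsum(c(0, spr))
  for (i in seq_len(ns)) {
    take <- unlist(lapply(seq_len(nrec) - 1L, function(r) {
      r * total_per_rec + offs[i] + seq_len(spr[i])
    }))
    gain <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    signals[[i]] <- (raw[take] - dmin[i]) * gain + pmin[i]
  }
  names(signals) <- labels
  list(signals = signals, rates = spr / recdur, units = units,
       header = list(version = version, patientID = patientID,
                     recordingID = recordingID, nRecords = nrec,
                     recordDuration = recdur))
}
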