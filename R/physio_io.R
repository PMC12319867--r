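#' Read a physiological trace from a BIDS-style TSV (+ JSON sidecar)
#'
#' Reads a single-column or labeled-column TSV (optionally gzip-compressed)
#' holding one uniformly sampled physiological signal. The sampling rate is
#' taken from the JSON sidecar (key `SamplingFrequency`; `StartTime` and
#' `Columns` are honoured when present) or, failing that, from the `fs`
#' argument. A bare two-column (time, value) file is also accepted: the rate
#' is then inferred from the time column.
#'
#' @param path TSV or TSV.GZ file path.
#' @param sidecar optional JSON sidecar path. If `NULL`, a file named like
#'   `path` with a `.json` extension is used when it exists.
#' @param column column name (or index) to read when the file has several.
#' @param fs fallback sampling rate in Hz when no sidecar is available.
#' @param units declared units of the signal.
#' @param provenance provenance tag stored on the trace.
#' @return A [PhysioTrace-class]. No resampling is performed.
#' @export
readPhysio <- function(path, sidecar = NULL, column = 1L, fs = NULL,
                       units = "arbitrary", provenance = "unknown") {
  if (!file.exists(path)) stop("physio file not found: ", path)
  if (is.null(sidecar)) {
    guess <- sub("\\.tsv(\\.gz)?$", ".json", path)
    if (guess != path && file.exists(guess)) sidecar <- guess
  }
  t0 <- 0
  colnames_sc <- NULL
  if (!is.null(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(sc$SamplingFrequency)) fs <- as.numeric(sc$SamplingFrequency)
    if (!is.null(sc$StartTime)) t0 <- as.numeric(sc$StartTime)
    if (!is.null(sc$Columns)) colnames_sc <- as.character(sc$Columns)
    if (!is.null(sc$Units)) units <- as.character(sc$Units)
    if (!is.null(sc$Provenance)) provenance <- as.character(sc$Provenance)
  }

  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con), add = TRUE)
  lines <- readLines(con)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty physio file: ", path)

  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- NULL
  first <- suppressWarnings(as.numeric(fields[[1]]))
  if (anyNA(first)) { # header row
    header <- trimws(fields[[1]])
    fields <- fields[-1]
    row_offset <- 1L
  } else {
    header <- colnames_sc
    row_offset <- 0L
  }
  ncol_file <- length(fields[[1]])
  mat <- suppressWarnings(vapply(fields, function(f) as.numeric(f[seq_len(ncol_file)]),
    numeric(ncol_file)
  ))
  mat <- if (ncol_file == 1L) matrix(mat, nrow = 1) else mat
  bad <- which(apply(mat, 2, anyNA))
  if (length(bad)) {
    stop(sprintf("non-numeric value in physio file %s at row %d", path, bad[1] + row_offset))
  }

  ci <- column
  if (is.character(column)) {
    if (is.null(header)) stop("column name given but file has no header/Columns: ", column)
    ci <- match(column, header)
    if (is.na(ci)) stop("column not found in physio file: ", column)
  }
  # bare (time, value) fallback: two columns, first strictly increasing & no
  # sampling rate declared
  if (is.null(fs) && ncol_file == 2L && is.null(header)) {
    tcol <- mat[1, ]
    if (all(diff(tcol) > 0)) {
      fs <- 1 / stats::median(diff(tcol))
      t0 <- tcol[1]
      ci <- 2L
    }
  }
  if (is.null(fs)) {
    stop("sampling rate unavailable: provide a sidecar with SamplingFrequency or the fs argument")
  }
  physioTrace(mat[ci, ], fs = fs, units = units, t0 = t0, provenance = provenance)
}

#' Write a physiological trace as TSV + JSON sidecar
#'
#' @param trace a [PhysioTrace-class].
#' @param path output TSV path (`.gz` suffix triggers gzip compression).
#' @param sidecar output JSON path; default replaces the TSV extension.
#' @param column column label recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
writePhysio <- function(trace, path, sidecar = NULL, column = "signal") {
  if (is.null(sidecar)) sidecar <- sub("\\.tsv(\\.gz)?$", ".json", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  writeLines(format(trace@samples, digits = 17, trim = TRUE, scientific = FALSE), con)
  close(con)
  jsonlite::write_json(
    list(
      SamplingFrequency = trace@fs, StartTime = trace@t0,
      Columns = list(column), Units = trace@units,
      Provenance = trace@provenance, ConvolvedWith = trace@convolvedWith
    ),
    sidecar,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Convert a CO2 trace from volts to mmHg
#'
#' Applies the gas-analyzer calibration `mmHg = gain * volts + offset`.
#'
#' @param trace a [PhysioTrace-class] with units `"volts"`.
#' @param gain mmHg per volt (> 0).
#' @param offset additive offset in mmHg.
#' @return The calibrated trace with units `"mmHg"`.
#' @export
voltsToMmHg <- function(trace, gain, offset = 0) {
  stopifnot(is(trace, "PhysioTrace"))
  if (trace@units != "volts") {
    stop("voltsToMmHg: input trace units are '", trace@units, "', expected 'volts'")
  }
  if (gain <= 0) stop("gain must be > 0")
  out <- trace
  out@samples <- gain * trace@samples + offset
  out@units <- "mmHg"
  out
}

#' Resample a trace by linear interpolation
#'
#' Resamples onto a uniform grid at `fsOut` starting at the trace's `t0`.
#' End-tidal and RVT series are themselves piecewise-linear interpolants of
#' sparse points, so linear resampling introduces no new extrema.
#'
#' @param trace a [PhysioTrace-class].
#' @param fsOut output sampling rate, Hz (> 0).
#' @return The resampled [PhysioTrace-class]; duration preserved to within
#'   one output sample.
#' @export
resampleTrace <- function(trace, fsOut) {
  stopifnot(is(trace, "PhysioTrace"))
  if (!is.finite(fsOut) || fsOut <= 0) stop("fsOut must be > 0")
  if (isTRUE(all.equal(fsOut, trace@fs))) return(trace)
  tin <- traceTimes(trace)
  n_out <- floor((length(trace@samples) - 1) / trace@fs * fsOut) + 1
  tout <- trace@t0 + (seq_len(n_out) - 1) / fsOut
  out <- trace
  out@samples <- stats::approx(tin, trace@samples, xout = tout, rule = 2)$y
  out@fs <- fsOut
  out
}

#' Read / write a NIfTI volume
#'
#' Thin wrappers over RNifti used by the mapping module for 4D BOLD series,
#' masks and output maps.
#'
#' @param path NIfTI file path.
#' @return `readVolume()` returns a plain numeric array with an attached
#'   `pixdim` attribute; `writeVolume()` returns `path`, invisibly.
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attr(arr, "pixdim") <- RNifti::pixdim(img)
  arr
}

#' @rdname readVolume
#' @param arr numeric array (3D or 4D).
#' @param pixdim voxel dimensions (mm; 4th entry = TR in s for 4D data).
#' @export
writeVolume <- function(arr, path, pixdim = NULL) {
  a <- arr
  attr(a, "pixdim") <- NULL
  img <- RNifti::asNifti(a)
  if (!is.null(pixdim)) RNifti::pixdim(img) <- pixdim
  RNifti::writeNifti(img, path)
  invisible(path)
}
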