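# MS1 run model and mzML I/O (via mzR), plus retention-time filtering and
# resolution-aware spectrum averaging.

#' Construct an MS run
#'
#' @param scans List of scans; each scan is a list with `rt` (minutes),
#'   `mz` (strictly ascending), `intensity` (same length, non-negative).
#' @param metadata Named list of run metadata (e.g. `resolution`,
#'   `mz_range`).
#' @return An `ms_run` object.
#' @export
ms_run <- function(scans, metadata = list()) {
  if (!length(scans)) stop("an ms_run needs at least one scan")
  rt <- vapply(scans, `[[`, 0, "rt")
  if (is.unsorted(rt)) stop("scan retention times must be non-decreasing")
  for (s in scans) {
    if (length(s$mz) != length(s$intensity)) {
      stop("mz and intensity arrays differ in length")
    }
    if (length(s$mz) > 1L && any(diff(s$mz) <= 0)) {
      stop("mz array must be strictly ascending")
    }
    if (any(s$intensity < 0)) stop("negative intensity")
  }
  structure(list(scans = scans, metadata = metadata), class = "ms_run")
}

#' @export
print.ms_run <- function(x, ...) {
  rt <- scan_times(x)
  cat(sprintf("<ms_run> %d MS1 scans, rt %.2f-%.2f min\n",
              length(x$scans), min(rt), max(rt)))
  invisible(x)
}

#' Retention times of all scans
#'
#' @param run An `ms_run`.
#' @return Numeric vector, minutes.
#' @export
scan_times <- function(run) vapply(run$scans, `[[`, 0, "rt")

#' Read MS1 scans from an mzML file
#'
#' Loads all MS1 spectra (higher MS levels are skipped) with retention
#' times converted to minutes.
#'
#' @param path mzML file.
#' @return An `ms_run`.
#' @export
read_run <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hd <- mzR::header(fh)
  ms1 <- which(hd$msLevel == 1L)
  if (!length(ms1)) stop("no MS1 scans in ", path)
  scans <- lapply(ms1, function(i) {
    pk <- mzR::peaks(fh, i)
    list(rt = hd$retentionTime[i] / 60, mz = pk[, 1L], intensity = pk[, 2L])
  })
  meta <- list()
  if (all(is.finite(hd$scanWindowLowerLimit[ms1]))) {
    meta$mz_range <- c(min(hd$scanWindowLowerLimit[ms1]),
                       max(hd$scanWindowUpperLimit[ms1]))
  }
  ms_run(scans, metadata = meta)
}

#' Write an MS run to mzML
#'
#' Writes standards-conformant mzML (centroid MS1 spectra) readable by
#' common parsers; lossless for centroid data within float precision.
#'
#' @param run An `ms_run`.
#' @param path Output file path.
#' @export
write_run <- function(run, path) {
  n <- length(run$scans)
  mzr <- run$metadata$mz_range %||% c(NA_real_, NA_real_)
  hd <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L,
    peaksCount = vapply(run$scans, function(s) length(s$mz), 0L),
    totIonCurrent = vapply(run$scans, function(s) sum(s$intensity), 0),
    retentionTime = scan_times(run) * 60,
    basePeakMZ = vapply(run$scans, function(s) {
      if (length(s$mz)) s$mz[which.max(s$intensity)] else 0
    }, 0),
    basePeakIntensity = vapply(run$scans, function(s) {
      if (length(s$intensity)) max(s$intensity) else 0
    }, 0),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(run$scans, function(s) {
      if (length(s$mz)) min(s$mz) else 0
    }, 0),
    highMZ = vapply(run$scans, function(s) {
      if (length(s$mz)) max(s$mz) else 0
    }, 0),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = mzr[1L], scanWindowUpperLimit = mzr[2L],
    stringsAsFactors = FALSE
  )
  pk <- lapply(run$scans, function(s) cbind(mz = s$mz, intensity = s$intensity))
  mzR::writeMSData(pk, file = path, header = hd)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scan indices inside a half-open retention-time window
#'
#' Windows follow the half-open convention `[start, end)`: a scan exactly
#' at `end` is excluded, so adjacent windows never double-count.
#'
#' @param run An `ms_run`.
#' @param rt_window Numeric `c(start, end)` in minutes.
#' @return Integer vector of scan indices.
#' @export
scans_in_window <- function(run, rt_window) {
  rt <- scan_times(run)
  which(rt >= rt_window[1L] & rt < rt_window[2L])
}

#' Average spectra over a retention-time window
#'
#' Sums scan intensities on a common m/z grid of resolution-aware bins:
#' bin width is (m/z)/R divided by 4 (fourfold oversampling of the peak
#' width), i.e. a logarithmic grid. The result is linear in intensities
#' and invariant to scan order. Each output m/z is the intensity-weighted
#' centroid of its bin.
#'
#' @param run An `ms_run`.
#' @param rt_window Half-open `[start, end)` window, minutes.
#' @param resolution Resolving power defining the bin width (default
#'   17500, the acquisition setting this workflow targets).
#' @return A `spectrum`: list with `mz` and `intensity`.
#' @export
average_spectrum <- function(run, rt_window, resolution = 17500) {
  idx <- scans_in_window(run, rt_window)
  if (!length(idx)) stop("retention-time window contains no scans")
  mz <- unlist(lapply(run$scans[idx], `[[`, "mz"))
  it <- unlist(lapply(run$scans[idx], `[[`, "intensity"))
  if (!length(mz)) {
    return(structure(list(mz = numeric(0), intensity = numeric(0)),
                     class = "spectrum"))
  }
  # logarithmic grid: bin k covers mz0 * (1 + 1/(4R))^[k, k+1)
  w <- log1p(1 / (4 * resolution))
  bin <- floor(log(mz) / w)
  o <- order(bin)
  bin <- bin[o]; mz <- mz[o]; it <- it[o]
  grp <- cumsum(c(1L, diff(bin) != 0))
  sum_i <- rowsum(it, grp)[, 1L]
  wmz <- rowsum(mz * it, grp)[, 1L]
  ctr <- ifelse(sum_i > 0, wmz / sum_i,
                rowsum(mz, grp)[, 1L] / tabulate(grp))
  keep <- sum_i > 0
  structure(list(mz = unname(ctr[keep]), intensity = unname(sum_i[keep])),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d centroids", length(x$mz)))
  if (length(x$mz)) cat(sprintf(", m/z %.1f-%.1f", min(x$mz), max(x$mz)))
  cat("\n")
  invisible(x)
}
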