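# EICC quantitation: theoretical m/z series, extracted ion current
# chromatograms, trapezoidal integration, fractional abundances, glycan
# quality attributes, and replicate confidence intervals.

PROTON_MASS <- 1.007276466

#' Theoretical m/z of a proton adduct
#'
#' Positive-mode `[M + zH]^z+`: `(mass + z * 1.007276) / z`.
#'
#' @param mass Neutral mass in Da (> 0).
#' @param z Positive integer charge(s).
#' @return m/z in Th (vectorized over `z`).
#' @export
theoretical_mz <- function(mass, z) {
  if (any(z < 1) || any(z != round(z))) stop("charge must be a positive integer")
  if (any(mass <= 0)) stop("mass must be positive")
  (mass + z * PROTON_MASS) / z
}

#' Quantitation configuration
#'
#' @param charges Integer charge range used for extraction (default
#'   22:32, which keeps a ~147 kDa antibody inside m/z 2500-8000).
#' @param tol_ppm Extraction tolerance in ppm (default 50).
#' @param tol_mz Absolute extraction tolerance floor in Th (default 0.4;
#'   the wider of the two wins). The floor covers the width of the
#'   unresolved isotope envelope of an intact mAb at this resolving
#'   power; it is kept below 0.5 Th because library species separated by
#'   the lysine/hexose composition difference (~34 Da) approach 1.06 Th
#'   spacing at z = 32, and wider windows would cross-assign their
#'   signal.
#' @param mz_range Usable acquisition range; charges whose theoretical
#'   m/z leaves it are dropped with a warning.
#' @param rt_windows Optional named list of half-open `[start, end)`
#'   retention-time windows (minutes), one per variant group; NULL means
#'   auto-windowing at quantitation time.
#' @return A `quant_config` list.
#' @export
quant_config <- function(charges = 22:32, tol_ppm = 50, tol_mz = 0.4,
                         mz_range = c(2500, 8000), rt_windows = NULL) {
  stopifnot(all(charges >= 1), tol_ppm > 0 || tol_mz > 0)
  structure(list(charges = as.integer(charges), tol_ppm = tol_ppm,
                 tol_mz = tol_mz, mz_range = mz_range,
                 rt_windows = rt_windows),
            class = "quant_config")
}

usable_charges <- function(mass, config, warn = TRUE) {
  mz <- theoretical_mz(mass, config$charges)
  ok <- mz >= config$mz_range[1L] & mz <= config$mz_range[2L]
  if (warn && any(!ok)) {
    warning(sprintf("dropping charge(s) %s: m/z outside [%g, %g]",
                    paste(config$charges[!ok], collapse = ","),
                    config$mz_range[1L], config$mz_range[2L]),
            call. = FALSE)
  }
  config$charges[ok]
}

#' Extract an ion current chromatogram
#'
#' For every scan, sums the intensity of all centroids lying within the
#' extraction tolerance (the wider of `tol_ppm` and `tol_mz`) of any
#' theoretical m/z of the species across the configured charge states.
#' Charges falling outside the acquisition m/z range are dropped with a
#' warning.
#'
#' @param run An `ms_run`.
#' @param mass Neutral (average) mass of the proteoform in Da.
#' @param config A [quant_config()].
#' @param label Species label attached to the chromatogram.
#' @return A `chromatogram`: list with `rt`, `intensity`, `label`,
#'   `charges`.
#' @export
extract_eicc <- function(run, mass, config = quant_config(), label = "") {
  z <- usable_charges(mass, config)
  if (!length(z)) stop("no usable charges for mass ", mass)
  centers <- theoretical_mz(mass, z)
  tol <- pmax(config$tol_ppm * 1e-6 * centers, config$tol_mz)
  lo <- centers - tol
  hi <- centers + tol
  intensity <- vapply(run$scans, function(s) {
    if (!length(s$mz)) return(0)
    i1 <- findInterval(lo, s$mz) + 1L
    i2 <- findInterval(hi, s$mz)
    tot <- 0
    for (k in seq_along(i1)) {
      if (i2[k] >= i1[k]) tot <- tot + sum(s$intensity[i1[k]:i2[k]])
    }
    tot
  }, 0)
  structure(list(rt = scan_times(run), intensity = intensity,
                 label = label, charges = z),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram> %s: %d points, z %s, max %.3g\n",
              if (nzchar(x$label)) x$label else "(unnamed)",
              length(x$rt), paste(range(x$charges), collapse = "-"),
              if (length(x$intensity)) max(x$intensity) else 0))
  invisible(x)
}

#' Integrate a chromatogram over a retention-time window
#'
#' Trapezoidal integral of intensity over rt, with the trace linearly
#' interpolated at the window edges so the half-open `[start, end)`
#' convention splits the total area exactly between adjacent windows.
#'
#' @param chrom A `chromatogram`.
#' @param rt_window Numeric `c(start, end)` minutes; must overlap the
#'   trace.
#' @return Area in intensity * minutes.
#' @export
integrate_eicc <- function(chrom, rt_window) {
  lo <- max(rt_window[1L], min(chrom$rt))
  hi <- min(rt_window[2L], max(chrom$rt))
  if (hi <= lo) stop("retention-time window does not overlap chromatogram")
  inside <- chrom$rt > lo & chrom$rt < hi
  rt <- c(lo, chrom$rt[inside], hi)
  it <- c(stats::approx(chrom$rt, chrom$intensity, lo)$y,
          chrom$intensity[inside],
          stats::approx(chrom$rt, chrom$intensity, hi)$y)
  sum(diff(rt) * (utils::head(it, -1L) + utils::tail(it, -1L)) / 2)
}

#' Fractional abundances from integrated areas
#'
#' Each fraction is `area / sum(areas)` over the quantified set, so the
#' result is invariant under global intensity scaling and sums to 1.
#'
#' @param areas Named numeric vector of areas (>= 1 positive entry).
#' @return Tibble with `label`, `area`, `fraction`.
#' @export
fractional_abundances <- function(areas) {
  if (!length(areas) || all(areas <= 0)) stop("need at least one positive area")
  if (any(areas < 0)) stop("negative area")
  tibble::tibble(label = names(areas) %||% as.character(seq_along(areas)),
                 area = as.numeric(areas),
                 fraction = as.numeric(areas) / sum(areas))
}

#' Automatic retention-time windows from EICC apexes
#'
#' Fits a Gaussian around the apex of each species' EICC (moment fit on
#' the points above 10% of apex) and proposes `apex +/- 3 sigma` windows;
#' overlapping windows are merged. Used when no windows are configured.
#'
#' @param run An `ms_run`.
#' @param masses Numeric vector of species masses.
#' @param config A [quant_config()].
#' @return Named list of `c(start, end)` windows, ordered by apex rt.
#' @export
auto_rt_windows <- function(run, masses, config = quant_config()) {
  props <- lapply(masses, function(m) {
    ch <- extract_eicc(run, m, config)
    if (max(ch$intensity) <= 0) return(NULL)
    top <- ch$intensity >= 0.1 * max(ch$intensity)
    mu <- sum(ch$rt[top] * ch$intensity[top]) / sum(ch$intensity[top])
    sg <- sqrt(sum((ch$rt[top] - mu)^2 * ch$intensity[top]) /
                 sum(ch$intensity[top]))
    sg <- max(sg, diff(range(ch$rt)) / length(ch$rt))  # >= one scan interval
    c(mu - 3 * sg, mu + 3 * sg, apex = max(ch$intensity))
  })
  props <- props[!vapply(props, is.null, TRUE)]
  if (!length(props)) stop("no species produced signal; cannot auto-window")
  props <- props[order(vapply(props, `[`, 0, 1L))]
  wins <- list(props[[1L]][1:2])
  for (p in props[-1L]) {
    last <- wins[[length(wins)]]
    if (p[1L] < last[2L]) {
      wins[[length(wins)]] <- c(last[1L], max(last[2L], p[2L]))
    } else {
      wins[[length(wins) + 1L]] <- p[1:2]
    }
  }
  stats::setNames(wins, paste0("window_", seq_along(wins)))
}

#' Quantify a proteoform library on an MS run
#'
#' The core semi-quantitation step: per retention-time window, extracts
#' one EICC per library entry, integrates it, and converts areas to
#' fractional abundances over the window's quantified set.
#'
#' @param run An `ms_run`.
#' @param library A [build_library()] tibble.
#' @param config A [quant_config()]; if `config$rt_windows` is NULL a
#'   single window spanning the whole run is used.
#' @return Tibble: one row per (window, proteoform) with `window`,
#'   `label`, `area`, `fraction`, plus the library's class-flag columns.
#' @export
quantify_run <- function(run, library, config = quant_config()) {
  wins <- config$rt_windows
  if (is.null(wins)) {
    rt <- scan_times(run)
    wins <- list(all = c(min(rt), max(rt) + 1e-9))
  }
  if (is.null(names(wins))) names(wins) <- paste0("window_", seq_along(wins))
  out <- list()
  for (wn in names(wins)) {
    areas <- vapply(seq_len(nrow(library)), function(i) {
      ch <- extract_eicc(run, library$avg[i], config, label = library$label[i])
      integrate_eicc(ch, wins[[wn]])
    }, 0)
    fa <- fractional_abundances(stats::setNames(pmax(areas, 0), library$label))
    fa$window <- wn
    fa <- cbind(fa, library[, c("glycan_pair", "nlys", "gal_count", "is_main",
                                "is_sialylated", "is_afucosylated",
                                "is_oligomannose")])
    out[[wn]] <- fa
  }
  tibble::as_tibble(do.call(rbind, out))
}

#' Galactosylation level of the main glycoforms
#'
#' Weighted galactose occupancy over the four possible galactose sites of
#' the fucosylated biantennary glycan pair set (G0F/G0F ... G2F/G2F):
#' `100 * sum(fraction_i * gal_i) / (4 * sum(fraction_i))`. The isobaric
#' combined pair counts 2 galactoses, which is identical under either
#' reading of its label. The normalizing set is selectable: `"main"`
#' (default) restricts to the fucosylated biantennary pairs, `"all"` uses
#' every entry carrying a galactose count.
#'
#' @param abundance A [quantify_run()] tibble (single window).
#' @param scope `"main"` or `"all"`.
#' @return Percent in [0, 100].
#' @export
galactosylation_level <- function(abundance, scope = c("main", "all")) {
  scope <- match.arg(scope)
  sel <- if (scope == "main") {
    abundance$is_main & !is.na(abundance$gal_count)
  } else {
    !is.na(abundance$gal_count)
  }
  if (!any(sel)) stop("no glycoforms in the galactosylation scope")
  a <- abundance$fraction[sel]
  g <- abundance$gal_count[sel]
  100 * sum(a * g) / (4 * sum(a))
}

#' Aggregate fraction of a glycoform class
#'
#' @param abundance A [quantify_run()] tibble (single window).
#' @param class One of `"sialylated"`, `"afucosylated"`,
#'   `"oligomannose"`, or a logical vector / predicate function over the
#'   abundance rows.
#' @return Percent in [0, 100].
#' @export
class_fraction <- function(abundance, class) {
  sel <- if (is.character(class)) {
    abundance[[paste0("is_", match.arg(class, c("sialylated", "afucosylated",
                                                "oligomannose")))]]
  } else if (is.function(class)) {
    vapply(seq_len(nrow(abundance)), function(i) isTRUE(class(abundance[i, ])), TRUE)
  } else {
    as.logical(class)
  }
  100 * sum(abundance$fraction[sel])
}

#' t-based confidence interval over replicate measurements
#'
#' Mean and `t_{1-(1-conf)/2, n-1} * s / sqrt(n)` halfwidth; for the
#' default triplicate at 95%, t = 4.3027.
#'
#' @param values Replicate values (n >= 2; typically 3).
#' @param conf Confidence level (default 0.95).
#' @return Named numeric `c(mean, halfwidth)`.
#' @export
triplicate_ci <- function(values, conf = 0.95) {
  n <- length(values)
  if (n < 2L) stop("need at least two replicates")
  tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1L)
  c(mean = mean(values), halfwidth = tq * stats::sd(values) / sqrt(n))
}
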