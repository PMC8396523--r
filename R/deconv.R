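# Simplified zero-charge deconvolution and glycosylation-pattern
# mass-shift detection.
#
# The deconvolution here is deliberately a transparent grid-projection
# scorer, NOT a reimplementation of vendor sliding-window algorithms: for
# each candidate neutral mass it collects, per charge state, the most
# intense centroid near the theoretical m/z, down-weighted linearly with
# distance. Score peaks are picked above a robust noise floor and refined
# by centroiding, which is what delivers ppm-level mass accuracy from a
# coarse (Da-level) grid.

#' Zero-charge deconvolution of a spectrum
#'
#' Projects a multiply-charged spectrum onto a neutral-mass grid. The
#' score at mass M is the sum over charges of the best matching centroid
#' intensity within tolerance of `theoretical_mz(M, z)`, tapered
#' linearly with m/z distance. Peaks are local maxima above
#' `median + noise_k * MAD` of the score trace; each reported mass is the
#' score-weighted centroid of the contiguous region above half the local
#' apex.
#'
#' @param spectrum A `spectrum` (or any list with `mz`, `intensity`).
#' @param mass_grid `c(lo, hi, step)` in Da; step should be well below
#'   the expected peak spacing (default step 1 Da for ~150 kDa species
#'   separated by >= 100 Da).
#' @param charges Integer charge states to project (default 22:32).
#' @param tol_ppm,tol_mz Matching tolerance (wider of the two; defaults
#'   25 ppm, 0.2 Th).
#' @param noise_k MAD multiplier for the noise floor (default 3).
#' @param rel_floor Additional relative floor as a fraction of the
#'   maximum score (default 0.001); score traces are mostly zero for
#'   sparse centroid data, where median + MAD alone admits every stray
#'   charge coincidence as a peak.
#' @param min_support Minimum number of charge states that must
#'   contribute before a mass can score (default 3). A real species is
#'   supported by its whole envelope, whereas the wrong-charge ghost of
#'   a peak (apparent mass M*z'/z) is supported by a single charge;
#'   gating on support removes these ghost ridges.
#' @return Tibble `mass`, `score` with masses ascending (zero rows if
#'   the spectrum is empty or featureless).
#' @export
deconvolute <- function(spectrum, mass_grid = c(140000, 155000, 1),
                        charges = 22:32, tol_ppm = 25, tol_mz = 0.2,
                        noise_k = 3, rel_floor = 0.001, min_support = 3) {
  if (!length(charges)) stop("empty charge range")
  empty <- tibble::tibble(mass = numeric(0), score = numeric(0))
  if (!length(spectrum$mz)) return(empty)
  step <- mass_grid[3L]
  grid <- seq(mass_grid[1L], mass_grid[2L], by = step)
  ng <- length(grid)
  score <- numeric(ng)
  support <- integer(ng)
  mz <- spectrum$mz
  it <- spectrum$intensity
  for (z in charges) {
    # project each centroid into the neutral-mass domain at this charge:
    # a triangular contribution of half-width tol*z around mz*z - z*mp
    tol <- pmax(tol_ppm * 1e-6 * mz, tol_mz)
    m0 <- mz * z - z * PROTON_MASS
    hw <- tol * z
    k1 <- pmax(1L, as.integer(ceiling((m0 - hw - grid[1L]) / step)) + 1L)
    k2 <- pmin(ng, as.integer(floor((m0 + hw - grid[1L]) / step)) + 1L)
    span <- k2 - k1 + 1L
    use <- which(span > 0L)
    if (!length(use)) next
    cells <- sequence(span[use], from = k1[use])
    pt <- rep.int(use, span[use])
    w <- 1 - abs(grid[cells] - m0[pt]) / hw[pt]
    val <- it[pt] * w
    # per grid cell, keep the best-matching centroid (max contribution)
    o <- order(cells, -val)
    first <- !duplicated(cells[o])
    contrib <- numeric(ng)
    contrib[cells[o][first]] <- val[o][first]
    score <- score + contrib
    support <- support + (contrib > 0)
  }
  score[support < min_support] <- 0
  if (all(score <= 0)) return(empty)
  floor_ <- max(stats::median(score) + noise_k * stats::mad(score),
                rel_floor * max(score))
  n <- length(score)
  is_max <- score > floor_ &
    score >= c(-Inf, score[-n]) & score > c(score[-1L], -Inf)
  apexes <- which(is_max)
  if (!length(apexes)) return(empty)
  peaks <- lapply(apexes, function(a) {
    half <- score[a] / 2
    l <- a; while (l > 1L && score[l - 1L] >= half && score[l - 1L] <= score[l]) l <- l - 1L
    r <- a; while (r < n && score[r + 1L] >= half && score[r + 1L] <= score[r]) r <- r + 1L
    reg <- l:r
    c(mass = sum(grid[reg] * score[reg]) / sum(score[reg]), score = score[a])
  })
  res <- do.call(rbind, peaks)
  res <- res[order(res[, "mass"]), , drop = FALSE]
  # merge refinements that collapsed onto the same mass (within one step)
  keep <- c(TRUE, diff(res[, "mass"]) > mass_grid[3L])
  res <- res[keep, , drop = FALSE]
  tibble::tibble(mass = res[, "mass"], score = res[, "score"])
}

#' Detect a constant mass shift between two peak patterns
#'
#' Searches an offset grid for the shift delta maximizing the matched
#' overlap between a reference and a query zero-charge peak list: peak
#' scores are normalized to unit sum, reference peaks are greedily
#' matched in descending score order (each peak used once) to the
#' highest-scoring unused query peak within `tol` of `mass_ref + delta`,
#' and the offset score is the sum of `min(score_ref, score_query)` over
#' matches — 1.0 for a perfectly conserved, purely shifted pattern. Only
#' grid offsets near some pairwise mass difference are evaluated (all
#' others score 0). The winning offset is refined to the score-weighted
#' mean of the matched residuals, snapped back to the grid, so the
#' reported shift is not limited by the `tol`-wide score plateau.
#'
#' @param reference,query Tibbles with `mass`, `score` (e.g. from
#'   [deconvolute()]).
#' @param offset_grid `c(lo, hi, step)` Da; default -600..600 step 0.05.
#' @param tol Match tolerance in Da (default 0.5, average-mass domain).
#' @return List with `offset` (Da), `score` in [0, 1], `n_matched`, and
#'   the `grid` spec searched.
#' @export
detect_pattern_shift <- function(reference, query,
                                 offset_grid = c(-600, 600, 0.05),
                                 tol = 0.5) {
  if (!nrow(reference) || !nrow(query)) stop("empty peak list")
  if (offset_grid[2L] <= offset_grid[1L] || offset_grid[3L] <= 0) {
    stop("invalid offset grid")
  }
  mr <- reference$mass; sr <- reference$score / sum(reference$score)
  mq <- query$mass;     sq <- query$score / sum(query$score)
  step <- offset_grid[3L]
  diffs <- as.vector(outer(mq, mr, `-`))
  diffs <- diffs[diffs >= offset_grid[1L] - tol & diffs <= offset_grid[2L] + tol]
  snap <- function(x) offset_grid[1L] + round((x - offset_grid[1L]) / step) * step
  cand <- sort(unique(unlist(lapply(diffs, function(d) {
    snap(seq(d - tol, d + tol, by = step))
  }))))
  cand <- cand[cand >= offset_grid[1L] & cand <= offset_grid[2L]]
  if (!length(cand)) {
    return(list(offset = snap(0), score = 0, n_matched = 0L,
                grid = offset_grid))
  }
  ord <- order(sr, decreasing = TRUE)
  match_at <- function(delta) {
    used <- logical(length(mq))
    sc <- 0; nm <- 0L; resid <- 0; wsum <- 0
    for (i in ord) {
      ok <- which(!used & abs(mq - (mr[i] + delta)) <= tol)
      if (!length(ok)) next
      j <- ok[which.max(sq[ok])]
      used[j] <- TRUE
      w <- min(sr[i], sq[j])
      sc <- sc + w
      nm <- nm + 1L
      resid <- resid + w * (mq[j] - mr[i])
      wsum <- wsum + w
    }
    list(score = sc, n = nm, shift = if (wsum > 0) resid / wsum else delta)
  }
  best <- list(offset = cand[1L], score = -1, n_matched = 0L)
  for (delta in cand) {
    m <- match_at(delta)
    if (m$score > best$score) {
      best <- list(offset = delta, score = m$score, n_matched = m$n,
                   refined = m$shift)
    }
  }
  best$offset <- min(max(snap(best$refined), offset_grid[1L]), offset_grid[2L])
  best$refined <- NULL
  best$score <- min(best$score, 1)
  best$grid <- offset_grid
  best
}
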