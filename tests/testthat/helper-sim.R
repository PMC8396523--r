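# Shared fixtures, built in code and cached per test file.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Noise-free copy-product preset run (three lysine groups).
clean_copy_sim <- function() {
  cached("clean_copy", {
    cfg <- preset_rituximab_like(noise_cv = 0, jitter_ppm = 0,
                                 baseline_rate = 0, seed = 3)
    sim <- simulate_run(cfg)
    sim$config <- cfg
    sim$library <- attr(cfg, "library")
    sim
  })
}

# Retention-time windows bracketing the three lysine groups of the preset.
k_windows <- function() {
  list(`0K` = c(7.6, 10.2), `1K` = c(9.2, 11.7), `2K` = c(10.7, 13.2))
}

# Recovered within-group fractions for one lysine group, renormalized
# over that group's species, aligned to the simulated truth.
group_recovery <- function(tab, truth, kn) {
  w <- tab[tab$window == kn, ]
  sel <- grepl(paste0("^", kn), w$label)
  rec <- w$fraction[sel] / sum(w$fraction[sel])
  names(rec) <- w$label[sel]
  tr <- truth[grepl(paste0("^", kn), truth$label), ]
  tr$group_fraction <- tr$fraction / sum(tr$fraction)
  # simulated labels are plain; library labels may be isobar-merged
  idx <- vapply(tr$label, function(l) {
    grep(l, names(rec), fixed = TRUE)[1L]
  }, 0L)
  tr$recovered <- unname(rec[idx])
  tr
}

# Renormalized single-group abundance table (for attribute computation).
group_table <- function(tab, kn) {
  w <- tab[tab$window == kn, ]
  w <- w[grepl(paste0("^", kn), w$label), ]
  w$fraction <- w$fraction / sum(w$fraction)
  w
}

# Brute-force Riemann integration oracle on a piecewise-linear trace.
riemann_area <- function(rt, intensity, window, n = 20000L) {
  lo <- max(window[1L], min(rt)); hi <- min(window[2L], max(rt))
  x <- seq(lo, hi, length.out = n)
  y <- stats::approx(rt, intensity, x)$y
  sum(y) * (hi - lo) / n
}
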