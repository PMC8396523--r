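# Synthetic native LC-MS run generator with known proteoform ground
# truth. Emulates the qualitative behavior of cation-exchange separation
# of an intact antibody: variant-class retention shifts (sialylated
# glycoforms elute earlier, oligomannose later, C-terminal lysine
# variants later as separate groups), Gaussian charge-state envelopes,
# multiplicative intensity noise, ppm-level m/z jitter, and a sparse
# random baseline. Centroid-mode output; isotopic fine structure is not
# simulated — the unresolved envelope is subsumed in the centroid, which
# matches the average-mass bookkeeping of the quantitation side.

#' Simulated proteoform component
#'
#' @param label Species label (should match a library label for
#'   recovery studies).
#' @param mass Neutral average mass, Da.
#' @param fraction True fractional abundance in [0, 1].
#' @param rt Chromatographic peak center, minutes.
#' @param rt_sigma Gaussian peak width (sigma), minutes.
#' @param z0,z_sigma Center and sigma of the Gaussian charge-state
#'   envelope.
#' @return A `sim_component` list.
#' @export
sim_component <- function(label, mass, fraction, rt, rt_sigma = 0.10,
                          z0 = 26, z_sigma = 2) {
  stopifnot(mass > 0, fraction >= 0, fraction <= 1, rt_sigma > 0, z_sigma > 0)
  structure(list(label = label, mass = mass, fraction = fraction, rt = rt,
                 rt_sigma = rt_sigma, z0 = z0, z_sigma = z_sigma),
            class = "sim_component")
}

#' Simulation configuration
#'
#' @param components List of [sim_component()]; fractions must sum to 1.
#' @param rt_range Run span `c(start, end)` in minutes.
#' @param scan_interval Seconds between MS1 scans (default 2 s — a slow
#'   duty cycle consistent with 10 microscans at long injection times).
#' @param resolution Resolving power setting (default 17500).
#' @param mz_range Acquisition m/z range (default `c(2500, 8000)`).
#' @param noise_cv Multiplicative (log-normal, mean-preserving) intensity
#'   noise CV (default 0.05).
#' @param jitter_ppm Gaussian m/z jitter sigma in ppm (default 10).
#' @param baseline_rate Poisson mean of random baseline centroids per
#'   scan (default 20).
#' @param baseline_intensity Mean (exponential) baseline centroid
#'   intensity (default 100, i.e. ~3 orders below a main-species apex at
#'   the default scale).
#' @param scale Total ion current scale factor (default 1e6).
#' @param seed Integer RNG seed; the same seed reproduces the run
#'   exactly.
#' @return A `sim_config` list.
#' @export
sim_config <- function(components, rt_range = c(7.5, 13.5),
                       scan_interval = 2, resolution = 17500,
                       mz_range = c(2500, 8000), noise_cv = 0.05,
                       jitter_ppm = 10, baseline_rate = 20,
                       baseline_intensity = 100, scale = 1e6, seed = 1L) {
  stopifnot(scan_interval > 0, length(components) >= 1)
  fr <- vapply(components, `[[`, 0, "fraction")
  if (abs(sum(fr) - 1) > 1e-9) {
    stop("component fractions must sum to 1 (got ", sum(fr), ")")
  }
  rts <- vapply(components, `[[`, 0, "rt")
  if (any(rts < rt_range[1L] | rts > rt_range[2L])) {
    stop("component retention-time centers must lie within rt_range")
  }
  structure(list(components = components, rt_range = rt_range,
                 scan_interval = scan_interval, resolution = resolution,
                 mz_range = mz_range, noise_cv = noise_cv,
                 jitter_ppm = jitter_ppm, baseline_rate = baseline_rate,
                 baseline_intensity = baseline_intensity, scale = scale,
                 seed = as.integer(seed)),
            class = "sim_config")
}

component_charges <- function(cp) {
  z <- seq.int(max(1L, floor(cp$z0 - 3 * cp$z_sigma)),
               ceiling(cp$z0 + 3 * cp$z_sigma))
  w <- stats::dnorm(z, cp$z0, cp$z_sigma)
  list(z = z, w = w / sum(w))
}

#' Simulate an MS1 run with known ground truth
#'
#' Per scan at time t and component i, the total component ion current is
#' `scale * fraction_i * N(t; rt_i, rt_sigma_i)`, split over charge
#' states by a normalized Gaussian envelope; each (component, charge)
#' yields one centroid at the proton-adduct m/z with ppm-level jitter and
#' mean-preserving log-normal intensity noise. Charges whose m/z leaves
#' the acquisition range are discarded. Deterministic under the seed.
#'
#' @param config A [sim_config()].
#' @return List with `run` (an `ms_run`) and `truth` (tibble `label`,
#'   `mass`, `fraction`, `rt`; attributes `seed` and `config_hash`).
#' @export
simulate_run <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  rts <- seq(config$rt_range[1L], config$rt_range[2L],
             by = config$scan_interval / 60)
  comps <- config$components
  envs <- lapply(comps, component_charges)
  sdlog <- config$noise_cv
  scans <- withr::with_seed(config$seed, lapply(rts, function(t) {
    mz_all <- numeric(0)
    it_all <- numeric(0)
    for (i in seq_along(comps)) {
      cp <- comps[[i]]
      amp <- config$scale * cp$fraction * stats::dnorm(t, cp$rt, cp$rt_sigma)
      if (amp < config$scale * 1e-9) next
      ev <- envs[[i]]
      mz0 <- theoretical_mz(cp$mass, ev$z)
      keep <- mz0 >= config$mz_range[1L] & mz0 <= config$mz_range[2L]
      if (!any(keep)) next
      nz <- sum(keep)
      jit <- if (config$jitter_ppm > 0) {
        1 + stats::rnorm(nz, 0, config$jitter_ppm * 1e-6)
      } else 1
      noise <- if (sdlog > 0) {
        exp(stats::rnorm(nz, -sdlog^2 / 2, sdlog))
      } else 1
      mz_all <- c(mz_all, mz0[keep] * jit)
      it_all <- c(it_all, amp * ev$w[keep] * noise)
    }
    if (config$baseline_rate > 0) {
      nb <- stats::rpois(1L, config$baseline_rate)
      if (nb > 0) {
        mz_all <- c(mz_all, stats::runif(nb, config$mz_range[1L],
                                         config$mz_range[2L]))
        it_all <- c(it_all, stats::rexp(nb, 1 / config$baseline_intensity))
      }
    }
    o <- order(mz_all)
    mz_all <- mz_all[o]; it_all <- it_all[o]
    if (length(mz_all) > 1L) {
      dup <- c(FALSE, diff(mz_all) <= 0)
      if (any(dup)) {  # collapse coincident centroids
        grp <- cumsum(!dup)
        it_all <- rowsum(it_all, grp)[, 1L]
        mz_all <- mz_all[!dup]
      }
    }
    list(rt = t, mz = mz_all, intensity = it_all)
  }))
  truth <- tibble::tibble(
    label = vapply(comps, `[[`, "", "label"),
    mass = vapply(comps, `[[`, 0, "mass"),
    fraction = vapply(comps, `[[`, 0, "fraction"),
    rt = vapply(comps, `[[`, 0, "rt")
  )
  attr(truth, "seed") <- config$seed
  attr(truth, "config_hash") <- rlang::hash(unclass(config))
  run <- ms_run(scans, metadata = list(resolution = config$resolution,
                                       mz_range = config$mz_range))
  list(run = run, truth = truth)
}

# Within-group glycoform distributions. Each is a named vector over the
# nine simulated glycan pairs summing to 1. The "copy"-product defaults
# carry the lysine-variant-resolved character: the 0K group richer in
# oligomannose and slightly more galactosylated than 1K/2K.
glycoform_pairs_default <- c(
  g0 = "A2G0F/A2G0F", g1 = "A2G0F/A2G1F", g2 = "A2G1F/A2G1F",
  g3 = "A2G1F/A2G2F", g4 = "A2G2F/A2G2F",
  m5 = "M5/M5", afuc = "A2G0/A2G0F",
  sia1 = "A2G1F/A2S1G1F", sia2 = "A2G1F/A2S2F"
)

group_fractions_copy <- list(
  `0` = c(g0 = 0.9169 * 0.3298, g1 = 0.9169 * 0.4000, g2 = 0.9169 * 0.2050,
          g3 = 0.9169 * 0.0500, g4 = 0.9169 * 0.0152,
          m5 = 0.0324, afuc = 0.0428, sia1 = 0.0056, sia2 = 0.0023),
  `1` = c(g0 = 0.9386 * 0.3735, g1 = 0.9386 * 0.4000, g2 = 0.9386 * 0.1750,
          g3 = 0.9386 * 0.0420, g4 = 0.9386 * 0.0095,
          m5 = 0.0107, afuc = 0.0428, sia1 = 0.0056, sia2 = 0.0023),
  `2` = c(g0 = 0.9400 * 0.3743, g1 = 0.9400 * 0.4000, g2 = 0.9400 * 0.1750,
          g3 = 0.9400 * 0.0420, g4 = 0.9400 * 0.0087,
          m5 = 0.0093, afuc = 0.0428, sia1 = 0.0056, sia2 = 0.0023)
)

group_fractions_originator <- list(
  `0` = c(g0 = 0.9687 * 0.2158, g1 = 0.9687 * 0.3950, g2 = 0.9687 * 0.2750,
          g3 = 0.9687 * 0.0950, g4 = 0.9687 * 0.0192,
          m5 = 0.0045, afuc = 0.0044, sia1 = 0.0160, sia2 = 0.0064)
)

# Class-dependent retention offsets (minutes) relative to the group
# center: sialylated glycoforms elute earlier (one sialic acid ~ -0.68,
# two ~ -1.35), oligomannose slightly later (+0.21), galactosylation
# degree has no effect.
rt_offsets_default <- c(g0 = 0, g1 = 0, g2 = 0, g3 = 0, g4 = 0,
                        m5 = 0.21, afuc = 0,
                        sia1 = -0.68, sia2 = -1.35)

#' Rituximab-like simulation preset
#'
#' Builds a ready-to-run [sim_config()] over a realistic intact-antibody
#' proteoform set: five fucosylated biantennary main glycoform pairs
#' (the Delta-162.14 galactose ladder), an oligomannose pair (M5/M5), an
#' afucosylated pair, and mono-/di-sialylated pairs, replicated over
#' C-terminal lysine groups (Delta+128.17 each) at class-shifted
#' retention times. `product = "copy"` (default) yields three lysine
#' groups (0K/1K/2K) with lysine-variant-dependent glycosylation;
#' `product = "originator"` a single fully des-lysine group with higher
#' galactosylation and sialylation and little oligomannose.
#'
#' @param product `"copy"` or `"originator"`.
#' @param chains Antibody chains (default: bundled rituximab fixture).
#' @param k_weights Relative weight of the 0K/1K/2K groups (copy default
#'   `c(0.45, 0.35, 0.20)`).
#' @param rt_centers Group retention centers in minutes (default 9.5,
#'   11.0, 12.5 for 0K/1K/2K).
#' @param group_fractions Optional named list (per lysine count, names
#'   "0"/"1"/"2") of within-group glycoform fractions over the nine pair
#'   slots g0..g4, m5, afuc, sia1, sia2; each must sum to 1.
#' @param seed RNG seed forwarded to the config.
#' @param ... Further arguments to [sim_config()] (noise levels etc.).
#' @return A `sim_config` whose attribute `"library"` holds the matching
#'   [build_library()] tibble.
#' @export
preset_rituximab_like <- function(product = c("copy", "originator"),
                                  chains = read_chains(rituximab_fasta()),
                                  k_weights = NULL,
                                  rt_centers = c(`0` = 9.5, `1` = 11.0,
                                                 `2` = 12.5),
                                  group_fractions = NULL, seed = 1L, ...) {
  product <- match.arg(product)
  if (is.null(group_fractions)) {
    group_fractions <- switch(product, copy = group_fractions_copy,
                              originator = group_fractions_originator)
  }
  if (is.null(k_weights)) {
    k_weights <- switch(product,
                        copy = c(`0` = 0.45, `1` = 0.35, `2` = 0.20),
                        originator = c(`0` = 1))
  }
  k_weights <- k_weights / sum(k_weights)
  ks <- as.integer(names(group_fractions))
  lib <- build_library(chains, as.list(unname(glycoform_pairs_default)),
                       lysine_variants = ks)
  comps <- list()
  for (kn in names(group_fractions)) {
    gf <- group_fractions[[kn]]
    stopifnot(abs(sum(gf) - 1) < 1e-9)
    for (slot in names(glycoform_pairs_default)) {
      pair <- glycoform_pairs_default[[slot]]
      arms <- normalize_pair(pair)
      label <- paste0(kn, "K ", paste(arms, collapse = "/"))
      row <- match(label, lib$label)
      if (is.na(row)) stop("preset label not in library: ", label)
      frac <- k_weights[[kn]] * gf[[slot]]
      if (frac <= 0) next
      comps[[length(comps) + 1L]] <- sim_component(
        label = label, mass = lib$avg[row], fraction = frac,
        rt = rt_centers[[kn]] + rt_offsets_default[[slot]]
      )
    }
  }
  cfg <- sim_config(comps, seed = seed, ...)
  attr(cfg, "library") <- lib
  cfg
}
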