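# Proteoform library: chain sequences x glycan pairs x C-terminal lysine
# variants x optional modification deltas, with theoretical masses and
# glycan-class flags, plus ppm annotation of observed masses.

#' Read antibody chain sequences from FASTA
#'
#' @param path FASTA file with one record per chain (e.g. heavy and light).
#' @return Named character vector of amino-acid sequences; names are the
#'   first word of each FASTA header.
#' @export
read_chains <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[`, "", 1L)
  seqs
}

#' Bundled rituximab chain fixture
#'
#' Path to the editable heavy/light chain FASTA shipped with the package
#' (public-record rituximab sequences). Absolute proteoform masses depend
#' on this fixture; all delta-mass logic (lysine ladder, glycan ladders,
#' truncations) does not.
#'
#' @return File path.
#' @export
rituximab_fasta <- function() .pkg_file("extdata", "rituximab.fasta")

# Base composition of the intact 2HC+2LC antibody with zero C-terminal
# lysines. A heavy chain ending in K is clipped so lysine variants count
# up from 0K. Each disulfide removes two hydrogens; pyroGlu (-NH3) is
# applied to every chain starting with Gln when pyroglu = TRUE.
mab_base_composition <- function(heavy, light, disulfides = 16L,
                                 pyroglu = TRUE) {
  clip <- function(s) sub("K$", "", s)
  heavy0 <- clip(heavy)
  total <- 2L * sequence_composition(heavy0, water = TRUE) +
    2L * sequence_composition(light, water = TRUE)
  total <- total - comp(H = 2L * disulfides)
  if (pyroglu) {
    n_pg <- sum(startsWith(c(heavy, heavy, light, light), "Q"))
    if (n_pg > 0) total <- total + n_pg * mod_registry()[["pyroglu"]]$delta
  }
  total
}

normalize_pair <- function(pair) {
  if (is.character(pair) && length(pair) == 1L) {
    pair <- strsplit(pair, "/", fixed = TRUE)[[1]]
  }
  if (length(pair) != 2L) stop("a glycan pair needs exactly two labels")
  sort(pair)  # unordered: (X,Y) == (Y,X)
}

arm_flags <- function(g) {
  list(
    fuc_bi = g[["HexNAc"]] == 4L && g[["Fuc"]] >= 1L && g[["NeuAc"]] == 0L,
    oligo  = g[["HexNAc"]] == 2L,
    # oligomannose arms carry no core fucose by construction and are
    # reported in their own class, so they do not count as afucosylated
    afuc   = g[["Fuc"]] == 0L && g[["HexNAc"]] > 2L,
    sial   = g[["NeuAc"]] >= 1L,
    gal    = g[["Hex"]] - 3L
  )
}

#' Build a proteoform library
#'
#' Enumerates the cartesian product of glycan pairs, C-terminal lysine
#' counts and optional extra modification deltas on top of the intact
#' antibody backbone, computing theoretical monoisotopic and average
#' masses and glycan-class flags for each species. Entries with identical
#' elemental composition (e.g. the isobaric A2G1F/A2G1F and A2G0F/A2G2F
#' pairs) are merged into one row with a combined label, since no
#' mass-based method can separate them.
#'
#' @param chains Named character vector with elements `heavy` and `light`
#'   (or the first two records of [read_chains()] output, heavy first).
#' @param glycan_pairs List of pairs, each either `c("A2G0F","A2G1F")` or
#'   a single `"A2G0F/A2G1F"` string. Pairs are unordered.
#' @param lysine_variants Integer vector of C-terminal lysine counts
#'   (default `0:2` for 0K/1K/2K).
#' @param extra_deltas Optional list of [mod_delta()] applied to *every*
#'   member in addition (each delta multiplies the library).
#' @param disulfides Number of disulfide bonds (2 H subtracted per bond);
#'   default 16 for an intact IgG1.
#' @param pyroglu Cyclize N-terminal Gln to pyroglutamate on every chain
#'   starting with Q? Default TRUE.
#' @param custom_glycans Named list of `glycan_comp` for labels outside
#'   the Oxford grammar.
#' @param merge_isobars Merge entries with identical composition? Default
#'   TRUE.
#' @return A tibble sorted by average mass with columns `label`,
#'   `glycan_pair`, `nlys`, `mono`, `avg`, `gal_count` (NA outside the
#'   fucosylated biantennary main set), `is_main`, `is_sialylated`,
#'   `is_afucosylated`, `is_oligomannose`, and a `composition` list
#'   column of `elem_comp`.
#' @export
build_library <- function(chains, glycan_pairs, lysine_variants = 0:2,
                          extra_deltas = NULL, disulfides = 16L,
                          pyroglu = TRUE, custom_glycans = NULL,
                          merge_isobars = TRUE) {
  if (!length(glycan_pairs)) stop("glycan pair list is empty")
  if (is.character(glycan_pairs)) glycan_pairs <- as.list(glycan_pairs)
  nm <- names(chains)
  heavy <- if ("heavy" %in% nm) chains[["heavy"]] else chains[[1L]]
  light <- if ("light" %in% nm) chains[["light"]] else chains[[2L]]
  base <- mab_base_composition(heavy, light, disulfides = disulfides,
                               pyroglu = pyroglu)
  lys <- residue_table()[["K"]]

  deltas <- c(list(mod_delta("", comp())), extra_deltas)
  rows <- list()
  for (pair in glycan_pairs) {
    arms <- normalize_pair(pair)
    g1 <- glycan_from_name(arms[1L], custom = custom_glycans)
    g2 <- glycan_from_name(arms[2L], custom = custom_glycans)
    f1 <- arm_flags(g1); f2 <- arm_flags(g2)
    pair_label <- paste(arms, collapse = "/")
    glyco <- base + glycan_to_composition(g1) + glycan_to_composition(g2)
    is_main <- f1$fuc_bi && f2$fuc_bi
    for (nk in lysine_variants) {
      for (d in deltas) {
        cmp <- glyco + nk * lys + d$delta
        label <- paste0(nk, "K ", pair_label,
                        if (nzchar(d$name)) paste0(" ", d$name) else "")
        m <- mass_of(cmp)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          label = label,
          glycan_pair = pair_label,
          nlys = as.integer(nk),
          mods = d$name,
          mono = m$mono,
          avg = m$avg,
          gal_count = if (is_main) as.integer(f1$gal + f2$gal) else NA_integer_,
          is_main = is_main,
          is_sialylated = f1$sial || f2$sial,
          is_afucosylated = f1$afuc || f2$afuc,
          is_oligomannose = f1$oligo && f2$oligo,
          composition = list(cmp)
        )
      }
    }
  }
  lib <- do.call(rbind, rows)
  if (merge_isobars) {
    key <- vapply(lib$composition, format, "")
    if (anyDuplicated(key)) {
      keep <- !duplicated(key)
      merged_label <- vapply(key[keep], function(k) {
        labs <- lib$label[key == k]
        if (length(labs) > 1L) paste(labs, collapse = "|") else labs
      }, "")
      lib <- lib[keep, ]
      lib$label <- merged_label
    }
  }
  lib <- lib[order(lib$avg), ]
  lib
}

#' Signed mass error in parts per million
#'
#' @param observed,theoretical Masses in Da; `theoretical` must be > 0.
#' @return `(observed - theoretical) / theoretical * 1e6`.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical mass must be positive")
  (observed - theoretical) / theoretical * 1e6
}

#' Annotate observed masses against a proteoform library
#'
#' Each peak is assigned the library entry minimizing |ppm error| within
#' the tolerance; ties go to the smaller |ppm|, then the lighter
#' proteoform. Peaks with no candidate inside the tolerance stay
#' unassigned (NA label). The result is independent of input peak order.
#'
#' @param peaks Data frame with columns `mass` (Da) and optionally
#'   `intensity`.
#' @param library A [build_library()] tibble.
#' @param tol_ppm Assignment tolerance in ppm (default 20, the accuracy
#'   achievable for major intact-mAb variants; minor variants may need up
#'   to 50).
#' @param mass_col Which theoretical mass to match: `"avg"` (default —
#'   deconvoluted intact-mAb masses are average masses at this resolving
#'   power) or `"mono"`.
#' @return `peaks` with added columns `label`, `theoretical`, `ppm`.
#' @export
annotate_peaks <- function(peaks, library, tol_ppm = 20, mass_col = c("avg", "mono")) {
  mass_col <- match.arg(mass_col)
  stopifnot("mass" %in% names(peaks))
  theo <- library[[mass_col]]
  ord <- order(theo, library$label)
  theo <- theo[ord]
  labs <- library$label[ord]
  assign_one <- function(m) {
    ppm <- ppm_error(m, theo)
    ok <- which(abs(ppm) <= tol_ppm)
    if (!length(ok)) return(c(NA_character_, NA, NA))
    best <- ok[order(abs(ppm[ok]), theo[ok])][1L]
    c(labs[best], theo[best], ppm[best])
  }
  res <- t(vapply(peaks$mass, assign_one, character(3L)))
  peaks$label <- res[, 1L]
  peaks$theoretical <- as.numeric(res[, 2L])
  peaks$ppm <- as.numeric(res[, 3L])
  peaks
}
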