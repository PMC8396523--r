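# Oxford-style glycan nomenclature -> monosaccharide residue compositions.

#' Glycan residue masses
#'
#' Compositions of the dehydrated monosaccharide residues (HexNAc, Hex,
#' Fuc, NeuAc, NeuGc) as incorporated in a glycan chain.
#'
#' @return Named list of `elem_comp`.
#' @export
glycan_residues <- function() {
  if (is.null(.mabquant_env$glyres)) {
    tab <- utils::read.delim(.pkg_file("extdata", "glycan_residues.tsv"),
                             stringsAsFactors = FALSE)
    .mabquant_env$glyres <- stats::setNames(
      lapply(tab$formula, parse_formula), tab$residue)
  }
  .mabquant_env$glyres
}

glycan_residue_names <- c("HexNAc", "Hex", "Fuc", "NeuAc", "NeuGc")

#' Construct a glycan composition
#'
#' @param HexNAc,Hex,Fuc,NeuAc,NeuGc Non-negative residue counts.
#' @return A `glycan_comp`: named integer vector of residue counts.
#' @export
glycan_composition <- function(HexNAc = 0, Hex = 0, Fuc = 0, NeuAc = 0,
                               NeuGc = 0) {
  x <- c(HexNAc = HexNAc, Hex = Hex, Fuc = Fuc, NeuAc = NeuAc, NeuGc = NeuGc)
  if (any(x < 0) || any(x != round(x))) {
    stop("glycan residue counts must be non-negative integers")
  }
  structure(stats::setNames(as.integer(x), names(x)), class = "glycan_comp")
}

#' @export
print.glycan_comp <- function(x, ...) {
  nz <- x[x > 0]
  lab <- if (length(nz)) paste0(names(nz), unclass(nz), collapse = " ") else "(none)"
  cat("<glycan> ", lab, "\n", sep = "")
  invisible(x)
}

#' Parse an Oxford-style glycan name
#'
#' Supported grammar: oligomannose `M5`..`M9`; mono-/biantennary complex
#' types `A1`/`A2` with optional sialylation `S1`/`S2`, galactosylation
#' `G0`..`G2`, and core fucose `F` (e.g. `A2G0F`, `A2G1`, `A2S1G1F`,
#' `A2S2F`). Each antenna counts one HexNAc on top of the HexNAc2Hex3
#' core; every galactose and every sialic-acid-capped arm adds one Hex.
#' Unknown labels can be supplied through `custom` (name -> `glycan_comp`),
#' which takes precedence, so users may register arbitrary structures
#' instead of relying on the grammar.
#'
#' @param name Glycan label.
#' @param custom Optional named list of `glycan_comp` overrides.
#' @return A `glycan_comp`.
#' @export
glycan_from_name <- function(name, custom = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.null(custom) && name %in% names(custom)) {
    g <- custom[[name]]
    stopifnot(inherits(g, "glycan_comp"))
    return(g)
  }
  m <- regmatches(name, regexec("^M([5-9])$", name))[[1]]
  if (length(m)) {
    return(glycan_composition(HexNAc = 2, Hex = as.integer(m[2])))
  }
  m <- regmatches(name, regexec("^A([12])(?:S([12]))?(?:G([0-2]))?(F)?$",
                                name))[[1]]
  if (length(m)) {
    ant <- as.integer(m[2])
    sia <- if (nzchar(m[3])) as.integer(m[3]) else 0L
    gal <- if (nzchar(m[4])) as.integer(m[4]) else 0L
    if (sia + gal > ant) {
      stop("glycan '", name, "': more decorated arms than antennae")
    }
    return(glycan_composition(
      HexNAc = 2L + ant,
      Hex    = 3L + sia + gal,
      Fuc    = if (nzchar(m[5])) 1L else 0L,
      NeuAc  = sia
    ))
  }
  stop("cannot parse glycan name: ", name)
}

#' Elemental composition of a glycan
#'
#' @param g A `glycan_comp` (or a glycan name string).
#' @return An `elem_comp` (sum of dehydrated residue compositions).
#' @export
glycan_to_composition <- function(g) {
  if (is.character(g)) g <- glycan_from_name(g)
  stopifnot(inherits(g, "glycan_comp"))
  res <- glycan_residues()
  total <- comp()
  for (nm in names(g)) {
    if (g[[nm]] > 0) total <- total + g[[nm]] * res[[nm]]
  }
  total
}

#' Mass of a glycan
#'
#' @inheritParams glycan_to_composition
#' @return A `mass_value`.
#' @export
glycan_mass <- function(g) mass_of(glycan_to_composition(g))
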