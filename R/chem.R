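# Elemental-composition arithmetic and mass computation.
#
# An elemental composition is the unit of all mass bookkeeping in this
# package: a named integer vector (element symbol -> signed count) with
# class "elem_comp". Zero counts are never stored, so identical molecules
# always compare equal element-wise.

.mabquant_env <- new.env(parent = emptyenv())

.pkg_file <- function(...) {
  system.file(..., package = "mabquant", mustWork = TRUE)
}

#' Element mass table
#'
#' Returns the fixed atomic-mass snapshot bundled with the package:
#' monoisotopic masses (principal isotope, AME2020/CODATA) and average
#' masses (IUPAC 2021 abridged standard atomic weights). Bundling a
#' snapshot keeps computed masses bit-stable across environments.
#'
#' @return A data frame with columns `symbol`, `mono`, `avg`.
#' @export
element_masses <- function() {
  if (is.null(.mabquant_env$elements)) {
    .mabquant_env$elements <- utils::read.delim(
      .pkg_file("extdata", "elements.tsv"),
      stringsAsFactors = FALSE
    )
  }
  .mabquant_env$elements
}

new_comp <- function(counts) {
  counts <- counts[counts != 0L]
  if (length(counts)) counts <- counts[order(names(counts))]
  structure(as.integer(counts), names = names(counts), class = "elem_comp")
}

#' Construct an elemental composition
#'
#' @param ... Named integer counts, e.g. `comp(C = 6, H = 12, O = 6)`.
#' @return An `elem_comp` object. Zero counts are dropped.
#' @export
comp <- function(...) {
  counts <- c(...)
  if (is.null(counts)) counts <- integer(0)
  if (length(counts) && is.null(names(counts))) {
    stop("composition counts must be named by element symbol")
  }
  known <- element_masses()$symbol
  bad <- setdiff(names(counts), known)
  if (length(bad)) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  new_comp(counts)
}

#' Parse a molecular formula
#'
#' Parses strings like `"C6H12N2O"` into an elemental composition.
#' Counts may be negative (e.g. `"H-1N-1O"`), which is how modification
#' deltas such as deamidation are written; an omitted count means 1.
#'
#' @param formula A formula string; `""` yields the empty composition.
#' @return An `elem_comp`.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  if (is.na(formula) || formula == "") return(new_comp(integer(0)))
  m <- gregexpr("([A-Z][a-z]?)(-?[0-9]+)?", formula, perl = TRUE)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    stop("cannot parse formula: ", formula)
  }
  sym <- sub("(-?[0-9]+)$", "", toks)
  cnt <- suppressWarnings(as.integer(sub("^[A-Z][a-z]?", "", toks)))
  cnt[is.na(cnt)] <- 1L
  known <- element_masses()$symbol
  bad <- setdiff(sym, known)
  if (length(bad)) {
    stop("unknown element symbol(s) in '", formula, "': ",
         paste(bad, collapse = ", "))
  }
  counts <- tapply(cnt, sym, sum)
  comp_obj <- new_comp(stats::setNames(as.integer(counts), names(counts)))
  comp_obj
}

#' Canonical formula string of a composition
#'
#' Hill order (C, H, then alphabetical); negative counts keep their sign,
#' so `parse_formula(format(x)) == x` for every composition.
#'
#' @param x An `elem_comp`.
#' @param ... Ignored.
#' @export
format.elem_comp <- function(x, ...) {
  if (!length(x)) return("")
  sym <- names(x)
  ord <- order(match(sym, c("C", "H"), nomatch = 3L), sym)
  paste0(sym[ord], unclass(x)[ord], collapse = "")
}

#' @export
print.elem_comp <- function(x, ...) {
  cat("<elem_comp> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Composition arithmetic
#'
#' `+`, `-` and integer `*` act element-wise; results never carry zero
#' counts, so addition followed by subtraction is the exact identity.
#'
#' @param e1,e2 `elem_comp` objects (or an integer scalar for `*`).
#' @export
Ops.elem_comp <- function(e1, e2) {
  op <- .Generic
  if (op %in% c("+", "-")) {
    a <- unclass(e1); b <- unclass(e2)
    sym <- union(names(a), names(b))
    av <- stats::setNames(integer(length(sym)), sym)
    bv <- av
    av[names(a)] <- a
    bv[names(b)] <- b
    return(new_comp(if (op == "+") av + bv else av - bv))
  }
  if (op == "*") {
    if (inherits(e1, "elem_comp")) { cmp <- e1; k <- e2 } else { cmp <- e2; k <- e1 }
    stopifnot(length(k) == 1L, k == round(k))
    return(new_comp(unclass(cmp) * as.integer(k)))
  }
  if (op == "==") {
    return(isTRUE(all.equal(sort_named(unclass(e1)), sort_named(unclass(e2)))))
  }
  if (op == "!=") return(!(e1 == e2))
  stop("operation '", op, "' not defined for elem_comp")
}

sort_named <- function(x) x[order(names(x))]

#' Monoisotopic and average mass of a composition
#'
#' Masses are linear in the composition: `mass_of(a + b)` equals
#' `mass_of(a) + mass_of(b)` component-wise to floating precision.
#'
#' @param x An `elem_comp` (or a formula string, parsed on the fly).
#' @return A `mass_value`: list with numeric fields `mono` and `avg` (Da).
#' @export
mass_of <- function(x) {
  if (is.character(x)) x <- parse_formula(x)
  stopifnot(inherits(x, "elem_comp"))
  tab <- element_masses()
  idx <- match(names(x), tab$symbol)
  structure(
    list(mono = sum(unclass(x) * tab$mono[idx]),
         avg  = sum(unclass(x) * tab$avg[idx])),
    class = "mass_value"
  )
}

#' @export
print.mass_value <- function(x, ...) {
  cat(sprintf("<mass> mono %.4f Da, avg %.4f Da\n", x$mono, x$avg))
  invisible(x)
}

#' Amino-acid residue composition table
#'
#' The 20 canonical residues (amino acid minus water), read from the
#' bundled TSV so users can audit or extend it.
#'
#' @return Named list of `elem_comp`, keyed by one-letter code.
#' @export
residue_table <- function() {
  if (is.null(.mabquant_env$residues)) {
    tab <- utils::read.delim(.pkg_file("extdata", "residues.tsv"),
                             stringsAsFactors = FALSE)
    .mabquant_env$residues <- stats::setNames(
      lapply(tab$formula, parse_formula), tab$code)
  }
  .mabquant_env$residues
}

#' Elemental composition of a peptide or protein sequence
#'
#' Sums residue compositions; with `water = TRUE` one H2O is added so the
#' result is the free (hydrolysed) peptide, with `water = FALSE` the bare
#' residue sum, which is what internal gain/loss accounting needs (e.g.
#' the light-chain N-terminal QIVLS truncation).
#'
#' @param seq Amino-acid string (one-letter codes).
#' @param water Add one water for the free peptide termini? Default TRUE.
#' @return An `elem_comp`.
#' @export
sequence_composition <- function(seq, water = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  res <- residue_table()
  total <- new_comp(integer(0))
  if (nzchar(seq)) {
    codes <- strsplit(seq, "")[[1]]
    bad <- setdiff(unique(codes), names(res))
    if (length(bad)) {
      stop("unknown residue code(s): ", paste(bad, collapse = ", "))
    }
    counts <- table(factor(codes, levels = names(res)))
    for (code in names(res)) {
      n <- counts[[code]]
      if (n > 0) total <- total + n * res[[code]]
    }
  }
  if (water) total <- total + comp(H = 2, O = 1)
  total
}

#' Modification delta
#'
#' A named, signed composition change (e.g. deamidation = `H-1N-1O`,
#' one hexose = `C6H10O5`). Applying then removing a delta is the exact
#' identity on the composition.
#'
#' @param name Label for the modification.
#' @param delta An `elem_comp` or formula string.
#' @export
mod_delta <- function(name, delta) {
  if (is.character(delta)) delta <- parse_formula(delta)
  stopifnot(inherits(delta, "elem_comp"), is.character(name))
  structure(list(name = name, delta = delta), class = "mod_delta")
}

#' @export
print.mod_delta <- function(x, ...) {
  m <- mass_of(x$delta)
  cat(sprintf("<mod> %s: %s (%+.4f Da mono)\n", x$name, format(x$delta), m$mono))
  invisible(x)
}

#' Modification registry
#'
#' Loads a YAML mapping of modification names to formula strings. With no
#' path, returns the built-in registry (lysine, hexose, glycation,
#' deamidation, pyroGlu, QIVLS truncation). Note hexose and glycation are
#' isobaric by construction: distinct names, one composition.
#'
#' @param path Optional YAML file; defaults to the bundled registry.
#' @return Named list of `mod_delta`.
#' @export
mod_registry <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.mabquant_env$mods)) return(.mabquant_env$mods)
    path <- .pkg_file("extdata", "mods.yaml")
    raw <- yaml::read_yaml(path)
    .mabquant_env$mods <- mapply(mod_delta, names(raw), raw, SIMPLIFY = FALSE)
    return(.mabquant_env$mods)
  }
  raw <- yaml::read_yaml(path)
  mapply(mod_delta, names(raw), raw, SIMPLIFY = FALSE)
}

#' Apply modification deltas to a composition
#'
#' Element-wise, order-independent sum; the caller is responsible for the
#' result being a physically meaningful molecule.
#'
#' @param base An `elem_comp`.
#' @param mods A list of `mod_delta` (or registry names as characters).
#' @return The modified `elem_comp`.
#' @export
apply_mods <- function(base, mods) {
  stopifnot(inherits(base, "elem_comp"))
  if (inherits(mods, "mod_delta")) mods <- list(mods)
  reg <- NULL
  for (m in mods) {
    if (is.character(m)) {
      if (is.null(reg)) reg <- mod_registry()
      if (!m %in% names(reg)) stop("unknown modification: ", m)
      m <- reg[[m]]
    }
    base <- base + m$delta
  }
  base
}
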