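# Glycan nomenclature, library enumeration, and mass annotation.

test_that("Oxford glycan names map to the expected compositions", {
  a2g0f <- glycan_from_name("A2G0F")
  expect_equal(unclass(a2g0f)[c("HexNAc", "Hex", "Fuc", "NeuAc")],
               c(HexNAc = 4L, Hex = 3L, Fuc = 1L, NeuAc = 0L))
  m5 <- glycan_from_name("M5")
  expect_equal(unclass(m5)[c("HexNAc", "Hex")], c(HexNAc = 2L, Hex = 5L))

  d <- glycan_mass("A2G2F")$mono - glycan_mass("A2G0F")$mono
  expect_equal(d, 324.106, tolerance = 1e-3)  # two hexose residues

  s1 <- glycan_from_name("A2S1G1F")
  expect_equal(unclass(s1)[c("HexNAc", "Hex", "Fuc", "NeuAc")],
               c(HexNAc = 4L, Hex = 5L, Fuc = 1L, NeuAc = 1L))

  expect_error(glycan_from_name("B3X"), "cannot parse")
  expect_error(glycan_from_name("A1S1G1"), "more decorated arms")

  custom <- list(FA2 = glycan_composition(HexNAc = 4, Hex = 3, Fuc = 1))
  expect_true(all(glycan_from_name("FA2", custom = custom) ==
                    glycan_from_name("A2G0F")))
})

test_that("galactose ladder is arithmetic with the hexose spacing", {
  masses <- vapply(paste0("A2G", 0:2, "F"), function(n) glycan_mass(n)$avg, 0)
  steps <- diff(masses)
  expect_equal(steps, rep(mass_of("C6H10O5")$avg, 2), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("library enumerates the cartesian product with ladder invariants", {
  chains <- read_chains(rituximab_fasta())
  pairs <- list("A2G0F/A2G0F", "A2G0F/A2G1F", "A2G1F/A2G2F", "A2G2F/A2G2F",
                "M5/M5")
  lib <- build_library(chains, pairs, lysine_variants = 0:2)
  expect_equal(nrow(lib), 15L)
  expect_false(is.unsorted(lib$avg))

  lysm <- mass_of(residue_table()[["K"]])
  for (p in c("A2G0F/A2G0F", "M5/M5")) {
    sub <- lib[lib$glycan_pair == p, ]
    sub <- sub[order(sub$nlys), ]
    expect_equal(diff(sub$mono), rep(lysm$mono, 2), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(diff(sub$avg), rep(lysm$avg, 2), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }

  # truncation delta shifts every member by the QIVLS residue mass
  trunc <- mod_delta("trunc", comp() - sequence_composition("QIVLS", water = FALSE))
  lib_t <- build_library(chains, pairs, lysine_variants = 0,
                         extra_deltas = list(trunc))
  base <- lib_t[lib_t$mods == "", ]
  shifted <- lib_t[lib_t$mods == "trunc", ]
  m <- match(base$glycan_pair, shifted$glycan_pair)
  expect_equal(shifted$mono[m] - base$mono, rep(-540.3271, nrow(base)),
               tolerance = 1e-4, ignore_attr = TRUE)

  expect_error(build_library(chains, list()), "empty")
})

test_that("isobaric glycoform pairs merge into one combined entry", {
  chains <- read_chains(rituximab_fasta())
  lib <- build_library(chains, list("A2G1F/A2G1F", "A2G0F/A2G2F"),
                       lysine_variants = 0)
  expect_equal(nrow(lib), 1L)
  expect_match(lib$label, "A2G1F/A2G1F")
  expect_match(lib$label, "A2G0F/A2G2F")
  expect_equal(lib$gal_count, 2L)
})

test_that("glycan pair order does not matter", {
  chains <- read_chains(rituximab_fasta())
  a <- build_library(chains, list(c("A2G0F", "A2G1F")), lysine_variants = 0)
  b <- build_library(chains, list(c("A2G1F", "A2G0F")), lysine_variants = 0)
  expect_equal(a$label, b$label)
  expect_equal(a$avg, b$avg)
})

test_that("ppm error is signed and exact", {
  expect_equal(ppm_error(147000, 147000), 0)
  expect_equal(ppm_error(147002.94, 147000), 20, tolerance = 1e-6)
  expect_equal(ppm_error(146997.06, 147000), -20, tolerance = 1e-6)
  expect_error(ppm_error(1, 0), "positive")
})

test_that("annotation assigns within tolerance, order-independently", {
  chains <- read_chains(rituximab_fasta())
  lib <- build_library(chains,
                       list("A2G0F/A2G0F", "A2G0F/A2G1F", "A2G1F/A2G1F",
                            "A2G1F/A2G2F", "A2G2F/A2G2F"),
                       lysine_variants = 0:1)
  expect_equal(nrow(lib), 10L)

  exact <- data.frame(mass = lib$avg[4])
  ann <- annotate_peaks(exact, lib)
  expect_equal(ann$label, lib$label[4])
  expect_equal(ann$ppm, 0)

  off <- data.frame(mass = lib$avg[1] * (1 + 25e-6))
  expect_true(is.na(annotate_peaks(off, lib, tol_ppm = 20)$label))

  set.seed(5)
  jit <- data.frame(mass = lib$avg * (1 + stats::rnorm(10, 0, 5e-6)))
  ann <- annotate_peaks(jit, lib, tol_ppm = 20)
  expect_equal(ann$label, lib$label)

  perm <- sample.int(10)
  ann_p <- annotate_peaks(jit[perm, , drop = FALSE], lib, tol_ppm = 20)
  expect_equal(ann_p$label, ann$label[perm])

  # idempotent: annotating the annotated table again gives the same labels
  ann2 <- annotate_peaks(ann, lib, tol_ppm = 20)
  expect_equal(ann2$label, ann$label)
})
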