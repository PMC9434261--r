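# Compositional algebra for nucleotide-linked muropeptide precursors.
#
# Neutral species are assembled by condensation: element-wise sum of the
# free-molecule formulas of the building blocks minus one water per
# inter-block bond. Stereochemistry (L-/D-) is metadata only and never
# affects mass.

# Monoisotopic atomic masses (Da), most abundant isotope, NIST/CODATA.
# 12C is exactly 12 by definition. Embedded so no lookup happens at runtime.
.ATOMIC_MASS <- c(
  C = 12,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  P = 30.97376163
)
.MASS_NA     <- 22.9897692809  # sodium atom
.MASS_H      <- 1.00782503207  # hydrogen atom
.MASS_PROTON <- 1.00727646688  # bare proton (optional ionisation convention)
.ELEMENTS <- names(.ATOMIC_MASS)

#' Create an elemental composition
#'
#' An elemental composition is a named integer vector of atom counts over
#' the elements C, H, N, O and P -- sufficient for UDP-linked muropeptide
#' precursors. Compositions add and subtract element-wise via `+` and `-`;
#' subtraction that would drive any count negative is an error.
#'
#' @param C,H,N,O,P Non-negative integer atom counts.
#' @return An object of class `elemental_composition`.
#' @examples
#' h2o <- elemental_composition(H = 2, O = 1)
#' monoisotopic_mass(h2o)
#' @export
elemental_composition <- function(C = 0, H = 0, N = 0, O = 0, P = 0) {
  counts <- c(C = C, H = H, N = N, O = O, P = P)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("atom counts must be non-negative integers")
  structure(as.integer(counts), names = .ELEMENTS,
            class = "elemental_composition")
}

#' @export
Ops.elemental_composition <- function(e1, e2) {
  if (!.Generic %in% c("+", "-"))
    stop("only + and - are defined for elemental compositions")
  out <- unclass(e1) + if (.Generic == "+") unclass(e2) else -unclass(e2)
  if (any(out < 0))
    stop("composition subtraction would give a negative atom count")
  structure(as.integer(out), names = .ELEMENTS, class = "elemental_composition")
}

#' Chemical formula in Hill order
#'
#' @param comp An `elemental_composition`.
#' @return A single string, e.g. `"C17H27N3O17P2"`; `""` for the empty
#'   composition.
#' @export
format_formula <- function(comp) {
  stopifnot(inherits(comp, "elemental_composition"))
  n <- unclass(comp)
  parts <- vapply(.ELEMENTS, function(e) {
    if (n[[e]] == 0L) "" else paste0(e, if (n[[e]] > 1L) n[[e]] else "")
  }, character(1))
  paste0(parts, collapse = "")
}

#' @export
print.elemental_composition <- function(x, ...) {
  cat("<elemental composition> ", format_formula(x),
      "  (", sprintf("%.4f", monoisotopic_mass(x)), " Da)\n", sep = "")
  invisible(x)
}

#' Monoisotopic mass of a composition
#'
#' Sum of atom counts times monoisotopic atomic masses taken from the
#' embedded constants table (12C exactly 12).
#'
#' @param comp An `elemental_composition`.
#' @return Mass in Da. The empty composition has mass 0.
#' @export
monoisotopic_mass <- function(comp) {
  stopifnot(inherits(comp, "elemental_composition"))
  sum(unclass(comp) * .ATOMIC_MASS)
}

# Free-molecule formulas of the building-block library. MurNAc is carried
# as its own block (not GlcNAc + lactyl) so that bond counting stays
# uniform at one water per inter-block bond; the enolpyruvyl group is
# entered through its free acid (enolpyruvic acid, C3H4O3) for the same
# reason. Ala-Ala is the D-Ala--D-Ala dipeptide added in one step by MurF.
.BLOCKS <- list(
  UDP            = list(class = "nucleotide", C = 9,  H = 14, N = 2, O = 12, P = 2),
  GlcNAc         = list(class = "sugar",      C = 8,  H = 15, N = 1, O = 6,  P = 0),
  MurNAc         = list(class = "sugar",      C = 11, H = 19, N = 1, O = 8,  P = 0),
  enolpyruvate   = list(class = "sugar",      C = 3,  H = 4,  N = 0, O = 3,  P = 0),
  Ala            = list(class = "amino-acid", C = 3,  H = 7,  N = 1, O = 2,  P = 0),
  Glu            = list(class = "amino-acid", C = 5,  H = 9,  N = 1, O = 4,  P = 0),
  `meso-DAP`     = list(class = "amino-acid", C = 7,  H = 14, N = 2, O = 4,  P = 0),
  Lys            = list(class = "amino-acid", C = 6,  H = 14, N = 2, O = 2,  P = 0),
  `Ala-Ala`      = list(class = "dipeptide",  C = 6,  H = 12, N = 2, O = 3,  P = 0)
)

.block_composition <- function(name) {
  b <- .BLOCKS[[name]]
  if (is.null(b))
    stop("unknown building block: '", name, "'")
  elemental_composition(C = b$C, H = b$H, N = b$N, O = b$O, P = b$P)
}

#' Building-block library
#'
#' The free-molecule formulas and monoisotopic masses of the muropeptide
#' building blocks: the UDP nucleotide, the GlcNAc and MurNAc amino sugars
#' (plus the enolpyruvyl group as its free acid), the stem-peptide amino
#' acids and the terminal D-Ala--D-Ala dipeptide.
#'
#' @return A data frame with columns `block`, `class`, `formula`, `mass`.
#' @export
building_blocks <- function() {
  nm <- names(.BLOCKS)
  comps <- lapply(nm, .block_composition)
  data.frame(
    block   = nm,
    class   = vapply(.BLOCKS, `[[`, character(1), "class"),
    formula = vapply(comps, format_formula, character(1)),
    mass    = vapply(comps, monoisotopic_mass, numeric(1)),
    row.names = NULL
  )
}

#' Condense building blocks into a neutral composition
#'
#' Element-wise sum of the free-molecule compositions of the named blocks
#' minus one water per inter-block bond (n - 1 waters for n blocks).
#'
#' @param blocks Character vector of block names, in assembly order. An
#'   empty vector gives the empty composition.
#' @return An `elemental_composition` of the condensed neutral molecule.
#' @examples
#' format_formula(compose(c("UDP", "GlcNAc")))  # "C17H27N3O17P2"
#' @export
compose <- function(blocks) {
  if (length(blocks) == 0L) return(elemental_composition())
  comps <- lapply(blocks, .block_composition)
  total <- Reduce(`+`, comps)
  n_bonds <- length(blocks) - 1L
  if (n_bonds > 0L) {
    water <- elemental_composition(H = 2L * n_bonds, O = n_bonds)
    total <- total - water
  }
  total
}

# Canonical species identifiers used across the package; the third stem
# residue is spelt out so DAP and Lys ladders never share peptide ids.
.ladder_block_lists <- function(third_residue, include_murnac, include_enolpyruvyl) {
  third_block <- if (third_residue == "DAP") "meso-DAP" else "Lys"
  out <- list(`UDP-GlcNAc` = c("UDP", "GlcNAc"))
  if (include_enolpyruvyl)
    out[["UDP-GlcNAc-enolpyruvate"]] <- c("UDP", "GlcNAc", "enolpyruvate")
  if (include_murnac)
    out[["UDP-MurNAc"]] <- c("UDP", "MurNAc")
  out[["UDP-MurNAc-Ala"]] <- c("UDP", "MurNAc", "Ala")
  out[["UDP-MurNAc-Ala-Glu"]] <- c("UDP", "MurNAc", "Ala", "Glu")
  out[[paste0("UDP-MurNAc-Ala-Glu-", third_residue)]] <-
    c("UDP", "MurNAc", "Ala", "Glu", third_block)
  out[[paste0("UDP-MurNAc-Ala-Glu-", third_residue, "-Ala-Ala")]] <-
    c("UDP", "MurNAc", "Ala", "Glu", third_block, "Ala-Ala")
  out
}

#' Build the cytoplasmic precursor ladder
#'
#' Returns the UDP-linked intermediates of the peptidoglycan stem-peptide
#' pathway in biosynthetic order: UDP-GlcNAc, then (optionally) the MurA
#' enolpyruvyl intermediate and UDP-MurNAc, then the MurC-F ladder up to
#' the UDP-MurNAc-pentapeptide. The third stem residue is either meso-DAP
#' (Gram-negative type, including cyanobacteria and the moss pathway) or
#' L-Lys (typical Gram-positive type); the two differ by exactly one CO2.
#'
#' @param third_residue `"DAP"` or `"Lys"`.
#' @param include_murnac Include UDP-MurNAc (MurB product) itself.
#' @param include_enolpyruvyl Include the UDP-GlcNAc-enolpyruvate (MurA
#'   product). Both optional intermediates default off.
#' @return A data frame of class `precursor_ladder` with columns `species`
#'   (identifier), `blocks` (list column of block names), `formula`,
#'   `mass` (neutral monoisotopic, Da), `pathway_index`, `third_residue`.
#'   Masses are strictly increasing along the ladder.
#' @examples
#' build_ladder("DAP")$mass
#' @export
build_ladder <- function(third_residue = c("DAP", "Lys"),
                         include_murnac = FALSE,
                         include_enolpyruvyl = FALSE) {
  third_residue <- match.arg(third_residue)
  bl <- .ladder_block_lists(third_residue, include_murnac, include_enolpyruvyl)
  comps <- lapply(bl, compose)
  out <- data.frame(
    species       = names(bl),
    formula       = vapply(comps, format_formula, character(1)),
    mass          = vapply(comps, monoisotopic_mass, numeric(1)),
    pathway_index = seq_along(bl),
    third_residue = third_residue,
    row.names     = NULL
  )
  out$blocks <- unname(bl)
  out <- out[, c("species", "blocks", "formula", "mass",
                 "pathway_index", "third_residue")]
  class(out) <- c("precursor_ladder", "data.frame")
  out
}

#' Combine precursor ladders
#'
#' Concatenates ladders (e.g. the DAP and Lys variants) into one search
#' space, dropping species with duplicated identifiers (the sugar and
#' dipeptide intermediates below MurE are common to both variants).
#'
#' @param ... `precursor_ladder` data frames.
#' @return A `precursor_ladder` with unique species.
#' @export
combine_ladders <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  out <- out[!duplicated(out$species), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("precursor_ladder", "data.frame")
  out
}

#' Export a ladder as delimited text
#'
#' Writes identifier, Hill-order formula and neutral monoisotopic mass as
#' tab-separated text.
#'
#' @param ladder A `precursor_ladder`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ladder <- function(ladder, path) {
  stopifnot(inherits(ladder, "precursor_ladder"))
  out <- data.frame(species = ladder$species,
                    formula = ladder$formula,
                    mass    = sprintf("%.4f", ladder$mass))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
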