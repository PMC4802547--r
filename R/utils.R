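# Internal helpers: seeded RNG scoping, residue-name tables, small checks.

# Run `expr` under a private RNG stream; the caller's .Random.seed is
# untouched.  Every stochastic generator in the package funnels through this
# so that fixtures are pure functions of (spec, seed).
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# 1-letter -> 3-letter residue codes, 20 standard amino acids.
AA_3LETTER <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

# Residue names recognised as protein when classifying molecules.
PROTEIN_RESNAMES <- unname(AA_3LETTER)

#' Default molecule classification table
#'
#' Maps residue names to molecule classes (`protein`, `lipid`, `water`);
#' names absent from the table classify as `other`.  Used by
#' [readStructure()] and overridable there.
#'
#' @return Named character vector: names are residue names, values classes.
#' @export
#' @examples
#' defaultClassification()[c("POPC", "SOL", "ALA")]
defaultClassification <- function() {
  c(setNames(rep("protein", length(PROTEIN_RESNAMES)), PROTEIN_RESNAMES),
    POPC = "lipid", POPS = "lipid", DPPC = "lipid",
    SOL = "water", HOH = "water", WAT = "water")
}

#' The 42-residue beta-amyloid monomer sequence
#'
#' One-letter sequence of the A-beta(1-42) peptide used throughout the
#' examples; the 40-residue isoform is this sequence without its last two
#' residues (Ile-41, Ala-42).
#'
#' @return Single character string of length-42 sequence.
#' @export
#' @examples
#' nchar(abeta42Sequence())
abeta42Sequence <- function() "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA"

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

isString <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

isCount <- function(x, min = 1L)
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == trunc(x)

isNum <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
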