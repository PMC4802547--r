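# S4 containers for structures, trajectories and derived analyses.

ATOM_COLS <- c("serial", "name", "element", "resid", "resname", "chain",
               "moleculeId", "moleculeClass")
MOLECULE_CLASSES <- c("protein", "lipid", "water", "other")

#' MDSystem: a molecular system snapshot
#'
#' Holds an atom table (identity, residue/chain/molecule grouping and
#' molecule class), a coordinate matrix in Angstrom, and an orthorhombic
#' box.  Created by [readStructure()], [buildDimer()] or the fixture
#' generators; never constructed slot-by-slot by users.
#'
#' @slot atoms data.frame with columns serial, name, element, resid (global
#'   1-based residue index), resname, chain, moleculeId, moleculeClass.
#' @slot coords numeric matrix (atoms x 3), Angstrom.
#' @slot box numeric length-3 box vector (Lx, Ly, Lz), Angstrom.
#' @slot periodic logical; when TRUE distances use the minimum-image
#'   convention in the box.
#'
#' @aliases MDSystem
#' @exportClass MDSystem
setClass("MDSystem",
  representation(atoms = "data.frame", coords = "matrix",
                 box = "numeric", periodic = "logical"),
  prototype(atoms = data.frame(), coords = matrix(numeric(), 0L, 3L),
            box = c(0, 0, 0), periodic = FALSE))

setValidity("MDSystem", function(object) {
  a <- object@atoms
  msgs <- character()
  if (!all(ATOM_COLS %in% names(a)))
    return(paste("atoms table must have columns:",
                 paste(ATOM_COLS, collapse = ", ")))
  if (nrow(object@coords) != nrow(a) || ncol(object@coords) != 3L)
    msgs <- c(msgs, "coords must be an (atoms x 3) matrix")
  if (nrow(a) > 0L) {
    if (anyDuplicated(a$serial))
      msgs <- c(msgs, "atom serial numbers must be unique")
    if (!all(is.finite(object@coords)))
      msgs <- c(msgs, "all coordinates must be finite")
    if (!all(a$moleculeClass %in% MOLECULE_CLASSES))
      msgs <- c(msgs, "unknown molecule class")
    bad <- vapply(split(a$moleculeClass, a$moleculeId),
                  function(x) length(unique(x)) > 1L, logical(1L))
    if (any(bad))
      msgs <- c(msgs, "atoms sharing a moleculeId must share moleculeClass")
    for (ch in unique(a$chain)) {
      r <- sort(unique(a$resid[a$chain == ch]))
      if (length(r) > 1L && any(diff(r) != 1L))
        msgs <- c(msgs, sprintf("residue indices not contiguous in chain %s", ch))
    }
  }
  if (length(object@box) != 3L)
    msgs <- c(msgs, "box must have 3 components")
  if (isTRUE(object@periodic) && any(object@box <= 0))
    msgs <- c(msgs, "periodic system requires positive box lengths")
  if (length(msgs)) msgs else TRUE
})

#' MDTrajectory: time-ordered frames over one topology
#'
#' @slot system the [MDSystem-class] topology (its coords slot holds frame 1).
#' @slot times strictly increasing frame times, ns.
#' @slot frames numeric array (atoms x 3 x frames), Angstrom.
#'
#' @aliases MDTrajectory
#' @exportClass MDTrajectory
setClass("MDTrajectory",
  representation(system = "MDSystem", times = "numeric", frames = "array"))

setValidity("MDTrajectory", function(object) {
  msgs <- character()
  d <- dim(object@frames)
  if (length(d) != 3L || d[2L] != 3L)
    return("frames must be an (atoms x 3 x frames) array")
  if (d[1L] != nrow(object@system@atoms))
    msgs <- c(msgs, "every frame must have exactly one position per atom")
  if (d[3L] != length(object@times))
    msgs <- c(msgs, "number of frames must match number of times")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    msgs <- c(msgs, "times must be strictly increasing")
  if (length(msgs)) msgs else TRUE
})

#' DomainPartition: N/C-terminal domain split of each chain
#'
#' @slot splitResidue chain-local index of the last N-terminal-domain residue.
#' @slot table data.frame with columns chain, domain ("N"/"C"), from, to
#'   (global residue indices, inclusive).
#'
#' @aliases DomainPartition
#' @exportClass DomainPartition
setClass("DomainPartition",
  representation(splitResidue = "integer", table = "data.frame"))

setValidity("DomainPartition", function(object) {
  t <- object@table
  if (!all(c("chain", "domain", "from", "to") %in% names(t)))
    return("table must have columns chain, domain, from, to")
  for (ch in unique(t$chain)) {
    sub <- t[t$chain == ch, ]
    res <- unlist(Map(seq, sub$from, sub$to))
    if (anyDuplicated(res))
      return(sprintf("domains overlap in chain %s", ch))
  }
  TRUE
})

#' SSMatrix: residues-by-frames secondary-structure codes
#'
#' Nine-state alphabet: H, G, I (helices), E, B (strand/bridge), T (turn),
#' S (bend), C (coil) plus X marking the separator row between chains.
#'
#' @slot residues global residue indices; NA for chain-separator rows.
#' @slot times frame times, ns.
#' @slot codes character matrix (rows = residues + separators, cols = frames).
#'
#' @aliases SSMatrix
#' @exportClass SSMatrix
setClass("SSMatrix",
  representation(residues = "integer", times = "numeric", codes = "matrix"))

SS_CODES <- c("H", "G", "I", "E", "B", "T", "S", "C", "X")

setValidity("SSMatrix", function(object) {
  msgs <- character()
  if (nrow(object@codes) != length(object@residues))
    msgs <- c(msgs, "one residue label per code row required")
  if (ncol(object@codes) != length(object@times))
    msgs <- c(msgs, "one time per code column required")
  if (!all(object@codes %in% SS_CODES))
    msgs <- c(msgs, "codes outside the 9-state alphabet")
  sep <- is.na(object@residues)
  if (any(sep) && !all(object@codes[sep, , drop = FALSE] == "X"))
    msgs <- c(msgs, "chain-separator rows must be constant X")
  if (length(msgs)) msgs else TRUE
})

#' ContactMap: residue-residue minimum distances
#'
#' @slot residues global residue indices (size R).
#' @slot map symmetric R x R matrix of minimum inter-atomic distances, nm.
#' @slot frameCount number of frames averaged into the map.
#'
#' @aliases ContactMap
#' @exportClass ContactMap
setClass("ContactMap",
  representation(residues = "integer", map = "matrix", frameCount = "integer"))

setValidity("ContactMap", function(object) {
  m <- object@map
  msgs <- character()
  if (nrow(m) != ncol(m) || nrow(m) != length(object@residues))
    msgs <- c(msgs, "map must be square with one row per residue")
  else {
    if (any(m < 0)) msgs <- c(msgs, "distances must be non-negative")
    if (any(abs(diag(m)) > 1e-12)) msgs <- c(msgs, "diagonal must be zero")
    if (max(abs(m - t(m))) > 1e-9) msgs <- c(msgs, "map must be symmetric")
  }
  if (length(msgs)) msgs else TRUE
})

#' ZoneDirectory: the 10 domain-pair contact zones of a two-chain dimer
#'
#' Zones 1-3 pair domains within chain A, 4-6 within chain B, and 7-10 pair
#' domains across the two chains.
#'
#' @slot zones data.frame with columns zone, domainA, domainB (labels among
#'   N_A, C_A, N_B, C_B).
#' @slot partition the [DomainPartition-class] the zones were built from.
#'
#' @aliases ZoneDirectory
#' @exportClass ZoneDirectory
setClass("ZoneDirectory",
  representation(zones = "data.frame", partition = "DomainPartition"))

setValidity("ZoneDirectory", function(object) {
  if (nrow(object@zones) != 10L) return("exactly 10 zones required")
  TRUE
})
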