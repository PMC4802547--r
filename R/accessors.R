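# Accessor generics and show() methods.

#' Accessors for memsurf containers
#'
#' Slot access for [MDSystem-class], [MDTrajectory-class] and derived
#' objects goes through these accessors.
#'
#' @param x a memsurf S4 object.
#' @param i frame index (for `frameSystem`).
#' @return `atoms`: the atom table; `coords`: (atoms x 3) matrix in
#'   Angstrom; `boxDims`: length-3 box in Angstrom; `isPeriodic`: logical;
#'   `nAtoms`/`nResidues`/`nFrames`: integer counts; `chainIds`: character
#'   vector; `frameTimes`: numeric, ns; `frameSystem`: the [MDSystem-class]
#'   at frame `i`; `ssCodes`: character code matrix; `contactMatrix`: the
#'   distance matrix in nm; `zoneTable`: the 10-zone data.frame.
#' @name accessors
#' @aliases atoms coords boxDims isPeriodic nAtoms nResidues chainIds
#'   nFrames frameTimes frameSystem ssCodes contactMatrix zoneTable
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("boxDims", function(x) standardGeneric("boxDims"))
#' @rdname accessors
#' @export
setGeneric("isPeriodic", function(x) standardGeneric("isPeriodic"))
#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))
#' @rdname accessors
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setGeneric("frameSystem", function(x, i) standardGeneric("frameSystem"))
#' @rdname accessors
#' @export
setGeneric("ssCodes", function(x) standardGeneric("ssCodes"))
#' @rdname accessors
#' @export
setGeneric("contactMatrix", function(x) standardGeneric("contactMatrix"))
#' @rdname accessors
#' @export
setGeneric("zoneTable", function(x) standardGeneric("zoneTable"))

#' @rdname accessors
setMethod("atoms", "MDSystem", function(x) x@atoms)
#' @rdname accessors
setMethod("coords", "MDSystem", function(x) x@coords)
#' @rdname accessors
setMethod("boxDims", "MDSystem", function(x) x@box)
#' @rdname accessors
setMethod("isPeriodic", "MDSystem", function(x) x@periodic)
#' @rdname accessors
setMethod("nAtoms", "MDSystem", function(x) nrow(x@atoms))
#' @rdname accessors
setMethod("nResidues", "MDSystem",
          function(x) length(unique(x@atoms$resid[x@atoms$moleculeClass ==
                                                    "protein"])))
#' @rdname accessors
setMethod("chainIds", "MDSystem", function(x) unique(x@atoms$chain))

#' @rdname accessors
setMethod("atoms", "MDTrajectory", function(x) x@system@atoms)
#' @rdname accessors
setMethod("nAtoms", "MDTrajectory", function(x) nrow(x@system@atoms))
#' @rdname accessors
setMethod("nFrames", "MDTrajectory", function(x) dim(x@frames)[3L])
#' @rdname accessors
setMethod("frameTimes", "MDTrajectory", function(x) x@times)
#' @rdname accessors
setMethod("frameSystem", "MDTrajectory", function(x, i) {
  if (!isCount(i) || i > dim(x@frames)[3L])
    stopf("frame index %s out of range", format(i))
  s <- x@system
  s@coords <- x@frames[, , i, drop = TRUE]
  dim(s@coords) <- c(dim(x@frames)[1L], 3L)
  s
})

#' @rdname accessors
setMethod("ssCodes", "SSMatrix", function(x) x@codes)
#' @rdname accessors
setMethod("frameTimes", "SSMatrix", function(x) x@times)
#' @rdname accessors
setMethod("contactMatrix", "ContactMap", function(x) x@map)
#' @rdname accessors
setMethod("zoneTable", "ZoneDirectory", function(x) x@zones)

setMethod("show", "MDSystem", function(object) {
  a <- object@atoms
  cls <- table(factor(a$moleculeClass, levels = MOLECULE_CLASSES))
  cat(sprintf("MDSystem: %d atoms, %d chains (%s)\n", nrow(a),
              length(unique(a$chain)),
              paste(unique(a$chain), collapse = ",")))
  cat("  molecules by class:",
      paste(sprintf("%s=%d", names(cls), as.integer(
        vapply(names(cls), function(k)
          length(unique(a$moleculeId[a$moleculeClass == k])), numeric(1)))),
        collapse = " "), "\n")
  if (object@periodic)
    cat(sprintf("  periodic box: %.2f x %.2f x %.2f A\n",
                object@box[1L], object@box[2L], object@box[3L]))
  else cat("  non-periodic\n")
})

setMethod("show", "MDTrajectory", function(object) {
  cat(sprintf("MDTrajectory: %d frames, %d atoms, t = %.3f..%.3f ns\n",
              dim(object@frames)[3L], dim(object@frames)[1L],
              min(object@times), max(object@times)))
})

setMethod("show", "DomainPartition", function(object) {
  cat(sprintf("DomainPartition (split after chain-local residue %d):\n",
              object@splitResidue))
  print(object@table, row.names = FALSE)
})

setMethod("show", "SSMatrix", function(object) {
  tab <- table(factor(object@codes, levels = SS_CODES))
  cat(sprintf("SSMatrix: %d rows x %d frames\n", nrow(object@codes),
              ncol(object@codes)))
  cat("  code counts:", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                              collapse = " "), "\n")
})

setMethod("show", "ContactMap", function(object) {
  cat(sprintf(
    "ContactMap: %d residues, %d frame(s) averaged, range %.3f..%.3f nm\n",
    length(object@residues), object@frameCount,
    min(object@map[upper.tri(object@map)]),
    max(object@map)))
})

setMethod("show", "ZoneDirectory", function(object) {
  cat("ZoneDirectory (10 zones over N_A, C_A, N_B, C_B):\n")
  print(object@zones, row.names = FALSE)
})
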