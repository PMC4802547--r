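# Sorting of lipids and waters into annular (AL) and non-annular (nAL)
# regions around a membrane-bound protein: a molecule is annular when any
# of its atoms comes within `cutoff` of any protein atom, measured either
# in the x-y projection (lateral mode, the default reading of
# surround-style sorting) or in full 3D.

#' Sort lipid and water molecules into annular / non-annular regions
#'
#' Whole-molecule assignment: a lipid or water is annular iff the minimum
#' distance from any of its atoms to any protein atom is at most `cutoff`,
#' measured laterally (x-y, minimum image in x and y) or spatially (3D).
#'
#' @param frame an [MDSystem-class] with protein and lipid/water molecules.
#' @param cutoff annular shell cutoff, Angstrom (default 6, about one
#'   lipid coordination shell; a tunable, not a literature constant).
#' @param mode `"lateral"` (x-y projection) or `"spatial"` (3D).
#' @return data.frame with columns moleculeId, moleculeClass, label
#'   (`"annular"`/`"non_annular"`); attributes `cutoff` and `mode`.
#' @export
sortRegions <- function(frame, cutoff = 6, mode = c("lateral", "spatial")) {
  mode <- match.arg(mode)
  if (!isNum(cutoff) || cutoff <= 0) stopf("cutoff must be positive")
  a <- atoms(frame)
  protRows <- which(a$moleculeClass == "protein")
  if (!length(protRows)) stopf("frame contains no protein atoms")
  target <- which(a$moleculeClass %in% c("lipid", "water"))
  if (!length(target)) stopf("frame contains no lipid or water molecules")
  xyz <- coords(frame)
  prot <- xyz[protRows, , drop = FALSE]
  ids <- unique(a$moleculeId[target])
  lab <- character(length(ids))
  for (k in seq_along(ids)) {
    rows <- target[a$moleculeId[target] == ids[k]]
    d <- minPairDistance(xyz[rows, , drop = FALSE], prot,
                         boxDims(frame), isPeriodic(frame),
                         lateral = (mode == "lateral"))
    lab[k] <- if (d <= cutoff) "annular" else "non_annular"
  }
  out <- data.frame(
    moleculeId = ids,
    moleculeClass = a$moleculeClass[match(ids, a$moleculeId)],
    label = lab, stringsAsFactors = FALSE)
  attr(out, "cutoff") <- cutoff
  attr(out, "mode") <- mode
  out
}

#' Census of annular / non-annular molecules
#'
#' Counts annular and non-annular lipids per leaflet plus waters overall.
#'
#' @param labels output of [sortRegions()] for the same frame.
#' @param frame the [MDSystem-class] the labels were computed from.
#' @param headgroup_atom headgroup atom name for leaflet assignment.
#' @return data.frame with columns group ("upper", "lower", "water"),
#'   annular, non_annular, total.
#' @export
regionCensus <- function(labels, frame, headgroup_atom = "P") {
  a <- atoms(frame)
  expected <- unique(a$moleculeId[a$moleculeClass %in% c("lipid", "water")])
  if (!setequal(labels$moleculeId, expected))
    stopf("label/frame mismatch: molecule ids do not agree")
  isLip <- labels$moleculeClass == "lipid"
  rows <- list()
  if (any(isLip)) {
    lf <- assignLeaflets(frame, headgroup_atom)
    side <- lf$leaflet[match(labels$moleculeId[isLip], lf$moleculeId)]
    for (s in c("upper", "lower")) {
      sub <- labels$label[isLip][side == s]
      rows[[s]] <- data.frame(group = s,
                              annular = sum(sub == "annular"),
                              non_annular = sum(sub == "non_annular"),
                              total = length(sub))
    }
  }
  wat <- labels$label[labels$moleculeClass == "water"]
  if (length(wat))
    rows$water <- data.frame(group = "water",
                             annular = sum(wat == "annular"),
                             non_annular = sum(wat == "non_annular"),
                             total = length(wat))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
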