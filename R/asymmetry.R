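# Leaflet assignment and the asymmetric-bilayer mismatch metrics:
# lipid-number mismatch and surface-area-per-lipid (SAPL) mismatch, both
# defined as |difference| / larger value * 100.

#' Assign lipids to bilayer leaflets
#'
#' The midplane is the mean z of all headgroup atoms; a lipid is in the
#' upper leaflet iff its headgroup sits above the midplane.  Using the
#' headgroup mean rather than the box centre keeps the assignment correct
#' for bilayers not centred in the box.
#'
#' @param frame an [MDSystem-class] containing lipids.
#' @param headgroup_atom headgroup atom name (default "P", the phosphate).
#' @return data.frame with columns moleculeId and leaflet
#'   (`"upper"`/`"lower"`); attribute `counts` holds the per-leaflet totals.
#' @export
#' @examples
#' attr(assignLeaflets(makeBilayer(bilayerSpec(8, 4))), "counts")
assignLeaflets <- function(frame, headgroup_atom = "P") {
  a <- atoms(frame)
  lip <- which(a$moleculeClass == "lipid")
  if (!length(lip)) stopf("frame contains no lipids")
  ids <- unique(a$moleculeId[lip])
  head <- lip[a$name[lip] == headgroup_atom]
  missing <- setdiff(ids, a$moleculeId[head])
  if (length(missing))
    stopf("lipid molecule %d has no '%s' headgroup atom",
          missing[1L], headgroup_atom)
  z <- coords(frame)[head, 3L]
  mid <- mean(z)
  if (any(z == mid))
    stopf("ambiguous leaflet: headgroup of molecule %d lies exactly on the midplane",
          a$moleculeId[head][which(z == mid)[1L]])
  out <- data.frame(moleculeId = a$moleculeId[head],
                    leaflet = ifelse(z > mid, "upper", "lower"),
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- c(upper = sum(out$leaflet == "upper"),
                           lower = sum(out$leaflet == "lower"))
  out
}

#' Lipid-number mismatch percentage
#'
#' `|n_a - n_b| / max(n_a, n_b) * 100`.
#'
#' @param n_a,n_b leaflet lipid counts (>= 1).
#' @return Percentage in [0, 100].
#' @export
#' @examples
#' numberMismatch(576, 288)  # 50
numberMismatch <- function(n_a, n_b) {
  if (!isCount(n_a) || !isCount(n_b))
    stopf("leaflet lipid counts must be positive")
  abs(n_a - n_b) / max(n_a, n_b) * 100
}

#' Surface-area-per-lipid mismatch percentage
#'
#' `|apl_a - apl_b| / max(apl_a, apl_b) * 100`.  When both leaflets share
#' one lateral box area A (so apl = A / n), this equals the lipid-number
#' mismatch exactly.
#'
#' @param apl_a,apl_b areas per lipid, Angstrom^2 (> 0).
#' @return Percentage in [0, 100].
#' @export
#' @examples
#' saplMismatch(68, 34)  # 50
saplMismatch <- function(apl_a, apl_b) {
  if (!isNum(apl_a) || !isNum(apl_b) || apl_a <= 0 || apl_b <= 0)
    stopf("areas per lipid must be positive")
  abs(apl_a - apl_b) / max(apl_a, apl_b) * 100
}

#' Leaflet statistics of a bilayer frame
#'
#' Combines leaflet assignment, the shared lateral box area and both
#' mismatch metrics.  Per-leaflet areas default to the shared lateral box
#' area; externally measured per-leaflet areas may be supplied instead.
#'
#' @param frame a periodic [MDSystem-class] containing a bilayer.
#' @param headgroup_atom headgroup atom name.
#' @param area_upper,area_lower optional externally measured leaflet
#'   areas, Angstrom^2; default is the lateral box area for both.
#' @return List of class `"LeafletStats"`: n_upper, n_lower, area,
#'   apl_upper, apl_lower, number_mismatch_pct, sapl_mismatch_pct.
#' @export
#' @examples
#' leafletStats(makeBilayer(bilayerSpec(576, 288)))$number_mismatch_pct
leafletStats <- function(frame, headgroup_atom = "P",
                         area_upper = NULL, area_lower = NULL) {
  if (!isPeriodic(frame))
    stopf("leaflet statistics require a periodic frame")
  counts <- attr(assignLeaflets(frame, headgroup_atom), "counts")
  area <- boxDims(frame)[1L] * boxDims(frame)[2L]
  aU <- if (is.null(area_upper)) area else area_upper
  aL <- if (is.null(area_lower)) area else area_lower
  aplU <- aU / counts[["upper"]]
  aplL <- aL / counts[["lower"]]
  structure(list(
    n_upper = counts[["upper"]], n_lower = counts[["lower"]],
    area = area, apl_upper = aplU, apl_lower = aplL,
    number_mismatch_pct = numberMismatch(counts[["upper"]],
                                         counts[["lower"]]),
    sapl_mismatch_pct = saplMismatch(aplU, aplL)),
    class = "LeafletStats")
}

#' @export
print.LeafletStats <- function(x, ...) {
  cat(sprintf(
    "LeafletStats: %d upper / %d lower lipids, area %.1f A^2\n",
    x$n_upper, x$n_lower, x$area))
  cat(sprintf("  APL upper %.2f, lower %.2f A^2/lipid\n",
              x$apl_upper, x$apl_lower))
  cat(sprintf("  number mismatch %.2f%%, SAPL mismatch %.2f%%\n",
              x$number_mismatch_pct, x$sapl_mismatch_pct))
  invisible(x)
}
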