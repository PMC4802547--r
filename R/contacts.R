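# Residue-contact minimum-distance maps, the 10-zone domain directory for
# a two-chain dimer, and last-window / cross-replicate averaging.

#' Residue-contact map of one frame
#'
#' Symmetric matrix of minimum inter-atomic distances between every pair
#' of protein residues (minimum-image convention when periodic), reported
#' in nm; the diagonal is zero.
#'
#' @param frame an [MDSystem-class] with at least two protein residues.
#' @param heavy_only drop hydrogens before taking minima (default TRUE;
#'   fixtures may carry no hydrogens, and including them would bias the
#'   minima when present).
#' @return A [ContactMap-class].
#' @export
contactMap <- function(frame, heavy_only = TRUE) {
  a <- atoms(frame)
  sel <- a$moleculeClass == "protein"
  if (heavy_only) sel <- sel & a$element != "H"
  idx <- which(sel)
  resids <- sort(unique(a$resid[idx]))
  R <- length(resids)
  if (R < 2L) stopf("need at least 2 protein residues")
  xyz <- coords(frame)[idx, , drop = FALSE]
  grp <- match(a$resid[idx], resids)
  D <- pairDistanceMatrix(xyz, xyz, boxDims(frame), isPeriodic(frame))
  m <- matrix(0, R, R)
  byRes <- split(seq_along(grp), grp)
  for (i in seq_len(R - 1L)) for (j in (i + 1L):R) {
    v <- min(D[byRes[[i]], byRes[[j]]])
    m[i, j] <- v; m[j, i] <- v
  }
  new("ContactMap", residues = as.integer(resids), map = m / 10,
      frameCount = 1L)
}

#' Time series of contact maps over a trajectory
#'
#' @param traj an [MDTrajectory-class].
#' @param heavy_only see [contactMap()].
#' @return List with `times` (ns) and `maps` (list of [ContactMap-class]).
#' @export
contactMapSeries <- function(traj, heavy_only = TRUE) {
  nf <- nFrames(traj)
  maps <- vector("list", nf)
  for (k in seq_len(nf)) maps[[k]] <- contactMap(frameSystem(traj, k),
                                                 heavy_only)
  list(times = frameTimes(traj), maps = maps)
}

.windowMean <- function(series, window_ns, label) {
  tt <- series$times
  if (max(tt) - min(tt) < window_ns && length(tt) > 1L)
    stopf("replicate '%s' spans %.3f ns, shorter than the %.3f ns window",
          label, max(tt) - min(tt), window_ns)
  keep <- which(tt >= max(tt) - window_ns)
  ms <- series$maps[keep]
  acc <- Reduce(`+`, lapply(ms, contactMatrix))
  list(map = acc / length(ms), n = length(ms),
       residues = ms[[1L]]@residues)
}

#' Average contact maps over a trailing window and across replicates
#'
#' Two-stage mean matching the usual reporting convention: per replicate,
#' the arithmetic mean over frames in the trailing `window_ns`; then an
#' unweighted mean across replicates.
#'
#' @param maps_by_replicate list of replicates, each a
#'   [contactMapSeries()] result (elements `times`, `maps`).
#' @param window_ns trailing window length, ns (default 50).
#' @return A [ContactMap-class]; `frameCount` is the total frame count.
#' @export
averageMaps <- function(maps_by_replicate, window_ns = 50) {
  if (!length(maps_by_replicate)) stopf("no replicates supplied")
  labs <- names(maps_by_replicate)
  if (is.null(labs)) labs <- as.character(seq_along(maps_by_replicate))
  wm <- Map(.windowMean, maps_by_replicate, window_ns, labs)
  acc <- Reduce(`+`, lapply(wm, `[[`, "map")) / length(wm)
  new("ContactMap", residues = wm[[1L]]$residues, map = acc,
      frameCount = as.integer(sum(vapply(wm, `[[`, 0, "n"))))
}

#' Build the 10-zone contact directory of a two-chain dimer
#'
#' Enumerates the unordered pairs of the four domains N_A, C_A, N_B, C_B:
#' zones 1-3 pair domains within chain A, 4-6 within chain B, 7-10 across
#' the chains.
#'
#' @param partition a two-chain [DomainPartition-class].
#' @return A [ZoneDirectory-class].
#' @export
#' @examples
#' zoneDirectory(assignDomains(buildDimer(abeta42Sequence())))
zoneDirectory <- function(partition) {
  ch <- unique(partition@table$chain)
  if (length(ch) != 2L)
    stopf("zone directory requires exactly 2 chains, found %d", length(ch))
  A <- ch[1L]; B <- ch[2L]
  dn <- function(d, c) paste0(d, "_", c)
  zones <- rbind(
    c(dn("N", A), dn("N", A)), c(dn("N", A), dn("C", A)),
    c(dn("C", A), dn("C", A)),
    c(dn("N", B), dn("N", B)), c(dn("N", B), dn("C", B)),
    c(dn("C", B), dn("C", B)),
    c(dn("N", A), dn("N", B)), c(dn("N", A), dn("C", B)),
    c(dn("C", A), dn("N", B)), c(dn("C", A), dn("C", B)))
  new("ZoneDirectory",
      zones = data.frame(zone = 1:10, domainA = zones[, 1L],
                         domainB = zones[, 2L], stringsAsFactors = FALSE),
      partition = partition)
}

#' Zone membership of residue pairs
#'
#' @param directory a [ZoneDirectory-class].
#' @param i,j equal-length vectors of global residue indices.
#' @return Integer vector of zone ids (1..10).
#' @export
#' @examples
#' zd <- zoneDirectory(assignDomains(buildDimer(abeta42Sequence())))
#' zoneOf(zd, 5, 60)  # N_A paired with C_B -> zone 8
zoneOf <- function(directory, i, j) {
  di <- domainLabels(directory@partition, i)
  dj <- domainLabels(directory@partition, j)
  z <- directory@zones
  key <- paste(pmin(di, dj), pmax(di, dj))
  zkey <- paste(pmin(z$domainA, z$domainB), pmax(z$domainA, z$domainB))
  id <- z$zone[match(key, zkey)]
  if (anyNA(id)) stopf("residue pair outside the zone directory")
  id
}

# Per-zone mean of one map: within-domain zones use i < j (diagonal
# excluded), cross-domain zones the full rectangle of pairs.
.zoneMeans <- function(map, residues, directory) {
  lab <- domainLabels(directory@partition, residues)
  z <- directory@zones
  out <- numeric(nrow(z))
  for (k in seq_len(nrow(z))) {
    ia <- which(lab == z$domainA[k]); ib <- which(lab == z$domainB[k])
    if (z$domainA[k] == z$domainB[k]) {
      pairs <- map[ia, ib, drop = FALSE]
      out[k] <- mean(pairs[upper.tri(pairs)])
    } else out[k] <- mean(map[ia, ib])
  }
  out
}

#' Zone-averaged contact distances with replicate SEMs
#'
#' Per replicate, contact maps are averaged over the trailing `window_ns`
#' and summarised as the mean distance within each of the 10 zones; the
#' function then reports the cross-replicate mean and the standard error
#' of the mean (sd over replicates / sqrt(n), sd with n - 1 denominator).
#' With a single replicate the SEM is reported as NA, not zero.
#'
#' @param maps_by_replicate list of [contactMapSeries()] results.
#' @param directory a [ZoneDirectory-class].
#' @param window_ns trailing window, ns.
#' @return data.frame with columns zone, domainA, domainB, mean (nm),
#'   sem (nm), n_replicates.
#' @export
zoneStats <- function(maps_by_replicate, directory, window_ns = 50) {
  if (!length(maps_by_replicate)) stopf("no replicates supplied")
  labs <- names(maps_by_replicate)
  if (is.null(labs)) labs <- as.character(seq_along(maps_by_replicate))
  perRep <- vapply(seq_along(maps_by_replicate), function(r) {
    wm <- .windowMean(maps_by_replicate[[r]], window_ns, labs[r])
    .zoneMeans(wm$map, wm$residues, directory)
  }, numeric(10L))
  perRep <- matrix(perRep, nrow = 10L)
  n <- ncol(perRep)
  mean_ <- rowMeans(perRep)
  sem <- if (n >= 2L) apply(perRep, 1L, sd) / sqrt(n) else rep(NA_real_, 10L)
  cbind(directory@zones,
        data.frame(mean = mean_, sem = sem, n_replicates = n))
}
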