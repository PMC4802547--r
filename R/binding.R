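# Surface-binding kinetics: protein-lipid minimum-distance series,
# attachment-time detection by a two-segment changepoint fit, and the
# membrane-orientation angle.

#' Select atom indices of a system
#'
#' @param system an [MDSystem-class].
#' @param class,chain,name,resid optional filters on molecule class, chain
#'   id, atom name and global residue index; NULL means no restriction.
#' @return Integer vector of atom row indices.
#' @export
#' @examples
#' b <- makeBilayer(bilayerSpec(4, 4))
#' length(selectAtoms(b, name = "P"))  # 8 headgroups
selectAtoms <- function(system, class = NULL, chain = NULL, name = NULL,
                        resid = NULL) {
  a <- atoms(system)
  keep <- rep(TRUE, nrow(a))
  if (!is.null(class)) keep <- keep & a$moleculeClass %in% class
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  which(keep)
}

.resolveSelection <- function(system, sel, label) {
  idx <- if (is.numeric(sel)) as.integer(sel)
  else if (is.list(sel)) do.call(selectAtoms, c(list(system), sel))
  else stopf("selection '%s' must be atom indices or a filter list", label)
  if (!length(idx)) stopf("selection error: '%s' selects no atoms", label)
  if (any(idx < 1L | idx > nAtoms(system)))
    stopf("selection error: '%s' indexes atoms outside the system", label)
  idx
}

#' Protein-lipid minimum-distance time series
#'
#' For every frame, the minimum over all atom pairs (one atom from each
#' selection) of the minimum-image Euclidean distance.  Exact all-pairs
#' evaluation.
#'
#' @param traj an [MDTrajectory-class].
#' @param sel_a,sel_b atom selections: integer atom indices, or a list of
#'   filters passed to [selectAtoms()] (e.g. `list(class = "protein")`).
#' @return data.frame with columns `time` (ns) and `distance` (Angstrom);
#'   attributes `selection_a`/`selection_b` record the selections.
#' @export
minDistanceSeries <- function(traj, sel_a, sel_b) {
  sys <- traj@system
  ia <- .resolveSelection(sys, sel_a, "sel_a")
  ib <- .resolveSelection(sys, sel_b, "sel_b")
  nf <- nFrames(traj)
  d <- numeric(nf)
  for (k in seq_len(nf)) {
    xyz <- traj@frames[, , k]
    d[k] <- minPairDistance(xyz[ia, , drop = FALSE],
                            xyz[ib, , drop = FALSE],
                            boxDims(sys), isPeriodic(sys))
  }
  out <- data.frame(time = frameTimes(traj), distance = d)
  attr(out, "selection_a") <- deparse1(substitute(sel_a))
  attr(out, "selection_b") <- deparse1(substitute(sel_b))
  out
}

#' Detect the attachment time of a binding trace
#'
#' Fits the two-line model used to read attachment times off
#' minimum-distance plots: a least-squares decline line over samples
#' `1..k` and a horizontal plateau (segment mean) over samples `k..n`, for
#' every interior breakpoint k; the breakpoint minimising the total sum of
#' squared errors wins (ties broken toward the earliest k).  The
#' attachment time is the abscissa where the decline line crosses the
#' plateau level, clamped to the observed time range.
#'
#' @param series data.frame with columns `time` and `distance` (such as
#'   from [minDistanceSeries()]).
#' @param plateau_fraction fraction of trailing samples whose mean sets
#'   the reference scale of the flatness guard: a series whose total
#'   spread is negligible on that scale is rejected as "no attachment".
#' @return List with `t_attach` (ns), `decline_slope` (Angstrom/ns),
#'   `plateau_level` (Angstrom), `breakpoint_index`, `sse`.
#' @export
#' @examples
#' tr <- data.frame(time = 0:19, distance = c(20 - 2 * (0:8), rep(2, 11)))
#' detectAttachment(tr)$t_attach  # 9
detectAttachment <- function(series, plateau_fraction = 0.25) {
  t <- series$time; y <- series$distance
  n <- length(t)
  if (n < 8L) stopf("need at least 8 samples, got %d", n)
  tailN <- max(2L, ceiling(plateau_fraction * n))
  scale0 <- max(1, abs(mean(tail(y, tailN))))
  if (diff(range(y)) <= 1e-9 * scale0)
    stopf("no attachment detected: series is flat")
  ks <- 3:(n - 1L)  # decline needs >= 3 samples, plateau >= 2 (k shared)
  # prefix sums for the decline fit over [1..k]
  Sx <- cumsum(t); Sy <- cumsum(y)
  Sxx <- cumsum(t * t); Sxy <- cumsum(t * y); Syy <- cumsum(y * y)
  k <- ks
  vx <- Sxx[k] - Sx[k]^2 / k
  cxy <- Sxy[k] - Sx[k] * Sy[k] / k
  slope <- cxy / vx
  sseD <- pmax(0, (Syy[k] - Sy[k]^2 / k) - slope * cxy)
  # suffix stats for the plateau over [k..n] (sample k in both segments)
  m <- n - k + 1L
  Ty <- sum(y) - c(0, Sy)[k]  # sum over k..n
  Tyy <- sum(y * y) - c(0, Syy)[k]
  mu <- Ty / m
  sseP <- pmax(0, Tyy - Ty^2 / m)
  tot <- sseD + sseP
  best <- which.min(tot)  # which.min takes the earliest tie
  kb <- ks[best]
  b <- slope[best]
  if (!is.finite(b) || b >= 0)
    stopf("no attachment detected: decline slope is not negative")
  a0 <- Sy[kb] / kb - b * Sx[kb] / kb
  lvl <- mu[best]
  ta <- (lvl - a0) / b
  list(t_attach = min(max(ta, t[1L]), t[n]),
       decline_slope = b, plateau_level = lvl,
       breakpoint_index = kb, sse = tot[best])
}

#' Membrane-orientation angle series
#'
#' Per frame, the angle between the vector from one residue's reference
#' atom to another's (e.g. the C-terminal Ala to the loop-tip Lys of a
#' membrane-bound amyloid chain) and the bilayer normal (+z), in degrees
#' within [0, 180].
#'
#' @param traj an [MDTrajectory-class].
#' @param from_res,to_res global residue indices of the vector's tail and
#'   head.
#' @param atom_name reference atom within each residue (default "CA").
#' @return data.frame with columns `time` (ns) and `angle` (degrees);
#'   attributes `from_residue`, `to_residue`.
#' @export
orientationSeries <- function(traj, from_res, to_res, atom_name = "CA") {
  sys <- traj@system
  a <- atoms(sys)
  iFrom <- which(a$resid == from_res & a$name == atom_name)
  iTo <- which(a$resid == to_res & a$name == atom_name)
  if (length(iFrom) != 1L || length(iTo) != 1L)
    stopf("residues %s and %s must each contain one '%s' atom",
          format(from_res), format(to_res), atom_name)
  nf <- nFrames(traj)
  ang <- numeric(nf)
  for (k in seq_len(nf)) {
    v <- traj@frames[iTo, , k] - traj@frames[iFrom, , k]
    if (vnorm(v) == 0)
      stopf("degenerate geometry at frame %d: zero-length vector", k)
    ang[k] <- vecAngle(v, c(0, 0, 1))
  }
  out <- data.frame(time = frameTimes(traj), angle = ang)
  attr(out, "from_residue") <- from_res
  attr(out, "to_residue") <- to_res
  out
}
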