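# Synthetic fixture generators with analytically known ground truth:
# pseudo-lipid bilayers, protein surface-binding trajectories, and ideal
# helix / antiparallel-strand geometries.  Every generator is a pure
# function of (spec, seed); randomness never touches the caller's RNG.

#' Bilayer fixture specification
#'
#' @param n_upper,n_lower lipid counts per leaflet.
#' @param apl target area per lipid, Angstrom^2 (default 65, a typical
#'   fluid-phase phosphatidylcholine value).
#' @param leaflet_sep headgroup-plane separation, Angstrom.
#' @param seed integer RNG seed for the lateral grid jitter.
#' @return A list of class `"BilayerSpec"`.
#' @export
bilayerSpec <- function(n_upper = 64L, n_lower = 64L, apl = 65,
                        leaflet_sep = 38, seed = 1L) {
  if (!isCount(n_upper) || !isCount(n_lower))
    stopf("leaflet lipid counts must be >= 1")
  if (!isNum(apl) || apl <= 0) stopf("apl must be positive")
  if (!isNum(leaflet_sep) || leaflet_sep <= 0)
    stopf("leaflet_sep must be positive")
  structure(list(n_upper = as.integer(n_upper),
                 n_lower = as.integer(n_lower),
                 apl = apl, leaflet_sep = leaflet_sep,
                 seed = as.integer(seed)),
            class = "BilayerSpec")
}

# One leaflet of 3-atom pseudo-lipids: headgroup P on a jittered square
# grid at z = +/- sep/2, two tail beads stepping toward the midplane.
.leafletAtoms <- function(n, L, zsign, sep) {
  ng <- ceiling(sqrt(n))
  sp <- L / ng
  cell <- which(matrix(TRUE, ng, ng), arr.ind = TRUE)[seq_len(n), , drop = FALSE]
  jit <- matrix(runif(2L * n, -0.2, 0.2) * sp, n, 2L)
  x <- (cell[, 1L] - 0.5) * sp + jit[, 1L]
  y <- (cell[, 2L] - 0.5) * sp + jit[, 2L]
  zP <- zsign * sep / 2
  xyz <- rbind(cbind(x, y, zP),
               cbind(x, y, zP - zsign * 4),
               cbind(x, y, zP - zsign * 8))
  ord <- c(t(matrix(seq_len(3L * n), n, 3L)))  # P, C1, C2 per lipid
  xyz[ord, , drop = FALSE]
}

#' Generate a two-leaflet pseudo-lipid bilayer
#'
#' Each lipid is a three-atom caricature (headgroup `P` plus two tail
#' beads) on a laterally jittered square grid; headgroup planes sit at
#' z = +/- leaflet_sep/2.  Both leaflets share one lateral box of area
#' `max(n_upper, n_lower) * apl`.  Deterministic at fixed seed.
#'
#' @param spec a [bilayerSpec()].
#' @return A periodic [MDSystem-class]; upper-leaflet lipids on chain "L",
#'   lower on chain "M", residue name POPC.
#' @export
#' @examples
#' b <- makeBilayer(bilayerSpec(16, 16, seed = 7))
#' nAtoms(b)  # 96
makeBilayer <- function(spec) {
  stopifnot(inherits(spec, "BilayerSpec"))
  area <- max(spec$n_upper, spec$n_lower) * spec$apl
  L <- sqrt(area)
  withSeed(spec$seed, {
    up <- .leafletAtoms(spec$n_upper, L, +1, spec$leaflet_sep)
    lo <- .leafletAtoms(spec$n_lower, L, -1, spec$leaflet_sep)
  })
  n <- spec$n_upper + spec$n_lower
  df <- data.frame(
    serial = seq_len(3L * n),
    name = rep(c("P", "C1", "C2"), n),
    element = rep(c("P", "C", "C"), n),
    resid = rep(seq_len(n), each = 3L),
    resname = "POPC",
    chain = rep(c("L", "M"), c(3L * spec$n_upper, 3L * spec$n_lower)),
    moleculeId = rep(seq_len(n), each = 3L),
    moleculeClass = "lipid", stringsAsFactors = FALSE)
  new("MDSystem", atoms = df, coords = rbind(up, lo),
      box = c(L, L, spec$leaflet_sep + 80), periodic = TRUE)
}

#' Surface-binding trace specification
#'
#' Parameters of the piecewise-linear approach profile: the exact
#' protein-headgroup minimum distance follows
#' `d(t) = max(plateau, d0 - (d0 - plateau)/t_attach * t)`, i.e. a linear
#' decline reaching `plateau` exactly at `t_attach`, plus optional
#' Gaussian jitter applied to the rigid-body z offset.
#'
#' @param t_attach attachment time, ns.
#' @param d0 initial minimum distance, Angstrom.
#' @param plateau stabilised minimum distance, Angstrom.
#' @param noise_sd standard deviation of the z-offset jitter, Angstrom.
#' @param t_end trajectory length, ns.
#' @param dt frame spacing, ns.
#' @param seed integer RNG seed for the jitter.
#' @return A list of class `"BindingTraceSpec"`.
#' @export
bindingTraceSpec <- function(t_attach = 4, d0 = 50, plateau = 5,
                             noise_sd = 0, t_end = 60, dt = 0.1,
                             seed = 1L) {
  if (!isNum(t_attach) || !isNum(t_end) || t_attach <= 0 ||
      t_attach >= t_end)
    stopf("need 0 < t_attach < t_end")
  if (!isNum(plateau) || plateau <= 0)
    stopf("geometric infeasibility: plateau must be positive")
  if (!isNum(d0) || plateau >= d0) stopf("need plateau < d0")
  if (!isNum(noise_sd) || noise_sd < 0) stopf("noise_sd must be >= 0")
  if (!isNum(dt) || dt <= 0 || dt >= t_end) stopf("bad frame spacing")
  structure(list(t_attach = t_attach, d0 = d0, plateau = plateau,
                 noise_sd = noise_sd, t_end = t_end, dt = dt,
                 seed = as.integer(seed)),
            class = "BindingTraceSpec")
}

# Concatenate two systems, renumbering serials and molecule ids and
# offsetting the second system's residue indices past the first's.
mergeSystems <- function(a, b) {
  at <- atoms(a); bt <- atoms(b)
  if (any(bt$chain %in% at$chain))
    stopf("cannot merge systems sharing chain ids")
  off <- max(at$resid)
  bt$resid <- bt$resid + off
  bt$moleculeId <- bt$moleculeId + max(at$moleculeId)
  m <- rbind(at, bt)
  m$serial <- seq_len(nrow(m))
  rownames(m) <- NULL
  per <- isPeriodic(a) || isPeriodic(b)
  box <- if (isPeriodic(a)) boxDims(a) else boxDims(b)
  new("MDSystem", atoms = m, coords = rbind(coords(a), coords(b)),
      box = box, periodic = per)
}

#' Generate a protein-approach trajectory over a bilayer
#'
#' Builds a peptide dimer from `sequence`, places it above the upper
#' leaflet of a [makeBilayer()] membrane, and translates it rigidly so
#' that the exact protein-to-upper-leaflet minimum distance at frame time
#' t equals the prescribed profile of `spec` (plus the seeded z jitter).
#' The dimer's lowest atom is aligned vertically over one headgroup
#' phosphorus, so the minimum distance is realised exactly by that pair.
#'
#' @param spec a [bindingTraceSpec()].
#' @param bilayer a [bilayerSpec()].
#' @param sequence one-letter protein sequence (default the 42-residue
#'   amyloid-beta monomer, built as a dimer).
#' @return An [MDTrajectory-class]; lipids static, protein translated.
#' @export
makeBindingTrajectory <- function(spec, bilayer = bilayerSpec(),
                                  sequence = abeta42Sequence()) {
  stopifnot(inherits(spec, "BindingTraceSpec"))
  mem <- makeBilayer(bilayer)
  prot <- buildDimer(sequence)
  sys <- mergeSystems(prot, mem)
  a <- atoms(sys)
  protRows <- which(a$moleculeClass == "protein")
  times <- seq(0, spec$t_end, by = spec$dt)
  nf <- length(times)
  noise <- if (spec$noise_sd > 0)
    withSeed(spec$seed, rnorm(nf, 0, spec$noise_sd)) else numeric(nf)
  xyz <- coords(sys)
  pxyz <- xyz[protRows, , drop = FALSE]
  low <- which.min(pxyz[, 3L])[1L]
  # anchor headgroup: upper-leaflet P nearest the lateral box centre
  upperP <- which(a$chain == "L" & a$name == "P")
  ctr <- boxDims(sys)[1:2] / 2
  anchor <- upperP[which.min((xyz[upperP, 1L] - ctr[1L])^2 +
                               (xyz[upperP, 2L] - ctr[2L])^2)]
  zP <- xyz[anchor, 3L]
  rate <- (spec$d0 - spec$plateau) / spec$t_attach
  frames <- array(0, c(nrow(a), 3L, nf))
  for (k in seq_len(nf)) {
    d <- max(spec$plateau, spec$d0 - rate * times[k]) + noise[k]
    shift <- c(xyz[anchor, 1L] - pxyz[low, 1L],
               xyz[anchor, 2L] - pxyz[low, 2L],
               zP + d - pxyz[low, 3L])
    fr <- xyz
    fr[protRows, ] <- sweep(pxyz, 2L, shift, "+")
    frames[, , k] <- fr
  }
  sys@coords <- frames[, , 1L, drop = TRUE]
  new("MDTrajectory", system = sys, times = times, frames = frames)
}

#' Ideal alpha-helix backbone
#'
#' Single chain with canonical helical torsions (phi = -57, psi = -47
#' degrees; ~1.5 Angstrom rise per residue), poly-alanine backbone.
#'
#' @param n_res number of residues (>= 6, the shortest span that can carry
#'   an i -> i+4 hydrogen bond pattern).
#' @return An [MDSystem-class].
#' @export
makeIdealHelix <- function(n_res) {
  if (!isCount(n_res) || n_res < 6L)
    stopf("n_res must be >= 6 for i -> i+4 hydrogen bonding")
  xyz <- buildBackbone(n_res, -57, -47)
  .proteinSystem(xyz, rep("ALA", 4L * n_res),
                 rep(seq_len(n_res), each = 4L), "A", 1L)
}

# Two-fold (C2) map sending a strand onto its antiparallel partner.
# Axis tilt and offset were fitted once so that the image of residue i
# hydrogen-bonds residue 13 - i of a 12-residue reference strand with
# ideal N-H...O=C geometry; for other lengths the strand is first shifted
# along its own two-residue repeat vector to recentre the registry.
BETA_C2_AXIS_TILT <- 0.087124288  # radians, axis tilt in the y-z plane
BETA_C2_SHIFT <- c(34.354781691, 21.160789664, -6.340891407)
BETA_C2_NREF <- 12L

#' Ideal antiparallel beta-strand pair
#'
#' Two extended strands (phi = -139, psi = 135 degrees) on chains A and B,
#' the second being the two-fold rotation image of the first, positioned
#' for inter-strand hydrogen bonding (~4.8 Angstrom strand separation, the
#' antiparallel ladder registry pairing residue i with the partner's
#' residue n - i + 1).
#'
#' @param n_res residues per strand (>= 3).
#' @return An [MDSystem-class] with two chains; global residue indices
#'   1..n and n+1..2n.
#' @export
#' @examples
#' table(assignSS(makeBetaPair(6)))
makeBetaPair <- function(n_res) {
  if (!isCount(n_res) || n_res < 3L)
    stopf("n_res must be >= 3 per strand")
  n_res <- as.integer(n_res)
  s1 <- buildBackbone(n_res, -139, 135)
  u <- c(0, sin(BETA_C2_AXIS_TILT), cos(BETA_C2_AXIS_TILT))
  M <- 2 * outer(u, u) - diag(3)
  ref <- buildBackbone(9L, -139, 135)
  v2 <- ref[4L * 6L + 2L, ] - ref[4L * 4L + 2L, ]  # CA(7) - CA(5)
  k2 <- BETA_C2_NREF - n_res
  k <- if (k2 %% 2L == 0L) k2 / 2 else (k2 - 1L) / 2
  s2 <- sweep(sweep(s1, 2L, k * v2, "+") %*% t(M), 2L, BETA_C2_SHIFT, "+")
  a <- .proteinSystem(s1, rep("ALA", 4L * n_res),
                      rep(seq_len(n_res), each = 4L), "A", 1L)
  b <- .proteinSystem(s2, rep("ALA", 4L * n_res),
                      rep(seq_len(n_res), each = 4L), "B", 1L)
  b@atoms$chain <- "B"
  mergeSystems(a, b)
}
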