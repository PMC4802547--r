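# Nine-state secondary-structure assignment from backbone hydrogen-bond
# patterns (Kabsch-Sander electrostatic model): H/G/I helices from
# consecutive n-turns, E/B strands from bridge patterns, T turns, S bends,
# C coil, and X as the separator row between chains in stacked output.

HB_COUPLING <- 0.084 * 332  # kcal/mol * Angstrom
HB_CUTOFF <- -0.5           # kcal/mol; bond declared below this
HB_CA_MAX <- 9              # Angstrom; donor/acceptor CA prefilter

#' Kabsch-Sander hydrogen-bond energy
#'
#' Electrostatic energy of a backbone N-H...O=C contact,
#' `E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN)` kcal/mol, where the
#' donor contributes N and H and the acceptor C and O.  A hydrogen bond is
#' declared when E < -0.5 kcal/mol.
#'
#' @param n,h donor backbone N and amide H positions (length-3, Angstrom).
#' @param c,o acceptor backbone C and O positions.
#' @return List with `energy` (kcal/mol) and `bonded` (logical).
#' @export
#' @examples
#' # degenerate square geometry: the four terms cancel exactly
#' hbondEnergy(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))$energy
hbondEnergy <- function(n, h, c, o) {
  pts <- rbind(n, h, c, o)
  if (!all(is.finite(pts))) stopf("all four positions must be finite")
  dd <- as.matrix(dist(pts))
  if (any(dd[upper.tri(dd)] < 0.5))
    stopf("geometry error: atoms closer than 0.5 Angstrom")
  e <- HB_COUPLING * (1 / dd["o", "n"] + 1 / dd["c", "h"] -
                        1 / dd["o", "h"] - 1 / dd["c", "n"])
  list(energy = e, bonded = e < HB_CUTOFF)
}

# Ordered protein-residue backbone index: one row per residue with atom
# row numbers for N, CA, C, O (NA when absent), chain and global resid.
.backboneTable <- function(system) {
  a <- atoms(system)
  prot <- which(a$moleculeClass == "protein")
  if (!length(prot)) stopf("system contains no protein")
  key <- paste(a$chain[prot], a$resid[prot])
  resKey <- unique(key)
  idx <- function(nm) {
    r <- rep(NA_integer_, length(resKey))
    hit <- prot[a$name[prot] == nm]
    r[match(paste(a$chain[hit], a$resid[hit]), resKey)] <- hit
    r
  }
  first <- prot[match(resKey, key)]
  data.frame(chain = a$chain[first], resid = a$resid[first],
             resname = a$resname[first],
             N = idx("N"), CA = idx("CA"), C = idx("C"), O = idx("O"),
             H = idx("H"), stringsAsFactors = FALSE)
}

#' Place backbone amide hydrogens
#'
#' Adds an `H` atom to every protein residue that lacks one, 1.0 Angstrom
#' from its N along the direction of the preceding residue's C=O bond
#' (the standard DSSP convention).  Prolines and chain-initial residues
#' get no hydrogen; residues whose preceding C/O atoms are missing are
#' skipped with a warning.
#'
#' @param system an [MDSystem-class] with backbone N, C, O atoms.
#' @return A new [MDSystem-class] including the placed hydrogens.
#' @export
placeAmideHydrogens <- function(system) {
  bb <- .backboneTable(system)
  xyz <- coords(system)
  a <- atoms(system)
  newAtoms <- list(); newXyz <- list()
  for (i in seq_len(nrow(bb))) {
    if (!is.na(bb$H[i]) || bb$resname[i] == "PRO") next
    prev <- if (i > 1L && bb$chain[i - 1L] == bb$chain[i]) i - 1L else NA
    if (is.na(prev)) next
    if (is.na(bb$C[prev]) || is.na(bb$O[prev]) || is.na(bb$N[i])) {
      warning(sprintf(
        "skipping amide H of residue %d: previous-residue backbone incomplete",
        bb$resid[i]), call. = FALSE)
      next
    }
    co <- xyz[bb$C[prev], ] - xyz[bb$O[prev], ]
    hpos <- xyz[bb$N[i], ] + unitv(co) * 1.0
    ref <- a[bb$N[i], , drop = FALSE]
    ref$name <- "H"; ref$element <- "H"
    newAtoms[[length(newAtoms) + 1L]] <- ref
    newXyz[[length(newXyz) + 1L]] <- hpos
  }
  if (!length(newAtoms)) return(system)
  a2 <- rbind(a, do.call(rbind, newAtoms))
  a2$serial <- seq_len(nrow(a2))
  rownames(a2) <- NULL
  initialize(system, atoms = a2,
             coords = rbind(xyz, do.call(rbind, newXyz)))
}

# Hydrogen-bond matrix: hb[a, b] TRUE when CO of residue a accepts the
# N-H of residue b with Kabsch-Sander energy < -0.5 kcal/mol.
.hbondMatrix <- function(bb, xyz) {
  R <- nrow(bb)
  hb <- matrix(FALSE, R, R)
  hasDon <- !is.na(bb$H) & !is.na(bb$N)
  hasAcc <- !is.na(bb$C) & !is.na(bb$O)
  if (!any(hasDon) || !any(hasAcc)) return(hb)
  ca <- xyz[bb$CA, , drop = FALSE]
  near <- pairDistanceMatrix(ca, ca) < HB_CA_MAX
  Opos <- xyz[ifelse(is.na(bb$O), 1L, bb$O), , drop = FALSE]
  Cpos <- xyz[ifelse(is.na(bb$C), 1L, bb$C), , drop = FALSE]
  Npos <- xyz[ifelse(is.na(bb$N), 1L, bb$N), , drop = FALSE]
  Hpos <- xyz[ifelse(is.na(bb$H), 1L, bb$H), , drop = FALSE]
  rON <- pairDistanceMatrix(Opos, Npos)
  rCH <- pairDistanceMatrix(Cpos, Hpos)
  rOH <- pairDistanceMatrix(Opos, Hpos)
  rCN <- pairDistanceMatrix(Cpos, Npos)
  E <- HB_COUPLING * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
  ok <- outer(hasAcc, hasDon, "&") & near & !diag(TRUE, R)
  clash <- rON < 0.5 | rCH < 0.5 | rOH < 0.5 | rCN < 0.5
  hb <- ok & !clash & E < HB_CUTOFF
  hb
}

#' Assign secondary structure to one frame
#'
#' Kabsch-Sander pattern assignment over the backbone hydrogen-bond graph:
#' n-turns (CO of i to NH of i+n, n = 3, 4, 5) combine into G/H/I helices
#' when two start consecutively; parallel and antiparallel bridge patterns
#' give B, and ladders of consecutive bridges give E; remaining turn spans
#' give T; a CA-trace direction change above 70 degrees gives the bend S;
#' everything else is coil C.  Per-residue priority H > E/B > G > I > T > S.
#' Amide hydrogens are placed first if absent.
#'
#' @param frame an [MDSystem-class] containing a protein.
#' @return Character vector of codes, one per protein residue in global
#'   residue order; names are the global residue indices.
#' @export
#' @examples
#' table(assignSS(makeIdealHelix(12)))
assignSS <- function(frame) {
  bb <- .backboneTable(frame)
  if (all(is.na(bb$H))) {
    frame <- suppressWarnings(placeAmideHydrogens(frame))
    bb <- .backboneTable(frame)
  }
  incomplete <- is.na(bb$N) | is.na(bb$CA) | is.na(bb$C) | is.na(bb$O)
  if (any(incomplete))
    warning(sprintf("%d residue(s) with incomplete backbone assigned C",
                    sum(incomplete)), call. = FALSE)
  xyz <- coords(frame)
  R <- nrow(bb)
  hb <- .hbondMatrix(bb, xyz)
  sameChain <- function(i, j)
    !is.na(i) & !is.na(j) & i >= 1L & j <= R & i <= R & j >= 1L &
      bb$chain[pmax(pmin(i, R), 1L)] == bb$chain[pmax(pmin(j, R), 1L)]
  turn <- list()
  for (n in 3:5) {
    t <- rep(FALSE, R)
    i <- seq_len(max(0L, R - n))
    ok <- bb$chain[i] == bb$chain[i + n]
    t[i[ok]] <- hb[cbind(i[ok], i[ok] + n)]
    turn[[as.character(n)]] <- t
  }
  ss <- rep("C", R)
  ss[incomplete] <- "C"
  # alpha helices: two consecutive 4-turns at i-1 and i span residues i..i+3
  t4 <- turn[["4"]]
  for (i in seq_len(R)) {
    if (i >= 2L && i + 3L <= R && t4[i - 1L] && t4[i] &&
        bb$chain[i - 1L] == bb$chain[i + 3L])
      ss[i:(i + 3L)] <- "H"
  }
  # bridges
  hbAt <- function(a, b) {
    if (is.na(a) || is.na(b) || a < 1L || b < 1L || a > R || b > R)
      return(FALSE)
    hb[a, b]
  }
  inChain <- function(i, lo, hi)
    lo >= 1L && hi <= R && bb$chain[lo] == bb$chain[i] &&
      bb$chain[hi] == bb$chain[i]
  bridges <- list()
  for (i in seq_len(R)) for (j in seq_len(R)) {
    if (j < i + 3L) next
    pOK <- inChain(i, i - 1L, i + 1L) && inChain(j, j - 1L, j + 1L)
    par <- pOK && ((hbAt(i - 1L, j) && hbAt(j, i + 1L)) ||
                     (hbAt(j - 1L, i) && hbAt(i, j + 1L)))
    anti <- (hbAt(i, j) && hbAt(j, i)) ||
      (pOK && hbAt(i - 1L, j + 1L) && hbAt(j - 1L, i + 1L))
    if (par || anti)
      bridges[[length(bridges) + 1L]] <-
        list(i = i, j = j, type = if (anti) "A" else "P")
  }
  inLadder <- rep(FALSE, R); inBridge <- rep(FALSE, R)
  if (length(bridges)) {
    key <- vapply(bridges, function(b)
      paste(b$i, b$j, b$type), character(1L))
    for (b in bridges) {
      inBridge[c(b$i, b$j)] <- TRUE
      nxt <- if (b$type == "P") paste(b$i + 1L, b$j + 1L, "P")
             else paste(b$i + 1L, b$j - 1L, "A")
      prv <- if (b$type == "P") paste(b$i - 1L, b$j - 1L, "P")
             else paste(b$i - 1L, b$j + 1L, "A")
      if (nxt %in% key || prv %in% key) inLadder[c(b$i, b$j)] <- TRUE
    }
  }
  ss[inLadder & ss == "C"] <- "E"
  ss[inBridge & !inLadder & ss == "C"] <- "B"
  # 3-10 and pi helices: accepted only on spans free of higher classes
  markHelix <- function(ss, tn, n, code) {
    for (i in seq_len(R)) {
      if (i >= 2L && i + n - 1L <= R && tn[i - 1L] && tn[i] &&
          bb$chain[i - 1L] == bb$chain[i + n - 1L]) {
        span <- i:(i + n - 1L)
        if (all(ss[span] %in% c("C", "T", "S", code))) ss[span] <- code
      }
    }
    ss
  }
  ss <- markHelix(ss, turn[["3"]], 3L, "G")
  ss <- markHelix(ss, turn[["5"]], 5L, "I")
  # turns: interior residues of any unconsumed n-turn
  for (n in 3:5) {
    tn <- turn[[as.character(n)]]
    for (i in which(tn)) {
      span <- (i + 1L):(i + n - 1L)
      span <- span[span <= R]
      ss[span][ss[span] == "C"] <- "T"
    }
  }
  # bends: CA-trace kink > 70 degrees
  for (i in seq_len(R)) {
    if (ss[i] != "C") next
    if (i <= 2L || i + 2L > R) next
    if (bb$chain[i - 2L] != bb$chain[i] || bb$chain[i + 2L] != bb$chain[i])
      next
    if (any(is.na(bb$CA[c(i - 2L, i, i + 2L)]))) next
    u <- xyz[bb$CA[i], ] - xyz[bb$CA[i - 2L], ]
    v <- xyz[bb$CA[i + 2L], ] - xyz[bb$CA[i], ]
    if (vecAngle(u, v) > 70) ss[i] <- "S"
  }
  setNames(ss, bb$resid)
}

#' Secondary-structure matrix over a trajectory
#'
#' Runs [assignSS()] on every frame and stacks the per-residue codes into
#' an [SSMatrix-class]; one constant-`X` separator row is inserted between
#' consecutive chains, matching the 9-colour residue-by-time matrices of
#' membrane-binding studies.
#'
#' @param traj an [MDTrajectory-class] containing a protein.
#' @return An [SSMatrix-class].
#' @export
ssMatrix <- function(traj) {
  sys0 <- frameSystem(traj, 1L)
  bb <- .backboneTable(sys0)
  chains <- unique(bb$chain)
  rowsPerChain <- lapply(chains, function(ch) which(bb$chain == ch))
  resids <- integer(0); sep <- logical(0)
  for (k in seq_along(chains)) {
    resids <- c(resids, bb$resid[rowsPerChain[[k]]])
    sep <- c(sep, rep(FALSE, length(rowsPerChain[[k]])))
    if (k < length(chains)) { resids <- c(resids, NA); sep <- c(sep, TRUE) }
  }
  nf <- nFrames(traj)
  codes <- matrix("X", length(resids), nf)
  for (f in seq_len(nf)) {
    cc <- assignSS(frameSystem(traj, f))
    codes[!sep, f] <- unname(cc)
  }
  new("SSMatrix", residues = as.integer(resids), times = frameTimes(traj),
      codes = codes)
}

#' Reduce a secondary-structure matrix to hydrogen-bonded class counts
#'
#' Counts, per frame and per domain (N and C, pooled over chains), the
#' residues in the reduced classes BE (strand/bridge), GHI (all helices)
#' and T (turn), plus their sum BEGHIT; bend, coil and separator rows are
#' not hydrogen-bonded classes and never enter the counts.
#'
#' @param ssmat an [SSMatrix-class].
#' @param partition a [DomainPartition-class] covering its residues.
#' @return data.frame with columns time, domain, BE, GHI, T, BEGHIT.
#' @export
reduceCounts <- function(ssmat, partition) {
  keep <- !is.na(ssmat@residues)
  resids <- ssmat@residues[keep]
  lab <- domainLabels(partition, resids)         # errors if outside
  dom <- substr(lab, 1L, 1L)                     # pool chains: N or C
  codes <- ssmat@codes[keep, , drop = FALSE]
  out <- list()
  for (d in c("N", "C")) {
    m <- codes[dom == d, , drop = FALSE]
    be <- colSums(m == "B" | m == "E")
    ghi <- colSums(m == "G" | m == "H" | m == "I")
    tt <- colSums(m == "T")
    out[[d]] <- data.frame(time = ssmat@times, domain = d, BE = be,
                           GHI = ghi, T = tt, BEGHIT = be + ghi + tt)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
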