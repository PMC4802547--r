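# Peptide construction from sequence and domain bookkeeping.
#
# Backbones are generated from internal coordinates (ideal bond lengths
# N-CA 1.458, CA-C 1.525, C-N 1.329, C=O 1.231 Angstrom; standard backbone
# bond angles) by natural-extension placement, so any (phi, psi) pattern
# can be realised: fully extended chains for dimers, helical and strand
# geometries for the secondary-structure fixtures.

BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N <- 1.329
BOND_C_O <- 1.231
ANG_N_CA_C <- 111.2
ANG_CA_C_N <- 116.2
ANG_C_N_CA <- 121.7
ANG_CA_C_O <- 120.8

# Backbone coordinates for one chain: (4L x 3) matrix, atoms N, CA, C, O
# per residue.  phi/psi recycled to length L; omega fixed trans (180).
buildBackbone <- function(L, phi, psi) {
  phi <- rep_len(phi, L)
  psi <- rep_len(psi, L)
  xyz <- matrix(0, 4L * L, 3L)
  rowN <- function(i) 4L * (i - 1L) + 1L
  n <- c(0, 0, 0)
  ca <- c(BOND_N_CA, 0, 0)
  ang <- ANG_N_CA_C * pi / 180
  cc <- ca + BOND_CA_C * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(L)) {
    r <- rowN(i)
    xyz[r, ] <- n; xyz[r + 1L, ] <- ca; xyz[r + 2L, ] <- cc
    xyz[r + 3L, ] <- placeAtom(n, ca, cc, BOND_C_O, ANG_CA_C_O,
                               psi[i] + 180)
    if (i < L) {
      n2 <- placeAtom(n, ca, cc, BOND_C_N, ANG_CA_C_N, psi[i])
      ca2 <- placeAtom(ca, cc, n2, BOND_N_CA, ANG_C_N_CA, 180)
      cc2 <- placeAtom(cc, n2, ca2, BOND_CA_C, ANG_N_CA_C, phi[i + 1L])
      n <- n2; ca <- ca2; cc <- cc2
    }
  }
  xyz
}

.checkSequence <- function(sequence) {
  if (!isString(sequence) || nchar(sequence) == 0L)
    stopf("sequence error: sequence must be a non-empty string")
  letters1 <- strsplit(toupper(sequence), "")[[1L]]
  bad <- which(!(letters1 %in% names(AA_3LETTER)))
  if (length(bad))
    stopf("sequence error: invalid residue letter '%s' at position %d",
          letters1[bad[1L]], bad[1L])
  letters1
}

.proteinSystem <- function(xyz, resname, resid, chain, moleculeId) {
  n <- length(resname)
  name <- rep(c("N", "CA", "C", "O"), n / 4L)
  df <- data.frame(serial = seq_len(n), name = name,
                   element = substr(name, 1L, 1L),
                   resid = resid, resname = resname, chain = chain,
                   moleculeId = moleculeId, moleculeClass = "protein",
                   stringsAsFactors = FALSE)
  new("MDSystem", atoms = df, coords = xyz, box = c(0, 0, 0),
      periodic = FALSE)
}

#' Build a multi-chain peptide from a one-letter sequence
#'
#' Constructs `n_chains` copies of the sequence as extended-conformation
#' backbones (N, CA, C, O per residue; ideal bond lengths), laid side by
#' side with a 10 Angstrom lateral offset to avoid clashes.  Chains are
#' labelled A, B, ... and residue indices run continuously across chains
#' (chain A residues 1..L, chain B residues L+1..2L, ...), matching the
#' 1..84 numbering convention used for dimers throughout the package.
#'
#' @param sequence one-letter amino-acid string (20 standard residues).
#' @param n_chains number of identical chains (default 2: a dimer).
#' @param spacing lateral chain offset, Angstrom.
#' @return An [MDSystem-class], protein only, non-periodic.
#' @export
#' @examples
#' d42 <- buildDimer(abeta42Sequence())
#' nResidues(d42)  # 84
buildDimer <- function(sequence, n_chains = 2L, spacing = 10) {
  letters1 <- .checkSequence(sequence)
  if (!isCount(n_chains)) stopf("n_chains must be a positive integer")
  L <- length(letters1)
  res3 <- unname(AA_3LETTER[letters1])
  systems <- lapply(seq_len(n_chains), function(k) {
    xyz <- buildBackbone(L, 180, 180)
    xyz[, 2L] <- xyz[, 2L] + (k - 1L) * spacing
    .proteinSystem(xyz, rep(res3, each = 4L),
                   rep((k - 1L) * L + seq_len(L), each = 4L),
                   LETTERS[k], k)
  })
  atoms <- do.call(rbind, lapply(systems, atoms))
  atoms$serial <- seq_len(nrow(atoms))
  new("MDSystem", atoms = atoms,
      coords = do.call(rbind, lapply(systems, coords)),
      box = c(0, 0, 0), periodic = FALSE)
}

#' Remove C-terminal residues from every protein chain
#'
#' Drops the last `n_remove` residues of each protein chain (e.g. 2 to turn
#' a 42-residue isoform into the 40-residue one) and renumbers the
#' remaining protein residues continuously from 1 across chains.
#'
#' @param system an [MDSystem-class] containing protein chains.
#' @param n_remove number of C-terminal residues to drop per chain.
#' @return A new [MDSystem-class].
#' @export
#' @examples
#' d40 <- truncateCterm(buildDimer(abeta42Sequence()), 2)
#' nResidues(d40)  # 80
truncateCterm <- function(system, n_remove) {
  if (!isCount(n_remove, min = 0L))
    stopf("n_remove must be a non-negative integer")
  if (n_remove == 0L) return(system)
  a <- atoms(system)
  prot <- a$moleculeClass == "protein"
  if (!any(prot)) stopf("system has no protein chains")
  keep <- rep(TRUE, nrow(a))
  for (ch in unique(a$chain[prot])) {
    inch <- prot & a$chain == ch
    res <- sort(unique(a$resid[inch]))
    if (n_remove >= length(res))
      stopf("cannot remove %d residues from chain %s of length %d",
            n_remove, ch, length(res))
    drop <- tail(res, n_remove)
    keep[inch & a$resid %in% drop] <- FALSE
  }
  a2 <- a[keep, , drop = FALSE]
  xyz <- coords(system)[keep, , drop = FALSE]
  prot2 <- a2$moleculeClass == "protein"
  old <- unique(a2$resid[prot2])
  a2$resid[prot2] <- match(a2$resid[prot2], old)
  a2$serial <- seq_len(nrow(a2))
  rownames(a2) <- NULL
  initialize(system, atoms = a2, coords = xyz)
}

#' Partition protein chains into N- and C-terminal domains
#'
#' Splits every protein chain after chain-local residue `split_residue`
#' (default 17, the N-terminal domain of the amyloid-beta peptide): the
#' N domain covers chain-local residues 1..split, the C domain the
#' remainder.
#'
#' @param system an [MDSystem-class] with protein chains.
#' @param split_residue chain-local index of the last N-domain residue.
#' @return A [DomainPartition-class] with global residue ranges per domain.
#' @export
#' @examples
#' assignDomains(buildDimer(abeta42Sequence()))
assignDomains <- function(system, split_residue = 17L) {
  a <- atoms(system)
  prot <- a$moleculeClass == "protein"
  if (!any(prot)) stopf("system has no protein chains")
  chains <- unique(a$chain[prot])
  lens <- vapply(chains, function(ch)
    length(unique(a$resid[prot & a$chain == ch])), integer(1L))
  if (!isCount(split_residue) || split_residue >= min(lens))
    stopf("split_residue must lie in 1..%d", min(lens) - 1L)
  rows <- lapply(chains, function(ch) {
    res <- sort(unique(a$resid[prot & a$chain == ch]))
    data.frame(chain = ch, domain = c("N", "C"),
               from = c(res[1L], res[split_residue] + 1L),
               to = c(res[split_residue], res[length(res)]),
               stringsAsFactors = FALSE)
  })
  new("DomainPartition", splitResidue = as.integer(split_residue),
      table = do.call(rbind, rows))
}

# Domain label ("N_A", "C_B", ...) for each global residue index.
domainLabels <- function(partition, resids) {
  t <- partition@table
  lab <- rep(NA_character_, length(resids))
  for (i in seq_len(nrow(t))) {
    hit <- resids >= t$from[i] & resids <= t$to[i]
    lab[hit] <- paste0(t$domain[i], "_", t$chain[i])
  }
  if (anyNA(lab))
    stopf("residue %d outside the domain partition",
          resids[which(is.na(lab))[1L]])
  lab
}
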