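# Shared test helpers: ad-hoc systems built in code and independent
# brute-force oracles.

# A bare protein system with one atom ("CA") per residue at given coords.
pointResidueSystem <- function(xyz, box = NULL, chain = "A",
                               resid = seq_len(nrow(xyz))) {
  xyz <- matrix(xyz, ncol = 3L)
  n <- nrow(xyz)
  df <- data.frame(serial = seq_len(n), name = "CA", element = "C",
                   resid = resid, resname = "ALA", chain = chain,
                   moleculeId = 1L, moleculeClass = "protein",
                   stringsAsFactors = FALSE)
  new("MDSystem", atoms = df, coords = xyz,
      box = if (is.null(box)) c(0, 0, 0) else box,
      periodic = !is.null(box))
}

# A one-frame trajectory wrapped around a system.
oneFrameTrajectory <- function(sys, times = 0) {
  nf <- length(times)
  fr <- array(rep(coords(sys), nf), c(nAtoms(sys), 3L, nf))
  new("MDTrajectory", system = sys, times = as.numeric(times), frames = fr)
}

# Brute-force minimum distance over all 27 periodic images; the
# independent oracle for the minimum-image implementation.
bruteMinDistance <- function(a, b, box, lateral = FALSE) {
  shifts <- as.matrix(expand.grid(sx = -1:1, sy = -1:1, sz = -1:1))
  if (lateral) shifts <- unique(shifts[, 1:2, drop = FALSE])
  best <- Inf
  for (s in seq_len(nrow(shifts))) {
    off <- if (lateral) c(shifts[s, ] * box[1:2], 0)
           else shifts[s, ] * box
    bs <- sweep(b, 2L, off, "+")
    d2 <- 0
    for (k in seq_len(if (lateral) 2L else 3L))
      d2 <- d2 + outer(a[, k], bs[, k], "-")^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}

# Reference DSSP codes computed with the mdtraj implementation (blank ->
# coil); returns NULL when the oracle is unavailable.
mdtrajDssp <- function(system) {
  pdb <- tempfile(fileext = ".pdb")
  on.exit(unlink(pdb))
  writeStructure(system, pdb, "pdb")
  py <- Sys.which("python")
  if (py == "") return(NULL)
  out <- suppressWarnings(system2(py, c("-c", shQuote(paste0(
    "import mdtraj as md;",
    "print(''.join(md.compute_dssp(md.load('", pdb,
    "'), simplified=False)[0]))"))), stdout = TRUE, stderr = FALSE))
  if (!is.null(attr(out, "status")) || !length(out)) return(NULL)
  codes <- strsplit(tail(out, 1L), "")[[1L]]
  codes[codes == " "] <- "C"
  codes
}

# A compact protein + bilayer frame for region sorting.
annularFrame <- function(seed = 1L, n = 16L) {
  prot <- buildDimer("DAEFR", n_chains = 1L)
  mem <- makeBilayer(bilayerSpec(n, n, seed = seed))
  sys <- memsurf:::mergeSystems(prot, mem)
  # park the protein just above the upper headgroup plane, box centre
  a <- atoms(sys)
  prows <- which(a$moleculeClass == "protein")
  xyz <- coords(sys)
  shift <- c(boxDims(sys)[1:2] / 2 - colMeans(xyz[prows, 1:2, drop = FALSE]),
             max(xyz[-prows, 3L]) + 3 - min(xyz[prows, 3L]))
  xyz[prows, ] <- sweep(xyz[prows, , drop = FALSE], 2L, shift, "+")
  sys@coords <- xyz
  sys
}

# Deterministic random SSMatrix for reduction tests.
randomSSMatrix <- function(nres, nframes, seed, nchains = 2L) {
  stopifnot(nres %% nchains == 0)
  rows <- nres + nchains - 1L
  resids <- integer(0)
  per <- nres / nchains
  for (k in seq_len(nchains)) {
    resids <- c(resids, (k - 1L) * per + seq_len(per))
    if (k < nchains) resids <- c(resids, NA)
  }
  codes <- matrix("X", rows, nframes)
  set.seed(seed)
  body <- !is.na(resids)
  codes[body, ] <- sample(c("H", "G", "I", "E", "B", "T", "S", "C"),
                          sum(body) * nframes, replace = TRUE)
  new("SSMatrix", residues = as.integer(resids),
      times = seq_len(nframes) - 1, codes = codes)
}
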