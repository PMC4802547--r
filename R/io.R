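# Structure and trajectory I/O: PDB (wwPDB v3.3 columns, single- and
# multi-model) and GRO.  GRO stores nm; everything is converted to Angstrom
# on the way in and back to nm on the way out.

.inputLines <- function(input) {
  if (!is.character(input)) stopf("input must be a file path or text")
  if (length(input) == 1L && !grepl("\n", input, fixed = TRUE) &&
      file.exists(input))
    return(readLines(input, warn = FALSE))
  unlist(strsplit(input, "\n", fixed = TRUE), use.names = FALSE)
}

.substrTrim <- function(x, a, b) trimws(substr(x, a, b))

.parseNum <- function(s, line, what) {
  v <- suppressWarnings(as.numeric(s))
  if (any(is.na(v)))
    stopf("parse error at line %d: bad %s field '%s'", line, what, s)
  v
}

.elementFromName <- function(name) {
  # strip leading digits (e.g. "1H"), element = leading letter(s)
  nm <- sub("^[0-9]+", "", name)
  two <- toupper(substr(nm, 1L, 2L))
  ifelse(two %in% c("CL", "NA", "MG", "FE", "ZN", "BR"), two,
         toupper(substr(nm, 1L, 1L)))
}

.classify <- function(resname, classification) {
  cls <- unname(classification[resname])
  cls[is.na(cls)] <- "other"
  cls
}

# Group atoms into molecules: a protein chain is one molecule; every
# lipid/water/other residue is its own molecule.
.assignMolecules <- function(df) {
  key <- ifelse(df$moleculeClass == "protein",
                paste0("P:", df$chain),
                paste0("R:", df$chain, ":", df$resid, ":", df$resname))
  match(key, unique(key))
}

.parsePdbAtoms <- function(lines, classification) {
  isAtom <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(isAtom)
  if (!length(idx)) stopf("parse error: no ATOM/HETATM records found")
  ln <- lines[idx]
  alt <- .substrTrim(ln, 17, 17)
  if (any(alt != ""))
    stopf("parse error at line %d: alternate locations are not supported",
          idx[which(alt != "")[1L]])
  icode <- .substrTrim(ln, 27, 27)
  if (any(icode != ""))
    stopf("parse error at line %d: insertion codes are not supported",
          idx[which(icode != "")[1L]])
  serial <- .parseNum(.substrTrim(ln, 7, 11), idx[1L], "serial")
  name <- .substrTrim(ln, 13, 16)
  resname <- .substrTrim(ln, 18, 21)
  chain <- substr(ln, 22, 22)
  resid <- .parseNum(.substrTrim(ln, 23, 26), idx[1L], "residue number")
  xyz <- matrix(0, length(ln), 3L)
  for (k in 1:3) {
    a <- 31L + (k - 1L) * 8L
    s <- .substrTrim(ln, a, a + 7L)
    bad <- which(is.na(suppressWarnings(as.numeric(s))))
    if (length(bad))
      stopf("parse error at line %d: bad coordinate field '%s'",
            idx[bad[1L]], s[bad[1L]])
    xyz[, k] <- as.numeric(s)
  }
  elem <- .substrTrim(ln, 77, 78)
  elem[elem == ""] <- .elementFromName(name[elem == ""])
  cls <- .classify(resname, classification)
  df <- data.frame(serial = as.integer(serial), name = name,
                   element = elem, resid = as.integer(resid),
                   resname = resname, chain = chain,
                   moleculeId = 0L, moleculeClass = cls,
                   stringsAsFactors = FALSE)
  df$moleculeId <- .assignMolecules(df)
  list(atoms = df, coords = xyz)
}

.parsePdbBox <- function(lines) {
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cl)) return(NULL)
  .parseNum(c(.substrTrim(cl[1L], 7, 15), .substrTrim(cl[1L], 16, 24),
              .substrTrim(cl[1L], 25, 33)),
            grep("^CRYST1", lines)[1L], "CRYST1")
}

#' Read a molecular structure from PDB or GRO text
#'
#' Parses a structure file into an [MDSystem-class].  GRO coordinates (nm)
#' are converted to Angstrom.  Molecule classes are inferred from residue
#' names via a classification table; unknown names classify as `other`.
#' For multi-model PDB input only the first model is read (use
#' [readTrajectory()] for all models).
#'
#' @param input path to a file, or the file content as a string / character
#'   vector of lines.
#' @param format `"pdb"` or `"gro"`.
#' @param classification named character vector mapping residue names to
#'   classes; see [defaultClassification()].
#' @return An [MDSystem-class].
#' @export
#' @examples
#' s <- buildDimer("AG", n_chains = 1)
#' txt <- writeStructure(s, format = "pdb")
#' identical(nAtoms(readStructure(txt, "pdb")), nAtoms(s))
readStructure <- function(input, format = c("pdb", "gro"),
                          classification = defaultClassification()) {
  format <- match.arg(format)
  lines <- .inputLines(input)
  if (format == "pdb") {
    endmdl <- grep("^ENDMDL", lines)
    if (length(endmdl)) lines <- lines[seq_len(endmdl[1L])]
    p <- .parsePdbAtoms(lines, classification)
    box <- .parsePdbBox(lines)
    periodic <- !is.null(box) && all(box > 1)
    if (is.null(box)) box <- c(0, 0, 0)
    new("MDSystem", atoms = p$atoms, coords = p$coords,
        box = box, periodic = periodic)
  } else {
    if (length(lines) < 4L) stopf("parse error: GRO file too short")
    n <- suppressWarnings(as.integer(trimws(lines[2L])))
    if (is.na(n)) stopf("parse error at line 2: bad atom count")
    if (length(lines) < 3L + n) stopf("parse error: truncated GRO file")
    ln <- lines[3L:(2L + n)]
    lineNo <- 3L:(2L + n)
    resid <- .parseNum(.substrTrim(ln, 1, 5), lineNo[1L], "residue number")
    resname <- .substrTrim(ln, 6, 10)
    name <- .substrTrim(ln, 11, 15)
    serial <- seq_len(n)  # GRO serials wrap at 99999; renumber
    xyz <- matrix(0, n, 3L)
    for (k in 1:3) {
      a <- 21L + (k - 1L) * 8L
      s <- .substrTrim(ln, a, a + 7L)
      bad <- which(is.na(suppressWarnings(as.numeric(s))))
      if (length(bad))
        stopf("parse error at line %d: bad coordinate field '%s'",
              lineNo[bad[1L]], s[bad[1L]])
      xyz[, k] <- as.numeric(s) * 10  # nm -> Angstrom
    }
    boxline <- .parseNum(strsplit(trimws(lines[3L + n]), "\\s+")[[1L]],
                         3L + n, "box")
    box <- boxline[1:3] * 10
    cls <- .classify(resname, classification)
    df <- data.frame(serial = serial, name = name,
                     element = .elementFromName(name),
                     resid = as.integer(resid), resname = resname,
                     chain = ifelse(cls == "protein", "A", "X"),
                     moleculeId = 0L, moleculeClass = cls,
                     stringsAsFactors = FALSE)
    df$moleculeId <- .assignMolecules(df)
    new("MDSystem", atoms = df, coords = xyz, box = box,
        periodic = all(box > 0))
  }
}

.formatPdbAtomName <- function(name, element) {
  # one-letter elements start in column 14 per wwPDB convention
  ifelse(nchar(name) >= 4L, substr(name, 1L, 4L),
         ifelse(nchar(element) == 1L, sprintf(" %-3s", name),
                sprintf("%-4s", name)))
}

#' Write a molecular structure as PDB or GRO text
#'
#' @param system an [MDSystem-class].
#' @param file optional output path; when NULL the text is returned only.
#' @param format `"pdb"` or `"gro"`.
#' @return Invisibly (visibly when `file` is NULL), the file content as a
#'   single string.
#' @export
writeStructure <- function(system, file = NULL, format = c("pdb", "gro")) {
  format <- match.arg(format)
  a <- atoms(system)
  if (nrow(a) == 0L) stopf("cannot write an empty system")
  xyz <- coords(system)
  if (format == "pdb") {
    if (any(a$resid > 9999L))
      stopf("overflow: residue index exceeds PDB width (9999)")
    if (any(nchar(a$chain) != 1L))
      stopf("overflow: PDB chain id must be a single character")
    if (any(abs(xyz) >= 10000))
      stopf("overflow: coordinate exceeds PDB field width")
    out <- character()
    if (isPeriodic(system))
      out <- sprintf(
        "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
        system@box[1L], system@box[2L], system@box[3L], 90, 90, 90)
    serial <- ((seq_len(nrow(a)) - 1L) %% 99999L) + 1L
    rec <- sprintf("ATOM  %5d %s%1s%-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   serial, .formatPdbAtomName(a$name, a$element), "",
                   a$resname, a$chain, a$resid, "",
                   xyz[, 1L], xyz[, 2L], xyz[, 3L], 1, 0,
                   substr(a$element, 1L, 2L))
    out <- c(out, rec, "END")
  } else {
    if (any(a$resid > 99999L))
      stopf("overflow: residue index exceeds GRO width")
    rec <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                   a$resid %% 100000L, substr(a$resname, 1L, 5L),
                   substr(a$name, 1L, 5L),
                   ((seq_len(nrow(a)) - 1L) %% 99999L) + 1L,
                   xyz[, 1L] / 10, xyz[, 2L] / 10, xyz[, 3L] / 10)
    box <- if (isPeriodic(system)) system@box / 10 else c(0, 0, 0)
    out <- c("written by memsurf", sprintf("%5d", nrow(a)), rec,
             sprintf("%10.5f%10.5f%10.5f", box[1L], box[2L], box[3L]))
  }
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(txt))
  }
  txt
}

#' Read a multi-model PDB as a trajectory
#'
#' Splits a multi-model PDB (MODEL/ENDMDL blocks) into frames sharing one
#' topology.  Frame times come either from `times` (one per model, ns) or
#' from a constant stride `dt` starting at 0 ns.
#'
#' @param input path or text of a multi-model PDB (a single-model file
#'   yields a one-frame trajectory).
#' @param times numeric vector of frame times, ns; overrides `dt` and any
#'   `REMARK 250 TIME_NS` records embedded by [writeTrajectory()].
#' @param dt constant frame spacing, ns (default 1), used when neither
#'   `times` nor embedded time records are available.
#' @param classification residue-name classification table.
#' @return An [MDTrajectory-class].
#' @export
readTrajectory <- function(input, times = NULL, dt = 1,
                           classification = defaultClassification()) {
  lines <- .inputLines(input)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  blocks <- if (length(starts)) {
    if (length(starts) != length(ends))
      stopf("parse error: unbalanced MODEL/ENDMDL records")
    Map(function(s, e) lines[s:e], starts, ends)
  } else list(lines)
  header <- if (length(starts) && starts[1L] > 1L)
    lines[seq_len(starts[1L] - 1L)] else character()
  sys0 <- readStructure(c(header, blocks[[1L]]), "pdb", classification)
  nf <- length(blocks)
  if (is.null(times)) {
    embedded <- vapply(blocks, function(b) {
      r <- grep("^REMARK 250 TIME_NS", b, value = TRUE)
      if (length(r) == 1L)
        suppressWarnings(as.numeric(sub("^REMARK 250 TIME_NS +", "", r[1L])))
      else NA_real_
    }, numeric(1L))
    times <- if (!anyNA(embedded)) embedded else (seq_len(nf) - 1L) * dt
  }
  if (length(times) != nf)
    stopf("need one time per model: %d models, %d times", nf, length(times))
  if (nf > 1L && any(diff(times) <= 0))
    stopf("times must be strictly increasing")
  frames <- array(0, c(nAtoms(sys0), 3L, nf))
  frames[, , 1L] <- coords(sys0)
  for (k in seq_len(nf)[-1L]) {
    p <- .parsePdbAtoms(blocks[[k]], classification)
    if (nrow(p$atoms) != nAtoms(sys0))
      stopf("congruence error: model %d has %d atoms, expected %d",
            k, nrow(p$atoms), nAtoms(sys0))
    frames[, , k] <- p$coords
  }
  new("MDTrajectory", system = sys0, times = as.numeric(times),
      frames = frames)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj an [MDTrajectory-class].
#' @param file optional output path.
#' @return Invisibly, the text.
#' @export
writeTrajectory <- function(traj, file = NULL) {
  nf <- nFrames(traj)
  parts <- character(nf)
  for (k in seq_len(nf)) {
    body <- writeStructure(frameSystem(traj, k), format = "pdb")
    body <- sub("\nEND\n$", "\nENDMDL\n", paste0("\n", body))
    body <- sub("^\n", "", body)
    # move any CRYST1 of later frames out; keep it once up front
    if (k > 1L) body <- sub("^CRYST1[^\n]*\n", "", body)
    parts[k] <- paste0(sprintf("MODEL     %4d\n", k),
                       sprintf("REMARK 250 TIME_NS %.9g\n",
                               frameTimes(traj)[k]), body)
  }
  # hoist CRYST1 from frame 1 above the first MODEL record
  m <- regmatches(parts[1L], regexpr("CRYST1[^\n]*\n", parts[1L]))
  if (length(m) && nchar(m)) {
    parts[1L] <- sub("CRYST1[^\n]*\n", "", parts[1L])
    parts[1L] <- paste0(m, parts[1L])
  }
  txt <- paste0(paste(parts, collapse = ""), "END\n")
  if (!is.null(file)) {
    cat(txt, file = file)
    return(invisible(txt))
  }
  txt
}
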