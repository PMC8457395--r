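## Structure and shift-table I/O.
##
## SDF (V2000) is parsed with ChemmineR; formal charges are pulled from the
## "M  CHG" property lines of the raw record.  SMILES input is converted to
## explicit-hydrogen SDF by OpenBabel (obabel must be on PATH).  XYZ frames
## are read directly (the format carries no connectivity).
##
## Unit conventions, enforced here and never converted implicitly:
## Angstrom for coordinates, ppm for shifts, kcal/mol for energies.
## In-memory atom indices are 1-based; the CSV schema's `atom_index`
## column is 0-based and converted at this boundary.

.NUCLEI <- c("H1", "C13")
.PROVENANCE <- c("computed", "experimental", "predicted")

.sdfRecordsText <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) return(list())
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends)) ends <- length(lines)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  mapply(function(s, e) lines[s:e], starts, ends, SIMPLIFY = FALSE)
}

.chargesFromRecord <- function(recLines, n) {
  charges <- integer(n)
  for (ln in grep("^M  CHG", recLines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    k <- f[1]
    for (m in seq_len(k)) charges[f[2 * m]] <- f[2 * m + 1]
  }
  charges
}

## Property blocks from the raw record text (ChemmineR's datablock drops
## the continuation lines of multi-line values, which the per-atom shift
## properties need).
.recordProps <- function(recLines) {
  starts <- grep("^> *<.+>", recLines)
  props <- list()
  for (s in starts) {
    key <- sub("^> *<([^>]+)>.*$", "\\1", recLines[s])
    e <- s
    while (e < length(recLines) && nzchar(trimws(recLines[e + 1L])) &&
           !startsWith(recLines[e + 1L], ">") &&
           !startsWith(recLines[e + 1L], "$$$$")) e <- e + 1L
    props[[key]] <- if (e > s) recLines[(s + 1L):e] else character()
  }
  props
}

.parsePropShifts <- function(props, molId) {
  keys <- intersect(names(props), c("SHIFT_H1", "SHIFT_C13"))
  if (!length(keys)) return(NULL)
  out <- lapply(keys, function(k) {
    rows <- strsplit(trimws(props[[k]]), "\\s+")
    rows <- unname(rows[vapply(rows, length, integer(1)) >= 2L])
    data.frame(molecule_id = molId,
               atom = as.integer(vapply(rows, `[`, "", 1L)),  # 1-based in SDF
               nucleus = sub("SHIFT_", "", k),
               shift = as.numeric(vapply(rows, `[`, "", 2L)),
               provenance = "computed", stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

.readSDF <- function(path) {
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path, skipErrors = TRUE))
  ok <- ChemmineR::validSDF(sdfset)
  if (any(!ok))
    warning(sum(!ok), " unparseable SDF record(s) in '", path,
            "' skipped (records ", paste(which(!ok), collapse = ", "), ")")
  sdfset <- sdfset[ok]
  recText <- .sdfRecordsText(path)[ok]
  out <- vector("list", length(sdfset))
  for (k in seq_along(sdfset)) {
    sdf <- sdfset[[k]]
    ab <- ChemmineR::atomblock(sdf)
    el <- sub("_.*$", "", rownames(ab))
    n <- nrow(ab)
    bb <- ChemmineR::bondblock(sdf)
    bonds <- if (nrow(bb)) cbind(as.integer(bb[, 1]), as.integer(bb[, 2]),
                                 as.integer(bb[, 3])) else NULL
    id <- unname(trimws(ChemmineR::header(sdf)[1]))
    if (!nzchar(id) || grepl("^Molecule_Name$", id)) id <- sprintf("mol%d", k)
    unknown <- setdiff(unique(el), names(.ATOMIC_WEIGHTS))
    if (length(unknown))
      warning("molecule '", id, "': unknown element symbol(s) ",
              paste(unknown, collapse = ", "))
    outside <- setdiff(unique(el), .SUPPORTED_ELEMENTS)
    if (length(outside))
      warning("molecule '", id, "' contains element(s) outside the supported ",
              "set (", paste(outside, collapse = ", "),
              "); retained but unusable for prediction")
    db <- .recordProps(recText[[k]])
    stereo <- logical()
    if ("STEREO_DEFINED" %in% names(db))
      stereo <- as.logical(strsplit(trimws(db[["STEREO_DEFINED"]][1]),
                                    "[;,\\s]+")[[1]])
    charges <- .chargesFromRecord(recText[[k]], n)
    mol <- Molecule(id, el, bonds = bonds, formalCharges = charges,
                    stereoDefined = stereo)
    xyz <- unname(ab[, 1:3, drop = FALSE])
    degenerate <- n > 1 && any(stats::dist(xyz) < 1e-8)
    confs <- list()
    if (!degenerate) {
      relE <- NA_real_
      for (key in c("REL_ENERGY", "ENERGY"))
        if (key %in% names(db)) { relE <- as.numeric(db[[key]][1]); break }
      src <- if ("GEOM_SOURCE" %in% names(db)) db[["GEOM_SOURCE"]][1] else "user"
      confs <- list(Conformer(id, xyz, relE, src))
    }
    out[[k]] <- list(molecule = mol, conformers = confs,
                     shifts = .parsePropShifts(db, id))
  }
  out
}

.haveOpenBabel <- function() nzchar(Sys.which("obabel"))

.readSMILES <- function(path) {
  if (!.haveOpenBabel())
    stop("reading SMILES requires OpenBabel (obabel) on the PATH")
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(list())
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp))
  ## explicit hydrogens, no 3D embedding: SMILES entries carry no conformers
  status <- suppressWarnings(system2("obabel",
    c("-ismi", shQuote(path), "-osdf", "-O", shQuote(tmp), "-h"),
    stdout = FALSE, stderr = FALSE))
  if (status != 0 || !file.exists(tmp))
    stop("obabel failed to convert SMILES file '", path, "'")
  entries <- .readSDF(tmp)
  toks <- strsplit(lines, "\\s+")
  for (k in seq_along(entries)) {
    entries[[k]]$conformers <- list()   # 2D placeholders are not geometries
    if (k <= length(toks) && length(toks[[k]]) >= 2L) {
      entries[[k]]$molecule@id <- toks[[k]][2L]
    } else if (molId(entries[[k]]$molecule) == sprintf("mol%d", k)) {
      entries[[k]]$molecule@id <- sprintf("smi%d", k)
    }
  }
  entries
}

.readXYZ <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list(); k <- 1L; rec <- 0L
  while (k <= length(lines)) {
    if (!nzchar(trimws(lines[k]))) { k <- k + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[k])))
    if (is.na(n) || n < 1L || k + 1L + n > length(lines))
      stop("malformed XYZ frame starting at line ", k, " of '", path, "'")
    rec <- rec + 1L
    comment <- trimws(lines[k + 1L])
    id <- if (nzchar(comment)) strsplit(comment, "\\s+")[[1]][1] else
      sprintf("xyz%d", rec)
    rows <- strsplit(trimws(lines[(k + 2L):(k + 1L + n)]), "\\s+")
    bad <- which(vapply(rows, length, integer(1)) < 4L)
    if (length(bad))
      stop("malformed XYZ atom line ", k + 1L + bad[1], " in '", path, "'")
    el <- vapply(rows, `[`, "", 1L)
    xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    mol <- Molecule(id, el)
    out[[rec]] <- list(molecule = mol,
                       conformers = list(Conformer(id, xyz, NA_real_, "user")),
                       shifts = NULL)
    k <- k + 2L + n
  }
  out
}

#' Read molecular structures
#'
#' @param path input file.
#' @param fmt \code{"sdf"} (V2000, 3D), \code{"smiles"} (one SMILES per
#'   line, optional id token; requires OpenBabel; entries carry no
#'   conformers) or \code{"xyz"} (no connectivity).
#' @return A list of entries, each \code{list(molecule, conformers,
#'   shifts)}; \code{shifts} is a shift-record data.frame when the SDF
#'   carried \code{<SHIFT_H1>}/\code{<SHIFT_C13>} property blocks, else
#'   NULL.  Hydrogens are always explicit.  Unparseable records are skipped
#'   with a warning; molecules with elements outside the supported set are
#'   retained but flagged.
#' @export
readStructures <- function(path, fmt = c("sdf", "smiles", "xyz")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) return(list())
  switch(fmt, sdf = .readSDF(path), smiles = .readSMILES(path),
         xyz = .readXYZ(path))
}

#' Parse a shift table CSV
#'
#' Expected header: \code{molecule_id, atom_index, nucleus, shift_ppm,
#' provenance} with 0-based \code{atom_index}.  Returns records with
#' 1-based \code{atom} for in-memory use.
#'
#' @param path CSV file.
#' @return data.frame with columns \code{molecule_id}, \code{atom},
#'   \code{nucleus}, \code{shift}, \code{provenance}.
#' @export
parseShiftTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("molecule_id", "atom_index", "nucleus", "shift_ppm", "provenance")
  if (!identical(names(df)[seq_along(need)], need))
    stop("shift table must have header: ", paste(need, collapse = ", "))
  if (!nrow(df))
    return(data.frame(molecule_id = character(), atom = integer(),
                      nucleus = character(), shift = numeric(),
                      provenance = character(), stringsAsFactors = FALSE))
  shift <- suppressWarnings(as.numeric(df$shift_ppm))
  if (anyNA(shift))
    stop("non-numeric shift_ppm in row(s): ",
         paste(which(is.na(shift)), collapse = ", "))
  if (!all(df$nucleus %in% .NUCLEI))
    stop("unknown nucleus token(s): ",
         paste(unique(setdiff(df$nucleus, .NUCLEI)), collapse = ", "))
  if (!all(df$provenance %in% .PROVENANCE))
    stop("unknown provenance token(s): ",
         paste(unique(setdiff(df$provenance, .PROVENANCE)), collapse = ", "))
  atom <- suppressWarnings(as.integer(df$atom_index))
  if (anyNA(atom) || any(atom < 0L))
    stop("atom_index must be a non-negative integer (0-based)")
  key <- paste(df$molecule_id, atom, df$nucleus, df$provenance, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate shift record(s) for key(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  data.frame(molecule_id = df$molecule_id, atom = atom + 1L,
             nucleus = df$nucleus, shift = shift,
             provenance = df$provenance, stringsAsFactors = FALSE)
}

#' Write a shift table CSV
#'
#' Inverse of [parseShiftTable()]; the on-disk \code{atom_index} is 0-based.
#'
#' @param records shift-record data.frame (1-based \code{atom} column).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeShiftTable <- function(records, path) {
  out <- data.frame(molecule_id = records$molecule_id,
                    atom_index = records$atom - 1L,
                    nucleus = records$nucleus,
                    shift_ppm = sprintf("%.6f", records$shift),
                    provenance = records$provenance)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write predicted shifts
#'
#' @param records shift records, all with provenance \code{"predicted"}.
#' @param path output file.
#' @param fmt \code{"csv"} (round-trips through [parseShiftTable()] to
#'   1e-6 ppm) or \code{"sdf_annotated"} (structures with
#'   \code{<SHIFT_C13>}/\code{<SHIFT_H1>} property blocks holding 1-based
#'   "index value" pairs).
#' @param structures for \code{sdf_annotated}: list of entries as returned
#'   by [readStructures()] (one conformer each) matching the record
#'   molecule ids.
#' @return \code{path}, invisibly.
#' @export
writePredictions <- function(records, path, fmt = c("csv", "sdf_annotated"),
                             structures = NULL) {
  fmt <- match.arg(fmt)
  if (nrow(records) && !all(records$provenance == "predicted"))
    stop("writePredictions expects homogeneous provenance 'predicted'")
  if (fmt == "csv") return(writeShiftTable(records, path))
  if (is.null(structures))
    stop("sdf_annotated output needs the structures to annotate")
  con <- file(path, "w"); on.exit(close(con))
  for (e in structures) {
    mol <- e$molecule
    recs <- records[records$molecule_id == molId(mol), , drop = FALSE]
    shiftProps <- lapply(split(recs, recs$nucleus), function(r)
      paste(sprintf("%d %.6f", r$atom, r$shift), collapse = "\n"))
    names(shiftProps) <- paste0("SHIFT_", names(shiftProps))
    .writeMolV2000(con, mol, e$conformers[[1]], props = shiftProps)
  }
  invisible(path)
}

## Minimal V2000 writer (ChemmineR's writer expects its own block layout;
## emitting the fixed-width format directly keeps full control over
## properties and precision).
.writeMolV2000 <- function(con, mol, conf, props = list()) {
  el <- atomElements(mol)
  xyz <- coords(conf)
  b <- bondTable(mol)
  writeLines(c(molId(mol), "  ShiftGNN", ""), con)
  writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     length(el), nrow(b)), con)
  writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                     xyz[, 1], xyz[, 2], xyz[, 3], el), con)
  if (nrow(b))
    writeLines(sprintf("%3d%3d%3d  0  0  0  0", b[, 1], b[, 2], b[, 3]), con)
  ch <- formalCharges(mol)
  for (i in which(ch != 0L))
    writeLines(sprintf("M  CHG  1 %3d %3d", i, ch[i]), con)
  writeLines("M  END", con)
  if (!is.na(relEnergy(conf)))
    props <- c(props, list(REL_ENERGY = sprintf("%.6f", relEnergy(conf))))
  if (length(stereoDefined(mol)))
    props <- c(props, list(STEREO_DEFINED =
      paste(tolower(as.character(stereoDefined(mol))), collapse = ";")))
  for (nm in names(props))
    writeLines(c(sprintf(">  <%s>", nm), props[[nm]], ""), con)
  writeLines("$$$$", con)
}

#' Write molecules and conformers to an SDF file
#'
#' Each conformer becomes one record (same molecule block, different
#' coordinates); relative energies and stereo annotations are stored as
#' property fields understood by [readStructures()].
#'
#' @param mol a [Molecule-class].
#' @param conformers list of [Conformer-class] objects.
#' @param path output file.
#' @param shifts optional shift-record data.frame stored as
#'   \code{<SHIFT_*>} property blocks on every record.
#' @return \code{path}, invisibly.
#' @export
writeStructuresSDF <- function(mol, conformers, path, shifts = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  props <- list()
  if (!is.null(shifts)) {
    sp <- lapply(split(shifts, shifts$nucleus), function(r)
      paste(sprintf("%d %.6f", r$atom, r$shift), collapse = "\n"))
    names(sp) <- paste0("SHIFT_", names(sp))
    props <- sp
  }
  for (cf in conformers) .writeMolV2000(con, mol, cf, props)
  invisible(path)
}
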