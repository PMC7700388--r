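#' Read a multi-frame coordinate file
#'
#' Reads fixed-column GRO (possibly concatenated multi-frame) or multi-model
#' PDB (`MODEL`/`ENDMDL`) files into a [memtraj]. All coordinates are stored
#' in nanometres: GRO is nm-native, PDB Angstrom values are divided by 10 on
#' read. Only orthorhombic boxes are supported; triclinic box records raise
#' an error rather than being silently truncated.
#'
#' @param path file to read
#' @param format `"auto"` (by extension), `"gro"` or `"pdb"`
#' @return a [memtraj]
#' @export
read_trajectory <- function(path, format = c("auto", "gro", "pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gro = "gro", pdb = "pdb", ent = "pdb",
                     stop("cannot infer format from extension '.", ext,
                          "'; pass format explicitly"))
  }
  switch(format, gro = read_gro(path), pdb = read_pdb_multimodel(path))
}

#' Write a trajectory to disk
#'
#' @param traj a [memtraj]
#' @param path output file
#' @param format `"auto"` (by extension), `"gro"` or `"pdb"`. GRO keeps nm
#'   with 3 decimals; PDB converts to Angstrom with 3 decimals.
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, path, format = c("auto", "gro", "pdb")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gro = "gro", pdb = "pdb",
                     stop("cannot infer format from extension '.", ext, "'"))
  }
  switch(format,
         gro = write_gro(traj, path),
         pdb = write_pdb_multimodel(traj, path))
  invisible(path)
}

# ---- GRO (fixed-column, nm) -------------------------------------------------
# No established R reader exists for the GROMACS GRO format, so the
# fixed-column layout is parsed here directly:
#   title line (may carry "t= <ps>"), atom count, atom records
#   %5d%-5s%5s%5d%8.3f%8.3f%8.3f (velocities, if present, are ignored),
#   then the box line (>=3 floats; 9 floats = triclinic, rejected unless the
#   off-diagonal terms are zero).

read_gro <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop("GRO parse error: file has fewer than 3 lines")
  n_at <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n_at) || n_at < 1)
    stop("GRO parse error at line 2: invalid atom count '",
         trimws(lines[2]), "'")
  block <- n_at + 3L
  if (length(lines) %% block != 0) {
    # allow trailing blank lines only
    extra <- lines[(length(lines) %/% block) * block + seq_len(length(lines) %% block)]
    if (!all(trimws(extra) == ""))
      stop("GRO structural error: file length ", length(lines),
           " is not a multiple of the frame block (", block, " lines)")
    lines <- lines[seq_len((length(lines) %/% block) * block)]
  }
  nf <- length(lines) %/% block
  # every frame must declare the same atom count
  count_lines <- lines[(seq_len(nf) - 1L) * block + 2L]
  counts <- suppressWarnings(as.integer(trimws(count_lines)))
  if (any(is.na(counts)) || any(counts != n_at))
    stop("GRO structural error: atom count changes across frames (",
         paste(unique(counts), collapse = ", "), ")")

  atom_rows <- as.vector(vapply(seq_len(nf), function(f)
    (f - 1L) * block + 2L + seq_len(n_at), integer(n_at)))
  al <- lines[atom_rows]
  bad <- which(nchar(al) < 44)
  if (length(bad))
    stop("GRO parse error at line ", atom_rows[bad[1]],
         ": atom record shorter than 44 characters")
  xs <- suppressWarnings(as.numeric(substr(al, 21, 28)))
  ys <- suppressWarnings(as.numeric(substr(al, 29, 36)))
  zs <- suppressWarnings(as.numeric(substr(al, 37, 44)))
  if (anyNA(xs) || anyNA(ys) || anyNA(zs)) {
    bad <- which(is.na(xs) | is.na(ys) | is.na(zs))[1]
    stop("GRO parse error at line ", atom_rows[bad],
         ": unreadable coordinate field")
  }
  first <- seq_len(n_at)  # metadata from frame 1; constant by contract
  resno <- suppressWarnings(as.integer(substr(al[first], 1, 5)))
  resname <- trimws(substr(al[first], 6, 10))
  name <- trimws(substr(al[first], 11, 15))
  index <- suppressWarnings(as.integer(substr(al[first], 16, 20)))
  if (anyNA(resno) || anyNA(index))
    stop("GRO parse error: unreadable residue/atom number in frame 1")
  if (anyDuplicated(index)) index <- seq_len(n_at)

  box_lines <- lines[(seq_len(nf) - 1L) * block + 2L + n_at + 1L]
  box <- t(vapply(seq_along(box_lines), function(f) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(box_lines[f]), "\\s+")[[1]]))
    if (length(v) < 3 || anyNA(v))
      stop("GRO parse error at line ", (f - 1L) * block + 2L + n_at + 1L,
           ": unreadable box line")
    if (length(v) > 3 && any(abs(v[-(1:3)]) > 1e-9))
      stop("unsupported format: triclinic box (off-diagonal components ",
           "present); only orthorhombic boxes are handled")
    v[1:3]
  }, numeric(3)))

  titles <- lines[(seq_len(nf) - 1L) * block + 1L]
  tm <- regmatches(titles, regexpr("t=\\s*[-0-9.eE+]+", titles))
  time <- if (length(tm) == nf && all(nzchar(tm))) {
    as.numeric(sub("t=\\s*", "", tm))
  } else seq_len(nf) - 1

  atoms <- data.frame(index = index, name = name, resno = resno,
                      resname = resname, segid = "",
                      stringsAsFactors = FALSE)
  xyz <- array(NA_real_, dim = c(n_at, 3L, nf))
  xyz[, 1, ] <- xs; xyz[, 2, ] <- ys; xyz[, 3, ] <- zs
  memtraj(atoms, xyz, box, time)
}

write_gro <- function(traj, path) {
  nf <- n_frames(traj)
  n_at <- n_atoms(traj)
  a <- traj$atoms
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    m <- traj$xyz[, , f]
    body <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                    a$resno %% 100000L, a$resname, a$name,
                    a$index %% 100000L, m[, 1], m[, 2], m[, 3])
    writeLines(c(sprintf("memorient frame %d t= %.5f", f, traj$time[f]),
                 sprintf("%5d", n_at), body,
                 sprintf("%10.5f%10.5f%10.5f", traj$box[f, 1],
                         traj$box[f, 2], traj$box[f, 3])), con)
  }
  invisible(path)
}

# ---- multi-model PDB (Angstrom) --------------------------------------------

read_pdb_multimodel <- function(path) {
  # bio3d parses the ATOM records; the CRYST1 box is extracted separately
  # because bio3d does not carry it through.
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  cl <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (!length(cl))
    stop("PDB parse error: no CRYST1 record (box required)")
  v <- suppressWarnings(as.numeric(c(
    substr(cl[1], 7, 15), substr(cl[1], 16, 24), substr(cl[1], 25, 33),
    substr(cl[1], 34, 40), substr(cl[1], 41, 47), substr(cl[1], 48, 54))))
  if (anyNA(v)) stop("PDB parse error: unreadable CRYST1 record")
  if (any(abs(v[4:6] - 90) > 1e-6))
    stop("unsupported format: triclinic box (CRYST1 angles != 90); ",
         "only orthorhombic boxes are handled")
  box_nm <- v[1:3] / 10
  xyz <- pdb$xyz
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  n_at <- ncol(xyz) / 3L
  arr <- array(NA_real_, dim = c(n_at, 3L, nf))
  for (f in seq_len(nf))
    arr[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE) / 10
  segid <- pdb$atom$segid
  segid[is.na(segid)] <- ""
  atoms <- data.frame(index = pdb$atom$eleno, name = pdb$atom$elety,
                      resno = pdb$atom$resno, resname = pdb$atom$resid,
                      segid = segid, stringsAsFactors = FALSE)
  memtraj(atoms, arr, box_nm, seq_len(nf) - 1)
}

write_pdb_multimodel <- function(traj, path) {
  nf <- n_frames(traj)
  n_at <- n_atoms(traj)
  xyz <- matrix(NA_real_, nrow = nf, ncol = 3L * n_at)
  for (f in seq_len(nf))
    xyz[f, ] <- as.vector(t(traj$xyz[, , f])) * 10   # nm -> Angstrom
  a <- traj$atoms
  tmp <- tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = tmp, xyz = xyz, resno = a$resno, resid = a$resname,
                   eleno = a$index, elety = a$name,
                   chain = rep("A", n_at))
  b <- traj$box[1, ] * 10
  cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                   b[1], b[2], b[3], 90, 90, 90)
  writeLines(c(cryst, readLines(tmp, warn = FALSE)), path)
  unlink(tmp)
  invisible(path)
}
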