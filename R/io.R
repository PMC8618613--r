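# coordinate-file I/O: GRO (fixed column, nm), PDB (Angstrom, via bio3d),
# extended XYZ (free format, nm).  Conversion to internal nm happens here.

.guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gro", "pdb", "xyz")) ext
  else .stopf("cannot guess format from extension: %s", path)
}

#' Read coordinate frames with role assignment
#'
#' Reads one or more frames from a GRO, PDB or extended-XYZ file and
#' attaches semantic roles and masses via a role map.  Multi-frame input is
#' supported as concatenated GRO blocks, PDB `MODEL` records, or stacked XYZ
#' blocks.  Coordinates are returned in nm regardless of the source format
#' (PDB files are Angstrom on disk); coordinates are not wrapped into the
#' primary box — periodic wrapping is applied per analysis.
#'
#' Frame times are taken from the file where the format can carry them (GRO
#' title `t=`, XYZ comment `Time=`); otherwise they are assigned as
#' `t0 + (i-1) * dt`.
#'
#' @param path input file.
#' @param format `"gro"`, `"pdb"`, `"xyz"`, or `"auto"` (from extension).
#' @param map a [rolemap()].
#' @param fallback allow unmapped atoms as role `"other"` (see
#'   [assign_roles()]).
#' @param dt,t0 frame time stride and origin (ns) used when the file carries
#'   no times.
#' @return List of [monolayer_frame()] in time order.
#' @export
read_frames <- function(path, format = c("auto", "gro", "pdb", "xyz"),
                        map = default_rolemap(), fallback = TRUE,
                        dt = 1, t0 = 0) {
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  frames <- switch(format,
    gro = .read_gro(path, map, fallback),
    pdb = .read_pdb(path, map, fallback),
    xyz = .read_xyz(path, map, fallback))
  if (!length(frames)) .stopf("format error: no frames in %s", path)
  # fill missing times by fixed stride
  times <- vapply(frames, function(f) f$time, 0)
  if (anyNA(times)) times <- t0 + (seq_along(frames) - 1) * dt
  for (i in seq_along(frames)) frames[[i]]$time <- times[i]
  frames[order(times)]
}

#' Write a frame (or frames) to a coordinate file
#'
#' The emitted file re-parses to an equal frame within format precision:
#' 0.001 nm for GRO, 0.001 Angstrom for PDB, full double precision for XYZ.
#' Writing an empty frame is refused.
#'
#' @param frame a [monolayer_frame()], or a list of them.
#' @param path output file.
#' @param format `"gro"`, `"pdb"`, `"xyz"`, or `"auto"`.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frame, path, format = c("auto", "gro", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  frames <- if (inherits(frame, "monolayer_frame")) list(frame) else frame
  if (!length(frames)) .stopf("refusing to write zero frames")
  for (f in frames) {
    stopifnot(inherits(f, "monolayer_frame"))
    if (nrow(f$atoms) == 0L) .stopf("refusing to write a frame with 0 atoms")
  }
  con <- tryCatch(file(path, "w"), error = function(e)
    .stopf("I/O error: cannot open %s for writing", path))
  on.exit(close(con))
  switch(format,
    gro = .write_gro(frames, con),
    pdb = .write_pdb(frames, con),
    xyz = .write_xyz(frames, con))
  invisible(path)
}

#' @rdname write_frames
#' @export
write_frame <- write_frames

## ---- GRO ------------------------------------------------------------------

.write_gro <- function(frames, con) {
  for (f in frames) {
    a <- f$atoms
    writeLines(sprintf("undulayer frame t= %.6f", f$time), con)
    writeLines(sprintf("%5d", nrow(a)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       a$mol %% 100000L, substr(a$resname, 1L, 5L),
                       substr(a$name, 1L, 5L), a$id %% 100000L,
                       a$x, a$y, a$z), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", f$box[1], f$box[2], f$box[3]),
               con)
  }
}

.read_gro <- function(path, map, fallback) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) .stopf("format error: empty file %s", path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    title <- lines[i]
    if (i + 1L > length(lines))
      .stopf("format error in %s at line %d: missing atom count", path, i + 1L)
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat) || nat < 0L)
      .stopf("format error in %s at line %d: bad atom count", path, i + 1L)
    if (i + 1L + nat + 1L > length(lines))
      .stopf("format error in %s at line %d: truncated frame", path,
             length(lines))
    rows <- lines[(i + 2L):(i + 1L + nat)]
    x <- suppressWarnings(as.numeric(substr(rows, 21L, 28L)))
    y <- suppressWarnings(as.numeric(substr(rows, 29L, 36L)))
    z <- suppressWarnings(as.numeric(substr(rows, 37L, 44L)))
    if (anyNA(x) || anyNA(y) || anyNA(z))
      .stopf("format error in %s at line %d: unparseable coordinates",
             path, i + 1L + which(is.na(x) | is.na(y) | is.na(z))[1L])
    boxv <- suppressWarnings(as.numeric(
      strsplit(trimws(lines[i + 2L + nat]), "\\s+")[[1L]]))
    if (length(boxv) < 3L || anyNA(boxv[1:3]))
      .stopf("format error in %s at line %d: bad box line", path, i + 2L + nat)
    resname <- trimws(substr(rows, 6L, 10L))
    name <- trimws(substr(rows, 11L, 15L))
    ra <- assign_roles(resname, name, map, fallback)
    tm <- regmatches(title, regexec("t=\\s*([0-9eE.+-]+)", title))[[1L]]
    time <- if (length(tm) == 2L) as.numeric(tm[2L]) else NA_real_
    atoms <- data.frame(
      id = as.integer(substr(rows, 16L, 20L)),
      mol = as.integer(substr(rows, 1L, 5L)),
      resname = resname, name = name,
      role = ra$role, mass = ra$mass, x = x, y = y, z = z)
    frames[[length(frames) + 1L]] <-
      monolayer_frame(atoms, boxv[1:3], time)
    i <- i + nat + 3L
  }
  frames
}

## ---- PDB ------------------------------------------------------------------

.write_pdb <- function(frames, con) {
  b <- frames[[1L]]$box * 10  # nm -> Angstrom
  writeLines(sprintf(
    "CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
    b[1], b[2], b[3]), con)
  multi <- length(frames) > 1L
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    a <- f$atoms
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      a$id %% 100000L, substr(a$name, 1L, 4L), substr(a$resname, 1L, 3L),
      a$mol %% 10000L, a$x * 10, a$y * 10, a$z * 10), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

.read_pdb <- function(path, map, fallback) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) .stopf("format error: empty file %s", path)
  if (!any(grepl("^(ATOM|HETATM)", lines)))
    .stopf("format error: no ATOM records in %s", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e)
                    .stopf("format error reading %s: %s", path,
                           conditionMessage(e)))
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cl)) .stopf("format error: no CRYST1 box record in %s", path)
  box <- as.numeric(c(substr(cl[1L], 7L, 15L), substr(cl[1L], 16L, 24L),
                      substr(cl[1L], 25L, 33L))) / 10  # Angstrom -> nm
  at <- pdb$atom
  ra <- assign_roles(at$resid, at$elety, map, fallback)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  lapply(seq_len(nrow(xyz)), function(k) {
    m <- matrix(xyz[k, ], ncol = 3L, byrow = TRUE) / 10  # Angstrom -> nm
    monolayer_frame(data.frame(
      id = at$eleno, mol = at$resno, resname = at$resid, name = at$elety,
      role = ra$role, mass = ra$mass,
      x = m[, 1L], y = m[, 2L], z = m[, 3L]), box, NA_real_)
  })
}

## ---- extended XYZ ---------------------------------------------------------

.write_xyz <- function(frames, con) {
  for (f in frames) {
    a <- f$atoms
    writeLines(as.character(nrow(a)), con)
    writeLines(sprintf(
      paste0('Lattice="%.6f 0.0 0.0 0.0 %.6f 0.0 0.0 0.0 %.6f" ',
             'Properties=species:S:1:pos:R:3:mol:I:1:resname:S:1 Time=%.6f'),
      f$box[1], f$box[2], f$box[3], f$time), con)
    writeLines(sprintf("%-5s %15.9f %15.9f %15.9f %6d %-5s",
                       a$name, a$x, a$y, a$z, a$mol, a$resname), con)
  }
}

.read_xyz <- function(path, map, fallback) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) .stopf("format error: empty file %s", path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat <= 0L)
      .stopf("format error in %s at line %d: bad atom count", path, i)
    if (i + 1L + nat > length(lines))
      .stopf("format error in %s at line %d: truncated frame", path,
             length(lines))
    comment <- lines[i + 1L]
    lm_ <- regmatches(comment, regexec(
      'Lattice="([0-9eE.+-]+) [0-9eE.+-]+ [0-9eE.+-]+ [0-9eE.+-]+ ([0-9eE.+-]+) [0-9eE.+-]+ [0-9eE.+-]+ [0-9eE.+-]+ ([0-9eE.+-]+)"',
      comment))[[1L]]
    if (length(lm_) != 4L)
      .stopf("format error in %s at line %d: no Lattice in comment", path,
             i + 1L)
    box <- as.numeric(lm_[2:4])
    tm <- regmatches(comment, regexec("Time=([0-9eE.+-]+)", comment))[[1L]]
    time <- if (length(tm) == 2L) as.numeric(tm[2L]) else NA_real_
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + nat)]), "\\s+")
    nf <- lengths(rows)
    if (any(nf < 4L))
      .stopf("format error in %s at line %d: short atom record", path,
             i + 1L + which(nf < 4L)[1L])
    name <- vapply(rows, `[`, "", 1L)
    x <- as.numeric(vapply(rows, `[`, "", 2L))
    y <- as.numeric(vapply(rows, `[`, "", 3L))
    z <- as.numeric(vapply(rows, `[`, "", 4L))
    if (anyNA(x) || anyNA(y) || anyNA(z))
      .stopf("format error in %s at line %d: unparseable coordinates", path,
             i + 1L + which(is.na(x) | is.na(y) | is.na(z))[1L])
    mol <- if (all(nf >= 5L)) as.integer(vapply(rows, `[`, "", 5L))
           else seq_len(nat)
    resname <- if (all(nf >= 6L)) vapply(rows, `[`, "", 6L)
               else rep("UNK", nat)
    ra <- assign_roles(resname, name, map, fallback)
    frames[[length(frames) + 1L]] <- monolayer_frame(data.frame(
      id = seq_len(nat), mol = mol, resname = resname, name = name,
      role = ra$role, mass = ra$mass, x = x, y = y, z = z), box, time)
    i <- i + nat + 2L
  }
  frames
}
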