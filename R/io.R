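#' Read and write trajectories
#'
#' Extended XYZ is the canonical, human-diffable text format: each frame is an
#' atom count, a comment line carrying `Lattice=`, `Time=` and `Wrapped=`
#' fields, then one `species x y z` row per particle.  DCD (CHARMM binary
#' layout) is supported for bulk runs; since DCD carries neither species
#' labels nor irregular frame times, the writer emits a JSON sidecar
#' (`<path>.meta.json`) with times, species labels, box and wrapped flag,
#' which the reader consumes to reconstruct the trajectory exactly.
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @param format `"xyz"` or `"dcd"`; `read_trajectory` auto-detects from the
#'   file content when `format = NULL` and errors when an explicitly
#'   requested format does not match the file.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a [trajectory()].
#' @export
write_trajectory <- function(traj, path, format = c("xyz", "dcd")) {
  format <- match.arg(format)
  if (n_frames(traj) < 1) stop("empty trajectory")
  if (format == "xyz") write_xyz(traj, path) else write_dcd(traj, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @param species_table Optional [species_table()] to attach on read (XYZ
#'   files reconstruct one from the stored labels when omitted).
#' @export
read_trajectory <- function(path, format = NULL, species_table = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  detected <- detect_traj_format(path)
  if (is.null(format)) {
    format <- detected
  } else if (!identical(format, detected)) {
    stop("format mismatch: file looks like '", detected,
         "' but '", format, "' was requested")
  }
  if (format == "xyz") read_xyz(path, species_table)
  else read_dcd(path, species_table)
}

detect_traj_format <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head8 <- readBin(con, "raw", 8)
  if (length(head8) >= 8 && rawToChar(head8[5:8]) == "CORD") return("dcd")
  first <- strsplit(readLines(path, n = 1, warn = FALSE), "[ \t]+")[[1]]
  first <- first[nzchar(first)]
  if (length(first) == 1 && grepl("^[0-9]+$", first)) return("xyz")
  stop("unrecognised trajectory format in ", path)
}

# ---- extended XYZ ---------------------------------------------------------

write_xyz <- function(traj, path) {
  L <- box_L(traj$box)
  np <- n_particles(traj)
  labels <- traj$table$name[traj$species_index]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    co <- frame_coords(traj, f)
    writeLines(sprintf("%d", np), con)
    writeLines(sprintf(
      paste0("Lattice=\"%.6f 0 0 0 %.6f 0 0 0 %.6f\" ",
             "Properties=species:S:1:pos:R:3 Time=%.6f Wrapped=%s"),
      L, L, L, traj$times[f], if (traj$wrapped) "T" else "F"), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", labels, co[, 1], co[, 2],
                       co[, 3]), con)
  }
}

xyz_field <- function(comment, key) {
  m <- regmatches(comment, regexpr(paste0(key, "=(\"[^\"]*\"|\\S+)"),
                                   comment))
  if (!length(m)) return(NA_character_)
  gsub("\"", "", sub(paste0(key, "="), "", m))
}

read_xyz <- function(path, table = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty trajectory file: ", path)
  pos <- 1L
  frames <- list(); times <- c(); wrapped <- TRUE; L <- 0
  labels <- NULL
  np <- NA_integer_
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n)) stop("malformed XYZ frame header at line ", pos)
    if (is.na(np)) np <- n
    if (n != np)
      stop("frame at line ", pos, " has ", n, " particles, expected ", np)
    comment <- lines[pos + 1L]
    lat <- xyz_field(comment, "Lattice")
    if (!is.na(lat)) L <- as.numeric(strsplit(lat, "\\s+")[[1]][1])
    tm <- suppressWarnings(as.numeric(xyz_field(comment, "Time")))
    times <- c(times, if (is.na(tm)) length(times) else tm)
    wr <- xyz_field(comment, "Wrapped")
    if (!is.na(wr)) wrapped <- wrapped && identical(wr, "T")
    body <- lines[pos + 1L + seq_len(n)]
    if (length(body) < n || anyNA(body))
      stop("truncated XYZ frame starting at line ", pos)
    parts <- strsplit(trimws(body), "[ \t]+")
    if (any(lengths(parts) < 4))
      stop("malformed XYZ atom line in frame starting at line ", pos)
    lab <- vapply(parts, `[`, "", 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (anyNA(xyz)) stop("malformed coordinates in frame at line ", pos)
    if (is.null(labels)) labels <- lab
    else if (!identical(lab, labels))
      stop("particle ordering/labels change between frames")
    frames[[length(frames) + 1L]] <- xyz
    pos <- pos + 2L + n
  }
  co <- array(0, c(length(frames), np, 3))
  for (f in seq_along(frames)) co[f, , ] <- frames[[f]]
  if (is.null(table)) {
    un <- unique(labels)
    cnt <- as.integer(tabulate(match(labels, un), length(un)))
    table <- species_table(un, rep(10, length(un)), cnt)
  }
  sp <- match(labels, table$name)
  if (anyNA(sp)) stop("species label(s) missing from the supplied table: ",
                      paste(unique(labels[is.na(sp)]), collapse = ", "))
  box <- if (L > 0) sim_box(L) else NULL
  trajectory(times, co, sp, table, box, wrapped = wrapped)
}

# ---- DCD (CHARMM binary layout) ------------------------------------------

write_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- n_frames(traj); np <- n_particles(traj)
  dt <- if (nf > 1) traj$times[2] - traj$times[1] else 1
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 0L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[11] <- 1L   # crystal record present
  icntrl[20] <- 24L  # CHARMM version tag
  writeBin(84L, con, size = 4)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  writeBin(icntrl[1:9], con, size = 4)
  writeBin(as.numeric(dt), con, size = 4)  # delta as float
  writeBin(icntrl[11:20], con, size = 4)
  writeBin(84L, con, size = 4)
  title <- sprintf("%-80s", paste("crowdbd", packageVersion("crowdbd")))
  writeBin(4L + 80L, con, size = 4)
  writeBin(1L, con, size = 4)
  writeChar(title, con, nchars = 80, eos = NULL)
  writeBin(4L + 80L, con, size = 4)
  writeBin(4L, con, size = 4); writeBin(np, con, size = 4)
  writeBin(4L, con, size = 4)
  L <- box_L(traj$box)
  for (f in seq_len(nf)) {
    writeBin(48L, con, size = 4)
    writeBin(as.numeric(c(L, 90, L, 90, 90, L)), con, size = 8)
    writeBin(48L, con, size = 4)
    co <- frame_coords(traj, f)
    for (d in 1:3) {
      writeBin(4L * np, con, size = 4)
      writeBin(as.numeric(co[, d]), con, size = 4)
      writeBin(4L * np, con, size = 4)
    }
  }
  meta <- list(times = traj$times,
               species = traj$table$name[traj$species_index],
               table = unclass(as.data.frame(traj$table)),
               edge_length = L, wrapped = traj$wrapped)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
}

read_dcd <- function(path, table = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  sz <- readBin(con, "integer", 1, 4)
  magic <- rawToChar(readBin(con, "raw", 4))
  if (sz != 84L || magic != "CORD") stop("not a DCD file: ", path)
  icntrl1 <- readBin(con, "integer", 9, 4)
  readBin(con, "numeric", 1, 4)        # delta
  icntrl2 <- readBin(con, "integer", 10, 4)
  readBin(con, "integer", 1, 4)        # trailing 84
  nf <- icntrl1[1]
  has_cell <- icntrl2[1] == 1L
  tsz <- readBin(con, "integer", 1, 4)
  ntitle <- readBin(con, "integer", 1, 4)
  readBin(con, "raw", 80 * ntitle)
  readBin(con, "integer", 1, 4)
  stopifnot(tsz == 4L + 80L * ntitle)
  readBin(con, "integer", 1, 4)
  np <- readBin(con, "integer", 1, 4)
  readBin(con, "integer", 1, 4)
  co <- array(0, c(nf, np, 3))
  L <- 0
  for (f in seq_len(nf)) {
    if (has_cell) {
      readBin(con, "integer", 1, 4)
      cell <- readBin(con, "numeric", 6, 8)
      readBin(con, "integer", 1, 4)
      L <- cell[1]
    }
    for (d in 1:3) {
      n1 <- readBin(con, "integer", 1, 4)
      if (!length(n1) || n1 != 4L * np)
        stop("corrupt DCD frame ", f, " (wrong particle count)")
      co[f, , d] <- readBin(con, "numeric", np, 4)
      readBin(con, "integer", 1, 4)
    }
  }
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    tab <- table %||%
      validate_species_table(as.data.frame(meta$table))
    sp <- match(meta$species, tab$name)
    trajectory(meta$times, co, sp, tab,
               if (meta$edge_length > 0) sim_box(meta$edge_length) else NULL,
               wrapped = isTRUE(meta$wrapped))
  } else {
    trajectory(seq_len(nf) - 1, co, species_index = NULL,
               table = table,
               box = if (L > 0) sim_box(L) else NULL, wrapped = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round-trip a trajectory through a file format
#'
#' Writes `traj` to `path` and reads it back; the result equals the input in
#' frame count, species labels and times exactly, and in coordinates to
#' within format precision (better than 1e-3 A).
#'
#' @inheritParams write_trajectory
#' @export
trajectory_roundtrip <- function(traj, path, format = c("xyz", "dcd")) {
  format <- match.arg(format)
  write_trajectory(traj, path, format)
  read_trajectory(path, format, species_table = traj$table)
}

# ---- atom-group selections ------------------------------------------------

#' Atom-group selections
#'
#' Labelled index sets on a trajectory's particles, with a role tag used by
#' the structural metrics (RMSD cores, ligand-binding sites, reference
#' atoms).
#'
#' @param label Selection name.
#' @param indices Integer particle indices (1-based, non-empty).
#' @param role One of `"core"`, `"ligand_site_1"`, `"ligand_site_2"`,
#'   `"active_site"`, `"reference_atoms"`.
#' @export
atom_group_selection <- function(label, indices,
                                 role = c("core", "ligand_site_1",
                                          "ligand_site_2", "active_site",
                                          "reference_atoms")) {
  role <- match.arg(role)
  indices <- as.integer(indices)
  if (!length(indices)) stop("selection '", label, "' is empty")
  if (any(indices < 1)) stop("selection indices must be >= 1")
  structure(list(label = as.character(label), indices = indices,
                 role = role),
            class = "atom_group_selection")
}

#' @rdname atom_group_selection
#' @param selections List of selections to write.
#' @param path JSON file path.
#' @export
write_selections <- function(selections, path) {
  jsonlite::write_json(lapply(selections, unclass), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname atom_group_selection
#' @export
read_selections <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(raw)), function(i)
    atom_group_selection(raw$label[i], raw$indices[[i]], raw$role[i]))
}
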