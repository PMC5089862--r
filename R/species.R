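#' Species tables
#'
#' A species table describes the composition of a coarse-grained system: one
#' row per molecular species with its Stokes radius (the sphere radius used
#' both for excluded volume and for the dilute diffusion constant), copy
#' number, group label, charge and (optionally) molecular weight.
#'
#' Group labels are drawn from the closed set
#' `c("glycolytic", "protein", "RNA", "huge", "metabolite", "ion")`;
#' "glycolytic" marks glycolysis-pathway enzymes, which are analysed as their
#' own group in the quinary-interaction statistics, and "huge" marks
#' ribosome/GroEL-sized complexes.
#'
#' @param name Character vector of unique species names.
#' @param stokes_radius Stokes radii in Angstrom (> 0).
#' @param copies Non-negative integer copy numbers.
#' @param group Group labels from the closed set (recycled if length 1).
#' @param charge Net charge in elementary charges (default 0).
#' @param molecular_weight Molecular weight in Da (optional, `NA` allowed);
#'   used only by the radius-vs-weight power-law fit.
#' @return A `data.frame` of class `"species_table"`.
#' @seealso [read_species_table()], [synthetic_cytoplasm()]
#' @export
species_table <- function(name, stokes_radius, copies,
                          group = "protein", charge = 0,
                          molecular_weight = NA_real_) {
  x <- data.frame(name = as.character(name),
                  stokes_radius = as.numeric(stokes_radius),
                  copies = as.integer(copies),
                  group = as.character(group),
                  charge = as.numeric(charge),
                  molecular_weight = as.numeric(molecular_weight),
                  stringsAsFactors = FALSE)
  validate_species_table(x)
}

species_groups <- c("glycolytic", "protein", "RNA", "huge", "metabolite",
                    "ion")

validate_species_table <- function(x) {
  req <- c("name", "stokes_radius", "copies", "group")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("species table is missing column(s): ", paste(miss, collapse = ", "))
  if (!"charge" %in% names(x)) x$charge <- 0
  if (!"molecular_weight" %in% names(x)) x$molecular_weight <- NA_real_
  bad <- which(!is.finite(x$stokes_radius) | x$stokes_radius <= 0)
  if (length(bad))
    stop("stokes_radius must be > 0; offending row(s): ",
         paste(bad, collapse = ", "))
  if (anyDuplicated(x$name))
    stop("species names must be unique; duplicated: ",
         paste(unique(x$name[duplicated(x$name)]), collapse = ", "))
  bad <- which(!x$group %in% species_groups)
  if (length(bad))
    stop("unknown group label(s) in row(s) ", paste(bad, collapse = ", "),
         ": ", paste(unique(x$group[bad]), collapse = ", "),
         " (allowed: ", paste(species_groups, collapse = ", "), ")")
  if (any(!is.finite(x$copies) | x$copies < 0))
    stop("copies must be non-negative integers")
  class(x) <- c("species_table", "data.frame")
  x
}

#' Read a species table from TSV
#'
#' The file must have a header row with at least the columns `name`,
#' `stokes_radius`, `copies`, `group` (plus optional `charge`,
#' `molecular_weight`).  Lines starting with `#` are treated as metadata
#' comments and skipped.
#'
#' @param path Path to a tab-separated file.
#' @return A validated [species_table()].
#' @export
read_species_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  for (col in intersect(c("stokes_radius", "copies", "charge",
                          "molecular_weight"), names(x))) {
    v <- x[[col]]
    if (is.character(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & nzchar(v))
      if (length(bad))
        stop("malformed numeric field in column '", col, "', row(s): ",
             paste(bad, collapse = ", "))
      x[[col]] <- vn
    }
  }
  validate_species_table(x)
}

#' Write a species table to TSV with a metadata header
#'
#' @param x A [species_table()].
#' @param path Output path.
#' @param seed Optional seed to record in the metadata header.
#' @export
write_species_table <- function(x, path, seed = NULL) {
  x <- validate_species_table(as.data.frame(x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# crowdbd %s", as.character(packageVersion("crowdbd"))),
             con)
  if (!is.null(seed)) writeLines(sprintf("# seed %d", as.integer(seed)), con)
  writeLines(sprintf("# hash %s", config_hash(unclass(x))), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.species_table <- function(x, ...) {
  cat(sprintf("Species table: %d species, %d particles total\n",
              nrow(x), sum(x$copies)))
  NextMethod()
  invisible(x)
}

# expand a species table into per-particle vectors
expand_species <- function(table) {
  idx <- rep(seq_len(nrow(table)), table$copies)
  list(index = idx,
       radius = table$stokes_radius[idx],
       charge = table$charge[idx],
       name = table$name[idx])
}

#' Total sphere volume fraction of a species table in a cubic box
#'
#' @param table A [species_table()].
#' @param box A [sim_box()] or edge length in Angstrom.
#' @return Dimensionless volume fraction.
#' @export
volume_fraction <- function(table, box) {
  L <- if (inherits(box, "sim_box")) box$edge_length else box
  sum(table$copies * 4 / 3 * pi * table$stokes_radius^3) / L^3
}

#' Synthetic coarse-grained cytoplasm composition
#'
#' A synthetic stand-in for a Mycoplasma-like coarse-grained cytoplasm:
#' nine sphere species spanning ribosome-sized (105 A) to small-protein-sized
#' (15.8 A) Stokes radii, with copy numbers weighted towards small abundant
#' enzymes and a glycolytic sub-population.  The base composition holds 81
#' molecules; `scale_factor = 8` applies the eightfold copy-number scaling
#' used to build production-size coarse-grained systems (ribosome and GroEL
#' base copies of 3 become 24).
#'
#' The matching cubic box returned by [synthetic_cytoplasm_box()] is sized so
#' the sphere volume fraction is 0.45, the upper end of the 25-45 vol%
#' cytoplasmic occupancy range, appropriate for spheres drawn at Stokes
#' (hydrodynamic) radii which overestimate physical molecular volumes.
#' The smallest radius (15.8 A) is the radius whose suggested BD timestep
#' (see [suggest_timestep()]) is 8 ps.
#'
#' This table is synthetic: real per-species copy numbers of the organism are
#' not bundled; supply your own table via [read_species_table()] to model a
#' measured composition.
#'
#' @param scale_factor Integer copy-number multiplier (default 1).
#' @return A [species_table()].
#' @examples
#' tab <- synthetic_cytoplasm(scale_factor = 8)
#' sum(tab$copies) # 648 spheres
#' @export
synthetic_cytoplasm <- function(scale_factor = 1) {
  stopifnot(scale_factor >= 1, scale_factor == round(scale_factor))
  tab <- species_table(
    name = c("ribosome", "groel", "pdh_complex", "pyk_tetramer", "eno_dimer",
             "pgk", "trna", "small_protein", "if1"),
    stokes_radius = c(105, 80, 55, 40, 33, 30, 24, 22, 15.8),
    copies = c(3, 3, 6, 9, 12, 15, 12, 12, 9),
    group = c("huge", "huge", "protein", "glycolytic", "glycolytic",
              "glycolytic", "RNA", "protein", "protein"),
    charge = c(-50, -20, -15, -10, -8, -6, -20, -5, -3),
    molecular_weight = c(2.7e6, 8.0e5, 2.0e5, 2.3e5, 9.0e4, 4.5e4, 2.5e4,
                         2.0e4, 9.0e3))
  tab$copies <- as.integer(tab$copies * scale_factor)
  tab
}

#' @rdname synthetic_cytoplasm
#' @param target_phi Sphere volume fraction the box is sized for.
#' @export
synthetic_cytoplasm_box <- function(scale_factor = 1, target_phi = 0.45) {
  tab <- synthetic_cytoplasm(scale_factor)
  vol <- sum(tab$copies * 4 / 3 * pi * tab$stokes_radius^3)
  sim_box((vol / target_phi)^(1 / 3))
}
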