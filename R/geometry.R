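#' Cubic periodic simulation box
#'
#' @param edge_length Box edge in Angstrom (> 0).
#' @param periodic Logical; production systems are always periodic.
#' @return An object of class `"sim_box"`.
#' @export
sim_box <- function(edge_length, periodic = TRUE) {
  stopifnot(is.numeric(edge_length), length(edge_length) == 1,
            is.finite(edge_length), edge_length > 0)
  structure(list(edge_length = as.numeric(edge_length),
                 periodic = isTRUE(periodic)),
            class = "sim_box")
}

#' @export
print.sim_box <- function(x, ...) {
  cat(sprintf("Cubic box, edge %.3f A%s\n", x$edge_length,
              if (x$periodic) " (periodic)" else ""))
  invisible(x)
}

#' Box edge length accessor
#'
#' Returns the edge length of a periodic box (0 for aperiodic input).
#' @param box A [sim_box()], a bare number, or `NULL`.
#' @export
box_L <- function(box) {
  if (inherits(box, "sim_box")) {
    if (!box$periodic) return(0)
    box$edge_length
  } else if (is.null(box)) 0 else as.numeric(box)
}

#' Minimum-image displacement and distance
#'
#' Displacements and distances under the minimum-image convention in a cubic
#' periodic box.  `min_image_disp` maps each displacement component into
#' `[-L/2, L/2)`; `min_image_dist` returns pairwise Euclidean distances of
#' two coordinate matrices under that convention.
#'
#' @param dx Numeric vector/matrix of displacement components.
#' @param box A [sim_box()] or edge length (0 or `NULL` = aperiodic).
#' @return Same shape as `dx`.
#' @export
min_image_disp <- function(dx, box) {
  L <- box_L(box)
  if (L <= 0) return(dx)
  dx - L * round(dx / L)
}

#' @rdname min_image_disp
#' @param x,y Coordinate matrices (n x 3 and m x 3) or 3-vectors.
#' @export
min_image_dist <- function(x, y, box) {
  x <- rbind(x); y <- rbind(y)
  L <- box_L(box)
  out <- matrix(0, nrow(x), nrow(y))
  for (d in 1:3) {
    dd <- outer(x[, d], y[, d], "-")
    if (L > 0) dd <- dd - L * round(dd / L)
    out <- out + dd^2
  }
  sqrt(out)
}

#' Wrap coordinates into the primary box `[0, L)`
#'
#' @param coords Coordinate matrix (n x 3).
#' @inheritParams min_image_disp
#' @export
wrap_coords <- function(coords, box) {
  L <- box_L(box)
  if (L <= 0) return(coords)
  w <- coords %% L
  w[w >= L] <- 0  # guard against floating point x %% L == L
  w
}
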