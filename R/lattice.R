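#' Create a cubic simulation lattice
#'
#' The lattice is the shared spatial scaffold of all model layers: each site
#' can host at most one cell agent, vessel nodes are anchored on sites, and
#' the diffusible fields are discretized on the site centres. Site `(1,1,1)`
#' has its centre at `(spacing/2, spacing/2, spacing/2)` (cell-centred
#' convention).
#'
#' @param dims integer vector of length 3, sites per axis (each >= 1).
#' @param spacing_um lattice spacing in micrometres (> 0). Default 20.
#' @return an object of class `vm_lattice` with elements `dims`,
#'   `spacing_um`, `n_sites` and `side_um` (physical side length per axis).
#' @examples
#' lat <- vm_lattice(c(64, 64, 64), 20)
#' lat$side_um / 1000  # 1.28 mm
#' @export
vm_lattice <- function(dims = c(64L, 64L, 64L), spacing_um = 20) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 1L))
    stop("dims must be three integers >= 1")
  if (!is.numeric(spacing_um) || length(spacing_um) != 1L || spacing_um <= 0)
    stop("spacing_um must be a positive scalar")
  structure(
    list(dims = dims, spacing_um = as.numeric(spacing_um),
         n_sites = prod(dims), side_um = dims * as.numeric(spacing_um)),
    class = "vm_lattice")
}

#' @export
print.vm_lattice <- function(x, ...) {
  cat(sprintf("<vm_lattice %d x %d x %d, spacing %g um, side %s um>\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing_um,
              paste(format(x$side_um), collapse = " x ")))
  invisible(x)
}

# 26-neighbourhood offsets (3D Moore), excluding the origin; rows are offsets.
# In degenerate (flat) lattices out-of-range neighbours are dropped at lookup.
vm_neighbour_offsets <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0L, , drop = FALSE]
}

# Neighbour site indices (rows of an n x 3 matrix) of site p within lattice
# bounds. p is a length-3 integer vector.
vm_neighbours <- function(p, dims, offsets = vm_neighbour_offsets()) {
  nb <- offsets + matrix(p, nrow = nrow(offsets), ncol = 3L, byrow = TRUE)
  keep <- nb[, 1] >= 1L & nb[, 1] <= dims[1] &
          nb[, 2] >= 1L & nb[, 2] <= dims[2] &
          nb[, 3] >= 1L & nb[, 3] <= dims[3]
  nb[keep, , drop = FALSE]
}

# linear index of site triples (matrix n x 3) in column-major array order
vm_site_index <- function(xyz, dims) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3L)
  (xyz[, 3] - 1L) * (dims[1] * dims[2]) + (xyz[, 2] - 1L) * dims[1] + xyz[, 1]
}

# new, empty occupancy array (0 = empty, otherwise cell id)
vm_empty_occupancy <- function(lattice) {
  array(0L, dim = lattice$dims)
}
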