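#' Default parameters of the diffusible species
#'
#' All internal computations use a single unit system: length in um, time in
#' hours, glucose in mmol/l; oxygen and VEGF in framework units (vessel
#' plasma oxygen = 20). Diffusion coefficients given in cm^2/s are converted
#' at config load (1 cm^2/s = 3.6e11 um^2/h).
#'
#' Per species:
#' \describe{
#'   \item{d_um2_h}{interstitial diffusion coefficient (um^2/h); glucose
#'     default 7.2e5 = 2.0e-6 cm^2/s.}
#'   \item{perm_um_h}{vessel-wall permeation coefficient (um/h).}
#'   \item{c_blood}{intravascular concentration (glucose 5 mmol/l,
#'     physiological plasma; VEGF 0, so vessels act as a sink).}
#'   \item{decay_h}{first-order decay rate (1/h; VEGF only).}
#'   \item{uptake}{cellular sink: Michaelis-Menten
#'     `list(kind="michaelis", rmax=c(cancer=..., normal=...), km=...)`
#'     or linear `list(kind="linear", k=...)`, or NULL.}
#'   \item{bc}{boundary condition: `list(kind="neumann0")` (zero flux, the
#'     default) or `list(kind="dirichlet", faces=list(xlo=value, ...))`.}
#' }
#' @return named list with elements `glucose`, `oxygen`, `vegf`.
#' @export
vm_default_field_params <- function() {
  list(
    glucose = list(d_um2_h = 7.2e5, perm_um_h = 500, c_blood = 5,
                   decay_h = 0,
                   uptake = list(kind = "michaelis",
                                 rmax = c(cancer = 3.3, normal = 0.66),
                                 km = 0.2),
                   bc = list(kind = "neumann0")),
    oxygen = list(d_um2_h = 7.2e6, perm_um_h = 4e5, c_blood = 20,
                  decay_h = 0,
                  uptake = list(kind = "michaelis",
                                rmax = c(cancer = 6000, normal = 2500),
                                km = 1),
                  bc = list(kind = "neumann0")),
    vegf = list(d_um2_h = 3.6e4, perm_um_h = 10, c_blood = 0,
                decay_h = 0.65, uptake = NULL,
                secretion_coeff = 2,
                bc = list(kind = "neumann0")))
}

#' Michaelis-Menten glucose uptake rate
#'
#' `r(c) = rmax * c / (km + c)`: zero at `c = 0`, `rmax/2` at `c = km`,
#' saturating at `rmax`. Cancer cells take glucose up five-fold faster than
#' normal cells (defaults 3.3 vs 0.66 mmol/(l h), km = 0.2 mmol/l).
#'
#' @param c extracellular concentration, mmol/l (>= 0, vectorized).
#' @param rmax maximum uptake rate, mmol/(l h).
#' @param km half-saturation concentration, mmol/l.
#' @return uptake rate in mmol/(l h).
#' @examples
#' glucose_uptake_rate(0.2, rmax = 3.3, km = 0.2)  # 1.65
#' @export
glucose_uptake_rate <- function(c, rmax = 3.3, km = 0.2) {
  if (any(c < 0)) stop("concentration must be >= 0")
  if (rmax <= 0 || km <= 0) stop("rmax and km must be > 0")
  rmax * c / (km + c)
}

# Per-site vessel exchange coefficient gamma = 2 pi R P Lhalf / h^3 (1/h):
# each functional segment contributes half its length, weighted by its
# radius, to each of its endpoint sites.
vm_vessel_exchange <- function(network, lattice, perm_um_h) {
  h <- lattice$spacing_um
  gam <- array(0, dim = lattice$dims)
  segs <- network$segments[network$segments$functional, , drop = FALSE]
  if (!nrow(segs)) return(gam)
  nodes <- network$nodes
  for (end in c("from", "to")) {
    nd <- nodes[match(segs[[end]], nodes$id), ]
    contrib <- 2 * pi * segs$radius_um * perm_um_h * (segs$length_um / 2) / h^3
    idx <- cbind(nd$x, nd$y, nd$z)
    for (r in seq_len(nrow(idx)))
      gam[idx[r, 1], idx[r, 2], idx[r, 3]] <-
        gam[idx[r, 1], idx[r, 2], idx[r, 3]] + contrib[r]
  }
  gam
}

# discrete Laplacian with zero-flux (reflection) closure, cell-centred
vm_lap_neumann <- function(c, h, dims) {
  out <- array(0, dim = dims)
  for (k in 1:3) {
    n <- dims[k]
    if (n == 1L) next
    ip <- c(2:n, n); im <- c(1L, 1:(n - 1))
    if (k == 1L) out <- out + (c[ip, , , drop = FALSE] +
                               c[im, , , drop = FALSE] - 2 * c)
    else if (k == 2L) out <- out + (c[, ip, , drop = FALSE] +
                                    c[, im, , drop = FALSE] - 2 * c)
    else out <- out + (c[, , ip, drop = FALSE] + c[, , im, drop = FALSE] -
                       2 * c)
  }
  out / h^2
}

# Dirichlet faces add 2D/h^2 to the diagonal of the boundary layer and
# 2 D c_bc / h^2 to the right-hand side (ghost cell elimination).
vm_dirichlet_terms <- function(bc, dims, d_um2_h, h) {
  addA <- array(0, dim = dims); addb <- array(0, dim = dims)
  if (is.null(bc) || identical(bc$kind, "neumann0"))
    return(list(addA = addA, addb = addb))
  if (!identical(bc$kind, "dirichlet")) stop("unknown bc kind: ", bc$kind)
  co <- 2 * d_um2_h / h^2
  for (face in names(bc$faces)) {
    val <- bc$faces[[face]]
    sl <- switch(face,
      xlo = list(1L, TRUE, TRUE), xhi = list(dims[1], TRUE, TRUE),
      ylo = list(TRUE, 1L, TRUE), yhi = list(TRUE, dims[2], TRUE),
      zlo = list(TRUE, TRUE, 1L), zhi = list(TRUE, TRUE, dims[3]),
      stop("unknown face: ", face))
    addA[sl[[1]], sl[[2]], sl[[3]]] <- addA[sl[[1]], sl[[2]], sl[[3]]] + co
    addb[sl[[1]], sl[[2]], sl[[3]]] <- addb[sl[[1]], sl[[2]], sl[[3]]] +
      co * val
  }
  list(addA = addA, addb = addb)
}

# matrix-free preconditioned conjugate gradient for (a - D lap) c = b
vm_cg_solve <- function(a, b, d_um2_h, h, dims, bcA, tol = 1e-10,
                        max_iter = 20000L, c0 = NULL) {
  applyA <- function(x) (a + bcA) * x - d_um2_h * vm_lap_neumann(x, h, dims)
  nax <- sum(dims > 1L)
  diagA <- a + bcA + d_um2_h * 2 * nax / h^2
  x <- if (is.null(c0)) array(0, dim = dims) else c0
  r <- b - applyA(x)
  z <- r / diagA
  p <- z
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(array(0, dim = dims))
  rz <- sum(r * z)
  for (it in seq_len(max_iter)) {
    if (sqrt(sum(r^2)) / bnorm < tol) return(x)
    Ap <- applyA(p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    z <- r / diagA
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop(sprintf("field solve did not converge: relative residual %.3e",
               sqrt(sum(r^2)) / bnorm))
}

#' Solve one diffusible species to quasi-steady state
#'
#' Solves `D lap(c) + gamma (c_blood - c) - uptake(c) + source - decay c = 0`
#' on the lattice: vessel permeation is active on sites hosting functional
#' segments (scaled by `2 pi R` and the segment length per site volume),
#' the cellular sink uses the Michaelis-Menten law evaluated by Picard
#' iteration (uptake denominator lagged one outer iteration), and the inner
#' linear problem is solved matrix-free by preconditioned conjugate
#' gradients on the second-order 7-point stencil. The discrete operator is
#' an M-matrix, so non-negativity of the converged solution holds by the
#' scheme, without clipping.
#'
#' @param lattice a [vm_lattice()].
#' @param params one species entry of [vm_default_field_params()].
#' @param occupancy site-occupancy array (0 = empty) or NULL.
#' @param cells cell table (types resolve per-type uptake rates) or NULL.
#' @param network vessel network or NULL (no vessel exchange).
#' @param source optional per-site volumetric production array.
#' @param c_init optional initial guess.
#' @param tol relative residual tolerance of the inner linear solve.
#' @param picard_tol relative change tolerance of the outer iteration.
#' @return the concentration array (same dims as the lattice).
#' @export
solve_quasi_steady <- function(lattice, params, occupancy = NULL,
                               cells = NULL, network = NULL, source = NULL,
                               c_init = NULL, tol = 1e-8,
                               picard_tol = 1e-7) {
  dims <- lattice$dims; h <- lattice$spacing_um
  if (params$d_um2_h <= 0) stop("diffusion coefficient must be > 0")
  if (params$perm_um_h < 0 || params$c_blood < 0)
    stop("perm_um_h and c_blood must be >= 0")
  gam <- if (is.null(network)) array(0, dim = dims) else
    vm_vessel_exchange(network, lattice, params$perm_um_h)
  src <- if (is.null(source)) array(0, dim = dims) else source
  dec <- if (is.null(params$decay_h)) 0 else params$decay_h
  bct <- vm_dirichlet_terms(params$bc, dims, params$d_um2_h, h)
  # per-site maximum uptake rate (by occupant type) and kinetics
  up <- params$uptake
  rmax_site <- array(0, dim = dims); lin_site <- array(0, dim = dims)
  if (!is.null(up) && !is.null(occupancy) && !is.null(cells) && nrow(cells)) {
    idx <- cbind(cells$x, cells$y, cells$z)
    if (identical(up$kind, "michaelis")) {
      rmax_site[idx] <- unname(up$rmax[cells$type])
    } else if (identical(up$kind, "linear")) {
      lin_site[idx] <- if (length(up$k) > 1) unname(up$k[cells$type]) else up$k
    } else stop("unknown uptake kind: ", up$kind)
  }
  mm <- any(rmax_site > 0)
  b <- gam * params$c_blood + src + bct$addb
  c_prev <- if (is.null(c_init)) array(params$c_blood, dim = dims) else c_init
  scale <- max(params$c_blood, max(abs(b)) / max(dec + max(gam), 1), 1e-12)
  n_outer <- if (mm) 60L else 1L
  for (outer in seq_len(n_outer)) {
    a <- gam + dec + lin_site
    if (mm) a <- a + rmax_site / (up$km + pmax(c_prev, 0))
    c_new <- vm_cg_solve(a, b, params$d_um2_h, h, dims, bct$addA, tol = tol,
                         c0 = c_prev)
    if (!mm || max(abs(c_new - c_prev)) / scale < picard_tol) {
      return(c_new)
    }
    c_prev <- c_new
  }
  stop("Picard iteration on the uptake nonlinearity did not converge")
}

#' Per-site VEGF secretion source
#'
#' The feedback from the intracellular to the diffusible scale: each
#' occupied site produces VEGF at a rate proportional to its occupant's
#' intracellular VEGF level, which the subcellular ODE makes predominantly
#' nonzero for hypoxic cells. Empty sites produce nothing.
#'
#' @param cells cell table.
#' @param lattice a [vm_lattice()].
#' @param coeff secretion rate coefficient (1/h per unit intracellular
#'   VEGF).
#' @return per-site production array.
#' @export
vegf_secretion_source <- function(cells, lattice, coeff = 10) {
  src <- array(0, dim = lattice$dims)
  if (nrow(cells))
    src[cbind(cells$x, cells$y, cells$z)] <- coeff * cells$ivegf
  src
}
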