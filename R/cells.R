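#' Default subcellular parameter sets for normal and cancer cells
#'
#' Intracellular dynamics follow the hybrid multiscale tumour-growth
#' framework: cell-cycle progression at an oxygen-Michaelis rate saturating
#' at 1/t_cycle_min_h, and linear production--degradation kinetics for p53
#' and intracellular VEGF whose coefficients depend on local oxygen.
#' Oxygen is carried in mmHg-like framework units (vessel plasma ~ 20).
#'
#' Per cell type:
#' \describe{
#'   \item{t_cycle_min_h}{minimum cell-cycle time (h); progression rate
#'     saturates at 1/t_cycle_min_h.}
#'   \item{k_phi_o2}{oxygen half-saturation of cycle progression.}
#'   \item{p53_prod, p53_deg, k_p53_o2}{p53 kinetics
#'     dp/dt = p53_prod - p53_deg * O2/(O2 + k_p53_o2) * p: degradation is
#'     oxygen-dependent, so p53 accumulates under hypoxia.}
#'   \item{vegf_prod, vegf_deg, k_vegf_o2, vegf_o2_hill}{intracellular
#'     VEGF kinetics dv/dt = vegf_prod * k^n/(k^n + O2^n) - vegf_deg * v
#'     (k = k_vegf_o2, n = vegf_o2_hill): production is hypoxia-driven,
#'     with a steep sigmoidal oxygen shutoff centred just below the
#'     quiescence range so normoxic cells secrete very little.}
#'   \item{p53_thresh_low, p53_thresh_high}{apoptosis thresholds applied in
#'     low/high local cell-density context (occupied-neighbour fraction
#'     below/above density_thresh).}
#'   \item{density_thresh}{occupied-neighbour fraction separating the two
#'     p53 threshold regimes.}
#'   \item{o2_enter_quiescence, o2_leave_quiescence}{oxygen thresholds for
#'     entering / leaving quiescence (enter <= leave).}
#'   \item{max_quiescence_h}{maximum survival time in quiescence (h).}
#'   \item{movement_rate}{random-walk hop rate (1/h).}
#' }
#'
#' @return named list with elements `normal` and `cancer`.
#' @export
vm_default_cell_params <- function() {
  normal <- list(
    t_cycle_min_h = 48, k_phi_o2 = 3,
    p53_prod = 0.05, p53_deg = 0.05, k_p53_o2 = 1,
    vegf_prod = 1, vegf_deg = 0.5, k_vegf_o2 = 6, vegf_o2_hill = 4,
    p53_thresh_low = 1.5, p53_thresh_high = 3.0, density_thresh = 0.75,
    o2_enter_quiescence = 8, o2_leave_quiescence = 9.5,
    max_quiescence_h = 48, movement_rate = 0.05,
    # homeostatic turnover: normal tissue is renewed, so space opens up
    # for competing cells; cancer cells have no background death
    base_death_rate = 0.01)
  cancer <- normal
  cancer$t_cycle_min_h <- 24
  # cancer cells are insensitive to p53-mediated apoptosis by default
  cancer$p53_thresh_low <- 1e9
  cancer$p53_thresh_high <- 1e9
  cancer$max_quiescence_h <- 96
  cancer$movement_rate <- 0.1
  cancer$base_death_rate <- 0
  list(normal = normal, cancer = cancer)
}

vm_check_cell_params <- function(params) {
  for (ct in c("normal", "cancer")) {
    p <- params[[ct]]
    num <- vapply(p, is.numeric, logical(1))
    if (!all(num)) stop("non-numeric cell parameter for type ", ct)
    pos <- c("t_cycle_min_h", "k_phi_o2", "p53_prod", "p53_deg", "k_p53_o2",
             "vegf_prod", "vegf_deg", "k_vegf_o2", "max_quiescence_h")
    bad <- pos[vapply(pos, function(k) p[[k]] <= 0, logical(1))]
    if (length(bad)) stop("cell parameters must be > 0 for ", ct, ": ",
                          paste(bad, collapse = ", "))
    if (p$o2_enter_quiescence > p$o2_leave_quiescence)
      stop("o2_enter_quiescence must be <= o2_leave_quiescence for ", ct)
    if (p$movement_rate < 0) stop("movement_rate must be >= 0 for ", ct)
    if (p$base_death_rate < 0)
      stop("base_death_rate must be >= 0 for ", ct)
  }
  invisible(params)
}

# Canonical empty cell table. States: "proliferating", "quiescent".
# Removed (apoptotic) cells are dropped from the table and occupancy map.
vm_empty_cells <- function() {
  data.frame(id = integer(), type = character(), x = integer(), y = integer(),
             z = integer(), phase = numeric(), state = character(),
             p53 = numeric(), ivegf = numeric(), quiesc_h = numeric(),
             stringsAsFactors = FALSE)
}

vm_new_cells <- function(type, xyz, phase = 0, state = "proliferating",
                         p53 = 1, ivegf = 0, id_start = 1L) {
  n <- nrow(xyz)
  data.frame(id = seq.int(id_start, length.out = n), type = rep_len(type, n),
             x = as.integer(xyz[, 1]), y = as.integer(xyz[, 2]),
             z = as.integer(xyz[, 3]), phase = rep_len(phase, n),
             state = rep_len(state, n), p53 = rep_len(p53, n),
             ivegf = rep_len(ivegf, n), quiesc_h = 0,
             stringsAsFactors = FALSE)
}

#' Advance the subcellular state of cells by one time step
#'
#' Integrates, with the local oxygen frozen over the step, the subcellular
#' layer of each cell: cycle phase advances at rate
#' `O2/(O2 + k_phi_o2) / t_cycle_min_h` (only while proliferating), and p53
#' and intracellular VEGF follow their linear production--degradation ODEs.
#' The linear ODEs are advanced with their exact exponential solution, so
#' the update is unconditionally stable for any `dt` (0.5 h default step).
#'
#' @param cells cell table (as in `state$cells`); a single-row table works
#'   for one cell.
#' @param local_oxygen oxygen concentration at each cell's site (recycled).
#' @param dt time step in hours (> 0).
#' @param params per-type subcellular parameters
#'   (default [vm_default_cell_params()]).
#' @return the cell table with updated `phase`, `p53`, `ivegf`.
#' @export
advance_subcellular <- function(cells, local_oxygen, dt,
                                params = vm_default_cell_params()) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  if (any(local_oxygen < 0)) stop("local_oxygen must be >= 0")
  if (nrow(cells) == 0L) return(cells)
  o2 <- rep_len(local_oxygen, nrow(cells))
  for (ct in unique(cells$type)) {
    p <- params[[ct]]
    i <- which(cells$type == ct)
    C <- o2[i]
    prolif <- cells$state[i] == "proliferating"
    rate <- C / (C + p$k_phi_o2) / p$t_cycle_min_h
    cells$phase[i[prolif]] <- pmin(1, cells$phase[i][prolif] +
                                     rate[prolif] * dt)
    # p53: dp/dt = a - b(C) p, exact step
    b <- p$p53_deg * C / (C + p$k_p53_o2)
    a <- p$p53_prod
    cells$p53[i] <- vm_linear_ode_step(cells$p53[i], a, b, dt)
    # intracellular VEGF: dv/dt = a(C) - b v, steep hypoxia switch
    hn <- p$vegf_o2_hill
    av <- p$vegf_prod * p$k_vegf_o2^hn / (C^hn + p$k_vegf_o2^hn)
    cells$ivegf[i] <- vm_linear_ode_step(cells$ivegf[i], av, p$vegf_deg, dt)
  }
  cells
}

# exact solution of dy/dt = a - b y over dt (a, b vectors; b may be 0)
vm_linear_ode_step <- function(y, a, b, dt) {
  a <- rep_len(a, length(y)); b <- rep_len(b, length(y))
  out <- numeric(length(y))
  z <- b <= 0
  out[z] <- y[z] + a[z] * dt
  if (any(!z)) {
    e <- exp(-b[!z] * dt)
    out[!z] <- a[!z] / b[!z] + (y[!z] - a[!z] / b[!z]) * e
  }
  out
}

#' Implant a spherical tumour into the tissue
#'
#' Replaces the occupants of all sites within `radius_sites` (Euclidean
#' distance in site units, so radius 1 gives the 6-connected ball of 7
#' sites) of `centre` by cancer cells with cycle phase drawn uniformly in
#' [0, 1). Replaced normal cells are removed. Implanting twice is idempotent
#' up to the redrawn phases.
#'
#' @param state simulation state (see [initialize_scenario()]).
#' @param centre integer site triple.
#' @param radius_sites non-negative integer radius in site units.
#' @return the updated simulation state.
#' @export
implant_tumour <- function(state, centre, radius_sites) {
  dims <- state$lattice$dims
  centre <- as.integer(centre)
  if (any(centre < 1L) || any(centre > dims))
    stop("centre must lie inside the lattice")
  if (radius_sites < 0) stop("radius_sites must be >= 0")
  r <- as.integer(floor(radius_sites))
  if (any(centre - r < 1L) || any(centre + r > dims)) {
    warning("implant radius clipped at the lattice boundary")
  }
  rng <- function(k, n) max(1L, centre[k] - r):min(dims[k], centre[k] + r)
  ball <- as.matrix(expand.grid(x = rng(1), y = rng(2), z = rng(3)))
  d2 <- (ball[, 1] - centre[1])^2 + (ball[, 2] - centre[2])^2 +
        (ball[, 3] - centre[3])^2
  ball <- ball[d2 <= r^2, , drop = FALSE]
  idx <- vm_site_index(ball, dims)
  # remove current occupants (normal or previously implanted cancer cells)
  old <- state$occupancy[idx]
  old <- old[old > 0L]
  if (length(old)) {
    state$cells <- state$cells[!(state$cells$id %in% old), , drop = FALSE]
    state <- vm_drop_metab_states(state, old)
  }
  newc <- vm_new_cells("cancer", ball, phase = stats::runif(nrow(ball)),
                       id_start = state$next_cell_id)
  state$next_cell_id <- state$next_cell_id + nrow(newc)
  state$cells <- rbind(state$cells, newc)
  state$occupancy[idx] <- newc$id
  state <- vm_init_metab_states(state, newc$id, type = "cancer")
  state
}
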