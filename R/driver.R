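#' Build the initial simulation state for the default scenario
#'
#' Constructs the reference scenario: two straight parent vessels spanning
#' the domain along x on opposite sides, with opposed prescribed pressure
#' gradients (countercurrent flow); healthy tissue at confluence (every
#' site a normal cell, phases uniform in [0,1); or grown in by the cellular
#' automaton if `run.burnin_h > 0`); quasi-steady fields solved; and a
#' small tumour implanted at the domain centre at t = 0. Deterministic
#' given `run.seed`.
#'
#' @param config a resolved configuration ([load_config()],
#'   [vm_default_config()]).
#' @return an object of class `vm_state`: lattice, occupancy, cell table,
#'   vessel network with active tips, per-species field arrays, per-cell
#'   metabolic states, clock and RNG state.
#' @export
initialize_scenario <- function(config = vm_default_config()) {
  config <- validate_config(config)
  set.seed(config$run$seed)
  lat <- vm_lattice(config$lattice$dims, config$lattice$spacing_um)
  state <- structure(list(
    lattice = lat, occupancy = vm_empty_occupancy(lat),
    cells = vm_empty_cells(), network = vm_empty_network(lat),
    fields = list(), metab = NULL, time_h = 0, step = 0L,
    next_cell_id = 1L, config = config,
    counters = NULL, vcounters = NULL), class = "vm_state")
  if (config$metabolism$enabled) {
    net <- if (nzchar(config$metabolism$network_file))
      load_network(config$metabolism$network_file) else hepg2_network()
    state$metab <- list(network = net,
                        states = matrix(numeric(0), ncol = nrow(net$species),
                                        dimnames = list(NULL,
                                                        net$species$name)))
  }
  state <- vm_build_parent_vessels(state)
  state$network <- compute_blood_flow(state$network, config$vasculature)
  # healthy tissue
  if (config$run$init_tissue == "confluent") {
    dims <- lat$dims
    sites <- as.matrix(expand.grid(x = seq_len(dims[1]),
                                   y = seq_len(dims[2]),
                                   z = seq_len(dims[3])))
    cells <- vm_new_cells("normal", sites, phase = stats::runif(nrow(sites)),
                          ivegf = 0.2, id_start = state$next_cell_id)
    state$next_cell_id <- state$next_cell_id + nrow(cells)
    state$cells <- cells
    state$occupancy[vm_site_index(sites, dims)] <- cells$id
    state <- vm_init_metab_states(state, cells$id, type = "normal")
  }
  state <- vm_solve_all_fields(state)
  if (config$run$burnin_h > 0) {
    n <- ceiling(config$run$burnin_h / config$run$dt_h)
    for (k in seq_len(n)) {
      state$cells <- advance_subcellular(
        state$cells, vm_local_oxygen(state), config$run$dt_h, config$cells)
      state <- ca_step(state, config$run$dt_h)
      state <- vm_solve_all_fields(state)
    }
  }
  if (isTRUE(config$run$implant_tumour)) {
    centre <- ceiling(lat$dims / 2)
    state <- implant_tumour(state, centre, config$run$tumour_radius_sites)
    state <- vm_solve_all_fields(state)
  }
  state
}

# two countercurrent parent vessels along x at quarter/three-quarter y,
# mid z; pressures prescribed at the domain boundary nodes
vm_build_parent_vessels <- function(state) {
  cfg <- state$config
  dims <- state$lattice$dims
  y1 <- max(1L, ceiling(dims[2] / 4)); y2 <- dims[2] - y1 + 1L
  z0 <- max(1L, ceiling(dims[3] / 2))
  pin <- cfg$run$parent_pressure_in; pout <- cfg$run$parent_pressure_out
  net <- state$network
  lay <- function(net, y, z, p_left, p_right) {
    prev <- NULL
    for (x in seq_len(dims[1])) {
      boundary <- x == 1L || x == dims[1]
      bp <- if (x == 1L) p_left else if (x == dims[1]) p_right else NA_real_
      res <- vm_node_at(net, c(x, y, z), boundary = boundary,
                        bc_pressure = bp)
      net <- res$network
      if (!is.null(prev))
        net <- vm_add_segment(net, prev, res$id, cfg$run$parent_radius_um,
                              state$lattice, functional = TRUE)
      prev <- res$id
    }
    net
  }
  net <- lay(net, y1, z0, pin, pout)   # flow in +x
  net <- lay(net, y2, z0, pout, pin)   # flow in -x (countercurrent)
  state$network <- net
  state
}

vm_local_oxygen <- function(state) {
  if (!nrow(state$cells)) return(numeric(0))
  state$fields$oxygen[cbind(state$cells$x, state$cells$y, state$cells$z)]
}

# solve oxygen, VEGF and glucose to quasi-steady state on the current
# tissue/vasculature configuration (warm-started from the previous fields)
vm_solve_all_fields <- function(state) {
  cfg <- state$config$field
  lat <- state$lattice
  tol <- state$config$run$field_tol
  ptol <- state$config$run$field_picard_tol
  state$fields$oxygen <- solve_quasi_steady(
    lat, cfg$oxygen, state$occupancy, state$cells, state$network,
    c_init = state$fields$oxygen, tol = tol, picard_tol = ptol)
  vsrc <- vegf_secretion_source(state$cells, lat, cfg$vegf$secretion_coeff)
  state$fields$vegf <- solve_quasi_steady(
    lat, cfg$vegf, NULL, NULL, state$network, source = vsrc,
    c_init = state$fields$vegf, tol = tol, picard_tol = ptol)
  state$fields$glucose <- solve_quasi_steady(
    lat, cfg$glucose, state$occupancy, state$cells, state$network,
    c_init = state$fields$glucose, tol = tol, picard_tol = ptol)
  state
}

#' Advance the full multiscale model by one time step
#'
#' Phase order within a step: (1) quasi-steady field solves; (2) subcellular
#' ODEs advanced with the local oxygen; (3) stochastic cellular-automaton
#' update; (4) vascular update (sprouting, tip migration, anastomosis, flow
#' solve, remodelling); (5) field re-solve on the updated configuration;
#' (6) per-cell metabolic integration over `dt` with external species
#' clamped to the frozen local glucose and oxygen. The coupling into the
#' metabolic layer is strictly one-way: phase (6) draws no random numbers
#' and writes nothing back, so disabling it leaves the growth trajectory
#' bitwise unchanged for the same seed.
#'
#' @param state a `vm_state`.
#' @param dt time step in hours (default `run.dt_h`).
#' @return the advanced state.
#' @export
sim_step <- function(state, dt = state$config$run$dt_h) {
  if (dt <= 0) stop("dt must be > 0")
  state <- vm_solve_all_fields(state)                          # (1)
  state$cells <- advance_subcellular(                          # (2)
    state$cells, vm_local_oxygen(state), dt, state$config$cells)
  state <- ca_step(state, dt)                                  # (3)
  state <- vm_vascular_step(state, dt)                         # (4)
  state <- vm_solve_all_fields(state)                          # (5)
  state <- vm_metabolism_phase(state, dt)                      # (6)
  state$time_h <- state$time_h + dt
  state$step <- state$step + 1L
  state
}

# frozen-steady-state metabolic phase: externals clamped to the local
# fields; identical (state, environment) pairs share one integration
vm_metabolism_phase <- function(state, dt) {
  mb <- state$metab
  if (is.null(mb) || !nrow(state$cells)) return(state)
  net <- mb$network
  c0 <- stats::setNames(net$species$c0, net$species$name)
  glc <- state$fields$glucose[cbind(state$cells$x, state$cells$y,
                                    state$cells$z)]
  oxy <- vm_local_oxygen(state)
  env_glc <- pmax(glc / c0[["glc_ext"]], 1e-9)
  env_o2 <- pmax(oxy / c0[["o2_ext"]], 1e-9)
  ids <- as.character(state$cells$id)
  tracked <- which(ids %in% rownames(mb$states))
  cache <- new.env(hash = TRUE)
  for (k in tracked) {
    x0 <- mb$states[ids[k], ]
    env <- c(glc_ext = env_glc[k], o2_ext = env_o2[k])
    key <- paste(sprintf("%.17g", c(x0, env)), collapse = ",")
    hit <- cache[[key]]
    if (is.null(hit)) {
      hit <- integrate_metabolism(net, x0, env, dt,
                                  rtol = state$config$metabolism$rtol,
                                  atol = state$config$metabolism$atol)
      cache[[key]] <- hit
    }
    mb$states[ids[k], ] <- hit
  }
  state$metab <- mb
  state
}

# --- per-cell metabolic state bookkeeping (no-ops with metabolism off) ---

vm_init_metab_states <- function(state, ids, type = "cancer") {
  if (is.null(state$metab) || !length(ids)) return(state)
  mode <- state$config$metabolism$cell_types
  if (!identical(mode, "all") && !identical(type, mode)) return(state)
  net <- state$metab$network
  m <- matrix(1, nrow = length(ids), ncol = nrow(net$species),
              dimnames = list(as.character(ids), net$species$name))
  state$metab$states <- rbind(state$metab$states, m)
  state
}

vm_drop_metab_states <- function(state, ids) {
  if (is.null(state$metab)) return(state)
  keep <- !(rownames(state$metab$states) %in% as.character(ids))
  state$metab$states <- state$metab$states[keep, , drop = FALSE]
  state
}

vm_copy_metab_state <- function(state, new_id, mother_id) {
  if (is.null(state$metab)) return(state)
  if (!as.character(mother_id) %in% rownames(state$metab$states))
    return(state)   # mother's type is not tracked by the metabolic layer
  m <- state$metab$states[as.character(mother_id), , drop = FALSE]
  rownames(m) <- as.character(new_id)
  state$metab$states <- rbind(state$metab$states, m)
  state
}

#' Run a full simulation with periodic snapshots
#'
#' Initializes the scenario, advances the model to `run.end_time_h` in
#' steps of `run.dt_h`, and writes a snapshot (cell table, vessel network,
#' field arrays, per-cell metabolite states, JSON manifest with the
#' resolved config and RNG state) every `run.snapshot_every_h` hours,
#' including the initial state.
#'
#' @param config resolved configuration.
#' @param out_dir snapshot output directory (created); NULL disables
#'   snapshot writing.
#' @return list with `state` (final), `snapshots` (paths written) and
#'   `history` (data.frame of per-step cell/vessel counts).
#' @export
run <- function(config = vm_default_config(), out_dir = NULL) {
  state <- initialize_scenario(config)
  snaps <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    snaps <- c(snaps, write_snapshot(state, out_dir))
  }
  dt <- config$run$dt_h
  every <- max(1L, round(config$run$snapshot_every_h / dt))
  n_steps <- floor(config$run$end_time_h / dt + 1e-9)
  hist <- vector("list", n_steps)
  for (k in seq_len(n_steps)) {
    state <- sim_step(state, dt)
    o2c <- vm_local_oxygen(state)
    thr <- state$config$cells$normal$o2_enter_quiescence
    hyp <- o2c < thr
    hist[[k]] <- data.frame(
      step = state$step, time_h = state$time_h,
      n_cells = nrow(state$cells),
      n_cancer = sum(state$cells$type == "cancer"),
      n_quiescent = sum(state$cells$state == "quiescent"),
      n_hypoxic = sum(hyp),
      ivegf_hypoxic = if (any(hyp)) mean(state$cells$ivegf[hyp])
                      else NA_real_,
      ivegf_normoxic = if (any(!hyp)) mean(state$cells$ivegf[!hyp])
                       else NA_real_,
      n_segments = nrow(state$network$segments),
      n_functional = sum(state$network$segments$functional),
      n_tips = nrow(state$network$tips),
      divisions = unname(state$counters["divisions"]),
      anastomoses = unname(state$vcounters["anastomoses"]))
    if (!is.null(out_dir) && (k %% every == 0L || k == n_steps))
      snaps <- c(snaps, write_snapshot(state, out_dir))
  }
  list(state = state, snapshots = snaps,
       history = do.call(rbind, hist))
}

#' @export
print.vm_state <- function(x, ...) {
  cat(sprintf(paste0("<vm_state t = %g h, %d cells (%d cancer), ",
                     "%d vessel segments (%d functional), %d tips>\n"),
              x$time_h, nrow(x$cells), sum(x$cells$type == "cancer"),
              nrow(x$network$segments), sum(x$network$segments$functional),
              nrow(x$network$tips)))
  invisible(x)
}

#' Aggregate per-cell metabolite concentrations onto the lattice
#'
#' Places each cell's absolute intracellular concentration (normalized
#' state times the reference concentration) of one species at its lattice
#' site; empty sites are NA.
#'
#' @param state a `vm_state` with metabolism enabled.
#' @param species species name in the metabolic network.
#' @return a 3D array over the lattice (mmol/l).
#' @export
metabolite_field <- function(state, species) {
  if (is.null(state$metab)) stop("metabolism is disabled in this state")
  net <- state$metab$network
  j <- match(species, net$species$name)
  if (is.na(j)) stop("unknown species: ", species)
  out <- array(NA_real_, dim = state$lattice$dims)
  tracked <- state$cells[as.character(state$cells$id) %in%
                           rownames(state$metab$states), , drop = FALSE]
  if (nrow(tracked)) {
    vals <- state$metab$states[as.character(tracked$id), j] *
      net$species$c0[j]
    out[cbind(tracked$x, tracked$y, tracked$z)] <- vals
  }
  out
}
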