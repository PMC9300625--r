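# All snapshot numerics go through %.17g, which round-trips doubles
# bit-exactly through text.
vm_fmt <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else x
}

vm_write_table <- function(df, path) {
  out <- df
  for (j in seq_along(out)) out[[j]] <- vm_fmt(out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  path
}

#' Write a simulation snapshot
#'
#' Writes one snapshot directory `step_NNNNNN/` containing plain-text
#' artifacts: `cells.csv` (step, time_h, x, y, z, cell_type, state, phase,
#' p53, ivegf), `nodes.csv`/`segments.csv`/`tips.csv` (vessel network
#' edge-list with radii, flows, pressures and functional flags),
#' `fields.csv` (long format x, y, z, species, value), `metab.csv`
#' (per-cell normalized metabolite states) and `manifest.json` (resolved
#' config, clock, counters and the RNG state needed for bit-exact restart).
#' Doubles are written with 17 significant digits, so a write/read round
#' trip restores the state bit-exactly.
#'
#' @param state a `vm_state`.
#' @param dir output directory (created if needed).
#' @param step step number used in the directory name (default the state's
#'   step counter).
#' @return the snapshot directory path, invisibly.
#' @export
write_snapshot <- function(state, dir, step = state$step) {
  sd <- file.path(dir, sprintf("step_%06d", step))
  dir.create(sd, recursive = TRUE, showWarnings = FALSE)
  cells <- state$cells
  ct <- data.frame(step = rep(step, nrow(cells)),
                   time_h = rep(state$time_h, nrow(cells)),
                   id = cells$id, x = cells$x, y = cells$y, z = cells$z,
                   cell_type = cells$type, state = cells$state,
                   phase = cells$phase, p53 = cells$p53,
                   ivegf = cells$ivegf, quiesc_h = cells$quiesc_h)
  vm_write_table(ct, file.path(sd, "cells.csv"))
  vm_write_table(state$network$nodes, file.path(sd, "nodes.csv"))
  vm_write_table(state$network$segments, file.path(sd, "segments.csv"))
  vm_write_table(state$network$tips, file.path(sd, "tips.csv"))
  dims <- state$lattice$dims
  grid <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                      z = seq_len(dims[3]))
  fl <- do.call(rbind, lapply(names(state$fields), function(sp)
    data.frame(grid, species = sp, value = as.vector(state$fields[[sp]]))))
  vm_write_table(fl, file.path(sd, "fields.csv"))
  if (!is.null(state$metab) && nrow(state$metab$states)) {
    ms <- state$metab$states
    md <- data.frame(cell_id = rep(rownames(ms), ncol(ms)),
                     species = rep(colnames(ms), each = nrow(ms)),
                     value = as.vector(ms))
    vm_write_table(md, file.path(sd, "metab.csv"))
  }
  rng <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("vascmet")),
    step = step, time_h = vm_fmt(state$time_h),
    next_cell_id = state$next_cell_id,
    next_node_id = state$network$next_node_id,
    next_seg_id = state$network$next_seg_id,
    next_tip_id = state$network$next_tip_id,
    n_cells = nrow(cells), rng_state = rng,
    config = rapply(state$config, vm_fmt, how = "replace"),
    config_hash = vm_config_hash(state$config))
  jsonlite::write_json(manifest, file.path(sd, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(sd)
}

vm_config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(rapply(config, vm_fmt, how = "replace"),
                              auto_unbox = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Read a snapshot back into a simulation state
#'
#' Inverse of [write_snapshot()]: restores the state (including the RNG
#' stream) bit-exactly, so a run resumed from a snapshot reproduces the
#' uninterrupted run.
#'
#' @param snapshot_dir a `step_NNNNNN` directory written by
#'   [write_snapshot()].
#' @return a `vm_state`.
#' @export
read_snapshot <- function(snapshot_dir) {
  man <- jsonlite::read_json(file.path(snapshot_dir, "manifest.json"),
                             simplifyVector = TRUE)
  cfg <- validate_config(vm_merge_config(vm_default_config(), man$config))
  lat <- vm_lattice(cfg$lattice$dims, cfg$lattice$spacing_um)
  rd <- function(f) utils::read.csv(file.path(snapshot_dir, f),
                                    stringsAsFactors = FALSE)
  ct <- rd("cells.csv")
  cells <- data.frame(id = as.integer(ct$id), type = ct$cell_type,
                      x = as.integer(ct$x), y = as.integer(ct$y),
                      z = as.integer(ct$z), phase = as.numeric(ct$phase),
                      state = ct$state, p53 = as.numeric(ct$p53),
                      ivegf = as.numeric(ct$ivegf),
                      quiesc_h = as.numeric(ct$quiesc_h),
                      stringsAsFactors = FALSE)
  occ <- vm_empty_occupancy(lat)
  if (nrow(cells))
    occ[cbind(cells$x, cells$y, cells$z)] <- cells$id
  net <- vm_empty_network(lat)
  nodes <- rd("nodes.csv")
  net$nodes <- data.frame(id = as.integer(nodes$id),
                          x = as.integer(nodes$x), y = as.integer(nodes$y),
                          z = as.integer(nodes$z),
                          pressure = as.numeric(nodes$pressure),
                          boundary = as.logical(nodes$boundary),
                          bc_pressure = as.numeric(nodes$bc_pressure),
                          stringsAsFactors = FALSE)
  if (nrow(net$nodes))
    net$nodemap[cbind(net$nodes$x, net$nodes$y, net$nodes$z)] <- net$nodes$id
  segs <- rd("segments.csv")
  net$segments <- data.frame(id = as.integer(segs$id),
                             from = as.integer(segs$from),
                             to = as.integer(segs$to),
                             radius_um = as.numeric(segs$radius_um),
                             length_um = as.numeric(segs$length_um),
                             flow = as.numeric(segs$flow),
                             functional = as.logical(segs$functional),
                             zero_flow_h = as.numeric(segs$zero_flow_h),
                             owner_tip = as.integer(segs$owner_tip),
                             stringsAsFactors = FALSE)
  tips <- rd("tips.csv")
  net$tips <- data.frame(id = as.integer(tips$id),
                         node = as.integer(tips$node),
                         x = as.integer(tips$x), y = as.integer(tips$y),
                         z = as.integer(tips$z),
                         origin_node = as.integer(tips$origin_node),
                         prev_x = as.integer(tips$prev_x),
                         prev_y = as.integer(tips$prev_y),
                         prev_z = as.integer(tips$prev_z),
                         trail_len = as.integer(tips$trail_len),
                         age_h = as.numeric(tips$age_h),
                         stringsAsFactors = FALSE)
  net$next_node_id <- as.integer(man$next_node_id)
  net$next_seg_id <- as.integer(man$next_seg_id)
  net$next_tip_id <- as.integer(man$next_tip_id)
  fl <- rd("fields.csv")
  fields <- lapply(split(fl, fl$species), function(d) {
    arr <- array(0, dim = lat$dims)
    arr[cbind(d$x, d$y, d$z)] <- as.numeric(d$value)
    arr
  })
  fields <- fields[intersect(c("oxygen", "vegf", "glucose"), names(fields))]
  metab <- NULL
  if (cfg$metabolism$enabled) {
    mnet <- if (nzchar(cfg$metabolism$network_file))
      load_network(cfg$metabolism$network_file) else hepg2_network()
    states <- matrix(numeric(0), ncol = nrow(mnet$species),
                     dimnames = list(NULL, mnet$species$name))
    mf <- file.path(snapshot_dir, "metab.csv")
    if (file.exists(mf)) {
      md <- utils::read.csv(mf, stringsAsFactors = FALSE)
      ids <- unique(md$cell_id)
      states <- matrix(NA_real_, nrow = length(ids),
                       ncol = nrow(mnet$species),
                       dimnames = list(as.character(ids),
                                       mnet$species$name))
      states[cbind(as.character(md$cell_id), md$species)] <-
        as.numeric(md$value)
    }
    metab <- list(network = mnet, states = states)
  }
  if (!is.null(man$rng_state))
    assign(".Random.seed", as.integer(man$rng_state), envir = globalenv())
  structure(list(lattice = lat, occupancy = occ, cells = cells,
                 network = net, fields = fields, metab = metab,
                 time_h = as.numeric(man$time_h),
                 step = as.integer(man$step),
                 next_cell_id = as.integer(man$next_cell_id),
                 config = cfg, counters = NULL, vcounters = NULL),
            class = "vm_state")
}

#' Resume a run from its latest snapshot
#'
#' @param out_dir directory containing `step_NNNNNN` snapshots.
#' @param end_time_h new end time (default: the configured one).
#' @return as [run()].
#' @export
resume <- function(out_dir, end_time_h = NULL) {
  snaps <- sort(list.dirs(out_dir, recursive = FALSE))
  snaps <- snaps[grepl("step_[0-9]+$", snaps)]
  if (!length(snaps)) stop("no snapshots under ", out_dir)
  state <- read_snapshot(snaps[length(snaps)])
  cfg <- state$config
  if (!is.null(end_time_h)) cfg$run$end_time_h <- end_time_h
  dt <- cfg$run$dt_h
  every <- max(1L, round(cfg$run$snapshot_every_h / dt))
  n_steps <- floor((cfg$run$end_time_h - state$time_h) / dt + 1e-9)
  written <- character(0)
  for (k in seq_len(n_steps)) {
    state <- sim_step(state, dt)
    if (k %% every == 0L || k == n_steps)
      written <- c(written, write_snapshot(state, out_dir))
  }
  list(state = state, snapshots = written, history = NULL)
}

#' Export an axis-aligned cross-section of a field
#'
#' Extracts one slice (default: the equatorial z slice) of an extracellular
#' field or, via [metabolite_field()], of an intracellular metabolite, as a
#' data.frame suitable for CSV export or plotting.
#'
#' @param state a `vm_state`.
#' @param species field name (`"glucose"`, `"oxygen"`, `"vegf"`) or a
#'   metabolic species name.
#' @param axis slicing axis, `"x"`, `"y"` or `"z"` (default).
#' @param index slice index (default: the middle).
#' @param file optional CSV path to write.
#' @return data.frame with the two in-plane coordinates and `value`.
#' @export
export_slice <- function(state, species, axis = "z", index = NULL,
                         file = NULL) {
  arr <- if (species %in% names(state$fields)) state$fields[[species]]
         else metabolite_field(state, species)
  k <- match(axis, c("x", "y", "z"))
  if (is.na(k)) stop("axis must be 'x', 'y' or 'z'")
  if (is.null(index)) index <- ceiling(dim(arr)[k] / 2)
  sl <- switch(axis, x = arr[index, , ], y = arr[, index, ],
               z = arr[, , index])
  d <- dim(sl)
  ax <- setdiff(c("x", "y", "z"), axis)
  out <- data.frame(rep(seq_len(d[1]), d[2]),
                    rep(seq_len(d[2]), each = d[1]),
                    value = as.vector(sl))
  names(out)[1:2] <- ax
  out$species <- species
  if (!is.null(file)) vm_write_table(out, file)
  out
}
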