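# Small scenario builders shared across tests. Everything is generated in
# code at test time; no stored fixtures.

# a tiny scenario with parent vessels, solved fields and configurable tissue
tiny_state <- function(dims = c(10, 10, 10), seed = 1,
                       init_tissue = "empty", implant = FALSE,
                       metabolism = FALSE, tweak = identity) {
  cfg <- vm_default_config()
  cfg$lattice$dims <- dims
  cfg$run$seed <- seed
  cfg$run$init_tissue <- init_tissue
  cfg$run$implant_tumour <- implant
  cfg$metabolism$enabled <- metabolism
  cfg <- tweak(cfg)
  initialize_scenario(cfg)
}

# place a single cell into a state by hand
place_cell <- function(state, xyz, type = "cancer", phase = 0,
                       cstate = "proliferating", p53 = 1, ivegf = 0) {
  nc <- data.frame(id = state$next_cell_id, type = type,
                   x = xyz[1], y = xyz[2], z = xyz[3], phase = phase,
                   state = cstate, p53 = p53, ivegf = ivegf, quiesc_h = 0,
                   stringsAsFactors = FALSE)
  state$cells <- rbind(state$cells, nc)
  rownames(state$cells) <- NULL
  state$occupancy[xyz[1], xyz[2], xyz[3]] <- nc$id
  state$next_cell_id <- state$next_cell_id + 1L
  state
}

# force a uniform oxygen level (for CA tests decoupled from the solver)
with_uniform_oxygen <- function(state, value) {
  state$fields$oxygen <- array(value, dim = state$lattice$dims)
  state
}

# cell-table comparison helper that ignores row order
sorted_cells <- function(cells) {
  cells[order(cells$id), , drop = FALSE]
}

# a hand-built two-node, one-segment network with prescribed pressures
single_vessel_network <- function(lattice, radius_um, p_in, p_out) {
  net <- vm_empty_network(lattice)
  res <- vm_node_at_test(net, c(1, 1, 1), TRUE, p_in); net <- res$network
  a <- res$id
  res <- vm_node_at_test(net, c(lattice$dims[1], 1, 1), TRUE, p_out)
  net <- res$network
  vascmet:::vm_add_segment(net, a, res$id, radius_um, lattice,
                           functional = TRUE)
}

vm_node_at_test <- function(net, xyz, boundary = FALSE, bc = NA_real_) {
  vascmet:::vm_node_at(net, xyz, boundary = boundary, bc_pressure = bc)
}
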