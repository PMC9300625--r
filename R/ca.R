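#' One stochastic cellular-automaton step
#'
#' Updates every cell once, in an order reshuffled with the current RNG
#' stream. For each cell, in sequence: (a) division — a proliferating cell
#' with phase >= 1 divides into a uniformly chosen empty site of its
#' 26-neighbourhood, both daughters restarting at phase 0; with no empty
#' neighbour the division is deferred (contact inhibition); (b) quiescence —
#' cells below the enter-quiescence oxygen threshold become quiescent,
#' quiescent cells above the leave threshold resume proliferation, and
#' quiescent cells exceeding their maximum quiescence time are removed;
#' (c) apoptosis — cells whose p53 exceeds the local-density-dependent
#' threshold are removed; (d) movement — surviving motile cells hop to a
#' uniformly chosen empty neighbour with probability `movement_rate * dt`.
#'
#' The site-occupancy invariant (<= 1 cell per site) is preserved; the
#' per-step event counts are attached as `state$counters`.
#'
#' @param state simulation state.
#' @param dt time step in hours (> 0).
#' @return the updated simulation state.
#' @export
ca_step <- function(state, dt) {
  if (dt <= 0) stop("dt must be > 0")
  dims <- state$lattice$dims
  occ <- state$occupancy
  params <- state$config$cells
  counters <- c(divisions = 0L, deferred = 0L, deaths_p53 = 0L,
                deaths_quiescence = 0L, deaths_background = 0L, moves = 0L)
  n0 <- nrow(state$cells)
  if (n0 == 0L) { state$counters <- counters; return(state) }
  if (!identical(sort(state$cells$id), sort(occ[occ > 0L])))
    stop("inconsistent occupancy map")
  # column vectors with headroom for newborns (at most one per cell)
  cap <- 2L * n0
  grow <- function(v, fill) { length(v) <- cap; v }
  id <- grow(state$cells$id); type <- grow(state$cells$type)
  cx <- grow(state$cells$x); cy <- grow(state$cells$y)
  cz <- grow(state$cells$z)
  phase <- grow(state$cells$phase); cstate <- grow(state$cells$state)
  p53 <- grow(state$cells$p53); ivegf <- grow(state$cells$ivegf)
  quiesc <- grow(state$cells$quiesc_h)
  parent <- integer(cap)
  alive <- c(rep(TRUE, n0), rep(FALSE, cap - n0))
  n <- n0
  # row index by cell id (ids are dense enough to index directly)
  idmap <- integer(state$next_cell_id + n0)
  idmap[id[seq_len(n0)]] <- seq_len(n0)
  next_id <- state$next_cell_id
  offsets <- vm_neighbour_offsets()
  oxy <- state$fields$oxygen
  order_ids <- sample(id[seq_len(n0)])
  for (cid in order_ids) {
    i <- idmap[cid]
    if (i == 0L || !alive[i]) next      # removed earlier this step
    p <- params[[type[i]]]
    pos <- c(cx[i], cy[i], cz[i])
    o2 <- oxy[pos[1], pos[2], pos[3]]
    nb <- vm_neighbours(pos, dims, offsets)
    nb_idx <- vm_site_index(nb, dims)
    free <- which(occ[nb_idx] == 0L)
    # (a) division
    if (cstate[i] == "proliferating" && phase[i] >= 1) {
      if (length(free)) {
        j <- free[sample.int(length(free), 1L)]
        site <- nb[j, ]
        n <- n + 1L
        if (n > cap) stop("cell buffer overflow")   # cannot happen
        id[n] <- next_id; type[n] <- type[i]
        cx[n] <- site[1]; cy[n] <- site[2]; cz[n] <- site[3]
        phase[n] <- 0; cstate[n] <- "proliferating"
        p53[n] <- p53[i]; ivegf[n] <- ivegf[i]; quiesc[n] <- 0
        parent[n] <- cid
        alive[n] <- TRUE
        if (next_id > length(idmap)) length(idmap) <- 2L * next_id
        idmap[next_id] <- n
        occ[site[1], site[2], site[3]] <- next_id
        next_id <- next_id + 1L
        phase[i] <- 0
        counters["divisions"] <- counters["divisions"] + 1L
      } else counters["deferred"] <- counters["deferred"] + 1L
    }
    # (b) quiescence
    if (cstate[i] == "proliferating" && o2 < p$o2_enter_quiescence) {
      cstate[i] <- "quiescent"; quiesc[i] <- 0
    } else if (cstate[i] == "quiescent") {
      if (o2 > p$o2_leave_quiescence) {
        cstate[i] <- "proliferating"; quiesc[i] <- 0
      } else {
        quiesc[i] <- quiesc[i] + dt
        if (quiesc[i] > p$max_quiescence_h) {
          occ[pos[1], pos[2], pos[3]] <- 0L
          alive[i] <- FALSE
          counters["deaths_quiescence"] <- counters["deaths_quiescence"] + 1L
          next
        }
      }
    }
    # (c) p53-mediated apoptosis, threshold set by local cell density
    dens <- sum(occ[nb_idx] > 0L) / length(nb_idx)
    thr <- if (dens < p$density_thresh) p$p53_thresh_low else p$p53_thresh_high
    if (p53[i] > thr) {
      occ[pos[1], pos[2], pos[3]] <- 0L
      alive[i] <- FALSE
      counters["deaths_p53"] <- counters["deaths_p53"] + 1L
      next
    }
    # (c') homeostatic background turnover (normal tissue renewal)
    if (p$base_death_rate > 0 &&
        stats::runif(1) < p$base_death_rate * dt) {
      occ[pos[1], pos[2], pos[3]] <- 0L
      alive[i] <- FALSE
      counters["deaths_background"] <- counters["deaths_background"] + 1L
      next
    }
    # (d) random-walk movement
    if (p$movement_rate > 0 && stats::runif(1) < p$movement_rate * dt) {
      free <- which(occ[nb_idx] == 0L)   # refresh: a daughter may sit there
      if (length(free)) {
        j <- free[sample.int(length(free), 1L)]
        site <- nb[j, ]
        occ[pos[1], pos[2], pos[3]] <- 0L
        occ[site[1], site[2], site[3]] <- cid
        cx[i] <- site[1]; cy[i] <- site[2]; cz[i] <- site[3]
        counters["moves"] <- counters["moves"] + 1L
      }
    }
  }
  keep <- which(alive[seq_len(n)])
  newborn_rows <- keep[keep > n0]
  removed <- state$cells$id[!alive[seq_len(n0)]]
  state$cells <- data.frame(
    id = id[keep], type = type[keep], x = cx[keep], y = cy[keep],
    z = cz[keep], phase = phase[keep], state = cstate[keep],
    p53 = p53[keep], ivegf = ivegf[keep], quiesc_h = quiesc[keep],
    stringsAsFactors = FALSE)
  state$occupancy <- occ
  state$counters <- counters
  state$next_cell_id <- next_id
  if (length(removed)) state <- vm_drop_metab_states(state, removed)
  for (r in newborn_rows)
    state <- vm_copy_metab_state(state, id[r], parent[r])
  state
}
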