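#' Default vascular parameters
#'
#' @return named list:
#' \describe{
#'   \item{dx_max_um}{maximum anastomosis distance (um, default 100).}
#'   \item{sprout_p_max, vegf_half, vegf_min}{sprouting probability law
#'     p = sprout_p_max * W/(W + vegf_half) * dt per functional node, with
#'     W = max(V - vegf_min, 0): VEGF must exceed the activation threshold
#'     vegf_min (set above the normoxic-tissue baseline) before a node can
#'     sprout, and saturates with half-constant vegf_half above it.}
#'   \item{tip_bias}{chemotactic bias weight (um per VEGF unit) of the
#'     biased random walk; step weights are
#'     exp(tip_bias * directional VEGF gradient).}
#'   \item{tip_speed_sites_h}{sprout-tip migration speed in sites per hour.}
#'   \item{min_trail_sites}{minimum trail length before a tip may attempt
#'     anastomosis.}
#'   \item{max_sprout_age_h}{tips older than this regress (trail removed).}
#'   \item{viscosity}{blood viscosity in mmHg h (plasma ~ 7.3e-9,
#'     i.e. 3.5 cP).}
#'   \item{shear_ref, remodel_tau_h}{wall-shear set point (mmHg) and
#'     remodelling time constant (h).}
#'   \item{r_min_um, r_max_um, r_sprout_um}{radius bounds and the radius of
#'     newly laid sprout segments (um).}
#'   \item{q_func_threshold}{minimum |flow| (um^3/h) for a segment to count
#'     as functional.}
#'   \item{prune_after_h}{segments with no flow for longer than this are
#'     removed.}
#'   \item{flow_tol, flow_max_sweeps, flow_omega}{pressure-solve relative
#'     residual tolerance, sweep budget and SOR relaxation factor.}
#' }
#' @export
vm_default_vascular_params <- function() {
  list(dx_max_um = 100, sprout_p_max = 0.5, vegf_half = 2, vegf_min = 0.5,
       tip_bias = 150, tip_speed_sites_h = 2, min_trail_sites = 3,
       max_sprout_age_h = 48, viscosity = 7.29e-9,
       shear_ref = 0.04, remodel_tau_h = 10,
       r_min_um = 2, r_max_um = 12, r_sprout_um = 3,
       q_func_threshold = 1e5, prune_after_h = 48,
       flow_tol = 5e-13, flow_max_sweeps = 5e5, flow_omega = 1.8)
}

#' Create an empty vessel network bound to a lattice
#'
#' @param lattice a [vm_lattice()].
#' @return a network list (nodes, segments, tips, site-to-node map).
#' @export
vm_empty_network <- function(lattice) {
  list(nodes = data.frame(id = integer(), x = integer(), y = integer(),
                          z = integer(), pressure = numeric(),
                          boundary = logical(), bc_pressure = numeric(),
                          stringsAsFactors = FALSE),
       segments = data.frame(id = integer(), from = integer(), to = integer(),
                             radius_um = numeric(), length_um = numeric(),
                             flow = numeric(), functional = logical(),
                             zero_flow_h = numeric(), owner_tip = integer(),
                             stringsAsFactors = FALSE),
       tips = data.frame(id = integer(), node = integer(), x = integer(),
                         y = integer(), z = integer(), origin_node = integer(),
                         prev_x = integer(), prev_y = integer(),
                         prev_z = integer(), trail_len = integer(),
                         age_h = numeric(), stringsAsFactors = FALSE),
       nodemap = array(0L, dim = lattice$dims),
       next_node_id = 1L, next_seg_id = 1L, next_tip_id = 1L)
}

#' Get or create a vessel node at a lattice site
#'
#' @param network a vessel network.
#' @param xyz integer site triple.
#' @param boundary mark as boundary node with prescribed pressure.
#' @param bc_pressure prescribed pressure for boundary nodes.
#' @return list with the updated `network` and the node `id`.
#' @export
vm_node_at <- function(network, xyz, boundary = FALSE, bc_pressure = NA_real_) {
  xyz <- as.integer(xyz)
  id <- network$nodemap[xyz[1], xyz[2], xyz[3]]
  if (id > 0L) {
    if (boundary) {
      i <- match(id, network$nodes$id)
      network$nodes$boundary[i] <- TRUE
      network$nodes$bc_pressure[i] <- bc_pressure
    }
    return(list(network = network, id = id))
  }
  id <- network$next_node_id
  network$next_node_id <- id + 1L
  network$nodes <- rbind(network$nodes, data.frame(
    id = id, x = xyz[1], y = xyz[2], z = xyz[3],
    pressure = if (boundary) bc_pressure else 0,
    boundary = boundary, bc_pressure = bc_pressure,
    stringsAsFactors = FALSE))
  rownames(network$nodes) <- NULL
  network$nodemap[xyz[1], xyz[2], xyz[3]] <- id
  list(network = network, id = id)
}

#' Add a vessel segment between two nodes
#'
#' Computes the segment length from the lattice distance of its nodes;
#' duplicate segments are ignored.
#'
#' @param network a vessel network.
#' @param from,to node ids.
#' @param radius_um segment radius (um).
#' @param lattice a [vm_lattice()].
#' @param owner_tip sprout-tip id while the segment is a private trail.
#' @param functional initial functional flag.
#' @return the updated network.
#' @export
vm_add_segment <- function(network, from, to, radius_um, lattice,
                           owner_tip = 0L, functional = FALSE) {
  if (from == to) return(network)
  has <- (network$segments$from == from & network$segments$to == to) |
         (network$segments$from == to & network$segments$to == from)
  if (any(has)) return(network)
  a <- network$nodes[match(from, network$nodes$id), ]
  b <- network$nodes[match(to, network$nodes$id), ]
  len <- sqrt(sum((c(a$x, a$y, a$z) - c(b$x, b$y, b$z))^2)) *
    lattice$spacing_um
  network$segments <- rbind(network$segments, data.frame(
    id = network$next_seg_id, from = from, to = to, radius_um = radius_um,
    length_um = len, flow = 0, functional = functional, zero_flow_h = 0,
    owner_tip = as.integer(owner_tip), stringsAsFactors = FALSE))
  rownames(network$segments) <- NULL
  network$next_seg_id <- network$next_seg_id + 1L
  network
}

#' Distance-dependent anastomosis probability
#'
#' The probability that a migrating sprout tip fuses with a target (another
#' tip or a functional vessel node) at separation `distance`:
#' `1 - distance/dx_max` for `distance < dx_max`, 0 otherwise. Piecewise
#' linear, continuous, non-increasing, with range `[0, 1]`.
#'
#' @param distance separation in micrometres (>= 0, vectorized).
#' @param dx_max_um maximum anastomosis distance in micrometres (default
#'   100).
#' @return probability in `[0, 1]`.
#' @examples
#' anastomosis_probability(c(0, 50, 100, 200))  # 1, 0.5, 0, 0
#' @export
anastomosis_probability <- function(distance, dx_max_um = 100) {
  if (any(distance < 0)) stop("distance must be >= 0")
  if (dx_max_um <= 0) stop("dx_max_um must be > 0")
  ifelse(distance < dx_max_um, 1 - distance / dx_max_um, 0)
}

# deterministic monotone lattice path between two sites (26-connected),
# excluding the start site, including the end site
vm_lattice_path <- function(from, to) {
  d <- to - from
  n <- max(abs(d))
  if (n == 0L) return(matrix(integer(0), ncol = 3))
  t(vapply(seq_len(n), function(s) as.integer(floor(from + d * s / n + 0.5)),
           integer(3)))
}

#' Attempt anastomosis for one sprout tip
#'
#' Candidate targets are all other active tips and all functional-vessel
#' nodes within `dx_max_um` of the tip (its own trail and origin node
#' excluded). Candidates are evaluated nearest first (ties broken by stable
#' id); for each, a uniform random number is drawn and compared with
#' [anastomosis_probability()]. On the first success the tip trail is
#' connected to the target by a deterministic monotone lattice path, the tip
#' (and a partner tip) is retired and its trail becomes candidate-functional.
#'
#' @param state simulation state.
#' @param tip_id id of an active tip.
#' @return list(state, event) where event is `NULL` if no anastomosis
#'   happened, otherwise a list with `target_kind` ("tip" or "node"),
#'   `distance_um` and `probability`.
#' @export
attempt_anastomosis <- function(state, tip_id) {
  net <- state$network
  par <- state$config$vasculature
  lat <- state$lattice
  ti <- match(tip_id, net$tips$id)
  if (is.na(ti)) stop("tip not active: ", tip_id)
  tip <- net$tips[ti, ]
  if (tip$trail_len < par$min_trail_sites)
    return(list(state = state, event = NULL))
  tp <- c(tip$x, tip$y, tip$z)
  h <- lat$spacing_um
  # own trail nodes: nodes of segments owned by this tip, plus origin
  own_segs <- net$segments[net$segments$owner_tip == tip_id, ]
  own_nodes <- unique(c(own_segs$from, own_segs$to, tip$origin_node, tip$node))
  # functional nodes = endpoints of functional segments
  fsegs <- net$segments[net$segments$functional, ]
  fnodes <- unique(c(fsegs$from, fsegs$to))
  fnodes <- setdiff(fnodes, own_nodes)
  cand <- data.frame(kind = character(), id = integer(), x = integer(),
                     y = integer(), z = integer(), stringsAsFactors = FALSE)
  if (length(fnodes)) {
    nn <- net$nodes[match(sort(fnodes), net$nodes$id), ]
    cand <- rbind(cand, data.frame(kind = "node", id = nn$id, x = nn$x,
                                   y = nn$y, z = nn$z,
                                   stringsAsFactors = FALSE))
  }
  others <- net$tips[net$tips$id != tip_id, ]
  if (nrow(others))
    cand <- rbind(cand, data.frame(kind = "tip", id = others$id, x = others$x,
                                   y = others$y, z = others$z,
                                   stringsAsFactors = FALSE))
  if (!nrow(cand)) return(list(state = state, event = NULL))
  dist <- sqrt((cand$x - tp[1])^2 + (cand$y - tp[2])^2 +
               (cand$z - tp[3])^2) * h
  keep <- dist < par$dx_max_um
  cand <- cand[keep, , drop = FALSE]; dist <- dist[keep]
  if (!nrow(cand)) return(list(state = state, event = NULL))
  ord <- order(dist, cand$kind, cand$id)   # nearest first, stable tie-break
  cand <- cand[ord, , drop = FALSE]; dist <- dist[ord]
  for (k in seq_len(nrow(cand))) {
    p <- anastomosis_probability(dist[k], par$dx_max_um)
    xi <- stats::runif(1)
    if (xi <= p) {
      target_site <- c(cand$x[k], cand$y[k], cand$z[k])
      path <- vm_lattice_path(tp, target_site)
      prev <- tip$node
      if (nrow(path)) for (s in seq_len(nrow(path))) {
        res <- vm_node_at(net, path[s, ])
        net <- res$network
        net <- vm_add_segment(net, prev, res$id, par$r_sprout_um, lat)
        prev <- res$id
      }
      # trails of the tip (and partner) become permanent
      net$segments$owner_tip[net$segments$owner_tip == tip_id] <- 0L
      net$tips <- net$tips[net$tips$id != tip_id, , drop = FALSE]
      if (cand$kind[k] == "tip") {
        pid <- cand$id[k]
        net$segments$owner_tip[net$segments$owner_tip == pid] <- 0L
        net$tips <- net$tips[net$tips$id != pid, , drop = FALSE]
      }
      rownames(net$tips) <- NULL
      state$network <- net
      return(list(state = state,
                  event = list(target_kind = cand$kind[k],
                               distance_um = dist[k], probability = p)))
    }
  }
  list(state = state, event = NULL)
}

#' Spawn new sprout tips from functional vessel nodes
#'
#' Each non-boundary functional-vessel node without an active tip spawns one
#' with probability `sprout_p_max * W/(W + vegf_half) * dt`, where
#' `W = max(V - vegf_min, 0)` and `V` is the local VEGF concentration: the
#' sprouting probability increases with local VEGF once it exceeds the
#' activation threshold.
#'
#' @param state simulation state.
#' @param dt time step in hours.
#' @return list(state, n_spawned).
#' @export
sprout_initiation <- function(state, dt) {
  net <- state$network
  par <- state$config$vasculature
  fsegs <- net$segments[net$segments$functional, ]
  fnodes <- sort(unique(c(fsegs$from, fsegs$to)))
  if (!length(fnodes)) return(list(state = state, n_spawned = 0L))
  nn <- net$nodes[match(fnodes, net$nodes$id), ]
  busy <- unique(c(net$tips$origin_node, net$tips$node))
  ok <- !nn$boundary & !(nn$id %in% busy)
  nn <- nn[ok, , drop = FALSE]
  if (!nrow(nn)) return(list(state = state, n_spawned = 0L))
  V <- state$fields$vegf[cbind(nn$x, nn$y, nn$z)]
  W <- pmax(V - par$vegf_min, 0)
  p <- pmin(1, par$sprout_p_max * W / (W + par$vegf_half) * dt)
  hit <- stats::runif(nrow(nn)) < p
  n <- sum(hit)
  if (n) {
    nn <- nn[hit, , drop = FALSE]
    tips <- data.frame(id = seq.int(net$next_tip_id, length.out = n),
                       node = nn$id, x = nn$x, y = nn$y, z = nn$z,
                       origin_node = nn$id, prev_x = NA_integer_,
                       prev_y = NA_integer_, prev_z = NA_integer_,
                       trail_len = 0L, age_h = 0, stringsAsFactors = FALSE)
    net$next_tip_id <- net$next_tip_id + n
    net$tips <- rbind(net$tips, tips)
    rownames(net$tips) <- NULL
    state$network <- net
  }
  list(state = state, n_spawned = as.integer(n))
}

#' One biased-random-walk migration step of a sprout tip
#'
#' The tip hops to one of its lattice neighbours with probability
#' proportional to `exp(tip_bias * (V_nb - V_here)/d_nb)` (the directional
#' VEGF gradient component), never re-entering its immediately previous
#' site, and lays down a vessel segment behind it.
#'
#' @param state simulation state.
#' @param tip_id id of an active tip.
#' @return the updated simulation state (tip stalls if fully blocked).
#' @export
tip_migration_step <- function(state, tip_id) {
  net <- state$network
  par <- state$config$vasculature
  lat <- state$lattice
  ti <- match(tip_id, net$tips$id)
  if (is.na(ti)) stop("tip not active: ", tip_id)
  tip <- net$tips[ti, ]
  pos <- c(tip$x, tip$y, tip$z)
  nb <- vm_neighbours(pos, lat$dims)
  if (!is.na(tip$prev_x)) {
    keep <- !(nb[, 1] == tip$prev_x & nb[, 2] == tip$prev_y &
              nb[, 3] == tip$prev_z)
    nb <- nb[keep, , drop = FALSE]
  }
  if (!nrow(nb)) return(state)     # fully blocked: stall
  V <- state$fields$vegf
  v0 <- V[pos[1], pos[2], pos[3]]
  dvec <- sqrt(rowSums(sweep(nb, 2L, pos, "-")^2)) * lat$spacing_um
  grad <- (V[nb] - v0) / dvec
  # numerically safe softmax over admissible neighbours
  w <- exp(par$tip_bias * grad - max(par$tip_bias * grad))
  pick <- sample.int(nrow(nb), 1L, prob = w)
  new_site <- nb[pick, ]
  res <- vm_node_at(net, new_site)
  net <- res$network
  net <- vm_add_segment(net, tip$node, res$id, par$r_sprout_um, lat,
                        owner_tip = tip_id)
  ti <- match(tip_id, net$tips$id)
  net$tips$prev_x[ti] <- pos[1]; net$tips$prev_y[ti] <- pos[2]
  net$tips$prev_z[ti] <- pos[3]
  net$tips$node[ti] <- res$id
  net$tips$x[ti] <- new_site[1]; net$tips$y[ti] <- new_site[2]
  net$tips$z[ti] <- new_site[3]
  net$tips$trail_len[ti] <- net$tips$trail_len[ti] + 1L
  state$network <- net
  state
}

#' Poiseuille blood flow on the vessel network
#'
#' Segment conductances are `g = pi R^4 / (8 mu L)`; interior node pressures
#' satisfy Kirchhoff flow conservation and are solved by chromatic
#' successive-displacement (multicolour SOR) iteration to the configured
#' relative residual tolerance; segment flows are `Q = g (p_from - p_to)`.
#' The functional flag is refreshed (`|Q| > q_func_threshold`); nodes not
#' connected to any boundary node carry zero flow.
#'
#' @param network vessel network (as in `state$network`).
#' @param params vascular parameters ([vm_default_vascular_params()]).
#' @return the network with updated pressures, flows and functional flags.
#' @export
compute_blood_flow <- function(network, params = vm_default_vascular_params()) {
  nodes <- network$nodes; segs <- network$segments
  if (!any(nodes$boundary)) stop("no boundary nodes with prescribed pressure")
  if (!nrow(segs)) return(network)
  n <- nrow(nodes)
  idx <- function(id) match(id, nodes$id)
  i <- idx(segs$from); j <- idx(segs$to)
  g <- pi * segs$radius_um^4 / (8 * params$viscosity * segs$length_um)
  G <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(g, g),
                            dims = c(n, n))
  D <- Matrix::rowSums(G)
  p <- nodes$pressure
  p[nodes$boundary] <- nodes$bc_pressure[nodes$boundary]
  # restrict the solve to nodes connected to a boundary node
  gr <- igraph::graph_from_data_frame(
    data.frame(from = i, to = j), directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(gr)$membership
  bcomp <- unique(comp[which(nodes$boundary)])
  solvable <- comp %in% bcomp
  free <- which(!nodes$boundary & solvable & D > 0)
  if (length(free)) {
    # greedy colouring so that same-colour nodes are never adjacent: their
    # SOR updates can be applied simultaneously (still Gauss-Seidel-type)
    col <- as.integer(igraph::greedy_vertex_coloring(gr))
    classes <- split(free, col[free])
    om <- params$flow_omega
    scale0 <- max(abs(p[nodes$boundary]), 1)
    ms <- as.integer(ceiling(params$flow_max_sweeps))
    rel <- Inf
    for (sweep in seq_len(ms)) {
      for (cl in classes) {
        p[cl] <- (1 - om) * p[cl] + om * as.numeric(G[cl, , drop = FALSE] %*% p) / D[cl]
      }
      if (sweep %% 20L == 0L || sweep == ms) {
        Gp <- as.numeric(G %*% p)
        res <- abs(D[free] * p[free] - Gp[free])
        sc <- as.numeric(G %*% abs(p)) + D * abs(p)
        rel <- max(res / pmax(sc[free], .Machine$double.eps * scale0))
        if (rel < params$flow_tol) break
      }
    }
    if (rel >= params$flow_tol)
      stop(sprintf("pressure solve did not converge: residual %.3e", rel))
  }
  p[!solvable] <- 0
  network$nodes$pressure <- p
  Q <- g * (p[i] - p[j])
  Q[!solvable[i]] <- 0
  network$segments$flow <- Q
  network$segments$functional <- abs(Q) > params$q_func_threshold
  network
}

#' Shear-driven radius remodelling and pruning
#'
#' Each functional segment's radius relaxes multiplicatively toward the
#' radius at which its wall shear stress `4 mu |Q| / (pi R^3)` matches
#' `shear_ref`: `d log R / dt = log(shear/shear_ref) / remodel_tau_h`,
#' clamped to `[r_min_um, r_max_um]`. Segments carrying no flow for longer
#' than `prune_after_h` (and not owned by an active tip) are removed, along
#' with any nodes left without segments.
#'
#' @param network vessel network with flows computed.
#' @param dt time step in hours.
#' @param params vascular parameters.
#' @return the remodelled network.
#' @export
remodel_radii <- function(network, dt, params = vm_default_vascular_params()) {
  segs <- network$segments
  if (!nrow(segs)) return(network)
  f <- segs$functional & abs(segs$flow) > 0
  if (any(f)) {
    shear <- 4 * params$viscosity * abs(segs$flow[f]) / (pi * segs$radius_um[f]^3)
    segs$radius_um[f] <- pmin(params$r_max_um, pmax(params$r_min_um,
      segs$radius_um[f] * exp(dt / params$remodel_tau_h *
                                log(shear / params$shear_ref))))
  }
  idle <- abs(segs$flow) <= params$q_func_threshold
  segs$zero_flow_h[idle] <- segs$zero_flow_h[idle] + dt
  segs$zero_flow_h[!idle] <- 0
  active_tips <- network$tips$id
  drop <- idle & segs$zero_flow_h > params$prune_after_h &
    !(segs$owner_tip %in% active_tips)
  if (any(drop)) {
    segs <- segs[!drop, , drop = FALSE]
    rownames(segs) <- NULL
    network$segments <- segs
    network <- vm_drop_orphan_nodes(network)
  } else network$segments <- segs
  network
}

vm_drop_orphan_nodes <- function(network) {
  used <- unique(c(network$segments$from, network$segments$to,
                   network$tips$node, network$tips$origin_node,
                   network$nodes$id[network$nodes$boundary]))
  gone <- !(network$nodes$id %in% used)
  if (any(gone)) {
    nn <- network$nodes[gone, ]
    network$nodemap[cbind(nn$x, nn$y, nn$z)] <- 0L
    network$nodes <- network$nodes[!gone, , drop = FALSE]
    rownames(network$nodes) <- NULL
  }
  network
}

# full vascular layer update: sprouting, migration, anastomosis, ageing,
# flow solve, remodelling. Returns state; event counts in state$vcounters.
vm_vascular_step <- function(state, dt) {
  par <- state$config$vasculature
  res <- sprout_initiation(state, dt)
  state <- res$state
  vc <- c(sprouts = res$n_spawned, anastomoses = 0L, regressed = 0L)
  for (tid in state$network$tips$id) {
    if (is.na(match(tid, state$network$tips$id))) next
    nm <- par$tip_speed_sites_h * dt
    n_moves <- floor(nm) + (stats::runif(1) < nm - floor(nm))
    moved <- FALSE
    if (n_moves >= 1) for (m in seq_len(n_moves)) {
      state <- tip_migration_step(state, tid)
      moved <- TRUE
    }
    if (moved) {
      out <- attempt_anastomosis(state, tid)
      state <- out$state
      if (!is.null(out$event))
        vc["anastomoses"] <- vc["anastomoses"] + 1L
    }
    ti <- match(tid, state$network$tips$id)
    if (!is.na(ti)) {
      state$network$tips$age_h[ti] <- state$network$tips$age_h[ti] + dt
      if (state$network$tips$age_h[ti] > par$max_sprout_age_h) {
        state$network <- vm_regress_tip(state$network, tid)
        vc["regressed"] <- vc["regressed"] + 1L
      }
    }
  }
  state$network <- compute_blood_flow(state$network, par)
  state$network <- remodel_radii(state$network, dt, par)
  state$vcounters <- vc
  state
}

# tip regression: remove the tip and the still-private trail it laid down
vm_regress_tip <- function(network, tip_id) {
  network$tips <- network$tips[network$tips$id != tip_id, , drop = FALSE]
  rownames(network$tips) <- NULL
  drop <- network$segments$owner_tip == tip_id
  if (any(drop)) {
    network$segments <- network$segments[!drop, , drop = FALSE]
    rownames(network$segments) <- NULL
    network <- vm_drop_orphan_nodes(network)
  }
  network
}
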