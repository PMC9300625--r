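# Angiogenesis rules, anastomosis law, blood flow and remodelling.

test_that("anastomosis probability is the linear distance law", {
  expect_identical(anastomosis_probability(0), 1)
  expect_identical(anastomosis_probability(100, 100), 0)
  expect_equal(anastomosis_probability(50, 100), 0.5)
  expect_equal(anastomosis_probability(25, 100), 0.75)
  d <- seq(0, 250, by = 5)
  p <- anastomosis_probability(d, 100)
  expect_true(all(diff(p) <= 0))
  expect_true(all(p >= 0 & p <= 1))
  expect_error(anastomosis_probability(-1), ">= 0")
})

test_that("acceptance frequency tracks 1 - d/dx_max (Monte Carlo)", {
  exp1 <- anastomosis_frequency_experiment(c(0, 100, 120), n_trials = 1000,
                                           seed = 1)
  expect_identical(exp1$frequency, c(1, 0, 0))   # endpoints are exact
  exp2 <- anastomosis_frequency_experiment(c(25, 50, 75), n_trials = 4000,
                                           seed = 2)
  se <- sqrt(exp2$expected * (1 - exp2$expected) / exp2$n)
  expect_true(all(abs(exp2$frequency - exp2$expected) < 3 * se))
})

test_that("a tip with no candidate in range reports a null event", {
  st <- tiny_state(dims = c(12, 6, 6), seed = 1)
  net <- st$network
  res <- vm_node_at_test(net, c(6, 3, 3)); net <- res$network
  net$tips <- data.frame(id = 1L, node = res$id, x = 6L, y = 3L, z = 3L,
                         origin_node = res$id, prev_x = NA_integer_,
                         prev_y = NA_integer_, prev_z = NA_integer_,
                         trail_len = 10L, age_h = 0)
  st$network <- net
  st$config$vasculature$dx_max_um <- 15   # below one lattice spacing
  out <- attempt_anastomosis(st, 1L)
  expect_null(out$event)
  expect_identical(out$state$network$segments, st$network$segments)
})

test_that("sprouting is silent without VEGF and binomial with it", {
  st <- tiny_state(dims = c(40, 4, 3), seed = 3)
  st$fields$vegf <- array(0, dim = st$lattice$dims)
  out <- sprout_initiation(st, dt = 0.5)
  expect_identical(out$n_spawned, 0L)
  # saturating VEGF: spawn count ~ Binomial(n_nodes, p_max dt)
  p <- st$config$vasculature
  counts <- vapply(1:40, function(s) {
    set.seed(s)
    st$fields$vegf <- array(1e9, dim = st$lattice$dims)
    sprout_initiation(st, dt = 0.5)$n_spawned
  }, 0L)
  fn <- sum(!st$network$nodes$boundary)
  pexp <- p$sprout_p_max * 0.5
  expect_lt(abs(mean(counts) - fn * pexp),
            3 * sqrt(fn * pexp * (1 - pexp) / length(counts)))
  # half-saturation: V - vegf_min = vegf_half halves the rate
  st$fields$vegf <- array(p$vegf_min + p$vegf_half,
                          dim = st$lattice$dims)
  counts2 <- vapply(1:60, function(s) {
    set.seed(s); sprout_initiation(st, dt = 0.5)$n_spawned
  }, 0L)
  pexp2 <- p$sprout_p_max * 0.5 / 2
  expect_lt(abs(mean(counts2) - fn * pexp2),
            3 * sqrt(fn * pexp2 * (1 - pexp2) / length(counts2)))
})

migration_counts <- function(st, tip_site, n_draws) {
  base <- st
  dirs <- integer(0)
  for (k in seq_len(n_draws)) {
    out <- tip_migration_step(base, 1L)
    tp <- out$network$tips[1, ]
    dirs <- c(dirs, (tp$x - tip_site[1] + 1) +
                    (tp$y - tip_site[2] + 1) * 3 +
                    (tp$z - tip_site[3] + 1) * 9)
  }
  table(dirs)
}

make_tip_state <- function(dims = c(7, 7, 7), seed = 1) {
  st <- tiny_state(dims = dims, seed = seed)
  net <- st$network
  res <- vm_node_at_test(net, c(4, 4, 4)); net <- res$network
  net$tips <- data.frame(id = 1L, node = res$id, x = 4L, y = 4L, z = 4L,
                         origin_node = res$id, prev_x = NA_integer_,
                         prev_y = NA_integer_, prev_z = NA_integer_,
                         trail_len = 0L, age_h = 0)
  st$network <- net
  st
}

test_that("tip migration is uniform on a flat VEGF field", {
  st <- make_tip_state(seed = 4)
  st$fields$vegf <- array(3, dim = st$lattice$dims)
  set.seed(99)
  counts <- migration_counts(st, c(4, 4, 4), 5200)
  expect_identical(length(counts), 26L)
  expect_gt(stats::chisq.test(as.vector(counts))$p.value, 0.01)
})

test_that("zero bias ignores the field; infinite bias follows it", {
  st <- make_tip_state(seed = 5)
  set.seed(7)
  st$fields$vegf <- array(stats::runif(prod(st$lattice$dims), 0, 50),
                          dim = st$lattice$dims)
  st$config$vasculature$tip_bias <- 0
  set.seed(123)
  counts <- migration_counts(st, c(4, 4, 4), 5200)
  expect_gt(stats::chisq.test(as.vector(counts))$p.value, 0.01)
  # deterministic limit: strict +x gradient, huge bias
  st$fields$vegf <- array(rep(seq_len(7), times = 49) * 5,
                          dim = st$lattice$dims)
  st$config$vasculature$tip_bias <- 1e6
  for (k in 1:20) {
    out <- tip_migration_step(st, 1L)
    tp <- out$network$tips[1, ]
    expect_identical(c(tp$x, tp$y, tp$z), c(5L, 4L, 4L))
  }
})

test_that("a blocked tip never re-enters its previous site", {
  st <- make_tip_state(seed = 6)
  st$fields$vegf <- array(1, dim = st$lattice$dims)
  set.seed(11)
  for (k in 1:50) {
    prev <- st$network$tips[1, c("x", "y", "z")]
    st <- tip_migration_step(st, 1L)
    cur <- st$network$tips[1, c("x", "y", "z")]
    expect_false(all(cur == prev))
    back <- st$network$tips[1, c("prev_x", "prev_y", "prev_z")]
    expect_identical(unlist(unname(back)), unlist(unname(prev)))
  }
})

test_that("single-vessel flow matches the Poiseuille closed form", {
  lat <- vm_lattice(c(11, 1, 1), 20)
  par <- vm_default_vascular_params()
  net <- single_vessel_network(lat, radius_um = 8, p_in = 25, p_out = 15)
  net <- compute_blood_flow(net, par)
  L <- 10 * 20
  want <- pi * 8^4 * (25 - 15) / (8 * par$viscosity * L)
  expect_equal(net$segments$flow[1], want, tolerance = 1e-12)
})

test_that("two identical parallel paths split the flow evenly", {
  lat <- vm_lattice(c(8, 5, 3), 20)
  net <- vm_empty_network(lat)
  res <- vm_node_at_test(net, c(1, 3, 2), TRUE, 30); net <- res$network
  src <- res$id
  res <- vm_node_at_test(net, c(8, 3, 2), TRUE, 10); net <- res$network
  snk <- res$id
  add_path <- function(net, y) {
    prev <- src
    for (x in 2:7) {
      res <- vm_node_at_test(net, c(x, y, 2)); net <- res$network
      net <- vascmet:::vm_add_segment(net, prev, res$id, 6, lat)
      prev <- res$id
    }
    vascmet:::vm_add_segment(net, prev, snk, 6, lat)
  }
  net <- add_path(net, 2)
  net <- add_path(net, 4)
  net <- compute_blood_flow(net, vm_default_vascular_params())
  q <- net$segments$flow
  up <- net$segments$from == src
  expect_equal(q[up][1], q[up][2], tolerance = 1e-10)
})

test_that("Kirchhoff balance holds on random trees and loops", {
  for (seed in c(21, 22)) {
    net <- random_vessel_network(seed)
    expect_lte(nrow(net$segments), 220)
    net <- compute_blood_flow(net, vm_default_vascular_params())
    qs <- max(abs(net$segments$flow))
    imb <- vapply(net$nodes$id[!net$nodes$boundary], function(nid) {
      s <- net$segments
      sum(s$flow[s$to == nid]) - sum(s$flow[s$from == nid])
    }, 0)
    expect_lt(max(abs(imb)) / qs, 1e-10)
    # global conservation: net inflow equals net outflow
    bnd <- net$nodes$id[net$nodes$boundary]
    bal <- sum(vapply(bnd, function(nid) {
      s <- net$segments
      sum(s$flow[s$from == nid]) - sum(s$flow[s$to == nid])
    }, 0))
    expect_lt(abs(bal) / qs, 1e-10)
  }
})

test_that("flow solve needs boundary pressures", {
  lat <- vm_lattice(c(5, 1, 1), 20)
  net <- vm_empty_network(lat)
  res <- vm_node_at_test(net, c(1, 1, 1)); net <- res$network
  a <- res$id
  res <- vm_node_at_test(net, c(2, 1, 1)); net <- res$network
  net <- vascmet:::vm_add_segment(net, a, res$id, 5, lat)
  expect_error(compute_blood_flow(net), "boundary")
})

test_that("radius remodelling relaxes to the shear set point", {
  lat <- vm_lattice(c(11, 1, 1), 20)
  par <- vm_default_vascular_params()
  net <- single_vessel_network(lat, radius_um = 8, p_in = 25, p_out = 15)
  net <- compute_blood_flow(net, par)
  Q <- abs(net$segments$flow[1])
  r_eq <- (4 * par$viscosity * Q / (pi * par$shear_ref))^(1 / 3)
  r_eq <- min(max(r_eq, par$r_min_um), par$r_max_um)
  # exact fixed point: a segment already at equilibrium does not move
  net_eq <- net
  net_eq$segments$radius_um <- r_eq
  out <- remodel_radii(net_eq, dt = 1, par)
  expect_equal(out$segments$radius_um, r_eq, tolerance = 1e-12)
  # monotone approach from below, matching the exact scalar solution of
  # d(log R)/dt = (log(4 mu Q/(pi ref)) - 3 log R)/tau with Q frozen
  radii <- numeric(30)
  cur <- net
  for (k in 1:30) {
    cur <- remodel_radii(cur, dt = 0.25, par)
    radii[k] <- cur$segments$radius_um[1]
  }
  expect_true(all(diff(c(8, radii)) > 0 | radii == par$r_max_um))
  u_inf <- log(4 * par$viscosity * Q / (pi * par$shear_ref)) / 3
  t <- 0.25 * (1:30)
  exact <- exp(u_inf + (log(8) - u_inf) * exp(-3 * t / par$remodel_tau_h))
  expect_lt(max(abs(radii - pmin(exact, par$r_max_um))) / r_eq, 0.05)
})

test_that("persistently flow-less segments are pruned", {
  lat <- vm_lattice(c(11, 3, 1), 20)
  par <- vm_default_vascular_params()
  net <- single_vessel_network(lat, 8, 25, 15)
  # dangling side branch off the vessel: no flow ever
  res <- vm_node_at_test(net, c(5, 2, 1)); net <- res$network
  net <- vascmet:::vm_add_segment(net, net$nodes$id[1], res$id, 4, lat)
  net <- compute_blood_flow(net, par)
  expect_false(net$segments$functional[2])
  for (k in seq_len(ceiling(par$prune_after_h / 10) + 1))
    net <- remodel_radii(net, dt = 10, par)
  expect_identical(nrow(net$segments), 1L)   # only the main vessel is left
  expect_false(any(net$nodes$x == 5 & net$nodes$y == 2))
})

test_that("functional segments lie on perfused boundary-to-boundary paths", {
  st <- tiny_state(dims = c(12, 12, 8), seed = 8, init_tissue = "confluent")
  for (k in 1:8) st <- sim_step(st, 0.5)
  net <- st$network
  fs <- net$segments[net$segments$functional, ]
  expect_gt(nrow(fs), 0)
  g <- igraph::graph_from_data_frame(fs[, c("from", "to")],
    directed = FALSE,
    vertices = data.frame(name = net$nodes$id))
  comp <- igraph::components(g)$membership
  bnd <- as.character(net$nodes$id[net$nodes$boundary])
  for (i in seq_len(nrow(fs))) {
    cmp <- comp[as.character(fs$from[i])]
    expect_gte(sum(comp[bnd] == cmp), 2)
  }
})
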