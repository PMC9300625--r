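# Lattice geometry, subcellular ODEs, tumour implantation and the
# cellular-automaton rules.

test_that("lattice geometry and invariants", {
  lat <- vm_lattice(c(64, 64, 64), 20)
  expect_identical(lat$side_um, c(1280, 1280, 1280))
  expect_identical(lat$n_sites, 64^3)
  expect_error(vm_lattice(c(0, 4, 4)), "dims")
  expect_error(vm_lattice(c(4, 4, 4), -1), "spacing")
})

test_that("cycle progression freezes at zero oxygen, saturates at high", {
  cell <- data.frame(id = 1L, type = "cancer", x = 1L, y = 1L, z = 1L,
                     phase = 0.5, state = "proliferating", p53 = 1,
                     ivegf = 0, quiesc_h = 0)
  out <- advance_subcellular(cell, local_oxygen = 0, dt = 12)
  expect_identical(out$phase, 0.5)
  # saturating oxygen: one full minimum cycle time gains ~ the full cycle
  p <- vm_default_cell_params()
  p$cancer$k_phi_o2 <- 1e-6
  cell$phase <- 0
  out <- advance_subcellular(cell, local_oxygen = 50,
                             dt = p$cancer$t_cycle_min_h, params = p)
  expect_equal(out$phase, 1, tolerance = 1e-6)
  expect_error(advance_subcellular(cell, -1, 1), ">= 0")
  expect_error(advance_subcellular(cell, 1, 0), "dt")
})

test_that("p53 follows its linear ODE exactly", {
  p <- vm_default_cell_params()$cancer
  o2 <- 12
  b <- p$p53_deg * o2 / (o2 + p$k_p53_o2)
  fix <- p$p53_prod / b
  cell <- data.frame(id = 1L, type = "cancer", x = 1L, y = 1L, z = 1L,
                     phase = 0, state = "proliferating", p53 = fix,
                     ivegf = 0, quiesc_h = 0)
  # production = degradation x level: the level is a fixed point
  out <- advance_subcellular(cell, o2, dt = 7)
  expect_equal(out$p53, fix, tolerance = 1e-12)
  # off the fixed point the closed-form exponential solution holds
  cell$p53 <- 3
  out <- advance_subcellular(cell, o2, dt = 7)
  expect_equal(out$p53, fix + (3 - fix) * exp(-b * 7), tolerance = 1e-12)
})

test_that("tumour implantation replaces occupants inside the ball", {
  st <- tiny_state(dims = c(9, 9, 9), seed = 1)
  st1 <- implant_tumour(st, c(5, 5, 5), 0)
  expect_identical(nrow(st1$cells), 1L)
  expect_identical(st1$cells$type, "cancer")
  # radius-1 Euclidean ball: independent enumeration over integer offsets
  ball_count <- function(r) {
    g <- expand.grid(-r:r, -r:r, -r:r)
    sum(rowSums(g^2) <= r^2)
  }
  st2 <- implant_tumour(st, c(5, 5, 5), 1)
  expect_identical(nrow(st2$cells), ball_count(1))   # 7 sites
  st3 <- implant_tumour(st, c(5, 5, 5), 2)
  expect_identical(nrow(st3$cells), ball_count(2))
  # re-implanting at the same site leaves occupancy unchanged
  st4 <- implant_tumour(st2, c(5, 5, 5), 1)
  expect_identical(sum(st4$occupancy > 0), sum(st2$occupancy > 0))
  expect_identical(nrow(st4$cells), nrow(st2$cells))
  # confluent tissue: replaced normal cells are removed
  stc <- tiny_state(dims = c(9, 9, 9), seed = 1, init_tissue = "confluent")
  n0 <- nrow(stc$cells)
  stc2 <- implant_tumour(stc, c(5, 5, 5), 1)
  expect_identical(nrow(stc2$cells), n0)
  expect_identical(sum(stc2$cells$type == "cancer"), ball_count(1))
  expect_error(implant_tumour(st, c(50, 5, 5), 1), "inside")
  expect_warning(implant_tumour(st, c(1, 1, 1), 2), "clipped")
})

test_that("an unconstrained cell divides; a surrounded cell defers", {
  st <- tiny_state(dims = c(7, 7, 7), seed = 2)
  st <- place_cell(st, c(4, 4, 4), phase = 1)
  st <- with_uniform_oxygen(st, 20)
  out <- ca_step(st, 0.5)
  expect_identical(nrow(out$cells), 2L)
  expect_identical(out$cells$phase, c(0, 0))
  expect_identical(unname(out$counters["divisions"]), 1L)
  # contact inhibition: fill the full 26-neighbourhood
  st2 <- tiny_state(dims = c(7, 7, 7), seed = 3)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1)
    st2 <- place_cell(st2, c(4 + dx, 4 + dy, 4 + dz),
                      phase = if (dx || dy || dz) 0 else 1)
  st2 <- with_uniform_oxygen(st2, 20)
  cfgp <- st2$config$cells
  st2$config$cells$cancer$movement_rate <- 0
  out2 <- ca_step(st2, 0.5)
  expect_identical(nrow(out2$cells), 27L)
  expect_identical(unname(out2$counters["deferred"]), 1L)
  expect_equal(out2$cells$phase[out2$cells$x == 4 & out2$cells$y == 4 &
                                out2$cells$z == 4], 1)
})

test_that("population doubles per cycle until space runs out", {
  st <- tiny_state(dims = c(6, 6, 6), seed = 4, tweak = function(cfg) {
    cfg$cells$cancer$movement_rate <- 0
    cfg$cells$cancer$k_phi_o2 <- 1e-9      # saturating progression
    cfg$run$dt_h <- 0.5
    cfg
  })
  st <- place_cell(st, c(3, 3, 3), phase = 0)
  st <- with_uniform_oxygen(st, 1e12)
  tcyc <- st$config$cells$cancer$t_cycle_min_h
  counts <- integer(0)
  for (gen in 1:10) {
    for (k in seq_len(tcyc / 0.5)) {
      st$cells <- advance_subcellular(st$cells, 1e12, 0.5,
                                      st$config$cells)
      st <- ca_step(st, 0.5)
      st <- with_uniform_oxygen(st, 1e12)
    }
    counts <- c(counts, nrow(st$cells))
  }
  oracle <- growth_recursion_oracle(1, 6^3, 10)[-1]
  # exact doubling while the blob is all surface; bounded by the scalar
  # recursion and saturating at capacity
  expect_identical(counts[1:4], as.integer(oracle[1:4]))
  expect_true(all(counts <= oracle))
  expect_true(all(diff(counts) >= 0))
  expect_identical(counts[length(counts)], 216L)
})

test_that("no cell ever divides without oxygen", {
  st <- tiny_state(dims = c(6, 6, 6), seed = 5, init_tissue = "confluent",
                   tweak = function(cfg) {
                     cfg$cells$normal$base_death_rate <- 0
                     cfg
                   })
  st <- with_uniform_oxygen(st, 0)
  st$cells$phase <- stats::runif(nrow(st$cells))
  n0 <- nrow(st$cells)
  for (k in 1:20) {
    st$cells <- advance_subcellular(st$cells, 0, 0.5, st$config$cells)
    st <- ca_step(st, 0.5)
    st <- with_uniform_oxygen(st, 0)
    expect_identical(unname(st$counters["divisions"]), 0L)
    expect_lte(nrow(st$cells), n0)
  }
})

test_that("hypoxia below the quiescence threshold halts proliferation", {
  st <- tiny_state(dims = c(6, 6, 6), seed = 6, init_tissue = "confluent")
  st <- with_uniform_oxygen(st, 5)   # below the enter threshold (8)
  prolif <- sum(st$cells$state == "proliferating")
  for (k in 1:10) {
    st <- ca_step(st, 0.5)
    st <- with_uniform_oxygen(st, 5)
    now <- sum(st$cells$state == "proliferating")
    expect_lte(now, prolif)
    prolif <- now
  }
  expect_identical(prolif, 0L)
  # and quiescent cells die once past their maximum quiescence time
  p <- st$config$cells$normal$max_quiescence_h
  for (k in seq_len(ceiling(p / 0.5) + 2)) {
    st <- ca_step(st, 0.5)
    st <- with_uniform_oxygen(st, 5)
  }
  expect_identical(sum(st$cells$type == "normal"), 0L)
})

test_that("occupancy stays consistent and identical seeds reproduce", {
  run_once <- function() {
    st <- tiny_state(dims = c(6, 6, 6), seed = 11,
                     init_tissue = "confluent")
    for (k in 1:100) {
      st$cells <- advance_subcellular(
        st$cells, vascmet:::vm_local_oxygen(st), 0.5, st$config$cells)
      st <- ca_step(st, 0.5)
      occ_ids <- sort(st$occupancy[st$occupancy > 0])
      expect_identical(occ_ids, sort(st$cells$id))
    }
    st
  }
  a <- run_once()
  b <- run_once()
  expect_identical(sorted_cells(a$cells), sorted_cells(b$cells))
  expect_identical(a$occupancy, b$occupancy)
})
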