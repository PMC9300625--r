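# Lin-log kinetic engine: rate law, mass balances, stiff integration,
# network IO and the bundled HEPG2-like network.

test_that("rate law reproduces the reference-state identity exactly", {
  net <- hepg2_network()
  r <- linlog_rate(net, reference_state(net))
  expect_identical(unname(r), net$J0 * net$cE)
  # and across randomly generated flux-balanced networks
  for (s in 1:25) {
    toy <- make_toy_metabolic_network(2 + s %% 5, seed = s)
    expect_equal(unname(linlog_rate(toy, reference_state(toy))), toy$J0,
                 tolerance = 1e-14)
  }
})

test_that("rate law follows the logarithmic elasticity form", {
  species <- data.frame(name = c("ext_in", "s1", "ext_out"),
                        c0 = c(1, 2, 1),
                        external = c(TRUE, FALSE, TRUE))
  rx <- list(
    list(name = "in", J0 = 1.5, stoich = list(ext_in = -1, s1 = 1),
         elasticities = list(substrate = list(ext_in = 1))),
    list(name = "out", J0 = 1.5, stoich = list(s1 = -1, ext_out = 1),
         elasticities = list(substrate = list(s1 = 1))))
  net <- vm_metabolic_network(species, rx)
  # epsilon = 1 and c = e * c0 doubles the flux (ln e = 1)
  x <- c(ext_in = 1, s1 = exp(1), ext_out = 1)
  expect_equal(unname(linlog_rate(net, x, "out")), 3.0, tolerance = 1e-12)
  # enzyme proportionality: cE = 0 silences the reaction
  rx[[2]]$cE <- 0
  net0 <- vm_metabolic_network(species, rx)
  expect_identical(unname(linlog_rate(net0, x, "out")), 0)
  # non-positive concentrations are a domain error naming the species
  expect_error(linlog_rate(net, c(ext_in = 1, s1 = 0, ext_out = 1)), "s1")
})

test_that("mass balances vanish at reference and clamp externals", {
  net <- hepg2_network()
  d <- metabolic_rhs(net, reference_state(net))
  expect_equal(max(abs(d)), 0, tolerance = 1e-12)
  # perturbing a chain species upward drives it back down
  toy <- make_toy_metabolic_network(3, seed = 4)
  x <- reference_state(toy)
  x["s2"] <- 1.3
  d <- metabolic_rhs(toy, x)
  expect_lt(d[["s2"]], 0)
  # clamped external derivative is exactly zero even off-reference
  x["ext_in"] <- 2
  expect_identical(metabolic_rhs(toy, x)[["ext_in"]], 0)
})

test_that("stiff integration preserves the reference equilibrium", {
  net <- hepg2_network()
  x <- integrate_metabolism(net, reference_state(net), duration_h = 1)
  expect_equal(unname(x), rep(1, length(x)), tolerance = 1e-6)
})

test_that("integration matches the matrix-exponential linearization", {
  toy <- make_toy_metabolic_network(2, seed = 11)
  x0 <- reference_state(toy)
  int <- toy$species$name[toy$internal]
  x0[int] <- 1 + c(1e-3, -8e-4)
  got <- integrate_metabolism(toy, x0, duration_h = 0.1,
                              rtol = 1e-10, atol = 1e-12)
  want <- linlog_matexp_oracle(toy, x0, 0.1)
  expect_lt(max(abs(got - want)), 1e-4)
  # and well within the perturbation scale itself
  expect_lt(max(abs(got - want)), 0.1 * 1e-3)
})

test_that("a glucose step drives the network to a faster steady state", {
  net <- hepg2_network()
  env <- c(glc_ext = 2)
  x <- integrate_metabolism(net, reference_state(net), env, 50,
                            rtol = 1e-10, atol = 1e-12)
  # converged: residual of the mass balances is tiny
  expect_lt(max(abs(metabolic_rhs(net, x))), 1e-6)
  # agrees with the independent algebraic steady-state solve
  ss <- linlog_steady_state(net, env)
  expect_equal(unname(x), unname(ss$steady_state), tolerance = 1e-6)
  # glycolytic flux exceeds its reference value
  expect_gt(linlog_rate(net, x, "hk"), net$J0[[1]])
})

test_that("moieties conserved by the stoichiometry stay conserved", {
  species <- data.frame(
    name = c("ext_a", "A", "nad", "nadh", "ext_b"),
    c0 = c(1, 0.5, 0.8, 0.4, 1),
    external = c(TRUE, FALSE, FALSE, FALSE, TRUE))
  rx <- list(
    list(name = "dehydrogenase", J0 = 1,
         stoich = list(ext_a = -1, nad = -1, A = 1, nadh = 1),
         elasticities = list(substrate = list(ext_a = 0.5, nad = 1))),
    list(name = "efflux", J0 = 1, stoich = list(A = -1, ext_b = 1),
         elasticities = list(substrate = list(A = 1))),
    list(name = "oxidase", J0 = 1, stoich = list(nadh = -1, nad = 1),
         elasticities = list(substrate = list(nadh = 1))))
  net <- vm_metabolic_network(species, rx)
  m <- c(ext_a = 0, A = 0, nad = 1, nadh = 1, ext_b = 0)   # m' N = 0
  expect_equal(max(abs(m %*% net$N)), 0)
  x0 <- reference_state(net)
  x0["nad"] <- 1.25; x0["nadh"] <- 0.5   # same absolute moiety total
  total0 <- sum(net$species$c0 * x0 * m)
  for (t in c(0.05, 0.2, 1, 5)) {
    x <- integrate_metabolism(net, x0, duration_h = t,
                              rtol = 1e-10, atol = 1e-12)
    expect_equal(sum(net$species$c0 * x * m), total0, tolerance = 1e-8)
  }
})

test_that("the local stability diagnostic is consistent with decay", {
  net <- hepg2_network()
  ss <- linlog_steady_state(net)
  expect_true(ss$stable)
  int <- net$species$name[net$internal]
  x0 <- reference_state(net)
  x0[int] <- x0[int] * (1 + 1e-2)
  x <- integrate_metabolism(net, x0, duration_h = 10)
  # all eigenvalues have negative real part, so the perturbation decays
  expect_lt(max(abs(x[int] - 1)), 1e-2 * 0.5)
})

test_that("the Warburg response holds on the bundled network", {
  net <- hepg2_network()
  flux <- vapply(c(0.7, 1, 1.5), function(g)
    linlog_steady_state(net, c(glc_ext = g))$rates[["ldh"]], 0)
  expect_true(all(diff(flux) > 0))
  # and hypoxia shifts pyruvate away from respiration, towards lactate
  hyp <- linlog_steady_state(net, c(o2_ext = 0.05))$rates
  ref <- linlog_steady_state(net)$rates
  expect_lt(hyp[["respiration"]], ref[["respiration"]])
  expect_gt(hyp[["ldh"]], ref[["ldh"]])
})

test_that("network files round-trip bit-exactly and validate on load", {
  net <- make_toy_metabolic_network(4, seed = 3)
  path <- withr::local_tempfile(fileext = ".yaml")
  save_network(net, path)
  back <- load_network(path)
  expect_identical(back$N, net$N)
  expect_identical(back$E, net$E)
  expect_identical(back$J0, net$J0)
  expect_identical(back$species, net$species)
  # second round trip is byte-identical
  path2 <- withr::local_tempfile(fileext = ".yaml")
  save_network(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("invalid networks are rejected with all violations listed", {
  species <- data.frame(name = c("ext", "a", "b"), c0 = c(1, 1, -1),
                        external = c(TRUE, FALSE, FALSE))
  rx <- list(
    list(name = "r1", J0 = 1, stoich = list(ext = -1, a = 1),
         elasticities = list(substrate = list(ext = 1, ghost = 0.5))),
    list(name = "r2", J0 = 2, stoich = list(a = -1, b = 1),
         elasticities = list(substrate = list(a = 1))))
  err <- tryCatch(vm_metabolic_network(species, rx),
                  error = conditionMessage)
  expect_match(err, "non-positive c0.*b")
  expect_match(err, "unknown species.*ghost")
  # flux imbalance names the species
  species$c0 <- c(1, 1, 1)
  rx[[1]]$elasticities$substrate$ghost <- NULL
  err <- tryCatch(vm_metabolic_network(species, rx),
                  error = conditionMessage)
  expect_match(err, "not balanced.*a")
})

test_that("toy network generation is flux-balanced and seed-stable", {
  for (s in 1:10) {
    toy <- make_toy_metabolic_network(2 + (s %% 4), seed = s)
    expect_equal(max(abs(toy$N[toy$internal, ] %*% toy$J0)), 0)
    expect_true(linlog_steady_state(toy)$stable)
  }
  expect_identical(make_toy_metabolic_network(5, seed = 42)$E,
                   make_toy_metabolic_network(5, seed = 42)$E)
})
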