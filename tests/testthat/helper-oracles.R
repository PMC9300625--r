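# Closed-form and randomized scenario builders shared by the unit and
# acceptance suites.

slab_case <- function(n, spacing_um = 10) {
  # 1D slab: Dirichlet c_blood at x = 0, zero flux at the far wall,
  # linear uptake k c everywhere -> c = cb cosh(kappa (L - x))/cosh(kappa L)
  lat <- vm_lattice(c(n, 1, 1), spacing_um)
  D <- 7.2e5; cb <- 5; k <- 3.3 / 0.2
  par <- list(d_um2_h = D, perm_um_h = 0, c_blood = cb, decay_h = 0,
              uptake = list(kind = "linear", k = k),
              bc = list(kind = "dirichlet", faces = list(xlo = cb)))
  cells <- data.frame(id = seq_len(n), type = "cancer", x = seq_len(n),
                      y = 1L, z = 1L, phase = 0, state = "proliferating",
                      p53 = 1, ivegf = 0, quiesc_h = 0)
  occ <- array(0L, dim = lat$dims)
  occ[cbind(cells$x, cells$y, cells$z)] <- cells$id
  sol <- solve_quasi_steady(lat, par, occ, cells, NULL, tol = 1e-12)
  L <- n * spacing_um
  xc <- (seq_len(n) - 0.5) * spacing_um
  exact <- cb * cosh(sqrt(k / D) * (L - xc)) / cosh(sqrt(k / D) * L)
  max(abs(sol[, 1, 1] - exact) / exact)
}

random_vessel_network <- function(seed, n_extra = 40) {
  # random spanning tree over ~160 lattice nodes plus extra loop edges
  set.seed(seed)
  lat <- vm_lattice(c(12, 12, 12), 20)
  net <- vm_empty_network(lat)
  sites <- unique(t(replicate(180, sample.int(12, 3, replace = TRUE))))
  ids <- integer(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    res <- vm_node_at_test(net, sites[i, ], i == 1,
                           if (i == 1) 40 else NA_real_)
    net <- res$network; ids[i] <- res$id
  }
  n <- length(ids)
  # mark a second boundary node
  res <- vm_node_at_test(net, sites[n, ], TRUE, 5); net <- res$network
  for (i in 2:n)   # spanning tree
    net <- vascmet:::vm_add_segment(net, ids[sample.int(i - 1, 1)], ids[i],
                                    stats::runif(1, 3, 10), lat)
  for (k in seq_len(n_extra)) {  # loops
    ab <- sample(ids, 2)
    net <- vascmet:::vm_add_segment(net, ab[1], ab[2],
                                    stats::runif(1, 3, 10), lat)
  }
  net
}

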