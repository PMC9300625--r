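# Programmatic toy-scenario generators and the independent brute-force
# oracles used by the test surface. Every oracle is implemented without
# sharing numerical kernels with the module it checks.

#' Random flux-balanced toy lin-log network
#'
#' A linear chain `ext_in -> s1 -> ... -> s_n -> ext_out` with one reaction
#' per edge. All reference fluxes are equal, so `N J0 = 0` holds on the
#' internal species by construction. Substrate elasticities are drawn in
#' [0.6, 1.4] and product elasticities in [-0.4, -0.1]; the reference
#' Jacobian of such a chain is strictly diagonally dominant with a negative
#' diagonal, and its stability is verified (and re-sampled, bounded
#' retries) rather than assumed.
#'
#' @param n_species number of internal chain species (>= 2).
#' @param seed RNG seed.
#' @param max_retries resampling budget for the stability requirement.
#' @return a validated, reference-stable `vm_metnet`.
#' @export
make_toy_metabolic_network <- function(n_species, seed = 1,
                                       max_retries = 20) {
  if (n_species < 2) stop("n_species must be >= 2")
  set.seed(seed)
  for (try in seq_len(max_retries)) {
    J <- stats::runif(1, 0.5, 5)
    sn <- c("ext_in", paste0("s", seq_len(n_species)), "ext_out")
    species <- data.frame(
      name = sn, c0 = stats::runif(length(sn), 0.05, 2),
      external = sn %in% c("ext_in", "ext_out"), stringsAsFactors = FALSE)
    reactions <- lapply(seq_len(n_species + 1), function(j) {
      sub <- sn[j]; prod <- sn[j + 1]
      el <- list(substrate = stats::setNames(
        list(stats::runif(1, 0.6, 1.4)), sub))
      if (j <= n_species)   # no product elasticity on the exit reaction
        el$product <- stats::setNames(list(stats::runif(1, -0.4, -0.1)),
                                      prod)
      list(name = paste0("r", j), J0 = J,
           stoich = stats::setNames(list(-1, 1), c(sub, prod)),
           elasticities = el)
    })
    net <- vm_metabolic_network(species, reactions)
    if (linlog_steady_state(net)$stable) return(net)
  }
  stop("could not sample a reference-stable network in ", max_retries,
       " tries")
}

#' Direct sparse-solve oracle for the linearized field equation
#'
#' Assembles the full sparse linear system of the 7-point discretization of
#' `D lap(c) - a c + b = 0` (zero-flux closure by reflection; Dirichlet
#' faces by ghost-cell elimination) and solves it directly with a sparse LU
#' factorization. Shares no numerical kernel with [solve_quasi_steady()]'s
#' matrix-free conjugate-gradient path; used as its equivalence oracle in
#' the linear-uptake regime.
#'
#' @param lattice a [vm_lattice()].
#' @param a per-site linear coefficient array (vessel exchange + decay +
#'   linearized uptake), >= 0.
#' @param b per-site source array (vessel influx + production).
#' @param d_um2_h diffusion coefficient (um^2/h).
#' @param bc boundary condition spec as in [vm_default_field_params()].
#' @return the concentration array.
#' @export
dense_linear_field_oracle <- function(lattice, a, b, d_um2_h,
                                      bc = list(kind = "neumann0")) {
  dims <- lattice$dims; h <- lattice$spacing_um
  n <- prod(dims)
  if (n > 32^3) stop("oracle restricted to <= 32^3 sites")
  idx <- array(seq_len(n), dim = dims)
  diag_v <- as.vector(a)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  co <- d_um2_h / h^2
  for (k in 1:3) {
    nk <- dims[k]
    if (nk == 1L) next
    # pairs of adjacent sites along axis k
    lo <- switch(k, idx[-nk, , , drop = FALSE], idx[, -nk, , drop = FALSE],
                 idx[, , -nk, drop = FALSE])
    hi <- switch(k, idx[-1, , , drop = FALSE], idx[, -1, , drop = FALSE],
                 idx[, , -1, drop = FALSE])
    lo <- as.vector(lo); hi <- as.vector(hi)
    ii <- c(ii, lo, hi); jj <- c(jj, hi, lo); xx <- c(xx, rep(-co, 2 * length(lo)))
    diag_v[lo] <- diag_v[lo] + co
    diag_v[hi] <- diag_v[hi] + co
  }
  rhs <- as.vector(b)
  if (identical(bc$kind, "dirichlet")) {
    for (face in names(bc$faces)) {
      val <- bc$faces[[face]]
      layer <- switch(face,
        xlo = idx[1, , ], xhi = idx[dims[1], , ],
        ylo = idx[, 1, ], yhi = idx[, dims[2], ],
        zlo = idx[, , 1], zhi = idx[, , dims[3]])
      layer <- as.vector(layer)
      diag_v[layer] <- diag_v[layer] + 2 * co
      rhs[layer] <- rhs[layer] + 2 * co * val
    }
  }
  A <- Matrix::sparseMatrix(i = c(ii, seq_len(n)), j = c(jj, seq_len(n)),
                            x = c(xx, diag_v), dims = c(n, n))
  sol <- as.numeric(Matrix::solve(A, rhs))
  array(sol, dim = dims)
}

#' Empirical anastomosis-acceptance frequencies
#'
#' Monte-Carlo experiment on isolated tip/target pairs: for each distance,
#' a sprout tip faces a single functional-vessel node at exactly that
#' separation and [attempt_anastomosis()] is run `n_trials` times; returns
#' the empirical acceptance frequency with binomial standard errors, for
#' comparison against the linear distance law.
#'
#' @param distances_um distances to probe (must be multiples of
#'   `spacing_um`).
#' @param n_trials trials per distance (>= 1000).
#' @param seed RNG seed.
#' @param dx_max_um maximum anastomosis distance.
#' @param spacing_um lattice spacing of the toy scenario (default 5 um).
#' @return data.frame with `distance_um`, `expected`, `frequency`, `se`,
#'   `n`.
#' @export
anastomosis_frequency_experiment <- function(distances_um, n_trials = 10000,
                                             seed = 1, dx_max_um = 100,
                                             spacing_um = 5) {
  if (n_trials < 1000) stop("n_trials must be >= 1000")
  if (any(distances_um %% spacing_um != 0))
    stop("distances must be multiples of spacing_um")
  set.seed(seed)
  rows <- lapply(distances_um, function(d) {
    ds <- as.integer(d / spacing_um)
    far_x <- 1L + ds + as.integer(ceiling(dx_max_um / spacing_um)) + 2L
    lat <- vm_lattice(c(far_x + 1L, 3, 3), spacing_um)
    cfg <- vm_default_config()
    cfg$lattice$dims <- lat$dims; cfg$lattice$spacing_um <- spacing_um
    cfg$vasculature$dx_max_um <- dx_max_um
    net <- vm_empty_network(lat)
    res <- vm_node_at(net, c(1L, 2L, 2L)); net <- res$network
    tip_node <- res$id
    mk_tip <- function(id, node, xyz) data.frame(
      id = id, node = node, x = xyz[1], y = xyz[2], z = xyz[3],
      origin_node = node, prev_x = NA_integer_, prev_y = NA_integer_,
      prev_z = NA_integer_, trail_len = 99L, age_h = 0,
      stringsAsFactors = FALSE)
    if (ds == 0L) {
      # zero separation: a co-located partner tip is the single candidate
      net$tips <- rbind(mk_tip(1L, tip_node, c(1L, 2L, 2L)),
                        mk_tip(2L, tip_node, c(1L, 2L, 2L)))
    } else {
      # target: functional segment whose far endpoint is out of range
      res <- vm_node_at(net, c(1L + ds, 2L, 2L)); net <- res$network
      target <- res$id
      res <- vm_node_at(net, c(far_x, 3L, 3L)); net <- res$network
      net <- vm_add_segment(net, target, res$id, 10, lat,
                            functional = TRUE)
      net$tips <- mk_tip(1L, tip_node, c(1L, 2L, 2L))
    }
    state <- structure(list(lattice = lat, network = net, config = cfg),
                       class = "vm_state")
    hits <- 0L
    for (t in seq_len(n_trials)) {
      out <- attempt_anastomosis(state, 1L)
      if (!is.null(out$event)) hits <- hits + 1L
    }
    freq <- hits / n_trials
    data.frame(distance_um = d,
               expected = anastomosis_probability(d, dx_max_um),
               frequency = freq,
               se = sqrt(freq * (1 - freq) / n_trials), n = n_trials)
  })
  do.call(rbind, rows)
}

#' Scalar birth-death oracle for unconstrained-to-saturating growth
#'
#' Independent recursion for the expected cell count of a synchronized
#' population with a fixed cycle time on a finite lattice: the count
#' doubles per completed cycle until the space is exhausted.
#'
#' @param n0 initial cell count.
#' @param capacity number of lattice sites.
#' @param generations completed cycles.
#' @return vector of counts after 0..generations cycles.
#' @export
growth_recursion_oracle <- function(n0, capacity, generations) {
  n <- numeric(generations + 1)
  n[1] <- n0
  for (g in seq_len(generations)) n[g + 1] <- min(capacity, 2 * n[g])
  n
}

#' Matrix-exponential oracle for lin-log relaxation near the reference
#'
#' Closed-form solution of the Jacobian linearization of the mass balances
#' around the reference state (environment clamped at reference):
#' `x_int(t) = 1 + expm(J t) (x0_int - 1)`. Valid for small perturbations;
#' used as the independent check of [integrate_metabolism()].
#'
#' @param network a `vm_metnet`.
#' @param x0 initial normalized state (named or ordered).
#' @param duration_h time in hours.
#' @return named normalized state at `duration_h`.
#' @export
linlog_matexp_oracle <- function(network, x0, duration_h) {
  xx <- vm_check_state(network, x0)
  int <- network$internal
  J <- linlog_steady_state(network)$jacobian_ref
  xi0 <- xx[int] - 1
  xi <- as.numeric(Matrix::expm(Matrix::Matrix(J) * duration_h) %*% xi0)
  xx[int] <- 1 + xi
  stats::setNames(xx, network$species$name)
}

#' Write all toy fixtures to a directory
#'
#' Materializes the bundled synthetic HEPG2-like network and a set of toy
#' chain networks as YAML files (used by the command-line interface's
#' `make-fixtures` subcommand).
#'
#' @param dir output directory.
#' @param seeds seeds of the toy chain networks.
#' @return written paths, invisibly.
#' @export
make_fixtures <- function(dir, seeds = 1:3) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, "hepg2_linlog_synthetic.yaml")
  save_network(hepg2_network(), paths)
  for (s in seeds) {
    p <- file.path(dir, sprintf("toy_chain_seed%d.yaml", s))
    save_network(make_toy_metabolic_network(4, seed = s), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Completed-loop efficiency of the distance-based anastomosis rule
#'
#' Fixed two-parent-vessel scenario with a static VEGF hotspot midway
#' between the vessels (no cells, fields frozen): sprouts form on both
#' parents, migrate up the hotspot gradient, and may fuse. Runs the
#' vascular layer alone for `n_hours` and counts completed anastomosis
#' loops, for the distance-dependent acceptance rule (`dx_max_um = 100` by
#' default) versus a contact-only rule (`dx_max_um` of one lattice
#' spacing): in 3D the distance-dependent rule completes strictly more
#' loops.
#'
#' @param seeds integer vector of seeds (one run per seed).
#' @param dx_max_um maximum anastomosis distance for this arm (um).
#' @param dims lattice dims of the scenario.
#' @param n_hours simulated hours of the vascular layer.
#' @param dt vascular time step (h).
#' @param hotspot_amp,hotspot_sigma_um VEGF hotspot amplitude and width.
#' @return data.frame with `seed` and `loops` (completed anastomoses).
#' @export
anastomosis_efficiency_experiment <- function(seeds, dx_max_um = 100,
                                              dims = c(16, 16, 9),
                                              n_hours = 24, dt = 0.5,
                                              hotspot_amp = 30,
                                              hotspot_sigma_um = 120) {
  rows <- lapply(seeds, function(sd) {
    cfg <- vm_default_config()
    cfg$lattice$dims <- dims
    cfg$run$seed <- sd
    cfg$run$init_tissue <- "empty"
    cfg$run$implant_tumour <- FALSE
    cfg$metabolism$enabled <- FALSE
    cfg$vasculature$dx_max_um <- dx_max_um
    st <- initialize_scenario(cfg)
    lat <- st$lattice
    ctr <- (dims + 1) / 2 * lat$spacing_um
    gx <- (seq_len(dims[1]) - 0.5) * lat$spacing_um
    gy <- (seq_len(dims[2]) - 0.5) * lat$spacing_um
    gz <- (seq_len(dims[3]) - 0.5) * lat$spacing_um
    d2 <- outer(outer((gx - ctr[1])^2, (gy - ctr[2])^2, "+"),
                (gz - ctr[3])^2, "+")
    st$fields$vegf <- hotspot_amp * exp(-d2 / (2 * hotspot_sigma_um^2))
    loops <- 0L
    for (k in seq_len(ceiling(n_hours / dt))) {
      st <- vascmet:::vm_vascular_step(st, dt)
      loops <- loops + st$vcounters[["anastomoses"]]
      st$fields$vegf <- hotspot_amp * exp(-d2 / (2 * hotspot_sigma_um^2))
    }
    data.frame(seed = sd, loops = loops)
  })
  do.call(rbind, rows)
}
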