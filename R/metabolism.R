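#' Construct and validate a lin-log metabolic network
#'
#' A lin-log network consists of species with reference concentrations
#' `c0 > 0` (external species are clamped to the environment), reactions
#' with reference fluxes `J0`, relative enzyme levels `cE` (default 1),
#' stoichiometry and signed elasticity coefficients stored per role
#' (substrate, product, activator, inhibitor). Validation checks that every
#' species referenced by stoichiometry or elasticities exists, that all
#' `c0 > 0`, and that the supplied parameterization is steady-state
#' consistent: `N J0 = 0` on internal species to 1e-10 (all violations are
#' reported together).
#'
#' @param species data.frame with columns `name`, `c0`, `external`
#'   (logical).
#' @param reactions list; each element a list with `name`, `J0`, optional
#'   `cE`, `stoich` (named numeric, signed), `elasticities` (named list of
#'   named numerics keyed by role: `substrate`, `product`, `activator`,
#'   `inhibitor`).
#' @return object of class `vm_metnet` with the inputs plus the assembled
#'   stoichiometric matrix `N` (species x reactions) and elasticity matrix
#'   `E` (reactions x species, signed exactly as stored).
#' @export
vm_metabolic_network <- function(species, reactions) {
  probs <- character(0)
  sn <- species$name
  if (anyDuplicated(sn)) probs <- c(probs, "duplicated species names")
  bad <- sn[species$c0 <= 0]
  if (length(bad)) probs <- c(probs,
    paste0("non-positive c0 for: ", paste(bad, collapse = ", ")))
  nr <- length(reactions)
  N <- matrix(0, nrow = length(sn), ncol = nr,
              dimnames = list(sn, vapply(reactions, `[[`, "", "name")))
  E <- matrix(0, nrow = nr, ncol = length(sn),
              dimnames = list(colnames(N), sn))
  J0 <- numeric(nr); cE <- rep(1, nr)
  for (j in seq_len(nr)) {
    rx <- reactions[[j]]
    J0[j] <- rx$J0
    if (!is.null(rx$cE)) cE[j] <- rx$cE
    unknown <- setdiff(names(rx$stoich), sn)
    if (length(unknown)) probs <- c(probs, paste0(
      "reaction ", rx$name, ": unknown species in stoichiometry: ",
      paste(unknown, collapse = ", ")))
    known <- intersect(names(rx$stoich), sn)
    N[known, j] <- unlist(rx$stoich[known])
    for (role in names(rx$elasticities)) {
      el <- rx$elasticities[[role]]
      unknown <- setdiff(names(el), sn)
      if (length(unknown)) probs <- c(probs, paste0(
        "reaction ", rx$name, ": unknown species in ", role,
        " elasticities: ", paste(unknown, collapse = ", ")))
      known <- intersect(names(el), sn)
      E[j, known] <- E[j, known] + unlist(el[known])
    }
  }
  internal <- !species$external
  if (!length(probs)) {
    imb <- as.numeric(N[internal, , drop = FALSE] %*% J0)
    off <- abs(imb) > 1e-10 * max(1, max(abs(J0)))
    if (any(off)) probs <- c(probs, paste0(
      "reference fluxes not balanced (N J0 != 0) for species: ",
      paste(sn[internal][off], collapse = ", ")))
  }
  if (length(probs))
    stop("invalid metabolic network:\n  - ", paste(probs, collapse = "\n  - "))
  structure(list(species = species, reactions = reactions, N = N, E = E,
                 J0 = J0, cE = cE, internal = internal),
            class = "vm_metnet")
}

#' @export
print.vm_metnet <- function(x, ...) {
  cat(sprintf("<vm_metnet: %d species (%d external), %d reactions>\n",
              nrow(x$species), sum(x$species$external), length(x$J0)))
  invisible(x)
}

#' Lin-log reaction rate
#'
#' `r_j = J0_j (cE_j/cE0_j) (1 + sum_M eps_{M,j} ln(c_M / c0_M))`, with the
#' elasticities entering with exactly their stored signs (substrates and
#' activators typically positive, products and inhibitors negative). At the
#' reference state all logarithms vanish and `r = J0` exactly.
#'
#' @param network a `vm_metnet`.
#' @param x named (or ordered) vector of normalized concentrations `c/c0`
#'   (strictly positive).
#' @param reaction index or name; NULL (default) returns all rates.
#' @return flux in the units of `J0`.
#' @export
linlog_rate <- function(network, x, reaction = NULL) {
  x <- vm_check_state(network, x)
  r <- network$J0 * network$cE * (1 + as.numeric(network$E %*% log(x)))
  names(r) <- colnames(network$N)
  if (is.null(reaction)) r else r[reaction]
}

vm_check_state <- function(network, x) {
  sn <- network$species$name
  if (!is.null(names(x))) x <- x[sn]
  if (length(x) != length(sn) || any(is.na(x)))
    stop("state must provide all species: ", paste(sn, collapse = ", "))
  bad <- sn[x <= 0]
  if (length(bad))
    stop("non-positive normalized concentration for species: ",
         paste(bad, collapse = ", "))
  as.numeric(x)
}

#' Mass-balance right-hand side of the lin-log model
#'
#' `d(c/c0)/dt = diag(c0)^-1 N r(c/c0)` for internal species; clamped
#' external species have derivative exactly 0.
#'
#' @inheritParams linlog_rate
#' @return named derivative vector of the normalized concentrations.
#' @export
metabolic_rhs <- function(network, x) {
  xx <- vm_check_state(network, x)
  r <- network$J0 * network$cE * (1 + as.numeric(network$E %*% log(xx)))
  d <- as.numeric(network$N %*% r) / network$species$c0
  d[!network$internal] <- 0
  names(d) <- network$species$name
  d
}

#' Integrate the per-cell metabolic ODEs over a time interval
#'
#' Integrates the lin-log mass balances with external species clamped to
#' `environment`, using a stiff adaptive implicit integrator (lsoda) on
#' log-concentrations, which preserves positivity by construction.
#'
#' @param network a `vm_metnet`.
#' @param x initial normalized concentrations (named or ordered).
#' @param environment named vector of normalized concentrations for the
#'   external species (missing externals keep their current value).
#' @param duration_h integration time in hours (> 0).
#' @param rtol,atol integrator error control.
#' @return the normalized concentration vector at the end time.
#' @export
integrate_metabolism <- function(network, x, environment = NULL, duration_h,
                                 rtol = 1e-8, atol = 1e-10) {
  if (duration_h <= 0) stop("duration_h must be > 0")
  xx <- vm_check_state(network, x)
  sn <- network$species$name
  if (!is.null(environment)) {
    if (any(environment <= 0))
      stop("clamped environment concentrations must be > 0")
    ext <- intersect(names(environment), sn[!network$internal])
    xx[match(ext, sn)] <- environment[ext]
  }
  int <- network$internal
  if (!any(int)) return(stats::setNames(xx, sn))
  c0i <- network$species$c0[int]
  Ni <- network$N[int, , drop = FALSE]
  lx_ext <- log(xx); lx_ext[int] <- 0   # template holding clamped logs
  rhs <- function(t, y, parms) {
    ly <- lx_ext; ly[int] <- y
    r <- network$J0 * network$cE * (1 + as.numeric(network$E %*% ly))
    # d(log x)/dt = (1/x) d x/dt
    list(as.numeric(Ni %*% r) / c0i / exp(y))
  }
  sol <- deSolve::lsoda(y = log(xx[int]), times = c(0, duration_h),
                        func = rhs, parms = NULL, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("metabolic integration failed at t = ",
         sol[nrow(sol), 1], " h")
  xx[int] <- exp(sol[nrow(sol), -1])
  stats::setNames(xx, sn)
}

#' Steady-state and stability diagnostics of a lin-log network
#'
#' Because lin-log rates are linear in `ln(c/c0)`, the steady state of the
#' internal species under a clamped environment solves a linear system in
#' the log-concentrations; the Jacobian of the mass balances at any state is
#' likewise available in closed form. Reported: the steady state, the
#' Jacobian at the reference state and its eigenvalues (all real parts
#' negative implies local asymptotic stability).
#'
#' @param network a `vm_metnet`.
#' @param environment named normalized concentrations for external species
#'   (default: all at reference, 1).
#' @return list with `steady_state` (named vector on the normalized scale),
#'   `rates` at that state, `jacobian_ref`, `eigenvalues_ref`, `stable`.
#' @export
linlog_steady_state <- function(network, environment = NULL) {
  sn <- network$species$name
  int <- network$internal
  lx <- rep(0, length(sn))
  if (!is.null(environment)) {
    ext <- intersect(names(environment), sn[!int])
    lx[match(ext, sn)] <- log(environment[ext])
  }
  Jc <- network$J0 * network$cE
  Ni <- network$N[int, , drop = FALSE]
  A <- Ni %*% (Jc * network$E[, int, drop = FALSE])
  b <- -as.numeric(Ni %*% (Jc * (1 + as.numeric(
    network$E[, !int, drop = FALSE] %*% lx[!int]))))
  lint <- solve(A, b)
  lx[int] <- lint
  x <- exp(lx); names(x) <- sn
  rts <- linlog_rate(network, x)
  rev <- which(sign(rts) != sign(network$J0) & network$J0 != 0)
  if (length(rev))
    warning("lin-log rates reversed sign relative to their reference ",
            "fluxes at this steady state: ",
            paste(names(rts)[rev], collapse = ", "))
  # Jacobian of d x_int/dt wrt x_int at the reference state (x = 1)
  Jref <- (Ni %*% (Jc * network$E[, int, drop = FALSE])) /
    network$species$c0[int]
  ev <- eigen(Jref, only.values = TRUE)$values
  list(steady_state = x, rates = rts,
       jacobian_ref = Jref, eigenvalues_ref = ev,
       stable = all(Re(ev) < 0))
}

#' Bundled HEPG2-like central-carbon lin-log network (synthetic parameters)
#'
#' Encodes the canonical topology of HEPG2 central carbon metabolism:
#' glucose uptake into glycolysis (glucose -> g6p -> f16bp -> pyruvate),
#' the pentose-phosphate shunt branching at g6p via 6-phosphogluconate,
#' the lactate branch (Warburg overflow), and pyruvate entry into the
#' citric-acid cycle via Acetyl-CoA with an oxygen-consuming respiration
#' reaction. Reference fluxes are scaled to the cancer-cell glucose uptake
#' rate (3.3 mmol/(l h)); all elasticities and reference concentrations are
#' synthetic but internally consistent (flux-balanced reference state,
#' locally stable reference Jacobian). The file format accepts a full
#' published parameterization verbatim when available.
#'
#' @return a validated `vm_metnet`.
#' @export
hepg2_network <- function() {
  species <- data.frame(
    name = c("glc_ext", "o2_ext", "lac_ext", "g6p", "p6g", "f16bp", "pyr",
             "lac", "accoa"),
    c0 = c(5, 20, 1.5, 0.3, 0.02, 0.3, 0.1, 1.5, 0.05),
    external = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                 FALSE),
    stringsAsFactors = FALSE)
  rx <- list(
    list(name = "hk", J0 = 3.3,
         stoich = list(glc_ext = -1, g6p = 1),
         elasticities = list(substrate = list(glc_ext = 0.5),
                             product = list(g6p = -0.2))),
    list(name = "ppp_ox", J0 = 0.66,
         stoich = list(g6p = -1, p6g = 1),
         elasticities = list(substrate = list(g6p = 1),
                             product = list(p6g = -0.2))),
    list(name = "ppp_return", J0 = 0.66,
         stoich = list(p6g = -1, f16bp = 1),
         elasticities = list(substrate = list(p6g = 1))),
    list(name = "pfk", J0 = 2.64,
         stoich = list(g6p = -1, f16bp = 1),
         elasticities = list(substrate = list(g6p = 0.9),
                             product = list(f16bp = -0.2))),
    list(name = "pk", J0 = 3.3,
         stoich = list(f16bp = -1, pyr = 2),
         elasticities = list(substrate = list(f16bp = 0.8),
                             product = list(pyr = -0.2))),
    list(name = "ldh", J0 = 4.0,
         stoich = list(pyr = -1, lac = 1),
         elasticities = list(substrate = list(pyr = 1.2),
                             product = list(lac = -0.2))),
    list(name = "lac_export", J0 = 4.0,
         stoich = list(lac = -1, lac_ext = 1),
         elasticities = list(substrate = list(lac = 1),
                             product = list(lac_ext = -0.1))),
    list(name = "pdh", J0 = 2.6,
         stoich = list(pyr = -1, accoa = 1),
         elasticities = list(substrate = list(pyr = 1),
                             activator = list(o2_ext = 0.2),
                             product = list(accoa = -0.2))),
    list(name = "respiration", J0 = 2.6,
         stoich = list(accoa = -1, o2_ext = -6),
         elasticities = list(substrate = list(accoa = 1, o2_ext = 0.5))))
  vm_metabolic_network(species, rx)
}

#' Read a metabolic-network definition file
#'
#' YAML with blocks `species: [{name, c0, external}, ...]` and
#' `reactions: [{name, J0, cE, stoich: {species: coeff},
#' elasticities: {role: {species: eps}}}, ...]`. The file is validated by
#' [vm_metabolic_network()]; all violations are listed together.
#'
#' @param path file path.
#' @return a validated `vm_metnet`.
#' @export
load_network <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$species) || is.null(doc$reactions))
    stop("network file must have 'species' and 'reactions' blocks")
  species <- data.frame(
    name = vapply(doc$species, `[[`, "", "name"),
    c0 = vapply(doc$species, function(s) as.numeric(s$c0), 0),
    external = vapply(doc$species, function(s) isTRUE(s$external),
                      logical(1)),
    stringsAsFactors = FALSE)
  reactions <- lapply(doc$reactions, function(rx) {
    list(name = rx$name, J0 = as.numeric(rx$J0),
         cE = if (is.null(rx$cE)) 1 else as.numeric(rx$cE),
         stoich = lapply(rx$stoich, as.numeric),
         elasticities = lapply(rx$elasticities,
                               function(role) lapply(role, as.numeric)))
  })
  vm_metabolic_network(species, reactions)
}

#' Write a metabolic-network definition file
#'
#' Inverse of [load_network()]. Numbers are written with 17 significant
#' digits, so a save/load round trip reproduces the network bit-exactly.
#'
#' @param network a `vm_metnet`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_network <- function(network, path) {
  fmt <- function(v) {
    # keep full double precision through the YAML round trip
    if (is.numeric(v)) as.numeric(sprintf("%.17g", v)) else v
  }
  doc <- list(
    species = lapply(seq_len(nrow(network$species)), function(i) list(
      name = network$species$name[i], c0 = fmt(network$species$c0[i]),
      external = network$species$external[i])),
    reactions = lapply(network$reactions, function(rx) list(
      name = rx$name, J0 = fmt(rx$J0),
      cE = fmt(if (is.null(rx$cE)) 1 else rx$cE),
      stoich = lapply(rx$stoich, fmt),
      elasticities = lapply(rx$elasticities,
                            function(role) lapply(role, fmt)))))
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}

#' Reference normalized state of a network
#'
#' @param network a `vm_metnet`.
#' @return named vector of ones (the reference state on the `c/c0` scale).
#' @export
reference_state <- function(network) {
  stats::setNames(rep(1, nrow(network$species)), network$species$name)
}
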