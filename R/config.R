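#' Default simulation configuration
#'
#' Nested list with sections `lattice`, `cells`, `vasculature`, `field`
#' (one entry per species), `metabolism` and `run`. All values are in the
#' internal unit system (um, h, mmol/l); alternative-unit keys accepted by
#' [load_config()] (`d_cm2_s`, `km_mol_l`) are converted at load. The run
#' defaults encode the reference scenario: a 64^3 lattice with 20 um
#' spacing (1.28 mm cube) perfused by two countercurrent parent vessels,
#' confluent healthy tissue, and a small tumour implanted at the centre at
#' t = 0, simulated to 350 h.
#'
#' @return the resolved default configuration list.
#' @export
vm_default_config <- function() {
  list(
    lattice = list(dims = c(64, 64, 64), spacing_um = 20),
    cells = vm_default_cell_params(),
    vasculature = vm_default_vascular_params(),
    field = vm_default_field_params(),
    metabolism = list(
      enabled = TRUE,
      network_file = "",          # empty: bundled hepg2_network()
      rtol = 1e-8, atol = 1e-10,
      # the HEPG2 network describes cancer cells; "all" also assigns it to
      # normal cells
      cell_types = "cancer",
      # quiescent cancer cells keep the cancer uptake rate by default
      quiescent_cancer_uptake = "cancer",
      # the extracellular field sink (Michaelis-Menten) and the lin-log
      # uptake reaction are independent laws; "reconcile" rescales the hk
      # reference flux to the local Michaelis-Menten rate
      glucose_coupling = "clamped_extracellular"),
    run = list(
      seed = 1, dt_h = 0.5, end_time_h = 350, snapshot_every_h = 50,
      field_tol = 1e-8, field_picard_tol = 1e-7,
      burnin_h = 0, init_tissue = "confluent",
      implant_tumour = TRUE, tumour_radius_sites = 2,
      parent_radius_um = 10, parent_pressure_in = 25,
      parent_pressure_out = 15))
}

# deep merge of a user config into the defaults: unknown keys are rejected
# (exhaustively, with their paths), leaves are coerced to the default's
# type so YAML and JSON round trips normalize identically.
vm_merge_config <- function(default, user, path = character(0),
                            problems = new.env()) {
  open_keys <- c("faces")   # free-form sub-maps (e.g. Dirichlet faces)
  if (!is.list(default) || length(path) && path[length(path)] %in% open_keys) {
    return(vm_coerce_leaf(default, user, path, problems))
  }
  for (key in names(user)) {
    p <- c(path, key)
    if (!key %in% names(default)) {
      assign(paste(p, collapse = "."), TRUE, envir = problems)
      next
    }
    default[[key]] <- vm_merge_config(default[[key]], user[[key]], p,
                                      problems)
  }
  default
}

vm_coerce_leaf <- function(default, user, path, problems) {
  if (is.list(default) || is.null(default)) {
    # free-form map (under an open key): accept as numeric-valued list
    return(lapply(user, as.numeric))
  }
  v <- unlist(user, use.names = TRUE)
  if (is.numeric(default)) {
    v2 <- suppressWarnings(as.numeric(v))
    if (any(is.na(v2))) {
      assign(paste(c(path, "<not numeric>"), collapse = "."), TRUE,
             envir = problems)
      return(default)
    }
    if (!is.null(names(default))) {
      if (is.null(names(v)) && length(v2) == length(default)) {
        names(v2) <- names(default)
      } else {
        v2 <- stats::setNames(v2[names(default)], names(default))
      }
    }
    return(v2)
  }
  if (is.logical(default)) return(as.logical(v))
  as.character(v)
}

#' Load, validate and unit-convert a simulation configuration
#'
#' Reads a YAML configuration, merges it over [vm_default_config()]
#' (unknown keys are rejected with their full paths, all listed together),
#' applies unit conversions — `field.<species>.d_cm2_s` to um^2/h
#' (x 3.6e11) and `field.<species>.uptake.km_mol_l` to mmol/l (x 1000) —
#' and validates all invariants via [validate_config()].
#'
#' @param path YAML file path; NULL returns the validated defaults.
#' @return the resolved configuration with every default materialized.
#' @export
load_config <- function(path = NULL) {
  cfg <- vm_default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such file: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    # pull unit-suffixed keys out before the merge
    conv <- list()
    for (sp in names(user$field)) {
      f <- user$field[[sp]]
      if (!is.null(f$d_cm2_s)) {
        conv[[paste0("field.", sp, ".d_um2_h")]] <-
          as.numeric(f$d_cm2_s) * 3.6e11
        user$field[[sp]]$d_cm2_s <- NULL
      }
      if (!is.null(f$uptake$km_mol_l)) {
        conv[[paste0("field.", sp, ".uptake.km")]] <-
          as.numeric(f$uptake$km_mol_l) * 1000
        user$field[[sp]]$uptake$km_mol_l <- NULL
      }
    }
    problems <- new.env()
    cfg <- vm_merge_config(cfg, user, problems = problems)
    bad <- ls(problems)
    if (length(bad))
      stop("unknown configuration keys:\n  - ",
           paste(sort(bad), collapse = "\n  - "))
    for (key in names(conv)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      cfg[[parts]] <- conv[[key]]
    }
  }
  validate_config(cfg)
}

#' Validate a resolved configuration
#'
#' Checks all configuration invariants (positivity of rates, lengths and
#' times, threshold ordering, probability bounds) and returns the
#' configuration invisibly-validated; violations are listed exhaustively.
#'
#' @param cfg a configuration list in the shape of [vm_default_config()].
#' @return `cfg` (validated).
#' @export
validate_config <- function(cfg) {
  probs <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) probs <<- c(probs, msg)
  chk(length(cfg$lattice$dims) == 3 && all(cfg$lattice$dims >= 1),
      "lattice.dims must be three values >= 1")
  chk(cfg$lattice$spacing_um > 0, "lattice.spacing_um must be > 0")
  res <- tryCatch({ vm_check_cell_params(cfg$cells); NULL },
                  error = function(e) conditionMessage(e))
  if (!is.null(res)) probs <- c(probs, res)
  v <- cfg$vasculature
  chk(v$dx_max_um > 0, "vasculature.dx_max_um must be > 0")
  chk(v$sprout_p_max >= 0 && v$sprout_p_max <= 1,
      "vasculature.sprout_p_max must be in [0,1]")
  chk(v$r_min_um > 0 && v$r_max_um >= v$r_min_um,
      "vasculature radius bounds must satisfy 0 < r_min <= r_max")
  chk(v$viscosity > 0, "vasculature.viscosity must be > 0")
  for (sp in names(cfg$field)) {
    f <- cfg$field[[sp]]
    chk(f$d_um2_h > 0, paste0("field.", sp, ".d_um2_h must be > 0"))
    chk(f$perm_um_h >= 0, paste0("field.", sp, ".perm_um_h must be >= 0"))
    chk(f$c_blood >= 0, paste0("field.", sp, ".c_blood must be >= 0"))
    if (!is.null(f$uptake) && identical(f$uptake$kind, "michaelis")) {
      chk(all(f$uptake$rmax > 0) && f$uptake$km > 0,
          paste0("field.", sp, ".uptake rmax and km must be > 0"))
    }
  }
  chk(cfg$run$dt_h > 0, "run.dt_h must be > 0")
  chk(cfg$run$end_time_h >= 0, "run.end_time_h must be >= 0")
  chk(cfg$run$init_tissue %in% c("confluent", "empty"),
      "run.init_tissue must be 'confluent' or 'empty'")
  if (length(probs))
    stop("invalid configuration:\n  - ", paste(probs, collapse = "\n  - "))
  cfg
}
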