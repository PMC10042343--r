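# Scenario configuration: one YAML file = one reproducible run.
# Strict parsing (unknown keys rejected), bundled presets, CSV/JSON export
# and a parameter-sweep utility.

scenario_schema <- list(
  campbell = list(required = c("model", "campbell", "init", "integrator"),
                  optional = c("name")),
  lvhpr_only = list(required = c("model", "pair", "habitat", "init", "integrator"),
                    optional = c("name", "v")),
  one_energy = list(required = c("model", "pair", "habitat", "energy", "relay",
                                 "init", "integrator"),
                    optional = c("name", "virulence")),
  two_energy_three_pair = list(required = c("model", "pairs", "habitat", "energy",
                                            "relay_E1", "relay_E2", "init",
                                            "integrator"),
                               optional = c("name", "virulence"))
)

block_keys <- list(
  campbell = c("a1", "a2", "b1", "b2", "L"),
  pair = c("a1", "a0", "b1", "b0"),
  habitat = c("H", "kappa", "sigma", "q"),
  energy1 = c("alpha", "beta", "gamma", "d", "t0_degen"),
  energy2 = c("alpha1", "alpha2", "gamma1", "gamma2", "gamma3", "theta",
              "e2_gain_sign"),
  relay = c("E_lower", "E_upper", "state"),
  virulence = c("mode", "smooth_dt"),
  integrator = c("t_end", "rel_tol", "abs_tol", "max_step", "extinction_eps",
                 "clamp_energy", "sample_dt", "max_events")
)

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(bad, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

call_ctor <- function(ctor, x, where) {
  tryCatch(do.call(ctor, x),
           error = function(e) stop(sprintf("invalid block '%s': %s", where,
                                            conditionMessage(e)), call. = FALSE))
}

#' Build a validated scenario from a plain list
#'
#' Performs the same strict validation as [load_scenario()] but takes an
#' in-memory list (useful for programmatic sweeps).
#'
#' @param x Named list mirroring the YAML scenario layout.
#' @param name Optional scenario name (overrides `x$name`).
#' @return An object of class `lvhpr_scenario`.
#' @export
scenario_from_list <- function(x, name = NULL) {
  if (is.null(x$model))
    stop("scenario must name its 'model' variant", call. = FALSE)
  model <- match.arg(x$model, names(scenario_schema))
  sch <- scenario_schema[[model]]
  check_keys(x, c(sch$required, sch$optional), sprintf("scenario (%s)", model))
  missing <- setdiff(sch$required, names(x))
  if (length(missing))
    stop(sprintf("scenario (%s) is missing block(s): %s", model,
                 paste(missing, collapse = ", ")), call. = FALSE)

  out <- list(model = model, name = name %||% x$name %||% "unnamed")

  if (model == "campbell") {
    check_keys(x$campbell, block_keys$campbell, "campbell")
    out$campbell <- call_ctor(campbell_params, x$campbell, "campbell")
  }
  if (model %in% c("lvhpr_only", "one_energy")) {
    check_keys(x$pair, block_keys$pair, "pair")
    out$pair <- call_ctor(pair_params, x$pair, "pair")
  }
  if (model == "two_energy_three_pair") {
    if (!is.list(x$pairs) || length(x$pairs) != 3L)
      stop("'pairs' must list exactly 3 parameter blocks", call. = FALSE)
    out$pairs <- lapply(seq_len(3L), function(k) {
      check_keys(x$pairs[[k]], block_keys$pair, sprintf("pairs[%d]", k))
      call_ctor(pair_params, x$pairs[[k]], sprintf("pairs[%d]", k))
    })
  }
  if (model != "campbell") {
    check_keys(x$habitat, block_keys$habitat, "habitat")
    out$habitat <- call_ctor(habitat_params, x$habitat, "habitat")
  }
  if (model == "one_energy") {
    check_keys(x$energy, block_keys$energy1, "energy")
    out$energy <- call_ctor(energy1_params, x$energy, "energy")
  }
  if (model == "two_energy_three_pair") {
    check_keys(x$energy, block_keys$energy2, "energy")
    out$energy <- call_ctor(energy2_params, x$energy, "energy")
  }
  if (model == "lvhpr_only") out$v <- x$v %||% 1

  init_names <- switch(model,
    campbell = c("X1", "Y1"),
    lvhpr_only = c("X1", "Y1"),
    one_energy = c("X1", "Y1", "E1"),
    two_energy_three_pair = c("X1", "Y1", "X2", "Y2", "X3", "Y3", "E1", "E2"))
  check_keys(x$init, init_names, "init")
  if (!all(init_names %in% names(x$init)))
    stop(sprintf("init must provide: %s", paste(init_names, collapse = ", ")),
         call. = FALSE)
  out$init <- unlist(x$init)[init_names]

  relay_from <- function(blk, E0, where) {
    check_keys(blk, block_keys$relay, where)
    call_ctor(virulence_relay,
              c(blk[setdiff(names(blk), "state")],
                list(state = blk$state, E0 = E0)), where)
  }
  if (model == "one_energy")
    out$relay <- relay_from(x$relay, out$init[["E1"]], "relay")
  if (model == "two_energy_three_pair") {
    out$relay_E1 <- relay_from(x$relay_E1, out$init[["E1"]], "relay_E1")
    out$relay_E2 <- relay_from(x$relay_E2, out$init[["E2"]], "relay_E2")
  }

  if (!is.null(x$virulence)) {
    check_keys(x$virulence, block_keys$virulence, "virulence")
    mode <- match.arg(x$virulence$mode %||% "step", c("step", "smooth"))
    out$smooth_dt <- if (mode == "smooth") {
      sdt <- x$virulence$smooth_dt %||% 1
      if (sdt <= 0) stop("virulence smooth_dt must be > 0", call. = FALSE)
      sdt
    } else 0
  } else out$smooth_dt <- 0

  check_keys(x$integrator, block_keys$integrator, "integrator")
  out$integrator <- call_ctor(integrator_config, x$integrator, "integrator")

  structure(out, class = "lvhpr_scenario")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load and validate a scenario configuration file
#'
#' Reads a YAML scenario (one file = one run) and validates it strictly:
#' unknown keys anywhere are rejected, required blocks per model variant
#' are checked, and every parameter invariant is enforced by the
#' corresponding constructor.
#'
#' @param path Path to a YAML scenario file, or the name of a bundled
#'   preset (see [lvhpr_presets()]).
#' @return An object of class `lvhpr_scenario`.
#' @seealso [run_scenario()], [write_scenario()], [lvhpr_presets()]
#' @export
#' @examples
#' sc <- load_scenario("one_energy_homeostasis")
#' sc$habitat$H  # 4
load_scenario <- function(path) {
  if (!file.exists(path)) {
    preset <- preset_path(path)
    if (is.na(preset))
      stop(sprintf("no such file or preset: '%s'", path), call. = FALSE)
    path <- preset
  }
  x <- yaml::read_yaml(path)
  scenario_from_list(x, name = x$name %||% sub("\\.ya?ml$", "", basename(path)))
}

#' Serialise a scenario back to YAML
#'
#' Writes the scenario in the same layout [load_scenario()] reads, so
#' load -> write -> load is the identity.
#'
#' @param sc An `lvhpr_scenario`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(sc, path) {
  stopifnot(inherits(sc, "lvhpr_scenario"))
  strip <- function(obj, drop = character(0)) {
    x <- unclass(obj)
    x[setdiff(names(x), drop)]
  }
  x <- list(name = sc$name, model = sc$model)
  for (blk in c("campbell", "pair", "habitat", "energy", "relay",
                "relay_E1", "relay_E2")) {
    if (!is.null(sc[[blk]])) x[[blk]] <- strip(sc[[blk]])
  }
  if (!is.null(sc[["pairs"]])) x$pairs <- lapply(sc$pairs, strip)
  if (!is.null(sc[["v"]]) && sc$model == "lvhpr_only") x$v <- sc$v
  if (sc$smooth_dt > 0)
    x$virulence <- list(mode = "smooth", smooth_dt = sc$smooth_dt)
  x$init <- as.list(sc$init)
  icfg <- strip(sc$integrator)
  x$integrator <- icfg[!vapply(icfg, is.null, logical(1))]
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

preset_dir <- function() system.file("extdata", "presets", package = "lvhpr")

preset_path <- function(name) {
  p <- file.path(preset_dir(), paste0(name, ".yaml"))
  if (file.exists(p)) p else NA_character_
}

#' List bundled scenario presets
#'
#' Presets realise the qualitative regimes of the models: sustained
#' one-energy homeostasis, degeneration-driven collapse, the two-energy
#' three-pair stabilised life cycle, and the plain host-nested pair. Their
#' rate constants are package choices documented in the methods vignette.
#'
#' @return Character vector of preset names usable with [load_scenario()].
#' @export
lvhpr_presets <- function() {
  sub("\\.yaml$", "", list.files(preset_dir(), pattern = "\\.yaml$"))
}

#' Copy a bundled preset to a writable location
#'
#' @param name Preset name (see [lvhpr_presets()]).
#' @param dest Destination file or directory.
#' @return The destination path, invisibly.
#' @export
copy_preset <- function(name, dest = ".") {
  src <- preset_path(name)
  if (is.na(src)) stop(sprintf("no such preset: '%s'", name), call. = FALSE)
  if (dir.exists(dest)) dest <- file.path(dest, basename(src))
  file.copy(src, dest, overwrite = TRUE)
  invisible(dest)
}

scenario_args <- function(sc) {
  params <- switch(sc$model,
    campbell = list(campbell = sc$campbell),
    lvhpr_only = list(pair = sc$pair, habitat = sc$habitat, v = sc$v),
    one_energy = list(pair = sc$pair, habitat = sc$habitat,
                      energy = sc$energy, relay = sc$relay),
    two_energy_three_pair = list(pairs = sc$pairs, habitat = sc$habitat,
                                 energy = sc$energy, relay_E1 = sc$relay_E1,
                                 relay_E2 = sc$relay_E2))
  list(model = sc$model, params = params, init = sc$init,
       cfg = sc$integrator, smooth_dt = sc$smooth_dt)
}

#' Analytic equilibria of a scenario
#'
#' @param sc An `lvhpr_scenario` (or path/preset name).
#' @return An `lvhpr_equilibrium`, or a list of three for the three-pair
#'   model.
#' @export
scenario_equilibria <- function(sc) {
  if (is.character(sc)) sc <- load_scenario(sc)
  stopifnot(inherits(sc, "lvhpr_scenario"))
  switch(sc$model,
    campbell = campbell_equilibrium(sc$campbell),
    lvhpr_only = lvhpr_equilibrium(sc$pair, sc$habitat),
    one_energy = lvhpr_equilibrium(sc$pair, sc$habitat),
    two_energy_three_pair = three_pair_equilibrium(sc$pairs, sc$habitat))
}

#' Run a scenario and optionally export its outputs
#'
#' Integrates the scenario and summarises it. With `outdir` set, writes
#' `trajectory.csv` (columns `t`, populations, energies, virulences,
#' `gamma_t` as applicable; fixed order), `events.csv` and
#' `summary.json`. Reruns with the same scenario are bit-identical.
#'
#' @param sc An `lvhpr_scenario`, or a path/preset name for
#'   [load_scenario()].
#' @param outdir Output directory (created if needed), or `NULL` to skip
#'   file export.
#' @return Invisibly, `list(trajectory =, summary =)`.
#' @export
run_scenario <- function(sc, outdir = NULL) {
  if (is.character(sc)) sc <- load_scenario(sc)
  stopifnot(inherits(sc, "lvhpr_scenario"))
  a <- scenario_args(sc)
  traj <- integrate_model(a$model, a$params, a$init, a$cfg, a$smooth_dt)
  summ <- summarize_run(traj)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(traj$states, file.path(outdir, "trajectory.csv"),
                     row.names = FALSE)
    utils::write.csv(traj$events, file.path(outdir, "events.csv"),
                     row.names = FALSE)
    sj <- list(scenario = sc$name, model = sc$model,
               collapse_time = summ$collapse_time,
               n_switches = as.list(summ$n_switches),
               duty_cycle = as.list(summ$duty_cycle),
               equilibrium_deviation = summ$equilibrium_deviation,
               late_means = as.list(summ$late_means),
               terminal_state = as.list(summ$terminal_state))
    jsonlite::write_json(sj, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  }
  invisible(list(trajectory = traj, summary = summ))
}

set_in <- function(x, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(keys) == 1L) { x[[keys]] <- value; return(x) }
  x[[keys[1]]] <- set_in(x[[keys[1]]], paste(keys[-1], collapse = "."), value)
  x
}

#' Sweep one parameter over a grid of values
#'
#' Reruns a base scenario with one parameter (addressed by a dotted path
#' such as `"habitat.H"` or `"energy.d"`) replaced by each grid value, and
#' collects one summary row per run. Individual run failures are recorded
#' in the `error` column and the sweep continues.
#'
#' @param sc Base scenario (`lvhpr_scenario` or path/preset name).
#' @param param Dotted path of the swept parameter.
#' @param values Non-empty numeric vector of finite grid values.
#' @param out_csv Optional path: write the table as CSV (swept value in
#'   the first column).
#' @return A data frame: `value`, `collapse_time`, switch counts, duty
#'   cycles, `equilibrium_deviation`, late-window population means,
#'   `error`.
#' @export
#' @examples
#' \donttest{
#' sweep_scenario("lvhpr_only", "habitat.H", c(1, 2, 4))
#' }
sweep_scenario <- function(sc, param, values, out_csv = NULL) {
  if (is.character(sc)) sc <- load_scenario(sc)
  stopifnot(inherits(sc, "lvhpr_scenario"))
  if (!length(values) || any(!is.finite(values)))
    stop("'values' must be a non-empty vector of finite values", call. = FALSE)
  # round-trip through the list form so constructors revalidate each run
  base <- yaml::yaml.load(yaml::as.yaml(scenario_to_list(sc), precision = 15L))
  rows <- lapply(values, function(v) {
    res <- tryCatch({
      sci <- scenario_from_list(set_in(base, param, v), name = sc$name)
      r <- run_scenario(sci)
      s <- r$summary
      cbind(data.frame(value = v, collapse_time = s$collapse_time),
            as.data.frame(as.list(c(
              if (length(s$n_switches))
                stats::setNames(as.numeric(s$n_switches),
                                paste0("n_switches_", names(s$n_switches))),
              if (length(s$duty_cycle))
                stats::setNames(s$duty_cycle,
                                paste0("duty_", names(s$duty_cycle))),
              equilibrium_deviation = s$equilibrium_deviation,
              stats::setNames(s$late_means,
                              paste0("late_", names(s$late_means)))))),
            data.frame(error = NA_character_))
    }, error = function(e) {
      data.frame(value = v, collapse_time = NA_real_,
                 error = conditionMessage(e))
    })
    res
  })
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (m in setdiff(all_cols, names(r))) r[[m]] <- NA
    r[all_cols]
  })
  tab <- do.call(rbind, rows)
  if (!is.null(out_csv)) utils::write.csv(tab, out_csv, row.names = FALSE)
  tab
}

# inverse of scenario_from_list (list layout identical to the YAML file)
scenario_to_list <- function(sc) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_scenario(sc, tmp)
  yaml::read_yaml(tmp)
}

#' @export
print.lvhpr_scenario <- function(x, ...) {
  cat(sprintf("<lvhpr_scenario> '%s': model = %s, t_end = %g\n",
              x$name, x$model, x$integrator$t_end))
  invisible(x)
}
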