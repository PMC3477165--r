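# Stochastic dynamics: Maxwell-Boltzmann initialisation, SHAKE constraints,
# a symmetric Langevin velocity-Verlet integrator (exactly velocity-Verlet
# at zero friction), steepest-descent minimisation, and the simulation
# pipeline partition -> topology -> walls -> minimise -> dynamics.

#' Run configuration
#'
#' Defaults are the standard study conditions of the scheme: 2 fs timestep,
#' 300 K, inverse friction constant 0.4 ps, 1.6 nm nonbonded cutoffs, 0.5 /
#' 0.6 nm region cutoffs, 3.1 nm membrane slab with a 2.0 nm water margin
#' and r_p = 0.2 nm walls.
#'
#' @param timestep integration step (ps).
#' @param n_steps number of SD steps (>= 0).
#' @param temperature target temperature (K).
#' @param tau inverse friction constant (ps); 0 disables friction and noise
#'   (NVE velocity-Verlet).
#' @param seed RNG seed for velocities and noise.
#' @param cutoff nonbonded cutoff (nm).
#' @param mm_cutoff,interface_cutoff region cutoffs (nm).
#' @param native_contact_cutoff Go contact cutoff (nm).
#' @param K_b,V_0,B_const Go-model parameters.
#' @param membrane_thickness,water_margin,r_p,beta,wall_eps,wall_sigma,d_rep,f_max
#'   wall parameters (see [build_walls()]).
#' @param out_stride store a frame every this many steps.
#' @param vel_stride store velocities every this many steps (0 = never).
#' @param skin neighbour-list skin (nm).
#' @param nb_rebuild rebuild the pair list every this many steps.
#' @param shake_tol,shake_maxiter SHAKE relative tolerance and iteration cap.
#' @param minimize steepest-descent minimise before dynamics.
#' @param min_tol stop minimising below this max force (kJ mol-1 nm-1).
#' @param min_maxiter maximum minimisation steps.
#' @param pbc,box optional periodic minimum image for nonbonded terms.
#' @return an object of class `mmcg_config`.
#' @export
mmcg_config <- function(timestep = 0.002, n_steps = 1000L, temperature = 300,
                        tau = 0.4, seed = 1L, cutoff = 1.6, mm_cutoff = 0.5,
                        interface_cutoff = 0.6, native_contact_cutoff = 1.2,
                        K_b = 1000, V_0 = 5.3, B_const = 5,
                        membrane_thickness = 3.1, water_margin = 2.0,
                        r_p = 0.2, beta = 50, wall_eps = 1.0,
                        wall_sigma = 0.17, d_rep = 0.7, f_max = 1000,
                        out_stride = 100L, vel_stride = 0L, skin = 0.2,
                        nb_rebuild = 10L, shake_tol = 1e-6,
                        shake_maxiter = 500L, minimize = TRUE, min_tol = 100,
                        min_maxiter = 200L, pbc = FALSE, box = NULL) {
  stopifnot(timestep > 0, tau >= 0, n_steps >= 0)
  structure(as.list(environment()), class = "mmcg_config")
}

#' Read / write a run configuration
#'
#' Plain `key = value` text files; unknown keys are rejected.
#'
#' @param path file path.
#' @return an `mmcg_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  known <- names(formals(mmcg_config))
  bad <- setdiff(keys, known)
  if (length(bad) > 0) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  args <- lapply(seq_along(keys), function(k) {
    v <- vals[k]
    if (v %in% c("TRUE", "FALSE")) as.logical(v)
    else if (grepl("^[-0-9.eE, ]+$", v) && grepl(",", v))
      as.numeric(strsplit(v, ",")[[1]])
    else suppressWarnings(if (!is.na(as.numeric(v))) as.numeric(v) else v)
  })
  names(args) <- keys
  do.call(mmcg_config, args)
}

#' @rdname read_run_config
#' @param config an `mmcg_config`.
#' @export
write_run_config <- function(config, path) {
  ln <- vapply(names(config), function(k) {
    v <- config[[k]]
    if (is.null(v)) return(NA_character_)
    paste0(k, " = ", paste(v, collapse = ","))
  }, "")
  writeLines(ln[!is.na(ln)], path)
  invisible(path)
}

#' Maxwell-Boltzmann velocities
#'
#' Each component is drawn from `N(0, kB T / m)` and the mass-weighted
#' center-of-mass velocity is removed. Deterministic for a fixed seed.
#'
#' @param structure an `mmcg_structure` (masses in amu).
#' @param temperature target temperature (K).
#' @param seed RNG seed (optional; uses the session RNG state if NULL).
#' @return `n x 3` velocity matrix (nm/ps).
#' @export
init_velocities <- function(structure, temperature = 300, seed = NULL) {
  m <- structure$atoms$mass
  if (any(m <= 0)) stop("non-positive mass")
  if (!is.null(seed)) set.seed(seed)
  n <- length(m)
  if (temperature <= 0) return(matrix(0, n, 3))
  sdv <- sqrt(.kB * temperature / m)
  v <- matrix(rnorm(3 * n), n, 3) * sdv
  vcom <- colSums(v * m) / sum(m)
  sweep(v, 2, vcom)
}

#' SHAKE constraint solver
#'
#' Iteratively corrects `positions_new` so every constrained distance
#' matches its target within a relative tolerance; corrections are applied
#' along the old bond vectors with mass weighting.
#'
#' @param positions_old reference positions satisfying the constraints.
#' @param positions_new positions after an unconstrained update.
#' @param constraints data frame with columns `i`, `j`, `d` (nm), e.g.
#'   `topology$constraints`.
#' @param masses atomic masses (amu).
#' @param tol relative tolerance on each constrained distance.
#' @param max_iter iteration cap; non-convergence raises an error reporting
#'   the worst violation.
#' @return corrected `n x 3` position matrix.
#' @export
shake <- function(positions_old, positions_new, constraints, masses,
                  tol = 1e-6, max_iter = 500L) {
  if (nrow(constraints) == 0) return(positions_new)
  cpp_shake(positions_old, positions_new, .pairs_mat(constraints),
            as.numeric(constraints$d), 1 / masses, tol, as.integer(max_iter))
}

#' Simulation state
#'
#' @param positions,velocities `n x 3` matrices (nm, nm/ps).
#' @param time time (ps).
#' @param step step counter.
#' @param forces optional `n x 3` force matrix.
#' @param temperature instantaneous temperature (K), if known.
#' @return an object of class `mmcg_state`.
#' @export
mmcg_state <- function(positions, velocities, time = 0, step = 0L,
                       forces = NULL, temperature = NA_real_) {
  stopifnot(all(dim(positions) == dim(velocities)))
  structure(list(positions = positions, velocities = velocities, time = time,
                 step = as.integer(step), forces = forces,
                 temperature = temperature), class = "mmcg_state")
}

#' @export
print.mmcg_state <- function(x, ...) {
  cat("MM/CG state:", nrow(x$positions), "atoms, t =", x$time, "ps, step",
      x$step, if (!is.na(x$temperature)) paste0(", T = ",
                                                signif(x$temperature, 4), " K"),
      "\n")
  invisible(x)
}

# shared wrapper around the compiled SD loop
#' @noRd
.run_sd <- function(positions, velocities, topology, wallset, config, n_steps,
                    out_stride = NULL, vel_stride = NULL) {
  tc <- .topo_cpp(topology, cutoff = config$cutoff, pbc = config$pbc,
                  box = config$box)
  wl <- NULL
  if (!is.null(wallset)) {
    if (is.null(wallset$coupled))
      stop("wall set has no coupled-atom list; use wall_coupled_atoms()")
    cc <- .coupled_cpp(wallset$coupled)
    tc$wall_idx <- cc$idx0
    tc$wall_mode <- cc$mode
    wl <- .wall_cpp(wallset)
  }
  n <- nrow(positions)
  ncons <- nrow(topology$constraints)
  # one dof per scalar constraint; subtract the conserved center-of-mass
  # momentum only in the frictionless (NVE) case
  ndof <- 3L * n - ncons - if (config$tau > 0) 0L else 3L
  cpp_run_sd(positions, velocities, tc, wl, config$timestep,
             as.integer(n_steps), config$temperature, config$tau,
             as.integer(out_stride %||% config$out_stride),
             as.integer(vel_stride %||% config$vel_stride),
             as.integer(config$nb_rebuild), config$skin, config$shake_tol,
             as.integer(config$shake_maxiter), as.integer(ndof))
}

#' One stochastic-dynamics step
#'
#' Advances the state by a single Langevin velocity-Verlet step (OBABO
#' splitting) with friction `1/tau` and noise satisfying
#' fluctuation-dissipation at the target temperature, followed by SHAKE.
#' With `tau = 0` the step is exactly velocity-Verlet. Uses the R session
#' RNG (seed with `set.seed()` for reproducibility).
#'
#' @param state an `mmcg_state`.
#' @param topology an `mmcg_topology`.
#' @param wallset an `mmcg_wallset` or NULL.
#' @param config an `mmcg_config`.
#' @return the advanced `mmcg_state`.
#' @export
sd_step <- function(state, topology, wallset, config) {
  res <- .run_sd(state$positions, state$velocities, topology, wallset, config,
                 n_steps = 1L, out_stride = 1L)
  mmcg_state(res$positions, res$velocities, time = state$time + config$timestep,
             step = state$step + 1L, forces = res$forces,
             temperature = res$temperature)
}

#' Steepest-descent minimisation
#'
#' Fixed-form steepest descent with adaptive step size, stopping when the
#' maximum per-atom force drops below `tol` or after `max_iter` steps.
#'
#' @param positions `n x 3` matrix (nm).
#' @param topology an `mmcg_topology`.
#' @param wallset optional `mmcg_wallset`.
#' @param step0 initial displacement of the largest-force atom (nm).
#' @param tol force tolerance (kJ mol-1 nm-1).
#' @param max_iter iteration cap.
#' @param cutoff,pbc,box as in [total_energy()].
#' @return list with `positions`, `energy`, `max_force`, `iterations`.
#' @export
minimize_sd <- function(positions, topology, wallset = NULL, step0 = 0.01,
                        tol = 100, max_iter = 200L, cutoff = 1.6,
                        pbc = FALSE, box = NULL) {
  x <- positions
  ev <- total_energy(x, topology, wallset, cutoff = cutoff, pbc = pbc, box = box)
  e <- ev$report$total
  h <- step0
  it <- 0L
  repeat {
    fmax <- max(abs(ev$forces))
    if (fmax < tol || it >= max_iter) break
    xt <- x + ev$forces * (h / fmax)
    # re-impose constraints after the trial move
    if (nrow(topology$constraints) > 0)
      xt <- shake(x, xt, topology$constraints, topology$mass)
    evt <- total_energy(xt, topology, wallset, cutoff = cutoff, pbc = pbc,
                        box = box)
    if (evt$report$total < e) {
      x <- xt; ev <- evt; e <- evt$report$total; h <- min(h * 1.2, 0.05)
    } else {
      h <- h / 2
      if (h < 1e-7) break
    }
    it <- it + 1L
  }
  list(positions = x, energy = e, max_force = max(abs(ev$forces)),
       iterations = it)
}

#' Run an MM/CG simulation
#'
#' The full pipeline: region assignment (when a ligand is present), hybrid
#' topology construction, wall construction, steepest-descent minimisation,
#' Maxwell-Boltzmann velocities, and `n_steps` of stochastic dynamics.
#' Fully reproducible for a fixed seed.
#'
#' @param structure an `mmcg_structure`, or a checkpoint from
#'   [save_checkpoint()] via `restart`.
#' @param config an `mmcg_config`.
#' @param mm_params an `mmcg_params`; defaults to the built-in toy set.
#' @param regions precomputed `mmcg_regions` (otherwise derived from the
#'   structure's ligand flag, or trivially atomistic without a ligand).
#' @param wallset precomputed `mmcg_wallset`; `NULL` builds walls from the
#'   structure when it has protein C-alphas, else runs without walls.
#' @param walls set to FALSE to force a wall-free run.
#' @param restart optional checkpoint path to resume positions/velocities.
#' @param verbose print stage progress.
#' @return an object of class `mmcg_run`: `trajectory` (an
#'   `mmcg_trajectory` with per-frame energies), `state`, `regions`,
#'   `topology`, `wallset`, `config`.
#' @export
run_simulation <- function(structure, config = mmcg_config(),
                           mm_params = NULL, regions = NULL, wallset = NULL,
                           walls = TRUE, restart = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message("mmcg: ", ...)
  a <- structure$atoms
  has_prot <- any(!a$is_water & !a$is_ligand)
  has_lig <- any(a$is_ligand)
  stage <- "partition"
  res <- tryCatch({
    if (is.null(regions)) {
      regions <- if (has_prot && has_lig)
        assign_regions(structure, "ligand", config$mm_cutoff,
                       config$interface_cutoff)
      else .trivial_regions(structure)
    }
    say("regions: ", paste(utils::capture.output(print(regions)),
                           collapse = ""))

    stage <- "topology"
    topology <- build_hybrid_topology(
      structure, regions,
      go_params = list(K_b = config$K_b, V_0 = config$V_0,
                       B_const = config$B_const),
      native_contact_cutoff = config$native_contact_cutoff,
      mm_params = mm_params)

    stage <- "walls"
    if (isFALSE(walls)) wallset <- NULL
    else if (is.null(wallset) && has_prot) {
      wallset <- build_walls(structure,
                             membrane_thickness = config$membrane_thickness,
                             water_margin = config$water_margin,
                             r_p = config$r_p, beta = config$beta,
                             eps = config$wall_eps, sigma = config$wall_sigma,
                             d_rep = config$d_rep, f_max = config$f_max)
    }
    if (!is.null(wallset) && is.null(wallset$coupled))
      wallset$coupled <- wall_coupled_atoms(structure, wallset)

    set.seed(config$seed)
    x <- coords(structure)
    v <- NULL
    if (!is.null(restart)) {
      chk <- load_checkpoint(restart)
      x <- chk$positions
      v <- chk$velocities
    }

    stage <- "minimisation"
    if (config$minimize && is.null(restart)) {
      mn <- minimize_sd(x, topology, wallset, tol = config$min_tol,
                        max_iter = config$min_maxiter, cutoff = config$cutoff,
                        pbc = config$pbc, box = config$box)
      x <- mn$positions
      say("minimised to max force ", signif(mn$max_force, 4), " in ",
          mn$iterations, " steps")
    }

    stage <- "velocities"
    if (is.null(v)) v <- init_velocities(structure, config$temperature)

    stage <- "dynamics"
    out <- .run_sd(x, v, topology, wallset, config, n_steps = config$n_steps)
    nf <- out$n_frames
    frames <- array(out$frames, dim = dim(out$frames))[, , seq_len(nf), drop = FALSE]
    etab <- as.data.frame(out$energies[seq_len(nf), , drop = FALSE])
    names(etab) <- c("time", "e_mm", "e_i", "e_mmi", "e_cg", "e_cgi",
                     "e_wall", "e_pot", "e_kin", "temperature", "e_total")
    vel <- NULL; vt <- NULL
    if (config$vel_stride > 0) {
      nv <- out$n_vframes
      vel <- array(out$vframes, dim = dim(out$vframes))[, , seq_len(nv), drop = FALSE]
      vt <- out$vtimes[seq_len(nv)]
    }
    traj <- mmcg_trajectory(structure, frames, out$frame_times[seq_len(nf)],
                            velocities = vel, vtimes = vt, energies = etab)
    state <- mmcg_state(out$positions, out$velocities,
                        time = config$n_steps * config$timestep,
                        step = config$n_steps, forces = out$forces,
                        temperature = out$temperature)
    structure(list(trajectory = traj, state = state, regions = regions,
                   topology = topology, wallset = wallset, config = config),
              class = "mmcg_run")
  }, error = function(e) {
    stop("simulation aborted at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  res
}

#' @export
print.mmcg_run <- function(x, ...) {
  cat("MM/CG run:", x$config$n_steps, "steps of", x$config$timestep * 1000,
      "fs at", x$config$temperature, "K;",
      n_frames(x$trajectory), "stored frames\n")
  invisible(x)
}

#' Save / load a simulation checkpoint
#'
#' Plain-text (TSV) positions and velocities for restarting runs.
#'
#' @param state an `mmcg_state`.
#' @param path file path.
#' @export
save_checkpoint <- function(state, path) {
  df <- data.frame(x = state$positions[, 1], y = state$positions[, 2],
                   z = state$positions[, 3], vx = state$velocities[, 1],
                   vy = state$velocities[, 2], vz = state$velocities[, 3])
  attr(df, "time") <- state$time
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mmcg checkpoint t= %.8f ps step= %d", state$time,
                     state$step), con)
  write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  hdr <- readLines(path, n = 1)
  tm <- as.numeric(sub(".*t= ([0-9.eE+-]+) ps.*", "\\1", hdr))
  stp <- as.integer(sub(".*step= ([0-9]+).*", "\\1", hdr))
  df <- read.table(path, header = TRUE, sep = "\t", skip = 1)
  mmcg_state(unname(as.matrix(df[, c("x", "y", "z")])),
             unname(as.matrix(df[, c("vx", "vy", "vz")])),
             time = tm, step = stp)
}
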