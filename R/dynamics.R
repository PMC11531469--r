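## Langevin (BAOAB) dynamics and temperature replica exchange.

#' Langevin run parameters
#'
#' @param n_steps Number of integration steps.
#' @param timestep Timestep in intrinsic time units (1 unit ~ 48.9 fs; the
#'   default 0.3 corresponds to ~14.7 fs).
#' @param temperature Thermostat temperature, K.
#' @param friction Langevin friction, inverse time units.
#' @param seed Integer seed for the thermostat noise.
#' @param save_interval Steps between saved frames.
#' @return Object of class `langevin_params`.
#' @export
langevin_params <- function(n_steps, timestep = 0.3, temperature = 300,
                            friction = 0.843, seed = 1, save_interval = 100) {
  stopifnot(timestep > 0, friction > 0, n_steps >= 1, save_interval >= 1)
  structure(list(n_steps = as.integer(n_steps), timestep = timestep,
                 temperature = temperature, friction = friction,
                 seed = seed, save_interval = as.integer(save_interval)),
            class = "langevin_params")
}

new_trajectory <- function(frames, step_ids, epot, ekin, params, metadata = list()) {
  structure(list(frames = frames, step_ids = step_ids, epot = epot,
                 ekin = ekin, params = params, metadata = metadata),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("cg_trajectory: %d frames x %d beads (steps %d..%d)\n",
              d[1], d[2], if (length(x$step_ids)) min(x$step_ids) else NA,
              if (length(x$step_ids)) max(x$step_ids) else NA))
  invisible(x)
}

n_frames <- function(traj) dim(traj$frames)[1]

#' Extract one frame of a trajectory
#'
#' @param traj A `cg_trajectory`.
#' @param f Frame number.
#' @return N x 3 coordinate matrix.
#' @export
traj_frame <- function(traj, f) {
  matrix(traj$frames[f, , ], ncol = 3)
}

#' Run Langevin dynamics
#'
#' Propagates a `cg_system` with the BAOAB splitting of Langevin dynamics.
#' Identical seeds give identical trajectories. If the potential energy
#' diverges the run stops and the trajectory is truncated to the last stable
#' frame (flagged in `metadata$diverged`).
#'
#' @param system A [cg_system()].
#' @param params A [langevin_params()].
#' @param coords,vels Optional initial conditions; velocities are drawn from
#'   the Maxwell distribution at the run temperature when omitted.
#' @return A `cg_trajectory` with per-frame potential and kinetic energies.
#' @export
run_langevin <- function(system, params, coords = system$coords, vels = NULL) {
  e0 <- total_energy_forces(system, coords)$breakdown$total
  if (!is.finite(e0)) stop("non-finite initial energy")
  res <- cpp_langevin(coords, vels, system$compiled, params$n_steps,
                      params$timestep, KB * params$temperature,
                      params$friction, params$save_interval, params$seed)
  new_trajectory(res$frames, res$step_ids, res$epot, res$ekin, params,
                 metadata = list(diverged = res$diverged,
                                 coords_last = res$coords_last,
                                 vels_last = res$vels_last,
                                 temperature = params$temperature,
                                 seed = params$seed,
                                 timestep = params$timestep,
                                 friction = params$friction,
                                 engine = "cgfork-BAOAB"))
}

#' Kinetic temperature of a trajectory
#'
#' @param traj A `cg_trajectory`.
#' @param burn_in Fraction of initial frames discarded.
#' @return Mean kinetic temperature in K (2 <KE> / (3 N kB)).
#' @export
kinetic_temperature <- function(traj, burn_in = 0.2) {
  n <- dim(traj$frames)[2]
  keep <- seq_len(length(traj$ekin)) > burn_in * length(traj$ekin)
  mean(traj$ekin[keep]) * 2 / (3 * n * KB)
}

#' Replica-exchange schedule
#'
#' @param temperatures Strictly increasing temperatures, K (>= 2 replicas).
#' @param exchange_interval Steps between exchange attempts.
#' @param seed Seed for the exchange decisions.
#' @return Object of class `replica_schedule`.
#' @export
replica_schedule <- function(temperatures, exchange_interval = 1000, seed = 1) {
  stopifnot(length(temperatures) >= 2, all(diff(temperatures) >= 0))
  structure(list(temperatures = temperatures,
                 exchange_interval = as.integer(exchange_interval),
                 seed = seed), class = "replica_schedule")
}

#' Run temperature replica-exchange molecular dynamics
#'
#' Runs one Langevin replica per temperature rung with neighbour-pair
#' Metropolis exchanges (acceptance min(1, exp((beta_i - beta_j)(E_i - E_j))))
#' at fixed intervals, alternating even/odd pairings. Configurations are
#' swapped on acceptance with velocity rescaling. Both the per-temperature
#' trajectories (returned) and the per-replica paths (recoverable from the
#' exchange log's replica map) are tracked.
#'
#' @param system A [cg_system()].
#' @param schedule A [replica_schedule()].
#' @param params A [langevin_params()]; its temperature is ignored, its
#'   n_steps is the total per-replica step count.
#' @return List with `trajectories` (one `cg_trajectory` per temperature,
#'   continuous in temperature), `exchange_log` (data frame), `replica_map`
#'   (rounds x rungs matrix of replica ids) and `acceptance` (per-pair rates).
#' @export
run_remd <- function(system, schedule, params) {
  temps <- schedule$temperatures
  m <- length(temps)
  betas <- 1 / (KB * temps)
  n_rounds <- params$n_steps %/% schedule$exchange_interval
  stopifnot(n_rounds >= 1)
  seg <- langevin_params(schedule$exchange_interval, params$timestep,
                         300, params$friction, 1, params$save_interval)
  states <- lapply(seq_len(m), function(t)
    list(coords = system$coords, vels = NULL, replica = t))
  frames <- vector("list", m)
  epots <- vector("list", m)
  ekins <- vector("list", m)
  steps <- vector("list", m)
  log <- list()
  replica_map <- matrix(NA_integer_, n_rounds, m)

  with_seed(schedule$seed, {
    for (round in seq_len(n_rounds)) {
      E_end <- numeric(m)
      for (t in seq_len(m)) {
        res <- cpp_langevin(states[[t]]$coords, states[[t]]$vels,
                            system$compiled, seg$n_steps, seg$timestep,
                            KB * temps[t], seg$friction, seg$save_interval,
                            params$seed * 1e4 + round * 100 + t)
        states[[t]]$coords <- res$coords_last
        states[[t]]$vels <- res$vels_last
        nf <- dim(res$frames)[1]
        frames[[t]][[round]] <- res$frames
        epots[[t]][[round]] <- res$epot
        ekins[[t]][[round]] <- res$ekin
        steps[[t]][[round]] <- res$step_ids + (round - 1) * seg$n_steps
        ef <- total_energy_forces(system, res$coords_last)
        E_end[t] <- ef$breakdown$total
      }
      replica_map[round, ] <- vapply(states, function(s) s$replica, 1L)
      first <- if (round %% 2 == 1) 1 else 2
      for (lo in if (first <= m - 1) seq(first, m - 1, by = 2) else integer(0)) {
        hi <- lo + 1
        delta <- (betas[lo] - betas[hi]) * (E_end[lo] - E_end[hi])
        p <- min(1, exp(delta))
        acc <- runif(1) <= p
        log[[length(log) + 1]] <- data.frame(
          round = round, rung_lo = lo, rung_hi = hi,
          delta_E = E_end[lo] - E_end[hi], p_accept = p, accepted = acc)
        if (acc) {
          tmp <- states[[lo]]
          states[[lo]] <- states[[hi]]
          states[[hi]] <- tmp
          states[[lo]]$vels <- states[[lo]]$vels * sqrt(temps[lo] / temps[hi])
          states[[hi]]$vels <- states[[hi]]$vels * sqrt(temps[hi] / temps[lo])
          e <- E_end[lo]; E_end[lo] <- E_end[hi]; E_end[hi] <- e
        }
      }
    }
  })

  trajs <- lapply(seq_len(m), function(t) {
    fr <- do.call(abind_frames, frames[[t]])
    new_trajectory(fr, unlist(steps[[t]]), unlist(epots[[t]]),
                   unlist(ekins[[t]]),
                   langevin_params(params$n_steps, params$timestep, temps[t],
                                   params$friction, params$seed,
                                   params$save_interval),
                   metadata = list(temperature = temps[t], kind = "remd_rung"))
  })
  log <- do.call(rbind, log)
  acc <- stats::aggregate(accepted ~ rung_lo, data = log, FUN = mean)
  list(trajectories = trajs, exchange_log = log, replica_map = replica_map,
       acceptance = acc, temperatures = temps)
}

# bind frame arrays (nf x n x 3) along the first dimension
abind_frames <- function(...) {
  parts <- list(...)
  n <- dim(parts[[1]])[2]
  nf <- sum(vapply(parts, function(p) dim(p)[1], 1))
  out <- array(NA_real_, c(nf, n, 3))
  at <- 0
  for (p in parts) {
    d <- dim(p)[1]
    if (d > 0) out[at + seq_len(d), , ] <- p
    at <- at + d
  }
  out
}

#' Free-energy differences between REMD temperature rungs
#'
#' Estimates the dimensionless free-energy difference f_j - f_i =
#' -ln(Z_j/Z_i) between adjacent temperature rungs by exponential averaging
#' of the potential-energy samples of the lower rung, with block-averaged
#' standard errors.
#'
#' @param remd Result of [run_remd()].
#' @param n_blocks Number of blocks for the standard error.
#' @param burn_in Fraction of initial samples discarded.
#' @return Data frame with one row per adjacent pair: `f_diff`, `se`.
#' @export
free_energy_differences <- function(remd, n_blocks = 10, burn_in = 0.2) {
  temps <- remd$temperatures
  betas <- 1 / (KB * temps)
  out <- NULL
  for (t in seq_len(length(temps) - 1)) {
    E <- remd$trajectories[[t]]$epot
    E <- E[seq_len(length(E)) > burn_in * length(E)]
    db <- betas[t + 1] - betas[t]
    x <- exp(-db * E)
    fd <- -log(mean(x))
    blocks <- split(x, cut(seq_along(x), n_blocks, labels = FALSE))
    fb <- vapply(blocks, function(b) -log(mean(b)), 1)
    out <- rbind(out, data.frame(
      rung_lo = t, rung_hi = t + 1, T_lo = temps[t], T_hi = temps[t + 1],
      f_diff = fd, se = sd(fb) / sqrt(length(fb))))
  }
  out
}
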