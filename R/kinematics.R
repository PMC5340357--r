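#' Unit constants used throughout the package
#'
#' Internal units are Angstrom (length), femtosecond (time), electron-volt
#' (energy) and the unified atomic mass unit (mass). Projectile speeds are
#' quoted in Bohr/fs, the natural unit for hyperthermal ions.
#'
#' @return A named list with components
#'   \describe{
#'     \item{bohr}{Bohr radius in Angstrom, 0.529177.}
#'     \item{amu_A2_fs2_in_eV}{Conversion factor: 1 u (Angstrom/fs)^2 in eV,
#'       103.642697.}
#'     \item{carbon_mass}{Default projectile mass in u, 12.011.}
#'   }
#' @examples
#' unit_constants()$bohr
#' @export
unit_constants <- function() {
  list(
    bohr = 0.529177,             # Angstrom per Bohr
    amu_A2_fs2_in_eV = 103.642697, # 1 u * (A/fs)^2 in eV
    carbon_mass = 12.011         # u
  )
}

#' Atomic masses for the elements handled by the package
#'
#' @param symbols character vector of element symbols (H, C, O).
#' @return numeric vector of masses in u.
#' @export
atomic_mass <- function(symbols) {
  tab <- c(H = 1.008, C = 12.011, O = 15.999)
  unknown <- setdiff(unique(symbols), names(tab))
  if (length(unknown) > 0L) {
    stop("no mass tabulated for element(s): ", paste(unknown, collapse = ", "))
  }
  unname(tab[symbols])
}

#' Convert projectile speed to kinetic energy
#'
#' Kinetic energy is the non-relativistic 1/2 m v^2 with the speed given in
#' Bohr/fs. For a carbon projectile (12.011 u) speeds of 1, 2, 3 and 4
#' Bohr/fs correspond to roughly 175 eV, 700 eV, 1.6 keV and 2.8 keV.
#'
#' @param speed speed in Bohr/fs, non-negative.
#' @param mass mass in u (default: carbon).
#' @return kinetic energy in eV.
#' @seealso [energy_to_speed()]
#' @examples
#' speed_to_energy(1)   # ~174 eV
#' speed_to_energy(4)   # ~2.8 keV
#' @export
speed_to_energy <- function(speed, mass = unit_constants()$carbon_mass) {
  if (any(mass <= 0)) stop("mass must be positive")
  if (any(speed < 0)) stop("speed must be non-negative")
  uc <- unit_constants()
  0.5 * mass * (speed * uc$bohr)^2 * uc$amu_A2_fs2_in_eV
}

#' Convert kinetic energy to projectile speed
#'
#' Inverse of [speed_to_energy()].
#'
#' @param energy kinetic energy in eV, non-negative.
#' @param mass mass in u.
#' @return speed in Bohr/fs.
#' @export
energy_to_speed <- function(energy, mass = unit_constants()$carbon_mass) {
  if (any(mass <= 0)) stop("mass must be positive")
  if (any(energy < 0)) stop("energy must be non-negative")
  uc <- unit_constants()
  sqrt(2 * energy / (mass * uc$amu_A2_fs2_in_eV)) / uc$bohr
}

# Speed in A/fs of a body of mass m (u) carrying ke (eV).
ke_to_afs <- function(ke, mass) {
  sqrt(2 * pmax(ke, 0) / (mass * unit_constants()$amu_A2_fs2_in_eV))
}

# Kinetic energy (eV) from a velocity matrix (A/fs) and masses (u).
ke_from_velocity <- function(vel, mass) {
  0.5 * mass * rowSums(vel^2) * unit_constants()$amu_A2_fs2_in_eV
}

#' Projectile kinetic energy per frame
#'
#' @param traj an `md_trajectory`.
#' @return numeric vector, one kinetic energy (eV) per frame.
#' @export
projectile_ke <- function(traj) {
  stopifnot(inherits(traj, "md_trajectory"))
  idx <- traj$frames[[1]]$projectile
  if (is.na(idx)) stop("trajectory has no projectile atom")
  mass <- atomic_mass(traj$frames[[1]]$symbols[idx])
  vapply(traj$frames, function(fr) {
    if (is.null(fr$velocities)) {
      stop("frame has no velocities; regenerate the trajectory with velocities enabled")
    }
    v <- fr$velocities[idx, , drop = FALSE]
    ke_from_velocity(v, mass)
  }, numeric(1))
}

#' Cumulative energy loss of the projectile versus position
#'
#' The energy-loss profile is the projectile's kinetic-energy deficit
#' relative to the first frame, sampled at every frame and keyed by the
#' projectile x coordinate (the shooting axis). Samples keep time order;
#' for backscattered segments x may decrease.
#'
#' @param traj an `md_trajectory` whose frames carry velocities.
#' @return A data frame of class `energy_loss_profile` with columns `x`
#'   (Angstrom), `time` (fs) and `loss` (eV, cumulative), plus attributes
#'   `e0` (initial kinetic energy) and `mass`.
#' @export
energy_loss_profile <- function(traj) {
  stopifnot(inherits(traj, "md_trajectory"))
  ke <- projectile_ke(traj)
  idx <- traj$frames[[1]]$projectile
  x <- vapply(traj$frames, function(fr) fr$positions[idx, 1L], numeric(1))
  tm <- vapply(traj$frames, function(fr) fr$time, numeric(1))
  out <- data.frame(x = x, time = tm, loss = ke[1L] - ke)
  attr(out, "e0") <- ke[1L]
  attr(out, "mass") <- atomic_mass(traj$frames[[1]]$symbols[idx])
  class(out) <- c("energy_loss_profile", "data.frame")
  out
}

#' Final kinetic energy of the projectile
#'
#' A trajectory ends in one of three states. If the projectile has passed
#' the downstream slab face by more than `buffer`, the final kinetic energy
#' is averaged over all post-exit frames (`"exited"`). If it remains inside
#' the slab with kinetic energy below `stop_threshold` for at least
#' `stop_window` fs of trailing frames, it is `"stopped"`. A trajectory
#' that ends mid-slab still carrying energy is `"indeterminate"`
#' (truncated run).
#'
#' @param traj an `md_trajectory` with velocities.
#' @param slab_interval numeric length-2, entry and exit x of the water
#'   region (Angstrom). Defaults to the trajectory's own `slab_interval`.
#' @param buffer distance beyond the exit face, in Angstrom, after which the
#'   projectile is considered free (default 2).
#' @param stop_threshold kinetic energy in eV below which the projectile
#'   counts as thermalised (default 1).
#' @param stop_window trailing time span in fs over which the energy must
#'   stay below `stop_threshold` to declare a stop (default 50).
#' @return A list of class `final_ke` with elements `status` (one of
#'   `"exited"`, `"stopped"`, `"indeterminate"`), `ke` (eV; `NA` unless
#'   exited) and `e0`.
#' @export
final_kinetic_energy <- function(traj, slab_interval = traj$slab_interval,
                                 buffer = 2, stop_threshold = 1,
                                 stop_window = 50) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (is.null(slab_interval)) stop("slab_interval must be supplied")
  ke <- projectile_ke(traj)
  idx <- traj$frames[[1]]$projectile
  x <- vapply(traj$frames, function(fr) fr$positions[idx, 1L], numeric(1))
  tm <- vapply(traj$frames, function(fr) fr$time, numeric(1))
  x_exit <- slab_interval[2L]

  out_frames <- x > x_exit + buffer
  res <- if (any(out_frames)) {
    list(status = "exited", ke = mean(ke[out_frames]), e0 = ke[1L])
  } else {
    n <- length(ke)
    trailing <- tm >= tm[n] - stop_window
    low <- all(ke[trailing] < stop_threshold)
    inside <- x[n] >= slab_interval[1L] && x[n] <= x_exit + buffer
    span_ok <- (tm[n] - tm[1L]) >= stop_window
    if (low && inside && span_ok) {
      list(status = "stopped", ke = NA_real_, e0 = ke[1L])
    } else {
      list(status = "indeterminate", ke = NA_real_, e0 = ke[1L])
    }
  }
  class(res) <- "final_ke"
  res
}

#' @export
print.final_ke <- function(x, ...) {
  cat("final projectile state:", x$status)
  if (x$status == "exited") cat(sprintf(" (KE %.3f eV of %.3f eV initial)", x$ke, x$e0))
  cat("\n")
  invisible(x)
}
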