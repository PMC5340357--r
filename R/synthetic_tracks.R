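#' Per-speed default encounter settings
#'
#' Dissociative-encounter spacing and channel mix are calibrated from the
#' published fragment production rates: at the lowest speed H fragments
#' appear one every 5 Angstrom and OH one every 7 Angstrom, which by rate
#' algebra (every single dissociation makes one H and one OH, every double
#' two H and no OH) corresponds to encounters every 5.83 Angstrom with a
#' 5/6 single, 1/6 double mix; at the highest speed the printed 20/30
#' Angstrom rates give encounters every 24 Angstrom at a 4/5, 1/5 mix.
#' Intermediate speeds are linearly interpolated. The continuous
#' (quasi-elastic/vibrational) loss rate scales with the projectile energy,
#' `0.0026 * E0` eV per Angstrom, i.e. a transiting projectile sheds about
#' 4 percent of its energy to non-dissociative channels over a 15.7
#' Angstrom slab.
#'
#' @param speed projectile speed in Bohr/fs (1 to 4).
#' @param mass projectile mass in u.
#' @return list with `encounter_spacing` (Angstrom), `p_single`,
#'   `p_double`, `continuous_loss_rate` (eV/Angstrom).
#' @export
speed_defaults <- function(speed, mass = unit_constants()$carbon_mass) {
  if (speed < 0) stop("speed must be non-negative")
  f <- (min(max(speed, 1), 4) - 1) / 3  # clamp + interpolate over 1..4
  list(
    encounter_spacing = 5.83 + f * (24 - 5.83),
    p_single = 5 / 6 + f * (4 / 5 - 5 / 6),
    p_double = 1 / 6 + f * (1 / 5 - 1 / 6),
    continuous_loss_rate = 0.0026 * speed_to_energy(speed, mass)
  )
}

#' Parameters of the synthetic track generator
#'
#' The generator is event-kinematic: the projectile advances along x,
#' discrete dissociative encounters are drawn with exponential spacing,
#' channel energy transfers come from fixed windows (25-50 eV single
#' dissociation, 100-150 eV double), binding costs 5.0 eV for the first H
#' and a further 4.4 eV for the second are paid out of the transfer, the
#' remainder is given to the fragments as kinetic energy, and a continuous
#' loss rate drains the projectile between encounters. Transient elastic
#' excursions are painted onto the kinetic-energy record and fully
#' restored. Encounter settings default to [speed_defaults()] at the speed
#' being generated when left `NULL`.
#'
#' @param n_molecules number of water molecules (default 128).
#' @param box_edge transverse box edge in Angstrom (default 15.736).
#' @param slab_length x extent of the water region (default `box_edge`).
#'   Scale `n_molecules` with it to keep liquid density.
#' @param vacuum_factor multiplier on the x edge for the vacuum region.
#' @param projectile element symbol of the projectile.
#' @param projectile_mass mass in u.
#' @param speeds speeds the ensemble protocol uses, Bohr/fs.
#' @param encounter_spacing,p_single,p_double,continuous_loss_rate override
#'   the per-speed defaults when non-`NULL`.
#' @param transfer_single,transfer_double length-2 uniform windows, eV.
#' @param binding_first_H,binding_second_H dissociation costs, eV.
#' @param elastic_peak_scale scale of the transient elastic excursion, eV
#'   (heights are drawn uniformly between half and the full scale).
#' @param fragment_ke_split `"inverse_mass"` (light fragments fastest) or
#'   `"equal"`.
#' @param h_mobility_factor straight-flight multiplier for H fragments:
#'   heavy fragments scatter and stop after `heavy_range` Angstrom, H flies
#'   straight for `h_mobility_factor * heavy_range`.
#' @param heavy_range range of O/OH fragments, Angstrom.
#' @param populations_mode paint per-atom electron populations (bound H
#'   0.7, bound O 6.6, fast free H 0.95, slow free H 0.3).
#' @param stop_ke kinetic energy in eV below which the projectile counts
#'   as stopped.
#' @param frame_interval frame emission stride, fs.
#' @param seed default seed used when none is passed to the generator.
#' @return list of class `generator_params`.
#' @export
generator_params <- function(n_molecules = 128, box_edge = 15.736,
                             slab_length = box_edge, vacuum_factor = 2,
                             projectile = "C",
                             projectile_mass = unit_constants()$carbon_mass,
                             speeds = c(1, 2, 3, 4),
                             encounter_spacing = NULL, p_single = NULL,
                             p_double = NULL, continuous_loss_rate = NULL,
                             transfer_single = c(25, 50),
                             transfer_double = c(100, 150),
                             binding_first_H = 5.0, binding_second_H = 4.4,
                             elastic_peak_scale = 30,
                             fragment_ke_split = c("inverse_mass", "equal"),
                             h_mobility_factor = 10, heavy_range = 3,
                             populations_mode = TRUE, stop_ke = 1,
                             frame_interval = 0.5, seed = 1L) {
  fragment_ke_split <- match.arg(fragment_ke_split)
  p <- list(n_molecules = n_molecules, box_edge = box_edge,
            slab_length = slab_length, vacuum_factor = vacuum_factor,
            projectile = projectile, projectile_mass = projectile_mass,
            speeds = speeds, encounter_spacing = encounter_spacing,
            p_single = p_single, p_double = p_double,
            continuous_loss_rate = continuous_loss_rate,
            transfer_single = transfer_single,
            transfer_double = transfer_double,
            binding_first_H = binding_first_H,
            binding_second_H = binding_second_H,
            elastic_peak_scale = elastic_peak_scale,
            fragment_ke_split = fragment_ke_split,
            h_mobility_factor = h_mobility_factor,
            heavy_range = heavy_range,
            populations_mode = populations_mode, stop_ke = stop_ke,
            frame_interval = frame_interval, seed = seed)
  ps <- if (is.null(p_single)) 0 else p_single
  pd <- if (is.null(p_double)) 0 else p_double
  if (ps < 0 || pd < 0 || ps + pd > 1 + 1e-12)
    stop("channel probabilities must lie in [0,1] and sum to at most 1")
  if (!is.null(encounter_spacing) && encounter_spacing <= 0)
    stop("encounter_spacing must be positive")
  if (transfer_single[1] < binding_first_H)
    stop("single-dissociation transfers must cover the first-H binding cost")
  if (transfer_double[1] < binding_first_H + binding_second_H)
    stop("double-dissociation transfers must cover both binding costs")
  class(p) <- "generator_params"
  p
}

# Effective encounter settings for one speed: explicit params win,
# otherwise the per-speed calibration.
resolve_speed_settings <- function(params, speed) {
  d <- speed_defaults(speed, params$projectile_mass)
  list(
    spacing = params$encounter_spacing %||% d$encounter_spacing,
    p_single = params$p_single %||% d$p_single,
    p_double = params$p_double %||% d$p_double,
    lambda = params$continuous_loss_rate %||% d$continuous_loss_rate
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rigid water geometry: O at origin, experimental gas-phase bond/angle.
water_template <- function() {
  b <- 0.9572
  half <- 104.52 / 2 * pi / 180
  rbind(O = c(0, 0, 0),
        H1 = b * c(cos(half), sin(half), 0),
        H2 = b * c(cos(half), -sin(half), 0))
}

random_rotation <- function() {
  # uniform random rotation from a normalised quaternion
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

min_image_dist2 <- function(p, pts, box) {
  d <- sweep(pts, 2, p)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  rowSums(d^2)
}

#' Build a random water slab
#'
#' Places `n_molecules` rigid water molecules with random orientations in
#' the water region of the vacuum-extended box by random sequential
#' addition: a placement is accepted when every intermolecular O-O
#' distance exceeds 2.5 Angstrom, O-H exceeds 1.4 and H-H exceeds 1.0
#' (minimum image). The defaults reproduce liquid-water density (~0.98
#' g/cm^3). Deterministic given the seed.
#'
#' @param params a [generator_params()] list.
#' @param snapshot_seed integer seed for this snapshot.
#' @param max_tries placement attempts per molecule before giving up.
#' @return an `xyz_frame` of `3 * n_molecules` atoms (O, H, H per
#'   molecule), no projectile.
#' @export
build_slab <- function(params = generator_params(), snapshot_seed = 1L,
                       max_tries = 2000L) {
  set.seed(snapshot_seed)
  L <- params$slab_length
  box <- c(params$vacuum_factor * L, params$box_edge, params$box_edge)
  n <- params$n_molecules
  tpl <- water_template()
  pos <- matrix(NA_real_, 3 * n, 3)
  sym <- rep(c("O", "H", "H"), n)
  placed <- 0L
  for (m in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      o <- c(stats::runif(1, 0, L), stats::runif(1, 0, box[2]),
             stats::runif(1, 0, box[3]))
      mol <- tpl %*% t(random_rotation())
      mol <- sweep(mol, 2, o, "+")
      if (placed > 0L) {
        prev <- pos[seq_len(3 * placed), , drop = FALSE]
        prev_sym <- sym[seq_len(3 * placed)]
        bad <- FALSE
        lim <- c(O = 2.5, H = 1.4)  # vs new O
        d2 <- min_image_dist2(mol[1, ], prev, box)
        if (any(d2 < ifelse(prev_sym == "O", 2.5, 1.4)^2)) bad <- TRUE
        if (!bad) for (h in 2:3) {
          d2 <- min_image_dist2(mol[h, ], prev, box)
          if (any(d2 < ifelse(prev_sym == "O", 1.4, 1.0)^2)) { bad <- TRUE; break }
        }
        if (bad) next
      }
      pos[(3 * placed + 1):(3 * placed + 3), ] <- mol
      placed <- placed + 1L
      ok <- TRUE
      break
    }
    if (!ok)
      stop("could not place molecule ", m, " without overlap after ",
           max_tries, " tries; use a larger box or fewer molecules")
  }
  pops <- if (params$populations_mode)
    rep(c(6.6, 0.7, 0.7), n) else NULL
  xyz_frame(sym, pos, box, time = 0, populations = pops)
}

# sample a unit vector in a forward cone of half-angle `half_deg` about +x
forward_direction <- function(half_deg = 60) {
  ct <- stats::runif(1, cos(half_deg * pi / 180), 1)
  st <- sqrt(1 - ct^2)
  phi <- stats::runif(1, 0, 2 * pi)
  c(ct, st * cos(phi), st * sin(phi))
}

#' Generate one synthetic projectile track with its ground-truth event log
#'
#' See [generator_params()] for the model. The returned event log closes
#' the energy ledger exactly: initial energy equals final kinetic energy
#' plus the sum of event transfers plus continuous losses (which include
#' the sub-threshold residue deposited on stopping). Fully reproducible
#' from the seed.
#'
#' @param params a [generator_params()] list.
#' @param speed initial projectile speed, Bohr/fs.
#' @param entry transverse (y, z) entry point in Angstrom.
#' @param seed integer seed.
#' @param slab optional prebuilt slab frame from [build_slab()]; built
#'   from `seed + 1` when omitted.
#' @param snapshot_id integer id recorded on the trajectory.
#' @return list with elements `trajectory` (an `md_trajectory`) and
#'   `events` (a data frame of class `event_log` with columns `x`, `time`,
#'   `channel`, `transfer`, `binding`, `peak`, `molecule`, list-columns
#'   `frag_atoms`, `frag_species`, `frag_ke`, and attributes `e0`,
#'   `final_ke`, `continuous_loss`, `stopped`, `track_length`).
#' @export
generate_track <- function(params = generator_params(), speed = 1,
                           entry = c(7.9, 7.9), seed = params$seed,
                           slab = NULL, snapshot_id = 1L) {
  if (any(entry < 0) || any(entry > params$box_edge))
    stop("entry point outside the transverse box")
  if (is.null(slab)) slab <- build_slab(params, snapshot_seed = seed + 1L)
  set.seed(seed)
  st <- resolve_speed_settings(params, speed)
  uc <- unit_constants()
  m <- params$projectile_mass
  e0 <- speed_to_energy(speed, m)
  L <- params$slab_length
  entry_offset <- 2
  delta <- 0.1  # fs, event micro-frame offset

  # --- encounter schedule -------------------------------------------------
  n_guess <- max(10, ceiling(L / st$spacing * 3 + 20))
  gaps <- stats::rexp(n_guess, rate = 1 / st$spacing)
  while (sum(gaps) < L)
    gaps <- c(gaps, stats::rexp(n_guess, rate = 1 / st$spacing))
  ex <- cumsum(gaps)
  ex <- ex[ex < L]
  u <- stats::runif(length(ex))
  chan <- ifelse(u < st$p_single, "single",
                 ifelse(u < st$p_single + st$p_double, "double", "none"))
  # the channel remainder is a no-op: vibrational/rotational excitation is
  # carried by the continuous loss rate, not by discrete encounters
  keep <- chan != "none"
  ex <- ex[keep]
  chan <- chan[keep]
  draw_transfer <- function(ch) {
    w <- switch(ch, single = params$transfer_single,
                double = params$transfer_double)
    stats::runif(1, w[1], w[2])
  }

  # --- march the projectile ----------------------------------------------
  # segments: piecewise motion with constant loss rate lambda (eV/A)
  segs <- list()   # each: t0, t1, x0, ke0, lambda
  events <- list()
  frag_paths <- list()
  used_mol <- integer(0)
  n_slab <- length(slab$symbols)
  a_coef <- sqrt(2 / (m * uc$amu_A2_fs2_in_eV))  # v = a * sqrt(KE)

  t_cur <- 0; x_cur <- -entry_offset; ke_cur <- e0
  cont_loss <- 0
  stopped <- FALSE

  seg_to <- function(x_target, lambda) {
    # advance to x_target under loss rate lambda; returns TRUE if reached,
    # FALSE if the projectile ran out of energy on the way
    if (x_target <= x_cur + 1e-12) return(TRUE)
    ke_t <- ke_cur - lambda * (x_target - x_cur)
    if (lambda > 0 && ke_t <= params$stop_ke) {
      # thermalises inside this segment: directed motion ends where the
      # energy falls to stop_ke; the residue is deposited as heat there
      x_stop <- x_cur + (ke_cur - params$stop_ke) / lambda
      t_stop <- t_cur +
        2 * (sqrt(ke_cur) - sqrt(params$stop_ke)) / (lambda * a_coef)
      segs[[length(segs) + 1L]] <<- list(t0 = t_cur, t1 = t_stop,
                                         x0 = x_cur, ke0 = ke_cur,
                                         lambda = lambda)
      cont_loss <<- cont_loss + ke_cur
      t_cur <<- t_stop; x_cur <<- x_stop; ke_cur <<- 0
      stopped <<- TRUE
      return(FALSE)
    }
    t1 <- if (lambda > 0)
      t_cur + 2 * (sqrt(ke_cur) - sqrt(ke_t)) / (lambda * a_coef)
    else
      t_cur + (x_target - x_cur) / (a_coef * sqrt(ke_cur))
    segs[[length(segs) + 1L]] <<- list(t0 = t_cur, t1 = t1, x0 = x_cur,
                                       ke0 = ke_cur, lambda = lambda)
    cont_loss <<- cont_loss + (ke_cur - ke_t)
    t_cur <<- t1; x_cur <<- x_target; ke_cur <<- ke_t
    TRUE
  }

  make_fragments <- function(ch, budget, mol, t_e) {
    atoms <- ((mol - 1L) * 3L + 1L):(mol * 3L)  # O, H1, H2
    o_i <- atoms[1L]; h1 <- atoms[2L]; h2 <- atoms[3L]
    frs <- if (ch == "single") {
      list(list(atoms = h1, species = "H", mass = atomic_mass("H")),
           list(atoms = c(o_i, h2), species = "OH",
                mass = sum(atomic_mass(c("O", "H")))))
    } else {
      list(list(atoms = h1, species = "H", mass = atomic_mass("H")),
           list(atoms = h2, species = "H", mass = atomic_mass("H")),
           list(atoms = o_i, species = "O", mass = atomic_mass("O")))
    }
    w <- vapply(frs, function(f)
      if (params$fragment_ke_split == "equal") 1 else 1 / f$mass, numeric(1))
    kes <- budget * w / sum(w)
    for (k in seq_along(frs)) {
      f <- frs[[k]]
      ke <- kes[k]
      v_abs <- sqrt(2 * ke / (f$mass * uc$amu_A2_fs2_in_eV))
      base <- slab$positions[f$atoms, , drop = FALSE]
      pieces <- list()
      if (v_abs > 1e-4) {
        if (f$species == "H") {
          rng <- params$h_mobility_factor * params$heavy_range
          dir <- forward_direction()
          pieces[[1L]] <- list(t0 = t_e, t1 = t_e + rng / v_abs,
                               v = v_abs * dir, base = base)
          base <- base + rep(rng * dir, each = nrow(base))
        } else {
          t_p <- t_e
          remaining <- params$heavy_range
          step <- 1
          while (remaining > 1e-9) {
            d <- min(step, remaining)
            dir <- forward_direction(half_deg = 80)
            pieces[[length(pieces) + 1L]] <-
              list(t0 = t_p, t1 = t_p + d / v_abs, v = v_abs * dir,
                   base = base)
            base <- base + rep(d * dir, each = nrow(base))
            t_p <- t_p + d / v_abs
            remaining <- remaining - d
          }
        }
      }
      frag_paths[[length(frag_paths) + 1L]] <<-
        list(atoms = f$atoms, species = f$species, mass = f$mass, ke = ke,
             t0 = t_e, pieces = pieces, rest = base)
    }
    list(atoms = lapply(frs, `[[`, "atoms"),
         species = vapply(frs, `[[`, character(1), "species"),
         ke = kes)
  }

  for (k in seq_along(ex)) {
    if (x_cur < 0) { if (!seg_to(0, 0)) break }
    if (!seg_to(ex[k], st$lambda)) break
    ke_pre <- ke_cur
    ch <- chan[k]
    transfer <- min(draw_transfer(ch), ke_pre)
    binding <- switch(ch, single = params$binding_first_H,
                      double = params$binding_first_H + params$binding_second_H)
    if (transfer < binding) {
      ch <- "vibrational"  # too little energy left to dissociate: dump only
      binding <- 0
    }
    peak <- 0
    frag <- NULL
    if (ch != "vibrational") {
      peak <- min(stats::runif(1, 0.5, 1) * params$elastic_peak_scale,
                  max(ke_pre - transfer, 0))
      # pick the nearest unused molecule to the collision point
      o_rows <- seq(1L, n_slab, by = 3L)
      mols <- setdiff(seq_len(params$n_molecules), used_mol)
      o_pos <- slab$positions[o_rows[mols], , drop = FALSE]
      d2 <- min_image_dist2(c(ex[k], entry[1], entry[2]), o_pos, slab$box)
      mol <- mols[which.min(d2)]
      used_mol <- c(used_mol, mol)
      frag <- make_fragments(ch, transfer - binding, mol, t_cur)
    }
    ke_cur <- ke_pre - transfer
    events[[length(events) + 1L]] <- list(
      x = ex[k], time = t_cur,
      channel = switch(ch, single = "single_dissociation",
                       double = "double_dissociation", "vibrational"),
      transfer = transfer, binding = binding, peak = peak,
      molecule = if (is.null(frag)) NA_integer_ else used_mol[length(used_mol)],
      frag_atoms = if (is.null(frag)) list() else frag$atoms,
      frag_species = if (is.null(frag)) character(0) else frag$species,
      frag_ke = if (is.null(frag)) numeric(0) else frag$ke)
    if (ke_cur <= params$stop_ke) {  # thermalised by the collision itself
      cont_loss <- cont_loss + ke_cur
      ke_cur <- 0
      stopped <- TRUE
      break
    }
  }
  if (!stopped) {
    if (x_cur < 0) seg_to(0, 0)
    if (!stopped && x_cur < L) seg_to(L, st$lambda)
    if (!stopped) seg_to(L + entry_offset + 2, 0)  # free flight past the face
  }
  t_end <- t_cur
  x_end <- x_cur
  final_ke <- ke_cur

  # --- frame times --------------------------------------------------------
  ev_t <- vapply(events, `[[`, numeric(1), "time")
  times <- seq(0, t_end, by = params$frame_interval)
  times <- c(times, t_end, as.vector(rbind(ev_t - delta, ev_t, ev_t + delta)))
  if (stopped) times <- c(times, t_end + seq(5, 55, by = 5))
  else times <- c(times, t_end + params$frame_interval * (1:3))
  times <- sort(unique(round(times, 6)))
  times <- times[times >= 0]
  times <- times[c(TRUE, diff(times) > 1e-6)]

  # projectile state at an arbitrary time
  seg_t0 <- vapply(segs, `[[`, numeric(1), "t0")
  seg_t1 <- vapply(segs, `[[`, numeric(1), "t1")
  proj_state <- function(t) {
    if (t >= t_end) {
      ke <- final_ke
      v <- a_coef * sqrt(ke) * (!stopped)
      return(c(x_end + v * (t - t_end), ke, v))
    }
    s <- segs[[max(1L, findInterval(t + 1e-12, seg_t0))]]
    dt <- min(t, s$t1) - s$t0
    if (s$lambda > 0) {
      ke <- (sqrt(s$ke0) - s$lambda * a_coef * dt / 2)^2
      x <- s$x0 + (s$ke0 - ke) / s$lambda
    } else {
      ke <- s$ke0
      x <- s$x0 + a_coef * sqrt(ke) * dt
    }
    c(x, ke, a_coef * sqrt(ke))
  }

  # event excursions: at exactly t_e the recorded KE dips by the peak
  ev_peak <- vapply(events, `[[`, numeric(1), "peak")
  ev_transfer <- vapply(events, `[[`, numeric(1), "transfer")

  n_atoms <- n_slab + 1L
  proj_i <- n_atoms
  sym <- c(slab$symbols, params$projectile)
  base_pop <- if (params$populations_mode) c(slab$populations, 3.6) else NULL

  frag_state <- function(fp, t) {
    # returns list(pos, v) for fragment atoms at time t
    for (pc in fp$pieces) {
      if (t < pc$t1) {
        dt <- t - pc$t0
        return(list(pos = pc$base + rep(pc$v * dt, each = length(fp$atoms)),
                    v = pc$v))
      }
    }
    list(pos = fp$rest, v = c(0, 0, 0))
  }

  frames <- vector("list", length(times))
  for (fi in seq_along(times)) {
    t <- times[fi]
    ps <- proj_state(t)
    ke_here <- ps[2]
    # excursion frame: the dip is relative to the post-event plateau
    hit <- which(abs(ev_t - t) < 2e-6)
    if (length(hit) > 0L && max(ev_peak[hit]) > 0) {
      post <- proj_state(min(ev_t[hit]) + 1e-7)
      ke_here <- max(post[2] - max(ev_peak[hit]), 0)
    }
    pos <- rbind(slab$positions, c(ps[1], entry[1], entry[2]))
    vel <- matrix(0, n_atoms, 3)
    vel[proj_i, 1] <- a_coef * sqrt(ke_here) * (!stopped || t < t_end)
    pop <- base_pop
    for (fp in frag_paths) {
      if (t < fp$t0) next
      fs <- frag_state(fp, t)
      pos[fp$atoms, ] <- fs$pos
      vel[fp$atoms, ] <- rep(fs$v, each = length(fp$atoms))
      if (!is.null(pop)) {
        if (fp$species == "H")
          pop[fp$atoms] <- if (fp$ke >= 10) 0.95 else 0.3
        else if (fp$species == "O")
          pop[fp$atoms] <- 6.0
        # OH keeps its bound-molecule painting
      }
    }
    frames[[fi]] <- xyz_frame(sym, pos, slab$box, time = t,
                              velocities = vel, populations = pop,
                              projectile = proj_i)
  }

  traj <- md_trajectory(frames, initial_speed = speed,
                        snapshot_id = snapshot_id, entry_point = entry,
                        seed = seed, slab_interval = c(0, L))

  ev_df <- if (length(events) == 0L) {
    data.frame(x = numeric(0), time = numeric(0), channel = character(0),
               transfer = numeric(0), binding = numeric(0),
               peak = numeric(0), molecule = integer(0))
  } else {
    data.frame(
      x = vapply(events, `[[`, numeric(1), "x"),
      time = ev_t,
      channel = vapply(events, `[[`, character(1), "channel"),
      transfer = ev_transfer,
      binding = vapply(events, `[[`, numeric(1), "binding"),
      peak = ev_peak,
      molecule = vapply(events, `[[`, integer(1), "molecule"))
  }
  ev_df$frag_atoms <- I(lapply(events, `[[`, "frag_atoms"))
  ev_df$frag_species <- I(lapply(events, `[[`, "frag_species"))
  ev_df$frag_ke <- I(lapply(events, `[[`, "frag_ke"))
  attr(ev_df, "e0") <- e0
  attr(ev_df, "final_ke") <- final_ke
  attr(ev_df, "continuous_loss") <- cont_loss
  attr(ev_df, "stopped") <- stopped
  attr(ev_df, "track_length") <- max(0, min(x_end, L))
  attr(ev_df, "seed") <- seed
  attr(ev_df, "speed") <- speed
  class(ev_df) <- c("event_log", "data.frame")
  list(trajectory = traj, events = ev_df)
}

#' Generate a full ensemble of tracks, written to disk
#'
#' One trajectory per (grid point, snapshot): entry points form a uniform
#' `grid_n` x `grid_n` square grid over the transverse cell, and each of
#' the `snapshots` slab realisations is shot at from every grid point,
#' reproducing the published protocol of 36 initial conditions per
#' snapshot and 72 trajectories per velocity for a 6 x 6 grid and two
#' snapshots. Per-track seeds derive deterministically from `base_seed`.
#'
#' @param params a [generator_params()] list.
#' @param speed projectile speed, Bohr/fs.
#' @param grid_n entry-grid side length.
#' @param snapshots number of slab realisations.
#' @param base_seed integer.
#' @param dir output directory (created if needed).
#' @return path of the written manifest CSV, invisibly; the manifest data
#'   frame is attached as attribute `entries`.
#' @export
generate_ensemble <- function(params = generator_params(), speed = 1,
                              grid_n = 6, snapshots = 2, base_seed = 1L,
                              dir = tempfile("ensemble")) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  g <- (seq_len(grid_n) - 0.5) / grid_n * params$box_edge
  entries <- expand.grid(entry_y = g, entry_z = g,
                         snapshot = seq_len(snapshots))
  # scatter derived seeds across the integer range: arithmetic seed
  # sequences can give correlated Mersenne-Twister streams
  set.seed(base_seed)
  snap_seeds <- sample.int(2147483646L, snapshots)
  track_seeds <- sample.int(2147483646L, nrow(entries))
  slabs <- lapply(seq_len(snapshots), function(s)
    build_slab(params, snapshot_seed = snap_seeds[s]))
  ev_path <- file.path(dir, "events.jsonl")
  if (file.exists(ev_path)) file.remove(ev_path)
  paths <- character(nrow(entries))
  for (k in seq_len(nrow(entries))) {
    seed_k <- track_seeds[k]
    tr <- generate_track(params, speed,
                         entry = c(entries$entry_y[k], entries$entry_z[k]),
                         seed = seed_k, slab = slabs[[entries$snapshot[k]]],
                         snapshot_id = entries$snapshot[k])
    paths[k] <- sprintf("track_%03d.xyz", k)
    write_trajectory(tr$trajectory, file.path(dir, paths[k]))
    rec <- list(track = paths[k], seed = seed_k,
                e0 = attr(tr$events, "e0"),
                final_ke = attr(tr$events, "final_ke"),
                continuous_loss = attr(tr$events, "continuous_loss"),
                stopped = attr(tr$events, "stopped"),
                events = tr$events[, c("x", "time", "channel", "transfer",
                                       "binding", "peak")])
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
        file = ev_path, append = TRUE, sep = "")
  }
  man <- data.frame(path = paths, speed_bohr_per_fs = speed,
                    snapshot = entries$snapshot,
                    entry_y = entries$entry_y, entry_z = entries$entry_z)
  man_path <- file.path(dir, "manifest.csv")
  write_manifest(man, man_path)
  structure(invisible(man_path), entries = man)
}
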