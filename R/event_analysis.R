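#' Parameters for collision-event detection
#'
#' The published analysis reads events off energy-loss plots; these
#' thresholds make that reading algorithmic. Defaults are chosen so that
#' the smallest dissociative transfer (25 eV) always registers as a
#' discrete event while sub-10 eV vibrational ripple never does.
#'
#' @param step_threshold minimum net loss step, eV, to count as a discrete
#'   event (default 10).
#' @param restoration_fraction fraction of a transient excursion that must
#'   be recovered for the excursion to count as elastic (default 0.5).
#' @param smoothing_window minimum profile length in samples; events
#'   separated by fewer samples are merged (default 5).
#' @param continuous_slope_threshold sustained slope, eV/Angstrom, above
#'   which an eventless segment is labelled a continuous vibrational loss
#'   (default 2).
#' @param jump_slope_threshold local slope, eV/Angstrom, above which
#'   consecutive samples are treated as part of a discrete jump
#'   (default 25; well above any continuous loss rate, well below the
#'   slope of a real collision step).
#' @return list of class `event_params`.
#' @export
event_params <- function(step_threshold = 10, restoration_fraction = 0.5,
                         smoothing_window = 5,
                         continuous_slope_threshold = 2,
                         jump_slope_threshold = 25) {
  p <- list(step_threshold = step_threshold,
            restoration_fraction = restoration_fraction,
            smoothing_window = smoothing_window,
            continuous_slope_threshold = continuous_slope_threshold,
            jump_slope_threshold = jump_slope_threshold)
  if (any(unlist(p) <= 0)) stop("all event parameters must be positive")
  class(p) <- "event_params"
  p
}

#' Segment an energy-loss profile into collision events
#'
#' Discrete collisions appear as sharp steps in the cumulative loss, often
#' overshooting transiently because kinetic energy is converted to
#' potential energy at closest approach and then recovered (the elastic
#' component). A step's net transfer is the plateau difference across the
#' jump; the recovered overshoot is reported as `peak` rather than as
#' transfer. Loss accumulated between discrete events is emitted as
#' continuous segments (`channel = "vibrational"` when the mean slope
#' exceeds the continuous-slope threshold, `"drift"` otherwise), so that
#' the transfers of all rows sum exactly to the terminal loss.
#'
#' @param profile an [energy_loss_profile()] (or data frame with columns
#'   `x`, `time`, `loss`, time-ordered).
#' @param params an [event_params()] list.
#' @return data frame of class `collision_events` with columns `x`, `time`,
#'   `transfer` (eV), `peak` (eV), `channel` (`"unresolved"` for discrete
#'   steps pending census annotation, `"elastic_only"`, `"vibrational"`,
#'   `"drift"`), `x_start`, `x_end`, `discrete`.
#' @export
detect_events <- function(profile, params = event_params()) {
  if (nrow(profile) < params$smoothing_window)
    stop("profile shorter than the smoothing window (",
         params$smoothing_window, " samples)")
  loss <- profile$loss
  x <- profile$x
  tm <- profile$time
  n <- length(loss)
  dx <- abs(diff(x))
  slope <- diff(loss) / pmax(dx, 1e-9)
  slope[dx < 1e-9 & abs(diff(loss)) < 1e-9] <- 0
  injump <- abs(slope) > params$jump_slope_threshold

  # contiguous jump runs; merge runs separated by a single calm sample
  runs <- rle(injump)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  jr <- which(runs$values)
  regions <- list()
  for (r in jr) {
    a <- starts[r]; b <- ends[r] + 1L   # sample indices spanned by the jump
    if (length(regions) > 0L) {
      last <- regions[[length(regions)]]
      if (a - last[2] <= 1L) {
        regions[[length(regions)]] <- c(last[1], b)
        next
      }
    }
    regions[[length(regions) + 1L]] <- c(a, b)
  }

  rows <- list()
  for (rg in regions) {
    a <- max(rg[1], 1L); b <- min(rg[2], n)
    net <- loss[b] - loss[a]
    mx <- max(loss[a:b])
    overshoot <- mx - loss[b]
    restored <- if (mx > loss[a]) overshoot / (mx - loss[a]) else 0
    peak <- if (restored >= params$restoration_fraction || net >=
                params$step_threshold) overshoot else 0
    if (net >= params$step_threshold) {
      k_ev <- a + which.max(diff(loss[a:b])) # steepest rise locates the hit
      rows[[length(rows) + 1L]] <- data.frame(
        x = x[k_ev], time = tm[k_ev], transfer = net, peak = peak,
        channel = "unresolved", x_start = x[a], x_end = x[b],
        i_start = a, i_end = b, discrete = TRUE)
    } else if (mx - loss[a] >= params$step_threshold) {
      k_ev <- a + which.max(loss[a:b]) - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        x = x[k_ev], time = tm[k_ev], transfer = net, peak = peak,
        channel = "elastic_only", x_start = x[a], x_end = x[b],
        i_start = a, i_end = b, discrete = TRUE)
    }
    # sub-threshold wiggles are left to the continuous drift rows
  }

  ev <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(x = numeric(0), time = numeric(0), transfer = numeric(0),
               peak = numeric(0), channel = character(0),
               x_start = numeric(0), x_end = numeric(0),
               i_start = integer(0), i_end = integer(0),
               discrete = logical(0))

  # continuous segments between event boundaries: telescoping closure
  bounds <- data.frame(i_start = c(NA_integer_, ev$i_start, n),
                       i_end = c(1L, ev$i_end, NA_integer_))
  segrows <- list()
  for (k in seq_len(nrow(bounds) - 1L)) {
    a <- bounds$i_end[k]; b <- bounds$i_start[k + 1L]
    if (is.na(a) || is.na(b) || b <= a) next
    drift <- loss[b] - loss[a]
    if (abs(drift) < 1e-9) next
    span <- abs(x[b] - x[a])
    sl <- if (span > 1e-9) drift / span else Inf
    segrows[[length(segrows) + 1L]] <- data.frame(
      x = (x[a] + x[b]) / 2, time = (tm[a] + tm[b]) / 2, transfer = drift,
      peak = 0,
      channel = if (sl >= params$continuous_slope_threshold) "vibrational"
                else "drift",
      x_start = x[a], x_end = x[b], i_start = a, i_end = b,
      discrete = FALSE)
  }
  out <- rbind(ev, if (length(segrows) > 0L) do.call(rbind, segrows))
  if (is.null(out)) out <- ev
  out <- out[order(out$time), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "terminal_loss") <- loss[n] - loss[1L]
  class(out) <- c("collision_events", "data.frame")
  out
}

#' Annotate discrete events with dissociation channels from the census
#'
#' A discrete step is a single dissociation when exactly one OH and one
#' isolated-H creation appear in the census within the matching window of
#' the event, and a double (complete) dissociation when two H and one
#' isolated-O creation do. The census wins over any transfer-based guess;
#' events whose neighbourhood shows neither pattern stay `"unresolved"`.
#'
#' @param events a `collision_events` data frame from [detect_events()].
#' @param census a [census_vs_projectile()] result for the same trajectory.
#' @param window_x spatial matching window, Angstrom (default 2).
#' @param window_t temporal matching window, fs (default 20).
#' @return `events` with updated `channel` and two new columns: `n_single`
#'   and `n_double`, the dissociation counts attributed to each discrete
#'   event from its creation window (a merged step covering two encounters
#'   keeps `channel = "unresolved"` but carries both counts).
#' @export
annotate_events <- function(events, census, window_x = 2, window_t = 20) {
  events$n_single <- integer(nrow(events))
  events$n_double <- integer(nrow(events))
  disc <- which(events$discrete & events$channel == "unresolved")
  disc_t <- sort(events$time[events$discrete])
  for (k in disc) {
    # window ends before the next discrete event so creations stay paired
    nxt <- disc_t[disc_t > events$time[k] + 1e-9]
    t_hi <- events$time[k] +
      min(window_t, if (length(nxt) > 0L) nxt[1L] - events$time[k] - 1 else Inf)
    sel <- census$time >= events$time[k] - 1 & census$time <= t_hi
    if (!any(sel)) next
    i0 <- max(1L, min(which(sel)) - 1L)
    i1 <- max(which(sel))
    d_h <- census$cum_H_isolated[i1] - census$cum_H_isolated[i0]
    d_o <- census$cum_O_isolated[i1] - census$cum_O_isolated[i0]
    # H and isolated-O creations are reliable counters (an OH fragment can
    # transiently relabel, but cumulative H/O counts are monotone truths)
    n_d <- d_o
    n_s <- max(d_h - 2L * d_o, 0L)
    events$n_single[k] <- n_s
    events$n_double[k] <- n_d
    if (n_s == 1L && n_d == 0L)
      events$channel[k] <- "single_dissociation"
    else if (n_s == 0L && n_d == 1L)
      events$channel[k] <- "double_dissociation"
  }
  events
}

#' Classify a whole trajectory
#'
#' Categories follow the energy-loss phenomenology: `stopped` when the
#' projectile thermalises inside the slab; `multiple_sequential` for two
#' or more dissociative events; `single_H_dissociation` or
#' `complete_dissociation` according to the single dissociative event's
#' channel; `continuous_loss` when there is no discrete event but the
#' total loss exceeds the step threshold; otherwise
#' `non_dissociative_transit`. An unresolved discrete event counts as
#' dissociative; when it is the only one, transfers of at least 75 eV are
#' taken as complete dissociation (the 100-150 eV window) and smaller ones
#' as single H loss.
#'
#' @param traj an `md_trajectory` (used only for its profile terminal loss
#'   when `events` lacks it).
#' @param events annotated `collision_events`.
#' @param final_ke a [final_kinetic_energy()] result.
#' @param params an [event_params()] list.
#' @return character scalar; attribute `truncated` is `TRUE` when the
#'   final state was indeterminate.
#' @export
classify_trajectory <- function(traj, events, final_ke,
                                params = event_params()) {
  truncated <- final_ke$status == "indeterminate"
  cls <- if (final_ke$status == "stopped") {
    "stopped"
  } else {
    disc <- events[events$discrete &
                   events$channel %in% c("single_dissociation",
                                         "double_dissociation",
                                         "unresolved"), , drop = FALSE]
    total_loss <- attr(events, "terminal_loss")
    if (is.null(total_loss)) total_loss <- sum(events$transfer)
    if (nrow(disc) >= 2L) {
      "multiple_sequential"
    } else if (nrow(disc) == 1L) {
      ch <- disc$channel[1L]
      if (ch == "single_dissociation") "single_H_dissociation"
      else if (ch == "double_dissociation") "complete_dissociation"
      else if (disc$transfer[1L] >= 75) "complete_dissociation"
      else "single_H_dissociation"
    } else if (total_loss > params$step_threshold) {
      "continuous_loss"
    } else {
      "non_dissociative_transit"
    }
  }
  attr(cls, "truncated") <- truncated
  cls
}

#' Energy partition of a dissociative event
#'
#' Of the energy transferred in a dissociative collision only the binding
#' cost (5.0 eV for the first H, a further 4.4 eV for the second) is spent
#' on breaking bonds; the remainder leaves as fragment kinetic energy.
#' The binding fraction is small, at most 5-10 percent at the lower edge
#' of the transfer windows.
#'
#' @param transfer energy transferred in the event, eV.
#' @param channel `"single_dissociation"` or `"double_dissociation"`.
#' @param bindings named numeric, binding costs in eV.
#' @return list with `binding_cost`, `fragment_budget`, `fraction` and
#'   logical `inconsistent` (transfer below the binding cost, i.e. the
#'   event cannot be of the claimed channel).
#' @export
event_energy_partition <- function(transfer,
                                   channel = c("single_dissociation",
                                               "double_dissociation"),
                                   bindings = c(first_H = 5.0,
                                                second_H = 4.4)) {
  channel <- match.arg(channel)
  if (transfer <= 0) stop("transfer must be positive")
  cost <- if (channel == "single_dissociation") bindings[["first_H"]]
          else bindings[["first_H"]] + bindings[["second_H"]]
  list(binding_cost = cost,
       fragment_budget = transfer - cost,
       fraction = cost / transfer,
       inconsistent = transfer < cost)
}

#' Track hyperthermal secondary fragments
#'
#' Fragments whose kinetic energy at creation exceeds `ke_threshold` are
#' followed until they thermalise (KE below 1 eV) or the trajectory ends.
#' Path length accumulates minimum-image frame-to-frame displacements;
#' straight-line displacement is the norm of their (unwrapped) sum. A
#' role handover is flagged when a secondary outruns the primary
#' projectile in kinetic energy.
#'
#' @param traj an `md_trajectory` with velocities.
#' @param census a [census_vs_projectile()] result for `traj` (its label
#'   history identifies fragment atoms and creation frames).
#' @param ke_threshold tracking threshold, eV (default 10).
#' @return data frame with one row per tracked secondary: `atom`,
#'   `species`, `created_frame`, `ke_created` (eV), `path_length`,
#'   `displacement` (Angstrom) and `handover` (logical).
#' @export
track_secondaries <- function(traj, census, ke_threshold = 10) {
  labels <- attr(census, "labels")
  symbols <- attr(census, "symbols")
  nf <- nrow(labels)
  proj_i <- traj$frames[[1]]$projectile
  proj_ke <- projectile_ke(traj)
  box <- traj$frames[[1]]$box
  frag_lab <- c("H_isolated", "OH", "O_isolated")
  is_frag <- labels %in% frag_lab
  dim(is_frag) <- dim(labels)

  first_frag <- apply(is_frag, 2L, function(col)
    if (any(col)) which(col)[1L] else NA_integer_)
  cand <- which(!is.na(first_frag) & seq_along(first_frag) != proj_i)
  # an OH fragment is represented by its oxygen; drop its hydrogen partner
  cand <- cand[!(symbols[cand] == "H" &
                 labels[cbind(first_frag[cand], cand)] == "OH")]
  rows <- list()
  for (a in cand) {
    k0 <- first_frag[a]
    mass <- atomic_mass(symbols[a])
    v0 <- traj$frames[[k0]]$velocities[a, , drop = FALSE]
    ke0 <- ke_from_velocity(v0, mass)
    if (ke0 < ke_threshold) next
    disp <- c(0, 0, 0)
    path <- 0
    handover <- FALSE
    for (k in seq_len(nf)[-seq_len(k0)]) {
      d <- traj$frames[[k]]$positions[a, ] - traj$frames[[k - 1L]]$positions[a, ]
      d <- d - box * round(d / box)
      path <- path + sqrt(sum(d^2))
      disp <- disp + d
      kek <- ke_from_velocity(traj$frames[[k]]$velocities[a, , drop = FALSE],
                              mass)
      if (kek > proj_ke[k]) handover <- TRUE
      if (kek < 1) break
    }
    rows[[length(rows) + 1L]] <- data.frame(
      atom = a, species = labels[k0, a], created_frame = k0,
      ke_created = ke0, path_length = path,
      displacement = sqrt(sum(disp^2)), handover = handover)
  }
  if (length(rows) == 0L)
    return(data.frame(atom = integer(0), species = character(0),
                      created_frame = integer(0), ke_created = numeric(0),
                      path_length = numeric(0), displacement = numeric(0),
                      handover = logical(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
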