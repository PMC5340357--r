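#' Electron-population thresholds for hydrogen charge labels
#'
#' A free hydrogen carrying 0.9-1 electron moves as a neutral atom; one
#' with fewer than 0.4 electrons moves as a proton (the residue accounts
#' for H basis functions describing electrons of nearby molecules). A
#' hydrogen bound in a molecule typically carries about 0.7 electrons.
#'
#' @param neutral_min minimum population, electrons, for a neutral label
#'   (default 0.9).
#' @param proton_max maximum population for a cation-like label
#'   (default 0.4).
#' @return list of class `population_thresholds`.
#' @export
population_thresholds <- function(neutral_min = 0.9, proton_max = 0.4) {
  if (!(proton_max > 0 && proton_max < neutral_min && neutral_min <= 1.2))
    stop("need 0 < proton_max < neutral_min <= 1.2")
  structure(list(neutral_min = neutral_min, proton_max = proton_max),
            class = "population_thresholds")
}

#' Total electron population of a group of atoms
#'
#' Per-atom population partitions are ambiguous; summed over a whole
#' molecule, radical or ion the ambiguity largely cancels, so charge
#' labelling always works on group sums.
#'
#' @param frame an `xyz_frame` carrying populations.
#' @param atoms integer vector of atom indices (may be empty).
#' @return numeric scalar, electrons.
#' @export
group_population <- function(frame, atoms) {
  stopifnot(inherits(frame, "xyz_frame"))
  if (is.null(frame$populations))
    stop("frame has no populations; regenerate with populations_mode = TRUE")
  if (length(atoms) == 0L) return(0)
  sum(frame$populations[atoms])
}

#' Charge label for a hydrogen from its electron population
#'
#' @param population electrons on the hydrogen (group sum for bound H).
#' @param thresholds a [population_thresholds()] list.
#' @param bound is the hydrogen part of a molecule according to the
#'   census? Populations between the thresholds are `molecular_bound`
#'   when bound and `ambiguous` otherwise; the open interval is never
#'   silently binned.
#' @return one of `"neutral_atom"`, `"cation_like"`, `"molecular_bound"`,
#'   `"ambiguous"`.
#' @export
classify_hydrogen_charge <- function(population,
                                     thresholds = population_thresholds(),
                                     bound = FALSE) {
  if (population < 0) stop("population must be non-negative")
  if (population >= thresholds$neutral_min) "neutral_atom"
  else if (population <= thresholds$proton_max) "cation_like"
  else if (bound) "molecular_bound"
  else "ambiguous"
}

#' Charge labels of fragments along a trajectory
#'
#' For every frame, isolated-H and OH fragments identified by the census
#' receive a charge label from their group population; the summary
#' contrasts hyperthermal fragments (kinetic energy above `ke_split`)
#' with slow ones, since fast hydrogens tend to move as neutral atoms and
#' slow ones as protons.
#'
#' @param traj an `md_trajectory` whose frames carry populations and
#'   velocities.
#' @param census a [census_vs_projectile()] result for `traj`.
#' @param thresholds a [population_thresholds()] list.
#' @param ke_split hyperthermal/slow kinetic-energy split, eV (default 10).
#' @return data frame of class `charge_census` with columns `frame`,
#'   `atom`, `species`, `ke_eV`, `population`, `label`, plus attribute
#'   `summary`: label fractions by speed class for isolated H.
#' @export
charge_census <- function(traj, census, thresholds = population_thresholds(),
                          ke_split = 10) {
  labels <- attr(census, "labels")
  symbols <- attr(census, "symbols")
  rows <- list()
  for (k in seq_len(nrow(labels))) {
    fr <- traj$frames[[k]]
    if (is.null(fr$populations))
      stop("frame ", k, " has no populations")
    h_iso <- which(labels[k, ] == "H_isolated" & symbols == "H")
    for (a in h_iso) {
      ke <- ke_from_velocity(fr$velocities[a, , drop = FALSE],
                             atomic_mass("H"))
      pop <- fr$populations[a]
      rows[[length(rows) + 1L]] <- data.frame(
        frame = k, atom = a, species = "H_isolated", ke_eV = ke,
        population = pop,
        label = classify_hydrogen_charge(pop, thresholds, bound = FALSE))
    }
    oh_o <- which(labels[k, ] == "OH" & symbols == "O")
    for (o in oh_o) {
      partner <- which(labels[k, ] == "OH" & symbols == "H")
      # nearest OH-labelled H belongs to this O
      if (length(partner) > 0L) {
        d2 <- min_image_dist2(fr$positions[o, ],
                              fr$positions[partner, , drop = FALSE], fr$box)
        grp <- c(o, partner[which.min(d2)])
      } else grp <- o
      mass <- sum(atomic_mass(symbols[grp]))
      ke <- sum(ke_from_velocity(fr$velocities[grp, , drop = FALSE],
                                 atomic_mass(symbols[grp])))
      rows[[length(rows) + 1L]] <- data.frame(
        frame = k, atom = o, species = "OH", ke_eV = ke,
        population = group_population(fr, grp), label = NA_character_)
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(frame = integer(0), atom = integer(0),
               species = character(0), ke_eV = numeric(0),
               population = numeric(0), label = character(0))
  rownames(out) <- NULL
  h <- out[out$species == "H_isolated", , drop = FALSE]
  summarise_class <- function(sub) {
    if (nrow(sub) == 0L) return(c(neutral_atom = NA_real_,
                                  cation_like = NA_real_,
                                  ambiguous = NA_real_))
    c(neutral_atom = mean(sub$label == "neutral_atom"),
      cation_like = mean(sub$label == "cation_like"),
      ambiguous = mean(sub$label == "ambiguous"))
  }
  attr(out, "summary") <- rbind(
    hyperthermal = summarise_class(h[h$ke_eV >= ke_split, , drop = FALSE]),
    slow = summarise_class(h[h$ke_eV < ke_split, , drop = FALSE]))
  class(out) <- c("charge_census", "data.frame")
  out
}
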