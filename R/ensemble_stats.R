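#' Average species counts versus projectile position
#'
#' Bins every trajectory's census by projectile x and averages the
#' per-species instantaneous counts across trajectories, bin by bin. Bins
#' no trajectory visits are absent from the output.
#'
#' @param censuses list of [census_vs_projectile()] results for an
#'   ensemble sharing one initial speed.
#' @param bin_width bin width in Angstrom (default 1).
#' @param speeds optional numeric vector of the trajectories' initial
#'   speeds; if given, mixed speeds raise an error.
#' @return data frame with columns `x` (bin centre), one mean-count column
#'   per species label, and `n_traj` (trajectories visiting the bin).
#' @export
average_species_curves <- function(censuses, bin_width = 1, speeds = NULL) {
  if (length(censuses) == 0L) stop("empty ensemble")
  if (!is.null(speeds) && length(unique(speeds)) > 1L)
    stop("mixed initial speeds in ensemble; average one speed at a time")
  labs <- species_labels()
  per_traj <- lapply(censuses, function(cs) {
    b <- floor(cs$projectile_x / bin_width)
    agg <- stats::aggregate(cs[, labs], by = list(bin = b), FUN = mean)
    agg
  })
  bins <- sort(unique(unlist(lapply(per_traj, `[[`, "bin"))))
  out <- data.frame(x = (bins + 0.5) * bin_width)
  for (s in labs) out[[s]] <- NA_real_
  out$n_traj <- 0L
  for (i in seq_along(bins)) {
    vals <- do.call(rbind, lapply(per_traj, function(a) {
      j <- match(bins[i], a$bin)
      if (is.na(j)) NULL else unlist(a[j, labs])
    }))
    out[i, labs] <- colMeans(vals)
    out$n_traj[i] <- nrow(vals)
  }
  out
}

#' Histogram of final projectile kinetic energies
#'
#' Exiting trajectories are histogrammed; stopped ones are tallied
#' separately; indeterminate (truncated) ones are excluded with a count.
#'
#' @param final_kes list of [final_kinetic_energy()] results.
#' @param bin_width histogram bin width in eV (default 25).
#' @return list of class `final_ke_histogram`: `breaks`, `counts`, `mids`,
#'   `stopped`, `indeterminate`, `ke` (the exit energies), `sd` (their
#'   standard deviation).
#' @export
final_ke_histogram <- function(final_kes, bin_width = 25) {
  if (length(final_kes) == 0L) stop("empty ensemble")
  status <- vapply(final_kes, `[[`, character(1), "status")
  ke <- vapply(final_kes, `[[`, numeric(1), "ke")[status == "exited"]
  stopped <- sum(status == "stopped")
  indet <- sum(status == "indeterminate")
  if (length(ke) > 0L) {
    lo <- floor(min(ke) / bin_width) * bin_width
    hi <- ceiling(max(ke) / bin_width + 1e-9) * bin_width
    if (hi <= lo) hi <- lo + bin_width
    breaks <- seq(lo, hi, by = bin_width)
    h <- graphics::hist(ke, breaks = breaks, plot = FALSE)
    counts <- h$counts; mids <- h$mids
  } else {
    breaks <- numeric(0); counts <- integer(0); mids <- numeric(0)
  }
  structure(list(breaks = breaks, counts = counts, mids = mids,
                 stopped = stopped, indeterminate = indet, ke = ke,
                 sd = stats::sd(ke)),
            class = "final_ke_histogram")
}

#' @export
print.final_ke_histogram <- function(x, ...) {
  cat(sprintf("final-KE histogram: %d exited (sd %.1f eV), %d stopped, %d indeterminate\n",
              length(x$ke), x$sd, x$stopped, x$indeterminate))
  invisible(x)
}

#' Nuclear stopping power of an ensemble
#'
#' The stopping power is estimated as the mean, over trajectories, of the
#' energy deposited along the track divided by the slab width. Exiting
#' trajectories deposit their initial minus final kinetic energy; stopped
#' trajectories deposit the full initial energy; indeterminate ones are
#' excluded.
#'
#' @param final_kes list of [final_kinetic_energy()] results.
#' @param slab_width width of the water region, Angstrom.
#' @return list with `stopping` (eV/Angstrom), `se` (standard error of the
#'   mean), `n`, `deposited` (per-trajectory energies, eV), `excluded`.
#' @export
nuclear_stopping <- function(final_kes, slab_width) {
  if (length(final_kes) == 0L) stop("empty ensemble")
  if (slab_width <= 0) stop("slab_width must be positive")
  status <- vapply(final_kes, `[[`, character(1), "status")
  e0 <- vapply(final_kes, `[[`, numeric(1), "e0")
  ke <- vapply(final_kes, `[[`, numeric(1), "ke")
  dep <- ifelse(status == "stopped", e0, e0 - ke)
  keep <- status != "indeterminate"
  dep <- dep[keep]
  s <- dep / slab_width
  list(stopping = mean(s),
       se = stats::sd(s) / sqrt(length(s)),
       n = length(s), deposited = dep, excluded = sum(!keep))
}

#' Mean track length between fragment creations
#'
#' Pools all trajectories: total track length traversed inside the slab
#' divided by the total number of cumulative creations of the species
#' (an atom that later recombines still counts as created). A bootstrap
#' over trajectories gives the confidence interval.
#'
#' @param censuses list of [census_vs_projectile()] results.
#' @param species one of `"H_isolated"`, `"OH"`, `"O_isolated"`.
#' @param slab_interval numeric length-2, the water region in x.
#' @param n_boot bootstrap replicates (default 200).
#' @param conf confidence level (default 0.95).
#' @return list with `spacing` (Angstrom), `ci` (bootstrap percentile
#'   interval), `se` (bootstrap standard error), `creations`, `length`;
#'   `spacing` is `NA` with a zero-creation marker when nothing was
#'   created.
#' @export
production_spacing <- function(censuses, species = "H_isolated",
                               slab_interval, n_boot = 200, conf = 0.95) {
  col <- paste0("cum_", species)
  lens <- vapply(censuses, function(cs) {
    mx <- max(cs$projectile_x, na.rm = TRUE)
    max(0, min(mx, slab_interval[2]) - slab_interval[1])
  }, numeric(1))
  crs <- vapply(censuses, function(cs) {
    if (!col %in% names(cs)) stop("census lacks column ", col)
    as.numeric(cs[[col]][nrow(cs)])
  }, numeric(1))
  total_cr <- sum(crs)
  if (total_cr == 0)
    return(list(spacing = NA_real_, ci = c(NA_real_, NA_real_),
                se = NA_real_, creations = 0, length = sum(lens),
                undefined = TRUE))
  boot <- replicate(n_boot, {
    idx <- sample.int(length(lens), replace = TRUE)
    if (sum(crs[idx]) == 0) NA_real_ else sum(lens[idx]) / sum(crs[idx])
  })
  alpha <- (1 - conf) / 2
  list(spacing = sum(lens) / total_cr,
       ci = unname(stats::quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE)),
       se = stats::sd(boot, na.rm = TRUE),
       creations = total_cr, length = sum(lens), undefined = FALSE)
}

#' Summarise an ensemble at one speed
#'
#' Convenience wrapper bundling the species curves, final-KE histogram,
#' stopping power and production spacings of an analysed ensemble.
#'
#' @param censuses list of census results.
#' @param final_kes list of final-KE results.
#' @param speed initial speed, Bohr/fs.
#' @param slab_interval water region in x, Angstrom.
#' @param bin_width_x,bin_width_e bin widths for the curves (Angstrom) and
#'   histogram (eV).
#' @return list of class `ensemble_summary`.
#' @export
ensemble_summary <- function(censuses, final_kes, speed, slab_interval,
                             bin_width_x = 1, bin_width_e = 25) {
  structure(list(
    speed = speed,
    e0 = speed_to_energy(speed),
    species_curves = average_species_curves(censuses, bin_width_x),
    final_ke_histogram = final_ke_histogram(final_kes, bin_width_e),
    stopping = nuclear_stopping(final_kes,
                                slab_interval[2] - slab_interval[1]),
    spacing_H = production_spacing(censuses, "H_isolated", slab_interval),
    spacing_OH = production_spacing(censuses, "OH", slab_interval)),
    class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("ensemble at %.2f Bohr/fs (E0 = %.0f eV)\n", x$speed, x$e0))
  cat(sprintf("  stopping power: %.2f +/- %.2f eV/A\n",
              x$stopping$stopping, x$stopping$se))
  cat(sprintf("  spacing: H every %.2f A, OH every %.2f A\n",
              x$spacing_H$spacing, x$spacing_OH$spacing))
  cat(sprintf("  stopped: %d of %d\n", x$final_ke_histogram$stopped,
              length(x$final_ke_histogram$ke) + x$final_ke_histogram$stopped))
  invisible(x)
}
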