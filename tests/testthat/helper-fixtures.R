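# Shared fixtures: tiny frames and generator settings kept small so the
# default suite stays fast.

water_frame <- function(box = c(10, 10, 10)) {
  xyz_frame(c("O", "H", "H"),
            rbind(c(5, 5, 5), c(5.97, 5, 5), c(4.76, 5.94, 5)),
            box)
}

# Brute-force neighbour oracle: enumerate all 27 periodic images.
brute_pairs <- function(frame, cutoffs) {
  n <- length(frame$symbols)
  box <- frame$box
  shifts <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      cut <- cutoffs[frame$symbols[i], frame$symbols[j]]
      dmin <- Inf
      for (s in seq_len(nrow(shifts))) {
        d <- frame$positions[j, ] + shifts[s, ] * box - frame$positions[i, ]
        dmin <- min(dmin, sqrt(sum(d^2)))
      }
      if (dmin <= cut)
        out[[length(out) + 1L]] <- data.frame(i = i, j = j, dist = dmin)
    }
  }
  if (length(out) == 0L)
    return(data.frame(i = integer(0), j = integer(0), dist = numeric(0)))
  do.call(rbind, out)
}

random_frame <- function(n = 50, box = c(8, 9, 10)) {
  sym <- sample(c("O", "H"), n, replace = TRUE, prob = c(0.4, 0.6))
  pos <- cbind(stats::runif(n, -2, box[1] + 2),  # deliberately unwrapped
               stats::runif(n, 0, box[2]),
               stats::runif(n, 0, box[3]))
  xyz_frame(sym, pos, box)
}

# A small, fast generator configuration: 20 molecules in a short slab.
tiny_params <- function(...) {
  generator_params(n_molecules = 20, box_edge = 9.5, slab_length = 9.5, ...)
}

# Deterministic lossless configuration (no encounters, no drag).
lossless_params <- function(...) {
  tiny_params(p_single = 0, p_double = 0, continuous_loss_rate = 0,
              encounter_spacing = 3, ...)
}
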