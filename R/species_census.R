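#' Distance cutoff table for bond detection
#'
#' Two presets are provided. `"standard"` uses 1.2 Angstrom for every pair
#' except H-H at 0.8 Angstrom; this is the convention used for the
#' coordination-number census. `"peroxide"` additionally extends the O-O
#' cutoff to 1.7 Angstrom so that the ~1.47 Angstrom peroxide O-O bond is
#' detectable; it is the default for molecular formula labelling. Carbon
#' cutoffs (C-H 1.2, C-O 1.6) cover the projectile.
#'
#' @param preset `"standard"` or `"peroxide"`.
#' @param overrides optional named numeric vector of overrides, names like
#'   `"O-O"` (element pair, order irrelevant), values in Angstrom.
#' @return A symmetric numeric matrix of class `cutoff_table` with
#'   dimnames `c("H","O","C")`, entries in Angstrom.
#' @export
cutoff_table <- function(preset = c("standard", "peroxide"), overrides = NULL) {
  preset <- match.arg(preset)
  el <- c("H", "O", "C")
  m <- matrix(1.2, 3, 3, dimnames = list(el, el))
  m["H", "H"] <- 0.8
  m["C", "O"] <- m["O", "C"] <- 1.6
  m["C", "C"] <- 1.6
  if (preset == "peroxide") m["O", "O"] <- 1.7
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      pair <- strsplit(nm, "-", fixed = TRUE)[[1]]
      if (length(pair) != 2L || !all(pair %in% el))
        stop("bad cutoff override name: ", nm)
      m[pair[1], pair[2]] <- m[pair[2], pair[1]] <- overrides[[nm]]
    }
  }
  if (any(m <= 0)) stop("cutoffs must be positive")
  class(m) <- c("cutoff_table", class(m))
  m
}

#' Bonded atom pairs under the minimum-image convention
#'
#' A pair (i, j) is reported once, with its minimum-image distance, iff
#' that distance is within the cutoff for the element pair. Cutoffs must be
#' below half the smallest box edge or the minimum image is ill-defined.
#'
#' @param frame an `xyz_frame`.
#' @param cutoffs a [cutoff_table()].
#' @return data frame with columns `i`, `j` (1-based, i < j), `dist`.
#' @export
neighbor_pairs <- function(frame, cutoffs = cutoff_table()) {
  stopifnot(inherits(frame, "xyz_frame"))
  if (max(cutoffs) >= min(frame$box) / 2)
    stop("cutoff (", max(cutoffs), " A) must be below half the smallest ",
         "box edge (", min(frame$box) / 2, " A)")
  el <- rownames(cutoffs)
  type <- match(frame$symbols, el)
  if (anyNA(type))
    stop("no cutoffs for element(s): ",
         paste(setdiff(unique(frame$symbols), el), collapse = ", "))
  res <- neighbor_pairs_cpp(frame$positions, type,
                            unclass(cutoffs)^2, frame$box)
  sw <- res$i > res$j
  if (any(sw)) {
    tmp <- res$i[sw]; res$i[sw] <- res$j[sw]; res$j[sw] <- tmp
  }
  res[order(res$i, res$j), , drop = FALSE]
}

#' Coordination numbers Z_X(Y) per atom
#'
#' For each atom, the number of neighbours of each element within the
#' cutoff: `Z_O(H) = 2` is an intact water oxygen, `Z_O(H) = 3` a
#' hydronium oxygen, `Z_H(H) = 1` half of an H2 molecule, and so on.
#'
#' @inheritParams neighbor_pairs
#' @return data frame of class `coordination_table` with columns `atom`,
#'   `symbol`, `nH`, `nO`, `nC`.
#' @export
coordination_table <- function(frame, cutoffs = cutoff_table()) {
  pairs <- neighbor_pairs(frame, cutoffs)
  n <- length(frame$symbols)
  Z <- matrix(0L, n, 3, dimnames = list(NULL, c("H", "O", "C")))
  if (nrow(pairs) > 0L) {
    for (elem in c("H", "O", "C")) {
      sel_j <- frame$symbols[pairs$j] == elem
      if (any(sel_j)) {
        t1 <- tabulate(pairs$i[sel_j], nbins = n)
        Z[, elem] <- Z[, elem] + t1
      }
      sel_i <- frame$symbols[pairs$i] == elem
      if (any(sel_i)) {
        t2 <- tabulate(pairs$j[sel_i], nbins = n)
        Z[, elem] <- Z[, elem] + t2
      }
    }
  }
  out <- data.frame(atom = seq_len(n), symbol = frame$symbols,
                    nH = Z[, "H"], nO = Z[, "O"], nC = Z[, "C"])
  class(out) <- c("coordination_table", "data.frame")
  out
}

#' Species labels recognised by the census
#' @return character vector of the label set.
#' @export
species_labels <- function() {
  c("H2O", "OH", "H2O2_O", "H3O_plus", "O_isolated", "H_isolated",
    "H2", "H5O2_bridge_H", "C_bound", "other")
}

#' Classify every atom by the coordination-number taxonomy
#'
#' Oxygen atoms: no neighbours at all is an isolated O atom or ion; one H
#' and no O neighbour is a hydroxyl; one H plus one O neighbour is a
#' peroxide oxygen; two H is water; three H is hydronium. Hydrogen atoms:
#' no neighbours is a free H atom or proton; one H neighbour is molecular
#' hydrogen; two O neighbours is a bridging H (H5O2+-like); one O
#' neighbour inherits the oxygen's molecular label. Carbon and anything
#' bonded to it is `C_bound`. Unexpected coordination patterns fall to
#' `other`. Every atom receives exactly one label.
#'
#' @param frame an `xyz_frame`.
#' @param Z a [coordination_table()] computed from the same frame. If
#'   omitted it is computed with the default cutoffs.
#' @param cutoffs cutoffs used when `Z` (and O-partner lookup) must be
#'   computed.
#' @return list of class `species_inventory`: `counts` (named integer
#'   vector over [species_labels()], counting molecular species, e.g. each
#'   H2 molecule once), `labels` (per-atom character vector).
#' @export
classify_species <- function(frame, Z = NULL, cutoffs = cutoff_table()) {
  if (is.null(Z)) Z <- coordination_table(frame, cutoffs)
  pairs <- neighbor_pairs(frame, cutoffs)
  n <- nrow(Z)
  lab <- rep("other", n)
  sym <- Z$symbol

  isO <- sym == "O"
  lab[isO & Z$nH == 0 & Z$nO == 0 & Z$nC == 0] <- "O_isolated"
  lab[isO & Z$nH == 1 & Z$nO == 0] <- "OH"
  lab[isO & Z$nH == 1 & Z$nO == 1] <- "H2O2_O"
  lab[isO & Z$nH == 2] <- "H2O"
  lab[isO & Z$nH == 3] <- "H3O_plus"

  isH <- sym == "H"
  lab[isH & Z$nH == 0 & Z$nO == 0 & Z$nC == 0] <- "H_isolated"
  lab[isH & Z$nH == 1 & Z$nO == 0] <- "H2"
  lab[isH & Z$nO == 2] <- "H5O2_bridge_H"

  # H with a single O partner inherits that oxygen's label
  inherit <- which(isH & Z$nO == 1)
  if (length(inherit) > 0L && nrow(pairs) > 0L) {
    o_of_h <- rep(NA_integer_, n)
    oi <- sym[pairs$i] == "O" & sym[pairs$j] == "H"
    o_of_h[pairs$j[oi]] <- pairs$i[oi]
    oj <- sym[pairs$j] == "O" & sym[pairs$i] == "H"
    o_of_h[pairs$i[oj]] <- pairs$j[oj]
    ok <- !is.na(o_of_h[inherit])
    lab[inherit[ok]] <- lab[o_of_h[inherit[ok]]]
  }

  # carbon and everything bonded to it
  lab[sym == "C"] <- "C_bound"
  lab[Z$nC > 0] <- "C_bound"

  counts <- integer(length(species_labels()))
  names(counts) <- species_labels()
  o_like <- c("H2O", "OH", "H2O2_O", "H3O_plus", "O_isolated")
  for (s in o_like) counts[s] <- sum(lab == s & isO)
  counts["H_isolated"] <- sum(lab == "H_isolated")
  counts["H2"] <- sum(lab == "H2") %/% 2L
  counts["H5O2_bridge_H"] <- sum(lab == "H5O2_bridge_H")
  counts["C_bound"] <- sum(lab == "C_bound")
  counts["other"] <- sum(lab == "other")

  structure(list(counts = counts, labels = lab),
            class = "species_inventory")
}

#' @export
print.species_inventory <- function(x, ...) {
  nz <- x$counts[x$counts > 0]
  cat("species inventory:",
      paste(sprintf("%s=%d", names(nz), nz), collapse = ", "), "\n")
  invisible(x)
}

#' Connected molecular fragments of the bond graph
#'
#' Builds the bond graph from [neighbor_pairs()] and returns its connected
#' components with molecular formulas in Hill order (C first, then H, then
#' the remaining elements alphabetically; without carbon, all elements
#' alphabetically).
#'
#' @inheritParams neighbor_pairs
#' @return data frame with columns `component`, `formula`, `n_atoms`, and
#'   attribute `members`, a list of atom-index vectors.
#' @export
molecular_components <- function(frame, cutoffs = cutoff_table("peroxide")) {
  pairs <- neighbor_pairs(frame, cutoffs)
  n <- length(frame$symbols)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(pairs) > 0L)
    g <- igraph::add_edges(g, rbind(pairs$i, pairs$j))
  comp <- igraph::components(g)$membership
  members <- split(seq_len(n), comp)
  formula <- vapply(members, function(idx)
    hill_formula(frame$symbols[idx]), character(1))
  out <- data.frame(component = seq_along(members), formula = unname(formula),
                    n_atoms = lengths(members), row.names = NULL)
  attr(out, "members") <- unname(members)
  out
}

hill_formula <- function(symbols) {
  tab <- table(symbols)
  els <- names(tab)
  if ("C" %in% els) {
    ord <- c("C", if ("H" %in% els) "H", sort(setdiff(els, c("C", "H"))))
  } else {
    ord <- sort(els)
  }
  paste0(vapply(ord, function(e)
    paste0(e, if (tab[[e]] > 1L) tab[[e]] else ""), character(1)),
    collapse = "")
}

#' Species census along a trajectory
#'
#' Runs [classify_species()] on every frame and keys the result by the
#' projectile x coordinate. Instantaneous counts are reported next to
#' cumulative creation counts, which are monotone non-decreasing: an atom
#' that has ever carried a fragment label stays counted even if it later
#' recombines. OH creations count only oxygens arriving at hydroxyl
#' coordination from a bound state (e.g. water losing one H): an isolated
#' O radical that drifts within the cutoff of a passing hydrogen is a
#' capture, not a dissociation product, and is excluded.
#'
#' @param traj an `md_trajectory`.
#' @param cutoffs a [cutoff_table()] (default: `"standard"` preset).
#' @return data frame of class `species_census` with one row per frame:
#'   `frame`, `time`, `projectile_x`, one column per species label,
#'   cumulative columns `cum_H_isolated`, `cum_OH`, `cum_O_isolated`, and
#'   attributes `labels` (frames x atoms character matrix) and `symbols`.
#' @export
census_vs_projectile <- function(traj, cutoffs = cutoff_table()) {
  stopifnot(inherits(traj, "md_trajectory"))
  nf <- length(traj$frames)
  idx <- traj$frames[[1]]$projectile
  n <- length(traj$frames[[1]]$symbols)
  counts <- matrix(0L, nf, length(species_labels()),
                   dimnames = list(NULL, species_labels()))
  labels <- matrix(NA_character_, nf, n)
  x <- numeric(nf)
  tm <- numeric(nf)
  ever_h <- logical(n)
  ever_oh <- logical(n)
  ever_o <- logical(n)
  oh_streak <- integer(n)
  pre_oh_lab <- rep("", n)
  cum <- matrix(0L, nf, 3,
                dimnames = list(NULL, c("cum_H_isolated", "cum_OH",
                                        "cum_O_isolated")))
  for (k in seq_len(nf)) {
    fr <- traj$frames[[k]]
    inv <- classify_species(fr, cutoffs = cutoffs)
    counts[k, ] <- inv$counts
    labels[k, ] <- inv$labels
    x[k] <- if (!is.na(idx)) fr$positions[idx, 1L] else NA_real_
    tm[k] <- fr$time
    ever_h <- ever_h | (inv$labels == "H_isolated" & fr$symbols == "H")
    # OH production = persistent arrival at hydroxyl coordination from a
    # bound state. Two guards against single-frame artefacts: a complete
    # dissociation whose two H's cross the cutoff a frame apart shows a
    # transient OH (persistence < 2 frames), and an isolated O radical
    # drifting past a hydrogen is capture, not production.
    is_oh <- inv$labels == "OH" & fr$symbols == "O"
    pre_oh_lab[!is_oh] <- inv$labels[!is_oh]
    oh_streak <- ifelse(is_oh, oh_streak + 1L, 0L)
    ever_oh <- ever_oh | (oh_streak >= 2L & pre_oh_lab != "O_isolated")
    ever_o <- ever_o | (inv$labels == "O_isolated" & fr$symbols == "O")
    cum[k, ] <- c(sum(ever_h), sum(ever_oh), sum(ever_o))
  }
  out <- data.frame(frame = seq_len(nf), time = tm, projectile_x = x,
                    counts, cum, check.names = FALSE)
  attr(out, "labels") <- labels
  attr(out, "symbols") <- traj$frames[[1]]$symbols
  class(out) <- c("species_census", "data.frame")
  out
}
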