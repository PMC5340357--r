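#' Construct a single trajectory frame
#'
#' A frame is one time-step snapshot: element symbols, Cartesian positions,
#' the orthorhombic box, and optionally per-atom velocities and electron
#' populations. Positions are stored unwrapped; periodicity is applied by
#' the distance routines via the minimum-image convention.
#'
#' @param symbols character vector of element symbols, one per atom.
#' @param positions numeric matrix, n x 3, Angstrom.
#' @param box numeric length-3, orthorhombic edge lengths in Angstrom.
#' @param time time stamp in fs.
#' @param velocities optional n x 3 matrix, Angstrom/fs.
#' @param populations optional numeric vector, electrons per atom (>= 0).
#' @param projectile 1-based index of the projectile atom, or `NA` if none.
#' @return A list of class `xyz_frame`.
#' @export
xyz_frame <- function(symbols, positions, box, time = 0,
                      velocities = NULL, populations = NULL,
                      projectile = NA_integer_) {
  positions <- as.matrix(positions)
  n <- length(symbols)
  if (n < 1L) stop("frame must contain at least one atom")
  if (!is.matrix(positions) || nrow(positions) != n || ncol(positions) != 3L)
    stop("positions must be an n x 3 matrix matching symbols")
  if (!all(is.finite(positions))) stop("positions must be finite")
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop("box must be three positive edge lengths")
  if (!is.null(velocities)) {
    velocities <- as.matrix(velocities)
    if (nrow(velocities) != n || ncol(velocities) != 3L)
      stop("velocities must be an n x 3 matrix")
  }
  if (!is.null(populations)) {
    if (length(populations) != n) stop("populations must have one entry per atom")
    if (any(populations < 0)) stop("populations must be non-negative")
  }
  if (!is.na(projectile) && (projectile < 1L || projectile > n))
    stop("projectile index out of range")
  structure(
    list(symbols = as.character(symbols), positions = positions,
         box = as.numeric(box), time = as.numeric(time),
         velocities = velocities, populations = populations,
         projectile = as.integer(projectile)),
    class = "xyz_frame")
}

#' Construct a trajectory from frames
#'
#' @param frames list of [xyz_frame()] objects with strictly increasing
#'   times, identical atom counts and a constant projectile index.
#' @param initial_speed initial projectile speed, Bohr/fs.
#' @param snapshot_id integer id of the originating slab snapshot.
#' @param entry_point numeric length-2, transverse (y, z) entry point in
#'   Angstrom.
#' @param seed integer seed the track was generated from, or `NA`.
#' @param slab_interval numeric length-2, (x_entry, x_exit) of the water
#'   region in Angstrom.
#' @return A list of class `md_trajectory`.
#' @export
md_trajectory <- function(frames, initial_speed = NA_real_,
                          snapshot_id = NA_integer_,
                          entry_point = c(NA_real_, NA_real_),
                          seed = NA_integer_, slab_interval = NULL) {
  if (length(frames) < 1L) stop("trajectory needs at least one frame")
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  n <- vapply(frames, function(f) length(f$symbols), integer(1))
  if (length(unique(n)) != 1L) stop("all frames must have the same atom count")
  proj <- vapply(frames, function(f) f$projectile, integer(1))
  if (length(unique(proj)) != 1L) stop("projectile index must be constant")
  structure(
    list(frames = frames, initial_speed = initial_speed,
         snapshot_id = as.integer(snapshot_id),
         entry_point = as.numeric(entry_point),
         seed = seed, slab_interval = slab_interval),
    class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  f1 <- x$frames[[1]]
  cat(sprintf("md_trajectory: %d frames, %d atoms, t = %.3f..%.3f fs\n",
              length(x$frames), length(f1$symbols),
              f1$time, x$frames[[length(x$frames)]]$time))
  if (!is.na(x$initial_speed))
    cat(sprintf("  initial speed %.3f Bohr/fs (%.1f eV)\n", x$initial_speed,
                speed_to_energy(x$initial_speed)))
  if (!is.null(x$slab_interval))
    cat(sprintf("  slab x-interval [%.3f, %.3f] A\n",
                x$slab_interval[1], x$slab_interval[2]))
  cat(sprintf("  velocities: %s, populations: %s\n",
              ifelse(is.null(f1$velocities), "absent", "present"),
              ifelse(is.null(f1$populations), "absent", "present")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Extended-XYZ dialect.
#
# Comment line: Lattice="ax 0 0 0 by 0 0 0 cz" Time=<fs> [Projectile=<i0>]
#   [Speed=<bohr/fs>] [Slab=<x0:x1>] Properties=species:S:1:pos:R:3[:vel:R:3]
#   [:mulliken:R:1]
# Projectile index is 0-based on disk (converted to 1-based in memory).
# Only orthorhombic lattices are supported.
# ---------------------------------------------------------------------------

fmt_num <- function(x) sprintf("%.10g", x)

comment_field <- function(line, key) {
  m <- regmatches(line, regexec(paste0(key, '="([^"]*)"'), line))[[1]]
  if (length(m) == 2L) return(m[2])
  m <- regmatches(line, regexec(paste0(key, "=([^ ]+)"), line))[[1]]
  if (length(m) == 2L) return(m[2])
  NULL
}

#' Write a trajectory to an extended-XYZ file
#'
#' Numeric fields are printed with 10 significant digits so that a
#' write/read round trip preserves values to better than 1e-9. Velocity and
#' population columns are written only when present on the frames.
#'
#' @param traj an `md_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_trajectory()]
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "md_trajectory"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (fr in traj$frames) {
    has_vel <- !is.null(fr$velocities)
    has_pop <- !is.null(fr$populations)
    props <- paste0("species:S:1:pos:R:3",
                    if (has_vel) ":vel:R:3" else "",
                    if (has_pop) ":mulliken:R:1" else "")
    meta <- sprintf('Lattice="%s 0 0 0 %s 0 0 0 %s" Time=%s',
                    fmt_num(fr$box[1]), fmt_num(fr$box[2]), fmt_num(fr$box[3]),
                    fmt_num(fr$time))
    if (!is.na(fr$projectile))
      meta <- paste0(meta, " Projectile=", fr$projectile - 1L)
    if (!is.na(traj$initial_speed))
      meta <- paste0(meta, " Speed=", fmt_num(traj$initial_speed))
    if (!is.null(traj$slab_interval))
      meta <- paste0(meta, " Slab=", fmt_num(traj$slab_interval[1]), ":",
                     fmt_num(traj$slab_interval[2]))
    meta <- paste0(meta, " Properties=", props)
    writeLines(c(as.character(length(fr$symbols)), meta), con)
    cols <- cbind(fr$positions,
                  if (has_vel) fr$velocities,
                  if (has_pop) fr$populations)
    body <- paste(fr$symbols, apply(cols, 1L, function(r)
      paste(fmt_num(r), collapse = " ")))
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a trajectory from an extended-XYZ file
#'
#' Accepts the dialect written by [write_trajectory()]: per-frame atom
#' count, a comment line declaring an orthorhombic `Lattice`, `Time`,
#' optional `Projectile` (0-based), `Speed` and `Slab` fields and a
#' `Properties` string, then one line per atom. Missing optional columns
#' yield absent fields, never zeros.
#'
#' @param path file path.
#' @return an `md_trajectory`.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  frames <- list()
  speed <- NA_real_
  slab <- NULL
  i <- 1L
  nl <- length(lines)
  while (i <= nl) {
    if (!grepl("^\\s*[0-9]+\\s*$", lines[i]))
      stop("malformed header at line ", i, ": expected atom count, got '",
           lines[i], "'")
    nat <- as.integer(lines[i])
    if (i + 1L > nl) stop("malformed header at line ", i + 1L, ": missing comment line")
    cm <- lines[i + 1L]
    lat <- comment_field(cm, "Lattice")
    if (is.null(lat)) stop("malformed header at line ", i + 1L, ": no Lattice field")
    lv <- as.numeric(strsplit(trimws(lat), "\\s+")[[1]])
    if (length(lv) != 9L || any(is.na(lv)))
      stop("malformed header at line ", i + 1L, ": bad Lattice field")
    off <- lv[c(2, 3, 4, 6, 7, 8)]
    if (any(abs(off) > 1e-12))
      stop("unsupported geometry at line ", i + 1L, ": lattice is not orthorhombic")
    box <- lv[c(1, 5, 9)]
    tm <- comment_field(cm, "Time")
    if (is.null(tm)) stop("malformed header at line ", i + 1L, ": no Time field")
    proj <- comment_field(cm, "Projectile")
    proj <- if (is.null(proj)) NA_integer_ else as.integer(proj) + 1L
    sp <- comment_field(cm, "Speed")
    if (!is.null(sp)) speed <- as.numeric(sp)
    sl <- comment_field(cm, "Slab")
    if (!is.null(sl)) slab <- as.numeric(strsplit(sl, ":")[[1]])
    props <- comment_field(cm, "Properties")
    if (is.null(props)) stop("malformed header at line ", i + 1L, ": no Properties field")
    has_vel <- grepl("vel:R:3", props, fixed = TRUE)
    has_pop <- grepl("mulliken:R:1", props, fixed = TRUE)
    ncol_expect <- 4L + (if (has_vel) 3L else 0L) + (if (has_pop) 1L else 0L)
    if (i + 1L + nat > nl)
      stop("structural error: frame starting at line ", i,
           " declares ", nat, " atoms but the file ends early")
    block <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(block), "\\s+")
    nt <- lengths(toks)
    if (any(nt != ncol_expect))
      stop("malformed atom line ", i + 1L + which(nt != ncol_expect)[1],
           ": expected ", ncol_expect, " columns")
    toks <- matrix(unlist(toks), nrow = nat, byrow = TRUE)
    num <- matrix(as.numeric(toks[, -1L, drop = FALSE]), nrow = nat)
    pos <- num[, 1:3, drop = FALSE]
    vel <- if (has_vel) num[, 4:6, drop = FALSE] else NULL
    pop <- if (has_pop) num[, ncol(num)] else NULL
    frames[[length(frames) + 1L]] <-
      xyz_frame(toks[, 1L], pos, box, time = as.numeric(tm),
                velocities = vel, populations = pop, projectile = proj)
    i <- i + 2L + nat
  }
  if (length(frames) == 0L) stop("file contains no frames: ", path)
  nat_all <- vapply(frames, function(f) length(f$symbols), integer(1))
  if (length(unique(nat_all)) != 1L)
    stop("structural error: inconsistent atom counts across frames")
  md_trajectory(frames, initial_speed = speed, slab_interval = slab)
}

#' Write an ensemble manifest
#'
#' @param entries data frame with columns `path`, `speed_bohr_per_fs`,
#'   `snapshot`, `entry_y`, `entry_z`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(entries, path) {
  need <- c("path", "speed_bohr_per_fs", "snapshot", "entry_y", "entry_z")
  if (!all(need %in% names(entries)))
    stop("manifest entries need columns: ", paste(need, collapse = ", "))
  utils::write.csv(entries[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load an ensemble of trajectories grouped by initial speed
#'
#' @param manifest path to a manifest CSV with header
#'   `path,speed_bohr_per_fs,snapshot,entry_y,entry_z`. Relative trajectory
#'   paths are resolved against the manifest's directory.
#' @return A named list (one element per declared speed, names are the
#'   speeds) of lists of `md_trajectory` objects, with attribute `counts`.
#' @export
load_ensemble <- function(manifest) {
  if (!file.exists(manifest)) stop("no such manifest: ", manifest)
  df <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("path", "speed_bohr_per_fs", "snapshot", "entry_y", "entry_z")
  if (!all(need %in% names(df)))
    stop("manifest is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (nrow(df) == 0L) {
    warning("manifest is empty: ", manifest)
    return(structure(list(), counts = integer(0)))
  }
  if (anyDuplicated(df$path))
    stop("duplicate path(s) in manifest: ",
         paste(unique(df$path[duplicated(df$path)]), collapse = ", "))
  base <- dirname(manifest)
  full <- ifelse(grepl("^(/|[A-Za-z]:)", df$path), df$path,
                 file.path(base, df$path))
  missing <- full[!file.exists(full)]
  if (length(missing) > 0L)
    stop("manifest references missing file(s): ",
         paste(missing, collapse = ", "))
  groups <- split(seq_len(nrow(df)), df$speed_bohr_per_fs)
  out <- lapply(groups, function(idx) {
    lapply(idx, function(k) {
      tr <- read_trajectory(full[k])
      tr$initial_speed <- df$speed_bohr_per_fs[k]
      tr$snapshot_id <- as.integer(df$snapshot[k])
      tr$entry_point <- c(df$entry_y[k], df$entry_z[k])
      tr
    })
  })
  attr(out, "counts") <- vapply(out, length, integer(1))
  out
}
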