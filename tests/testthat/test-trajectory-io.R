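test_that("a minimal positions-only file reads with optional fields absent", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c(
    "3",
    'Lattice="10 0 0 0 10 0 0 0 10" Time=0 Properties=species:S:1:pos:R:3',
    "O 5 5 5", "H 5.97 5 5", "H 4.76 5.94 5",
    "3",
    'Lattice="10 0 0 0 10 0 0 0 10" Time=0.5 Properties=species:S:1:pos:R:3',
    "O 5 5 5", "H 5.97 5 5", "H 4.76 5.94 5"), path)
  tr <- read_trajectory(path)
  expect_length(tr$frames, 2L)
  expect_null(tr$frames[[1]]$velocities)
  expect_null(tr$frames[[1]]$populations)
  expect_equal(tr$frames[[2]]$time, 0.5)
})

test_that("write/read round trip preserves every numeric field", {
  res <- generate_track(tiny_params(), speed = 2, entry = c(4, 5), seed = 21)
  traj <- res$trajectory
  path <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_length(back$frames, length(traj$frames))
  for (k in seq_along(traj$frames)) {
    a <- traj$frames[[k]]; b <- back$frames[[k]]
    expect_identical(a$symbols, b$symbols)
    expect_equal(a$positions, b$positions, tolerance = 1e-9)
    expect_equal(a$velocities, b$velocities, tolerance = 1e-9)
    expect_equal(a$populations, b$populations, tolerance = 1e-9)
    expect_equal(a$box, b$box, tolerance = 1e-12)
    expect_equal(a$time, b$time, tolerance = 1e-9)
    expect_identical(a$projectile, b$projectile)
  }
  expect_equal(back$initial_speed, 2)
  expect_equal(back$slab_interval, traj$slab_interval)
  # write/read/write is byte-identical (idempotent formatting)
  path2 <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("populations survive a generator round trip on every frame", {
  res <- generate_track(tiny_params(populations_mode = TRUE), speed = 1,
                        entry = c(5, 5), seed = 8)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(res$trajectory, path)
  back <- read_trajectory(path)
  expect_true(all(vapply(back$frames,
                         function(f) !is.null(f$populations), logical(1))))
})

test_that("the full 128-molecule slab with projectile writes 385 atom rows", {
  slab <- build_slab(generator_params(), snapshot_seed = 2)
  fr <- xyz_frame(c(slab$symbols, "C"),
                  rbind(slab$positions, c(-2, 7, 7)), slab$box,
                  projectile = 385L)
  tr <- md_trajectory(list(fr))
  path <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(tr, path)
  expect_identical(readLines(path, n = 1L), "385")
  # projectile index is 0-based on disk
  expect_match(readLines(path, n = 2L)[2], "Projectile=384", fixed = TRUE)
})

test_that("malformed files are rejected with located errors", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("not-a-count", "junk"), path)
  expect_error(read_trajectory(path), "line 1")

  writeLines(c(
    "1", 'Lattice="10 0 0 0 10 0 0 0 10" Time=0 Properties=species:S:1:pos:R:3',
    "O 1 1 1",
    "2", 'Lattice="10 0 0 0 10 0 0 0 10" Time=1 Properties=species:S:1:pos:R:3',
    "O 1 1 1", "H 2 1 1"), path)
  expect_error(read_trajectory(path), "inconsistent atom counts")

  writeLines(c(
    "1", 'Lattice="10 1 0 0 10 0 0 0 10" Time=0 Properties=species:S:1:pos:R:3',
    "O 1 1 1"), path)
  expect_error(read_trajectory(path), "orthorhombic")

  expect_error(read_trajectory(tempfile()), "no such file")
})

test_that("manifests group trajectories by speed and validate paths", {
  dir <- withr::local_tempdir()
  p <- lossless_params()
  n <- 0L
  entries <- list()
  for (speed in c(1, 2, 3, 4)) {
    for (r in 1:2) {
      n <- n + 1L
      tr <- generate_track(p, speed = speed, entry = c(4, 4),
                           seed = 100 + n)$trajectory
      f <- sprintf("t%02d.xyz", n)
      write_trajectory(tr, file.path(dir, f))
      entries[[n]] <- data.frame(path = f, speed_bohr_per_fs = speed,
                                 snapshot = 1L, entry_y = 4, entry_z = 4)
    }
  }
  man <- file.path(dir, "manifest.csv")
  write_manifest(do.call(rbind, entries), man)
  groups <- load_ensemble(man)
  expect_length(groups, 4L)
  expect_identical(unname(attr(groups, "counts")), rep(2L, 4))
  expect_equal(groups[["3"]][[1]]$initial_speed, 3)

  # duplicate path
  bad <- do.call(rbind, entries)
  bad$path[2] <- bad$path[1]
  man2 <- file.path(dir, "manifest2.csv")
  write_manifest(bad, man2)
  expect_error(load_ensemble(man2), "duplicate")

  # missing file
  bad2 <- do.call(rbind, entries)
  bad2$path[1] <- "missing.xyz"
  man3 <- file.path(dir, "manifest3.csv")
  write_manifest(bad2, man3)
  expect_error(load_ensemble(man3), "missing.xyz")

  # empty manifest warns and returns an empty grouping
  man4 <- file.path(dir, "manifest4.csv")
  write_manifest(do.call(rbind, entries)[0, ], man4)
  expect_warning(g0 <- load_ensemble(man4), "empty")
  expect_length(g0, 0L)
})
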