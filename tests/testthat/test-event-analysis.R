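step_profile <- function(x, loss) {
  structure(data.frame(x = x, time = seq_along(x), loss = loss),
            class = c("energy_loss_profile", "data.frame"))
}

test_that("a clean step is a single event with the step as transfer", {
  x <- seq(0, 2, by = 0.1)
  loss <- c(rep(0, 9), 10, 20, rep(30, 10))
  ev <- detect_events(step_profile(x, loss))
  disc <- ev[ev$discrete, ]
  expect_identical(nrow(disc), 1L)
  expect_equal(disc$transfer, 30)
  expect_equal(disc$peak, 0)
})

test_that("a restored excursion is peak height, not transfer", {
  x <- seq(0, 2, by = 0.1)
  loss <- c(rep(0, 9), 80, rep(30, 11))
  ev <- detect_events(step_profile(x, loss))
  disc <- ev[ev$discrete, ]
  expect_identical(nrow(disc), 1L)
  expect_equal(disc$transfer, 30)
  expect_equal(disc$peak, 50)
})

test_that("a fully restored excursion is elastic-only", {
  x <- seq(0, 2, by = 0.1)
  loss <- c(rep(0, 9), 40, rep(0, 11))
  ev <- detect_events(step_profile(x, loss))
  disc <- ev[ev$discrete, ]
  expect_identical(nrow(disc), 1L)
  expect_identical(disc$channel, "elastic_only")
  expect_equal(disc$peak, 40)
})

test_that("a linear ramp yields no discrete events, one continuous segment", {
  x <- seq(0, 15, length.out = 60)
  loss <- seq(0, 40, length.out = 60)
  ev <- detect_events(step_profile(x, loss))
  expect_identical(sum(ev$discrete), 0L)
  cont <- ev[!ev$discrete, ]
  expect_identical(nrow(cont), 1L)
  expect_identical(cont$channel, "vibrational")
  expect_equal(cont$transfer, 40)
})

test_that("profiles shorter than the smoothing window are rejected", {
  expect_error(detect_events(step_profile(1:3, c(0, 1, 2))), "smoothing")
})

test_that("event rows telescope to the terminal loss (ledger closure)", {
  p <- tiny_params()
  for (s in 1:6) {
    res <- generate_track(p, speed = sample(1:4, 1), entry = c(5, 5),
                          seed = 200 + s)
    prof <- energy_loss_profile(res$trajectory)
    ev <- detect_events(prof)
    expect_equal(sum(ev$transfer), attr(ev, "terminal_loss"),
                 tolerance = 1e-6)
    # and the ground-truth ledger closes too
    expect_equal(attr(res$events, "e0"),
                 attr(res$events, "final_ke") + sum(res$events$transfer) +
                   attr(res$events, "continuous_loss"),
                 tolerance = 1e-6)
  }
})

test_that("census annotation resolves dissociation channels", {
  p <- generator_params(encounter_spacing = 5, p_single = 0.5, p_double = 0.5)
  hits <- 0L
  for (s in 1:4) {
    res <- generate_track(p, speed = 2, entry = c(7, 7), seed = 300 + s)
    an <- analyze_track(res$trajectory)
    det <- an$events[an$events$discrete, ]
    truth <- res$events[res$events$channel != "vibrational", ]
    if (nrow(det) == nrow(truth) && nrow(det) > 0) {
      hits <- hits + sum(det$channel == truth$channel)
      expect_equal(det$transfer, truth$transfer, tolerance = 0.15)
    }
  }
  expect_gt(hits, 0L)
})

test_that("trajectory classification maps events to the published categories", {
  # lossless: non-dissociative transit
  res <- generate_track(lossless_params(), speed = 3, entry = c(5, 5), seed = 2)
  expect_identical(as.character(analyze_track(res$trajectory)$class),
                   "non_dissociative_transit")

  # one double dissociation: complete dissociation
  p2 <- tiny_params(p_single = 0, p_double = 1, encounter_spacing = 30,
                    continuous_loss_rate = 0)
  for (s in 1:10) {
    r2 <- generate_track(p2, speed = 3, entry = c(5, 5), seed = 400 + s)
    if (sum(r2$events$channel == "double_dissociation") == 1L) break
  }
  expect_identical(sum(r2$events$channel == "double_dissociation"), 1L)
  expect_identical(as.character(analyze_track(r2$trajectory)$class),
                   "complete_dissociation")

  # pure continuous loss above the step threshold
  p3 <- tiny_params(p_single = 0, p_double = 0, continuous_loss_rate = 3)
  r3 <- generate_track(p3, speed = 2, entry = c(5, 5), seed = 7)
  expect_identical(as.character(analyze_track(r3$trajectory)$class),
                   "continuous_loss")

  # stopped
  p4 <- tiny_params(p_single = 1, p_double = 0, encounter_spacing = 2,
                    transfer_single = c(400, 500), continuous_loss_rate = 0)
  r4 <- generate_track(p4, speed = 1, entry = c(5, 5), seed = 9)
  expect_identical(as.character(analyze_track(r4$trajectory)$class),
                   "stopped")
})

test_that("binding energies partition the transfer as a small fraction", {
  p <- event_energy_partition(50, "single_dissociation")
  expect_equal(p$binding_cost, 5)
  expect_equal(p$fraction, 0.10)
  expect_false(p$inconsistent)

  d <- event_energy_partition(150, "double_dissociation")
  expect_equal(d$binding_cost, 9.4)
  expect_equal(d$fragment_budget, 140.6)
  expect_equal(d$fraction, 9.4 / 150, tolerance = 1e-12)

  bad <- event_energy_partition(4, "single_dissociation")
  expect_true(bad$inconsistent)
})

test_that("hyperthermal secondaries are tracked; quiet tracks yield none", {
  p <- tiny_params(p_single = 1, p_double = 0, encounter_spacing = 4,
                   continuous_loss_rate = 0, transfer_single = c(45, 50))
  res <- generate_track(p, speed = 2, entry = c(5, 5), seed = 77)
  expect_gte(nrow(res$events), 1L)
  cs <- census_vs_projectile(res$trajectory)
  sec <- track_secondaries(res$trajectory, cs)
  expect_gte(nrow(sec), 1L)
  expect_true(all(sec$species == "H_isolated"))
  expect_true(all(sec$ke_created > 10))

  quiet <- generate_track(lossless_params(), speed = 2, entry = c(5, 5),
                          seed = 78)
  csq <- census_vs_projectile(quiet$trajectory)
  expect_identical(nrow(track_secondaries(quiet$trajectory, csq)), 0L)
})

test_that("a stopped projectile hands the lead to an energetic O fragment", {
  # equal split gives the O fragment a large share; big double transfer
  p <- tiny_params(p_single = 0, p_double = 1, encounter_spacing = 2,
                   transfer_double = c(170, 174), fragment_ke_split = "equal",
                   continuous_loss_rate = 0)
  res <- generate_track(p, speed = 1, entry = c(5, 5), seed = 12)
  expect_true(attr(res$events, "stopped"))
  cs <- census_vs_projectile(res$trajectory)
  sec <- track_secondaries(res$trajectory, cs)
  expect_gte(nrow(sec), 1L)
  expect_true(any(sec$handover))
})

test_that("H secondaries fly straighter and farther than heavy fragments", {
  p <- tiny_params(p_single = 0, p_double = 1, encounter_spacing = 4,
                   transfer_double = c(140, 150), fragment_ke_split = "equal",
                   continuous_loss_rate = 0)
  disp <- list(H = numeric(0), O = numeric(0))
  for (s in 1:5) {
    res <- generate_track(p, speed = 3, entry = c(5, 5), seed = 500 + s)
    cs <- census_vs_projectile(res$trajectory)
    sec <- track_secondaries(res$trajectory, cs)
    disp$H <- c(disp$H, sec$displacement[sec$species == "H_isolated"])
    disp$O <- c(disp$O, sec$displacement[sec$species != "H_isolated"])
  }
  expect_gt(length(disp$H), 0L)
  expect_gt(length(disp$O), 0L)
  expect_gt(mean(disp$H), mean(disp$O))
})
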