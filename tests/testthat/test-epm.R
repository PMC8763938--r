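# Zone classification (against an independent point-in-polygon oracle),
# debounced entry detection, per-epoch metrics and the latched gate.

test_that("zone classification matches an independent geometry oracle", {
  geom <- epm_geometry()
  g <- gen_epm_track(epm_config(duration = 60, seed = 23))
  zones <- classify_zone(g$track, geom)
  # oracle: mgcv::in.out on each polygon
  oracle <- rep("off_maze", nrow(g$track))
  pts <- cbind(g$track$x, g$track$y)
  for (nm in names(geom$polygons)) {
    hit <- mgcv::in.out(geom$polygons[[nm]], pts)
    oracle[hit & oracle == "off_maze"] <- nm
  }
  agree <- mean(zones$zone_detail == oracle)
  expect_gte(agree, 0.999)  # boundary-convention frames only
  # zone labels partition the frames
  expect_true(all(zones$zone %in% c("open", "closed", "centre",
                                    "off_maze")))
  expect_equal(nrow(zones), nrow(g$track))
})

test_that("known positions classify to the right zones", {
  geom <- epm_geometry()
  track <- data.frame(t = (0:3) / 25,
                      x = c(0, 6, 0, 200),
                      y = c(0, 0, -6, 200))
  z <- classify_zone(track, geom)
  expect_equal(z$zone, c("centre", "open", "closed", "off_maze"))
  expect_equal(z$zone_detail[2], "open1")
})

test_that("position gaps interpolate up to the limit, then go off_maze", {
  geom <- epm_geometry()
  t <- (0:99) / 25
  x <- rep(20, 100); y <- rep(0, 100)
  x[40:44] <- NA                       # 0.2 s gap -> interpolated
  x[60:90] <- NA                       # 1.2 s gap -> off_maze
  z <- classify_zone(data.frame(t = t, x = x, y = y), geom)
  expect_equal(unique(z$zone[40:44]), "open")
  expect_equal(unique(z$zone[60:90]), "off_maze")
})

test_that("scripted trajectories yield exact entry counts", {
  zones <- make_scripted_zones(list(list("closed1", 4), list("centre", 2),
                                    list("open1", 4), list("centre", 2),
                                    list("closed2", 4)))
  ev <- detect_arm_entries(zones)
  expect_equal(sum(ev$type == "open_entry"), 1)
  expect_equal(sum(ev$type == "closed_entry"), 2)  # start + re-entry
  expect_equal(ev$time[ev$type == "open_entry"], 6)

  # never leaves the closed arm -> a single initial entry, no others
  z2 <- make_scripted_zones(list(list("closed1", 10)))
  ev2 <- detect_arm_entries(z2)
  expect_equal(nrow(ev2), 1)

  # 0.2 s flicker into open is debounced away
  z3 <- make_scripted_zones(list(list("closed1", 5), list("open1", 0.2),
                                 list("closed1", 5)))
  ev3 <- detect_arm_entries(z3)
  expect_equal(sum(ev3$type == "open_entry"), 0)
})

test_that("entry detection mirrors under time reversal", {
  zones <- make_scripted_zones(list(list("closed1", 4), list("centre", 2),
                                    list("open1", 6), list("centre", 2),
                                    list("closed2", 4)))
  fwd <- detect_arm_entries(zones)
  rev_zones <- zones
  rev_zones$zone <- rev(zones$zone)
  rev_zones$zone_detail <- rev(zones$zone_detail)
  bwd <- detect_arm_entries(rev_zones)
  # entries of the reversed series are the exits of the forward one:
  # same per-type counts on this symmetric script
  expect_equal(table(fwd$type), table(bwd$type))
})

test_that("arm-end events mark the farthest point of each visit", {
  g <- gen_epm_track(epm_config(duration = 120, seed = 24))
  zones <- classify_zone(g$track)
  ev <- detect_arm_entries(zones, g$track)
  ends <- ev[ev$type == "arm_end_reached", ]
  expect_gt(nrow(ends), 0)
  for (i in seq_len(nrow(ends))) {
    fr <- which.min(abs(g$track$t - ends$time[i]))
    d <- sqrt(g$track$x[fr]^2 + g$track$y[fr]^2)
    expect_gt(d, dualpath:::epm_geometry()$centre_half)
  }
})

test_that("open-arm time per epoch follows scripted occupancy", {
  # 50% open occupancy alternating 2 s open / 2 s closed
  script <- rep(list(list("open1", 2), list("closed1", 2)), 135)
  zones <- make_scripted_zones(script)  # 540 s total
  ot <- open_arm_time_per_epoch(zones)
  expect_equal(length(ot), 3)
  expect_equal(ot, rep(90, 3), tolerance = 0.01)
  z0 <- make_scripted_zones(list(list("closed1", 540)))
  expect_equal(open_arm_time_per_epoch(z0), c(0, 0, 0))
})

test_that("entry probability counts open exits over all exits", {
  ev <- event_table(c(10, 30, 50, 70), c("open_entry", "open_entry",
                                         "open_entry", "closed_entry"))
  p <- entry_probability(ev, epochs = list(c(0, 90)))
  expect_equal(p, 0.75)
  expect_true(is.nan(entry_probability(event_table(numeric(0),
                                                   character(0)),
                                       epochs = list(c(0, 90)))))
  all_open <- event_table(c(10, 20), rep("open_entry", 2))
  expect_equal(entry_probability(all_open, epochs = list(c(0, 90))), 1)
})

test_that("latched gate obeys its invariants on a scripted session", {
  # epoch 2 = 180-360 s; centre entry 200 s, closed return 230 s
  zones <- make_scripted_zones(list(list("closed1", 200),
                                    list("centre", 10),
                                    list("open1", 20),
                                    list("closed1", 310)))
  gate <- closed_loop_gate(zones)
  on_t <- zones$t[gate$on]
  expect_equal(min(on_t), 200)
  expect_equal(max(on_t), 230 - 1 / 25)  # off at the closed-arm frame
  # all-off outside the stimulation epoch
  expect_true(all(on_t >= 180 & on_t < 360))

  # mouse in closed arms throughout -> never on
  z_closed <- make_scripted_zones(list(list("closed1", 540)))
  expect_false(any(closed_loop_gate(z_closed)$on))

  # constant variant: on during the whole middle epoch regardless
  gc <- closed_loop_gate(z_closed, mode = "constant")
  expect_equal(range(z_closed$t[gc$on]), c(180, 360 - 1 / 25))
})

test_that("gate invariants hold on random walks", {
  for (s in 1:5) {
    g <- gen_epm_track(epm_config(duration = 540, seed = 30 + s))
    zones <- classify_zone(g$track)
    gate <- closed_loop_gate(zones)
    ep <- dualpath:::epoch_of(zones$t, dualpath:::default_epochs())
    expect_true(all(ep[gate$on] == 2))
    # each on-interval starts centre/open; frame after the last is
    # closed, epoch end, or session end
    r <- rle(gate$on)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      expect_true(zones$zone[starts[i]] %in% c("centre", "open"))
      nxt <- ends[i] + 1L
      if (nxt <= nrow(zones)) {
        expect_true(zones$zone[nxt] == "closed" || ep[nxt] != 2)
      }
    }
  }
})

test_that("already-in-centre at epoch start turns the light on at once", {
  zones <- make_scripted_zones(list(list("centre", 200),
                                    list("closed1", 340)))
  gate <- closed_loop_gate(zones)
  expect_equal(min(zones$t[gate$on]), 180)
})
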