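test_that("lossless census emits one record per resident-second", {
  fac <- tiny_facility()
  cfg <- simulation_config(facility = fac, n_days = 1, sampling = "all_hours",
                           detection_prob = 1, duplication_prob = 0,
                           planted_clusters = stats::setNames(
                             rep(1:2, length.out = 5),
                             fac$residents$resident_id),
                           seed = 3)
  sim <- simulate_facility(cfg)
  expect_equal(nrow(sim$records), 5L * 86400L)
  # every resident occupies exactly one zone per second
  per_sec <- sim$records[, .N, by = .(device_id, timestamp)]
  expect_true(all(per_sec$N == 1L))
})

test_that("alternating-hours sampling halves the lossless record count", {
  fac <- tiny_facility()
  pc <- stats::setNames(rep(1:2, length.out = 5), fac$residents$resident_id)
  mk <- function(sampling) {
    simulate_facility(simulation_config(
      facility = fac, n_days = 1, sampling = sampling, detection_prob = 1,
      duplication_prob = 0, planted_clusters = pc, seed = 3))
  }
  all_h <- mk("all_hours")
  alt <- mk("alternating_hours")
  expect_equal(nrow(alt$records), nrow(all_h$records) / 2)
  hrs <- unique((alt$records$timestamp %% 86400L) %/% 3600L)
  expect_true(all(hrs %% 2L == 0L))
})

test_that("simulation is byte-identical under a fixed seed", {
  fac <- tiny_facility()
  pc <- stats::setNames(rep(1:2, length.out = 5), fac$residents$resident_id)
  cfg <- simulation_config(facility = fac, n_days = 1, seed = 17,
                           planted_clusters = pc)
  s1 <- simulate_facility(cfg)
  s2 <- simulate_facility(cfg)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_records(s1$records, f1)
  write_records(s2$records, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_identical(as_plain(s1$truth$true_events), as_plain(s2$truth$true_events))
})

test_that("record streams round-trip through the CSV reader", {
  fac <- tiny_facility()
  pc <- stats::setNames(rep(1:2, length.out = 5), fac$residents$resident_id)
  cfg <- simulation_config(facility = fac, n_days = 1, seed = 5,
                           planted_clusters = pc)
  sim <- simulate_facility(cfg)
  sel <- sim$records[1:10000]
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(sel, path)
  back <- read_records(path)
  expect_equal(as_plain(back), as_plain(sel))
  # empty stream -> header-only file; single record -> two lines
  write_records(sel[0], path)
  expect_equal(readLines(path), "device_id,timestamp,zone_id")
  write_records(sel[1], path)
  expect_equal(length(readLines(path)), 2L)
})

test_that("configuration validation rejects bad probabilities and partitions", {
  fac <- tiny_facility()
  expect_error(simulation_config(facility = fac, detection_prob = 1.2),
               class = "colocnet_config_error")
  expect_error(simulation_config(facility = fac, duplication_prob = -0.1),
               class = "colocnet_config_error")
  expect_error(simulation_config(facility = fac,
                                 planted_clusters = c(x = 1, y = 2)),
               class = "colocnet_config_error")
  aff <- matrix(1, 5, 5)  # nonzero diagonal
  expect_error(simulation_config(facility = fac, affinity = aff,
                                 planted_clusters = stats::setNames(
                                   rep(1:2, length.out = 5),
                                   fac$residents$resident_id)),
               class = "colocnet_config_error")
})

test_that("zero-noise detection reproduces ground truth exactly", {
  fac <- tiny_facility()
  pc <- stats::setNames(rep(1:2, length.out = 5), fac$residents$resident_id)
  cfg <- simulation_config(facility = fac, n_days = 1, sampling = "all_hours",
                           detection_prob = 1, duplication_prob = 0,
                           planted_clusters = pc, seed = 23)
  sim <- simulate_facility(cfg)
  ev <- detect_interactions(records_to_intervals(clean_records(sim$records)),
                            roster = fac$residents$resident_id)
  expect_equal(sort_events(ev), sort_events(sim$truth$true_events))
})

test_that("raising a dyad's affinity does not reduce its interaction count", {
  fac <- tiny_facility()
  ids <- fac$residents$resident_id
  pc <- stats::setNames(rep(1L, 5), ids)
  prof <- list(c(own = 0.3, other_bedroom = 0.5, common = 0.2))
  dyad_events <- function(aff_val, seed) {
    aff <- matrix(0.05, 5, 5, dimnames = list(ids, ids))
    diag(aff) <- 0
    aff["r1", "r3"] <- aff["r3", "r1"] <- aff_val
    cfg <- simulation_config(facility = fac, n_days = 1,
                             sampling = "all_hours", detection_prob = 1,
                             duplication_prob = 0, planted_clusters = pc,
                             cluster_profiles = prof, affinity = aff,
                             seed = seed)
    te <- simulate_facility(cfg)$truth$true_events
    nrow(te[(resident_a == "r1" & resident_b == "r3")])
  }
  lo <- mean(vapply(1:5, function(s) dyad_events(0.05, s), 0))
  hi <- mean(vapply(1:5, function(s) dyad_events(3, s), 0))
  expect_gte(hi, lo)
})

test_that("clipping events to sampled hours splits and re-filters", {
  ev <- data.frame(resident_a = "a", resident_b = "b", zone_id = "A",
                   start = 3000L, end = 8000L, duration_s = 5000L)
  # only hour 0 recorded: fragment [3000, 3600) = 600 s survives
  out <- clip_events_to_hours(ev, hours = 0)
  expect_equal(nrow(out), 1L)
  expect_equal(out$duration_s, 600L)
  # hour 1 only: [3600, 7200) = 3600 s
  out <- clip_events_to_hours(ev, hours = 1)
  expect_equal(out$duration_s, 3600L)
  # a fragment at exactly the threshold is dropped
  ev2 <- data.frame(resident_a = "a", resident_b = "b", zone_id = "A",
                    start = 3300L, end = 7000L, duration_s = 3700L)
  expect_equal(nrow(clip_events_to_hours(ev2, hours = 0)), 0L)
})
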