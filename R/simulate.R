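#' Default 48-resident facility
#'
#' Builds the reference facility used throughout: 48 tracked residents in
#' four shared-bedroom types — 7 in three-bed rooms, 18 in four-bed rooms
#' facing a corridor, 15 in four-bed rooms facing common areas, 8 in
#' five-bed rooms — plus common areas (lounge, dining, activity room,
#' lobby), transitional corridors and a nursing station. Bedroom
#' architectural attributes (adjacency class, transitional-space count,
#' visibility, visual exposure, bed capacity) are set so the privacy
#' instrument scores the four types (7, 5, 2, 4) as observed in the
#' reference audit. Rooms are not necessarily fully enrolled: every
#' resident has at least one tracked roommate.
#'
#' @return a [facility()].
#' @export
build_default_facility <- function() {
  bed_zone <- function(id, n, adj, ntr, sees, vis) {
    data.frame(zone_id = id, zone_class = "bedroom", adjacency_class = adj,
               n_transitional_to_common = ntr, sees_common = sees,
               beds_visible_from_common = vis, n_beds = n,
               stringsAsFactors = FALSE)
  }
  zones <- rbind(
    do.call(rbind, lapply(1:3, function(i)
      bed_zone(sprintf("B3_%d", i), 3, "semi_private", 2, FALSE, FALSE))),
    do.call(rbind, lapply(1:5, function(i)
      bed_zone(sprintf("B4C_%d", i), 4, "semi_public", 1, TRUE, FALSE))),
    do.call(rbind, lapply(1:4, function(i)
      bed_zone(sprintf("B4M_%d", i), 4, "public", 0, TRUE, TRUE))),
    do.call(rbind, lapply(1:2, function(i)
      bed_zone(sprintf("B5_%d", i), 5, "semi_public", 2, FALSE, FALSE))),
    data.frame(zone_id = c("lounge", "dining", "activity_room", "lobby",
                           "corridor_e", "corridor_w", "nursing_station"),
               zone_class = c(rep("common_area", 4), rep("transitional", 2), "other"),
               adjacency_class = NA_character_, n_transitional_to_common = NA_real_,
               sees_common = NA, beds_visible_from_common = NA, n_beds = NA_real_,
               stringsAsFactors = FALSE)
  )
  nb <- list(
    B3 = "corridor_w", B4C = "corridor_e", B4M = "lounge", B5 = "corridor_w",
    lounge = c("dining", "activity_room"), dining = c("lounge", "lobby"),
    activity_room = c("lounge"), lobby = c("dining", "corridor_e"),
    corridor_e = c("lobby", "lounge"), corridor_w = c("lounge"),
    nursing_station = c("corridor_e")
  )
  zones$neighbours <- lapply(zones$zone_id, function(z) {
    key <- sub("_[0-9]+$", "", z)
    as.character(nb[[key]] %||% "lounge")
  })
  # enrolment per room: 3B rooms 3+2+2, 4C rooms 4+4+4+3+3, 4M 4+4+4+3, 5B 4+4
  occ <- list(B3 = c(3, 2, 2), B4C = c(4, 4, 4, 3, 3), B4M = c(4, 4, 4, 3),
              B5 = c(4, 4))
  type_of <- c(B3 = "three_bed", B4C = "four_bed_corridor",
               B4M = "four_bed_common", B5 = "five_bed")
  rooms <- unlist(lapply(names(occ), function(g)
    rep(sprintf("%s_%d", g, seq_along(occ[[g]])), occ[[g]])))
  types <- type_of[sub("_[0-9]+$", "", rooms)]
  # sex composition: 3B 1M/6F, 4C 11M/7F, 4M 9M/6F, 5B 3M/5F
  sex_by_type <- list(three_bed = c("M", rep("F", 6)),
                      four_bed_corridor = c(rep("M", 11), rep("F", 7)),
                      four_bed_common = c(rep("M", 9), rep("F", 6)),
                      five_bed = c(rep("M", 3), rep("F", 5)))
  sex <- character(length(rooms))
  for (tp in names(sex_by_type)) sex[types == tp] <- sex_by_type[[tp]]
  residents <- data.frame(
    resident_id = sprintf("P%02d", seq_along(rooms)),
    bedroom_zone = rooms, bedroom_type = unname(types), sex = sex,
    stringsAsFactors = FALSE
  )
  facility(zones, residents)
}

#' Simulation configuration
#'
#' Assembles and validates the parameters of the movement/sensing
#' simulator. Defaults emulate the reference study regime: one month of
#' second-by-second records collected at alternating hours over the full
#' 24 h, with 85% detection accuracy and occasional duplicate registrations
#' on an adjacent sensor.
#'
#' Movement is a slot-based semi-Markov model: each resident occupies one
#' zone per `slot_s`-second slot; at night residents are almost always in
#' their own bedroom; during the day each planted cluster follows its own
#' behaviour profile (probabilities of staying in the own bedroom, visiting
#' another resident's bedroom, or using a common area). Bedroom visits pick
#' the host in proportion to the pairwise `affinity` matrix; common-area
#' trips favour the cluster's preferred common zone.
#'
#' @param facility a [facility()]; defaults to [build_default_facility()].
#' @param n_days number of simulated days (default 30).
#' @param sampling `"alternating_hours"` (default; every second hour is
#'   recorded) or `"all_hours"`.
#' @param sampling_phase 0 records even clock hours, 1 odd hours.
#' @param detection_prob per-second probability that a true record is
#'   registered (default 0.85).
#' @param duplication_prob per-second probability of a spurious duplicate
#'   registration in an adjacent zone (default 0.02).
#' @param planted_clusters integer vector of cluster memberships named by
#'   resident id; default partitions the roster round-robin into 3 blocks.
#' @param cluster_profiles list (one element per cluster) of day-time class
#'   probabilities `c(own=, other_bedroom=, common=)`; default cycles the
#'   archetypes common-oriented, bedroom-oriented, restricted.
#' @param affinity symmetric nonnegative matrix of pairwise visit
#'   propensities with zero diagonal; default block structure: 1 within a
#'   planted cluster, 0.02 between.
#' @param slot_s seconds per occupancy slot; must divide 3600 (default 900).
#' @param p_pref_common probability that a common-area trip goes to the
#'   cluster's preferred common zone (default 0.6).
#' @param night_hours clock hours treated as night (default 22:00-05:59).
#' @param seed integer RNG seed; all randomness derives from it.
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(facility = build_default_facility(),
                              n_days = 30,
                              sampling = c("alternating_hours", "all_hours"),
                              sampling_phase = 0,
                              detection_prob = 0.85,
                              duplication_prob = 0.02,
                              planted_clusters = NULL,
                              cluster_profiles = NULL,
                              affinity = NULL,
                              slot_s = 900,
                              p_pref_common = 0.6,
                              night_hours = c(22, 23, 0:5),
                              seed = 1L) {
  sampling <- match.arg(sampling)
  n_days <- assert_count(n_days, "n_days", min = 1L)
  detection_prob <- assert_prob(detection_prob, "detection_prob")
  duplication_prob <- assert_prob(duplication_prob, "duplication_prob")
  p_pref_common <- assert_prob(p_pref_common, "p_pref_common")
  slot_s <- assert_count(slot_s, "slot_s", min = 1L)
  if (3600 %% slot_s != 0) stop_config("slot_s must divide 3600")
  seed <- assert_count(seed, "seed", min = 0L)
  ids <- facility$residents$resident_id
  n <- length(ids)
  if (is.null(planted_clusters)) {
    planted_clusters <- stats::setNames(rep_len(1:3, n), ids)
  }
  if (is.null(names(planted_clusters)) ||
      !setequal(names(planted_clusters), ids)) {
    stop_config("planted_clusters must be named by resident id and cover the roster")
  }
  planted_clusters <- planted_clusters[ids]
  k <- length(unique(planted_clusters))
  archetypes <- list(
    common_oriented = c(own = 0.30, other_bedroom = 0.15, common = 0.55),
    bedroom_oriented = c(own = 0.20, other_bedroom = 0.65, common = 0.15),
    restricted = c(own = 0.92, other_bedroom = 0.02, common = 0.06)
  )
  if (is.null(cluster_profiles)) {
    cluster_profiles <- archetypes[rep_len(seq_along(archetypes), k)]
  }
  if (length(cluster_profiles) < k) {
    stop_config("need a behaviour profile for each of the %d planted clusters", k)
  }
  for (p in cluster_profiles) {
    if (!all(c("own", "other_bedroom", "common") %in% names(p)) ||
        any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop_config("each cluster profile must be probabilities over own/other_bedroom/common summing to 1")
    }
  }
  if (is.null(affinity)) {
    same <- outer(planted_clusters, planted_clusters, "==")
    affinity <- ifelse(same, 1, 0.02)
    diag(affinity) <- 0
    dimnames(affinity) <- list(ids, ids)
  }
  if (!is.matrix(affinity) || nrow(affinity) != n || ncol(affinity) != n) {
    stop_config("affinity must be a %d x %d matrix", n, n)
  }
  if (is.null(dimnames(affinity))) dimnames(affinity) <- list(ids, ids)
  affinity <- affinity[ids, ids]
  if (any(affinity < 0) || any(abs(affinity - t(affinity)) > 1e-12) ||
      any(diag(affinity) != 0)) {
    stop_config("affinity must be symmetric, nonnegative, with zero diagonal")
  }
  structure(list(
    facility = facility, n_days = n_days, sampling = sampling,
    sampling_phase = as.integer(sampling_phase) %% 2L,
    detection_prob = detection_prob, duplication_prob = duplication_prob,
    planted_clusters = planted_clusters, cluster_profiles = cluster_profiles,
    affinity = affinity, slot_s = slot_s, p_pref_common = p_pref_common,
    night_hours = as.integer(night_hours), seed = seed
  ), class = "simulation_config")
}

#' Hours recorded by a sampling pattern
#' @param config a [simulation_config()].
#' @return integer vector of recorded clock hours (0-23).
#' @export
sampled_hours <- function(config) {
  if (config$sampling == "all_hours") 0:23
  else (0:23)[(0:23) %% 2L == config$sampling_phase]
}

#' Simulate device-zone location streams with ground truth
#'
#' Runs the movement model, emits second-by-second location records for the
#' sampled hours, applies sensor noise (record loss and adjacent-zone
#' duplication), and returns both the noisy record stream and the ground
#' truth (true dyadic co-presence events derived directly from the
#' noiseless slot trajectories, the planted clusters and the affinity
#' matrix). Identical configurations (including the seed) give byte-identical
#' output.
#'
#' @param config a [simulation_config()].
#' @return list with elements `records` (data.table: `device_id`,
#'   `timestamp`, `zone_id`; timestamps are integer epoch seconds starting
#'   at 0) and `truth` (list: `true_events`, `planted_clusters`, `affinity`,
#'   `occupancy` slot table, `sampled_hours`).
#' @export
simulate_facility <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop_config("config must be a simulation_config")
  }
  fac <- config$facility
  ids <- fac$residents$resident_id
  n <- length(ids)
  slot_s <- config$slot_s
  slots_per_day <- 86400L %/% slot_s
  n_slots <- config$n_days * slots_per_day
  slot_hour <- as.integer((((seq_len(n_slots) - 1L) * slot_s) %/% 3600L) %% 24L)
  night <- slot_hour %in% config$night_hours
  zone_ids <- fac$zones$zone_id
  common_zones <- zone_ids[fac$zones$zone_class == "common_area"]
  own_zone <- fac$residents$bedroom_zone
  names(own_zone) <- ids
  pref_common <- common_zones[((config$planted_clusters - 1L) %% length(common_zones)) + 1L]
  names(pref_common) <- ids
  night_p <- c(own = 1, other_bedroom = 0, common = 0)

  # noiseless per-slot occupancy, one independent substream per resident
  occupancy <- matrix(NA_character_, nrow = n, ncol = n_slots,
                      dimnames = list(ids, NULL))
  for (i in seq_len(n)) {
    rid <- ids[i]
    set.seed((config$seed + 7919L * i) %% 2147483647L)
    prof <- config$cluster_profiles[[config$planted_clusters[[rid]]]]
    pm <- rbind(day = prof[c("own", "other_bedroom", "common")],
                night = night_p)
    which_row <- ifelse(night, 2L, 1L)
    u <- stats::runif(n_slots)
    cls <- ifelse(u < pm[cbind(which_row, 1L)], 1L,
                  ifelse(u < pm[cbind(which_row, 1L)] + pm[cbind(which_row, 2L)],
                         2L, 3L))
    zone <- rep(own_zone[[rid]], n_slots)
    n_visit <- sum(cls == 2L)
    if (n_visit > 0L) {
      w <- config$affinity[rid, ]
      if (sum(w) > 0) {
        hosts <- sample(ids, n_visit, replace = TRUE, prob = w)
        zone[cls == 2L] <- own_zone[hosts]
      }
    }
    n_common <- sum(cls == 3L)
    if (n_common > 0L) {
      pick_pref <- stats::runif(n_common) < config$p_pref_common
      cz <- sample(common_zones, n_common, replace = TRUE)
      cz[pick_pref] <- pref_common[[rid]]
      zone[cls == 3L] <- cz
    }
    occupancy[i, ] <- zone
  }

  occ_dt <- data.table::data.table(
    resident = rep(ids, n_slots),
    slot = rep(seq_len(n_slots), each = n),
    zone = as.vector(occupancy)
  )
  true_events <- events_from_slots(occ_dt, slot_s)

  # record emission over sampled hours
  hrs <- sampled_hours(config)
  keep_slot <- slot_hour %in% hrs
  slot_idx <- which(keep_slot)
  starts <- (slot_idx - 1L) * slot_s
  sec_off <- rep.int(0:(slot_s - 1L), length(slot_idx))
  rec_list <- vector("list", n)
  for (i in seq_len(n)) {
    ts <- rep(starts, each = slot_s) + sec_off
    rec_list[[i]] <- data.table::data.table(
      device_id = ids[i],
      timestamp = as.integer(ts),
      zone_id = rep(occupancy[i, slot_idx], each = slot_s)
    )
  }
  records <- data.table::rbindlist(rec_list)

  # sensor noise: independent loss and adjacent-zone duplication
  set.seed((config$seed + 104729L) %% 2147483647L)
  nb_map <- fac$zones$neighbours %||% lapply(zone_ids, function(z) zone_ids[zone_ids != z])
  names(nb_map) <- zone_ids
  dups <- NULL
  if (config$duplication_prob > 0) {
    is_dup <- stats::runif(nrow(records)) < config$duplication_prob
    if (any(is_dup)) {
      dups <- records[is_dup]
      nbs <- nb_map[dups$zone_id]
      len <- lengths(nbs)
      pick <- 1L + floor(stats::runif(nrow(dups)) * len)
      dups[, zone_id := mapply(`[`, nbs, pick)]
    }
  }
  if (config$detection_prob < 1) {
    records <- records[stats::runif(.N) < config$detection_prob]
  }
  if (!is.null(dups)) records <- data.table::rbindlist(list(records, dups))
  data.table::setorder(records, device_id, timestamp, zone_id)

  list(
    records = records[],
    truth = list(
      true_events = true_events,
      planted_clusters = config$planted_clusters,
      affinity = config$affinity,
      occupancy = occ_dt,
      sampled_hours = hrs
    )
  )
}

# Dyadic co-presence events straight from the slot occupancy table: two
# residents in the same zone in the same slot are co-present for the whole
# slot; consecutive co-present slots in the same zone merge into one event.
# This path never touches the record stream, so it can serve as an
# independent oracle for the detection pipeline.
events_from_slots <- function(occ_dt, slot_s) {
  pairs <- merge(occ_dt, occ_dt, by = c("slot", "zone"),
                 allow.cartesian = TRUE, suffixes = c("_a", "_b"))
  pairs <- pairs[resident_a < resident_b]
  if (nrow(pairs) == 0L) {
    return(data.table::data.table(
      resident_a = character(0), resident_b = character(0),
      zone_id = character(0), start = integer(0), end = integer(0),
      duration_s = integer(0)
    ))
  }
  data.table::setorder(pairs, resident_a, resident_b, zone, slot)
  pairs[, pair_run := cumsum(
    c(1L, (diff(slot) != 1L) |
        (resident_a[-1L] != resident_a[-.N]) |
        (resident_b[-1L] != resident_b[-.N]) |
        (zone[-1L] != zone[-.N]))
  )]
  ev <- pairs[, .(
    resident_a = resident_a[1L], resident_b = resident_b[1L],
    zone_id = zone[1L],
    start = as.integer((slot[1L] - 1L) * slot_s),
    end = as.integer(slot[.N] * slot_s)
  ), by = pair_run][, pair_run := NULL]
  ev[, duration_s := end - start]
  data.table::setorder(ev, resident_a, resident_b, start, zone_id)
  ev[]
}

#' Clip events to the sampled clock hours
#'
#' Restricts an event table to the recorded hours of a sampling pattern:
#' each event is intersected with the sampled windows and the minimum
#' duration rule is re-applied to the fragments. Used to compare ground
#' truth with what a sampling-limited sensor can observe.
#'
#' @param events event data.frame (`resident_a`, `resident_b`, `zone_id`,
#'   `start`, `end`, `duration_s`).
#' @param hours integer vector of recorded clock hours.
#' @param min_duration_s events must exceed this duration (strict), default
#'   300.
#' @return clipped event data.table.
#' @export
clip_events_to_hours <- function(events, hours, min_duration_s = 300) {
  ev <- data.table::as.data.table(events)
  if (nrow(ev) == 0L) return(ev)
  parts <- lapply(seq_len(nrow(ev)), function(i) {
    m <- iv_canon(cbind(ev$start[i], ev$end[i]))
    win <- do.call(rbind, lapply(hours, function(h)
      iv_clock_window(m, c(h, h + 1))))
    out <- iv_intersect(m, iv_canon(win))
    if (nrow(out) == 0L) return(NULL)
    data.table::data.table(
      resident_a = ev$resident_a[i], resident_b = ev$resident_b[i],
      zone_id = ev$zone_id[i], start = as.integer(out[, 1]),
      end = as.integer(out[, 2])
    )
  })
  out <- data.table::rbindlist(parts)
  if (nrow(out) == 0L) return(out)
  out[, duration_s := end - start]
  out <- out[duration_s > min_duration_s]
  data.table::setorder(out, resident_a, resident_b, start, zone_id)
  out[]
}

#' Write / read a location record stream
#'
#' CSV with header `device_id,timestamp,zone_id`; timestamps are integer
#' epoch seconds.
#'
#' @param records data.frame of location records.
#' @param path output file path.
#' @return `write_records()` returns `path` invisibly; `read_records()`
#'   returns a data.table.
#' @export
write_records <- function(records, path) {
  rec <- data.table::as.data.table(records)
  if (nrow(rec) == 0L) {
    rec <- data.table::data.table(device_id = character(0),
                                  timestamp = integer(0),
                                  zone_id = character(0))
  }
  data.table::fwrite(rec[, .(device_id, timestamp, zone_id)], path)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop_config("record file not found: %s", path)
  rec <- data.table::fread(path, colClasses = list(
    character = "device_id", integer = "timestamp", character = "zone_id"
  ))
  need <- c("device_id", "timestamp", "zone_id")
  if (!all(need %in% names(rec))) {
    stop_config("record file must have columns %s", paste(need, collapse = ", "))
  }
  rec[, need, with = FALSE]
}
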