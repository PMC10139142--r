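# Shared fixtures and independent oracles for the test suite.
# Oracles deliberately use brute-force per-second scans, never the
# interval-based production code paths.

tiny_facility <- function() {
  zones <- data.frame(
    zone_id = c("bedA", "bedB", "lounge", "hall"),
    zone_class = c("bedroom", "bedroom", "common_area", "transitional"),
    adjacency_class = c("semi_private", "public", NA, NA),
    n_transitional_to_common = c(1, 0, NA, NA),
    sees_common = c(FALSE, TRUE, NA, NA),
    beds_visible_from_common = c(FALSE, TRUE, NA, NA),
    n_beds = c(2, 3, NA, NA),
    stringsAsFactors = FALSE
  )
  zones$neighbours <- list("hall", "lounge", c("bedB", "hall"), c("bedA", "lounge"))
  residents <- data.frame(
    resident_id = c("r1", "r2", "r3", "r4", "r5"),
    bedroom_zone = c("bedA", "bedA", "bedB", "bedB", "bedB"),
    bedroom_type = c("three_bed", "three_bed", "four_bed_common",
                     "four_bed_common", "four_bed_common"),
    sex = c("F", "M", "F", "F", "M"),
    stringsAsFactors = FALSE
  )
  facility(zones, residents)
}

# contiguous presence block as second-level records
rec_block <- function(device, zone, from, len) {
  data.frame(device_id = device, timestamp = as.integer(from + 0:(len - 1)),
             zone_id = zone, stringsAsFactors = FALSE)
}

# random record stream: each device moves through random dwell episodes
random_records <- function(devices, zones, t_end, seed,
                           mean_dwell = 600, p_present = 0.9) {
  set.seed(seed)
  out <- list()
  for (d in devices) {
    t <- 0L
    while (t < t_end) {
      len <- min(as.integer(ceiling(stats::rexp(1, 1 / mean_dwell))) + 1L,
                 t_end - t)
      if (stats::runif(1) < p_present) {
        z <- sample(zones, 1)
        out[[length(out) + 1L]] <- rec_block(d, z, t, len)
      }
      t <- t + len
    }
  }
  do.call(rbind, out)
}

# Brute-force oracle: per-second, per-pair co-presence scan over cleaned
# records; maximal runs of consecutive shared seconds in one zone, kept if
# strictly longer than min_duration_s.
brute_force_events <- function(records, min_duration_s = 300) {
  recs <- as.data.frame(records)
  devices <- sort(unique(recs$device_id))
  res <- list()
  for (i in seq_along(devices)) {
    for (j in seq_along(devices)) {
      if (j <= i) next
      a <- recs[recs$device_id == devices[i], ]
      b <- recs[recs$device_id == devices[j], ]
      m <- merge(a, b, by = "timestamp")
      m <- m[m$zone_id.x == m$zone_id.y, ]
      if (nrow(m) == 0) next
      m <- m[order(m$timestamp), ]
      brk <- c(TRUE, diff(m$timestamp) != 1 |
                 m$zone_id.x[-1] != m$zone_id.x[-nrow(m)])
      run <- cumsum(brk)
      for (r in unique(run)) {
        sec <- m$timestamp[run == r]
        dur <- length(sec)
        if (dur > min_duration_s) {
          res[[length(res) + 1L]] <- data.frame(
            resident_a = devices[i], resident_b = devices[j],
            zone_id = m$zone_id.x[run == r][1],
            start = min(sec), end = max(sec) + 1L,
            duration_s = dur, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(resident_a = character(0), resident_b = character(0),
                      zone_id = character(0), start = integer(0),
                      end = integer(0), duration_s = integer(0)))
  }
  out <- do.call(rbind, res)
  out[order(out$resident_a, out$resident_b, out$start, out$zone_id), ]
}

# Brute-force solitude oracle: per-second scan of "present and sole
# occupant of my zone"; maximal runs strictly longer than min_duration_s.
brute_force_alone <- function(records, residents, min_duration_s = 300) {
  recs <- as.data.frame(records)
  out <- stats::setNames(integer(length(residents)), residents)
  occ <- table(paste(recs$timestamp, recs$zone_id))
  for (r in residents) {
    mine <- recs[recs$device_id == r, ]
    if (nrow(mine) == 0) next
    key <- paste(mine$timestamp, mine$zone_id)
    alone <- occ[key] == 1
    ts <- sort(mine$timestamp[alone])
    if (length(ts) == 0) next
    run <- cumsum(c(TRUE, diff(ts) != 1))
    lens <- tabulate(run)
    out[[r]] <- sum(lens > min_duration_s)
  }
  out
}

as_plain <- function(dt) {
  df <- as.data.frame(dt)
  attr(df, "cleaning_report") <- NULL
  rownames(df) <- NULL
  df
}

sort_events <- function(ev) {
  df <- as_plain(ev)
  df <- df[order(df$resident_a, df$resident_b, df$start, df$zone_id), ]
  rownames(df) <- NULL
  df
}
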