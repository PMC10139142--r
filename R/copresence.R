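#' Clean raw location records
#'
#' Indoor positioning streams carry two kinds of noise: exact duplicate
#' rows and conflicting registrations (one device in two zones in the same
#' second, typically sensor cross-talk). Cleaning enforces at most one zone
#' per (device, second): exact duplicates are collapsed, then each
#' conflicted second is resolved to the zone with the most registrations
#' for that device within a sliding context window around the second. Ties
#' go to the zone of the nearest earlier retained second, and failing that
#' to the lexicographically smallest zone id. Malformed rows (missing
#' fields, non-integer timestamps) are counted and dropped.
#'
#' In addition, very short isolated zone visits (sensor cross-talk whose
#' true-zone record happened to be lost, so no per-second conflict exists)
#' can be smoothed: a run of at most `flicker_s` seconds in a zone,
#' flanked within `window_s` on both sides by runs of one same other zone,
#' is reassigned to the flanking zone. Smoothing is off by default so that
#' conflict-free input passes through unchanged; the pipeline enables it.
#'
#' @param records data.frame with columns `device_id`, `timestamp`,
#'   `zone_id`.
#' @param window_s half-width in seconds of the majority-vote context
#'   window (default 60).
#' @param flicker_s reassign isolated foreign-zone runs of at most this
#'   many seconds (default 0 = no smoothing).
#' @return cleaned data.table (one zone per device-second, sorted), with a
#'   `cleaning_report` attribute: rows read, malformed, exact duplicates
#'   removed, conflicted seconds, how ties were resolved, and flickers
#'   smoothed.
#' @export
clean_records <- function(records, window_s = 60, flicker_s = 0) {
  rec <- data.table::as.data.table(records)
  n_in <- nrow(rec)
  report <- list(rows_in = n_in, malformed = 0L, exact_duplicates = 0L,
                 conflict_seconds = 0L, resolved_majority = 0L,
                 resolved_previous = 0L, resolved_lexicographic = 0L,
                 flickers_smoothed = 0L)
  if (n_in == 0L) {
    out <- data.table::data.table(device_id = character(0),
                                  timestamp = integer(0),
                                  zone_id = character(0))
    data.table::setattr(out, "cleaning_report", report)
    return(out)
  }
  rec[, timestamp := suppressWarnings(as.integer(timestamp))]
  bad <- is.na(rec$device_id) | rec$device_id == "" |
    is.na(rec$timestamp) | is.na(rec$zone_id) | rec$zone_id == ""
  report$malformed <- sum(bad)
  rec <- rec[!bad]
  n0 <- nrow(rec)
  rec <- unique(rec, by = c("device_id", "timestamp", "zone_id"))
  report$exact_duplicates <- n0 - nrow(rec)

  dup_key <- rec[, .N, by = .(device_id, timestamp)][N > 1L]
  report$conflict_seconds <- nrow(dup_key)
  if (nrow(dup_key) == 0L) {
    data.table::setorder(rec, device_id, timestamp, zone_id)
    sm <- smooth_flickers(rec, flicker_s, window_s)
    report$flickers_smoothed <- sm$n
    data.table::setattr(sm$records, "cleaning_report", report)
    return(sm$records[])
  }

  conf <- rec[dup_key, on = .(device_id, timestamp)][, .(device_id, timestamp, zone_id)]
  # votes: registrations of the same device in the same zone within the window
  lo <- conf$timestamp - as.integer(window_s)
  hi <- conf$timestamp + as.integer(window_s)
  votes <- rec[conf[, .(device_id, zone_id, lo = lo, hi = hi)],
               on = .(device_id, zone_id, timestamp >= lo, timestamp <= hi),
               .N, by = .EACHI]
  conf[, n_votes := votes$N]
  data.table::setorder(conf, device_id, timestamp, -n_votes, zone_id)
  best <- conf[, .(zone_id = list(zone_id[n_votes == max(n_votes)])),
               by = .(device_id, timestamp)]
  best[, n_cand := lengths(zone_id)]
  clear1 <- best[n_cand == 1L]
  clear <- data.table::data.table(
    device_id = clear1$device_id, timestamp = clear1$timestamp,
    zone_id = as.character(unlist(clear1$zone_id))
  )
  report$resolved_majority <- nrow(clear)

  tied <- best[n_cand > 1L]
  tied_pick <- NULL
  if (nrow(tied) > 0L) {
    # retained (unambiguous) seconds: conflict-free records + majority picks
    resolved <- rbind(
      rec[!dup_key, on = .(device_id, timestamp)][, .(device_id, timestamp, zone_id)],
      clear
    )
    data.table::setorder(resolved, device_id, timestamp)
    picks <- vector("list", 0L)
    for (dev in unique(tied$device_id)) {
      res_d <- resolved[device_id == dev]
      ts_d <- res_d$timestamp; zn_d <- res_d$zone_id
      td <- tied[device_id == dev][order(timestamp)]
      for (i in seq_len(nrow(td))) {
        ts_i <- td$timestamp[i]
        cand <- sort(td$zone_id[[i]])
        j <- findInterval(ts_i - 1L, ts_d)
        prev_zone <- if (j >= 1L) zn_d[j] else NA_character_
        if (!is.na(prev_zone) && prev_zone %in% cand) {
          pick <- prev_zone
          report$resolved_previous <- report$resolved_previous + 1L
        } else {
          pick <- cand[1L]
          report$resolved_lexicographic <- report$resolved_lexicographic + 1L
        }
        picks[[length(picks) + 1L]] <-
          data.table::data.table(device_id = dev, timestamp = ts_i, zone_id = pick)
        # make this decision visible to later ties of the same device
        k <- findInterval(ts_i, ts_d)
        ts_d <- append(ts_d, ts_i, after = k)
        zn_d <- append(zn_d, pick, after = k)
      }
    }
    tied_pick <- data.table::rbindlist(picks)
  }

  keep <- rec[!dup_key, on = .(device_id, timestamp)]
  out <- data.table::rbindlist(list(
    keep[, .(device_id, timestamp, zone_id)], clear, tied_pick
  ), use.names = TRUE)
  data.table::setorder(out, device_id, timestamp, zone_id)
  sm <- smooth_flickers(out, flicker_s, window_s)
  report$flickers_smoothed <- sm$n
  data.table::setattr(sm$records, "cleaning_report", report)
  sm$records[]
}

# Reassign isolated short foreign-zone runs to the zone that flanks them on
# both sides. Input must be sorted, one zone per (device, second).
smooth_flickers <- function(rec, flicker_s, window_s) {
  if (flicker_s <= 0 || nrow(rec) < 3L) return(list(records = rec, n = 0L))
  n <- nrow(rec)
  new_run <- c(TRUE, rec$device_id[-1L] != rec$device_id[-n] |
                 rec$zone_id[-1L] != rec$zone_id[-n])
  first <- which(new_run)
  last <- c(first[-1L] - 1L, n)
  runs <- data.table::data.table(
    device = rec$device_id[first], zone = rec$zone_id[first],
    start_ts = rec$timestamp[first], end_ts = rec$timestamp[last],
    first = first, last = last
  )
  prev_dev <- data.table::shift(runs$device)
  next_dev <- data.table::shift(runs$device, type = "lead")
  prev_zone <- data.table::shift(runs$zone)
  next_zone <- data.table::shift(runs$zone, type = "lead")
  prev_end <- data.table::shift(runs$end_ts)
  next_start <- data.table::shift(runs$start_ts, type = "lead")
  blip <- !is.na(prev_dev) & !is.na(next_dev) &
    prev_dev == runs$device & next_dev == runs$device &
    prev_zone == next_zone & prev_zone != runs$zone &
    (runs$end_ts - runs$start_ts + 1L) <= flicker_s &
    (runs$start_ts - prev_end) <= window_s &
    (next_start - runs$end_ts) <= window_s
  if (!any(blip)) return(list(records = rec, n = 0L))
  idx <- which(blip)
  rows <- unlist(lapply(idx, function(i) runs$first[i]:runs$last[i]))
  rec <- data.table::copy(rec)
  rec[rows, zone_id := rep(prev_zone[idx], runs$last[idx] - runs$first[idx] + 1L)]
  list(records = rec, n = length(idx))
}

#' Cleaning report of a cleaned record stream
#' @param records output of [clean_records()].
#' @return named list of cleaning counters.
#' @export
cleaning_report <- function(records) {
  attr(records, "cleaning_report")
}

#' Merge cleaned records into presence intervals
#'
#' Consecutive same-zone seconds of a device merge into half-open presence
#' intervals `[start, end)`. Short gaps within the same zone (dropped
#' registrations) are bridged when they are at most `max_gap_s` seconds and
#' do not cross a sampling blackout (an unrecorded clock hour); a zone
#' change always starts a new interval.
#'
#' @param records cleaned records ([clean_records()]).
#' @param max_gap_s largest same-zone gap to bridge, in seconds
#'   (default 60).
#' @param sampled_hours optional integer vector of recorded clock hours;
#'   when given, gaps that touch an unrecorded hour are never bridged.
#' @return data.table with columns `device_id`, `zone_id`, `start`, `end`
#'   (half-open epoch seconds).
#' @export
records_to_intervals <- function(records, max_gap_s = 60, sampled_hours = NULL) {
  rec <- data.table::as.data.table(records)
  if (nrow(rec) == 0L) {
    return(data.table::data.table(device_id = character(0),
                                  zone_id = character(0),
                                  start = integer(0), end = integer(0)))
  }
  data.table::setorder(rec, device_id, timestamp)
  nr <- nrow(rec)
  new_run <- c(TRUE, rec$device_id[-1L] != rec$device_id[-nr] |
                 rec$zone_id[-1L] != rec$zone_id[-nr] |
                 diff(rec$timestamp) != 1L)
  first <- which(new_run)
  last <- c(first[-1L] - 1L, nr)
  runs <- data.table::data.table(
    device_id = rec$device_id[first], zone_id = rec$zone_id[first],
    start = rec$timestamp[first], end = rec$timestamp[last] + 1L
  )
  # bridge same-zone gaps <= max_gap_s not crossing a blackout
  nrun <- nrow(runs)
  gap <- runs$start - data.table::shift(runs$end)
  same <- runs$device_id == data.table::shift(runs$device_id) &
    runs$zone_id == data.table::shift(runs$zone_id)
  bridge <- !is.na(same) & same & gap <= max_gap_s & gap > 0
  if (!is.null(sampled_hours) && any(bridge)) {
    idx <- which(bridge)
    gs <- runs$end[idx - 1L]; ge <- runs$start[idx]
    # a gap crosses a blackout iff any clock hour it touches is unrecorded;
    # bridged gaps are short, so at most two hours are involved
    h1 <- ((gs %% 86400L) %/% 3600L)
    h2 <- (((ge - 1L) %% 86400L) %/% 3600L)
    ok <- (h1 %in% sampled_hours) & (h2 %in% sampled_hours) &
      ((h2 - h1) %% 24L <= 1L)
    bridge[idx[!ok]] <- FALSE
  }
  mfirst <- which(!bridge)
  mlast <- c(mfirst[-1L] - 1L, nrun)
  out <- data.table::data.table(
    device_id = runs$device_id[mfirst], zone_id = runs$zone_id[mfirst],
    start = runs$start[mfirst], end = runs$end[mlast]
  )
  data.table::setorder(out, device_id, start)
  out[]
}

#' Detect meaningful interaction events
#'
#' Applies the co-presence rule: whenever two tracked residents are in the
#' same room or space for more than `min_duration_s` seconds (strictly; the
#' default is 5 minutes), the maximal overlap of their presence intervals
#' is one dyadic interaction event. k residents co-present together yield
#' all `choose(k, 2)` dyadic events.
#'
#' @param intervals presence intervals ([records_to_intervals()]).
#' @param roster optional character vector of tracked resident/device ids;
#'   intervals from unknown devices are skipped or rejected per
#'   `on_unknown_device`.
#' @param min_duration_s events must be strictly longer than this
#'   (default 300).
#' @param on_unknown_device `"skip"` (default) or `"fail"`.
#' @return data.table of events: `resident_a`, `resident_b` (sorted so
#'   `resident_a < resident_b`), `zone_id`, `start`, `end`, `duration_s`.
#' @export
detect_interactions <- function(intervals, roster = NULL, min_duration_s = 300,
                                on_unknown_device = c("skip", "fail")) {
  on_unknown_device <- match.arg(on_unknown_device)
  iv <- data.table::as.data.table(intervals)
  empty <- data.table::data.table(
    resident_a = character(0), resident_b = character(0),
    zone_id = character(0), start = integer(0), end = integer(0),
    duration_s = integer(0)
  )
  if (nrow(iv) == 0L) return(empty)
  if (!is.null(roster)) {
    unknown <- setdiff(unique(iv$device_id), roster)
    if (length(unknown) > 0L) {
      if (on_unknown_device == "fail") {
        stop_invalid("devices not in roster: %s", paste(unknown, collapse = ", "))
      }
      iv <- iv[device_id %in% roster]
    }
  }
  if (nrow(iv) == 0L) return(empty)
  a <- data.table::copy(iv)
  b <- data.table::copy(iv)
  data.table::setkey(b, zone_id, start, end)
  ov <- data.table::foverlaps(a, b, by.x = c("zone_id", "start", "end"),
                              type = "any", nomatch = NULL)
  # foverlaps is closed-interval; ends are exclusive, so drop point touches
  ov <- ov[device_id < i.device_id]
  if (nrow(ov) == 0L) return(empty)
  ov[, `:=`(ostart = pmax(start, i.start), oend = pmin(end, i.end))]
  ov <- ov[oend - ostart > min_duration_s]
  if (nrow(ov) == 0L) return(empty)
  ev <- ov[, .(resident_a = device_id, resident_b = i.device_id,
               zone_id, start = as.integer(ostart), end = as.integer(oend))]
  ev[, duration_s := end - start]
  data.table::setorder(ev, resident_a, resident_b, start, zone_id)
  ev[]
}

#' Count solitude episodes per resident
#'
#' An alone episode is a maximal run of seconds during which a resident is
#' present (registered somewhere) and shares their current zone with no
#' other tracked resident. Runs strictly longer than `min_duration_s`
#' count. The count can be restricted to a clock-hour window (e.g. after
#' midnight, `hours = c(0, 6)`) and/or to zone classes (e.g. common areas
#' only, which requires the `facility`).
#'
#' @param intervals presence intervals of all tracked residents.
#' @param all_residents character vector of resident ids to report
#'   (defaults to all device ids present).
#' @param min_duration_s minimum episode duration, strict (default 300).
#' @param hours optional `c(h1, h2)` clock-window restriction (half-open
#'   hours of day).
#' @param zone_classes optional character vector of zone classes to
#'   restrict to.
#' @param fac the [facility()]; required when `zone_classes` is given.
#' @return named integer vector of alone-episode counts per resident.
#' @export
count_alone_episodes <- function(intervals, all_residents = NULL,
                                 min_duration_s = 300, hours = NULL,
                                 zone_classes = NULL, fac = NULL) {
  iv <- data.table::as.data.table(intervals)
  all_residents <- all_residents %||% sort(unique(iv$device_id))
  if (!is.null(zone_classes)) {
    if (is.null(fac)) stop_invalid("zone_classes restriction needs `fac`")
    keep_zones <- fac$zones$zone_id[fac$zones$zone_class %in% zone_classes]
    iv <- iv[zone_id %in% keep_zones]
  }
  out <- stats::setNames(integer(length(all_residents)), all_residents)
  if (nrow(iv) == 0L) return(out)
  by_zone <- split(iv, iv$zone_id)
  for (r in all_residents) {
    mine <- iv[device_id == r]
    if (nrow(mine) == 0L) next
    alone_parts <- lapply(seq_len(nrow(mine)), function(i) {
      seg <- cbind(mine$start[i], mine$end[i])
      zv <- by_zone[[mine$zone_id[i]]]
      others <- zv[zv$device_id != r & zv$end > mine$start[i] &
                     zv$start < mine$end[i], ]
      if (nrow(others) > 0L) {
        seg <- iv_subtract(seg, cbind(others$start, others$end))
      }
      seg
    })
    alone <- iv_canon(do.call(rbind, alone_parts))
    if (!is.null(hours) && nrow(alone) > 0L) {
      alone <- iv_intersect(alone, iv_clock_window(alone, hours))
    }
    if (nrow(alone) > 0L) {
      out[[r]] <- sum((alone[, 2] - alone[, 1]) > min_duration_s)
    }
  }
  out
}

#' Aggregate events to hourly interaction records
#'
#' Collapses second-level events to one row per (dyad, zone, clock hour),
#' for parity with pipelines that work on hour-by-hour location records.
#'
#' @param events event table ([detect_interactions()]).
#' @return data.table: `resident_a`, `resident_b`, `zone_id`, `day`,
#'   `hour`, `overlap_s` (seconds of the event falling in that hour).
#' @export
events_to_hourly <- function(events) {
  ev <- data.table::as.data.table(events)
  if (nrow(ev) == 0L) {
    return(data.table::data.table(resident_a = character(0),
                                  resident_b = character(0),
                                  zone_id = character(0), day = integer(0),
                                  hour = integer(0), overlap_s = integer(0)))
  }
  parts <- lapply(seq_len(nrow(ev)), function(i) {
    h0 <- ev$start[i] %/% 3600L
    h1 <- (ev$end[i] - 1L) %/% 3600L
    hseq <- h0:h1
    ov <- pmin(ev$end[i], (hseq + 1L) * 3600L) - pmax(ev$start[i], hseq * 3600L)
    data.table::data.table(
      resident_a = ev$resident_a[i], resident_b = ev$resident_b[i],
      zone_id = ev$zone_id[i], day = as.integer(hseq %/% 24L),
      hour = as.integer(hseq %% 24L), overlap_s = as.integer(ov)
    )
  })
  out <- data.table::rbindlist(parts)
  out[, .(overlap_s = sum(overlap_s)),
      by = .(resident_a, resident_b, zone_id, day, hour)]
}

#' Write events to CSV
#' @param events event table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  ev <- data.table::as.data.table(events)
  if (nrow(ev) == 0L) {
    ev <- data.table::data.table(resident_a = character(0),
                                 resident_b = character(0),
                                 zone_id = character(0), start = integer(0),
                                 end = integer(0), duration_s = integer(0))
  }
  data.table::fwrite(ev[, .(resident_a, resident_b, zone_id, start, end, duration_s)],
                     path)
  invisible(path)
}
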