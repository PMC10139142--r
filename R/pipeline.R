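#' End-to-end analysis pipeline
#'
#' Runs the full chain on a record stream: cleaning, interval construction,
#' meaningful-interaction detection, two-mode and one-mode networks,
#' per-resident features, the k-means social-cluster typology, the
#' privacy-network association table and the bedroom privacy scores. Each
#' artifact is written under `output_dir`; a manifest records the package
#' version, seed and parameters. The pipeline is a pure function of
#' (records, facility, parameters): identical inputs give byte-identical
#' feature and assignment outputs. A stage failure halts with an error
#' naming the stage; artifacts of completed stages are retained.
#'
#' @param records raw location records (data.frame or path to a record
#'   CSV).
#' @param fac a [facility()] (or path to a facility YAML).
#' @param output_dir directory for artifacts (created if missing).
#' @param min_duration_s meaningful-interaction threshold, strict
#'   (default 300).
#' @param max_gap_s same-zone gap bridging (default 60).
#' @param flicker_s cross-talk smoothing threshold passed to
#'   [clean_records()] (default 2; the pipeline treats isolated 1-2 s
#'   foreign-zone visits as sensor artifacts).
#' @param hours_recorded optional vector of recorded clock hours (blocks
#'   gap bridging across sampling blackouts).
#' @param k_range k-means sweep range (default 1:10).
#' @param n_restarts k-means restarts (default 50).
#' @param k_override manual cluster count (default NULL = elbow).
#' @param standardize z-score features before clustering (default TRUE).
#' @param association_mode `"correlation"` or `"regression"`.
#' @param seed integer seed for the stochastic stages (required).
#' @param window_days frequency denominator; default = number of distinct
#'   days with records.
#' @return invisibly, a list bundle with all stage outputs and artifact
#'   paths.
#' @export
run_pipeline <- function(records, fac, output_dir,
                         min_duration_s = 300, max_gap_s = 60,
                         flicker_s = 2,
                         hours_recorded = NULL,
                         k_range = 1:10, n_restarts = 50, k_override = NULL,
                         standardize = TRUE,
                         association_mode = c("correlation", "regression"),
                         seed, window_days = NULL) {
  association_mode <- match.arg(association_mode)
  if (missing(seed)) stop_config("seed is required")
  if (is.character(fac)) fac <- read_facility(fac)
  if (is.character(records)) records <- read_records(records)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(output_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  cleaned <- stage("clean", clean_records(records, flicker_s = flicker_s))
  jsonlite::write_json(cleaning_report(cleaned), path("cleaning_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  intervals <- stage("intervals", records_to_intervals(
    cleaned, max_gap_s = max_gap_s, sampled_hours = hours_recorded))
  events <- stage("interactions", detect_interactions(
    intervals, roster = fac$residents$resident_id,
    min_duration_s = min_duration_s))
  write_events(events, path("events.csv"))

  two_mode <- stage("networks", build_two_mode(intervals))
  one_mode <- stage("networks", project_one_mode(events, fac))
  export_network(two_mode, path("two_mode.graphml"), "graphml")
  export_network(one_mode, path("one_mode.graphml"), "graphml")

  if (is.null(window_days)) {
    window_days <- max(1L, length(unique(cleaned$timestamp %/% 86400L)))
  }
  features <- stage("features", compute_features(
    events, fac, window_days = window_days, intervals = intervals,
    min_duration_s = min_duration_s))
  data.table::fwrite(data.table::as.data.table(features), path("features.csv"))

  fm <- feature_matrix(features, standardize = standardize)
  k_range <- k_range[k_range <= nrow(fm)]
  sweep_fit <- stage("cluster", kmeans_sweep(fm, k_range = k_range,
                                             n_restarts = n_restarts,
                                             seed = seed))
  k <- elbow_select(sweep_fit$wcss, sweep_fit$k_range, override = k_override)
  model <- sweep_fit$fits[[paste0("k", k)]]
  labels <- stage("cluster", label_clusters(model, features))
  assignments <- stats::setNames(model$cluster, rownames(fm))
  assign_df <- data.frame(resident_id = names(assignments),
                          cluster = as.integer(assignments),
                          label = labels$label[match(assignments, labels$cluster)])
  data.table::fwrite(data.table::as.data.table(assign_df), path("assignments.csv"))
  data.table::fwrite(data.table::data.table(k = sweep_fit$k_range,
                                            wcss = sweep_fit$wcss),
                     path("wcss.csv"))
  contingency <- cluster_by_bedroom_table(assignments, fac)
  data.table::fwrite(data.table::as.data.table(labels), path("cluster_centroids.csv"))
  utils::write.csv(contingency$counts, path("cluster_by_bedroom.csv"))

  privacy <- stage("privacy", privacy_by_resident(fac))
  data.table::fwrite(data.table::as.data.table(privacy), path("privacy.csv"))
  assoc <- stage("associate", association_table(features, privacy,
                                                mode = association_mode))
  data.table::fwrite(data.table::as.data.table(assoc), path("association.csv"))

  manifest <- list(
    package = "colocnet",
    version = as.character(utils::packageVersion("colocnet")),
    seed = seed,
    parameters = list(min_duration_s = min_duration_s, max_gap_s = max_gap_s,
                      flicker_s = flicker_s,
                      hours_recorded = hours_recorded, k_range = k_range,
                      n_restarts = n_restarts, k = k,
                      standardize = standardize,
                      association_mode = association_mode,
                      window_days = window_days),
    rows = list(records_in = nrow(records), events = nrow(events),
                residents = nrow(fac$residents))
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(
    cleaned = cleaned, intervals = intervals, events = events,
    two_mode = two_mode, one_mode = one_mode, features = features,
    sweep = sweep_fit, k = k, model = model, labels = labels,
    assignments = assignments, contingency = contingency,
    privacy = privacy, association = assoc, facility = fac,
    window_days = window_days, output_dir = output_dir,
    manifest = manifest
  ))
}

#' Report-shaped tables from a pipeline bundle
#'
#' Formats the pipeline outputs into the study-report table shapes:
#' roster composition (counts and % of sample), per-bedroom-type privacy
#' scores, network characteristics by bedroom type with an overall row,
#' typology centroids with cluster shares and extreme-value flags, the
#' cluster x bedroom-type contingency with column percentages, and the
#' association table with significance stars. Percentages and means are
#' displayed to 2 decimal places (contingency percentages to 1), rounded
#' half away from zero; underlying computation keeps full precision.
#'
#' @param bundle result of [run_pipeline()] (stages may be missing; their
#'   tables are skipped with a notice).
#' @return named list of data.frames.
#' @export
report_tables <- function(bundle) {
  out <- list()
  fac <- bundle$facility
  if (!is.null(fac)) {
    r <- fac$residents
    tab <- table(factor(r$bedroom_type, levels = BEDROOM_TYPES))
    comp <- data.frame(bedroom_type = names(tab), n = as.integer(tab),
                       pct_of_sample = round_half_up(as.integer(tab) / nrow(r) * 100, 2))
    if (!all(is.na(r$sex))) {
      for (s in sort(unique(r$sex))) {
        comp[[paste0("n_", s)]] <- as.integer(
          table(factor(r$bedroom_type[r$sex == s], levels = BEDROOM_TYPES)))
      }
    }
    out$participants <- comp
    pa <- assess_facility(fac)
    pa_type <- unique(pa[, c("bedroom_type", "occupancy_score", "adjacency_score",
                             "transitional_score", "visual_privacy_score",
                             "visibility_score", "total")])
    rownames(pa_type) <- NULL
    out$privacy_scores <- pa_type
  } else {
    message("facility missing; participant and privacy tables skipped")
  }
  if (!is.null(bundle$features) && !is.null(fac)) {
    grouping <- stats::setNames(fac$residents$bedroom_type,
                                fac$residents$resident_id)
    sm <- summarize_by_group(bundle$features, grouping)
    num <- vapply(sm, is.numeric, TRUE) & names(sm) != "n"
    sm[num] <- lapply(sm[num], round_half_up, digits = 2)
    out$network_characteristics <- sm
  } else {
    message("features missing; network characteristics table skipped")
  }
  if (!is.null(bundle$labels) && !is.null(bundle$contingency)) {
    cent <- bundle$labels
    fm <- as.matrix(cent[, FEATURE_COLS])
    overall <- colMeans(as.matrix(bundle$features[, FEATURE_COLS]))
    sds <- apply(as.matrix(bundle$features[, FEATURE_COLS]), 2, stats::sd)
    flags <- flag_extremes(fm, overall, sds)
    shares <- bundle$contingency$share_of_sample
    ct <- data.frame(cluster = cent$cluster, label = cent$label,
                     share_pct = round_half_up(
                       as.numeric(shares[as.character(cent$cluster)]), 2))
    cent_round <- as.data.frame(round_half_up(fm, 2))
    for (cl in FEATURE_COLS) {
      ct[[cl]] <- ifelse(flags[, cl], sprintf("*%.2f*", cent_round[[cl]]),
                         sprintf("%.2f", cent_round[[cl]]))
    }
    out$cluster_summary <- ct
    cc <- bundle$contingency
    disp <- matrix(sprintf("%d (%s%%)", cc$counts,
                           formatC(round_half_up(cc$col_pct, 1), format = "f",
                                   digits = 1)),
                   nrow = nrow(cc$counts), dimnames = dimnames(cc$counts))
    disp[cc$largest] <- paste0("**", disp[cc$largest], "**")
    out$cluster_by_bedroom <- as.data.frame(disp)
  } else {
    message("clustering missing; typology tables skipped")
  }
  if (!is.null(bundle$association)) {
    a <- bundle$association
    a$cell <- sprintf("%.3f %s(%.3f)", a$r,
                      ifelse(a$tier %in% c("*", "**"), a$tier, ""), a$p)
    wide <- data.table::dcast(data.table::as.data.table(a),
                              outcome ~ predictor, value.var = "cell")
    data.table::setcolorder(wide, c("outcome",
                                    intersect(ASSOCIATION_PREDICTORS, names(wide))))
    wide <- wide[match(ASSOCIATION_OUTCOMES, wide$outcome)]
    out$associations <- as.data.frame(wide)
  } else {
    message("association missing; association table skipped")
  }
  out
}

#' Write formatted report tables to disk
#' @param tables output of [report_tables()].
#' @param output_dir target directory.
#' @return invisibly, the written paths.
#' @export
write_report_tables <- function(tables, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(output_dir, paste0("table_", nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
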