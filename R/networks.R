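#' Two-mode (resident-location) network
#'
#' Builds the bipartite network linking residents to the zones they
#' visited: an edge (resident, zone) exists iff the resident has at least
#' one presence interval there, weighted by the number of distinct visit
#' intervals (or total dwell seconds).
#'
#' @param intervals presence intervals ([records_to_intervals()]).
#' @param weight `"visits"` (interval count, default) or `"dwell_s"`
#'   (total seconds).
#' @return an igraph bipartite graph; resident vertices have `type = FALSE`,
#'   zone vertices `type = TRUE`.
#' @export
build_two_mode <- function(intervals, weight = c("visits", "dwell_s")) {
  weight <- match.arg(weight)
  iv <- data.table::as.data.table(intervals)
  if (nrow(iv) == 0L) {
    g <- igraph::make_empty_graph(directed = FALSE)
    return(g)
  }
  ew <- iv[, .(weight = if (weight == "visits") .N else sum(end - start)),
           by = .(device_id, zone_id)]
  residents <- sort(unique(ew$device_id))
  zones <- sort(unique(ew$zone_id))
  verts <- data.frame(name = c(residents, zones),
                      type = c(rep(FALSE, length(residents)),
                               rep(TRUE, length(zones))))
  igraph::graph_from_data_frame(
    d = data.frame(from = ew$device_id, to = ew$zone_id, weight = ew$weight),
    directed = FALSE, vertices = verts
  )
}

#' One-mode (resident-resident) projection
#'
#' Converts interaction events into the undirected resident network: an
#' edge joins two residents iff they share at least one event; the edge
#' weight is the event count, with a per-edge breakdown by location class
#' (bedroom vs common/other) and by roommate relation.
#'
#' @param events event table ([detect_interactions()]).
#' @param fac optional [facility()]; when given, all roster residents
#'   become vertices (isolates included) with `bedroom_type` attributes,
#'   and edges carry `roommates` plus per-class event counts.
#' @return an undirected igraph graph.
#' @export
project_one_mode <- function(events, fac = NULL) {
  ev <- data.table::as.data.table(events)
  if (!is.null(fac)) {
    verts <- data.frame(name = fac$residents$resident_id,
                        bedroom_type = fac$residents$bedroom_type,
                        bedroom_zone = fac$residents$bedroom_zone)
  } else {
    verts <- data.frame(name = sort(unique(c(ev$resident_a, ev$resident_b))))
  }
  if (nrow(ev) == 0L) {
    return(igraph::graph_from_data_frame(
      data.frame(from = character(0), to = character(0), weight = numeric(0)),
      directed = FALSE, vertices = verts))
  }
  if (!is.null(fac)) {
    zc <- zone_class_of(fac, ev$zone_id)
    ev[, zclass := ifelse(zc == "bedroom", "bedroom", "common")]
  } else {
    ev[, zclass := "common"]
  }
  agg <- ev[, .(weight = .N,
                n_bedroom = sum(zclass == "bedroom"),
                n_common = sum(zclass != "bedroom")),
            by = .(resident_a, resident_b)]
  g <- igraph::graph_from_data_frame(
    data.frame(from = agg$resident_a, to = agg$resident_b,
               weight = agg$weight, n_bedroom = agg$n_bedroom,
               n_common = agg$n_common),
    directed = FALSE, vertices = verts
  )
  if (!is.null(fac)) {
    rm <- roommate_matrix(fac)
    el <- igraph::as_edgelist(g)
    igraph::E(g)$roommates <- rm[cbind(el[, 1], el[, 2])]
  }
  g
}

FEATURE_COLS <- c(
  "n_partners_roommates_own_bedroom", "n_partners_nonroommates_other_bedrooms",
  "n_partners_roommates_common", "n_partners_nonroommates_common",
  "freq_roommates_own_bedroom", "freq_nonroommates_other_bedrooms",
  "freq_alone", "freq_roommates_common", "freq_nonroommates_common"
)

#' Per-resident network features
#'
#' Computes, for every resident on the roster, the feature vector used by
#' the social-cluster typology and the association analysis: partner counts
#' and daily contact frequencies stratified by (roommate relation x
#' location class), the solitude frequency, totals, and degree centrality.
#'
#' Strata: an event between roommates in a bedroom counts as "roommates in
#' own bedrooms" for both (roommates share one bedroom); between
#' non-roommates in any bedroom as "non-roommates in other bedrooms";
#' events in common areas (and any non-bedroom zone) split into the two
#' common-area strata by roommate relation. A partner is counted once per
#' stratum regardless of event count; `n_partners_total` deduplicates
#' partners across strata. Frequencies are events per observed day
#' (`window_days`), with no extrapolation for unsampled hours. Degree
#' centrality is Freeman-normalised degree on the binarised network:
#' distinct partners / (N - 1); 0 iff the resident is an isolate.
#'
#' @param events event table ([detect_interactions()]).
#' @param fac the [facility()] (roster + zone classes).
#' @param window_days number of observed days the events cover (frequency
#'   denominator).
#' @param intervals optional presence intervals; when supplied, solitude
#'   episodes ([count_alone_episodes()]) feed `freq_alone`, otherwise
#'   `freq_alone` is 0.
#' @param min_duration_s threshold passed to the solitude scan.
#' @return data.frame, one row per roster resident: the nine stratified
#'   features, `n_partners_total`, `freq_total`, `degree_centrality`.
#' @export
compute_features <- function(events, fac, window_days, intervals = NULL,
                             min_duration_s = 300) {
  window_days <- as.numeric(window_days)
  if (length(window_days) != 1L || is.na(window_days) || window_days <= 0) {
    stop_invalid("window_days must be a positive number")
  }
  ids <- fac$residents$resident_id
  n <- length(ids)
  ev <- data.table::as.data.table(events)
  if (nrow(ev) > 0L) {
    missing_res <- setdiff(unique(c(ev$resident_a, ev$resident_b)), ids)
    if (length(missing_res) > 0L) {
      stop_invalid("residents not on roster: %s", paste(missing_res, collapse = ", "))
    }
  }
  out <- data.frame(resident_id = ids, stringsAsFactors = FALSE)
  for (cl in FEATURE_COLS) out[[cl]] <- 0
  out$n_partners_total <- 0
  out$freq_total <- 0
  out$degree_centrality <- 0
  if (nrow(ev) > 0L) {
    rm <- roommate_matrix(fac)
    zc <- zone_class_of(fac, ev$zone_id)
    long <- data.table::rbindlist(list(
      ev[, .(ego = resident_a, alter = resident_b, zone_id)],
      ev[, .(ego = resident_b, alter = resident_a, zone_id)]
    ))
    long[, zclass := rep(ifelse(zc == "bedroom", "bedroom", "common"), 2L)]
    long[, roommate := rm[cbind(ego, alter)]]
    long[, stratum := data.table::fcase(
      roommate & zclass == "bedroom", "roommates_own_bedroom",
      !roommate & zclass == "bedroom", "nonroommates_other_bedrooms",
      roommate & zclass == "common", "roommates_common",
      default = "nonroommates_common"
    )]
    parts <- long[, .(n_partners = data.table::uniqueN(alter), n_events = .N),
                  by = .(ego, stratum)]
    for (st in unique(parts$stratum)) {
      sub <- parts[stratum == st]
      i <- match(sub$ego, out$resident_id)
      out[[paste0("n_partners_", st)]][i] <- sub$n_partners
      out[[paste0("freq_", st)]][i] <- sub$n_events / window_days
    }
    tot <- long[, .(n_partners = data.table::uniqueN(alter), n_events = .N),
                by = ego]
    i <- match(tot$ego, out$resident_id)
    out$n_partners_total[i] <- tot$n_partners
    out$freq_total[i] <- tot$n_events / window_days
    out$degree_centrality <- out$n_partners_total / (n - 1)
  }
  if (!is.null(intervals)) {
    alone <- count_alone_episodes(intervals, all_residents = ids,
                                  min_duration_s = min_duration_s)
    out$freq_alone <- as.numeric(alone[out$resident_id]) / window_days
  }
  out
}

#' Group means of network characteristics
#'
#' Summarises features per group (typically bedroom type): unweighted
#' within-group means, plus an overall row computed as the
#' participant-weighted mean of the group means (equivalently the mean over
#' all residents when groups partition the roster).
#'
#' @param features feature data.frame ([compute_features()]).
#' @param grouping named character vector mapping `resident_id` to group.
#' @param vars feature columns to summarise.
#' @return data.frame: one row per group plus an `"overall"` row, with
#'   group sizes in column `n`. Empty groups are reported with `NA` means.
#' @export
summarize_by_group <- function(features, grouping,
                               vars = c("n_partners_total", "freq_total",
                                        "degree_centrality")) {
  miss <- setdiff(features$resident_id, names(grouping))
  if (length(miss) > 0L) {
    stop_invalid("grouping does not cover residents: %s",
                 paste(miss, collapse = ", "))
  }
  g <- grouping[features$resident_id]
  groups <- sort(unique(as.character(grouping)))
  rows <- lapply(groups, function(gr) {
    sel <- which(g == gr)
    m <- if (length(sel) == 0L) {
      stats::setNames(rep(NA_real_, length(vars)), vars)
    } else {
      vapply(vars, function(v) mean(features[[v]][sel]), 0)
    }
    cbind(data.frame(group = gr, n = length(sel)), as.data.frame(as.list(m)))
  })
  out <- do.call(rbind, rows)
  counts <- out$n
  ov <- vapply(vars, function(v) {
    overall_weighted_mean(out[[v]], counts)
  }, 0)
  out <- rbind(out, cbind(data.frame(group = "overall", n = sum(counts)),
                          as.data.frame(as.list(ov))))
  rownames(out) <- NULL
  out
}

#' Participant-weighted overall mean of group means
#'
#' The overall row of a group summary: group means weighted by the number
#' of participants in each group. Used both on computed features and to
#' reproduce overall means from published per-group summaries.
#'
#' @param means numeric vector of group means.
#' @param counts group sizes.
#' @return weighted mean (groups with `NA` mean and zero count dropped).
#' @export
#' @examples
#' overall_weighted_mean(c(1.10, 2.43, 1.85, 2.79), c(7, 15, 18, 8))
overall_weighted_mean <- function(means, counts) {
  if (length(means) != length(counts)) stop_invalid("means and counts differ in length")
  keep <- !(is.na(means) & counts == 0)
  sum(means[keep] * counts[keep]) / sum(counts[keep])
}

#' Export / import a network
#'
#' Serialises a network with node attributes and edge weights to GraphML,
#' GEXF or an edge-list CSV, round-trippably.
#'
#' @param g an igraph graph.
#' @param path output path.
#' @param format `"graphml"`, `"gexf"` or `"edgelist"`.
#' @return `path` invisibly for export; an igraph graph for import.
#' @export
export_network <- function(g, path, format = c("graphml", "gexf", "edgelist")) {
  format <- match.arg(format)
  switch(format,
    graphml = igraph::write_graph(g, path, format = "graphml"),
    gexf = write_gexf(g, path),
    edgelist = {
      el <- igraph::as_data_frame(g, what = "edges")
      data.table::fwrite(data.table::as.data.table(el), path)
    }
  )
  invisible(path)
}

#' @rdname export_network
#' @export
import_network <- function(path, format = c("graphml", "gexf", "edgelist")) {
  format <- match.arg(format)
  switch(format,
    graphml = igraph::read_graph(path, format = "graphml"),
    gexf = read_gexf(path),
    edgelist = {
      el <- data.table::fread(path)
      if (nrow(el) == 0L) {
        igraph::make_empty_graph(directed = FALSE)
      } else {
        igraph::graph_from_data_frame(el, directed = FALSE)
      }
    }
  )
}

# Minimal GEXF 1.3 writer/reader: node labels + declared node attributes,
# edge weights. Covers round-tripping of typed attributes.
write_gexf <- function(g, path) {
  doc <- xml2::xml_new_root("gexf",
                            xmlns = "http://gexf.net/1.3", version = "1.3")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected")
  vattrs <- setdiff(igraph::vertex_attr_names(g), "name")
  if (length(vattrs) > 0L) {
    attrs <- xml2::xml_add_child(graph, "attributes", class = "node")
    for (i in seq_along(vattrs)) {
      v <- igraph::vertex_attr(g, vattrs[i])
      tp <- if (is.numeric(v)) "double" else if (is.logical(v)) "boolean" else "string"
      xml2::xml_add_child(attrs, "attribute", id = as.character(i - 1L),
                          title = vattrs[i], type = tp)
    }
  }
  nodes <- xml2::xml_add_child(graph, "nodes")
  vnames <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
  for (vi in seq_len(igraph::vcount(g))) {
    nd <- xml2::xml_add_child(nodes, "node", id = vnames[vi], label = vnames[vi])
    if (length(vattrs) > 0L) {
      av <- xml2::xml_add_child(nd, "attvalues")
      for (i in seq_along(vattrs)) {
        xml2::xml_add_child(av, "attvalue", `for` = as.character(i - 1L),
                            value = as.character(igraph::vertex_attr(g, vattrs[i])[vi]))
      }
    }
  }
  edges <- xml2::xml_add_child(graph, "edges")
  if (igraph::ecount(g) > 0L) {
    el <- igraph::as_edgelist(g)
    w <- igraph::E(g)$weight %||% rep(1, igraph::ecount(g))
    for (ei in seq_len(nrow(el))) {
      xml2::xml_add_child(edges, "edge", id = as.character(ei - 1L),
                          source = el[ei, 1], target = el[ei, 2],
                          weight = as.character(w[ei]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

read_gexf <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  node_xml <- xml2::xml_find_all(doc, ".//nodes/node")
  ids <- xml2::xml_attr(node_xml, "id")
  attr_xml <- xml2::xml_find_all(doc, ".//attributes[@class='node']/attribute")
  adefs <- data.frame(id = xml2::xml_attr(attr_xml, "id"),
                      title = xml2::xml_attr(attr_xml, "title"),
                      type = xml2::xml_attr(attr_xml, "type"),
                      stringsAsFactors = FALSE)
  verts <- data.frame(name = ids, stringsAsFactors = FALSE)
  for (j in seq_len(nrow(adefs))) {
    vals <- vapply(node_xml, function(nd) {
      v <- xml2::xml_find_first(nd, sprintf(".//attvalue[@for='%s']", adefs$id[j]))
      xml2::xml_attr(v, "value")
    }, "")
    verts[[adefs$title[j]]] <- switch(adefs$type[j],
                                      double = as.numeric(vals),
                                      boolean = as.logical(vals),
                                      vals)
  }
  edge_xml <- xml2::xml_find_all(doc, ".//edges/edge")
  ed <- data.frame(from = xml2::xml_attr(edge_xml, "source"),
                   to = xml2::xml_attr(edge_xml, "target"),
                   stringsAsFactors = FALSE)
  w <- xml2::xml_attr(edge_xml, "weight")
  if (length(w) > 0L && !all(is.na(w))) ed$weight <- as.numeric(w)
  igraph::graph_from_data_frame(ed, directed = FALSE, vertices = verts)
}
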