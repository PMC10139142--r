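test_that("two-mode network weights count visit intervals", {
  rec <- rbind(rec_block("a", "A", 0, 100), rec_block("a", "A", 300, 100),
               rec_block("a", "A", 600, 100))
  iv <- records_to_intervals(rec, max_gap_s = 60)
  g <- build_two_mode(iv)
  expect_true(igraph::is_bipartite(g))
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(igraph::E(g)$weight, 3)
  # dwell weighting
  g2 <- build_two_mode(iv, weight = "dwell_s")
  expect_equal(igraph::E(g2)$weight, 300)
  # no intervals -> empty graph
  expect_equal(igraph::ecount(build_two_mode(iv[0])), 0L)
})

test_that("one-mode projection counts events and conserves total weight", {
  fac <- tiny_facility()
  ev <- data.frame(
    resident_a = c("r1", "r1", "r1", "r1", "r1", "r2"),
    resident_b = c("r2", "r2", "r2", "r2", "r2", "r3"),
    zone_id = c(rep("bedA", 5), "lounge"),
    start = 0L, end = 400L, duration_s = 400L
  )
  g <- project_one_mode(ev, fac)
  expect_equal(igraph::vcount(g), 5L)  # all roster residents, isolates too
  w <- igraph::E(g)$weight
  expect_equal(sum(w), nrow(ev))  # projection conservation
  e12 <- igraph::get_edge_ids(g, c("r1", "r2"))
  expect_equal(igraph::E(g)$weight[e12], 5)
  expect_true(igraph::E(g)$roommates[e12])
  expect_equal(igraph::E(g)$n_bedroom[e12], 5)
  # path graph r1-r2-r3
  expect_equal(igraph::ecount(g), 2L)
  expect_false(igraph::are_adjacent(g, "r1", "r3"))
})

test_that("projection adjacency equals brute-force pair counting", {
  fac <- tiny_facility()
  set.seed(42)
  ids <- fac$residents$resident_id
  n_ev <- 60
  pairs <- t(replicate(n_ev, sort(sample(ids, 2))))
  ev <- data.frame(resident_a = pairs[, 1], resident_b = pairs[, 2],
                   zone_id = sample(c("bedA", "bedB", "lounge"), n_ev, TRUE),
                   start = 0L, end = 400L, duration_s = 400L)
  g <- project_one_mode(ev, fac)
  counted <- table(paste(ev$resident_a, ev$resident_b))
  el <- igraph::as_edgelist(g)
  for (i in seq_len(nrow(el))) {
    key <- paste(min(el[i, ]), max(el[i, ]))
    expect_equal(igraph::E(g)$weight[i], as.numeric(counted[[key]]))
  }
  expect_equal(igraph::ecount(g), length(counted))
})

test_that("feature computation: isolates, strata and centrality normalisation", {
  fac <- tiny_facility()
  ev <- data.frame(
    resident_a = c("r1", "r1", "r3"),
    resident_b = c("r2", "r3", "r4"),
    zone_id = c("bedA", "lounge", "bedB"),
    start = 0L, end = 400L, duration_s = 400L
  )
  f <- compute_features(ev, fac, window_days = 2)
  rownames(f) <- f$resident_id
  # r5 has no events: all-zero row
  expect_true(all(f["r5", c(colocnet:::FEATURE_COLS, "n_partners_total",
                            "freq_total", "degree_centrality")] == 0))
  # r1: roommate r2 in own bedroom; non-roommate r3 in common
  expect_equal(f["r1", "n_partners_roommates_own_bedroom"], 1)
  expect_equal(f["r1", "n_partners_nonroommates_common"], 1)
  expect_equal(f["r1", "freq_roommates_own_bedroom"], 0.5)  # 1 event / 2 days
  expect_equal(f["r1", "n_partners_total"], 2)
  expect_equal(f["r1", "degree_centrality"], 2 / 4)
  # r3-r4 are roommates meeting in their own bedroom
  expect_equal(f["r3", "n_partners_roommates_own_bedroom"], 1)
  expect_error(compute_features(
    data.frame(resident_a = "rx", resident_b = "r1", zone_id = "bedA",
               start = 0L, end = 400L, duration_s = 400L),
    fac, window_days = 1), class = "colocnet_invalid_input")
})

test_that("star centre attains degree centrality 1", {
  fac <- tiny_facility()
  others <- c("r2", "r3", "r4", "r5")
  ev <- data.frame(resident_a = pmin("r1", others),
                   resident_b = pmax("r1", others),
                   zone_id = "lounge", start = 0L, end = 400L,
                   duration_s = 400L)
  f <- compute_features(ev, fac, window_days = 1)
  expect_equal(f$degree_centrality[f$resident_id == "r1"], 1)
  expect_true(all(f$degree_centrality >= 0 & f$degree_centrality <= 1))
  expect_true(all((f$degree_centrality == 0) == (f$n_partners_total == 0)))
})

test_that("features equal a per-resident brute-force tally on simulated data", {
  fac <- tiny_facility()
  pc <- stats::setNames(rep(1:2, length.out = 5), fac$residents$resident_id)
  cfg <- simulation_config(facility = fac, n_days = 1, sampling = "all_hours",
                           detection_prob = 1, duplication_prob = 0,
                           planted_clusters = pc, seed = 31)
  sim <- simulate_facility(cfg)
  iv <- records_to_intervals(clean_records(sim$records))
  ev <- as_plain(detect_interactions(iv, roster = fac$residents$resident_id))
  f <- compute_features(ev, fac, window_days = 1, intervals = iv)
  rm <- roommate_matrix(fac)
  bed_zones <- fac$zones$zone_id[fac$zones$zone_class == "bedroom"]
  for (r in fac$residents$resident_id) {
    mine <- ev[ev$resident_a == r | ev$resident_b == r, ]
    alter <- ifelse(mine$resident_a == r, mine$resident_b, mine$resident_a)
    isrm <- rm[cbind(rep(r, nrow(mine)), alter)]
    isbed <- mine$zone_id %in% bed_zones
    row <- f[f$resident_id == r, ]
    expect_equal(row$n_partners_roommates_own_bedroom,
                 length(unique(alter[isrm & isbed])))
    expect_equal(row$n_partners_nonroommates_common,
                 length(unique(alter[!isrm & !isbed])))
    expect_equal(row$freq_nonroommates_other_bedrooms, sum(!isrm & isbed))
    expect_equal(row$freq_total, nrow(mine))
    expect_equal(row$n_partners_total, length(unique(alter)))
  }
})

test_that("group summaries weight the overall row by participants", {
  fac <- tiny_facility()
  f <- data.frame(resident_id = fac$residents$resident_id,
                  n_partners_total = c(1, 2, 3, 4, 5),
                  freq_total = c(2, 2, 4, 4, 4),
                  degree_centrality = c(0.1, 0.2, 0.3, 0.4, 0.5))
  grouping <- stats::setNames(fac$residents$bedroom_type,
                              fac$residents$resident_id)
  sm <- summarize_by_group(f, grouping)
  expect_equal(sm$n_partners_total[sm$group == "three_bed"], 1.5)
  expect_equal(sm$n_partners_total[sm$group == "four_bed_common"], 4)
  expect_equal(sm$n_partners_total[sm$group == "overall"], 3)  # mean of all 5
  # single group: overall equals the group mean
  sm1 <- summarize_by_group(f, stats::setNames(rep("g", 5), f$resident_id))
  expect_equal(sm1$freq_total[sm1$group == "overall"],
               sm1$freq_total[sm1$group == "g"])
  # summaries invariant to resident order
  sm2 <- summarize_by_group(f[5:1, ], grouping)
  expect_equal(sm, sm2)
})

test_that("network export round-trips across formats", {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "b", "c"), to = c("b", "c", "a"),
               weight = c(1.5, 2, 7)),
    directed = FALSE,
    vertices = data.frame(name = c("a", "b", "c"),
                          bedroom_type = c("three_bed", "five_bed", "five_bed"),
                          cluster = c(1, 2, 2))
  )
  for (fmt in c("graphml", "gexf", "edgelist")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    export_network(g, path, fmt)
    g2 <- import_network(path, fmt)
    expect_equal(igraph::vcount(g2), 3L, info = fmt)
    expect_equal(igraph::ecount(g2), 3L, info = fmt)
    perm <- match(igraph::V(g)$name, igraph::V(g2)$name)
    for (i in seq_len(3)) {
      e <- igraph::as_edgelist(g)[i, ]
      id2 <- igraph::get_edge_ids(g2, e)
      expect_equal(igraph::E(g2)$weight[id2], igraph::E(g)$weight[i], info = fmt)
    }
    if (fmt != "edgelist") {
      expect_equal(igraph::V(g2)$bedroom_type[perm], igraph::V(g)$bedroom_type,
                   info = fmt)
      expect_equal(as.numeric(igraph::V(g2)$cluster[perm]),
                   as.numeric(igraph::V(g)$cluster), info = fmt)
    }
  }
  # empty graph serialises and parses
  g0 <- igraph::make_empty_graph(directed = FALSE)
  path <- withr::local_tempfile(fileext = ".gexf")
  export_network(g0, path, "gexf")
  expect_equal(igraph::ecount(import_network(path, "gexf")), 0L)
})
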