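toy_net <- function(edges, n = 4, prov = NA_character_) {
  ids <- sprintf("N%d", seq_len(n))
  confidant_network(ids, data.frame(from = as.character(edges[, 1]),
                                    to = as.character(edges[, 2]),
                                    provenance = rep(prov, nrow(edges)),
                                    stringsAsFactors = FALSE))
}

test_that("potential-tie count is n(n-1)/2", {
  expect_equal(max_potential_ties(660), 217470)
  expect_equal(max_potential_ties(2), 1)
  expect_equal(max_potential_ties(1), 0)
  expect_error(max_potential_ties(0), ">= 1")
})

test_that("density collapses reciprocated duplicates before dividing", {
  # empty network
  expect_equal(network_density(toy_net(matrix(nrow = 0, ncol = 2))), 0)
  # fully mutual complete graph
  full <- expand.grid(i = 1:4, j = 1:4)
  full <- full[full$i != full$j, ]
  net <- toy_net(cbind(sprintf("N%d", full$i), sprintf("N%d", full$j)))
  expect_equal(network_density(net), 1)
  # 300 directed ties, 180 in reciprocated pairs, over 660 nodes:
  # 120 + 90 collapsed ties against 217470 potential
  ids <- sprintf("P%03d", 1:660)
  mut <- cbind(ids[seq(1, 179, 2)], ids[seq(2, 180, 2)])      # 90 pairs
  one <- cbind(ids[181:300], ids[301:420])                    # 120 one-way
  big <- confidant_network(ids, data.frame(
    from = c(mut[, 1], mut[, 2], one[, 1]),
    to = c(mut[, 2], mut[, 1], one[, 2]), stringsAsFactors = FALSE))
  expect_equal(nrow(big$edges), 300)
  expect_equal(network_density(big), 210 / 217470)
  expect_equal(round(network_density(big), 3), 0.001)
  expect_error(network_density(confidant_network("solo")), "2 nodes")
})

test_that("reciprocity partition classifies every directed tie", {
  net <- toy_net(rbind(c("N1", "N2"), c("N2", "N1"), c("N3", "N1")))
  expect_equal(reciprocity_partition(net),
               c(one_way = 1L, reciprocal = 2L))
  expect_equal(reciprocity_partition(toy_net(matrix(nrow = 0, ncol = 2))),
               c(one_way = 0L, reciprocal = 0L))
  mutual <- toy_net(rbind(c("N1", "N2"), c("N2", "N1"),
                          c("N3", "N4"), c("N4", "N3")))
  expect_equal(reciprocity_partition(mutual),
               c(one_way = 0L, reciprocal = 4L))
})

test_that("components and geodesics work on the undirected collapse", {
  two_pairs <- toy_net(rbind(c("N1", "N2"), c("N2", "N1"),
                             c("N3", "N4"), c("N4", "N3")))
  cg <- components_and_geodesics(two_pairs)
  expect_equal(cg$component_count, 2)
  expect_equal(cg$size_range, c(2, 2))
  expect_equal(cg$mean_geodesic, 1.0)

  path <- toy_net(rbind(c("N1", "N2"), c("N2", "N3")), n = 4)
  cg2 <- components_and_geodesics(path)
  expect_equal(cg2$component_count, 1)  # the isolate N4 is excluded
  expect_equal(cg2$size_range, c(3, 3))
  expect_equal(cg2$mean_geodesic, 4 / 3)

  single <- toy_net(rbind(c("N1", "N2"), c("N2", "N1")), n = 2)
  cg3 <- components_and_geodesics(single)
  expect_equal(unlist(cg3), c(component_count = 1, size_range1 = 2,
                              size_range2 = 2, mean_geodesic = 1),
               ignore_attr = TRUE)

  none <- components_and_geodesics(toy_net(matrix(nrow = 0, ncol = 2)))
  expect_equal(none$component_count, 0)
  expect_true(is.na(none$mean_geodesic))
})

test_that("score-difference profile counts matches and near-matches", {
  ids <- c("A", "B", "C", "D")
  nd <- data.frame(participant_id = ids, gds_total = c(3, 3, 5, 12))
  net <- confidant_network(ids, data.frame(
    from = c("A", "A", "C"), to = c("B", "C", "D")), nd)
  prof <- score_difference_profile(net, "gds_total")
  expect_equal(prof$n_exact_match, 1)   # differences are {0, 2, 7}
  expect_equal(prof$n_within_five, 2)
  expect_equal(as.integer(prof$histogram[c("0", "2", "7")]), c(1, 1, 1))
  expect_equal(prof$n_ties_scored, 3)
})

test_that("score-difference profile excludes ties with missing scores", {
  ids <- c("A", "B", "C")
  nd <- data.frame(participant_id = ids, gds_total = c(3, NA, 5))
  net <- confidant_network(ids, data.frame(from = c("A", "A"),
                                           to = c("B", "C")), nd)
  prof <- score_difference_profile(net)
  expect_equal(prof$n_ties_scored, 1)
  expect_equal(prof$n_ties_dropped, 1)
})

test_that("descriptives satisfy their internal identities", {
  set.seed(42)
  for (rep in 1:5) {
    net <- random_network(25, p = 0.06)
    d <- describe_network(net)
    expect_equal(d$undirected_tie_count,
                 d$one_way_tie_count + d$reciprocal_directed_tie_count / 2)
    expect_equal(d$density, d$undirected_tie_count / d$max_potential_ties)
    expect_equal(d$reciprocal_directed_tie_count %% 2, 0)
    expect_gte(d$mean_geodesic, 1)
    expect_true(d$density >= 0 && d$density <= 1)
    # component sizes account for every non-isolated vertex
    expect_equal(d$vertices_with_tie,
                 sum(igraph::components(
                   igraph::delete_vertices(g <- as_igraph(net, TRUE),
                                           igraph::V(g)[igraph::degree(g)
                                                        == 0]))$csize))
    # adding a tie never decreases density
    absent <- which(!as_adjacency(net), arr.ind = TRUE)
    absent <- absent[absent[, 1] != absent[, 2], , drop = FALSE]
    pick <- absent[sample(nrow(absent), 1), ]
    net2 <- confidant_network(net$nodes, rbind(
      net$edges[, c("from", "to")],
      data.frame(from = net$nodes[pick[1]], to = net$nodes[pick[2]])),
      net$node_data)
    expect_gte(network_density(net2), d$density)
  }
})

test_that("the mean geodesic is 1 exactly when every component is a clique", {
  clique <- toy_net(rbind(c("N1", "N2"), c("N2", "N3"), c("N1", "N3")),
                    n = 3)
  expect_equal(components_and_geodesics(clique)$mean_geodesic, 1)
  chain <- toy_net(rbind(c("N1", "N2"), c("N2", "N3")), n = 3)
  expect_gt(components_and_geodesics(chain)$mean_geodesic, 1)
})
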