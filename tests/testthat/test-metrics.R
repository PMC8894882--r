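test_that("degree profiles group correctly and flag degenerate groups", {
  star <- fixture_network(rep("P1", 3), c("A00", "B00", "C00"))
  side <- degree_profile(star, "side")
  expect_equal(side$mean_degree[side$group == "patients"], 3)
  expect_equal(side$mean_degree[side$group == "diseases"], 1)
  expect_true(side$degenerate[side$group == "patients"])

  # I10 with degree 2, I20 with degree 4, both chapter IX -> mean 3
  net <- fixture_network(
    c("P1", "P2", "P1", "P2", "P3", "P4"),
    c("I10", "I10", "I20", "I20", "I20", "I20"))
  chap <- degree_profile(net, "chapter")
  expect_equal(chap$mean_degree[chap$group == "IX"], 3)
  expect_equal(chap$ci_hi[chap$group == "IX"] -
                 chap$ci_lo[chap$group == "IX"],
               2 * 1.96 * sd(c(2, 4)) / sqrt(2))
})

test_that("mixing profile reproduces hand-computed knn and tau", {
  net <- fixture_network(c("P1", "P1", "P2"), c("A00", "B00", "A00"))
  mp <- mixing_profile(net, "patients")
  pn <- mp$per_node[order(mp$per_node$node), ]
  expect_equal(pn$k, c(2, 1))
  expect_equal(pn$knn, c(1.5, 2))
  expect_equal(mp$tau, -1)  # one discordant pair

  # complete bipartite: no variance in k, tau undefined
  full <- fixture_network(rep(c("P1", "P2"), 3),
                          rep(c("A00", "B00", "C00"), each = 2))
  expect_true(is.na(mixing_profile(full, "patients")$tau))
  expect_equal(unique(mixing_profile(full, "patients")$per_node$knn), 2)
  # single node on a side
  star <- fixture_network(rep("P1", 3), c("A00", "B00", "C00"))
  expect_true(is.na(mixing_profile(star, "patients")$tau))
})

test_that("second-order neighbourhoods are distance-2, same-parity sets", {
  # disease v on 3 patients, each with one other distinct disease -> |NN| = 3
  net_a <- fixture_network(
    c("P1", "P2", "P3", "P1", "P2", "P3"),
    c("V00", "V00", "V00", "A00", "B00", "C00"))
  expect_equal(second_order(net_a, "V00"), c("A00", "B00", "C00"))
  # disease v on 1 patient with 3 other diseases -> |NN| = 3
  net_b <- fixture_network(rep("P1", 4), c("V00", "A00", "B00", "C00"))
  expect_equal(second_order(net_b, "V00"), c("A00", "B00", "C00"))
  # isolated edge
  net_c <- fixture_network(c("P1", "P2"), c("A00", "B00"))
  expect_equal(second_order(net_c, "A00"), character(0))
  expect_error(second_order(net_c, "Z99"), "not in network")
  # same-parity property on a random network
  net_r <- random_network(12, 8, 40, seed = 1)
  for (v in net_r$diseases$code3[1:4]) {
    expect_true(all(second_order(net_r, v) %in% net_r$diseases$code3))
  }
  for (p in net_r$patients$patient_id[1:4]) {
    expect_true(all(second_order(net_r, p) %in% net_r$patients$patient_id))
  }
})

test_that("degree/second-order correlations behave on planted instances", {
  full <- fixture_network(rep(c("P1", "P2"), 3),
                          rep(c("A00", "B00", "C00"), each = 2))
  sc <- second_order_correlations(full, "diseases")
  expect_true(is.na(sc$tau_k_nn))
  # planted monotone instance: hub X00 with (k, |NN|) = (4, 3), three leaf
  # diseases at (1, 1); every untied pair is concordant, so tau-b = 1
  net <- fixture_network(
    c("P1", "P2", "P3", "P4", "P1", "P2", "P3"),
    c("X00", "X00", "X00", "X00", "A00", "B00", "C00"))
  sc2 <- second_order_correlations(net, "diseases")
  pn <- sc2$per_node[order(sc2$per_node$node), ]
  expect_equal(pn$nn_size, c(1, 1, 1, 3))
  expect_equal(sc2$tau_k_nn, 1)
})

test_that("peer attributes average over second-order patients", {
  net <- fixture_network(c("P1", "P2"), c("A00", "A00"), ages = c(30, 50))
  pa <- peer_attribute(net, "age_at_smi")
  pn <- pa$per_node[order(pa$per_node$node), ]
  expect_equal(pn$peer_mean, c(50, 30), tolerance = 0.01)
  # a patient sharing no disease is excluded
  net2 <- fixture_network(c("P1", "P2", "P3"), c("A00", "A00", "B00"),
                          ages = c(30, 50, 70))
  pa2 <- peer_attribute(net2, "age_at_smi")
  expect_true(is.na(pa2$per_node$peer_mean[pa2$per_node$node == "P3"]))
  expect_error(peer_attribute(net2, "shoe_size"), "shoe_size")
})

test_that("average efficiency matches closed forms", {
  k22 <- fixture_network(rep(c("P1", "P2"), each = 2),
                         rep(c("A00", "B00"), 2))
  expect_equal(efficiency(k22, "all")$value, 5 / 6)
  two <- fixture_network(c("P1", "P2"), c("A00", "B00"))
  expect_equal(efficiency(two, "all")$value, 1 / 3)
  path <- fixture_network(c("P1", "P2"), c("A00", "A00"))
  expect_equal(efficiency(path, "patients")$value, 1 / 2)
  expect_error(efficiency(fixture_network("P1", "A00"), "patients"),
               "at least 2")
})

test_that("chapter lift reproduces the hand-computed ratio", {
  splits <- data.frame(patient_id = c("P1", "P2", "P3"),
                       stringsAsFactors = FALSE)
  splits$pre_existing <- list("A00", "A00", "C00")  # chapters I, I, II
  splits$post_set <- list("B00", "E00", "B00")      # chapters I, IV, I
  cl <- chapter_lift(splits)
  # lift(chapter I pre, chapter I post) = (1/3) / ((2/3) * (2/3)) = 0.75
  expect_equal(cl$lift["I", "I"], 0.75)
  expect_equal(cl$support["I", "I"], 1)
  single <- data.frame(patient_id = "P1", stringsAsFactors = FALSE)
  single$pre_existing <- list("A00")
  single$post_set <- list("J45")
  expect_equal(chapter_lift(single)$lift["I", "X"], 1.0)
})

test_that("chapter lift is near 1 under an independence cohort", {
  cfg <- cohort_config(n_patients = 400, seed = 8, recurrence_prob = 0)
  pat <- generate_cohort(cfg)
  ep <- generate_episodes(pat, cfg)
  ev <- build_event_stream(ep, pat)
  sp <- condition_splits(ev, pat)
  cl <- chapter_lift(sp)
  big <- cl$support >= 30   # well-supported cells only
  expect_true(all(abs(cl$lift[big] - 1) < 0.35))
})

test_that("projection modularity follows the e/a bookkeeping", {
  # two disjoint projected edges, communities = components -> Q = 0.5
  net <- fixture_network(c("P1", "P2", "P3", "P4"),
                         c("A00", "A00", "B00", "B00"))
  pr <- project(net, "patients")
  member <- c(P1 = 1, P2 = 1, P3 = 2, P4 = 2)
  expect_equal(graph_modularity(pr, member), 0.5)
  expect_equal(graph_modularity(pr, c(P1 = 1, P2 = 1, P3 = 1, P4 = 1)), 0)
  expect_error(graph_modularity(pr, c(P1 = 1, P2 = 1, P3 = 1)), "P4")
  # random partition of a dense random projection stays near 0
  net_r <- random_network(120, 40, 700, seed = 2)
  pr_r <- project(net_r, "patients")
  set.seed(3)
  ids <- net_r$patients$patient_id
  member_r <- setNames(sample(1:2, length(ids), replace = TRUE), ids)
  expect_lt(abs(graph_modularity(pr_r, member_r)), 0.1)
})

test_that("adding an edge never decreases efficiency", {
  for (seed in 1:20) {
    net <- random_network(8, 6, 14, seed = seed)
    e_before <- efficiency(net, "all")$value
    missing <- expand.grid(p = net$patients$patient_id,
                           d = net$diseases$code3,
                           stringsAsFactors = FALSE)
    have <- paste(net$edges$patient_id, net$edges$code3)
    missing <- missing[!paste(missing$p, missing$d) %in% have, ]
    if (nrow(missing) == 0) next
    set.seed(seed)
    pick <- missing[sample.int(nrow(missing), 1), ]
    net2 <- net
    net2$edges <- rbind(net2$edges,
                        data.frame(patient_id = pick$p, code3 = pick$d,
                                   weight = 1L, age_first_dx = 40L))
    e_after <- efficiency(net2, "all")$value
    expect_gte(e_after, e_before)
  }
})
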