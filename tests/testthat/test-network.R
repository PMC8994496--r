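edge <- function(s, t, type = "Regulation", refs = 3L) {
  data.frame(source = s, target = t, relation_type = type,
             n_references = as.integer(refs), stringsAsFactors = FALSE)
}

test_that("database loading merges duplicates and indexes degree", {
  empty <- load_interaction_db(edge("a", "b")[0, ])
  expect_equal(nrow(empty$edges), 0L)
  expect_length(empty$nodes, 0L)

  db <- load_interaction_db(rbind(edge("a", "b", refs = 2),
                                  edge("a", "b", refs = 1)))
  expect_equal(nrow(db$edges), 1L)
  expect_equal(db$edges$n_references, 3L)

  chain <- load_interaction_db(rbind(edge("a", "b"), edge("b", "c")))
  expect_equal(unname(chain$degree[c("a", "b", "c")]), c(1L, 2L, 1L))

  expect_error(load_interaction_db(edge("a", "b", type = "Binding")),
               "malformed")
  expect_error(load_interaction_db(edge("a", "a")), "self-loop")
})

test_that("regulator admission follows the profile-specific degree cut", {
  # regulator r: Regulation edges to 2 seeds, refs 3, total degree 2
  db <- load_interaction_db(rbind(edge("r", "s1"), edge("r", "s2")))
  seeds <- c("s1", "s2")
  muscle <- extract_network(db, seeds, profile = "muscle")
  expect_equal(muscle$regulators, "r")       # degree 2 >= 2
  common <- extract_network(db, seeds, profile = "common")
  expect_length(common$regulators, 0L)       # degree 2 < 5

  # same regulator but with reference count 2 on every seed edge
  db2 <- load_interaction_db(rbind(edge("r", "s1", refs = 2),
                                   edge("r", "s2", refs = 2)))
  expect_length(extract_network(db2, seeds, profile = "muscle")$regulators, 0L)
})

test_that("targets require two seeds, references and degree six", {
  seeds <- c("s1", "s2", "s3")
  base <- rbind(edge("s1", "t", "Expression", 4),
                edge("s2", "t", "Expression", 1),
                edge("x1", "t", "Expression", 1),
                edge("x2", "t", "Expression", 1),
                edge("x3", "t", "Expression", 1),
                edge("x4", "t", "Expression", 1))
  db <- load_interaction_db(base)         # degree 6, max seed refs 4
  expect_equal(extract_network(db, seeds)$targets, "t")

  db5 <- load_interaction_db(base[1:5, ]) # degree 5
  expect_length(extract_network(db5, seeds)$targets, 0L)

  one_seed <- rbind(edge("s1", "t", "Expression", 9),
                    base[3:6, ],
                    edge("x5", "t", "Expression", 1))
  db1 <- load_interaction_db(one_seed)
  expect_length(extract_network(db1, seeds)$targets, 0L)
})

test_that("extraction equals the brute-force node scan on random databases", {
  set.seed(17)
  for (i in 1:15) {
    el <- random_edge_list(n_nodes = sample(40:120, 1),
                           n_edges = sample(150:400, 1))
    db <- load_interaction_db(el)
    seeds <- sample(db$nodes, 12)
    for (prof in c("muscle", "common")) {
      got <- extract_network(db, seeds, profile = prof)
      want <- network_bruteforce(db, seeds, filter_params(), prof)
      expect_identical(got$regulators, want$regulators)
      expect_identical(got$targets, want$targets)
    }
  }
})

test_that("raising any threshold never admits a node", {
  set.seed(18)
  el <- random_edge_list(80, 300)
  db <- load_interaction_db(el)
  seeds <- sample(db$nodes, 10)
  base <- extract_network(db, seeds, filter_params(min_refs_target = 1,
                                                   min_degree_target = 1,
                                                   min_refs_regulator = 1,
                                                   min_degree_regulator = 1,
                                                   min_connected = 1))
  prev_r <- base$regulators
  prev_t <- base$targets
  for (lvl in 2:6) {
    nx <- extract_network(db, seeds, filter_params(
      min_refs_target = lvl, min_degree_target = lvl,
      min_refs_regulator = lvl, min_degree_regulator = lvl,
      min_connected = min(lvl, 3)))
    expect_true(all(nx$regulators %in% prev_r))
    expect_true(all(nx$targets %in% prev_t))
    prev_r <- nx$regulators
    prev_t <- nx$targets
  }
})

test_that("major nodes are the intersection across extracts", {
  e1 <- stub_extract(c("AKT1", "TNF", "EGF"), c("IL6"))
  e2 <- stub_extract(c("AKT1", "TNF", "INS"), c("IL6", "BCL2"))
  e3 <- stub_extract(c("AKT1", "TNF"), c("IL6"))
  expect_equal(major_nodes(list(e1, e2, e3), "regulator"),
               c("AKT1", "TNF"))
  expect_equal(major_nodes(list(e1, e2, e3), "target"), "IL6")
  expect_length(major_nodes(list(e1, stub_extract(character())), "regulator"), 0L)
  expect_error(major_nodes(list(e1), "regulator"), "at least two")
})

test_that("subnetworks keep only edges inside the node set", {
  db <- load_interaction_db(rbind(edge("s1", "s2"),
                                  edge("r", "s1"), edge("r", "s2"),
                                  edge("r", "s3"), edge("u", "v")))
  expect_equal(nrow(subnetwork(db, c("s1", "s2"))), 1L)  # inter-seed only
  expect_equal(nrow(subnetwork(db, c("s1", "s2", "s3"), "r")), 4L)
  expect_equal(nrow(subnetwork(db, c("zz"), c("yy"))), 0L)
})
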