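final_model <- umr_final_model()

test_that("the final-model degree table matches the published structure", {
  tab <- degree_table(final_model)
  sc <- tab[tab$factor == "social_contacts", ]
  expect_equal(sc$indegree_abs, 6)
  expect_equal(sc$outdegree_abs, 3)
  # climate receives nothing: absolute and weighted indegree exactly zero
  pc <- tab[tab$factor == "political_climate", ]
  expect_equal(pc$indegree_abs, 0)
  expect_identical(pc$indegree_weight_pct, 0)
  # rows sorted by impact descending
  expect_equal(tab$factor[1], "social_contacts")
  expect_true(all(diff(tab$impact) <= 0))
  # impact ties (housing/health care at 0.77) broken by factor id
  tied <- tab$factor[tab$impact == 0.77]
  expect_equal(tied, sort(tied))
})

test_that("degree statistics equal the brute-force summation oracle", {
  set.seed(5)
  for (rep in 1:30) {
    m <- random_fcm(n = sample(3:8, 1), density = runif(1, 0.1, 0.9))
    for (d_only in c(TRUE, FALSE)) {
      tab <- degree_table(m, display_only = d_only)
      tab <- tab[order(tab$factor), ]
      ora <- oracle_degree(m, display_only = d_only)
      ora <- ora[order(ora$factor), ]
      expect_equal(tab$indegree_abs, ora$indegree_abs)
      expect_equal(tab$outdegree_abs, ora$outdegree_abs)
      expect_equal(tab$indegree_weight_pct, ora$indegree_weight_pct)
      expect_equal(tab$outdegree_weight_pct, ora$outdegree_weight_pct)
    }
  }
})

test_that("an empty graph yields an all-zero table", {
  m <- fcm_model(data.frame(id = c("a", "b", "c")))
  tab <- degree_table(m)
  expect_true(all(tab$indegree_abs == 0) && all(tab$outdegree_abs == 0))
  expect_true(all(tab$indegree_weight_pct == 0))
  expect_true(all(tab$outdegree_weight_pct == 0))
})

test_that("motif census finds the published self-reinforcing triad", {
  mc <- motif_census(final_model)
  full <- mc$fully_reciprocal_triads
  expect_equal(nrow(full), 1)
  expect_setequal(unlist(full),
                  c("sociocultural_adaptation", "german_language",
                    "social_contacts"))
  # every listed motif's edges exist in the model
  W <- coef(final_model) != 0
  for (i in seq_len(nrow(mc$reciprocal_pairs))) {
    p <- mc$reciprocal_pairs[i, ]
    expect_true(W[p$a, p$b] && W[p$b, p$a])
  }
  for (i in seq_len(nrow(mc$triads))) {
    t3 <- mc$triads[i, ]
    expect_true(W[t3$a, t3$b] && W[t3$b, t3$c] && W[t3$c, t3$a])
  }
})

test_that("degenerate and complete graphs have the expected motif counts", {
  lone <- fcm_model(data.frame(id = c("a", "b")),
                    data.frame(source = "a", target = "b", weight = 6))
  mc <- motif_census(lone)
  expect_equal(nrow(mc$reciprocal_pairs), 0)
  expect_equal(nrow(mc$triads), 0)
  expect_equal(nrow(mc$fully_reciprocal_triads), 0)

  ids <- letters[1:4]
  pairs <- expand.grid(source = ids, target = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  pairs$weight <- 8
  complete <- fcm_model(data.frame(id = ids), pairs)
  mc4 <- motif_census(complete)
  expect_equal(nrow(mc4$reciprocal_pairs), choose(4, 2))
  expect_equal(nrow(mc4$fully_reciprocal_triads), choose(4, 3))
  # each of the C(4,3) triples carries a cycle in both orientations
  expect_equal(nrow(mc4$triads), 2 * choose(4, 3))
})

test_that("motif counts agree with matrix-trace and igraph oracles", {
  set.seed(19)
  for (rep in 1:25) {
    m <- random_fcm(n = sample(3:7, 1), density = runif(1, 0.2, 0.9))
    mc <- motif_census(m, display_only = FALSE)
    ora <- oracle_motif_counts(m, display_only = FALSE)
    expect_equal(nrow(mc$reciprocal_pairs), ora$reciprocal_pairs)
    expect_equal(nrow(mc$triads), ora$triads)
    expect_equal(nrow(mc$fully_reciprocal_triads), ora$fully_reciprocal_triads)
    # cross-check mutual dyads against igraph
    g <- igraph::graph_from_data_frame(m$edges[, c("source", "target")],
                                       directed = TRUE,
                                       vertices = m$nodes$id)
    expect_equal(nrow(mc$reciprocal_pairs),
                 sum(igraph::which_mutual(g)) / 2)
  }
})

test_that("influence paths are enumerated with product strengths", {
  line <- fcm_model(data.frame(id = c("a", "b", "c")),
                    data.frame(source = c("a", "b"), target = c("b", "c"),
                               weight = c(10, 10)))
  p <- influence_paths(line, "a", "c", max_len = 3)
  expect_equal(nrow(p), 1)
  expect_equal(p$strength, 1)
  expect_equal(p$path, "a -> b -> c")

  none <- fcm_model(data.frame(id = c("a", "b")))
  expect_equal(nrow(influence_paths(none, "a", "b")), 0)

  # two-step influence of the societal climate on language acquisition
  # passes through the social-contacts hub
  p2 <- influence_paths(final_model, "political_climate", "german_language",
                        max_len = 2)
  expect_true("political_climate -> social_contacts -> german_language"
              %in% p2$path)
  expect_false(any(p2$length > 2))
  # sorted by strength, strongest first
  expect_true(all(diff(p2$strength) <= 0))

  expect_error(influence_paths(final_model, "nope", "housing"), "unknown factor")
  expect_error(influence_paths(final_model, "housing", "housing"), "differ")
})

test_that("path enumeration agrees with igraph's simple-path search", {
  set.seed(29)
  for (rep in 1:10) {
    m <- random_fcm(n = 6, density = 0.35)
    g <- igraph::graph_from_data_frame(m$edges[, c("source", "target")],
                                       directed = TRUE, vertices = m$nodes$id)
    ids <- m$nodes$id
    st <- sample(ids, 2)
    for (cutoff in 2:4) {
      mine <- influence_paths(m, st[1], st[2], max_len = cutoff,
                              display_only = FALSE)
      ig <- igraph::all_simple_paths(g, from = st[1], to = st[2],
                                     cutoff = cutoff)
      ig_paths <- sort(vapply(ig, function(p)
        paste(names(p), collapse = " -> "), character(1)))
      expect_equal(sort(mine$path), ig_paths)
    }
  }
})

test_that("degree conservation holds and weight percentages sum to 100", {
  set.seed(41)
  for (rep in 1:50) {
    m <- random_fcm(n = sample(3:9, 1), density = runif(1))
    tab <- degree_table(m, display_only = FALSE)
    expect_equal(sum(tab$indegree_abs), nrow(m$edges))
    expect_equal(sum(tab$outdegree_abs), nrow(m$edges))
    if (nrow(m$edges)) {
      expect_equal(sum(tab$indegree_weight_pct), 100)
      expect_equal(sum(tab$outdegree_weight_pct), 100)
    }
  }
})
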