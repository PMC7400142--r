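test_that("the quorum-and-mean rule reproduces worked examples", {
  # nobody above zero: no consensus
  expect_true(is.na(consensus_weight(rep(0, 6))))
  # 5 raters clear the ceiling(2/3*6)=4 quorum; mean 32/6 retained as weight
  expect_equal(consensus_weight(c(8, 7, 6, 6, 5, 0)), 32 / 6)
  # quorum met (4 raters) but group mean 4.0 is not strictly above 5
  expect_true(is.na(consensus_weight(c(6, 6, 6, 6, 0, 0))))
  # ... while the rater-only mean 6.0 clears the threshold
  expect_equal(consensus_weight(c(6, 6, 6, 6, 0, 0),
                                mean_over = "raters_only"), 6)
  # boundary is strict: mean exactly 5 is rejected
  expect_true(is.na(consensus_weight(c(5, 5, 5, 5, 5, 5))))
  expect_error(consensus_weight(c(11, 0, 0)), "outside")
  expect_error(consensus_weight(c(-1, 0, 0)), "outside")
})

test_that("a unanimous maximal rating yields a single full-weight edge", {
  pairs <- expand.grid(source = c("a", "b"), target = c("a", "b"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  inf <- do.call(rbind, lapply(paste0("e", 1:6), function(ex) {
    data.frame(expert_id = ex, pairs,
               rating = ifelse(pairs$source == "a" & pairs$target == "b", 10, 0))
  }))
  m <- fcm_consensus(fcm_panel(inf))
  expect_equal(nrow(m$edges), 1)
  expect_equal(m$edges$source, "a")
  expect_equal(m$edges$target, "b")
  expect_equal(m$edges$weight, 10)
  expect_true(m$edges$display)
})

test_that("node impact is the mean impact rating on the 0-1 scale", {
  imp <- data.frame(expert_id = paste0("e", 1:6), factor = "a", rating = 7.8)
  inf <- data.frame(expert_id = paste0("e", 1:6), source = "a", target = "b",
                    rating = 10)
  m <- fcm_consensus(fcm_panel(inf, impact = imp))
  expect_equal(m$nodes$impact[m$nodes$id == "a"], 0.78)
  expect_true(is.na(m$nodes$impact[m$nodes$id == "b"]))
})

test_that("retained edge weights equal the configured mean exactly", {
  set.seed(11)
  for (rep in 1:20) {
    truth <- generate_truth(5, edge_density = 0.5)
    panel <- simulate_panel(truth, n_experts = 6, rating_noise_sd = 2,
                            miss_prob = 0.2, false_pos_prob = 0.2)
    for (mo in c("all_experts", "raters_only")) {
      m <- fcm_consensus(panel, mean_over = mo)
      for (i in seq_len(nrow(m$edges))) {
        sub <- panel$influence[panel$influence$source == m$edges$source[i] &
                                 panel$influence$target == m$edges$target[i], ]
        expected <- if (mo == "all_experts") {
          sum(sub$rating) / length(panel$experts)
        } else sum(sub$rating) / sum(sub$rating > 0)
        expect_equal(m$edges$weight[i], expected, tolerance = 1e-12)
      }
    }
  }
})

test_that("aggregation matches the brute-force pairwise oracle on small panels", {
  set.seed(23)
  for (rep in 1:30) {
    n_f <- sample(2:4, 1)
    n_e <- sample(1:4, 1)
    truth <- generate_truth(n_f, edge_density = 0.6)
    panel <- simulate_panel(truth, n_experts = n_e, rating_noise_sd = 3,
                            miss_prob = 0.3, false_pos_prob = 0.4)
    m <- fcm_consensus(panel)
    expect_equal(m$edges[, c("source", "target", "weight")],
                 oracle_aggregate_edges(panel))
  }
})

test_that("raising one rating never removes the rated edge", {
  set.seed(37)
  for (rep in 1:50) {
    r <- sample(0:10, 6, replace = TRUE)
    w <- consensus_weight(r)
    if (is.na(w)) next
    i <- sample(6, 1)
    r2 <- r
    r2[i] <- min(10, r2[i] + runif(1, 0, 10 - r2[i]))
    expect_false(is.na(consensus_weight(r2)))
  }
})

test_that("weight and impact categories partition the scale with closed-left bins", {
  w <- c(0, 4.99, 5, 5.5, 5.9, 6, 6.9, 7, 7.2, 10)
  expect_equal(as.character(categorize_weight(w)),
               c("below", "below", "medium", "medium", "medium",
                 "strong", "strong", "powerful", "powerful", "powerful"))
  expect_equal(as.character(categorize_impact(c(0.72, 0.70, 0.58))),
               c("powerful", "powerful", "medium"))
  expect_true(is.ordered(categorize_weight(5)))
  expect_error(categorize_weight(10.5), "\\[0, 10\\]")
  expect_error(categorize_impact(1.2), "\\[0, 1\\]")
})

test_that("panels reject out-of-range ratings, self-pairs and emptiness", {
  base <- data.frame(expert_id = "e1", source = "a", target = "b", rating = 5)
  expect_error(fcm_panel(transform(base, rating = 12)), "row 1")
  expect_error(fcm_panel(transform(base, target = "a")), "self-rating")
  expect_error(fcm_panel(base[0, ]), "no experts")
  expect_error(fcm_panel(rbind(base, base)), "duplicate rating")
})

test_that("display flag marks edges below the display threshold", {
  inf <- do.call(rbind, lapply(paste0("e", 1:6), function(ex) {
    rbind(data.frame(expert_id = ex, source = "a", target = "b", rating = 5.5),
          data.frame(expert_id = ex, source = "b", target = "c", rating = 8))
  }))
  m <- fcm_consensus(fcm_panel(inf), display_threshold = 7)
  expect_equal(nrow(m$edges), 2)
  expect_equal(m$edges$display[m$edges$source == "a"], FALSE)
  expect_equal(m$edges$display[m$edges$source == "b"], TRUE)
})
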