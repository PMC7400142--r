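# Shared builders and independent brute-force oracles used across tests.

# A panel built from an experts x named-pair rating spec:
# make_panel(list(e1 = c("a->b" = 8, "b->c" = 0), ...))
make_panel <- function(ratings, impact = NULL, factors = NULL) {
  rows <- do.call(rbind, lapply(names(ratings), function(ex) {
    r <- ratings[[ex]]
    st <- do.call(rbind, strsplit(names(r), "->", fixed = TRUE))
    data.frame(expert_id = ex, source = st[, 1], target = st[, 2],
               rating = as.numeric(r), stringsAsFactors = FALSE)
  }))
  fcm_panel(rows, impact = impact, factors = factors)
}

# Random weighted digraph with n nodes; uses the ambient RNG stream.
random_fcm <- function(n = 6, density = 0.4, wmin = 0.5, wmax = 10,
                       with_impact = TRUE) {
  ids <- sprintf("n%02d", seq_len(n))
  nodes <- data.frame(id = ids,
                      impact = if (with_impact) runif(n) else NA_real_)
  pairs <- expand.grid(source = ids, target = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  keep <- runif(nrow(pairs)) < density
  edges <- pairs[keep, , drop = FALSE]
  if (nrow(edges)) {
    edges$weight <- runif(nrow(edges), wmin, wmax)
    edges$display <- edges$weight >= 5
  }
  fcm_model(nodes, if (nrow(edges)) edges else NULL)
}

# Brute-force consensus rule, written from the elicitation protocol: count
# experts above zero, compare against the quorum, average, compare against
# the mean threshold.
oracle_consensus <- function(r, n = length(r), quorum_fraction = 2 / 3,
                             mean_threshold = 5,
                             mean_over = "all_experts") {
  above_zero <- 0
  total <- 0
  for (x in r) {
    if (x > 0) above_zero <- above_zero + 1
    total <- total + x
  }
  if (above_zero < ceiling(quorum_fraction * n)) return(NA_real_)
  avg <- if (mean_over == "all_experts") total / n else total / above_zero
  if (avg > mean_threshold) avg else NA_real_
}

# Brute-force panel aggregation: filter the long rating table pair by pair.
oracle_aggregate_edges <- function(panel, ...) {
  ids <- panel$factors$id
  out <- list()
  for (s in ids) for (t in ids) {
    if (s == t) next
    r <- numeric(length(panel$experts))
    names(r) <- panel$experts
    sub <- panel$influence[panel$influence$source == s &
                             panel$influence$target == t, ]
    r[sub$expert_id] <- sub$rating
    w <- oracle_consensus(unname(r), length(r), ...)
    if (!is.na(w)) out[[paste(s, t)]] <- data.frame(source = s, target = t,
                                                    weight = w)
  }
  if (!length(out)) {
    return(data.frame(source = character(), target = character(),
                      weight = numeric()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$source, res$target), ]
  rownames(res) <- NULL
  res
}

# Brute-force degree statistics by explicit loops over the edge list.
oracle_degree <- function(model, display_only = TRUE) {
  e <- model$edges
  if (display_only) e <- e[e$display, , drop = FALSE]
  total <- sum(e$weight)
  rows <- lapply(model$nodes$id, function(id) {
    in_i <- which(e$target == id)
    out_i <- which(e$source == id)
    data.frame(
      factor = id,
      indegree_abs = length(in_i),
      indegree_weight_pct = if (total > 0) 100 * sum(e$weight[in_i]) / total else 0,
      outdegree_abs = length(out_i),
      outdegree_weight_pct = if (total > 0) 100 * sum(e$weight[out_i]) / total else 0)
  })
  do.call(rbind, rows)
}

# Matrix-algebra motif counts: trace(A^3)/3 directed 3-cycles (no self
# loops, so closed 3-walks are exactly triangles), mutual dyads from the
# symmetrised adjacency, trace(M^3)/6 fully reciprocal triples.
oracle_motif_counts <- function(model, display_only = TRUE) {
  A <- (coef(model, display_only = display_only) != 0) * 1
  M <- A * t(A)
  tr <- function(X) sum(diag(X))
  list(reciprocal_pairs = sum(M) / 2,
       triads = tr(A %*% A %*% A) / 3,
       fully_reciprocal_triads = tr(M %*% M %*% M) / 6)
}
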