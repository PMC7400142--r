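#' Degree and weighted-degree table of a system model
#'
#' For every factor: the impact score, the absolute in/out degree (number of
#' incident directed edges) and the weighted in/out degree as the percentage
#' of the model's total edge weight carried by the factor's in/out edges.
#' Percentages are kept at full precision; each column sums to exactly 100
#' on a non-empty graph (round only when rendering). Rows are sorted by
#' impact descending with ties broken by factor id.
#'
#' @param model an [fcm_model()].
#' @param display_only restrict to edges at the display threshold (default
#'   TRUE, matching how final models are published).
#' @return Data frame with columns `factor`, `name`, `impact`,
#'   `indegree_abs`, `indegree_weight_pct`, `outdegree_abs`,
#'   `outdegree_weight_pct`.
#' @export
degree_table <- function(model, display_only = TRUE) {
  stopifnot(inherits(model, "fcm"))
  e <- model$edges
  if (display_only) e <- e[e$display, , drop = FALSE]
  ids <- model$nodes$id
  zero <- setNames(numeric(length(ids)), ids)
  add_by <- function(values, by) {
    out <- zero
    if (length(values)) {
      s <- tapply(values, by, sum)
      out[names(s)] <- s
    }
    out
  }
  in_abs <- add_by(rep(1, nrow(e)), e$target)
  out_abs <- add_by(rep(1, nrow(e)), e$source)
  in_w <- add_by(e$weight, e$target)
  out_w <- add_by(e$weight, e$source)
  total_w <- sum(e$weight)
  pct <- function(w) if (total_w > 0) 100 * w / total_w else w * 0

  tab <- data.frame(factor = ids, name = model$nodes$name,
                    impact = model$nodes$impact,
                    indegree_abs = as.integer(in_abs),
                    indegree_weight_pct = pct(in_w),
                    outdegree_abs = as.integer(out_abs),
                    outdegree_weight_pct = pct(out_w),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-xtfrm(tab$impact), tab$factor, na.last = TRUE), ]
  rownames(tab) <- NULL
  tab
}

#' Census of reciprocal dyads and self-reinforcing triads
#'
#' Enumerates, each exactly once: unordered factor pairs connected in both
#' directions (reciprocal relations), node triples carrying a directed
#' 3-cycle (self-reinforcing triads; a triple may carry one cycle per
#' orientation), and triples in which all six directed edges are present
#' (fully reciprocal triads).
#'
#' @inheritParams degree_table
#' @return An `fcm_motifs` list with data frames `reciprocal_pairs`
#'   (columns a, b), `triads` (columns a, b, c tracing the cycle
#'   a -> b -> c -> a) and `fully_reciprocal_triads` (columns a, b, c).
#' @export
motif_census <- function(model, display_only = TRUE) {
  stopifnot(inherits(model, "fcm"))
  A <- coef(model, display_only = display_only) != 0
  ids <- rownames(A)
  n <- length(ids)

  pairs <- list(); triads <- list(); full <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (A[i, j] && A[j, i]) pairs[[length(pairs) + 1L]] <- c(ids[i], ids[j])
    }
  }
  if (n >= 3) {
    for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      # two possible cycle orientations through the triple {i,j,k}
      if (A[i, j] && A[j, k] && A[k, i]) {
        triads[[length(triads) + 1L]] <- ids[c(i, j, k)]
      }
      if (A[i, k] && A[k, j] && A[j, i]) {
        triads[[length(triads) + 1L]] <- ids[c(i, k, j)]
      }
      if (A[i, j] && A[j, i] && A[j, k] && A[k, j] && A[i, k] && A[k, i]) {
        full[[length(full) + 1L]] <- ids[c(i, j, k)]
      }
    }
  }
  as_df <- function(x, cols) {
    if (!length(x)) {
      return(as.data.frame(setNames(rep(list(character()), length(cols)), cols),
                           stringsAsFactors = FALSE))
    }
    setNames(as.data.frame(do.call(rbind, x), stringsAsFactors = FALSE), cols)
  }
  structure(list(reciprocal_pairs = as_df(pairs, c("a", "b")),
                 triads = as_df(triads, c("a", "b", "c")),
                 fully_reciprocal_triads = as_df(full, c("a", "b", "c"))),
            class = "fcm_motifs")
}

#' @export
print.fcm_motifs <- function(x, ...) {
  cat("Motif census:\n")
  cat("  reciprocal pairs:        ", nrow(x$reciprocal_pairs), "\n")
  cat("  directed 3-cycles:       ", nrow(x$triads), "\n")
  cat("  fully reciprocal triads: ", nrow(x$fully_reciprocal_triads), "\n")
  for (i in seq_len(nrow(x$fully_reciprocal_triads))) {
    cat("    {", paste(unlist(x$fully_reciprocal_triads[i, ]),
                       collapse = ", "), "}\n")
  }
  invisible(x)
}

#' Enumerate directed influence paths between two factors
#'
#' Lists all simple directed paths from `source` to `target` up to
#' `max_len` edges. Each path is scored by the product of its edge weights
#' rescaled to \[0, 1\] (weight / 10), a conventional measure of indirect
#' influence strength; paths are returned strongest first.
#'
#' @inheritParams degree_table
#' @param source,target factor ids (must differ).
#' @param max_len maximum number of edges in a path (>= 1).
#' @return Data frame with columns `path` (factors joined by " -> "),
#'   `length` and `strength`, sorted by strength descending.
#' @export
influence_paths <- function(model, source, target, max_len = 3,
                            display_only = TRUE) {
  stopifnot(inherits(model, "fcm"))
  ids <- model$nodes$id
  for (f in c(source, target)) {
    if (!f %in% ids) stop("unknown factor: ", f)
  }
  if (source == target) stop("`source` and `target` must differ")
  if (max_len < 1) stop("`max_len` must be at least 1")

  W <- abs(coef(model, display_only = display_only)) / 10
  paths <- list()
  walk <- function(node, visited, strength) {
    if (length(visited) - 1L > max_len) return()
    nxt <- ids[W[node, ] > 0]
    for (v in nxt) {
      s <- strength * W[node, v]
      if (v == target) {
        if (length(visited) <= max_len) {
          paths[[length(paths) + 1L]] <<- list(path = c(visited, v), strength = s)
        }
      } else if (!v %in% visited && length(visited) < max_len) {
        walk(v, c(visited, v), s)
      }
    }
  }
  walk(source, source, 1)

  if (!length(paths)) {
    return(data.frame(path = character(), length = integer(),
                      strength = numeric(), stringsAsFactors = FALSE))
  }
  out <- data.frame(
    path = vapply(paths, function(p) paste(p$path, collapse = " -> "), ""),
    length = vapply(paths, function(p) length(p$path) - 1L, 0L),
    strength = vapply(paths, function(p) p$strength, 0),
    stringsAsFactors = FALSE)
  out <- out[order(-out$strength, out$path), ]
  rownames(out) <- NULL
  out
}

#' Summarise a cognitive map
#'
#' Combines the degree table, the motif census and the category legend in
#' one object.
#'
#' @param object an `fcm` model.
#' @param display_only see [degree_table()].
#' @param ... unused.
#' @export
summary.fcm <- function(object, display_only = TRUE, ...) {
  structure(list(degree = degree_table(object, display_only = display_only),
                 motifs = motif_census(object, display_only = display_only),
                 n_nodes = nrow(object$nodes),
                 n_edges = nrow(object$edges),
                 n_display = sum(object$edges$display),
                 config = object$config),
            class = "summary.fcm")
}

#' @export
print.summary.fcm <- function(x, ...) {
  cat("Consensus system model: ", x$n_nodes, " factors, ", x$n_edges,
      " edges (", x$n_display, " at display threshold)\n\n", sep = "")
  tab <- x$degree
  tab$impact <- ifelse(is.na(tab$impact), "  .", sprintf("%.2f", tab$impact))
  tab$indegree_weight_pct <- round(tab$indegree_weight_pct)
  tab$outdegree_weight_pct <- round(tab$outdegree_weight_pct)
  names(tab) <- c("factor", "name", "impact", "in", "in_w%", "out", "out_w%")
  print(tab[, c("name", "impact", "in", "in_w%", "out", "out_w%")],
        row.names = FALSE)
  cat("\n")
  print(x$motifs)
  cat("\nInfluence categories: medium [5.0, 6.0), strong [6.0, 7.0),",
      "powerful [7.0, 10]\n")
  invisible(x)
}
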