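#' Construct a weighted directed system model
#'
#' An `fcm` object is a fuzzy cognitive map: a set of named factors (nodes),
#' each optionally carrying an impact-on-outcome score on the 0-1 scale, and
#' signed weighted directed edges on the 0-10 rating scale. Self-loops are
#' rejected; retained edges must have positive weight.
#'
#' @param nodes data frame with columns `id` (unique, non-empty), `name`
#'   (display name; defaults to `id`) and optionally `impact` in \[0, 1\]
#'   (NA allowed when impacts were not elicited).
#' @param edges data frame with columns `source`, `target` (factor ids),
#'   `weight` in (0, 10\], and optionally `sign` (+1 or -1, default +1) and
#'   `display` (logical; whether the edge meets the display threshold,
#'   default TRUE).
#' @param config optional list recording how the model was built (consensus
#'   thresholds, panel summary); stored as provenance.
#'
#' @return An object of class `fcm`: a list with elements `nodes`, `edges`
#'   (sorted lexicographically by source then target) and `config`.
#' @seealso [fcm_consensus()] to fit a model from an expert panel,
#'   [degree_table()], [motif_census()], [run_scenario()].
#' @export
#' @examples
#' m <- fcm_model(
#'   nodes = data.frame(id = c("a", "b"), impact = c(0.7, 0.5)),
#'   edges = data.frame(source = "a", target = "b", weight = 6)
#' )
#' m
fcm_model <- function(nodes, edges = NULL, config = list()) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (!"id" %in% names(nodes)) stop("`nodes` must have an `id` column")
  nodes$id <- as.character(nodes$id)
  if (any(!nzchar(nodes$id))) stop("node ids must be non-empty")
  if (anyDuplicated(nodes$id)) {
    stop("duplicate node ids: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  }
  if (is.null(nodes$name)) nodes$name <- nodes$id
  if (is.null(nodes$impact)) nodes$impact <- NA_real_
  nodes$impact <- as.numeric(nodes$impact)
  bad <- !is.na(nodes$impact) & (nodes$impact < 0 | nodes$impact > 1)
  if (any(bad)) {
    stop("impact scores must lie in [0, 1]; offending factor(s): ",
         paste(nodes$id[bad], collapse = ", "))
  }
  nodes <- nodes[order(nodes$id), c("id", "name", "impact")]
  rownames(nodes) <- NULL

  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- data.frame(source = character(), target = character(),
                        weight = numeric(), sign = numeric(),
                        display = logical(), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    need <- c("source", "target", "weight")
    if (!all(need %in% names(edges))) {
      stop("`edges` must have columns source, target, weight")
    }
    edges$source <- as.character(edges$source)
    edges$target <- as.character(edges$target)
    edges$weight <- as.numeric(edges$weight)
    if (is.null(edges$sign)) edges$sign <- 1
    if (is.null(edges$display)) edges$display <- TRUE
    unknown <- setdiff(c(edges$source, edges$target), nodes$id)
    if (length(unknown)) {
      stop("edge endpoint(s) not in node set: ",
           paste(unique(unknown), collapse = ", "))
    }
    if (any(edges$source == edges$target)) stop("self-loops are not allowed")
    if (any(edges$weight <= 0 | edges$weight > 10)) {
      stop("edge weights must lie in (0, 10]")
    }
    if (!all(edges$sign %in% c(-1, 1))) stop("edge signs must be +1 or -1")
    key <- paste(edges$source, edges$target)
    if (anyDuplicated(key)) {
      stop("duplicate edge(s): ", paste(unique(key[duplicated(key)]), collapse = "; "))
    }
    edges <- edges[order(edges$source, edges$target),
                   c("source", "target", "weight", "sign", "display")]
    rownames(edges) <- NULL
  }

  structure(list(nodes = nodes, edges = edges, config = config),
            class = "fcm")
}

#' @export
print.fcm <- function(x, ...) {
  n_disp <- sum(x$edges$display)
  cat("Fuzzy cognitive map: ", nrow(x$nodes), " factors, ",
      nrow(x$edges), " edges (", n_disp, " at display threshold)\n", sep = "")
  if (any(!is.na(x$nodes$impact))) {
    top <- x$nodes[order(-x$nodes$impact, x$nodes$id), ]
    top <- top[!is.na(top$impact), , drop = FALSE]
    cat("Impact on outcome (0-1 scale), highest first:\n")
    shown <- head(top, 5L)
    for (i in seq_len(nrow(shown))) {
      cat(sprintf("  %-28s %.2f (%s)\n", shown$name[i], shown$impact[i],
                  as.character(categorize_impact(shown$impact[i]))))
    }
    if (nrow(top) > 5L) cat("  ... and", nrow(top) - 5L, "more\n")
  }
  invisible(x)
}

#' Extract the signed weight matrix of a cognitive map
#'
#' @param object an [fcm_model()] object.
#' @param display_only if TRUE, only edges meeting the display threshold
#'   enter the matrix.
#' @param ... unused.
#' @return A square numeric matrix W with `W[source, target]` equal to
#'   sign x weight on the 0-10 rating scale (0 where no edge).
#' @export
coef.fcm <- function(object, display_only = FALSE, ...) {
  ids <- object$nodes$id
  W <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  e <- object$edges
  if (display_only) e <- e[e$display, , drop = FALSE]
  if (nrow(e)) W[cbind(e$source, e$target)] <- e$sign * e$weight
  W
}

#' Plot a cognitive map
#'
#' Draws the model as a directed graph. Edge colour encodes the influence
#' category (medium / strong / powerful in increasingly dark green; negative
#' edges in red), node colour the impact category in blues; edges below the
#' display threshold are dashed grey.
#'
#' @param x an `fcm` object.
#' @param display_only drop edges below the display threshold entirely
#'   instead of dashing them.
#' @param ... passed to [igraph::plot.igraph()].
#' @export
plot.fcm <- function(x, display_only = FALSE, ...) {
  e <- x$edges
  if (display_only) e <- e[e$display, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    e[, c("source", "target")], directed = TRUE,
    vertices = x$nodes[, "id", drop = FALSE])
  pos_col <- c(below = "grey70", medium = "#a1d99b",
               strong = "#41ab5d", powerful = "#006d2c")
  neg_col <- c(below = "grey70", medium = "#fcae91",
               strong = "#fb6a4a", powerful = "#cb181d")
  cat <- as.character(categorize_weight(e$weight))
  ecol <- ifelse(e$sign >= 0, pos_col[cat], neg_col[cat])
  ecol[!e$display] <- "grey80"
  node_col <- rep("grey90", nrow(x$nodes))
  has_imp <- !is.na(x$nodes$impact)
  imp_col <- c(below = "grey90", medium = "#c6dbef",
               strong = "#6baed6", powerful = "#2171b5")
  node_col[has_imp] <-
    imp_col[as.character(categorize_impact(x$nodes$impact[has_imp]))]
  igraph::plot.igraph(
    g,
    vertex.label = x$nodes$name,
    vertex.color = node_col,
    edge.color = ecol,
    edge.lty = ifelse(e$display, 1, 2),
    edge.width = 1 + e$weight / 4,
    edge.arrow.size = 0.4,
    ...)
  invisible(x)
}

# Internal: ordered pairs of a factor set, lexicographic, no self-pairs.
all_ordered_pairs <- function(ids) {
  ids <- sort(ids)
  g <- expand.grid(target = ids, source = ids,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[g$source != g$target, c("source", "target")]
  g <- g[order(g$source, g$target), ]
  rownames(g) <- NULL
  g
}
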