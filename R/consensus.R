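#' Consensus weight of a single rated influence
#'
#' The elicitation protocol retains a directed influence only when a quorum
#' of the expert group sees it at all and the group's average rating clears
#' a threshold: at least `ceiling(quorum_fraction * n_experts)` experts must
#' rate the pair strictly above 0, and the mean rating must be strictly
#' greater than `mean_threshold`. With six experts and the default 2/3
#' quorum this is the "at least four persons above zero, average above 5.0"
#' rule. The retained weight is the mean itself, so edge weights stay on the
#' 0-10 rating scale.
#'
#' @param ratings numeric vector of one rating per expert in \[0, 10\]
#'   (zeros for experts who saw no influence).
#' @param n_experts size of the group; defaults to `length(ratings)`.
#' @param quorum_fraction fraction of the group that must rate above zero
#'   (default 2/3).
#' @param mean_threshold the mean rating must strictly exceed this value
#'   (default 5).
#' @param mean_over `"all_experts"` (default) averages over the whole group
#'   including zero raters, reading the protocol's group average literally;
#'   `"raters_only"` averages over the experts who rated above zero, which
#'   estimates the influence strength without attenuation when some experts
#'   simply failed to consider the pair.
#' @return The consensus weight (a mean in (`mean_threshold`, 10\]) or
#'   `NA_real_` when the pair does not reach consensus.
#' @export
#' @examples
#' consensus_weight(c(8, 7, 6, 6, 5, 0))   # 32/6 = 5.33, retained
#' consensus_weight(c(6, 6, 6, 6, 0, 0))   # quorum met but mean 4 <= 5: NA
consensus_weight <- function(ratings, n_experts = length(ratings),
                             quorum_fraction = 2 / 3, mean_threshold = 5,
                             mean_over = c("all_experts", "raters_only")) {
  mean_over <- match.arg(mean_over)
  ratings <- as.numeric(ratings)
  if (length(ratings) != n_experts) {
    stop("`ratings` must have one entry per expert (zeros for non-raters)")
  }
  check_rating_range(ratings, "influence")
  n_raters <- sum(ratings > 0)
  if (n_raters < ceiling(quorum_fraction * n_experts)) return(NA_real_)
  m <- if (mean_over == "all_experts") mean(ratings) else
    sum(ratings) / n_raters
  if (m > mean_threshold) m else NA_real_
}

#' Fit a consensus system model from an expert panel
#'
#' Aggregates per-expert 0-10 influence ratings into a single weighted
#' directed cognitive map. Every ordered factor pair is passed through the
#' quorum-and-mean rule of [consensus_weight()]; pairs that reach consensus
#' become edges weighted by the group mean. Node impact scores are the
#' plain mean of the impact ratings divided by 10, giving the conventional
#' 0-1 impact scale. Edges whose weight falls below `display_threshold`
#' are retained but flagged `display = FALSE` — published final models
#' typically draw only edges at 5.0 or higher, while the weaker consensus
#' relations remain part of the model.
#'
#' @param panel an [fcm_panel()].
#' @param quorum_fraction,mean_threshold,mean_over see [consensus_weight()].
#' @param display_threshold weight at or above which an edge is flagged for
#'   display (default 5).
#' @return An [fcm_model()] object; `$config` records the thresholds and
#'   panel size.
#' @export
#' @examples
#' ratings <- expand.grid(expert_id = paste0("e", 1:6),
#'                        source = "a", target = "b")
#' ratings$rating <- c(8, 7, 6, 6, 5, 0)
#' m <- fcm_consensus(fcm_panel(ratings))
#' m$edges
fcm_consensus <- function(panel, quorum_fraction = 2 / 3,
                          mean_threshold = 5, display_threshold = 5,
                          mean_over = c("all_experts", "raters_only")) {
  if (!inherits(panel, "fcm_panel")) stop("`panel` must be an fcm_panel")
  mean_over <- match.arg(mean_over)
  if (quorum_fraction <= 0 || quorum_fraction > 1) {
    stop("quorum_fraction must lie in (0, 1]")
  }
  if (mean_threshold < 0 || mean_threshold > 10 ||
      display_threshold < 0 || display_threshold > 10) {
    stop("thresholds must lie in [0, 10]")
  }

  rm_ <- panel_rating_matrix(panel)
  n_experts <- length(panel$experts)
  w <- apply(rm_$ratings, 2, consensus_weight, n_experts = n_experts,
             quorum_fraction = quorum_fraction,
             mean_threshold = mean_threshold, mean_over = mean_over)
  keep <- which(!is.na(w))
  edges <- NULL
  if (length(keep)) {
    edges <- cbind(rm_$pairs[keep, , drop = FALSE],
                   weight = w[keep], sign = 1)
    edges$display <- edges$weight >= display_threshold
  }

  nodes <- panel$factors
  nodes$impact <- NA_real_
  if (!is.null(panel$impact)) {
    # plain mean over the ratings given; /10 puts impact on the 0-1 scale
    agg <- tapply(panel$impact$rating, panel$impact$factor, mean)
    nodes$impact[match(names(agg), nodes$id)] <- as.numeric(agg) / 10
  }

  fcm_model(nodes, edges,
            config = list(quorum_fraction = quorum_fraction,
                          mean_threshold = mean_threshold,
                          display_threshold = display_threshold,
                          mean_over = mean_over,
                          n_experts = n_experts))
}

#' Categorize influence weights and impact scores
#'
#' Weights on the 0-10 rating scale fall into the standard reporting bins:
#' below 5.0 (`below`), 5.0-5.9 (`medium`), 6.0-6.9 (`strong`) and 7.0 and
#' above (`powerful`). Bins are closed on the left, so the categories
#' partition \[0, 10\] and 7.0 is `powerful`. The same bins apply to
#' impact scores after rescaling by 10 ([categorize_impact()]).
#'
#' @param weight numeric vector in \[0, 10\].
#' @return An ordered factor with levels below < medium < strong < powerful.
#' @export
#' @examples
#' categorize_weight(c(4.9, 5.5, 6.9, 7.0))
categorize_weight <- function(weight) {
  if (any(!is.na(weight) & (weight < 0 | weight > 10))) {
    stop("weights must lie in [0, 10]")
  }
  cut(weight, breaks = c(0, 5, 6, 7, 10),
      labels = c("below", "medium", "strong", "powerful"),
      right = FALSE, include.lowest = TRUE, ordered_result = TRUE)
}

#' @param impact numeric vector in \[0, 1\] (node impact scale).
#' @rdname categorize_weight
#' @export
categorize_impact <- function(impact) {
  if (any(!is.na(impact) & (impact < 0 | impact > 1))) {
    stop("impact scores must lie in [0, 1]")
  }
  categorize_weight(impact * 10)
}
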