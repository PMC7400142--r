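#' Assemble an expert rating panel
#'
#' A panel holds every expert's influence ratings (ordered factor pairs on
#' the 0-10 scale, 0 = no influence, 10 = most substantial influence) and,
#' optionally, their impact-on-outcome ratings per factor on the same scale.
#' Pairs an expert did not rate are treated as 0 throughout.
#'
#' @param influence data frame in long format with columns `expert_id`,
#'   `source`, `target`, `rating`. Self-pairs and ratings outside \[0, 10\]
#'   are rejected.
#' @param impact optional data frame with columns `expert_id`, `factor`,
#'   `rating` (0-10 impact of the factor on the modeled outcome).
#' @param factors optional data frame with columns `id` and optionally
#'   `name` fixing the shared factor set; defaults to the union of factors
#'   seen in `influence` and `impact`.
#' @return An object of class `fcm_panel` with elements `factors`,
#'   `influence`, `impact`, `experts` (sorted ids).
#' @seealso [fcm_consensus()], [read_panel()], [simulate_panel()].
#' @export
fcm_panel <- function(influence, impact = NULL, factors = NULL) {
  influence <- as.data.frame(influence, stringsAsFactors = FALSE)
  need <- c("expert_id", "source", "target", "rating")
  if (!all(need %in% names(influence))) {
    stop("`influence` must have columns ", paste(need, collapse = ", "))
  }
  influence$expert_id <- as.character(influence$expert_id)
  influence$source <- as.character(influence$source)
  influence$target <- as.character(influence$target)
  influence$rating <- as.numeric(influence$rating)

  experts <- sort(unique(influence$expert_id))
  if (length(experts) == 0L) stop("no experts found")
  check_rating_range(influence$rating, "influence")
  loops <- influence$source == influence$target
  if (any(loops)) {
    stop("self-rating not allowed (factor cannot influence itself): row ",
         paste(which(loops), collapse = ", "))
  }
  key <- paste(influence$expert_id, influence$source, influence$target)
  if (anyDuplicated(key)) {
    stop("duplicate rating for the same expert and pair: row ",
         paste(which(duplicated(key)), collapse = ", "))
  }

  if (!is.null(impact)) {
    impact <- as.data.frame(impact, stringsAsFactors = FALSE)
    if (!all(c("expert_id", "factor", "rating") %in% names(impact))) {
      stop("`impact` must have columns expert_id, factor, rating")
    }
    impact$expert_id <- as.character(impact$expert_id)
    impact$factor <- as.character(impact$factor)
    impact$rating <- as.numeric(impact$rating)
    check_rating_range(impact$rating, "impact")
    ikey <- paste(impact$expert_id, impact$factor)
    if (anyDuplicated(ikey)) {
      stop("duplicate impact rating for the same expert and factor: row ",
           paste(which(duplicated(ikey)), collapse = ", "))
    }
    experts <- sort(unique(c(experts, impact$expert_id)))
  }

  seen <- unique(c(influence$source, influence$target,
                   if (!is.null(impact)) impact$factor))
  if (is.null(factors)) {
    factors <- data.frame(id = sort(seen), stringsAsFactors = FALSE)
  } else {
    factors <- as.data.frame(factors, stringsAsFactors = FALSE)
    if (!"id" %in% names(factors)) stop("`factors` must have an `id` column")
    factors$id <- as.character(factors$id)
    unknown <- setdiff(seen, factors$id)
    if (length(unknown)) {
      stop("rating(s) reference factor(s) outside the shared set: ",
           paste(unknown, collapse = ", "))
    }
    factors <- factors[order(factors$id), , drop = FALSE]
  }
  if (is.null(factors$name)) factors$name <- factors$id
  rownames(factors) <- NULL
  if (nrow(factors) < 2L) stop("a panel needs at least two factors")

  structure(list(factors = factors[, c("id", "name")],
                 influence = influence, impact = impact,
                 experts = experts),
            class = "fcm_panel")
}

check_rating_range <- function(r, what) {
  bad <- which(is.na(r) | r < 0 | r > 10)
  if (length(bad)) {
    stop(sprintf("%s rating(s) outside [0, 10] at row %s", what,
                 paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}

#' @export
print.fcm_panel <- function(x, ...) {
  cat("Expert panel: ", length(x$experts), " experts, ",
      nrow(x$factors), " factors, ", nrow(x$influence),
      " influence ratings", sep = "")
  if (!is.null(x$impact)) cat(", ", nrow(x$impact), " impact ratings", sep = "")
  cat("\n")
  invisible(x)
}

# Internal: n_experts x n_pairs rating matrix (zeros for unrated pairs),
# pairs in lexicographic (source, target) order.
panel_rating_matrix <- function(panel) {
  pairs <- all_ordered_pairs(panel$factors$id)
  m <- matrix(0, nrow = length(panel$experts), ncol = nrow(pairs),
              dimnames = list(panel$experts,
                              paste(pairs$source, pairs$target, sep = "->")))
  inf <- panel$influence
  idx <- cbind(match(inf$expert_id, panel$experts),
               match(paste(inf$source, inf$target, sep = "->"), colnames(m)))
  m[idx] <- inf$rating
  list(pairs = pairs, ratings = m)
}
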