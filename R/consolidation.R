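#' Define a factor-consolidation action
#'
#' Workshop participants elicit raw risk factors on moderation cards; a
#' consolidation round turns those raw labels into the main-factor set of
#' the final system model. Each action covers one or more raw labels from
#' one source panel and either keeps, merges, splits or excludes them:
#'
#' * `keep`: one raw label, one main target.
#' * `merge`: two or more raw labels collapsed into one main target.
#' * `split`: one raw label divided into two or more main targets.
#' * `exclude`: raw label(s) dropped from the model, no targets.
#'
#' @param raw_labels character vector of raw factor labels covered by this
#'   action.
#' @param action one of `"keep"`, `"merge"`, `"split"`, `"exclude"`.
#' @param main_targets character vector of main-factor display names the
#'   raw labels map to (empty for `exclude`).
#' @param source_panel which workshop panel the raw labels come from
#'   (`"scientists"` or `"practitioners"`).
#' @param rationale free-text justification, kept for provenance.
#' @return A `consolidation_action` object.
#' @export
consolidation_action <- function(raw_labels, action,
                                 main_targets = character(),
                                 source_panel = c("scientists", "practitioners"),
                                 rationale = "") {
  action <- match.arg(action, c("keep", "merge", "split", "exclude"))
  source_panel <- match.arg(source_panel)
  raw_labels <- as.character(raw_labels)
  main_targets <- as.character(main_targets)
  if (length(raw_labels) == 0L || any(!nzchar(trimws(raw_labels)))) {
    stop("raw_labels must be non-empty")
  }
  n_t <- length(main_targets)
  ok <- switch(action,
    exclude = n_t == 0L,
    keep = n_t == 1L && length(raw_labels) == 1L,
    merge = n_t == 1L && length(raw_labels) >= 2L,
    split = n_t >= 2L && length(raw_labels) == 1L)
  if (!ok) {
    stop(sprintf(
      "malformed %s action on [%s]: %d raw label(s), %d target(s)",
      action, paste(raw_labels, collapse = ", "), length(raw_labels), n_t))
  }
  if (anyDuplicated(normalize_label(main_targets))) {
    stop("split targets must be distinct")
  }
  structure(list(raw_labels = raw_labels, action = action,
                 main_targets = main_targets, source_panel = source_panel,
                 rationale = rationale),
            class = "consolidation_action")
}

#' @export
print.consolidation_action <- function(x, ...) {
  rhs <- if (x$action == "exclude") "(excluded)" else
    paste(x$main_targets, collapse = " + ")
  cat(sprintf("[%s/%s] %s -> %s\n", x$source_panel, x$action,
              paste(x$raw_labels, collapse = " + "), rhs))
  invisible(x)
}

#' Consolidate raw workshop factors into the main-factor set
#'
#' Applies keep/merge/split/exclude actions to the raw factor lists of the
#' source panels and returns the de-duplicated main-factor set. Raw labels
#' are matched case-insensitively after trimming and collapsing whitespace
#' (moderation-card handwriting is not orthographically stable). Actions
#' from different panels that name the same main target are unified into a
#' single main factor, which is how factors named independently by both
#' panels (e.g. housing) end up as one node.
#'
#' @param raw_factors data frame with columns `label` and `source_panel`
#'   (`"scientists"` / `"practitioners"`); one row per raw workshop factor.
#' @param mapping a list of [consolidation_action()] objects covering every
#'   raw factor exactly once.
#' @param main_factors optional data frame (`id`, `name`) assigning stable
#'   short ids to the main-factor names; defaults to the declaration
#'   attached by [read_mapping()], with slugified names as fallback ids.
#' @return Data frame of main factors with columns `id`, `name`.
#' @export
#' @examples
#' raw <- data.frame(label = c("Friends", "Contacts", "Housing"),
#'                   source_panel = "scientists")
#' acts <- list(
#'   consolidation_action(c("Friends", "Contacts"), "merge", "Social contacts"),
#'   consolidation_action("Housing", "keep", "Housing")
#' )
#' apply_consolidation(raw, acts)
apply_consolidation <- function(raw_factors, mapping,
                                main_factors = attr(mapping, "main_factors")) {
  rep <- validate_mapping(raw_factors, mapping)
  if (length(rep$uncovered)) {
    stop("raw factor(s) not covered by any action: ",
         paste(rep$uncovered, collapse = ", "))
  }
  if (length(rep$multiply_covered)) {
    stop("raw factor(s) covered by more than one action: ",
         paste(rep$multiply_covered, collapse = ", "))
  }
  if (length(rep$malformed)) {
    stop("malformed action(s): ", paste(rep$malformed, collapse = "; "))
  }
  targets <- unlist(lapply(mapping, function(a) {
    if (a$action == "exclude") character() else a$main_targets
  }))
  if (!length(targets)) {
    return(data.frame(id = character(), name = character(),
                      stringsAsFactors = FALSE))
  }
  keep <- !duplicated(normalize_label(targets))
  nm <- targets[keep]
  ids <- slugify(nm)
  if (!is.null(main_factors)) {
    main_factors <- as.data.frame(main_factors, stringsAsFactors = FALSE)
    hit <- match(normalize_label(nm), normalize_label(main_factors$name))
    ids[!is.na(hit)] <- main_factors$id[hit[!is.na(hit)]]
  }
  out <- data.frame(id = ids, name = nm, stringsAsFactors = FALSE)
  out <- out[order(out$id), ]
  rownames(out) <- NULL
  out
}

#' Validate a consolidation mapping against the raw factor lists
#'
#' Report-returning companion to [apply_consolidation()]: an empty report
#' means the mapping is valid.
#'
#' @inheritParams apply_consolidation
#' @param declared_main optional character vector of main-factor names the
#'   mapping is expected to produce; names never targeted by any action are
#'   reported as unreachable.
#' @return A `consolidation_report`: list with character vectors
#'   `uncovered`, `multiply_covered`, `malformed`, `unreachable`. Use
#'   `length(unlist(report)) == 0` (or print it) to check validity.
#' @export
validate_mapping <- function(raw_factors, mapping, declared_main = NULL) {
  raw_factors <- as.data.frame(raw_factors, stringsAsFactors = FALSE)
  if (nrow(raw_factors) && !all(c("label", "source_panel") %in% names(raw_factors))) {
    stop("`raw_factors` must have columns label, source_panel")
  }
  raw_key <- if (nrow(raw_factors)) {
    paste(raw_factors$source_panel, normalize_label(raw_factors$label), sep = "\r")
  } else character()
  if (anyDuplicated(raw_key)) {
    stop("duplicate raw factor(s) within a panel: ",
         paste(raw_factors$label[duplicated(raw_key)], collapse = ", "))
  }

  malformed <- character()
  cov_keys <- character()
  for (i in seq_along(mapping)) {
    a <- mapping[[i]]
    if (!inherits(a, "consolidation_action")) {
      # re-validate plain lists (e.g. straight from a mapping file)
      a <- tryCatch(
        consolidation_action(a$raw_labels, a$action,
                             a$main_targets %||% character(),
                             a$source_panel, a$rationale %||% ""),
        error = function(e) e)
      if (inherits(a, "error")) {
        malformed <- c(malformed, conditionMessage(a))
        next
      }
    }
    cov_keys <- c(cov_keys,
                  paste(a$source_panel, normalize_label(a$raw_labels), sep = "\r"))
  }

  tab <- table(cov_keys)
  pretty <- function(keys) {
    if (!length(keys)) return(character())
    vapply(strsplit(as.character(keys), "\r", fixed = TRUE),
           function(p) sprintf("%s (%s)", p[2], p[1]), character(1))
  }
  uncovered <- pretty(setdiff(raw_key, cov_keys))
  multiply <- pretty(names(tab)[tab > 1L])
  unknown <- pretty(setdiff(cov_keys, raw_key))
  if (length(unknown)) {
    malformed <- c(malformed,
                   paste0("action covers unknown raw factor: ", unknown))
  }

  unreachable <- character()
  if (!is.null(declared_main)) {
    if (is.data.frame(declared_main)) declared_main <- declared_main$name
    targeted <- normalize_label(unlist(lapply(mapping, function(a)
      if (identical(a$action, "exclude")) character() else a$main_targets)))
    unreachable <- declared_main[!normalize_label(declared_main) %in% targeted]
  }

  structure(list(uncovered = uncovered, multiply_covered = multiply,
                 malformed = malformed, unreachable = unreachable),
            class = "consolidation_report")
}

#' @export
print.consolidation_report <- function(x, ...) {
  if (!length(unlist(x))) {
    cat("Consolidation mapping is valid.\n")
    return(invisible(x))
  }
  for (f in names(x)) {
    if (length(x[[f]])) {
      cat(gsub("_", " ", f), ":\n", sep = "")
      cat(paste0("  - ", x[[f]], "\n"), sep = "")
    }
  }
  invisible(x)
}
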