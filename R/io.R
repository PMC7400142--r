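#' Read an expert rating panel from delimited text
#'
#' Influence ratings come as long-format CSV with header
#' `expert_id,source,target,rating`; impact ratings as
#' `expert_id,factor,impact_rating` (a plain `rating` column is also
#' accepted). Validation is strict: ratings outside \[0, 10\], self-pairs
#' and duplicate ratings raise errors naming the offending row.
#'
#' @param influence_path path to the influence-rating CSV.
#' @param impact_path optional path to the impact-rating CSV.
#' @param factors optional data frame (`id`, `name`) fixing the shared
#'   factor set.
#' @return An [fcm_panel()].
#' @export
read_panel <- function(influence_path, impact_path = NULL, factors = NULL) {
  influence <- read.csv(influence_path, stringsAsFactors = FALSE)
  impact <- NULL
  if (!is.null(impact_path)) {
    impact <- read.csv(impact_path, stringsAsFactors = FALSE)
    if (!is.null(impact$impact_rating) && is.null(impact$rating)) {
      names(impact)[names(impact) == "impact_rating"] <- "rating"
    }
  }
  if (nrow(influence) == 0L) stop("no experts found in ", influence_path)
  fcm_panel(influence, impact = impact, factors = factors)
}

#' Read a factor-consolidation mapping from YAML
#'
#' The file holds an `actions` list (fields `raw_labels`, `source_panel`,
#' `action`, `main_targets`, `rationale`) and optionally a `main_factors`
#' list declaring the expected main-factor set, attached to the result as
#' attribute `main_factors`.
#'
#' @param path path to the YAML mapping file.
#' @return List of [consolidation_action()] objects.
#' @export
read_mapping <- function(path) {
  doc <- yaml::read_yaml(path)
  acts <- doc$actions %||% doc
  mapping <- lapply(seq_along(acts), function(i) {
    a <- acts[[i]]
    tryCatch(
      consolidation_action(a$raw_labels, a$action,
                           a$main_targets %||% character(),
                           a$source_panel, a$rationale %||% ""),
      error = function(e) {
        stop("invalid action ", i, " in ", path, ": ", conditionMessage(e),
             call. = FALSE)
      })
  })
  if (!is.null(doc$main_factors)) {
    nm <- vapply(doc$main_factors, function(m) m$name %||% m, character(1))
    id <- vapply(doc$main_factors, function(m) m$id %||% slugify(m$name %||% m),
                 character(1))
    attr(mapping, "main_factors") <- data.frame(id = id, name = nm,
                                                stringsAsFactors = FALSE)
  }
  mapping
}

#' Read a signed qualitative workshop model
#'
#' Workshop groups draw signed relations in one of two dialects: symbolic
#' strengths (`+`, `++`, `+++`, `-`, `--`, `---`; light / medium / strong)
#' or numeric strengths in \[-1, 1\]. A file must use one dialect
#' throughout. Symbolic strengths are mapped to numeric display values at
#' 0.33 / 0.66 / 1.0 of scale (times the sign); these values are for
#' display only and never enter consensus aggregation.
#'
#' @param path CSV with header `source,target,strength`.
#' @return An `fcm_qualitative` list: `nodes` (data frame, column `id`),
#'   `edges` (columns `source`, `target`, `sign`, `strength_label`,
#'   `value`), `dialect` (`"symbolic"` or `"numeric"`).
#' @export
read_qualitative <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(strength = "character"))
  if (!all(c("source", "target", "strength") %in% names(df))) {
    stop("qualitative model must have columns source, target, strength")
  }
  if (any(df$source == df$target)) {
    stop("self-loop at row ", which(df$source == df$target)[1])
  }
  s <- trimws(df$strength)
  symbolic <- grepl("^\\++$|^−+$|^-+$", s)
  numeric_ok <- suppressWarnings(!is.na(as.numeric(s)))
  if (all(symbolic)) {
    n_sym <- nchar(s)
    if (any(n_sym > 3)) stop("symbolic strength longer than 3 at row ",
                             which(n_sym > 3)[1])
    label <- c("light", "medium", "strong")[n_sym]
    sign <- ifelse(substr(s, 1, 1) == "+", 1, -1)
    value <- sign * c(0.33, 0.66, 1.0)[n_sym]
    dialect <- "symbolic"
  } else if (all(numeric_ok)) {
    value <- as.numeric(s)
    if (any(value < -1 | value > 1)) {
      stop("numeric strength outside [-1, 1] at row ",
           which(value < -1 | value > 1)[1])
    }
    if (any(value == 0)) stop("zero strength at row ", which(value == 0)[1])
    sign <- ifelse(value >= 0, 1, -1)
    label <- c("light", "medium", "strong")[
      pmin(3L, findInterval(abs(value), c(0, 1 / 3, 2 / 3), left.open = TRUE))]
    dialect <- "numeric"
  } else {
    bad <- which(!symbolic & !numeric_ok)[1]
    stop("mixed or unparseable strength dialect (row ", bad,
         "): use all-symbolic (+/-) or all-numeric strengths")
  }
  nodes <- data.frame(id = sort(unique(c(df$source, df$target))),
                      stringsAsFactors = FALSE)
  edges <- data.frame(source = df$source, target = df$target, sign = sign,
                      strength_label = label, value = value,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, dialect = dialect),
            class = "fcm_qualitative")
}

#' Write a system model to GraphML or DOT
#'
#' Both formats carry the node attributes `name` and `impact` and the edge
#' attributes `weight`, `sign`, `category` and `display`; GraphML output
#' round-trips losslessly through [read_model()].
#'
#' @param model an [fcm_model()].
#' @param path output file path.
#' @param format `"graphml"` or `"dot"`; inferred from the file extension
#'   when omitted.
#' @return The path, invisibly.
#' @export
write_model <- function(model, path, format = c("auto", "graphml", "dot")) {
  stopifnot(inherits(model, "fcm"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     graphml = "graphml", xml = "graphml",
                     dot = "dot", gv = "dot",
                     stop("cannot infer format from extension of ", path))
  }
  if (format == "graphml") write_graphml(model, path) else write_dot(model, path)
  invisible(path)
}

num_str <- function(x) sprintf("%.15g", x)

write_graphml <- function(model, path) {
  doc <- xml2::xml_new_root("graphml",
                            xmlns = "http://graphml.graphdrawing.org/xmlns")
  keys <- list(
    c("k_name", "node", "name", "string"),
    c("k_impact", "node", "impact", "double"),
    c("k_weight", "edge", "weight", "double"),
    c("k_sign", "edge", "sign", "int"),
    c("k_category", "edge", "category", "string"),
    c("k_display", "edge", "display", "boolean"))
  for (k in keys) {
    xml2::xml_add_child(doc, "key", id = k[1], "for" = k[2],
                        attr.name = k[3], attr.type = k[4])
  }
  g <- xml2::xml_add_child(doc, "graph", id = "fcm", edgedefault = "directed")
  for (i in seq_len(nrow(model$nodes))) {
    nd <- xml2::xml_add_child(g, "node", id = model$nodes$id[i])
    xml2::xml_add_child(nd, "data", model$nodes$name[i], key = "k_name")
    if (!is.na(model$nodes$impact[i])) {
      xml2::xml_add_child(nd, "data", num_str(model$nodes$impact[i]),
                          key = "k_impact")
    }
  }
  e <- model$edges
  cat_ <- as.character(categorize_weight(e$weight))
  for (i in seq_len(nrow(e))) {
    ed <- xml2::xml_add_child(g, "edge", source = e$source[i],
                              target = e$target[i])
    xml2::xml_add_child(ed, "data", num_str(e$weight[i]), key = "k_weight")
    xml2::xml_add_child(ed, "data", as.character(as.integer(e$sign[i])),
                        key = "k_sign")
    xml2::xml_add_child(ed, "data", cat_[i], key = "k_category")
    xml2::xml_add_child(ed, "data", if (e$display[i]) "true" else "false",
                        key = "k_display")
  }
  xml2::write_xml(doc, path)
}

write_dot <- function(model, path) {
  esc <- function(x) gsub('"', '\\\\"', x)
  lines <- c("digraph fcm {", "  rankdir=LR;")
  for (i in seq_len(nrow(model$nodes))) {
    imp <- if (is.na(model$nodes$impact[i])) "" else
      sprintf(", impact=\"%s\"", num_str(model$nodes$impact[i]))
    lines <- c(lines, sprintf("  \"%s\" [label=\"%s\"%s];",
                              esc(model$nodes$id[i]),
                              esc(model$nodes$name[i]), imp))
  }
  e <- model$edges
  cat_ <- as.character(categorize_weight(e$weight))
  for (i in seq_len(nrow(e))) {
    lines <- c(lines, sprintf(
      "  \"%s\" -> \"%s\" [weight=\"%s\", sign=\"%d\", category=\"%s\", display=\"%s\"];",
      esc(e$source[i]), esc(e$target[i]), num_str(e$weight[i]),
      as.integer(e$sign[i]), cat_[i], if (e$display[i]) "true" else "false"))
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}

#' Read a system model written by [write_model()]
#'
#' @param path a GraphML or DOT file produced by this package.
#' @param format inferred from the extension when `"auto"`.
#' @return An [fcm_model()].
#' @export
read_model <- function(path, format = c("auto", "graphml", "dot")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     graphml = "graphml", xml = "graphml",
                     dot = "dot", gv = "dot",
                     stop("cannot infer format from extension of ", path))
  }
  if (format == "graphml") read_graphml(path) else read_dot(path)
}

read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  keys <- xml2::xml_find_all(doc, ".//key")
  key_name <- setNames(xml2::xml_attr(keys, "attr.name"),
                       xml2::xml_attr(keys, "id"))
  get_data <- function(el) {
    d <- xml2::xml_find_all(el, "./data")
    setNames(xml2::xml_text(d), key_name[xml2::xml_attr(d, "key")])
  }
  nodes_xml <- xml2::xml_find_all(doc, ".//node")
  nodes <- do.call(rbind, lapply(nodes_xml, function(nd) {
    d <- get_data(nd)
    data.frame(id = xml2::xml_attr(nd, "id"),
               name = unname(d["name"]),
               impact = as.numeric(d["impact"] %|na|% NA),
               stringsAsFactors = FALSE)
  }))
  edges_xml <- xml2::xml_find_all(doc, ".//edge")
  edges <- if (length(edges_xml)) {
    do.call(rbind, lapply(edges_xml, function(ed) {
      d <- get_data(ed)
      data.frame(source = xml2::xml_attr(ed, "source"),
                 target = xml2::xml_attr(ed, "target"),
                 weight = as.numeric(d["weight"]),
                 sign = as.numeric(d["sign"]),
                 display = identical(unname(d["display"]), "true"),
                 stringsAsFactors = FALSE)
    }))
  } else NULL
  fcm_model(nodes, edges)
}

`%|na|%` <- function(a, b) if (is.na(a)) b else a

read_dot <- function(path) {
  lines <- trimws(readLines(path))
  node_re <- '^"([^"]+)" \\[label="([^"]*)"(, impact="([^"]+)")?\\];$'
  edge_re <- paste0('^"(.+)" -> "(.+)" \\[weight="([^"]+)", sign="(-?\\d+)", ',
                    'category="[a-z]+", display="(true|false)"\\];$')
  nm <- regmatches(lines, regexec(node_re, lines))
  nodes <- do.call(rbind, lapply(nm[lengths(nm) > 0], function(m) {
    data.frame(id = m[2], name = m[3],
               impact = if (nzchar(m[5])) as.numeric(m[5]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  em <- regmatches(lines, regexec(edge_re, lines))
  em <- em[lengths(em) > 0]
  edges <- if (length(em)) {
    do.call(rbind, lapply(em, function(m) {
      data.frame(source = m[2], target = m[3], weight = as.numeric(m[4]),
                 sign = as.numeric(m[5]), display = m[6] == "true",
                 stringsAsFactors = FALSE)
    }))
  } else NULL
  if (is.null(nodes)) stop("no nodes found in ", path)
  fcm_model(nodes, edges)
}

#' Write the degree table as delimited text
#'
#' Columns follow the conventional reporting order: factor, name, impact,
#' absolute indegree, indegree weight percent, absolute outdegree,
#' outdegree weight percent. Percentages are written at full precision
#' unless `digits` is given (published tables round to integer percent).
#'
#' @param model an `fcm` model (or a data frame from [degree_table()]).
#' @param path output CSV path.
#' @param digits optional rounding for the percentage columns.
#' @param display_only see [degree_table()].
#' @return The path, invisibly.
#' @export
write_metrics <- function(model, path, digits = NULL, display_only = TRUE) {
  tab <- if (inherits(model, "fcm")) {
    degree_table(model, display_only = display_only)
  } else as.data.frame(model)
  if (!is.null(digits)) {
    tab$indegree_weight_pct <- round(tab$indegree_weight_pct, digits)
    tab$outdegree_weight_pct <- round(tab$outdegree_weight_pct, digits)
  }
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Path to a packaged example data file
#'
#' The package ships the published post-migration risk-factor study data
#' for unaccompanied minor refugees as plain-text fixtures:
#'
#' * `umr_workshop_factors.csv` — raw factors elicited by the scientist
#'   and practitioner panels.
#' * `umr_consolidation.yaml` — keep/merge/split/exclude actions turning
#'   the raw factors into the 11 main factors.
#' * `umr_final_model_impacts.csv` — main factors with their group-mean
#'   impact scores (0-1 scale).
#' * `umr_final_model_edges.csv` — the text-attested edges of the final
#'   system model with category-midpoint weights (see the vignette;
#'   numeric edge weights were not published).
#' * `umr_subthreshold_edges.csv` — relations reported to exist below the
#'   display threshold (no weights known).
#'
#' @param file file name; with no argument, lists the available files.
#' @return Full path to the file.
#' @export
#' @examples
#' fcm_example()
#' impacts <- read.csv(fcm_example("umr_final_model_impacts.csv"))
fcm_example <- function(file = NULL) {
  if (is.null(file)) {
    return(list.files(system.file("extdata", package = "fcmpanel")))
  }
  path <- system.file("extdata", file, package = "fcmpanel")
  if (!nzchar(path)) stop("no packaged file named ", file)
  path
}

#' Load the packaged final system model
#'
#' Builds the published final model of post-migration risk factors (11
#' factors, text-attested edges, impact scores) as an [fcm_model()].
#'
#' @return An `fcm` model.
#' @export
#' @examples
#' m <- umr_final_model()
#' summary(m)
umr_final_model <- function() {
  nodes <- read.csv(fcm_example("umr_final_model_impacts.csv"),
                    stringsAsFactors = FALSE)
  edges <- read.csv(fcm_example("umr_final_model_edges.csv"),
                    stringsAsFactors = FALSE)
  fcm_model(nodes[, c("id", "name", "impact")],
            edges[, c("source", "target", "weight")],
            config = list(source = "umr_final_model fixtures",
                          weights = "category midpoints, see vignette"))
}
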