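#' Write a decision instance as a JSON document
#'
#' Serializes the full instance — panel (with ranks), attribute catalogue,
#' alternatives and the complete preference structure — to a single JSON
#' file. Orderings are encoded as lists of tie-group lists, so ties and
#' missing attributes round-trip losslessly.
#'
#' @param instance An [opa_instance()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_opa_json()]
#' @export
write_opa_json <- function(instance, path) {
  stopifnot(inherits(instance, "opa_instance"))
  doc <- list(
    experts = instance$experts,
    attributes = instance$attributes,
    alternatives = instance$alternatives,
    attr_rankings = lapply(instance$attr_rank, tie_groups),
    alt_rankings = lapply(instance$alt_rank, function(per_attr)
      lapply(per_attr, tie_groups)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a decision instance from a JSON document
#'
#' @param path Path to a file written by [write_opa_json()] (or hand-written
#'   in the same schema).
#' @return A validated [opa_instance()]; validation findings raise an error.
#' @export
read_opa_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  as_df <- function(rows) {
    do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  }
  as_ordering <- function(groups) lapply(groups, function(g)
    unlist(g, use.names = FALSE))
  experts <- as_df(doc$experts)
  inst <- opa_instance(
    experts, as_df(doc$attributes), as_df(doc$alternatives),
    lapply(doc$attr_rankings, as_ordering),
    lapply(doc$alt_rankings, function(per_attr)
      lapply(per_attr, as_ordering)))
  findings <- validate_instance(inst)
  if (length(findings))
    stop("instance in '", path, "' is invalid: ",
         paste(findings, collapse = "; "))
  inst
}

#' Write a decision instance as a CSV trio
#'
#' Writes `experts.csv` (panel and ranks), `attr_ranks.csv` (expert by
#' attribute matrix of dense ranks, empty cells for unranked attributes) and
#' `alt_ranks.csv` (long format: expert, attribute, alternative, rank) into
#' a directory. Ties are encoded by equal integer ranks.
#'
#' @param instance An [opa_instance()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @seealso [read_opa_csv()]
#' @export
write_opa_csv <- function(instance, dir) {
  stopifnot(inherits(instance, "opa_instance"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- as.character(instance$experts$expert)
  attrs <- as.character(instance$attributes$attribute)
  paths <- c(experts = file.path(dir, "experts.csv"),
             attr_ranks = file.path(dir, "attr_ranks.csv"),
             alt_ranks = file.path(dir, "alt_ranks.csv"))
  utils::write.csv(instance$experts, paths["experts"], row.names = FALSE)

  mat <- data.frame(expert = ids, stringsAsFactors = FALSE)
  for (a in attrs)
    mat[[a]] <- vapply(ids, function(e) {
      r <- instance$attr_rank[[e]][a]
      if (is.na(r)) NA_integer_ else as.integer(r)
    }, 1L)
  utils::write.csv(mat, paths["attr_ranks"], row.names = FALSE, na = "")

  long <- list()
  for (e in ids) for (a in names(instance$attr_rank[[e]])) {
    arv <- instance$alt_rank[[e]][[a]]
    long[[length(long) + 1L]] <- data.frame(
      expert = e, attribute = a, alternative = names(arv),
      rank = as.integer(arv), stringsAsFactors = FALSE)
  }
  utils::write.csv(do.call(rbind, long), paths["alt_ranks"],
                   row.names = FALSE)
  invisible(paths)
}

#' Read a decision instance from a CSV trio
#'
#' @param experts_csv,attr_ranks_csv,alt_ranks_csv Paths to the three files
#'   in the [write_opa_csv()] layout.
#' @return A validated [opa_instance()]. Non-integer or negative ranks and
#'   expert ids that do not cross-reference between the files raise errors.
#' @export
read_opa_csv <- function(experts_csv, attr_ranks_csv, alt_ranks_csv) {
  experts <- utils::read.csv(experts_csv, stringsAsFactors = FALSE)
  amat <- utils::read.csv(attr_ranks_csv, stringsAsFactors = FALSE,
                          check.names = FALSE)
  along <- utils::read.csv(alt_ranks_csv, stringsAsFactors = FALSE)
  if (is.null(experts$expert)) stop(experts_csv, ": no 'expert' column")
  ids <- as.character(experts$expert)
  check_ranks <- function(x, where) {
    x <- x[!is.na(x)]
    if (!is.numeric(x) || any(x != round(x)) || any(x < 1))
      stop(where, ": ranks must be positive integers")
  }
  for (src in list(list(amat$expert, attr_ranks_csv),
                   list(along$expert, alt_ranks_csv))) {
    bad <- setdiff(as.character(src[[1]]), ids)
    if (length(bad))
      stop(src[[2]], ": unknown expert id(s) ", paste(bad, collapse = ", "))
  }
  attrs <- setdiff(names(amat), "expert")
  check_ranks(unlist(amat[attrs]), attr_ranks_csv)
  check_ranks(along$rank, alt_ranks_csv)

  attr_rankings <- stats::setNames(lapply(as.character(amat$expert),
    function(e) {
      row <- amat[amat$expert == e, attrs, drop = FALSE]
      r <- suppressWarnings(as.integer(unlist(row[1, ])))
      names(r) <- attrs
      r[!is.na(r)]
    }), as.character(amat$expert))
  alt_rankings <- lapply(split(along, along$expert), function(df)
    lapply(split(df, df$attribute), function(g)
      stats::setNames(as.integer(g$rank), as.character(g$alternative))))
  alternatives <- sort(unique(as.character(along$alternative)))

  inst <- opa_instance(experts, attrs, alternatives,
                       attr_rankings, alt_rankings[names(attr_rankings)])
  findings <- validate_instance(inst)
  if (length(findings))
    stop("CSV instance is invalid: ", paste(findings, collapse = "; "))
  inst
}

#' Write the report tables of a fit
#'
#' Writes the three report tables (experts, attributes, alternatives; weight
#' and rank, rounded half-up to `digits`), the expert-by-attribute
#' significance matrix, and a full-precision machine-readable `report.json`
#' (weights, ranks, objective, solver tag).
#'
#' @param fit An `"opa"` fit.
#' @param dir Output directory (created if needed).
#' @param digits Decimal places for the CSV tables.
#' @return Named character vector of file paths, invisibly.
#' @export
write_report <- function(fit, dir, digits = 4) {
  stopifnot(inherits(fit, "opa"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- summary(fit, digits = digits)
  paths <- c(experts = file.path(dir, "expert_weights.csv"),
             attributes = file.path(dir, "attribute_weights.csv"),
             alternatives = file.path(dir, "alternative_weights.csv"),
             significance = file.path(dir, "significance_matrix.csv"),
             json = file.path(dir, "report.json"))
  utils::write.csv(s$experts, paths["experts"], row.names = FALSE)
  utils::write.csv(s$attributes, paths["attributes"], row.names = FALSE)
  utils::write.csv(s$alternatives, paths["alternatives"], row.names = FALSE)
  utils::write.csv(data.frame(expert = rownames(fit$significance),
                              fit$significance, check.names = FALSE),
                   paths["significance"], row.names = FALSE)
  jsonlite::write_json(
    list(solver = fit$solver_tag, z = fit$z,
         weights = lapply(fit$weights, as.list),
         ranks = lapply(fit$ranks, as.list)),
    paths["json"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Run the full decision pipeline on input files
#'
#' Reads an instance (JSON document or CSV trio), validates it, fits the
#' model and writes the report tables. Progress is logged to standard error
#' so file output stays pipe-safe.
#'
#' @param input Path to an instance JSON, or a character vector of the three
#'   CSV paths (experts, attr_ranks, alt_ranks).
#' @param out_dir Report output directory.
#' @param solver,tol Passed to [opa()].
#' @param digits Decimal places for report tables.
#' @return The `"opa"` fit, invisibly.
#' @export
opa_pipeline <- function(input, out_dir, solver = "auto", tol = 1e-8,
                         digits = 4) {
  stage <- function(...) message("[opa] ", ...)
  inst <- if (length(input) == 3L) {
    stage("reading CSV trio")
    read_opa_csv(input[1], input[2], input[3])
  } else {
    stage("reading JSON instance: ", input)
    read_opa_json(input)
  }
  stage("instance: ", nrow(inst$experts), " experts, ",
        nrow(inst$attributes), " attributes, ",
        nrow(inst$alternatives), " alternatives")
  fit <- opa(inst, solver = solver, tol = tol)
  stage("solved (", fit$solver_tag, "), Z = ", format(fit$z, digits = 6))
  paths <- write_report(fit, out_dir, digits = digits)
  stage("report written to ", out_dir)
  invisible(fit)
}
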