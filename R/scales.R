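#' Ordinal category scale
#'
#' An ordered set of category labels, best level first. Scales describe the
#' four profile characteristics used to prioritize experts (role, professional
#' position, experience bracket, education level).
#'
#' @param name Scale name (a single string).
#' @param levels Character vector of category labels, most preferred first.
#'   Must be non-empty with no duplicates.
#' @param aliases Optional named list mapping a canonical level to a character
#'   vector of alternative spellings accepted on input.
#' @return An object of class `"opa_scale"`.
#' @examples
#' ordinal_scale("role", c("end-user/caregiver", "therapist/physiotherapist",
#'                         "developer"))
#' @export
ordinal_scale <- function(name, levels, aliases = list()) {
  stopifnot(is.character(name), length(name) == 1L)
  levels <- as.character(levels)
  if (length(levels) == 0L) stop("scale '", name, "': levels must be non-empty")
  if (anyDuplicated(normalize_label(levels)))
    stop("scale '", name, "': duplicated levels")
  if (length(aliases) && !all(names(aliases) %in% levels))
    stop("scale '", name, "': alias keys must be existing levels")
  structure(list(name = name, levels = levels, aliases = aliases),
            class = "opa_scale")
}

# Canonical form used for all category matching: case, surrounding space,
# dash variants and parentheticals (e.g. "(Ph.D.)") are not significant.
normalize_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("\\s*\\([^)]*\\)", "", x)
  x <- gsub("[–—−]", "-", x)  # en/em dash, minus -> hyphen
  x <- gsub("\\s*-\\s*", "-", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' Position of a category on an ordinal scale
#'
#' @param scale An [ordinal_scale()].
#' @param value Character vector of category labels (any accepted spelling).
#' @return Integer vector of 1-based positions (1 = most preferred).
#'   Unknown labels raise an error naming the scale and the offending value.
#' @export
scale_position <- function(scale, value) {
  stopifnot(inherits(scale, "opa_scale"))
  keys <- normalize_label(scale$levels)
  vals <- normalize_label(value)
  for (lv in names(scale$aliases)) {
    hit <- vals %in% normalize_label(scale$aliases[[lv]])
    vals[hit] <- normalize_label(lv)
  }
  pos <- match(vals, keys)
  if (anyNA(pos)) {
    bad <- value[which(is.na(pos))[1L]]
    stop("unknown level '", bad, "' on scale '", scale$name, "'")
  }
  pos
}

#' Default expert-profile scales
#'
#' The four ordinal scales used to prioritize the expert panel, best level
#' first: role (end-user/caregiver over therapist/physiotherapist over
#' developer), professional position (ISCO-style major groups), experience
#' bracket in years (compared by bracket lower bound) and educational
#' attainment.
#'
#' @return Named list of [ordinal_scale()] objects (`role`, `position`,
#'   `experience`, `education`).
#' @export
opa_scales <- function() {
  list(
    role = ordinal_scale("role",
      c("end-user/caregiver", "therapist/physiotherapist", "developer"),
      aliases = list("end-user/caregiver" = c("end user/caregiver",
                                              "end-user / caregiver"))),
    position = ordinal_scale("position",
      c("professionals, scientists and intellectuals",
        "technicians and mid-level",
        "elementary occupations"),
      aliases = list(
        "professionals, scientists and intellectuals" =
          "professionals scientists and intellectuals",
        "technicians and mid-level" =
          c("technicians and mid-level and professionals",
            "technicians and mid-level professionals"))),
    experience = ordinal_scale("experience",
      c("more than 20", "15-20", "10-15", "5-10", "1-5"),
      aliases = list("more than 20" = c(">20", "more-than-20", "20+"))),
    education = ordinal_scale("education",
      c("doctorate", "postgraduate", "ordinary degree",
        "technical/vocational", "upper secondary", "lower secondary",
        "primary"))
  )
}

#' Expert ranking policy
#'
#' Lexicographic prioritization of experts: profiles are compared criterion by
#' criterion in the stated order, the first criterion on which two experts
#' differ decides; experts with fully identical profiles share a dense rank.
#'
#' @param criteria Character vector of profile fields, in comparison order.
#' @param scales Named list of [ordinal_scale()]s covering every criterion.
#' @return An object of class `"opa_policy"`.
#' @export
ranking_policy <- function(criteria = c("role", "position", "experience",
                                        "education"),
                           scales = opa_scales()) {
  criteria <- as.character(criteria)
  if (anyDuplicated(criteria)) stop("criteria must be distinct")
  missing_scale <- setdiff(criteria, names(scales))
  if (length(missing_scale))
    stop("no scale for criterion: ", paste(missing_scale, collapse = ", "))
  structure(list(criteria = criteria, scales = scales[criteria]),
            class = "opa_policy")
}

# p x length(criteria) matrix of scale positions (smaller = better)
profile_key <- function(panel, policy) {
  sapply(policy$criteria, function(cr) {
    if (is.null(panel[[cr]]))
      stop("panel is missing profile column '", cr, "'")
    scale_position(policy$scales[[cr]], panel[[cr]])
  })
}

#' Rank an expert panel lexicographically
#'
#' Assigns each expert a priority rank i (1 = most influential) by comparing
#' profiles criterion by criterion in policy order. Ranks are dense: experts
#' with identical profiles share a rank and the next distinct rank increments
#' by one; when ties occur the result carries a `tie_groups` attribute and a
#' warning is raised.
#'
#' @param panel Data frame with column `expert` (unique ids) and one column
#'   per policy criterion.
#' @param policy A [ranking_policy()].
#' @return Named integer vector of dense ranks (names = expert ids), invariant
#'   to the row order of `panel`.
#' @examples
#' rank_experts(phyxio_panel())
#' @export
rank_experts <- function(panel, policy = ranking_policy()) {
  panel <- as.data.frame(panel)
  if (is.null(panel$expert)) stop("panel must have an 'expert' column")
  ids <- as.character(panel$expert)
  if (anyDuplicated(ids)) stop("duplicate expert ids in panel")
  key <- profile_key(panel, policy)
  if (!is.matrix(key)) key <- matrix(key, nrow = nrow(panel))
  # lexicographic order, then dense ranks over distinct profile keys
  ord <- do.call(order, c(lapply(seq_len(ncol(key)), function(c) key[, c]),
                          list(seq_along(ids))))  # stable
  sorted <- key[ord, , drop = FALSE]
  new_group <- c(TRUE, rowSums(sorted[-1, , drop = FALSE] !=
                               sorted[-nrow(sorted), , drop = FALSE]) > 0)
  dense <- cumsum(new_group)
  ranks <- integer(length(ids))
  ranks[ord] <- dense
  names(ranks) <- ids
  if (max(dense) < length(ids)) {
    tg <- split(ids, ranks)
    tg <- tg[vapply(tg, length, 1L) > 1L]
    attr(ranks, "tie_groups") <- unname(tg)
    warning("expert profiles tie: ", length(tg), " tied group(s)")
  }
  ranks
}

#' Explain an expert ranking
#'
#' For every adjacent pair in the final priority order, names the first
#' policy criterion on which the two profiles differ (or `"tie"` for fully
#' identical profiles).
#'
#' @inheritParams rank_experts
#' @return Data frame with columns `higher`, `lower`, `decided_by`.
#' @examples
#' explain_ranking(phyxio_panel())
#' @export
explain_ranking <- function(panel, policy = ranking_policy()) {
  panel <- as.data.frame(panel)
  ranks <- suppressWarnings(rank_experts(panel, policy))
  ids <- names(sort(ranks))  # stable: ties keep panel order
  key <- profile_key(panel, policy)
  rownames(key) <- as.character(panel$expert)
  decided <- character(length(ids) - 1L)
  for (q in seq_len(length(ids) - 1L)) {
    a <- key[ids[q], ]; b <- key[ids[q + 1L], ]
    d <- which(a != b)
    decided[q] <- if (length(d)) policy$criteria[d[1L]] else "tie"
  }
  data.frame(higher = ids[-length(ids)], lower = ids[-1L],
             decided_by = decided, stringsAsFactors = FALSE)
}
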