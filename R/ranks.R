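#' Dense ranks from an ordering with tie groups
#'
#' Converts an ordering given as a list of tie groups (best group first) into
#' a dense rank vector: every member of group g receives rank g, so tied items
#' share a rank and the next distinct rank is the previous rank plus one.
#'
#' @param ordering List of character vectors (tie groups), most preferred
#'   group first. A plain character vector is treated as a strict ordering.
#' @return Named integer vector of dense ranks; empty input gives an empty
#'   vector.
#' @examples
#' dense_ranks(list(c("A", "C"), "B"))  # A=1, C=1, B=2
#' @export
dense_ranks <- function(ordering) {
  if (is.character(ordering)) ordering <- as.list(ordering)
  if (length(ordering) == 0L)
    return(structure(integer(0), names = character(0)))
  ordering <- lapply(ordering, as.character)
  sizes <- vapply(ordering, length, 1L)
  if (any(sizes == 0L)) stop("empty tie group in ordering")
  items <- unlist(ordering, use.names = FALSE)
  if (anyDuplicated(items))
    stop("malformed elicitation: item '",
         items[duplicated(items)][1L], "' appears twice")
  stats::setNames(rep.int(seq_along(ordering), sizes), items)
}

#' Tie groups from a dense rank vector
#'
#' Inverse of [dense_ranks()]: reads a dense rank vector back as an ordering
#' (list of tie groups, best first). Within a group, items keep their order of
#' appearance in the vector.
#'
#' @param ranks Named integer vector of dense ranks.
#' @return List of character vectors, one per rank position.
#' @export
tie_groups <- function(ranks) {
  if (length(ranks) == 0L) return(list())
  check_dense(ranks)
  lapply(seq_len(max(ranks)), function(g) names(ranks)[ranks == g])
}

# stop() unless ranks are {1,...,d} with no gaps and named uniquely
check_dense <- function(ranks, what = "rank vector") {
  if (is.null(names(ranks)) || anyDuplicated(names(ranks)))
    stop(what, ": items must be uniquely named")
  r <- as.integer(ranks)
  if (anyNA(r) || any(r < 1L)) stop(what, ": ranks must be positive integers")
  d <- max(r)
  if (!setequal(unique(r), seq_len(d)))
    stop(what, ": non-dense ranks (", paste(sort(unique(r)), collapse = ","),
         ")")
  invisible(ranks)
}

# findings-style (non-throwing) dense check used by validate_instance
dense_findings <- function(ranks, where) {
  out <- character(0)
  if (length(ranks) == 0L) return(out)
  r <- suppressWarnings(as.integer(ranks))
  if (anyNA(r) || any(r < 1L))
    return(paste0(where, ": ranks must be positive integers"))
  if (!setequal(unique(r), seq_len(max(r))))
    out <- c(out, paste0(where, ": non-dense ranks {",
                         paste(sort(unique(r)), collapse = ","), "}"))
  if (is.null(names(ranks)) || anyDuplicated(names(ranks)))
    out <- c(out, paste0(where, ": items not uniquely named"))
  out
}

# accept either a dense named rank vector or a tie-group ordering
as_rank_vector <- function(x, what = "ranking") {
  if (is.list(x) || (is.character(x) && is.null(names(x))))
    return(dense_ranks(x))
  if (!is.numeric(x)) stop(what, ": expected ranks or an ordering")
  check_dense(x, what)
  stats::setNames(as.integer(x), names(x))
}
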