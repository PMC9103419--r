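#' Fit the Ordinal Priority Approach model
#'
#' The main entry point: solves the OPA max-min program for a decision
#' instance and aggregates the weight tensor into expert, attribute and
#' alternative weights with dense ranks. The `"auto"` solver uses the exact
#' closed form when the instance is complete and strict, and the simplex LP
#' otherwise; both paths are available explicitly for cross-checking.
#'
#' @param instance An [opa_instance()].
#' @param solver `"auto"`, `"lp"` or `"closed-form"`.
#' @param tol Numerical tolerance for post-solve checks and rank ties.
#' @return An object of class `"opa"`: the instance, the weight array `w`
#'   (expert x attribute x alternative), objective `z`, `solver_tag`,
#'   `weights` and `ranks` (each a list with components `experts`,
#'   `attributes`, `alternatives`) and the expert x attribute `significance`
#'   matrix. Methods: [print.opa()], [summary.opa()], [coef.opa()],
#'   [plot.opa()].
#' @examples
#' fit <- opa(phyxio_instance())
#' fit
#' round(coef(fit, "experts"), 4)
#' @export
opa <- function(instance, solver = c("auto", "lp", "closed-form"),
                tol = 1e-8) {
  solver <- match.arg(solver)
  findings <- validate_instance(instance)
  if (length(findings))
    stop("invalid instance: ", paste(findings, collapse = "; "))
  if (solver == "auto")
    solver <- if (is_complete_strict(instance)) "closed-form" else "lp"
  tensor <- switch(solver,
    "closed-form" = opa_closed_form(instance),
    "lp" = solve_opa_lp(build_lp(instance), tol = tol))
  agg <- aggregate_weights(tensor, instance, tol = tol)
  structure(list(instance = instance, w = tensor$w, z = tensor$z,
                 solver_tag = tensor$solver_tag,
                 weights = agg$weights, ranks = agg$ranks,
                 significance = significance_matrix(tensor, instance),
                 tol = tol, call = match.call()),
            class = "opa")
}

# dense ranks over a weight vector, ties within tol share a rank
weight_ranks <- function(w, tol = 1e-8) {
  ord <- order(-w, seq_along(w))
  sorted <- w[ord]
  new_grp <- c(TRUE, (sorted[-length(sorted)] - sorted[-1]) > tol)
  dense <- cumsum(new_grp)
  out <- integer(length(w))
  out[ord] <- dense
  stats::setNames(out, names(w))
}

#' Aggregate a solved weight tensor into marginal weights
#'
#' Marginal sums of the weight tensor give the significance of each expert
#' (sum over attributes and alternatives), attribute (sum over experts and
#' alternatives, keyed by attribute identity) and alternative (sum over
#' experts and attributes). Each marginal sums to one; dense ranks are
#' attached with equal weights (within `tol`) tied.
#'
#' @param tensor An `"opa_tensor"` solved on `instance`.
#' @param instance The matching [opa_instance()].
#' @param tol Tolerance for the sum-to-one check and rank ties.
#' @return List with `weights` and `ranks`, each holding named vectors
#'   `experts`, `attributes`, `alternatives`.
#' @export
aggregate_weights <- function(tensor, instance, tol = 1e-8) {
  stopifnot(inherits(tensor, "opa_tensor"), inherits(instance, "opa_instance"))
  dn <- dimnames(tensor$w)
  if (!identical(dn$expert, as.character(instance$experts$expert)) ||
      !identical(dn$attribute, as.character(instance$attributes$attribute)) ||
      !identical(dn$alternative,
                 as.character(instance$alternatives$alternative)))
    stop("tensor and instance do not match")
  weights <- list(experts = apply(tensor$w, 1, sum),
                  attributes = apply(tensor$w, 2, sum),
                  alternatives = apply(tensor$w, 3, sum))
  for (side in names(weights))
    if (abs(sum(weights[[side]]) - 1) > tol)
      stop(side, " weights do not sum to 1 (off by ",
           abs(sum(weights[[side]]) - 1), ")")
  list(weights = weights,
       ranks = lapply(weights, weight_ranks, tol = tol))
}

#' Expert-by-attribute significance matrix
#'
#' Entry (i, j) is the total weight expert i assigns to attribute j,
#' \eqn{W_{ij} = \sum_k W_{ijk}}; row sums equal the expert weights.
#'
#' @inheritParams aggregate_weights
#' @return Numeric matrix, experts in rows, attributes in columns.
#' @export
significance_matrix <- function(tensor, instance) {
  stopifnot(inherits(tensor, "opa_tensor"))
  apply(tensor$w, c(1, 2), sum)
}

#' @export
print.opa <- function(x, digits = 4, ...) {
  d <- dim(x$w)
  cat("Ordinal Priority Approach fit (", x$solver_tag, ")\n", sep = "")
  cat("  ", d[1], " experts, ", d[2], " attributes, ", d[3],
      " alternatives; Z = ", format(x$z, digits = 6), "\n", sep = "")
  wk <- x$weights$alternatives
  ord <- order(x$ranks$alternatives, seq_along(wk))
  cat("  alternative ranking: ",
      paste(names(wk)[ord], collapse = " > "), "\n", sep = "")
  cat("  top alternative: ", names(wk)[ord[1]], " (weight ",
      round_half_up(wk[ord[1]], digits), ")\n", sep = "")
  invisible(x)
}

#' Summarize an OPA fit
#'
#' Produces the three report tables of the method — significance and ranking
#' of the experts, of the attributes and of the alternatives — with weights
#' rounded half-up to `digits` decimals, plus the expert-by-attribute
#' significance matrix.
#'
#' @param object An `"opa"` fit.
#' @param digits Decimal places for the displayed weights.
#' @param ... Unused.
#' @return An object of class `"summary.opa"` holding the three tables
#'   (`experts`, `attributes`, `alternatives`) and `significance`.
#' @export
summary.opa <- function(object, digits = 4, ...) {
  tab <- function(side, id_col) {
    w <- object$weights[[side]]
    r <- object$ranks[[side]]
    out <- data.frame(id = names(w),
                      weight = round_half_up(unname(w), digits),
                      rank = unname(r), stringsAsFactors = FALSE)
    names(out)[1] <- id_col
    out[order(out$rank, seq_len(nrow(out))), , drop = FALSE]
  }
  structure(list(experts = tab("experts", "expert"),
                 attributes = tab("attributes", "attribute"),
                 alternatives = tab("alternatives", "alternative"),
                 significance = round_half_up(object$significance, digits),
                 z = object$z, solver_tag = object$solver_tag,
                 digits = digits),
            class = "summary.opa")
}

#' @export
print.summary.opa <- function(x, ...) {
  cat("Ordinal Priority Approach (", x$solver_tag, "), Z = ",
      format(x$z, digits = 6), "\n\n", sep = "")
  cat("Significance and ranking of the experts:\n")
  print(x$experts, row.names = FALSE)
  cat("\nSignificance and ranking of the attributes:\n")
  print(x$attributes, row.names = FALSE)
  cat("\nSignificance and ranking of the alternatives:\n")
  print(x$alternatives, row.names = FALSE)
  invisible(x)
}

#' Extract weights from an OPA fit
#'
#' @param object An `"opa"` fit.
#' @param type Which marginal to return (`"alternatives"`, `"attributes"`,
#'   `"experts"`) or `"tensor"` for the full weight array.
#' @param ... Unused.
#' @return Named numeric vector (or the 3-d array for `"tensor"`).
#' @export
coef.opa <- function(object, type = c("alternatives", "attributes",
                                      "experts", "tensor"), ...) {
  type <- match.arg(type)
  if (type == "tensor") object$w else object$weights[[type]]
}

#' Plot an OPA fit
#'
#' Barplots of the three weight marginals, each sorted by rank.
#'
#' @param x An `"opa"` fit.
#' @param which Subset of `c("experts", "attributes", "alternatives")`.
#' @param ... Passed on to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.opa <- function(x, which = c("experts", "attributes", "alternatives"),
                     ...) {
  which <- match.arg(which, several.ok = TRUE)
  old <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(old))
  for (side in which) {
    w <- x$weights[[side]]
    ord <- order(x$ranks[[side]], seq_along(w))
    graphics::barplot(w[ord], main = paste("Weight of", side),
                      ylab = "weight", las = 2, ...)
  }
  invisible(x)
}

#' Leave-one-expert-out sensitivity analysis
#'
#' Refits the model once per removed expert: the remaining experts are
#' re-ranked densely (preserving their relative order), the program is
#' re-solved, and the resulting alternative ranking is compared with the
#' full-panel one.
#'
#' @param instance An [opa_instance()] with at least two experts, or an
#'   `"opa"` fit (its instance is used).
#' @param solver,tol Passed to [opa()].
#' @return An object of class `"opa_loo"`: per removed expert the refit
#'   objective, alternative weights and ranks, and a logical `changed` flag;
#'   plus the baseline ranking.
#' @export
loo_experts <- function(instance, solver = "auto", tol = 1e-8) {
  if (inherits(instance, "opa")) instance <- instance$instance
  stopifnot(inherits(instance, "opa_instance"))
  ids <- as.character(instance$experts$expert)
  if (length(ids) < 2L) stop("nothing to remove: need at least two experts")
  base <- opa(instance, solver = solver, tol = tol)
  res <- lapply(ids, function(drop_id) {
    keep <- instance$experts[ids != drop_id, , drop = FALSE]
    keep$rank <- match(keep$rank, sort(unique(keep$rank)))  # re-compact dense
    sub <- opa_instance(keep, instance$attributes, instance$alternatives,
                        instance$attr_rank[setdiff(ids, drop_id)],
                        instance$alt_rank[setdiff(ids, drop_id)],
                        expert_ranks = stats::setNames(keep$rank, keep$expert))
    fit <- opa(sub, solver = solver, tol = tol)
    list(removed = drop_id, z = fit$z,
         alt_weights = fit$weights$alternatives,
         alt_ranks = fit$ranks$alternatives,
         changed = !identical(unname(fit$ranks$alternatives),
                              unname(base$ranks$alternatives)))
  })
  structure(list(baseline = base$ranks$alternatives, results = res),
            class = "opa_loo")
}

#' @export
print.opa_loo <- function(x, ...) {
  cat("Leave-one-expert-out sensitivity (",
      length(x$results), " refits)\n", sep = "")
  base_ord <- names(sort(x$baseline))
  cat("  baseline alternative ranking: ",
      paste(base_ord, collapse = " > "), "\n", sep = "")
  for (r in x$results)
    cat("  - without ", r$removed, ": ",
        paste(names(sort(r$alt_ranks)), collapse = " > "),
        if (r$changed) "  [changed]" else "", "\n", sep = "")
  invisible(x)
}

# half-up decimal rounding (report convention; round() rounds half to even)
round_half_up <- function(x, digits = 4) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
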