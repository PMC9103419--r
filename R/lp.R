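#' Build the OPA max-min linear program
#'
#' Translates a decision instance into the OPA linear program: one
#' non-negative weight variable per (expert, ranked attribute, alternative),
#' plus the scalar objective Z. For each (expert, attribute) the alternative
#' ranking induces a telescoping chain over its distinct rank positions
#' r = 1..d with multipliers i*j*r (i = the expert's priority rank, j = that
#' expert's rank of the attribute, both after dense-tie compaction):
#' \deqn{Z \le i j r (W^{(r)} - W^{(r+1)}),\qquad Z \le i j d\, W^{(d)},}
#' together with the normalization \eqn{\sum W = 1}. Alternatives tied at a
#' rank position occupy one position in the chain, represented by their first
#' member, and carry equality rows binding their weights; attributes an
#' expert did not rank contribute no variables, the remaining attribute ranks
#' being already compact.
#'
#' @param instance A valid [opa_instance()].
#' @return An object of class `"opa_lp"`: variable table (`vars`), inequality
#'   rows (`A1`, `b1`, as `A1 x <= b1`), equality rows (`A3`, `b3`), objective
#'   coefficients (`obj`), and the inequality-row count `n_ineq`.
#' @seealso [solve_opa_lp()], [opa_closed_form()], [write_lp_dump()]
#' @export
build_lp <- function(instance) {
  findings <- validate_instance(instance)
  if (length(findings))
    stop("invalid instance: ", paste(findings, collapse = "; "))

  ids <- as.character(instance$experts$expert)
  erank <- stats::setNames(instance$experts$rank, ids)
  attrs <- as.character(instance$attributes$attribute)
  alts <- as.character(instance$alternatives$alternative)

  # deterministic variable order: expert rank, attribute rank, alternative
  # rank (catalogue order inside ties), Z last
  vars <- list(); ties <- list()
  for (e in ids[order(erank[ids], match(ids, ids))]) {
    rv <- instance$attr_rank[[e]]
    if (length(rv) == 0L) next
    a_order <- names(rv)[order(rv, match(names(rv), attrs))]
    for (a in a_order) {
      arv <- instance$alt_rank[[e]][[a]]
      k_order <- names(arv)[order(arv, match(names(arv), alts))]
      vars[[length(vars) + 1L]] <- data.frame(
        expert = e, attribute = a, alternative = k_order,
        i = unname(erank[e]), j = unname(rv[[a]]),
        r = unname(arv[k_order]), stringsAsFactors = FALSE)
    }
  }
  vars <- do.call(rbind, vars)
  nw <- nrow(vars)
  nv <- nw + 1L  # + Z
  zi <- nv

  blocks <- split(seq_len(nw), paste(vars$expert, vars$attribute, sep = "\r"))
  # keep deterministic block order (first variable index)
  blocks <- blocks[order(vapply(blocks, min, 1L))]

  n_ineq <- sum(vapply(blocks, function(ix) max(vars$r[ix]), 1L))
  A1 <- matrix(0, n_ineq, nv)
  eq_rows <- list()
  row <- 0L
  for (ix in blocks) {
    i <- vars$i[ix[1L]]; j <- vars$j[ix[1L]]
    d <- max(vars$r[ix])
    rep_of <- vapply(seq_len(d), function(r) ix[vars$r[ix] == r][1L], 1L)
    if (d > 1L) for (r in seq_len(d - 1L)) {
      row <- row + 1L
      A1[row, rep_of[r]] <- -i * j * r
      A1[row, rep_of[r + 1L]] <- i * j * r
      A1[row, zi] <- 1
    }
    row <- row + 1L
    A1[row, rep_of[d]] <- -i * j * d
    A1[row, zi] <- 1
    for (r in seq_len(d)) {                       # bind tied weights equal
      members <- ix[vars$r[ix] == r]
      for (mem in members[-1L]) {
        er <- numeric(nv); er[mem] <- 1; er[rep_of[r]] <- -1
        eq_rows[[length(eq_rows) + 1L]] <- er
      }
    }
  }
  A3 <- rbind(c(rep(1, nw), 0),
              if (length(eq_rows)) do.call(rbind, eq_rows))
  structure(list(vars = vars, A1 = A1, b1 = numeric(n_ineq),
                 A3 = A3, b3 = c(1, rep(0, length(eq_rows))),
                 obj = c(rep(0, nw), 1), n_ineq = n_ineq,
                 instance = instance),
            class = "opa_lp")
}

#' @export
print.opa_lp <- function(x, ...) {
  cat("OPA linear program:", nrow(x$vars), "weight variables + Z,",
      x$n_ineq, "inequality rows,", nrow(x$A3), "equality row(s)\n")
  invisible(x)
}

# assemble a weight tensor object from per-variable weights
as_tensor <- function(instance, vars, w, z, solver_tag) {
  ids <- as.character(instance$experts$expert)
  attrs <- as.character(instance$attributes$attribute)
  alts <- as.character(instance$alternatives$alternative)
  W <- array(0, dim = c(length(ids), length(attrs), length(alts)),
             dimnames = list(expert = ids, attribute = attrs,
                             alternative = alts))
  W[cbind(match(vars$expert, ids), match(vars$attribute, attrs),
          match(vars$alternative, alts))] <- w
  structure(list(w = W, z = z, solver_tag = solver_tag),
            class = "opa_tensor")
}

#' @export
print.opa_tensor <- function(x, ...) {
  d <- dim(x$w)
  cat("OPA weight tensor ", d[1], " x ", d[2], " x ", d[3],
      " (", x$solver_tag, "), Z = ", format(x$z, digits = 7),
      ", sum = ", format(sum(x$w), digits = 10), "\n", sep = "")
  invisible(x)
}

#' Solve the OPA linear program
#'
#' Maximizes Z over the constraint system of [build_lp()] with the simplex
#' method (`boot::simplex`). The solved instance always has a strictly
#' positive objective and weights summing to one; failure to solve signals a
#' construction bug and raises an error.
#'
#' @param lp An `"opa_lp"` from [build_lp()].
#' @param tol Feasibility/consistency tolerance for post-solve checks.
#' @return An `"opa_tensor"`: weight array `w` (expert x attribute x
#'   alternative; zero where an expert left an attribute unranked), objective
#'   `z`, and `solver_tag = "simplex-lp"`.
#' @examples
#' inst <- phyxio_instance()
#' tens <- solve_opa_lp(build_lp(inst))
#' sum(tens$w)  # 1
#' @export
solve_opa_lp <- function(lp, tol = 1e-8) {
  stopifnot(inherits(lp, "opa_lp"))
  nv <- length(lp$obj)
  s <- boot::simplex(a = lp$obj, A1 = lp$A1, b1 = lp$b1,
                     A3 = lp$A3, b3 = lp$b3, maxi = TRUE,
                     n.iter = max(500L, 30L * nv))
  if (s$solved != 1)
    stop("LP solver did not converge (status ", s$solved,
         "); this signals a model construction bug")
  w <- unname(s$soln[seq_len(nv - 1L)])
  z <- unname(s$value)
  if (abs(sum(w) - 1) > tol)
    stop("solved weights violate normalization by ", abs(sum(w) - 1))
  if (z <= 0) stop("non-positive objective at optimum")
  as_tensor(lp$instance, lp$vars, w, z, "simplex-lp")
}

#' Closed-form OPA solution for complete strict instances
#'
#' At the optimum of the OPA program for a complete strict instance every
#' constraint is tight, which yields the exact solution
#' \deqn{W_{ij}^{(r)} = \frac{Z}{ij}\sum_{s=r}^{m} \frac{1}{s},\qquad
#'       Z = \Big(m \sum_{i}\sum_{j} \frac{1}{ij}\Big)^{-1},}
#' with i the expert rank, j the expert's attribute rank, r the alternative
#' rank and m the number of alternatives. Instances with ties or missing
#' attributes are outside this regime and must go through [solve_opa_lp()].
#'
#' @param instance A valid, complete strict [opa_instance()].
#' @return An `"opa_tensor"` with `solver_tag = "closed-form"`.
#' @export
opa_closed_form <- function(instance) {
  findings <- validate_instance(instance)
  if (length(findings))
    stop("invalid instance: ", paste(findings, collapse = "; "))
  if (!is_complete_strict(instance))
    stop("closed form requires complete strict rankings; ",
         "use solve_opa_lp(build_lp(instance)) for ties/missing data")
  ids <- as.character(instance$experts$expert)
  erank <- stats::setNames(instance$experts$rank, ids)
  m <- nrow(instance$alternatives)
  tail_h <- rev(cumsum(1 / rev(seq_len(m))))  # sum_{s=r..m} 1/s
  inv_ij <- 0
  for (e in ids) inv_ij <- inv_ij +
      sum(1 / (erank[[e]] * as.numeric(instance$attr_rank[[e]])))
  z <- 1 / (m * inv_ij)
  rows <- list()
  for (e in ids) for (a in names(instance$attr_rank[[e]])) {
    arv <- instance$alt_rank[[e]][[a]]
    rows[[length(rows) + 1L]] <- data.frame(
      expert = e, attribute = a, alternative = names(arv),
      w = z / (erank[[e]] * instance$attr_rank[[e]][[a]]) *
        tail_h[as.integer(arv)],
      stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, rows)
  as_tensor(instance, rows, rows$w, z, "closed-form")
}

#' Write a plain-text dump of the linear program
#'
#' Emits the LP in a human-readable format (objective, inequality rows,
#' equality rows, bounds) for debugging against any external LP tool.
#'
#' @param lp An `"opa_lp"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lp_dump <- function(lp, path) {
  stopifnot(inherits(lp, "opa_lp"))
  vn <- c(sprintf("W[%s,%s,%s]", lp$vars$expert, lp$vars$attribute,
                  lp$vars$alternative), "Z")
  fmt_row <- function(coef, rel, rhs) {
    nz <- which(coef != 0)
    paste(paste(sprintf("%+g %s", coef[nz], vn[nz]), collapse = " "),
          rel, format(rhs))
  }
  lines <- c("maximize: Z", "subject to:",
             vapply(seq_len(nrow(lp$A1)), function(q)
               fmt_row(lp$A1[q, ], "<=", lp$b1[q]), ""),
             vapply(seq_len(nrow(lp$A3)), function(q)
               fmt_row(lp$A3[q, ], "=", lp$b3[q]), ""),
             "bounds: all variables >= 0")
  writeLines(lines, path)
  invisible(path)
}
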