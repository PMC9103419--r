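#' Kendall-tau distance between two strict orderings
#'
#' Number of discordant item pairs (pairs ordered oppositely by the two
#' orderings). Both orderings must be permutations of the same item set.
#'
#' @param a,b Character vectors, items best first.
#' @return Non-negative integer; 0 iff the orderings agree, maximum
#'   `choose(m, 2)` for reversed orderings of m items.
#' @export
kendall_distance <- function(a, b) {
  if (!setequal(a, b) || length(a) != length(b))
    stop("orderings must be permutations of the same items")
  pos <- match(a, b)
  sum(vapply(seq_along(pos), function(q) sum(pos[seq_len(q - 1L)] > pos[q]),
             1L))
}

#' Sample strict rankings from the Mallows model
#'
#' Draws orderings from the Kendall-distance exponential family
#' \deqn{P(\pi) \propto \exp(-\theta\, d_K(\pi, \pi_0)),}
#' the standard noise model for ordinal data, via the exact
#' repeated-insertion construction: the t-th reference item is inserted at
#' position s of the partial ordering with probability proportional to
#' \eqn{\exp(-\theta (t - s))}. `theta = 0` gives the uniform distribution
#' over permutations; large `theta` concentrates on the reference.
#'
#' @param n Number of draws.
#' @param reference Character vector of items, best first (the modal order).
#' @param theta Non-negative concentration parameter.
#' @return List of `n` character vectors (orderings, best first).
#' @examples
#' set.seed(1)
#' rmallows(3, c("A", "B", "C"), theta = 2)
#' @export
rmallows <- function(n, reference, theta) {
  stopifnot(theta >= 0, n >= 0)
  reference <- as.character(reference)
  m <- length(reference)
  replicate(n, {
    out <- character(0)
    for (t in seq_len(m)) {
      pr <- exp(-theta * (t - seq_len(t)))  # position 1..t, t = no discord
      s <- sample.int(t, 1L, prob = pr)
      out <- append(out, reference[t], after = s - 1L)
    }
    out
  }, simplify = FALSE)
}

#' Sample a panel of noisy expert rankings
#'
#' Convenience wrapper: `p` independent Mallows draws around a common
#' reference order, under a fixed seed.
#'
#' @param reference Character vector, best first.
#' @param theta Non-negative concentration (0 = uniform).
#' @param p Number of rankings.
#' @param seed Integer seed.
#' @return List of `p` orderings.
#' @export
gen_noisy_panel <- function(reference, theta, p, seed = 1) {
  set.seed(seed)
  rmallows(p, reference, theta)
}

#' Specification of a synthetic OPA instance
#'
#' Collects the generator parameters: problem sizes, the probability that an
#' adjacent rank boundary is merged into a tie, the probability that an
#' expert skips an attribute, the Mallows concentration of rank noise around
#' the reference orders (0 = uniform random), optional reference orders, the
#' expert-rank mode and the seed.
#'
#' @param p,n,m Numbers of experts, attributes, alternatives (all >= 1).
#' @param tie_prob,missing_prob Probabilities in \[0, 1\].
#' @param noise_theta Non-negative Mallows concentration.
#' @param attr_reference,alt_reference Optional reference orderings
#'   (character vectors, best first); default catalogue order.
#' @param expert_rank_mode `"random"` assigns a uniform random strict
#'   permutation of expert ranks; `"profile"` ranks the sampled profiles
#'   lexicographically (which may tie).
#' @param seed Integer seed.
#' @return An object of class `"opa_synth_spec"`.
#' @export
synthetic_spec <- function(p, n, m, tie_prob = 0, missing_prob = 0,
                           noise_theta = 0, attr_reference = NULL,
                           alt_reference = NULL,
                           expert_rank_mode = c("random", "profile"),
                           seed = 1) {
  stopifnot(p >= 1, n >= 1, m >= 1,
            tie_prob >= 0, tie_prob <= 1,
            missing_prob >= 0, missing_prob <= 1,
            noise_theta >= 0)
  structure(list(p = as.integer(p), n = as.integer(n), m = as.integer(m),
                 tie_prob = tie_prob, missing_prob = missing_prob,
                 noise_theta = noise_theta,
                 attr_reference = attr_reference,
                 alt_reference = alt_reference,
                 expert_rank_mode = match.arg(expert_rank_mode),
                 seed = as.integer(seed)),
            class = "opa_synth_spec")
}

# merge adjacent rank boundaries of a strict ordering into tie groups
inject_ties <- function(ordering, tie_prob) {
  groups <- as.list(ordering)
  if (tie_prob <= 0 || length(groups) < 2L) return(groups)
  out <- groups[1L]
  for (g in groups[-1L]) {
    if (stats::runif(1) < tie_prob)
      out[[length(out)]] <- c(out[[length(out)]], g)
    else out[[length(out) + 1L]] <- g
  }
  out
}

#' Generate a synthetic OPA instance
#'
#' Emulates an elicitation round: expert profiles are sampled uniformly over
#' the default category scales; attribute and per-attribute alternative
#' orderings are drawn from the Mallows model around the reference orders
#' (uniform random at `noise_theta = 0`); adjacent ranks are then merged into
#' ties with probability `tie_prob` and attributes dropped per expert with
#' probability `missing_prob` (an expert always keeps at least one
#' attribute). Fully reproducible from the spec's seed.
#'
#' @param spec An [synthetic_spec()].
#' @return An [opa_instance()].
#' @examples
#' inst <- gen_instance(synthetic_spec(p = 3, n = 2, m = 3, seed = 7))
#' validate_instance(inst)  # character(0)
#' @export
gen_instance <- function(spec) {
  stopifnot(inherits(spec, "opa_synth_spec"))
  set.seed(spec$seed)
  ids <- sprintf("E%d", seq_len(spec$p))
  attrs <- if (is.null(spec$attr_reference)) sprintf("j%d", seq_len(spec$n))
           else as.character(spec$attr_reference)
  alts <- if (is.null(spec$alt_reference)) sprintf("A%d", seq_len(spec$m))
          else as.character(spec$alt_reference)
  scales <- opa_scales()
  panel <- data.frame(
    expert = ids,
    role = sample(scales$role$levels, spec$p, replace = TRUE),
    position = sample(scales$position$levels, spec$p, replace = TRUE),
    experience = sample(scales$experience$levels, spec$p, replace = TRUE),
    education = sample(scales$education$levels, spec$p, replace = TRUE),
    stringsAsFactors = FALSE)
  expert_ranks <- if (spec$expert_rank_mode == "random")
    stats::setNames(sample.int(spec$p), ids)
  else suppressWarnings(rank_experts(panel))

  attr_rankings <- stats::setNames(lapply(seq_len(spec$p), function(e) {
    ord <- rmallows(1, attrs, spec$noise_theta)[[1]]
    if (spec$missing_prob > 0) {
      keep <- stats::runif(length(ord)) >= spec$missing_prob
      if (!any(keep)) keep[1L] <- TRUE  # never drop everything
      ord <- ord[keep]
    }
    inject_ties(ord, spec$tie_prob)
  }), ids)
  alt_rankings <- stats::setNames(lapply(ids, function(e) {
    ranked <- unlist(attr_rankings[[e]], use.names = FALSE)
    stats::setNames(lapply(ranked, function(a)
      inject_ties(rmallows(1, alts, spec$noise_theta)[[1]], spec$tie_prob)),
      ranked)
  }), ids)

  opa_instance(panel, attrs, alts, attr_rankings, alt_rankings,
               expert_ranks = expert_ranks)
}

#' Generate a consensus instance
#'
#' Every expert ranks the alternatives identically (the true order) under
#' every attribute; attribute orderings are uniform random and expert ranks a
#' random permutation. The aggregated alternative ranking of such an instance
#' always equals the true order.
#'
#' @param true_order Character vector of alternative ids, best first.
#' @param p,n Numbers of experts and attributes.
#' @param seed Integer seed.
#' @return An [opa_instance()].
#' @export
gen_consensus_instance <- function(true_order, p, n, seed = 1) {
  true_order <- as.character(true_order)
  set.seed(seed)
  ids <- sprintf("E%d", seq_len(p))
  attrs <- sprintf("j%d", seq_len(n))
  attr_rankings <- stats::setNames(lapply(seq_len(p), function(e)
    as.list(sample(attrs))), ids)
  alt_rankings <- stats::setNames(lapply(ids, function(e)
    stats::setNames(lapply(attrs, function(a) as.list(true_order)), attrs)),
    ids)
  opa_instance(ids, attrs, true_order, attr_rankings, alt_rankings,
               expert_ranks = stats::setNames(sample.int(p), ids))
}
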