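test_that("generation is deterministic given the seed", {
  spec <- synthetic_spec(p = 9, n = 6, m = 4, tie_prob = 0.2,
                         missing_prob = 0.2, noise_theta = 1, seed = 42)
  expect_identical(gen_instance(spec), gen_instance(spec))
  expect_identical(gen_noisy_panel(LETTERS[1:4], 2, 5, seed = 7),
                   gen_noisy_panel(LETTERS[1:4], 2, 5, seed = 7))
})

test_that("zero noise, ties and missingness give complete strict instances", {
  inst <- gen_instance(synthetic_spec(p = 5, n = 4, m = 3, seed = 3))
  expect_identical(validate_instance(inst), character(0))
  expect_true(is_complete_strict(inst))
})

test_that("uniformity at theta = 0: chi-square over the 6 permutations", {
  set.seed(2024)
  draws <- rmallows(10000, c("A", "B", "C"), theta = 0)
  labels <- vapply(draws, paste, "", collapse = "")
  perms <- c("ABC", "ACB", "BAC", "BCA", "CAB", "CBA")
  counts <- table(factor(labels, levels = perms))
  p <- stats::chisq.test(counts, p = rep(1 / 6, 6))$p.value
  expect_gt(p, 0.01)
})

test_that("large theta concentrates on the reference order", {
  set.seed(5)
  ref <- c("A1", "A2", "A3", "A4")
  draws <- rmallows(500, ref, theta = 20)
  frac <- mean(vapply(draws, identical, TRUE, ref))
  expect_gte(frac, 0.99)
})

test_that("expected Kendall distance decreases in theta", {
  set.seed(31)
  ref <- c("A1", "A2", "A3", "A4")
  mean_d <- vapply(c(0, 1, 2), function(th)
    mean(vapply(rmallows(1000, ref, th), kendall_distance, 1L, b = ref)),
    1.0)
  expect_true(all(diff(mean_d) < 0))
  # analytic spot-check: uniform mean distance is m(m-1)/4 = 3 for m = 4
  expect_equal(mean_d[1], 3, tolerance = 0.15)
})

test_that("kendall_distance counts discordant pairs", {
  expect_equal(kendall_distance(c("A", "B", "C"), c("A", "B", "C")), 0L)
  expect_equal(kendall_distance(c("C", "B", "A"), c("A", "B", "C")), 3L)
  expect_equal(kendall_distance(c("B", "A", "C"), c("A", "B", "C")), 1L)
  expect_error(kendall_distance(c("A", "B"), c("A", "C")), "permutations")
})

test_that("tie_prob = 1 collapses every ranking to a single group", {
  inst <- gen_instance(synthetic_spec(p = 3, n = 3, m = 4, tie_prob = 1,
                                      seed = 6))
  for (e in names(inst$attr_rank)) {
    expect_true(all(inst$attr_rank[[e]] == 1L))
    for (a in names(inst$alt_rank[[e]]))
      expect_true(all(inst$alt_rank[[e]][[a]] == 1L))
  }
  # and it still solves: all alternatives equally weighted
  fit <- opa(inst)
  expect_equal(unname(fit$weights$alternatives), rep(1 / 4, 4),
               tolerance = 1e-9)
})

test_that("missingness never strips an expert of every attribute", {
  for (s in 1:5) {
    inst <- gen_instance(synthetic_spec(p = 4, n = 3, m = 2,
                                        missing_prob = 0.95, seed = s))
    expect_identical(validate_instance(inst), character(0))
    expect_true(all(vapply(inst$attr_rank, length, 1L) >= 1L))
  }
})

test_that("near-degenerate noise reproduces the reference everywhere", {
  ref <- c("A2", "A3", "A1")
  inst <- gen_instance(synthetic_spec(p = 4, n = 2, m = 3, noise_theta = 50,
                                      alt_reference = ref, seed = 12))
  for (e in names(inst$alt_rank)) for (a in names(inst$alt_rank[[e]]))
    expect_equal(names(sort(inst$alt_rank[[e]][[a]])), ref)
})

test_that("profile mode derives expert ranks from the sampled panel", {
  inst <- gen_instance(synthetic_spec(p = 6, n = 2, m = 2,
                                      expert_rank_mode = "profile",
                                      seed = 19))
  panel <- inst$experts
  expect_equal(setNames(panel$rank, panel$expert),
               suppressWarnings(rank_experts(panel))[panel$expert])
})
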