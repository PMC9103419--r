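test_that("all three marginals sum to one on any solved instance", {
  set.seed(42)
  for (rep in 1:5) {
    spec <- synthetic_spec(p = sample(2:5, 1), n = sample(2:4, 1),
                           m = sample(2:4, 1),
                           tie_prob = sample(c(0, 0.3), 1),
                           missing_prob = sample(c(0, 0.3), 1),
                           seed = 500 + rep)
    fit <- opa(gen_instance(spec))
    for (side in c("experts", "attributes", "alternatives"))
      expect_equal(sum(fit$weights[[side]]), 1, tolerance = 1e-9)
  }
})

test_that("expert marginals equal (1/i)/H_p on complete strict instances", {
  set.seed(9)
  for (rep in 1:10) {
    p <- sample(2:6, 1)
    inst <- random_strict_instance(p, sample(1:4, 1), sample(1:4, 1))
    fit <- opa(inst, solver = if (rep %% 2) "lp" else "closed-form")
    i <- setNames(inst$experts$rank, inst$experts$expert)
    expect_equal(fit$weights$experts[names(i)],
                 (1 / i) / harmonic(p), tolerance = 1e-9)
  }
})

test_that("significance matrix rows sum to expert weights", {
  fit <- opa(phyxio_instance(seed = 4))
  expect_equal(rowSums(fit$significance), fit$weights$experts,
               tolerance = 1e-9)
  # complete strict: each row proportional to 1/j over that expert's ranking
  inst <- fit$instance
  for (e in inst$experts$expert) {
    j <- inst$attr_rank[[e]][colnames(fit$significance)]
    row <- fit$significance[e, ] / sum(fit$significance[e, ])
    expect_equal(row, (1 / j) / harmonic(6), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  # single-attribute instance: the column equals the expert weights
  one <- gen_consensus_instance(c("A1", "A2"), p = 3, n = 1, seed = 1)
  f1 <- opa(one)
  expect_equal(unname(f1$significance[, 1]), unname(f1$weights$experts),
               tolerance = 1e-9)
})

test_that("relabeling alternatives permutes weights identically", {
  set.seed(13)
  inst <- random_strict_instance(3, 3, 4)
  fit <- opa(inst)
  perm <- setNames(sprintf("B%d", sample(4)), inst$alternatives$alternative)
  relab <- opa_instance(
    inst$experts, inst$attributes, unname(perm[inst$alternatives$alternative]),
    inst$attr_rank,
    lapply(inst$alt_rank, function(per_attr) lapply(per_attr, function(rv)
      setNames(rv, unname(perm[names(rv)])))),
    expert_ranks = setNames(inst$experts$rank, inst$experts$expert))
  fit2 <- opa(relab)
  expect_equal(unname(fit2$weights$alternatives[unname(perm)]),
               unname(fit$weights$alternatives), tolerance = 1e-10)
})

test_that("consensus alternative order is returned exactly", {
  truth <- c("A3", "A1", "A4", "A2")
  for (s in 1:3) {
    fit <- opa(gen_consensus_instance(truth, p = 5, n = 3, seed = s))
    expect_equal(names(sort(fit$ranks$alternatives)), truth)
  }
})

test_that("aggregate_weights rejects a mismatched tensor", {
  tens <- opa_closed_form(micro_instance(2))
  expect_error(aggregate_weights(tens, micro_instance(3)), "do not match")
})

test_that("leave-one-expert-out behaves as the preference structure implies", {
  expect_error(loo_experts(micro_instance(2)), "at least two")

  # consensus survives any removal
  cons <- gen_consensus_instance(c("A2", "A1", "A3"), p = 4, n = 2, seed = 8)
  loo <- loo_experts(cons)
  expect_false(any(vapply(loo$results, `[[`, TRUE, "changed")))

  # two opposed experts: removing the dominant one flips the ranking
  inst <- opa_instance(c("E1", "E2"), "j1", c("A1", "A2"),
                       list(E1 = list("j1"), E2 = list("j1")),
                       list(E1 = list(j1 = list("A1", "A2")),
                            E2 = list(j1 = list("A2", "A1"))))
  base <- opa(inst)
  expect_equal(names(sort(base$ranks$alternatives)), c("A1", "A2"))
  loo2 <- loo_experts(inst)
  without_e1 <- loo2$results[[1]]
  expect_equal(names(sort(without_e1$alt_ranks)), c("A2", "A1"))
  expect_true(without_e1$changed)

  # fixture produces nine refits, each with a positive objective
  loo3 <- loo_experts(phyxio_instance())
  expect_length(loo3$results, 9L)
  expect_true(all(vapply(loo3$results, `[[`, 1, "z") > 0))
})

test_that("report tables are sorted by rank with rounded weights", {
  fit <- opa(phyxio_instance())
  s <- summary(fit)
  expect_equal(nrow(s$attributes), 6L)
  expect_equal(nrow(s$alternatives), 4L)
  expect_equal(s$experts$expert,
               c("E9", "E8", "E7", "E4", "E5", "E6", "E1", "E2", "E3"))
  expect_equal(s$experts$weight,
               c(0.3535, 0.1767, 0.1178, 0.0884, 0.0707, 0.0589,
                 0.0505, 0.0442, 0.0393))
  expect_true(all(diff(s$alternatives$weight) <= 0))
})
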