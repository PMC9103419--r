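# Hand-solved micro-instances (frozen): the chain and last-rank rows are all
# tight at the optimum, e.g. for one expert, one attribute, two alternatives
# Z <= W1 - W2 and Z <= 2 W2 with W1 + W2 = 1 give W = (3/4, 1/4), Z = 1/2.
test_that("micro-instances match their hand-solved optima on both paths", {
  cases <- list(
    list(m = 2, w = c(3, 1) / 4, z = 1 / 2),
    list(m = 3, w = c(11, 5, 2) / 18, z = 1 / 3))
  for (cs in cases) {
    inst <- micro_instance(cs$m)
    for (solver in c("lp", "closed-form")) {
      fit <- opa(inst, solver = solver)
      expect_equal(unname(fit$weights$alternatives), cs$w, tolerance = 1e-9)
      expect_equal(fit$z, cs$z, tolerance = 1e-9)
    }
  }
  # two experts, one attribute, one alternative: Z <= W1, Z <= 2 W2
  inst2 <- opa_instance(c("E1", "E2"), "j1", "A1",
                        list(E1 = list("j1"), E2 = list("j1")),
                        list(E1 = list(j1 = list("A1")),
                             E2 = list(j1 = list("A1"))))
  for (solver in c("lp", "closed-form")) {
    fit <- opa(inst2, solver = solver)
    expect_equal(unname(fit$weights$experts), c(2, 1) / 3, tolerance = 1e-9)
    expect_equal(fit$z, 2 / 3, tolerance = 1e-9)
  }
})

test_that("LP construction has the expected shape on the fixture", {
  lp <- build_lp(phyxio_instance())
  expect_equal(nrow(lp$vars), 9 * 6 * 4)        # one weight per (i, j, k)
  expect_equal(lp$n_ineq, 9 * 6 * 4)            # 3 chain + 1 last per block
  expect_equal(nrow(lp$A3), 1L)                 # normalization only
  expect_equal(unname(lp$A3[1, ]), c(rep(1, 216), 0))
  # every inequality row touches Z
  expect_true(all(lp$A1[, ncol(lp$A1)] == 1))
})

test_that("degenerate sizes solve correctly", {
  inst <- micro_instance(1)                     # p = n = m = 1
  lp <- build_lp(inst)
  expect_equal(nrow(lp$vars), 1L)
  expect_equal(lp$n_ineq, 1L)
  fit <- opa(inst, solver = "lp")
  expect_equal(unname(fit$weights$alternatives), 1)
  expect_equal(fit$z, 1, tolerance = 1e-9)
})

test_that("unranked attributes contribute no variables and compact ranks", {
  inst <- opa_instance("E1", c("j1", "j2"), c("A1", "A2"),
                       list(E1 = list("j2")),   # j1 never ranked
                       list(E1 = list(j2 = list("A1", "A2"))))
  lp <- build_lp(inst)
  expect_equal(nrow(lp$vars), 2L)
  expect_true(all(lp$vars$attribute == "j2"))
  expect_equal(unique(lp$vars$j), 1)            # compacted to rank 1
  fit <- opa(inst, solver = "lp")
  expect_equal(sum(fit$w[, "j1", ]), 0)
  expect_equal(unname(fit$weights$alternatives), c(3, 1) / 4,
               tolerance = 1e-9)
})

test_that("tied alternatives share one chain position and equal weights", {
  inst <- opa_instance("E1", "j1", c("A1", "A2", "A3"),
                       list(E1 = list("j1")),
                       list(E1 = list(j1 = list(c("A1", "A2"), "A3"))))
  lp <- build_lp(inst)
  expect_equal(lp$n_ineq, 2L)                   # two distinct positions
  expect_equal(nrow(lp$A3), 2L)                 # normalization + one binding
  fit <- opa(inst, solver = "lp")
  w <- fit$weights$alternatives
  expect_equal(unname(w["A1"]), unname(w["A2"]), tolerance = 1e-9)
  expect_gt(w["A1"], w["A3"])
  expect_equal(sum(w), 1, tolerance = 1e-9)
})

test_that("closed form refuses tied or missing instances", {
  tied <- opa_instance("E1", "j1", c("A1", "A2"),
                       list(E1 = list("j1")),
                       list(E1 = list(j1 = list(c("A1", "A2")))))
  expect_error(opa_closed_form(tied), "complete strict")
})

test_that("rank-position identity: sum_r sum_{s>=r} 1/s equals m", {
  for (m in c(1:10, 25, 50)) {
    tail_h <- rev(cumsum(1 / rev(seq_len(m))))
    expect_equal(sum(tail_h), m, tolerance = 1e-12)
  }
})

test_that("LP and closed form agree on random complete strict instances", {
  set.seed(101)
  for (rep in 1:30) {
    p <- sample(1:5, 1); n <- sample(1:5, 1); m <- sample(1:5, 1)
    inst <- random_strict_instance(p, n, m)
    a <- solve_opa_lp(build_lp(inst))
    b <- opa_closed_form(inst)
    expect_lt(max(abs(a$w - b$w)), 1e-8)
    expect_equal(a$z, b$z, tolerance = 1e-8)
  }
})

test_that("solved tensors satisfy the model invariants", {
  set.seed(55)
  for (rep in 1:10) {
    spec <- synthetic_spec(p = sample(2:4, 1), n = sample(2:4, 1),
                           m = sample(2:4, 1),
                           tie_prob = sample(c(0, 0.4), 1),
                           missing_prob = sample(c(0, 0.3), 1),
                           seed = 1000 + rep)
    inst <- gen_instance(spec)
    tens <- solve_opa_lp(build_lp(inst))
    expect_equal(sum(tens$w), 1, tolerance = 1e-9)   # normalization
    expect_true(all(tens$w >= -1e-12))               # non-negativity
    expect_gt(tens$z, 0)                             # strictly positive Z
    # within each (expert, ranked attribute): non-increasing in rank,
    # strictly decreasing across distinct rank positions
    for (e in names(inst$attr_rank)) for (a in names(inst$attr_rank[[e]])) {
      arv <- inst$alt_rank[[e]][[a]]
      w <- tens$w[e, a, names(arv)]
      byrank <- tapply(w, arv, mean)
      expect_true(all(diff(byrank) < 0))
      expect_true(all(tapply(w, arv, function(x) diff(range(x))) < 1e-9))
    }
  }
})

test_that("solution is invariant to expert relabeling (variable order)", {
  set.seed(77)
  inst <- random_strict_instance(4, 3, 3)
  perm <- sample(4)
  relab <- inst
  relab$experts <- inst$experts[perm, , drop = FALSE]
  relab$attr_rank <- inst$attr_rank[relab$experts$expert]
  relab$alt_rank <- inst$alt_rank[relab$experts$expert]
  a <- opa(inst, solver = "lp")
  b <- opa(relab, solver = "lp")
  expect_equal(b$w[dimnames(a$w)$expert, , ], a$w, tolerance = 1e-10)
  expect_equal(b$z, a$z, tolerance = 1e-10)
})

test_that("the LP dump lists every row of the program", {
  lp <- build_lp(micro_instance(2))
  path <- withr::local_tempfile(fileext = ".lp")
  write_lp_dump(lp, path)
  lines <- readLines(path)
  expect_equal(sum(grepl("<=", lines)), lp$n_ineq)
  expect_equal(sum(grepl(" = ", lines)), nrow(lp$A3))
})
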