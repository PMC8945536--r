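test_that("MLE CPTs equal frequency tables (with and without smoothing)", {
  d <- data.frame(A = factor(c(1, 1, 1, 1, 2, 2, 2, 2)),
                  B = factor(c(1, 1, 1, 1, 2, 2, 2, 1)))
  bn <- fit_cpts_mle(new_dag(c("A", "B")), d)
  expect_equal(as.numeric(bn$cpts$A), c(0.5, 0.5))
  # deterministic dependence: B == A
  d2 <- data.frame(A = factor(rep(1:2, 10)), B = factor(rep(1:2, 10)))
  bn2 <- fit_cpts_mle(new_dag(c("A", "B"), data.frame(p = "A", c = "B")), d2)
  expect_equal(bn2$cpts$B["1", "1"], 1)
  expect_equal(bn2$cpts$B["2", "2"], 1)
  # random 3-node data: CPTs equal independent tabulation
  withr::with_seed(5, {
    d3 <- data.frame(X = factor(sample(1:3, 60, TRUE)),
                     Y = factor(sample(1:2, 60, TRUE)),
                     Z = factor(sample(1:2, 60, TRUE)))
    dag <- new_dag(c("X", "Y", "Z"),
                   data.frame(p = c("X", "Y"), c = c("Z", "Z")))
    bn3 <- fit_cpts_mle(dag, d3)
    tab <- table(d3$Z, d3$X, d3$Y)
    for (x in 1:3) for (y in 1:2) {
      n <- sum(tab[, x, y])
      if (n > 0) {
        expect_equal(unname(bn3$cpts$Z[, x, y]), unname(tab[, x, y] / n))
      }
    }
  })
})

test_that("exact queries match full joint enumeration on random small networks", {
  for (seed in 1:8) {
    bn <- random_discrete_bn(5, sample(3:7, 1), arity = 3, seed = seed)
    # hard evidence on one node, query another
    ev_node <- bn$dag$nodes[1]
    target <- bn$dag$nodes[5]
    p_ve <- query(bn, target, setNames(list(2L), ev_node))
    p_brute <- brute_posterior(bn, target, setNames(list(2L), ev_node))
    expect_equal(unname(p_ve), p_brute, tolerance = 1e-9)
    # no evidence: marginal matches enumeration
    j <- brute_joint(bn)
    marg <- tapply(j$p, j[[target]], sum)
    expect_equal(unname(query(bn, target)), as.numeric(marg), tolerance = 1e-9)
  }
})

test_that("roots and deterministic chains behave as expected under queries", {
  # chain A -> B -> C with copy CPTs: evidence on A pins C
  dag <- new_dag(c("A", "B", "C"),
                 data.frame(p = c("A", "B"), c = c("B", "C")))
  d <- data.frame(A = factor(rep(1:2, 25)), B = factor(rep(1:2, 25)),
                  C = factor(rep(1:2, 25)))
  bn <- fit_cpts_mle(dag, d)
  expect_equal(unname(query(bn, "C", list(A = 1L))), c(1, 0))
  expect_equal(unname(query(bn, "A")), as.numeric(bn$cpts$A))
  expect_error(query(bn, "C", list(C = 1L)), "hard evidence")
})

test_that("impossible evidence is reported", {
  d <- data.frame(A = factor(c(1, 1, 2, 2)), B = factor(c(1, 1, 2, 2)))
  bn <- fit_cpts_mle(new_dag(c("A", "B"), data.frame(p = "A", c = "B")), d)
  expect_error(query(bn, "B", list(A = c(0, 0))), "impossible")
})

test_that("log-likelihood decomposes over families and matches closed forms", {
  # fair coin, 8 observations -> 8 bits
  d <- data.frame(X = factor(rep(1:2, 4)))
  bn <- fit_cpts_mle(new_dag("X"), d)
  expect_equal(loglik_bits(bn, d), 8)
  # deterministic model on consistent data -> 0 bits
  d2 <- data.frame(A = factor(rep(1:2, 10)), B = factor(rep(1:2, 10)))
  bn2 <- fit_cpts_mle(new_dag(c("A", "B"), data.frame(p = "A", c = "B")), d2)
  expect_equal(loglik_bits(bn2, d2), 20 * 1) # A costs 1 bit/row, B costs 0
  # equals -sum log2 joint via enumeration on a random case
  bn3 <- random_discrete_bn(4, 4, arity = 2, seed = 9)
  d3 <- sample_bn(bn3, 50, seed = 10)
  j <- brute_joint(bn3)
  key <- do.call(paste, j[bn3$dag$nodes])
  obs <- do.call(paste, lapply(d3, as.integer))
  expect_equal(loglik_bits(bn3, d3), -sum(log2(j$p[match(obs, key)])),
               tolerance = 1e-9)
  # MLE loglik equals N * sum of family conditional entropies
  dag <- new_dag(c("A", "B"), data.frame(p = "A", c = "B"))
  withr::with_seed(2, {
    d4 <- data.frame(A = factor(sample(1:2, 40, TRUE)),
                     B = factor(sample(1:3, 40, TRUE)))
  })
  bn4 <- fit_cpts_mle(dag, d4)
  h_a <- micropsem:::entropy_bits(table(d4$A))
  h_b_given_a <- sum(prop.table(table(d4$A)) *
                       vapply(split(d4$B, d4$A),
                              function(b) micropsem:::entropy_bits(table(b)),
                              numeric(1)))
  expect_equal(loglik_bits(bn4, d4), 40 * (h_a + h_b_given_a), tolerance = 1e-9)
})

test_that("zero-probability rows yield infinite code length with a warning", {
  d <- data.frame(A = factor(c(1, 1), levels = 1:2))
  bn <- fit_cpts_mle(new_dag("A"), d)
  d_new <- data.frame(A = factor(2, levels = 1:2))
  expect_warning(ll <- loglik_bits(bn, d_new), "zero-probability")
  expect_equal(ll, Inf)
})

test_that("DAG validation rejects cycles, self-arcs and duplicates", {
  expect_error(new_dag(c("A", "B"),
                       data.frame(p = c("A", "B"), c = c("B", "A"))), "cycle")
  expect_error(new_dag("A", data.frame(p = "A", c = "A")), "self")
  expect_error(new_dag(c("A", "B"),
                       data.frame(p = c("A", "A"), c = c("B", "B"))),
               "duplicate")
})

test_that("sampling respects the generating distribution", {
  bn <- random_discrete_bn(3, 2, arity = 2, strength = 0.9, seed = 3)
  d <- sample_bn(bn, 4000, seed = 4)
  target <- bn$dag$nodes[3]
  j <- brute_joint(bn)
  marg <- tapply(j$p, j[[target]], sum)
  emp <- prop.table(table(d[[target]]))
  expect_equal(as.numeric(emp), as.numeric(marg), tolerance = 0.05)
})
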