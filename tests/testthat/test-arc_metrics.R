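test_that("mutual information matches closed forms and the brute-force double sum", {
  # independent uniform table -> 0 bits
  x <- rep(1:2, each = 50); y <- rep(1:2, times = 50)
  expect_equal(mutual_information(x, y), 0)
  # diagonal table with uniform margins -> 1 bit
  expect_equal(mutual_information(x, x), 1)
  withr::with_seed(20, {
    for (rep in 1:10) {
      a <- sample(1:3, 80, TRUE); b <- sample(1:4, 80, TRUE)
      expect_equal(mutual_information(a, b), brute_mi(a, b), tolerance = 1e-12)
      z <- sample(1:2, 80, TRUE)
      expect_equal(mutual_information(a, b, z), brute_cmi(a, b, z),
                   tolerance = 1e-12)
    }
  })
})

test_that("G statistic is 2 N ln2 MI and matches the cell-by-cell formula", {
  # [[25,25],[25,25]] -> G = 0, p = 1
  x <- rep(1:2, each = 50); y <- rep(1:2, times = 50)
  g0 <- g_test(x, y)
  expect_equal(g0$g_stat, 0)
  expect_equal(g0$p_value, 1)
  # [[40,10],[10,40]] -> classical G = 2 sum O ln(O/E)
  x2 <- rep(1:2, each = 50)
  y2 <- c(rep(1, 40), rep(2, 10), rep(1, 10), rep(2, 40))
  gt <- g_test(x2, y2)
  O <- table(x2, y2)
  E <- outer(rowSums(O), colSums(O)) / 100
  expect_equal(gt$g_stat, 2 * sum(O * log(O / E)), tolerance = 1e-9)
  expect_equal(gt$df, 1L)
  expect_error(g_test(rep(1, 10), rep(1:2, 5)), "df = 0")
})

test_that("KL arc force: both routes agree and closed forms hold", {
  # deterministic copy of a uniform binary parent -> 1 bit
  d <- data.frame(A = factor(rep(1:2, 40)), B = factor(rep(1:2, 40)))
  dag <- new_dag(c("A", "B"), data.frame(p = "A", c = "B"))
  bn <- fit_cpts_mle(dag, d)
  expect_equal(arc_force_kl(bn, c("A", "B"), d), 1)
  expect_equal(arc_force_kl(bn, c("A", "B"), d, method = "refit"), 1,
               tolerance = 1e-9)
  # random network: conditional-MI route equals refit route for every arc
  bn2 <- random_discrete_bn(4, 4, arity = 3, seed = 55)
  d2 <- sample_bn(bn2, 150, seed = 56)
  bn2f <- fit_cpts_mle(new_dag(names(d2), tidy(bn2)), d2)
  arcs <- dag_arcs(bn2f$dag)
  for (i in seq_len(nrow(arcs))) {
    arc <- c(arcs$parent[i], arcs$child[i])
    expect_equal(arc_force_kl(bn2f, arc, d2),
                 arc_force_kl(bn2f, arc, d2, method = "refit"),
                 tolerance = 1e-9)
  }
  # independent variables -> force near 0
  withr::with_seed(57, {
    d3 <- data.frame(A = factor(sample(1:2, 400, TRUE)),
                     B = factor(sample(1:2, 400, TRUE)))
  })
  bn3 <- fit_cpts_mle(new_dag(c("A", "B"), data.frame(p = "A", c = "B")), d3)
  expect_lt(arc_force_kl(bn3, c("A", "B"), d3), 0.02)
})

test_that("KL force is invariant under category relabeling", {
  withr::with_seed(60, {
    a <- sample(1:3, 100, TRUE)
    b <- (a + sample(0:1, 100, TRUE)) %% 3 + 1
  })
  d <- data.frame(A = factor(a), B = factor(b))
  dag <- new_dag(c("A", "B"), data.frame(p = "A", c = "B"))
  kl1 <- arc_force_kl(fit_cpts_mle(dag, d), c("A", "B"), d)
  # relabel: swap categories 1 and 3 of A
  d2 <- d
  d2$A <- factor(c(3, 2, 1)[a])
  kl2 <- arc_force_kl(fit_cpts_mle(dag, d2), c("A", "B"), d2)
  expect_equal(kl1, kl2, tolerance = 1e-12)
})

test_that("removing an arc changes total MLE loglik by N times its KL force", {
  bn0 <- random_discrete_bn(5, 5, arity = 2, seed = 70)
  d <- sample_bn(bn0, 200, seed = 71)
  dag <- new_dag(names(d), tidy(bn0))
  bn <- fit_cpts_mle(dag, d)
  arcs <- dag_arcs(dag)
  arc <- c(arcs$parent[1], arcs$child[1])
  kl <- arc_force_kl(bn, arc, d)
  dag2 <- dag
  dag2$parents[[arc[2]]] <- setdiff(dag2$parents[[arc[2]]], arc[1])
  bn2 <- fit_cpts_mle(dag2, d)
  expect_equal(loglik_bits(bn2, d) - loglik_bits(bn, d), 200 * kl,
               tolerance = 1e-9)
})

test_that("the arc report reproduces column-wise recomputation and ranks by KL", {
  bn0 <- random_discrete_bn(5, 5, arity = 3, seed = 80)
  d <- sample_bn(bn0, 150, seed = 81)
  dag <- new_dag(names(d), tidy(bn0))
  bn <- fit_cpts_mle(dag, d)
  raw <- matrix(rnorm(150 * 5), 150, 5, dimnames = list(NULL, names(d)))
  rep_tab <- arc_report(bn, d, raw_values = raw)
  expect_true(all(diff(rep_tab$kl) <= 1e-12))
  cm <- micropsem:::as_cat_matrix(d)
  for (i in seq_len(nrow(rep_tab))) {
    pa <- rep_tab$parent[i]; ch <- rep_tab$child[i]
    others <- setdiff(dag$parents[[ch]], pa)
    z <- if (length(others)) cm$m[, others, drop = FALSE] else NULL
    expect_equal(rep_tab$kl[i], mutual_information(cm$m[, pa], cm$m[, ch], z))
    expect_equal(rep_tab$pearson_r[i], cor(raw[, pa], raw[, ch]))
  }
  # a deterministic copy arc tops the report with r = 1
  d2 <- data.frame(A = factor(rep(1:2, 75)), B = factor(rep(1:2, 75)))
  raw2 <- cbind(A = as.numeric(d2$A), B = as.numeric(d2$A))
  bn2 <- fit_cpts_mle(new_dag(c("A", "B"), data.frame(p = "A", c = "B")), d2)
  r2 <- arc_report(bn2, d2, raw2)
  expect_equal(r2$pearson_r[1], 1)
  expect_true(r2$significant[1])
})

test_that("Pearson column excludes zero-marked entries pairwise", {
  withr::with_seed(90, {
    x <- rnorm(60); y <- x + rnorm(60, 0, 0.1)
    xm <- x; xm[1:10] <- NA
  })
  d <- data.frame(A = factor(rep(1:2, 30)), B = factor(rep(1:2, 30)))
  bn <- fit_cpts_mle(new_dag(c("A", "B"), data.frame(p = "A", c = "B")), d)
  raw <- cbind(A = xm, B = y)
  r <- arc_report(bn, d, raw)$pearson_r[1]
  expect_equal(r, cor(xm[11:60], y[11:60]))
})
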