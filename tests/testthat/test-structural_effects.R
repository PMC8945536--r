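# effects machinery on hand-built CPTs (closed-form oracles) plus the
# cross-validated classifier; full mediation patterns live in
# test-acceptance.R

# hand-built network: S (3 cats, reps 1/2/3) -> T (2 cats, reps 0/10) with
# E[T | S = s] = 10 * P(T = 2 | s) = slope * rep(s); optional extra parent.
linear_bn <- function(slope = 0.8, prior_s = c(0.2, 0.5, 0.3)) {
  dag <- new_dag(c("S", "T"), data.frame(p = "S", c = "T"))
  cpt_s <- array(prior_s, 3, dimnames = list(S = as.character(1:3)))
  p2 <- slope * (1:3) / 10
  cpt_t <- array(rbind(1 - p2, p2), c(2, 3),
                 dimnames = list(T = c("1", "2"), S = as.character(1:3)))
  bn <- list(dag = dag, cpts = list(S = cpt_s, T = cpt_t),
             arities = c(S = 3L, T = 2L),
             levels = list(S = as.character(1:3), T = c("1", "2")),
             N = 0L, pseudocount = 0)
  class(bn) <- "discrete_bn"
  bn
}
lin_reps <- list(S = c(1, 2, 3), T = c(0, 10))

test_that("total and direct effects match the closed-form slope on a linear family", {
  bn <- linear_bn(slope = 0.8)
  te <- total_effect(bn, "S", "T", delta = 0.1, reps = lin_reps)
  expect_equal(te$total_effect, 0.8, tolerance = 0.01)
  de <- direct_effect(bn, "S", "T", reps = lin_reps)
  expect_equal(de$direct_effect, 0.8, tolerance = 1e-9)
  # local linearity: two perturbation sizes agree
  te2 <- total_effect(bn, "S", "T", delta = 0.05, reps = lin_reps)
  expect_equal(te$total_effect, te2$total_effect, tolerance = 0.05 * 0.8)
  # standardized effect follows its definition
  p0 <- query(bn, "S"); pt <- query(bn, "T")
  sd_s <- sqrt(sum(p0 * (1:3)^2) - sum(p0 * (1:3))^2)
  et <- sum(pt * c(0, 10))
  sd_t <- sqrt(sum(pt * c(0, 10)^2) - et^2)
  expect_equal(te$standardized_total, te$total_effect * sd_s / sd_t,
               tolerance = 1e-9)
})

test_that("standardized total is invariant to affine rescaling of target representatives", {
  bn <- linear_bn(slope = 0.6)
  s1 <- total_effect(bn, "S", "T", reps = lin_reps)$standardized_total
  s2 <- total_effect(bn, "S", "T",
                     reps = list(S = c(1, 2, 3),
                                 T = 5 + 3 * c(0, 10)))$standardized_total
  expect_equal(s1, s2, tolerance = 1e-9)
})

test_that("effects vanish where graph structure dictates", {
  # no directed path and no common ancestor: total ~ 0, direct = 0 exactly
  dag <- new_dag(c("A", "B"))
  d <- data.frame(A = factor(rep(1:2, 30)), B = factor(rep(1:3, 20)))
  bn <- fit_cpts_mle(dag, d, pseudocount = 0.5)
  reps <- list(A = c(0, 1), B = c(1, 2, 3))
  expect_lt(abs(total_effect(bn, "A", "B", reps = reps)$total_effect), 1e-6)
  expect_identical(direct_effect(bn, "A", "B", reps = reps)$direct_effect, 0)
  # mediation chain S -> M -> T: direct(S, T) = 0 while total != 0
  dagm <- new_dag(c("S", "M", "T"),
                  data.frame(p = c("S", "M"), c = c("M", "T")))
  withr::with_seed(200, {
    s <- sample(1:2, 400, TRUE)
    m <- ifelse(runif(400) < 0.9, s, 3 - s)
    t_ <- ifelse(runif(400) < 0.9, m, 3 - m)
  })
  dm <- data.frame(S = factor(s), M = factor(m), T = factor(t_))
  bnm <- fit_cpts_mle(dagm, dm, pseudocount = 0.5)
  repsm <- list(S = c(0, 1), M = c(0, 1), T = c(0, 1))
  expect_identical(direct_effect(bnm, "S", "T", reps = repsm)$direct_effect, 0)
  expect_gt(abs(total_effect(bnm, "S", "T", reps = repsm)$total_effect), 0.3)
  # degenerate single-category source errors
  d1 <- data.frame(S = factor(rep(1, 20), levels = "1"),
                   T = factor(rep(1:2, 10)))
  bn1 <- fit_cpts_mle(new_dag(c("S", "T")), d1, pseudocount = 0.5)
  expect_error(total_effect(bn1, "S", "T",
                            reps = list(S = 1, T = c(0, 1))), "degenerate")
})

test_that("direct effect adjusts for the other parents (weighted per-configuration slope)", {
  # T has parents S and Z; E[T | S, Z] = 2 * rep(S) + 5 * rep(Z)
  dag <- new_dag(c("S", "Z", "T"),
                 data.frame(p = c("S", "Z"), c = c("T", "T")))
  cpt_s <- array(c(0.4, 0.6), 2, dimnames = list(S = c("1", "2")))
  cpt_z <- array(c(0.5, 0.5), 2, dimnames = list(Z = c("1", "2")))
  # T in {0,10}: P(T=2 | s,z) = (2*s + 5*z)/10 with reps S=1:2, Z=0:1,
  # so E[T | s, z] = 2*s + 5*z exactly
  pt2 <- function(s, z) (2 * s + 5 * z) / 10
  cpt_t <- array(0, c(2, 2, 2),
                 dimnames = list(T = c("1", "2"), S = c("1", "2"),
                                 Z = c("1", "2")))
  for (s in 1:2) for (z in 1:2) {
    cpt_t[, s, z] <- c(1 - pt2(s, z - 1), pt2(s, z - 1))
  }
  bn <- list(dag = dag, cpts = list(S = cpt_s, Z = cpt_z, T = cpt_t),
             arities = c(S = 2L, Z = 2L, T = 2L),
             levels = list(S = c("1", "2"), Z = c("1", "2"),
                           T = c("1", "2")),
             N = 0L, pseudocount = 0)
  class(bn) <- "discrete_bn"
  reps <- list(S = c(1, 2), Z = c(0, 1), T = c(0, 10))
  expect_equal(direct_effect(bn, "S", "T", reps = reps)$direct_effect, 2,
               tolerance = 1e-9)
  expect_equal(direct_effect(bn, "Z", "T", reps = reps)$direct_effect, 5,
               tolerance = 1e-9)
})

test_that("rank-statistic AUC equals trapezoidal ROC integration (dual route)", {
  withr::with_seed(210, {
    for (rep in 1:20) {
      n <- 60
      labels <- sample(c(TRUE, FALSE), n, TRUE)
      scores <- rnorm(n, mean = ifelse(labels, 0.5, 0))
      if (rep %% 2 == 0) scores <- round(scores, 1) # force ties
      expect_equal(micropsem:::auc_rank(scores, labels),
                   trapezoid_auc(scores, labels), tolerance = 1e-9)
    }
  })
})

test_that("cross-validated AUC separates a predictive target and not a shuffled one", {
  withr::with_seed(220, {
    z <- sample(1:3, 240, TRUE)
    noisy <- function() factor(ifelse(runif(240) < 0.9, z, sample(1:3, 240, TRUE)))
    d <- tibble::tibble(weight = factor(z), X1 = noisy(), X2 = noisy())
    auc <- crossval_target_auc(d, target = "weight", folds = 5,
                               config = mdl_config(n_restarts = 0), seed = 1)
    expect_gt(attr(auc, "macro_auc"), 0.9)
    d_null <- d
    d_null$weight <- factor(sample(as.integer(d$weight)))
    auc0 <- crossval_target_auc(d_null, target = "weight", folds = 5,
                                config = mdl_config(n_restarts = 0), seed = 1)
    expect_lt(abs(attr(auc0, "macro_auc") - 0.5), 0.08)
  })
})

test_that("bagged structural learning degenerates to plain search at n_boot = 1", {
  withr::with_seed(230, {
    a <- sample(1:2, 150, TRUE)
    b <- ifelse(runif(150) < 0.9, a, 3 - a)
    d <- tibble::tibble(A = factor(a), B = factor(b),
                        C = factor(sample(1:2, 150, TRUE)))
  })
  sm <- learn_structural_model(d, sc = 1, n_boot = 1, freq_threshold = 1,
                               config = mdl_config(n_restarts = 0), seed = 1)
  plain <- tabu_search(d, mdl_config(sc = 1, n_restarts = 0, seed = 1))
  expect_equal(dag_arcs(sm$dag), dag_arcs(plain))
  expect_true(all(sm$arc_freq$frequency >= 0 & sm$arc_freq$frequency <= 1))
  # final arc set contains the prior arcs
  sm2 <- learn_structural_model(d, sc = 1, n_boot = 10, freq_threshold = 0.5,
                                config = mdl_config(n_restarts = 0), seed = 2)
  prior <- sm2$config$prior_arcs
  if (!is.null(prior) && nrow(prior)) {
    final <- paste(dag_arcs(sm2$dag)$parent, dag_arcs(sm2$dag)$child)
    expect_true(all(paste(prior$parent, prior$child) %in% final))
  }
})

test_that("bootstrap CIs flag a strong effect and cover zero for noise", {
  withr::with_seed(240, {
    s <- sample(1:3, 200, TRUE)
    t_ <- pmin(3, pmax(1, s + sample(c(-1, 0, 1), 200, TRUE,
                                     prob = c(0.1, 0.8, 0.1))))
    noise <- sample(1:2, 200, TRUE)
    d <- tibble::tibble(S = factor(s), T = factor(t_), U = factor(noise))
  })
  sdat <- structure(list(
    data = d,
    reps = list(S = c(1, 2, 3), T = c(1, 2, 3), U = c(0, 1)),
    binnings = list()), class = "structural_dataset")
  sm <- learn_structural_model(sdat, sc = 1, n_boot = 1, freq_threshold = 1,
                               config = mdl_config(n_restarts = 0), seed = 1)
  eff <- effect_significance(sm, target = "T", n_boot = 60, seed = 5)
  s_row <- eff[eff$source == "S", ]
  u_row <- eff[eff$source == "U", ]
  expect_true(s_row$total_significant)
  expect_false(u_row$total_significant)
  expect_s3_class(autoplot(eff), "ggplot")
})
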