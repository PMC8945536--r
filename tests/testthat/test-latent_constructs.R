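# measurement-part machinery on small constructed cases; full-scale
# recovery lives in test-acceptance.R

test_that("clustering respects connectivity, the size cap and the MI floor", {
  withr::with_seed(100, {
    # two disconnected 3-variable blocks of mutual copies
    z1 <- sample(1:3, 200, TRUE); z2 <- sample(1:3, 200, TRUE)
    noisy <- function(z) factor(ifelse(runif(200) < 0.9, z, sample(1:3, 200, TRUE)))
    d <- data.frame(A1 = noisy(z1), A2 = noisy(z1), A3 = noisy(z1),
                    B1 = noisy(z2), B2 = noisy(z2), B3 = noisy(z2))
  })
  dag <- new_dag(names(d), data.frame(
    p = c("A1", "A2", "B1", "B2"), c = c("A2", "A3", "B2", "B3")))
  cl <- cluster_variables(dag, d)
  expect_length(cl$clusters, 2)
  expect_setequal(cl$clusters[[1]], c("A1", "A2", "A3"))
  expect_setequal(cl$clusters[[2]], c("B1", "B2", "B3"))
  # size cap: a 12-variable connected chain of copies splits into >= 2 clusters
  withr::with_seed(101, {
    z <- sample(1:2, 300, TRUE)
    d12 <- as.data.frame(lapply(1:12, function(i) {
      factor(ifelse(runif(300) < 0.95, z, 3 - z))
    }))
    names(d12) <- paste0("V", 1:12)
  })
  dag12 <- new_dag(names(d12), data.frame(p = paste0("V", 1:11),
                                          c = paste0("V", 2:12)))
  cl12 <- cluster_variables(dag12, d12, max_size = 10)
  expect_gte(length(cl12$clusters), 2)
  expect_true(all(vapply(cl12$clusters, length, 1L) <= 10))
  # partition property
  expect_setequal(unlist(cl12$clusters), names(d12))
})

test_that("latent naive Bayes recovers a planted hidden coin", {
  withr::with_seed(110, {
    z <- sample(1:2, 500, TRUE)
    flip <- function(z) ifelse(runif(500) < 0.95, z, 3 - z)
    d <- data.frame(M1 = factor(flip(z)), M2 = factor(flip(z)),
                    M3 = factor(flip(z)))
  })
  nb <- fit_latent_naive_bayes(d, n_states = 2, seed = 1)
  # member CPT columns close to (0.95, 0.05) / (0.05, 0.95) up to label swap
  p11 <- nb$cpts$M1[1, 1]
  expected <- if (p11 > 0.5) c(0.95, 0.05) else c(0.05, 0.95)
  expect_lt(max(abs(unname(nb$cpts$M1[, 1]) - expected)), 0.05)
  expect_lt(max(abs(unname(nb$cpts$M2[, 2]) - rev(expected))), 0.05)
  # EM objective is non-decreasing
  expect_true(all(diff(nb$objective) >= -1e-6))
  # the recovered state tracks the planted coin for almost every sample
  post <- micropsem:::nb_posterior(nb, d)
  map <- max.col(post)
  expect_gt(abs(cor(map, z)), 0.9)
})

test_that("purity is 100 for deterministic members and ~50 for an uninformative latent", {
  d <- data.frame(M1 = factor(rep(1:2, 50)), M2 = factor(rep(1:2, 50)))
  nb <- fit_latent_naive_bayes(d, n_states = 2, seed = 1)
  expect_gt(purity(nb, d), 99)
  flat <- list(prior = c(0.5, 0.5),
               cpts = list(M1 = matrix(0.5, 2, 2), M2 = matrix(0.5, 2, 2)),
               members = c("M1", "M2"), n_states = 2)
  expect_equal(purity(flat, d), 50)
})

test_that("contingency-table fit matches hand-computed entropies", {
  withr::with_seed(120, {
    z <- sample(1:2, 400, TRUE)
    flip <- function() ifelse(runif(400) < 0.9, z, 3 - z)
    d <- data.frame(M1 = factor(flip()), M2 = factor(flip()),
                    M3 = factor(flip()))
  })
  nb <- fit_latent_naive_bayes(d, n_states = 2, seed = 2)
  ctf <- contingency_table_fit(nb, d)
  # oracle: entropies via explicit tabulation
  h <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  h_ind <- sum(vapply(d, function(col) h(prop.table(table(col))), numeric(1)))
  h_joint <- h(prop.table(table(do.call(paste, d))))
  m <- micropsem:::as_cat_matrix(d)$m
  pnb <- rep(0, 400)
  for (s in 1:2) {
    ps <- nb$prior[s]
    for (j in 1:3) ps <- ps * nb$cpts[[j]][m[, j], s]
    pnb <- pnb + ps
  }
  h_nb <- -mean(log2(pnb))
  expect_equal(ctf, 100 * (h_ind - h_nb) / (h_ind - h_joint), tolerance = 1e-9)
  expect_gt(ctf, 70) # naive-Bayes-generated data, large N
  # independent members: CTF undefined
  d_ind <- data.frame(M1 = factor(rep(1:2, each = 8)),
                      M2 = factor(rep(1:2, times = 8)))
  nb2 <- fit_latent_naive_bayes(d_ind, n_states = 2, seed = 3)
  expect_warning(val <- contingency_table_fit(nb2, d_ind), "independent")
  expect_true(is.na(val))
})

test_that("construct weights, state order and scores follow their definitions", {
  withr::with_seed(130, {
    z <- sample(1:2, 300, TRUE)
    d <- data.frame(
      M1 = factor(ifelse(runif(300) < 0.97, z, 3 - z)), # strongest member
      M2 = factor(ifelse(runif(300) < 0.8, z, 3 - z)),
      M3 = factor(ifelse(runif(300) < 0.7, z, 3 - z))
    )
  })
  cont <- cbind(M1 = rnorm(300, as.integer(d$M1)),
                M2 = rnorm(300, as.integer(d$M2)),
                M3 = rnorm(300, as.integer(d$M3)))
  binnings <- list(
    M1 = kmeans_discretize(cont[, 1], 2, variable = "M1"),
    M2 = kmeans_discretize(cont[, 2], 2, variable = "M2"),
    M3 = kmeans_discretize(cont[, 3], 2, variable = "M3")
  )
  cl <- structure(list(clusters = list(c("M1", "M2", "M3")), trace = tibble::tibble()),
                  class = "variable_clustering")
  cs <- build_constructs(cl, d, cont, binnings, n_states = 2, seed = 1)
  lc <- cs$constructs$LC0
  # exactly one weight equals 1 and it is the strongest member
  expect_equal(unname(lc$weights["M1"]), 1)
  expect_true(all(lc$weights > 0 & lc$weights <= 1))
  expect_lt(max(lc$weights[c("M2", "M3")]), 1)
  # scores are the weighted average of member values
  w <- lc$weights[c("M1", "M2", "M3")]
  expect_equal(lc$scores, as.numeric(cont %*% w / sum(w)))
  # canonical state order: higher latent state implies higher member means
  em <- vapply(1:2, function(s) sum(lc$nb$cpts$M1[, s] *
                                      binnings$M1$representatives), numeric(1))
  expect_true(em[1] < em[2])
})

test_that("hand-checked weighted score arithmetic", {
  # equal weights, members (-2, -4) -> -3; weights (1, .5), members (0, -3) -> -1
  cont <- cbind(A = c(-2, 0), B = c(-4, -3))
  expect_equal(micropsem:::weighted_scores(c("A", "B"), cont,
                                           c(A = 1, B = 1)),
               c(-3, -1.5))
  expect_equal(micropsem:::weighted_scores(c("A", "B"), cont,
                                           c(A = 1, B = 0.5))[2], -1)
  # single member: score equals the member value
  expect_equal(micropsem:::weighted_scores("A", cont, c(A = 1)), cont[, "A"])
  # zero marks enter one unit below the member's observed support
  cont_na <- cbind(A = c(NA, -2, -4))
  expect_equal(micropsem:::weighted_scores("A", cont_na, c(A = 1)),
               c(-5, -2, -4))
})

test_that("single-member clusters make the latent a copy of the member", {
  d <- data.frame(M1 = factor(c(1, 1, 2, 2, 3, 3)))
  cont <- cbind(M1 = c(-3, -3, -2, -2, -1, -1))
  binnings <- list(M1 = kmeans_discretize(cont[, 1], 3, variable = "M1"))
  cl <- structure(list(clusters = list("M1"), trace = tibble::tibble()),
                  class = "variable_clustering")
  cs <- build_constructs(cl, d, cont, binnings, seed = 1)
  lc <- cs$constructs$LC0
  expect_equal(lc$purity, 100)
  expect_equal(lc$scores, cont[, "M1"])
})

test_that("jackknife correspondence is 100 for stable clusters and low for noise", {
  withr::with_seed(140, {
    z1 <- sample(1:2, 240, TRUE); z2 <- sample(1:2, 240, TRUE)
    mk <- function(z) factor(ifelse(runif(240) < 0.95, z, 3 - z))
    d <- data.frame(A1 = mk(z1), A2 = mk(z1), A3 = mk(z1),
                    B1 = mk(z2), B2 = mk(z2), B3 = mk(z2))
  })
  cfg <- mdl_config(sc = 1, n_restarts = 0)
  dag <- tabu_search(d, cfg)
  ref <- cluster_variables(dag, d)
  st <- jackknife_cluster_stability(d, cfg, ref, folds = 5, seed = 1)
  expect_true(all(st$mean_correspondence >= 0 & st$mean_correspondence <= 100))
  expect_gt(attr(st, "overall_mean"), 90) # near-noiseless planted clusters
  # greedy matching oracle on a tiny hand case
  ref_cl <- list(c("a", "b", "c"), c("d", "e"))
  oth_cl <- list(c("a", "b"), c("c", "d", "e"))
  corr <- micropsem:::cluster_correspondence(ref_cl, oth_cl)
  expect_equal(corr, c(100 * 2 / 3, 100))
})
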