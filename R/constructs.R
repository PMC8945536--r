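# Measurement part of the pSEM: cluster taxa along the learned network,
# fit one latent naive-Bayes variable per cluster, score the fit (purity,
# contingency-table fit, jackknife stability) and emit per-sample
# construct scores as MI-weighted averages of member values.

#' Cluster variables along a network skeleton
#'
#' Agglomerative merging restricted to cluster pairs connected in the
#' network's skeleton; merge priority is the average symmetrized pairwise
#' mutual information between members, merging stops when no allowed merge
#' keeps the size cap and clears the MI floor.  Variables disconnected from
#' everything stay singleton clusters.
#'
#' @param dag The learned `dag` over the variables.
#' @param data Categorical data (factors / integer codes) covering the
#'   variables.
#' @param max_size Maximum cluster size (default 10).
#' @param mi_floor Minimum average pairwise MI (bits) for a merge, default
#'   0.02.
#' @return A `variable_clustering`: list of member-name vectors plus a
#'   merge trace tibble.
#' @export
cluster_variables <- function(dag, data, max_size = 10, mi_floor = 0.02) {
  cm <- as_cat_matrix(data)
  vars <- dag$nodes
  p <- length(vars)
  # symmetric MI matrix
  mi <- matrix(0, p, p, dimnames = list(vars, vars))
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    mi[i, j] <- mi[j, i] <- mutual_information(cm$m[, vars[i]], cm$m[, vars[j]])
  }
  adj <- dag_to_adj(dag)
  skel <- adj | t(adj)
  clusters <- as.list(vars)
  trace <- list()
  repeat {
    k <- length(clusters)
    best <- NULL; best_mi <- -Inf
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (length(clusters[[i]]) + length(clusters[[j]]) > max_size) next
      if (!any(skel[clusters[[i]], clusters[[j]]])) next
      m_ij <- mean(mi[clusters[[i]], clusters[[j]]])
      if (m_ij > best_mi + 1e-12) { best_mi <- m_ij; best <- c(i, j) }
    }
    if (is.null(best) || best_mi < mi_floor) break
    trace[[length(trace) + 1]] <- tibble(
      merged_a = paste(clusters[[best[1]]], collapse = "+"),
      merged_b = paste(clusters[[best[2]]], collapse = "+"),
      mean_mi = best_mi)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best[2]]
  }
  # stable order: by first member's position in `vars`
  ord <- order(vapply(clusters, function(cl) match(cl[1], vars), 1L))
  structure(list(clusters = clusters[ord],
                 trace = bind_rows(trace) %||% tibble()),
            class = "variable_clustering")
}

#' @export
print.variable_clustering <- function(x, ...) {
  cat("<variable_clustering> ", length(x$clusters), " clusters, sizes: ",
      paste(vapply(x$clusters, length, 1L), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.variable_clustering <- function(x, ...) {
  tibble(cluster = rep(seq_along(x$clusters) - 1L,
                       vapply(x$clusters, length, 1L)),
         variable = unlist(x$clusters, use.names = FALSE))
}

# ---- latent naive Bayes -------------------------------------------------

#' Fit a latent naive-Bayes model over cluster members by EM
#'
#' One hidden categorical parent with `n_states` states; members are
#' conditionally independent given the state.  EM is run from
#' `n_em_restarts` random responsibility initializations and the best
#' penalized log-likelihood wins.  A small pseudocount keeps CPTs off the
#' boundary.
#'
#' @param member_data Categorical data over the members only.
#' @param n_states Latent arity (>= 2).
#' @param seed RNG seed.
#' @param n_em_restarts Number of EM restarts (default 5).
#' @param max_iter,tol EM stopping controls.
#' @param pseudocount M-step smoothing (default 0.5).
#' @return List: `prior` (length `n_states`), `cpts` (per member,
#'   arity x n_states matrices of P(member | state)), `loglik`, `objective`
#'   trace, `arities`, `levels`.
#' @export
fit_latent_naive_bayes <- function(member_data, n_states = 3, seed = 1L,
                                   n_em_restarts = 5, max_iter = 200,
                                   tol = 1e-7, pseudocount = 0.5) {
  cm <- as_cat_matrix(member_data)
  m <- cm$m
  N <- nrow(m); p <- ncol(m)
  if (p < 1) abort("need at least one member")
  if (n_states < 2) abort("n_states must be >= 2")
  best <- NULL
  for (r in seq_len(n_em_restarts)) {
    fit <- with_seed(seed + r - 1, em_nb_once(m, cm$arities, n_states,
                                              max_iter, tol, pseudocount))
    if (is.null(best) || fit$loglik > best$loglik + 1e-9) best <- fit
  }
  best$arities <- cm$arities
  best$levels <- cm$levels
  best$members <- colnames(m)
  best$n_states <- n_states
  best
}

em_nb_once <- function(m, arities, S, max_iter, tol, pseudocount) {
  N <- nrow(m); p <- ncol(m)
  # random soft init
  R <- matrix(stats::rexp(N * S), N, S)
  R <- R / rowSums(R)
  obj_trace <- numeric(0)
  prev <- -Inf
  for (it in seq_len(max_iter)) {
    # M step (smoothed)
    prior <- (colSums(R) + pseudocount) / (N + S * pseudocount)
    cpts <- lapply(seq_len(p), function(j) {
      a <- arities[j]
      cnt <- matrix(pseudocount, a, S)
      for (c in seq_len(a)) {
        idx <- m[, j] == c
        if (any(idx)) cnt[c, ] <- cnt[c, ] + colSums(R[idx, , drop = FALSE])
      }
      sweep(cnt, 2, colSums(cnt), "/")
    })
    # E step
    logp <- matrix(log(prior), N, S, byrow = TRUE)
    for (j in seq_len(p)) logp <- logp + log(cpts[[j]][m[, j], , drop = FALSE])
    mx <- apply(logp, 1, max)
    lse <- mx + log(rowSums(exp(logp - mx)))
    R <- exp(logp - lse)
    ll <- sum(lse)
    obj_trace <- c(obj_trace, ll)
    if (ll - prev < tol * max(1, abs(ll)) && it > 1) break
    prev <- ll
  }
  if (any(colSums(R) < 1e-8)) {
    # degenerate empty state; caller's restarts usually avoid this
    warning("EM produced a near-empty latent state", call. = FALSE)
  }
  names(cpts) <- colnames(m)
  list(prior = prior, cpts = cpts, loglik = ll, objective = obj_trace,
       resp = R)
}

# posterior P(state | members) for each row
nb_posterior <- function(nb, member_data) {
  cm <- as_cat_matrix(member_data)
  m <- cm$m[, nb$members, drop = FALSE]
  S <- length(nb$prior)
  logp <- matrix(log(nb$prior), nrow(m), S, byrow = TRUE)
  for (j in seq_along(nb$members)) {
    logp <- logp + log(nb$cpts[[nb$members[j]]][m[, j], , drop = FALSE])
  }
  mx <- apply(logp, 1, max)
  R <- exp(logp - mx)
  R / rowSums(R)
}

#' Purity of a latent construct
#'
#' Mean over samples of the maximum posterior state-assignment
#' probability, in percent.
#'
#' @param nb A fitted latent naive-Bayes model (or a `latent_construct`).
#' @param member_data Member data.
#' @return Percentage in (0, 100].
#' @export
purity <- function(nb, member_data) {
  if (inherits(nb, "latent_construct")) nb <- nb$nb
  R <- nb_posterior(nb, member_data)
  100 * mean(apply(R, 1, max))
}

#' Contingency-table fit of a latent construct
#'
#' `100 * (H_indep - H_nb) / (H_indep - H_joint)` where `H_indep` is the
#' sum of member marginal entropies, `H_joint` the empirical joint entropy
#' of the members and `H_nb` the per-sample cross-entropy of the data under
#' the naive-Bayes model (all bits per sample).  Measures how much of the
#' gap between full independence and the empirical joint the latent model
#' closes; clipped to [0, 100].
#'
#' @inheritParams purity
#' @return Percentage in [0, 100], or `NA` (with a warning) when the
#'   members are mutually independent.
#' @export
contingency_table_fit <- function(nb, member_data) {
  if (inherits(nb, "latent_construct")) nb <- nb$nb
  cm <- as_cat_matrix(member_data)
  m <- cm$m[, nb$members, drop = FALSE]
  N <- nrow(m)
  h_indep <- sum(vapply(seq_len(ncol(m)), function(j) {
    entropy_bits(tabulate(m[, j], cm$arities[nb$members[j]]))
  }, numeric(1)))
  key <- apply(m, 1, paste, collapse = "\r")
  h_joint <- entropy_bits(table(key))
  # cross-entropy under the NB model
  S <- length(nb$prior)
  logp <- matrix(log(nb$prior), N, S, byrow = TRUE)
  for (j in seq_along(nb$members)) {
    logp <- logp + log(nb$cpts[[nb$members[j]]][m[, j], , drop = FALSE])
  }
  mx <- apply(logp, 1, max)
  h_nb <- -mean((mx + log(rowSums(exp(logp - mx)))) / log(2))
  denom <- h_indep - h_joint
  if (denom < 1e-9) {
    warning("members are mutually independent; contingency-table fit undefined",
            call. = FALSE)
    return(NA_real_)
  }
  min(100, max(0, 100 * (h_indep - h_nb) / denom))
}

# ---- constructs ---------------------------------------------------------

#' Build latent constructs from a variable clustering
#'
#' For each cluster: fits the latent naive-Bayes model, canonicalizes the
#' state order (states sorted by the MI-weighted mean of member bin
#' representatives, so high states mean high member abundances), computes
#' MI weights (`w_i = MI(member_i; LC) / max_j MI(member_j; LC)`),
#' per-sample scores (weighted average of continuous member values, zero
#' marks entering one unit below the member's observed support), quality
#' metrics, and a discretization of the scores for the structural model.
#'
#' @param clustering A `variable_clustering`.
#' @param disc_data Discretized categorical data over all members.
#' @param cont_values Samples-by-variables continuous matrix (log relative
#'   abundances, `NA` zero marks).
#' @param binnings Named list of `binning` objects per member (for
#'   representatives).
#' @param n_states Latent arity; default `NULL` = modal member arity within
#'   each cluster.
#' @param seed,n_em_restarts EM controls.
#' @param r2_target,k_candidates Passed to [r2_optimal_discretize()] for
#'   score discretization.
#' @return A `construct_set`: list of `latent_construct`s plus a summary
#'   tibble (construct, size, n_states, purity, ctf).
#' @export
build_constructs <- function(clustering, disc_data, cont_values, binnings,
                             n_states = NULL, seed = 1L, n_em_restarts = 5,
                             r2_target = 0.95, k_candidates = 2:5) {
  stopifnot(inherits(clustering, "variable_clustering"))
  cm <- as_cat_matrix(disc_data)
  constructs <- list()
  for (ci in seq_along(clustering$clusters)) {
    members <- clustering$clusters[[ci]]
    id <- paste0("LC", ci - 1)
    lc <- fit_one_construct(id, members, cm, disc_data, cont_values,
                            binnings, n_states, seed + ci, n_em_restarts,
                            r2_target, k_candidates)
    constructs[[id]] <- lc
  }
  summary <- bind_rows(lapply(constructs, function(lc) {
    tibble(construct = lc$id, size = length(lc$members),
           n_states = lc$n_states, purity = lc$purity, ctf = lc$ctf)
  }))
  structure(list(constructs = constructs, summary = summary),
            class = "construct_set")
}

fit_one_construct <- function(id, members, cm, disc_data, cont_values,
                              binnings, n_states, seed, n_em_restarts,
                              r2_target, k_candidates) {
  member_data <- disc_data[, members, drop = FALSE]
  # member numeric representatives per category (zero class one unit below
  # the smallest bin representative)
  reps <- lapply(members, function(v) {
    b <- binnings[[v]]
    r <- b$representatives
    if (b$has_zero_class) c(min(r) - 1, r) else r
  })
  names(reps) <- members
  if (length(members) == 1) {
    # degenerate: the latent equals the member
    v <- members[1]
    codes <- cm$m[, v]
    a <- cm$arities[[v]]
    S <- a
    prior <- tabulate(codes, a) / length(codes)
    cpts <- setNames(list(diag(a)), v)
    nb <- list(prior = prior, cpts = cpts,
               loglik = sum(log(prior[codes])),
               objective = numeric(0), arities = cm$arities[v],
               levels = cm$levels[v], members = v, n_states = S)
    weights <- setNames(1, v)
  } else {
    S <- n_states %||% modal_arity(cm$arities[members])
    nb <- fit_latent_naive_bayes(member_data, n_states = S, seed = seed,
                                 n_em_restarts = n_em_restarts)
    nb <- canonicalize_states(nb, member_data, reps)
    weights <- mi_weights(nb, member_data)
  }
  scores <- weighted_scores(members, cont_values, weights)
  sc_bin <- r2_optimal_discretize(scores, k_candidates = k_candidates,
                                  r2_target = r2_target, variable = id)
  structure(
    list(id = id, members = members, n_states = nb$n_states %||% length(nb$prior),
         nb = nb, weights = weights, scores = scores, score_binning = sc_bin,
         purity = purity(nb, member_data),
         ctf = suppressWarnings(contingency_table_fit(nb, member_data))),
    class = "latent_construct"
  )
}

modal_arity <- function(arities) {
  tab <- table(arities)
  as.integer(names(tab)[which.max(tab)])
}

# order latent states by the MI-weighted mean of member representatives
canonicalize_states <- function(nb, member_data, reps) {
  w <- mi_weights(nb, member_data)
  S <- length(nb$prior)
  state_mean <- vapply(seq_len(S), function(s) {
    vals <- vapply(nb$members, function(v) {
      sum(reps[[v]] * nb$cpts[[v]][, s])
    }, numeric(1))
    sum(w[nb$members] * vals) / sum(w)
  }, numeric(1))
  ord <- order(state_mean)
  nb$prior <- nb$prior[ord]
  nb$cpts <- lapply(nb$cpts, function(cpt) cpt[, ord, drop = FALSE])
  if (!is.null(nb$resp)) nb$resp <- nb$resp[, ord, drop = FALSE]
  nb
}

# MI of each member with the MAP latent assignment, normalized to max 1
mi_weights <- function(nb, member_data) {
  cm <- as_cat_matrix(member_data)
  R <- nb_posterior(nb, member_data)
  assign <- max.col(R, ties.method = "first")
  mis <- vapply(nb$members, function(v) {
    mutual_information(cm$m[, v], assign)
  }, numeric(1))
  mx <- max(mis)
  if (mx <= 0) return(setNames(rep(1, length(mis)), nb$members))
  w <- mis / mx
  pmax(w, 1e-6) # keep weights in (0, 1]
}

weighted_scores <- function(members, cont_values, weights) {
  vals <- cont_values[, members, drop = FALSE]
  for (j in seq_along(members)) {
    v <- vals[, j]
    if (anyNA(v)) {
      fill <- if (all(is.na(v))) 0 else min(v, na.rm = TRUE) - 1
      v[is.na(v)] <- fill
      vals[, j] <- v
    }
  }
  as.numeric(vals %*% weights[members] / sum(weights[members]))
}

#' @export
print.latent_construct <- function(x, ...) {
  cat("<latent_construct> ", x$id, ": ", length(x$members), " members, ",
      x$n_states, " states; purity ", round(x$purity, 1), "%, CTF ",
      round(x$ctf, 1), "%\n", sep = "")
  invisible(x)
}

#' @export
print.construct_set <- function(x, ...) {
  cat("<construct_set> ", length(x$constructs), " latent constructs\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.construct_set <- function(x, ...) {
  bind_rows(lapply(x$constructs, function(lc) {
    tibble(construct = lc$id, member = lc$members,
           weight = unname(lc$weights[lc$members]))
  }))
}

#' @exportS3Method generics::glance
glance.construct_set <- function(x, ...) {
  tibble(n_constructs = length(x$constructs),
         mean_purity = mean(x$summary$purity),
         mean_ctf = mean(x$summary$ctf, na.rm = TRUE))
}

#' Per-sample construct scores
#'
#' @param constructs A `construct_set`.
#' @param sample_ids Optional sample id column.
#' @return Tibble of continuous scores, one column per construct.
#' @export
lc_scores <- function(constructs, sample_ids = NULL) {
  out <- as_tibble(lapply(constructs$constructs, function(lc) lc$scores))
  if (!is.null(sample_ids)) out <- bind_cols(tibble(sample = sample_ids), out)
  out
}

#' Jackknife stability of the variable clustering
#'
#' Drops each of `folds` sample subsets in turn, relearns the network and
#' the clustering, and reports for every reference cluster the percentage
#' correspondence (best greedy-overlap match intersection over reference
#' size).
#'
#' @param data Categorical data.
#' @param config An [mdl_config()] for the per-fold relearn.
#' @param reference A `variable_clustering` on the full data.
#' @param folds Number of jackknife subsets (default 10).
#' @param max_size,mi_floor Passed to [cluster_variables()].
#' @param seed Fold-assignment seed.
#' @return Tibble (cluster, members, mean_correspondence) plus an
#'   `overall_mean` attribute.
#' @export
jackknife_cluster_stability <- function(data, config = mdl_config(),
                                        reference, folds = 10,
                                        max_size = 10, mi_floor = 0.02,
                                        seed = 1L) {
  stopifnot(folds >= 2)
  cm <- as_cat_matrix(data)
  N <- nrow(cm$m)
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), N)))
  ref <- reference$clusters
  corr <- matrix(NA_real_, length(ref), folds)
  for (f in seq_len(folds)) {
    keep <- fold_id != f
    sub <- data[keep, , drop = FALSE]
    dag_f <- tabu_search(sub, config)
    cl_f <- cluster_variables(dag_f, sub, max_size = max_size,
                              mi_floor = mi_floor)
    corr[, f] <- cluster_correspondence(ref, cl_f$clusters)
  }
  out <- tibble(
    cluster = paste0("LC", seq_along(ref) - 1),
    size = vapply(ref, length, 1L),
    mean_correspondence = rowMeans(corr)
  )
  attr(out, "overall_mean") <- mean(corr)
  attr(out, "per_fold") <- corr
  out
}

# greedy maximal-overlap matching; ties broken by (reference id, fold id)
cluster_correspondence <- function(ref, other) {
  ov <- matrix(0L, length(ref), length(other))
  for (i in seq_along(ref)) for (j in seq_along(other)) {
    ov[i, j] <- length(intersect(ref[[i]], other[[j]]))
  }
  res <- numeric(length(ref))
  avail_i <- rep(TRUE, length(ref)); avail_j <- rep(TRUE, length(other))
  repeat {
    sub <- ov
    sub[!avail_i, ] <- -1L
    sub[, !avail_j] <- -1L
    mx <- max(sub)
    if (mx <= 0 || !any(avail_i) || !any(avail_j)) break
    hit <- which(sub == mx, arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    res[i] <- 100 * ov[i, j] / length(ref[[i]])
    avail_i[i] <- FALSE; avail_j[j] <- FALSE
  }
  res
}
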