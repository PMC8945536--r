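# Structural part of the pSEM: the network over {weight class, age, sex,
# compartment, diet, latent-construct scores}, its jackknife ROC
# validation, and the decomposition of each node's influence on the
# target into total and direct effects.

#' Assemble the dataset for the structural model
#'
#' Discretizes weight (exact 1-D k-means) and the construct scores (their
#' own fitted binnings), and encodes the covariates as categories.  Numeric
#' representatives (bin means, age in days, 0/1 codes for binary
#' covariates) are attached so effects can be reported in physical units.
#'
#' @param constructs A `construct_set`.
#' @param metadata Per-sample metadata tibble with `weight_g`, `age_d`,
#'   `sex`, `compartment`, `bsf_pct`.
#' @param weight_k Number of weight classes (default 5).
#' @return A `structural_dataset`: `data` (tibble of factors), `reps`
#'   (named list of numeric representatives per category), `binnings`.
#' @export
assemble_structural_data <- function(constructs, metadata, weight_k = 5) {
  meta <- as_tibble(metadata)
  wb <- kmeans_discretize(meta$weight_g, k = weight_k, variable = "weight")
  cols <- list()
  reps <- list()
  binnings <- list(weight = wb)
  cols$weight <- binning_factor(apply_binning(meta$weight_g, wb), wb)
  reps$weight <- wb$representatives
  ages <- sort(unique(meta$age_d))
  cols$age <- factor(meta$age_d, levels = ages)
  reps$age <- as.numeric(ages)
  cols$sex <- factor(meta$sex)
  reps$sex <- as.numeric(seq_along(levels(cols$sex)) - 1)
  cols$compartment <- factor(meta$compartment)
  reps$compartment <- as.numeric(seq_along(levels(cols$compartment)) - 1)
  bsf <- sort(unique(meta$bsf_pct))
  cols$bsf <- factor(meta$bsf_pct, levels = bsf)
  reps$bsf <- as.numeric(bsf)
  for (id in names(constructs$constructs)) {
    lc <- constructs$constructs[[id]]
    b <- lc$score_binning
    codes <- apply_binning(lc$scores, b)
    cols[[id]] <- binning_factor(codes, b)
    r <- b$representatives
    reps[[id]] <- if (b$has_zero_class) c(min(r) - 1, r) else r
    binnings[[id]] <- b
  }
  structure(list(data = as_tibble(cols), reps = reps, binnings = binnings),
            class = "structural_dataset")
}

#' @export
print.structural_dataset <- function(x, ...) {
  cat("<structural_dataset> ", nrow(x$data), " samples x ", ncol(x$data),
      " nodes (", paste(head(names(x$data), 8), collapse = ", "),
      if (ncol(x$data) > 8) ", ..." else "", ")\n", sep = "")
  invisible(x)
}

#' Learn the structural network by structural-priors bagging
#'
#' Runs one MDL tabu search per bootstrap resample, turns arcs whose
#' inclusion frequency reaches `freq_threshold` into prior arcs (their
#' graph-coding bits are waived), and runs a final full-data search with
#' those priors.
#'
#' @param dataset A `structural_dataset` (or plain categorical data).
#' @param sc Structural coefficient (default 0.45, the low-density
#'   operating point for structural models).
#' @param n_boot Bootstrap resamples (default 100; `1` with threshold 1
#'   reduces to a plain search).
#' @param freq_threshold Arc inclusion frequency needed to become a prior
#'   (default 0.5).
#' @param config Base [mdl_config()]; its `sc` is overridden.
#' @param seed RNG seed for the resamples.
#' @return List of class `structural_model`: `bn` (fitted `discrete_bn`,
#'   pseudocount 0.5), `dag`, `arc_freq` tibble, `config`.
#' @export
learn_structural_model <- function(dataset, sc = 0.45, n_boot = 100,
                                   freq_threshold = 0.5,
                                   config = mdl_config(), seed = 1L) {
  data <- if (inherits(dataset, "structural_dataset")) dataset$data else dataset
  stopifnot(n_boot >= 1, freq_threshold > 0, freq_threshold <= 1)
  cfg <- config
  cfg$sc <- sc
  N <- nrow(data)
  nodes <- names(data)
  freq <- matrix(0, length(nodes), length(nodes),
                 dimnames = list(nodes, nodes))
  for (b in seq_len(n_boot)) {
    idx <- if (n_boot == 1) seq_len(N) else
      with_seed(seed + b, sample.int(N, N, replace = TRUE))
    cfg_b <- cfg
    cfg_b$seed <- seed + b
    dag_b <- tabu_search(data[idx, , drop = FALSE], cfg_b)
    a <- dag_arcs(dag_b)
    if (nrow(a)) freq[cbind(a$parent, a$child)] <-
        freq[cbind(a$parent, a$child)] + 1 / n_boot
  }
  idx <- which(freq > 0, arr.ind = TRUE)
  arc_freq <- tibble(parent = nodes[idx[, 1]], child = nodes[idx[, 2]],
                     frequency = freq[idx])
  arc_freq <- arc_freq[order(-arc_freq$frequency, arc_freq$parent,
                             arc_freq$child), ]
  prior <- arc_freq[arc_freq$frequency >= freq_threshold, c("parent", "child")]
  cfg$prior_arcs <- if (nrow(prior)) prior else NULL
  cfg$seed <- seed
  dag <- tabu_search(data, cfg)
  bn <- fit_cpts_mle(dag, data, pseudocount = 0.5)
  structure(list(bn = bn, dag = dag, arc_freq = arc_freq, config = cfg,
                 dataset = if (inherits(dataset, "structural_dataset")) dataset else NULL),
            class = "structural_model")
}

#' @export
print.structural_model <- function(x, ...) {
  cat("<structural_model> ", length(x$dag$nodes), " nodes, ",
      nrow(dag_arcs(x$dag)), " arcs (sc = ", x$config$sc, ")\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.structural_model <- function(x, ...) {
  left_join(dag_arcs(x$dag), x$arc_freq, by = c("parent", "child"))
}

# ---- cross-validated target classification ------------------------------

# rank-statistic (Mann-Whitney) AUC with midranks for ties
auc_rank <- function(scores, labels) {
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated one-vs-rest ROC AUC for the target node
#'
#' Splits the samples into `folds` subsets; for each fold the network is
#' relearned (plain tabu search with the model's config) and CPTs fitted on
#' the retained samples, the posterior of the target is computed for every
#' held-out sample given all other nodes, and one-vs-rest AUCs are
#' accumulated per target class from the pooled held-out posteriors.
#'
#' @param dataset A `structural_dataset` or categorical data.
#' @param target Target node name (default `"weight"`).
#' @param folds Number of folds (default 10).
#' @param config [mdl_config()] for the per-fold relearn.
#' @param sc Structural coefficient for the per-fold searches.
#' @param seed Fold assignment seed.
#' @return Tibble (class, n, auc) with attribute `macro_auc`; class
#'   `crossval_auc`.
#' @export
crossval_target_auc <- function(dataset, target = "weight", folds = 10,
                                config = mdl_config(), sc = 0.45,
                                seed = 1L) {
  data <- if (inherits(dataset, "structural_dataset")) dataset$data else dataset
  stopifnot(folds >= 2, target %in% names(data))
  cfg <- config
  cfg$sc <- sc
  N <- nrow(data)
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), N)))
  levs <- levels(data[[target]])
  post <- matrix(NA_real_, N, length(levs), dimnames = list(NULL, levs))
  others <- setdiff(names(data), target)
  for (f in seq_len(folds)) {
    train <- data[fold_id != f, , drop = FALSE]
    cfg_f <- cfg
    cfg_f$seed <- seed + f
    dag_f <- tabu_search(train, cfg_f)
    bn_f <- fit_cpts_mle(dag_f, train, pseudocount = 0.5)
    test_idx <- which(fold_id == f)
    for (i in test_idx) {
      ev <- as.list(data[i, others])
      ev <- lapply(ev, as.character)
      post[i, ] <- query(bn_f, target, ev)
    }
  }
  truth <- data[[target]]
  rows <- purrr::map(levs, function(cl) {
    lab <- truth == cl
    if (!any(lab) || all(lab)) {
      warning(paste0("target class '", cl, "' absent from a fold split; skipped"),
              call. = FALSE)
      return(tibble(class = cl, n = sum(lab), auc = NA_real_))
    }
    tibble(class = cl, n = sum(lab), auc = auc_rank(post[, cl], lab))
  })
  out <- bind_rows(rows)
  attr(out, "macro_auc") <- mean(out$auc, na.rm = TRUE)
  attr(out, "posteriors") <- post
  class(out) <- c("crossval_auc", class(out))
  out
}

# ---- effects ------------------------------------------------------------

# numeric representatives of a node's categories
node_reps <- function(dataset, node) {
  r <- dataset$reps[[node]]
  if (is.null(r)) abort(paste0("no numeric representatives for node ", node))
  r
}

# mean/sd of a node under a marginal probability vector
marg_mean <- function(p, reps) sum(p * reps)
marg_sd <- function(p, reps) {
  mu <- sum(p * reps)
  sqrt(max(0, sum(p * reps^2) - mu^2))
}

# minimal-KL soft evidence that shifts a discrete marginal's mean:
# exponential tilting q(s) = p(s) exp(theta * rep_s) / Z, theta solved 1-D
tilt_theta <- function(p, reps, target_mean) {
  rng <- diff(range(reps))
  if (rng == 0) abort("degenerate single-valued node")
  f <- function(th) {
    w <- p * exp(th * (reps - mean(reps)))
    sum(w * reps) / sum(w) - target_mean
  }
  lim <- 500 / rng
  uniroot(f, lower = -lim, upper = lim, tol = 1e-12)$root
}

#' Total effect of a node on the target
#'
#' Applies minimal-KL (exponentially tilted) soft evidence on the source
#' that shifts its posterior mean by `delta` baseline standard deviations,
#' propagates it exactly, and reports the change in the target's
#' expectation per unit change in the source's mean, in target units per
#' source unit.
#'
#' @param model A `structural_model` (or a `discrete_bn` plus `reps`).
#' @param source,target Node names.
#' @param delta Mean shift as a fraction of the source's sd (default 0.1).
#' @param reps Named list of numeric representatives (defaults to the
#'   model's dataset).
#' @return A one-row tibble (source, target, total_effect,
#'   standardized_total).
#' @export
total_effect <- function(model, source, target, delta = 0.1, reps = NULL) {
  bn <- if (inherits(model, "structural_model")) model$bn else model
  if (is.null(reps)) reps <- model$dataset$reps
  stopifnot(source != target)
  rs <- reps[[source]]; rt <- reps[[target]]
  if (is.null(rs) || is.null(rt)) abort("numeric representatives required")
  p0s <- query(bn, source)
  p0t <- query(bn, target)
  sd_s <- marg_sd(p0s, rs)
  if (sd_s <= 0 || length(unique(rs)) < 2) {
    abort(paste0("source '", source, "' has a degenerate marginal"))
  }
  mu0s <- marg_mean(p0s, rs)
  th <- tilt_theta(p0s, rs, mu0s + delta * sd_s)
  lik <- exp(th * (rs - mean(rs)))
  ev <- setNames(list(lik), source)
  p1s <- query(bn, source, ev)
  p1t <- query(bn, target, ev)
  e1s <- marg_mean(p1s, rs)
  total <- (marg_mean(p1t, rt) - marg_mean(p0t, rt)) / (e1s - mu0s)
  tibble(source = source, target = target, total_effect = total,
         standardized_total = total * sd_s / marg_sd(p0t, rt))
}

#' Direct effect of a node on the target
#'
#' Zero by construction when the source is not a parent of the target.
#' Otherwise the other parents are held fixed: for each configuration of
#' the target's other parents, the slope of `E[target | source, config]`
#' against the source's numeric representatives is fitted by weighted least
#' squares (weights `P(source | config)`), and slopes are averaged over
#' `P(config)`.
#'
#' @inheritParams total_effect
#' @return A one-row tibble (source, target, direct_effect).
#' @export
direct_effect <- function(model, source, target, reps = NULL) {
  bn <- if (inherits(model, "structural_model")) model$bn else model
  if (is.null(reps)) reps <- model$dataset$reps
  stopifnot(source != target)
  pa <- bn$dag$parents[[target]]
  if (!source %in% pa) {
    return(tibble(source = source, target = target, direct_effect = 0))
  }
  rs <- reps[[source]]; rt <- reps[[target]]
  others <- setdiff(pa, source)
  cpt <- bn$cpts[[target]] # dims: target, parents (in pa order)
  a_t <- bn$arities[[target]]
  # E[target | parent config] for all configs
  pa_dims <- unname(bn$arities[pa])
  cfg_grid <- as.matrix(expand.grid(lapply(pa_dims, seq_len)))
  colnames(cfg_grid) <- pa
  e_t <- apply(cfg_grid, 1, function(cfg) {
    idx <- cbind(seq_len(a_t), matrix(rep(cfg, each = a_t), a_t))
    sum(rt * cpt[lin_index(idx, c(a_t, pa_dims))])
  })
  # joint of the parents
  jp <- ve_joint(bn, pa)
  p_pa <- jp$tab # dims in pa order
  if (!length(others)) {
    w <- as.numeric(p_pa)
    x <- rs[cfg_grid[, source]]
    return(tibble(source = source, target = target,
                  direct_effect = wls_slope(x, e_t, w)))
  }
  oc <- cond_code(as.data.frame(cfg_grid[, others, drop = FALSE]),
                  nrow(cfg_grid))
  w_all <- as.numeric(p_pa)[lin_index(cfg_grid, pa_dims)]
  slopes <- 0
  for (lev in unique(oc)) {
    sel <- oc == lev
    pc <- sum(w_all[sel])
    if (pc <= 0) next
    x <- rs[cfg_grid[sel, source]]
    sl <- wls_slope(x, e_t[sel], w_all[sel] / pc)
    if (is.na(sl)) sl <- 0
    slopes <- slopes + pc * sl
  }
  tibble(source = source, target = target, direct_effect = slopes)
}

wls_slope <- function(x, y, w) {
  if (sum(w) <= 0) return(NA_real_)
  w <- w / sum(w)
  xb <- sum(w * x); yb <- sum(w * y)
  den <- sum(w * (x - xb)^2)
  if (den <= 0) return(NA_real_)
  sum(w * (x - xb) * (y - yb)) / den
}

#' Total, direct and standardized effects of every node on the target
#'
#' @param model A `structural_model`.
#' @param target Target node (default `"weight"`).
#' @param delta Perturbation size for total effects.
#' @param sources Nodes to evaluate (default all non-target nodes).
#' @return Tibble (source, total_effect, direct_effect,
#'   standardized_total), class `psem_effects`.
#' @export
estimate_effects <- function(model, target = "weight", delta = 0.1,
                             sources = NULL) {
  data_nodes <- model$bn$dag$nodes
  sources <- sources %||% setdiff(data_nodes, target)
  rows <- purrr::map(sources, function(s) {
    te <- total_effect(model, s, target, delta = delta)
    de <- direct_effect(model, s, target)
    tibble(source = s, total_effect = te$total_effect,
           direct_effect = de$direct_effect,
           standardized_total = te$standardized_total)
  })
  out <- bind_rows(rows)
  class(out) <- c("psem_effects", class(out))
  out
}

#' Bootstrap confidence intervals for the effects
#'
#' Nonparametric bootstrap over samples with the structure held fixed at
#' the full-data network; CPTs are refitted per resample and total/direct
#' effects recomputed.  95% percentile intervals; an effect is flagged
#' significant when its interval excludes zero.
#'
#' @param model A `structural_model` (with its dataset attached).
#' @param target Target node.
#' @param n_boot Bootstrap resamples (default 200).
#' @param delta Perturbation size.
#' @param level Confidence level (default 0.95).
#' @param seed RNG seed.
#' @param sources Nodes to evaluate.
#' @return Tibble (source, total_effect, total_lo, total_hi,
#'   total_significant, direct_effect, direct_lo, direct_hi,
#'   direct_significant, standardized_total), class `psem_effects`.
#' @export
effect_significance <- function(model, target = "weight", n_boot = 200,
                                delta = 0.1, level = 0.95, seed = 1L,
                                sources = NULL) {
  stopifnot(inherits(model, "structural_model"), n_boot >= 10)
  data <- model$dataset$data
  reps <- model$dataset$reps
  point <- estimate_effects(model, target = target, delta = delta,
                            sources = sources)
  sources <- point$source
  tot <- matrix(NA_real_, n_boot, length(sources),
                dimnames = list(NULL, sources))
  dir <- tot
  N <- nrow(data)
  # sources with no ancestral overlap with the target are d-separated from
  # it marginally: both effects are exactly zero in every resample
  anc_t <- dag_ancestors(model$dag, target)
  live <- sources[vapply(sources, function(s) {
    length(intersect(dag_ancestors(model$dag, s), anc_t)) > 0
  }, TRUE)]
  tot[, setdiff(sources, live)] <- 0
  dir[, setdiff(sources, live)] <- 0
  for (b in seq_len(n_boot)) {
    idx <- with_seed(seed + b, sample.int(N, N, replace = TRUE))
    bn_b <- fit_cpts_mle(model$dag, data[idx, , drop = FALSE],
                         pseudocount = 0.5)
    for (s in live) {
      tot[b, s] <- tryCatch(
        total_effect(bn_b, s, target, delta = delta, reps = reps)$total_effect,
        error = function(e) NA_real_)
      dir[b, s] <- direct_effect(bn_b, s, target, reps = reps)$direct_effect
    }
  }
  alpha2 <- (1 - level) / 2
  qs <- function(m) apply(m, 2, quantile, probs = c(alpha2, 1 - alpha2),
                          na.rm = TRUE)
  qt <- qs(tot); qd <- qs(dir)
  out <- point
  out$total_lo <- qt[1, sources]; out$total_hi <- qt[2, sources]
  out$total_significant <- out$total_lo > 0 | out$total_hi < 0
  out$direct_lo <- qd[1, sources]; out$direct_hi <- qd[2, sources]
  out$direct_significant <- out$direct_lo > 0 | out$direct_hi < 0
  class(out) <- c("psem_effects", class(out))
  out
}
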