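# Synthetic microbiome generator with known latent structure and known
# mediation.  The stated world mirrors the study design: 90 samples over
# three replicates (cloaca sampled young, caecum at slaughter), three diet
# groups with no effect on anything, age driving both weight and a subset
# of latent constructs, and zero-inflated compositional counts at a fixed
# sequencing depth.

#' Specification of a synthetic microbiome dataset
#'
#' @param n_samples Number of samples (default 90, the study size; the
#'   design table is resampled when it differs).
#' @param n_taxa Number of genera (default 62).
#' @param n_constructs Number of latent constructs (default 10); taxa are
#'   partitioned evenly across them (all sizes <= 10).
#' @param lambda Loading strength of a taxon on its construct (default 1.5;
#'   the strong-signal preset uses 2).
#' @param zero_inflation Independent dropout rate applied to counts
#'   (default 0.2).
#' @param depth Sequencing depth per sample (default 10000 reads).
#' @param beta_age_weight Weight gain per day of age, g (default 10.59).
#' @param beta_sex Additive male weight advantage, g (default 34.5).
#' @param alpha_age Per-construct effect of standardized age on the
#'   construct (default: 0.8 for the first five constructs, 0 elsewhere,
#'   mirroring an age-driven subset).
#' @param beta_bsf_weight,beta_bsf_construct Diet effects; both 0 by
#'   default (the null-diet world), nonzero only for power exploration.
#' @param sd_weight Residual weight sd, g (default 60).
#' @param sd_taxon Residual taxon log-intensity sd (default 1).
#' @param sd_intercept Spread of taxon intercepts on the log scale
#'   (default 1.5; induces realistic dominance of a few genera).
#' @param seed RNG seed.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(n_samples = 90, n_taxa = 62, n_constructs = 10,
                           lambda = 1.5, zero_inflation = 0.2, depth = 10000,
                           beta_age_weight = 10.59, beta_sex = 34.5,
                           alpha_age = NULL, beta_bsf_weight = 0,
                           beta_bsf_construct = 0, sd_weight = 60,
                           sd_taxon = 1, sd_intercept = 1.5, seed = 1L) {
  if (is.null(alpha_age)) {
    alpha_age <- rep(0, n_constructs)
    alpha_age[seq_len(min(5, n_constructs))] <- 0.8
  }
  stopifnot(length(alpha_age) == n_constructs, zero_inflation >= 0,
            zero_inflation < 1, depth > 0, n_taxa >= n_constructs)
  sizes <- rep(n_taxa %/% n_constructs, n_constructs)
  extra <- n_taxa - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  if (any(sizes > 10)) abort("construct sizes exceed 10; increase n_constructs")
  structure(
    list(n_samples = n_samples, n_taxa = n_taxa, n_constructs = n_constructs,
         sizes = sizes, lambda = lambda, zero_inflation = zero_inflation,
         depth = depth, beta_age_weight = beta_age_weight,
         beta_sex = beta_sex, alpha_age = alpha_age,
         beta_bsf_weight = beta_bsf_weight,
         beta_bsf_construct = beta_bsf_construct, sd_weight = sd_weight,
         sd_taxon = sd_taxon, sd_intercept = sd_intercept,
         seed = as.integer(seed)),
    class = "generator_spec"
  )
}

# the study's sampling frame: replicate x diet x (compartment, age, count)
study_design <- function() {
  frame <- expand.grid(replicate = c("R1", "R2", "R3"),
                       bsf_pct = c(0, 5, 10), stringsAsFactors = FALSE)
  rows <- purrr::pmap(frame, function(replicate, bsf_pct) {
    blocks <- switch(replicate,
      R1 = list(c("cloaca", 28, 5), c("caecum", 67, 5)),
      R2 = list(c("cloaca", 16, 4), c("caecum", 73, 8)),
      R3 = list(c("caecum", 39, 8)))
    bind_rows(lapply(blocks, function(b) {
      tibble(replicate = replicate, bsf_pct = bsf_pct,
             compartment = b[1], age_d = as.integer(b[2]),
             n = as.integer(b[3]))
    }))
  })
  tidyr::uncount(bind_rows(rows), weights = .data$n)
}

#' Generate a synthetic microbiome dataset with known ground truth
#'
#' Per sample: covariates follow the study design; each latent construct is
#' `alpha * standardized age + unit noise`; taxon log-intensities load on
#' their construct, pass through a softmax (inducing compositional
#' negative coupling) and a multinomial draw at fixed depth, then suffer
#' independent dropout; weight is a linear function of age and sex with
#' Gaussian noise, truncated positive.
#'
#' @param spec A [generator_spec()].
#' @return List: `counts` (tibble, taxa rows x sample columns), `metadata`
#'   (per-sample tibble), `truth` (membership, coefficients, implied DAG
#'   arcs, latent values).
#' @export
generate_microbiome <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  with_seed(spec$seed, {
    design <- study_design()
    N <- spec$n_samples
    if (N != nrow(design)) {
      design <- design[sample.int(nrow(design), N, replace = TRUE), ]
    }
    design <- design[sample.int(nrow(design)), ] # shuffle row order
    design$sample_id <- sprintf("S%03d", seq_len(N))
    design$sex <- sample(c("male", "female"), N, replace = TRUE)
    age <- design$age_d
    z_age <- (age - mean(age)) / sd(age)
    K <- spec$n_constructs
    members <- split(sprintf("T%02d", seq_len(spec$n_taxa)),
                     rep(seq_len(K), spec$sizes))
    names(members) <- paste0("C", seq_len(K))
    # latent construct values
    L <- vapply(seq_len(K), function(k) {
      spec$alpha_age[k] * z_age +
        spec$beta_bsf_construct * (design$bsf_pct / 10) + rnorm(N)
    }, numeric(N))
    colnames(L) <- names(members)
    # taxon log-intensities -> softmax -> multinomial
    taxa <- unlist(members, use.names = FALSE)
    intercepts <- rnorm(spec$n_taxa, 0, spec$sd_intercept)
    k_of <- rep(seq_len(K), spec$sizes)
    X <- matrix(0, N, spec$n_taxa, dimnames = list(design$sample_id, taxa))
    for (j in seq_len(spec$n_taxa)) {
      X[, j] <- intercepts[j] + spec$lambda * L[, k_of[j]] +
        rnorm(N, 0, spec$sd_taxon)
    }
    P <- exp(X - apply(X, 1, max))
    P <- P / rowSums(P)
    counts <- t(vapply(seq_len(N), function(i) {
      as.numeric(rmultinom(1, spec$depth, P[i, ]))
    }, numeric(spec$n_taxa)))
    dimnames(counts) <- list(design$sample_id, taxa)
    if (spec$zero_inflation > 0) {
      drop <- matrix(rbinom(length(counts), 1, spec$zero_inflation),
                     nrow(counts))
      counts[drop == 1] <- 0
    }
    # guard: no empty samples after dropout
    empty <- rowSums(counts) == 0
    if (any(empty)) counts[empty, 1] <- 1
    weight <- spec$beta_age_weight * age +
      spec$beta_sex * (design$sex == "male") +
      spec$beta_bsf_weight * (design$bsf_pct / 10) +
      rnorm(N, 0, spec$sd_weight)
    design$weight_g <- pmax(weight, 20)
    truth <- list(
      members = members,
      alpha_age = setNames(spec$alpha_age, names(members)),
      beta_age_weight = spec$beta_age_weight,
      beta_sex = spec$beta_sex,
      beta_bsf_weight = spec$beta_bsf_weight,
      lambda = spec$lambda,
      latent = L,
      z_age_sd = sd(age),
      implied_arcs = bind_rows(
        tibble(parent = "age", child = "weight"),
        tibble(parent = "sex", child = "weight"),
        tibble(parent = "age",
               child = names(members)[spec$alpha_age != 0])
      )
    )
    counts_tb <- tibble::as_tibble(t(counts), rownames = "taxon")
    meta <- as_tibble(design[, c("sample_id", "weight_g", "age_d", "sex",
                                 "compartment", "bsf_pct", "replicate")])
    list(counts = counts_tb, metadata = meta, truth = truth)
  })
}

#' Preset generator specifications
#'
#' `preset_study()` is the study-shaped world (90 x 62); `preset_strong()`
#' is the strong-signal measurement world (N = 400, lambda = 2);
#' `preset_mediation()` has a single age-driven construct, no diet effect
#' anywhere, and no direct construct-to-weight path, so the true direct
#' effect of every construct on weight is zero while totals are not.
#'
#' @param seed RNG seed.
#' @param ... Overrides passed to [generator_spec()].
#' @return A `generator_spec`.
#' @export
preset_study <- function(seed = 1L, ...) {
  generator_spec(seed = seed, ...)
}

#' @rdname preset_study
#' @export
preset_strong <- function(seed = 1L, ...) {
  generator_spec(n_samples = 400, lambda = 2, zero_inflation = 0.2,
                 seed = seed, ...)
}

#' @rdname preset_study
#' @export
preset_mediation <- function(seed = 1L, ...) {
  generator_spec(n_samples = 400, n_constructs = 3, n_taxa = 18, lambda = 2,
                 alpha_age = c(1, 0, 0), seed = seed, ...)
}

#' Compare pipeline results against the generator's ground truth
#'
#' @param clustering A `variable_clustering` (or membership tibble from
#'   `tidy()`) over taxa.
#' @param taxa_dag The learned taxa `dag` (optional).
#' @param structural_dag The learned structural `dag` (optional).
#' @param effects A `psem_effects` tibble (optional).
#' @param truth The generator's `truth` list.
#' @return One-row tibble of recovery metrics: clustering ARI, taxa-skeleton
#'   precision/recall against same-construct pairs, structural-arc recall,
#'   and absolute effect errors where closed forms exist (age total =
#'   `beta_age_weight`; construct direct = 0).
#' @export
evaluate_recovery <- function(truth, clustering = NULL, taxa_dag = NULL,
                              structural_dag = NULL, effects = NULL) {
  out <- list()
  truth_members <- truth$members
  if (!is.null(clustering)) {
    memb <- if (inherits(clustering, "variable_clustering")) {
      tidy(clustering)
    } else clustering
    taxa <- unlist(truth_members, use.names = FALSE)
    true_lab <- rep(seq_along(truth_members),
                    vapply(truth_members, length, 1L))
    names(true_lab) <- taxa
    common <- intersect(taxa, memb$variable)
    est_lab <- memb$cluster[match(common, memb$variable)]
    out$ari <- igraph::compare(as.integer(factor(est_lab)),
                               as.integer(true_lab[common]),
                               method = "adjusted.rand")
  }
  if (!is.null(taxa_dag)) {
    arcs <- dag_arcs(taxa_dag)
    taxa <- unlist(truth_members, use.names = FALSE)
    lab <- rep(seq_along(truth_members), vapply(truth_members, length, 1L))
    names(lab) <- taxa
    same <- lab[arcs$parent] == lab[arcs$child]
    out$skeleton_precision <- if (nrow(arcs)) mean(same) else NA_real_
    n_true_pairs <- sum(vapply(truth_members,
                               function(m) choose(length(m), 2), 1))
    out$skeleton_recall <- if (n_true_pairs) sum(same) / n_true_pairs else NA_real_
  }
  if (!is.null(structural_dag)) {
    skel <- dag_arcs(structural_dag)
    und <- unique(rbind(paste(skel$parent, skel$child),
                        paste(skel$child, skel$parent)))
    ia <- truth$implied_arcs
    # construct names in truth are C1..; structural nodes are LC ids --
    # match by index when needed
    hit <- paste(ia$parent, ia$child) %in% und
    out$structural_arc_recall <- mean(hit)
  }
  if (!is.null(effects)) {
    if ("age" %in% effects$source) {
      out$age_total_error <- abs(
        effects$total_effect[effects$source == "age"] - truth$beta_age_weight)
    }
    lcs <- grep("^LC", effects$source, value = TRUE)
    if (length(lcs)) {
      out$max_construct_direct_error <- max(abs(
        effects$direct_effect[effects$source %in% lcs]))
    }
  }
  as_tibble(out)
}
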