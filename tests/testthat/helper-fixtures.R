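# shared fixtures, built in code at test time

# small abundance table with metadata for 6 samples x 4 taxa
make_tiny_table <- function() {
  counts <- matrix(
    c(10, 30, 0, 60,
      5, 5, 0, 90,
      1, 0, 1, 98,
      20, 20, 0, 60,
      0, 50, 0, 50,
      25, 25, 2, 48),
    nrow = 4,
    dimnames = list(paste0("T", 1:4), paste0("S", 1:6))
  )
  meta <- tibble::tibble(
    sample_id = paste0("S", 1:6),
    weight_g = c(100, 150, 210, 400, 520, 610),
    age_d = c(16L, 16L, 28L, 39L, 67L, 73L),
    sex = c("male", "female", "male", "female", "male", "female"),
    compartment = c("cloaca", "cloaca", "cloaca", "caecum", "caecum", "caecum"),
    bsf_pct = c(0, 5, 10, 0, 5, 10),
    replicate = c("R1", "R1", "R2", "R2", "R3", "R3")
  )
  list(counts = counts, meta = meta)
}

# exhaustive optimal contiguous k-partition SSE (oracle for the DP)
brute_best_sse <- function(values, k) {
  v <- sort(values)
  n <- length(v)
  sse <- function(x) sum((x - mean(x))^2)
  if (k == 1) return(sse(v))
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (j in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, j], n)
    tot <- 0
    for (i in seq_len(k)) tot <- tot + sse(v[(b[i] + 1):b[i + 1]])
    best <- min(best, tot)
  }
  best
}

# brute-force MI in bits by the double sum over the contingency table
brute_mi <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p); py <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  }
  unname(s)
}

brute_cmi <- function(x, y, z) {
  s <- 0
  n <- length(x)
  for (lev in unique(z)) {
    idx <- z == lev
    s <- s + sum(idx) / n * brute_mi(x[idx], y[idx])
  }
  s
}

# joint distribution of a discrete BN by full enumeration
brute_joint <- function(bn) {
  nodes <- bn$dag$nodes
  grid <- expand.grid(lapply(nodes, function(v) seq_len(bn$arities[[v]])))
  names(grid) <- nodes
  p <- rep(1, nrow(grid))
  for (v in nodes) {
    pa <- bn$dag$parents[[v]]
    dims <- c(bn$arities[[v]], unname(bn$arities[pa]))
    idx <- as.matrix(grid[, c(v, pa), drop = FALSE])
    p <- p * bn$cpts[[v]][micropsem:::lin_index(idx, dims)]
  }
  grid$p <- p
  grid
}

# posterior of `target` under hard evidence by joint enumeration
brute_posterior <- function(bn, target, evidence) {
  j <- brute_joint(bn)
  keep <- rep(TRUE, nrow(j))
  for (v in names(evidence)) keep <- keep & j[[v]] == evidence[[v]]
  j <- j[keep, ]
  p <- tapply(j$p, j[[target]], sum)
  out <- rep(0, bn$arities[[target]])
  out[as.integer(names(p))] <- p
  out / sum(out)
}

# trapezoidal ROC AUC (independent route vs the rank statistic)
trapezoid_auc <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  n1 <- sum(lab); n0 <- sum(!lab)
  # sweep thresholds at distinct score values (handles ties correctly)
  tpr <- c(0); fpr <- c(0)
  i <- 1
  while (i <= length(sc)) {
    j <- i
    while (j < length(sc) && sc[j + 1] == sc[i]) j <- j + 1
    tpr <- c(tpr, tpr[length(tpr)] + sum(lab[i:j]) / n1)
    fpr <- c(fpr, fpr[length(fpr)] + sum(!lab[i:j]) / n0)
    i <- j + 1
  }
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# minimal discretized dataset builder for measurement tests
make_disc_pipeline <- function(spec) {
  sim <- generate_microbiome(spec)
  at <- compute_relative_abundances(sim$counts, sim$metadata)
  at <- filter_low_abundance(at)
  logra <- log_transform_nonzero(at)
  binnings <- setNames(
    lapply(at$taxa, function(v) r2_optimal_discretize(logra[, v], variable = v)),
    at$taxa)
  disc <- tibble::as_tibble(setNames(lapply(at$taxa, function(v) {
    micropsem:::binning_factor(apply_binning(logra[, v], binnings[[v]]),
                               binnings[[v]])
  }), at$taxa))
  list(sim = sim, at = at, logra = logra, binnings = binnings, disc = disc)
}
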