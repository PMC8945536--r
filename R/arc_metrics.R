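# Arc strength and significance: empirical (conditional) mutual
# information, the Kullback-Leibler arc force, the G-test, and the
# per-arc report combining them with Pearson correlations on the
# underlying continuous values.

#' Empirical (conditional) mutual information in bits
#'
#' @param x,y Categorical vectors (factors or integer codes) of equal
#'   length.
#' @param z Optional conditioning set: vector, or data frame / matrix of
#'   several conditioning variables (their joint configuration is used).
#' @return MI(x; y) or MI(x; y | z) in bits.
#' @export
mutual_information <- function(x, y, z = NULL) {
  x <- as.integer(as.factor(x)); y <- as.integer(as.factor(y))
  n <- length(x)
  stopifnot(length(y) == n, n >= 1)
  if (is.null(z)) {
    ax <- max(x); ay <- max(y)
    nxy <- tabulate(x + (y - 1L) * ax, ax * ay)
    # MI = H(x) + H(y) - H(x,y), all from counts
    (nlog2n(nxy) - nlog2n(tabulate(x, ax)) - nlog2n(tabulate(y, ay))) / n +
      log2(n)
  } else {
    zc <- cond_code(z, n)
    mi <- 0
    for (lev in unique(zc)) {
      idx <- zc == lev
      mi <- mi + sum(idx) / n * mutual_information(x[idx], y[idx])
    }
    mi
  }
}

# joint configuration code for a conditioning set
cond_code <- function(z, n) {
  if (is.null(dim(z)) && !is.data.frame(z)) z <- data.frame(z = z)
  z <- as.data.frame(z)
  stopifnot(nrow(z) == n)
  if (!ncol(z)) return(rep(1L, n))
  as.integer(interaction(z, drop = TRUE, lex.order = TRUE))
}

#' G-test of (conditional) independence
#'
#' `G = 2 N ln(2) * MI_bits` (the likelihood-ratio statistic); the p-value
#' is the chi-square upper tail with `(a_x - 1)(a_y - 1) * prod(a_z)`
#' degrees of freedom.
#'
#' @inheritParams mutual_information
#' @return Tibble (g_stat, df, p_value).
#' @export
g_test <- function(x, y, z = NULL) {
  xf <- as.factor(x); yf <- as.factor(y)
  ax <- nlevels(xf); ay <- nlevels(yf)
  df <- (ax - 1) * (ay - 1)
  if (!is.null(z)) {
    zc <- cond_code(z, length(x))
    df <- df * length(unique(zc))
  }
  if (df < 1) abort("degenerate single-category variable: df = 0")
  mi <- mutual_information(xf, yf, z)
  g <- 2 * length(x) * log(2) * mi
  tibble(g_stat = g, df = as.integer(df),
         p_value = pchisq(g, df, lower.tail = FALSE))
}

#' Kullback-Leibler force of an arc
#'
#' KL divergence between the joint distribution of the fitted network and
#' that of the same network with the arc removed (both with MLE CPTs).
#' Under MLE fitting this equals the empirical conditional mutual
#' information of parent and child given the child's other parents; both
#' routes are available and agree to numerical precision.
#'
#' @param bn A `discrete_bn` fitted on `data` (MLE semantics assumed).
#' @param arc Length-2 character vector `c(parent, child)`.
#' @param data The categorical data the network was fitted on.
#' @param method `"cmi"` (conditional-MI route, default) or `"refit"`
#'   (log-likelihood difference after removing the arc and refitting).
#' @return Arc force in bits (>= 0 up to numerical noise).
#' @export
arc_force_kl <- function(bn, arc, data, method = c("cmi", "refit")) {
  method <- match.arg(method)
  parent <- arc[[1]]; child <- arc[[2]]
  if (!parent %in% bn$dag$parents[[child]]) abort("arc not present in network")
  cm <- as_cat_matrix(data)
  others <- setdiff(bn$dag$parents[[child]], parent)
  if (method == "cmi") {
    z <- if (length(others)) cm$m[, others, drop = FALSE] else NULL
    mutual_information(cm$m[, parent], cm$m[, child], z)
  } else {
    dag2 <- bn$dag
    dag2$parents[[child]] <- others
    bn0 <- fit_cpts_mle(bn$dag, data, pseudocount = 0)
    bn2 <- fit_cpts_mle(dag2, data, pseudocount = 0)
    (loglik_bits(bn2, data) - loglik_bits(bn0, data)) / nrow(cm$m)
  }
}

#' Per-arc strength report
#'
#' For every arc of a fitted network: the KL arc force, a G-test of parent
#' vs child conditioned on the child's other parents (the same conditioning
#' as the force), and the Pearson correlation of the underlying continuous
#' values (zero-marked entries excluded pairwise).  Rows are sorted by
#' descending KL.
#'
#' @param bn A `discrete_bn`.
#' @param data Categorical data the network was learned on.
#' @param raw_values Optional samples-by-variables numeric matrix aligned
#'   with `data` (e.g. log relative abundances with `NA` zero marks) for
#'   the correlation column; if omitted `pearson_r` is `NA`.
#' @param alpha Significance level for the `significant` flag (default
#'   0.05, no multiplicity correction).
#' @return Tibble (parent, child, kl, g_stat, df, p_value, pearson_r,
#'   significant), class `arc_report`.
#' @export
arc_report <- function(bn, data, raw_values = NULL, alpha = 0.05) {
  arcs <- dag_arcs(bn$dag)
  if (!nrow(arcs)) {
    out <- tibble(parent = character(0), child = character(0),
                  kl = numeric(0), g_stat = numeric(0), df = integer(0),
                  p_value = numeric(0), pearson_r = numeric(0),
                  significant = logical(0))
    class(out) <- c("arc_report", class(out))
    return(out)
  }
  cm <- as_cat_matrix(data)
  rows <- purrr::pmap(arcs, function(parent, child) {
    others <- setdiff(bn$dag$parents[[child]], parent)
    z <- if (length(others)) cm$m[, others, drop = FALSE] else NULL
    gt <- g_test(cm$m[, parent], cm$m[, child], z)
    r <- NA_real_
    if (!is.null(raw_values) && all(c(parent, child) %in% colnames(raw_values))) {
      xp <- raw_values[, parent]; xc <- raw_values[, child]
      ok <- !is.na(xp) & !is.na(xc)
      if (sum(ok) >= 3 && sd(xp[ok]) > 0 && sd(xc[ok]) > 0) {
        r <- stats::cor(xp[ok], xc[ok])
      }
    }
    tibble(parent = parent, child = child,
           kl = mutual_information(cm$m[, parent], cm$m[, child], z),
           g_stat = gt$g_stat, df = gt$df, p_value = gt$p_value,
           pearson_r = r)
  })
  out <- bind_rows(rows)
  out <- out[order(-out$kl, out$parent, out$child), ]
  out$significant <- out$p_value < alpha
  class(out) <- c("arc_report", class(out))
  out
}
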