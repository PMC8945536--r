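# Optimal 1-D discretization.
#
# Both discretizers reduce to the same primitive: the contiguous partition of
# a sorted set of values into k intervals minimizing within-bin sum of
# squares (Fisher/Jenks partitioning).  Minimizing within-bin SSE is
# equivalent to maximizing the R-squared between the values and their bin
# means, and the optimal 1-D k-means solution is always contiguous in sorted
# order, so one exact dynamic program serves both.

# DP over unique sorted values with weights. Returns for each k in 1..kmax
# the optimal SSE and the cut positions (last index of each bin).
fisher_dp <- function(u, w, kmax) {
  n <- length(u)
  cw <- cumsum(w)
  cwx <- cumsum(w * u)
  cwx2 <- cumsum(w * u^2)
  # SSE of the segment (i..j) of unique values, weighted
  seg_sse <- function(i, j) {
    sw <- cw[j] - if (i > 1) cw[i - 1] else 0
    sx <- cwx[j] - if (i > 1) cwx[i - 1] else 0
    sx2 <- cwx2[j] - if (i > 1) cwx2[i - 1] else 0
    sx2 - sx^2 / sw
  }
  S <- matrix(Inf, n, n) # S[i,j] segment cost, i <= j
  for (i in seq_len(n)) for (j in i:n) S[i, j] <- seg_sse(i, j)
  kmax <- min(kmax, n)
  cost <- matrix(Inf, kmax, n)
  back <- matrix(NA_integer_, kmax, n)
  cost[1, ] <- S[1, ]
  if (kmax > 1) {
    for (k in 2:kmax) {
      for (j in k:n) {
        prev <- cost[k - 1, (k - 1):(j - 1)] + S[k:j, j]
        b <- which.min(prev)
        cost[k, j] <- prev[b]
        back[k, j] <- (k - 1) + b - 1 # last index of previous bin
      }
    }
  }
  cuts <- vector("list", kmax)
  for (k in seq_len(kmax)) {
    if (!is.finite(cost[k, n])) next
    idx <- integer(k)
    j <- n
    for (kk in k:1) {
      idx[kk] <- j
      j <- if (kk > 1) back[kk, j] else 0
    }
    cuts[[k]] <- idx
  }
  list(sse = cost[, n], cuts = cuts, kmax = kmax)
}

new_binning <- function(variable, thresholds, representatives, has_zero_class,
                        k, occupancy, zero_fraction = 0, r2 = NA_real_,
                        sse = NA_real_) {
  stopifnot(!is.unsorted(thresholds, strictly = TRUE),
            !is.unsorted(representatives, strictly = TRUE),
            length(representatives) == k,
            length(thresholds) == k - 1)
  structure(
    list(variable = variable, thresholds = thresholds,
         representatives = representatives, has_zero_class = has_zero_class,
         k = k, occupancy = occupancy, zero_fraction = zero_fraction,
         r2 = r2, sse = sse),
    class = "binning"
  )
}

#' @export
print.binning <- function(x, ...) {
  cat("<binning> ", x$variable, ": ", x$k, " bin(s)",
      if (x$has_zero_class) " + zero class", "\n", sep = "")
  if (x$k > 1) cat("  thresholds: ", paste(signif(x$thresholds, 6), collapse = ", "), "\n", sep = "")
  cat("  representatives: ", paste(signif(x$representatives, 6), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.binning <- function(x, ...) {
  lo <- c(-Inf, x$thresholds)
  hi <- c(x$thresholds, Inf)
  out <- tibble(
    variable = x$variable,
    category = seq_len(x$k),
    lower = lo, upper = hi,
    representative = x$representatives,
    occupancy = x$occupancy
  )
  if (x$has_zero_class) {
    out <- bind_rows(
      tibble(variable = x$variable, category = 0L, lower = NA_real_,
             upper = NA_real_, representative = NA_real_,
             occupancy = x$zero_fraction),
      out
    )
  }
  out
}

# shared tail: build a binning from DP cuts at a chosen k
binning_from_cuts <- function(values, u, w, cuts_k, variable, has_zero_class,
                              zero_fraction, sse_k) {
  k <- length(cuts_k)
  reps <- numeric(k)
  occ <- numeric(k)
  start <- 1
  for (b in seq_len(k)) {
    idx <- start:cuts_k[b]
    reps[b] <- sum(u[idx] * w[idx]) / sum(w[idx])
    occ[b] <- sum(w[idx]) / sum(w)
    start <- cuts_k[b] + 1
  }
  thr <- if (k > 1) {
    vapply(seq_len(k - 1), function(b) (u[cuts_k[b]] + u[cuts_k[b] + 1]) / 2,
           numeric(1))
  } else numeric(0)
  tot <- sum(w * (u - sum(w * u) / sum(w))^2)
  r2 <- if (tot > 0) 1 - sse_k / tot else 1
  new_binning(variable, thr, reps, has_zero_class, k, occ,
              zero_fraction = zero_fraction, r2 = r2, sse = sse_k)
}

#' Discretize by exact 1-D k-means
#'
#' Solves the 1-D k-means problem exactly (dynamic programming on sorted
#' values; the optimal solution is contiguous), then places interval
#' thresholds at midpoints between adjacent cluster means.  The seed only
#' matters for tie-breaking and is kept for interface stability.
#'
#' @param values Numeric vector (no `NA`).
#' @param k Number of classes (>= 2).
#' @param seed Unused by the exact solver; retained so configs are explicit.
#' @param variable Name recorded in the binning.
#' @return A `binning` object.
#' @export
kmeans_discretize <- function(values, k = 5, seed = 1L, variable = "value") {
  values <- as.numeric(values)
  if (anyNA(values)) abort("values must not contain NA")
  tab <- table(values)
  u <- as.numeric(names(tab))
  w <- as.numeric(tab)
  if (length(u) < k) abort("fewer distinct values than k")
  dp <- fisher_dp(u, w, k)
  binning_from_cuts(values, u, w, dp$cuts[[k]], variable,
                    has_zero_class = FALSE, zero_fraction = 0,
                    sse_k = dp$sse[k])
}

#' Discretize by the smallest k reaching a target R-squared
#'
#' For each candidate k the exact contiguous partition maximizing the
#' R-squared between values and their bin means is found by dynamic
#' programming; the smallest k whose optimum reaches `r2_target` wins.
#' When no candidate reaches the target (smooth, ungappy data) the elbow
#' of the R-squared curve is used instead of the raw maximum, which for
#' continuous data would degenerately always return the largest candidate.
#' `NA` entries (the
#' zero marks produced by [log_transform_nonzero()]) bypass binning into a
#' dedicated zero category, mirroring how null relative abundances are
#' treated as their own class.
#'
#' @param values Numeric vector, `NA` = zero mark.
#' @param k_candidates Candidate bin counts (default `2:5`).
#' @param r2_target Required R-squared (default 0.95).
#' @param variable Name recorded in the binning.
#' @return A `binning` with `has_zero_class = TRUE` iff any `NA` present.
#' @export
r2_optimal_discretize <- function(values, k_candidates = 2:5, r2_target = 0.95,
                                  variable = "value") {
  if (r2_target <= 0 || r2_target >= 1) abort("r2_target must be in (0,1)")
  values <- as.numeric(values)
  zero_fraction <- mean(is.na(values))
  nz <- values[!is.na(values)]
  has_zero <- anyNA(values)
  if (!length(nz)) {
    warn_msg <- "all values are zero-marked; binning has only the zero class"
    warning(warn_msg, call. = FALSE)
    return(structure(
      list(variable = variable, thresholds = numeric(0),
           representatives = numeric(0), has_zero_class = TRUE, k = 0L,
           occupancy = numeric(0), zero_fraction = 1, r2 = NA_real_,
           sse = NA_real_),
      class = "binning"
    ))
  }
  tab <- table(nz)
  u <- as.numeric(names(tab))
  w <- as.numeric(tab)
  k_candidates <- sort(unique(pmin(k_candidates, length(u))))
  dp <- fisher_dp(u, w, max(k_candidates))
  tot <- sum(w * (u - sum(w * u) / sum(w))^2)
  r2s <- if (tot > 0) 1 - dp$sse[k_candidates] / tot else rep(1, length(k_candidates))
  hit <- which(r2s >= r2_target)
  if (length(hit)) {
    pick <- hit[1]
  } else if (length(r2s) >= 3) {
    # no k reaches the target (smooth data): take the elbow of the R^2
    # curve (maximum curvature), where extra classes stop paying off
    curv <- -diff(diff(r2s))
    pick <- which.max(curv) + 1
  } else {
    pick <- which.max(r2s)
  }
  k <- k_candidates[pick]
  binning_from_cuts(nz, u, w, dp$cuts[[k]], variable,
                    has_zero_class = has_zero, zero_fraction = zero_fraction,
                    sse_k = dp$sse[k])
}

#' Map values onto the categories of a fitted binning
#'
#' Intervals are left-open/right-closed; a value equal to a threshold goes
#' to the lower bin, values beyond the training range clamp to the extreme
#' bins, and `NA` (zero mark) maps to category 0 when the binning has a zero
#' class.
#'
#' @param values Numeric vector, possibly with `NA` zero marks.
#' @param binning A `binning`.
#' @return Integer categories: 0 = zero class (if present), 1..k otherwise.
#' @export
apply_binning <- function(values, binning) {
  stopifnot(inherits(binning, "binning"))
  out <- integer(length(values))
  isna <- is.na(values)
  if (any(isna) && !binning$has_zero_class) {
    abort("values contain zero marks but the binning has no zero class")
  }
  # right-closed intervals: category = 1 + #(thresholds strictly below value)
  nz <- values[!isna]
  cat_nz <- findInterval(nz, binning$thresholds, left.open = TRUE) + 1L
  out[!isna] <- pmin(pmax(cat_nz, 1L), binning$k)
  out[isna] <- 0L
  out
}

# category -> numeric representative; the zero class gets `zero_rep`
# (defaults to one unit below the smallest representative, an ordered
# "below the support" placeholder).
bin_representative <- function(categories, binning, zero_rep = NULL) {
  if (is.null(zero_rep)) {
    zero_rep <- if (length(binning$representatives)) min(binning$representatives) - 1 else 0
  }
  out <- numeric(length(categories))
  out[categories == 0L] <- zero_rep
  nz <- categories > 0L
  out[nz] <- binning$representatives[categories[nz]]
  out
}

# factor with ordered levels from a binning's categories
binning_factor <- function(categories, binning) {
  levs <- if (binning$has_zero_class) 0:binning$k else seq_len(binning$k)
  factor(categories, levels = levs)
}

#' Serialize / restore a binning as plain-text JSON
#'
#' @param binning A `binning`.
#' @param path File path.
#' @return `read_binning` returns the restored `binning`.
#' @export
write_binning <- function(binning, path) {
  jsonlite::write_json(unclass(binning), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_binning
#' @export
read_binning <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$thresholds <- as.numeric(x$thresholds %||% numeric(0))
  x$representatives <- as.numeric(x$representatives %||% numeric(0))
  x$occupancy <- as.numeric(x$occupancy %||% numeric(0))
  x$k <- as.integer(x$k)
  structure(x[c("variable", "thresholds", "representatives", "has_zero_class",
                "k", "occupancy", "zero_fraction", "r2", "sse")],
            class = "binning")
}
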