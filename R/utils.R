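# internal helpers shared across modules

# Evaluate `expr` under a fixed RNG state without disturbing the caller's.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Shannon entropy (bits) of a count or probability vector.
entropy_bits <- function(p) {
  p <- p[p > 0]
  p <- p / sum(p)
  -sum(p * log2(p))
}

# x*log2(x) with 0 log 0 = 0, for count vectors
nlog2n <- function(n) {
  n <- n[n > 0]
  sum(n * log2(n))
}

# Coerce a data.frame / matrix of categorical variables into an integer
# matrix with codes 1..arity plus per-column level labels.  Factors keep
# their declared levels (so unobserved categories retain their slot).
as_cat_matrix <- function(data) {
  if (is.matrix(data)) {
    stopifnot(is.numeric(data))
    m <- matrix(as.integer(data), nrow(data), ncol(data),
                dimnames = dimnames(data))
    if (any(m < 1L)) stop("integer category codes must be >= 1", call. = FALSE)
    arities <- attr(data, "arities")
    if (is.null(arities)) arities <- apply(m, 2, max)
    levels <- lapply(seq_len(ncol(m)), function(j) as.character(seq_len(arities[j])))
    names(levels) <- colnames(m)
  } else {
    data <- as.data.frame(data)
    levels <- lapply(data, function(col) {
      if (is.factor(col)) levels(col) else as.character(sort(unique(col)))
    })
    m <- vapply(seq_along(data), function(j) {
      col <- data[[j]]
      if (is.factor(col)) as.integer(col)
      else as.integer(factor(col, levels = levels[[j]]))
    }, integer(nrow(data)))
    m <- matrix(m, nrow = nrow(data), dimnames = list(NULL, names(data)))
    names(levels) <- names(data)
    arities <- vapply(levels, length, 1L)
  }
  if (anyNA(m)) stop("categorical data contain missing values", call. = FALSE)
  list(m = m, arities = setNames(as.integer(arities), colnames(m)), levels = levels)
}

# linear index into an array with dims `dims` given a matrix of 1-based indices
lin_index <- function(idx, dims) {
  if (!length(dims)) return(rep(1L, nrow(idx)))
  mult <- cumprod(c(1, dims[-length(dims)]))
  as.vector(1 + (idx - 1L) %*% mult)
}
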