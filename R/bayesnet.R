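# Discrete Bayesian network core: DAG structure, maximum-likelihood CPTs,
# exact queries by variable elimination, per-family log-likelihood in bits.

#' Create a directed acyclic graph over named nodes
#'
#' @param nodes Character vector of node names.
#' @param arcs A two-column data frame / matrix of (parent, child) pairs, or
#'   NULL for the empty graph.
#' @return A `dag` object (nodes + named list of parent sets).
#' @export
new_dag <- function(nodes, arcs = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) abort("duplicate node names")
  parents <- setNames(vector("list", length(nodes)), nodes)
  parents[] <- list(character(0))
  if (!is.null(arcs) && NROW(arcs) > 0) {
    arcs <- as.data.frame(arcs, stringsAsFactors = FALSE)
    p <- as.character(arcs[[1]]); ch <- as.character(arcs[[2]])
    if (!all(c(p, ch) %in% nodes)) abort("arc endpoints must be nodes")
    if (any(p == ch)) abort("self-arcs are not allowed")
    if (anyDuplicated(paste(p, ch))) abort("duplicate arcs")
    for (i in seq_along(p)) parents[[ch[i]]] <- c(parents[[ch[i]]], p[i])
  }
  d <- structure(list(nodes = nodes, parents = parents), class = "dag")
  if (is.null(topo_order(d))) abort("arcs form a cycle")
  d
}

# topological order of node indices, or NULL if cyclic (Kahn's algorithm)
topo_order <- function(dag) {
  nodes <- dag$nodes
  indeg <- vapply(dag$parents, length, 1L)
  order <- character(0)
  avail <- nodes[indeg == 0]
  indeg <- setNames(indeg, nodes)
  children <- dag_children(dag)
  while (length(avail)) {
    v <- sort(avail)[1]
    avail <- setdiff(avail, v)
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) avail <- c(avail, ch)
    }
  }
  if (length(order) < length(nodes)) NULL else order
}

dag_children <- function(dag) {
  children <- setNames(vector("list", length(dag$nodes)), dag$nodes)
  children[] <- list(character(0))
  for (ch in dag$nodes) for (p in dag$parents[[ch]]) {
    children[[p]] <- c(children[[p]], ch)
  }
  children
}

#' @export
print.dag <- function(x, ...) {
  cat("<dag> ", length(x$nodes), " nodes, ", nrow(dag_arcs(x)), " arcs\n", sep = "")
  invisible(x)
}

#' Arcs of a DAG as a tibble
#' @param dag A `dag`.
#' @return Tibble with columns `parent`, `child`.
#' @export
dag_arcs <- function(dag) {
  ch <- rep(names(dag$parents), vapply(dag$parents, length, 1L))
  tibble(parent = unlist(dag$parents, use.names = FALSE) %||% character(0),
         child = ch)
}

#' @exportS3Method generics::tidy
tidy.dag <- function(x, ...) dag_arcs(x)

# ancestors of a node, including itself
dag_ancestors <- function(dag, v) {
  anc <- v
  repeat {
    grown <- unique(c(anc, unlist(dag$parents[anc], use.names = FALSE)))
    if (length(grown) == length(anc)) return(anc)
    anc <- grown
  }
}

# is `to` reachable from `from` via directed arcs?
dag_reaches <- function(children, from, to) {
  seen <- from
  frontier <- from
  while (length(frontier)) {
    nxt <- unique(unlist(children[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    if (to %in% nxt) return(TRUE)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  FALSE
}

#' Fit conditional probability tables by (regularized) maximum likelihood
#'
#' CPT entries are `(count + pseudocount) / (parent count + pseudocount *
#' arity)`; parent configurations never observed get a uniform distribution.
#'
#' @param dag A `dag`.
#' @param data Data frame of factors (one column per node) or integer matrix
#'   of codes 1..arity.
#' @param pseudocount Additive smoothing; 0 gives pure MLE (used for
#'   scoring), 0.5 is the inference default elsewhere in the package.
#' @return A `discrete_bn`: structure, per-node CPT arrays, level labels,
#'   and the fitted sample size.
#' @export
fit_cpts_mle <- function(dag, data, pseudocount = 0) {
  cm <- as_cat_matrix(data)
  if (!all(dag$nodes %in% colnames(cm$m))) abort("data must cover all nodes")
  N <- nrow(cm$m)
  if (N < 1) abort("need at least one observation")
  cpts <- setNames(vector("list", length(dag$nodes)), dag$nodes)
  for (v in dag$nodes) {
    pa <- dag$parents[[v]]
    a_v <- cm$arities[v]
    if (!length(pa)) {
      cnt <- tabulate(cm$m[, v], a_v) + pseudocount
      if (sum(cnt) == 0) cnt <- rep(1, a_v)
      cpt <- array(cnt / sum(cnt), dim = a_v,
                   dimnames = setNames(list(cm$levels[[v]]), v))
    } else {
      dims <- c(a_v, unname(cm$arities[pa]))
      idx <- cbind(cm$m[, v], cm$m[, pa, drop = FALSE])
      cnt <- array(tabulate(lin_index(idx, dims), prod(dims)) + pseudocount,
                   dim = dims, dimnames = setNames(c(list(cm$levels[[v]]),
                                                     cm$levels[pa]), c(v, pa)))
      tot <- apply(cnt, seq_along(dims)[-1], sum)
      cpt <- sweep(cnt, seq_along(dims)[-1], tot, "/")
      if (any(tot == 0)) { # unobserved parent configs -> uniform
        uni <- array(rep(tot == 0, each = a_v), dim = dims)
        cpt[uni] <- 1 / a_v
      }
    }
    cpts[[v]] <- cpt
  }
  structure(
    list(dag = dag, cpts = cpts, arities = cm$arities[dag$nodes],
         levels = cm$levels[dag$nodes], N = N, pseudocount = pseudocount),
    class = "discrete_bn"
  )
}

#' @export
print.discrete_bn <- function(x, ...) {
  cat("<discrete_bn> ", length(x$dag$nodes), " nodes, ",
      nrow(dag_arcs(x$dag)), " arcs, fitted on N = ", x$N, "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.discrete_bn <- function(x, ...) dag_arcs(x$dag)

#' @exportS3Method generics::glance
glance.discrete_bn <- function(x, ...) {
  tibble(n_nodes = length(x$dag$nodes), n_arcs = nrow(dag_arcs(x$dag)),
         n_fitted = x$N, pseudocount = x$pseudocount)
}

# ---- factors for variable elimination ----------------------------------

bn_factors <- function(bn, nodes = bn$dag$nodes) {
  lapply(nodes, function(v) {
    cpt <- bn$cpts[[v]]
    list(vars = c(v, bn$dag$parents[[v]]), tab = as.array(cpt))
  })
}

fac_mult <- function(f1, f2, arities) {
  # scalar (empty-scope) factors just scale the other one
  if (!length(f1$vars)) {
    return(list(vars = f2$vars, tab = f2$tab * as.numeric(f1$tab)))
  }
  if (!length(f2$vars)) {
    return(list(vars = f1$vars, tab = f1$tab * as.numeric(f2$tab)))
  }
  vars <- union(f1$vars, f2$vars)
  dims <- unname(arities[vars])
  n <- prod(dims)
  ai <- arrayInd(seq_len(n), dims)
  t1 <- f1$tab[lin_index(ai[, match(f1$vars, vars), drop = FALSE],
                         unname(arities[f1$vars]))]
  t2 <- f2$tab[lin_index(ai[, match(f2$vars, vars), drop = FALSE],
                         unname(arities[f2$vars]))]
  list(vars = vars, tab = array(t1 * t2, dims))
}

fac_marg <- function(f, var, arities) {
  keep <- setdiff(f$vars, var)
  if (!length(keep)) {
    return(list(vars = character(0), tab = array(sum(f$tab), dim = 1)))
  }
  perm <- c(match(keep, f$vars), match(var, f$vars))
  t2 <- aperm(array(f$tab, unname(arities[f$vars])), perm)
  dk <- unname(arities[keep])
  tab <- array(rowSums(matrix(t2, nrow = prod(dk))), dim = dk)
  list(vars = keep, tab = tab)
}

# evidence: named list; each element either a single category (integer code
# or level label = hard evidence) or a numeric likelihood vector over the
# node's categories (soft/virtual evidence).
evidence_factors <- function(bn, evidence) {
  lapply(names(evidence), function(v) {
    a <- bn$arities[[v]]
    e <- evidence[[v]]
    if (length(e) == 1 && !is.list(e)) {
      code <- if (is.character(e)) match(e, bn$levels[[v]]) else as.integer(e)
      if (is.na(code) || code < 1 || code > a) {
        abort(paste0("evidence category not found for node ", v))
      }
      lik <- rep(0, a); lik[code] <- 1
    } else {
      lik <- as.numeric(e)
      if (length(lik) != a || any(lik < 0)) {
        abort(paste0("soft evidence for ", v, " must be a length-", a,
                     " non-negative vector"))
      }
    }
    list(vars = v, tab = array(lik, a))
  })
}

# slice a factor on a hard-evidence category, dropping the dimension
fac_slice <- function(f, var, cat, arities) {
  pos <- match(var, f$vars)
  d <- unname(arities[f$vars])
  idx <- lapply(d, seq_len)
  idx[[pos]] <- cat
  tab <- do.call(`[`, c(list(array(f$tab, d)), idx, list(drop = FALSE)))
  keep <- d[-pos]
  list(vars = f$vars[-pos],
       tab = array(tab, if (length(keep)) keep else 1))
}

# exact joint marginal of `targets` under evidence, by variable elimination
# (hard evidence is sliced out of every factor; elimination order is greedy
# by smallest resulting scope)
ve_joint <- function(bn, targets, evidence = list()) {
  arities <- bn$arities
  is_hard <- vapply(evidence, function(e) length(e) == 1 && !is.list(e), TRUE)
  hard <- evidence[is_hard]
  hard_codes <- lapply(names(hard), function(v) {
    e <- hard[[v]]
    code <- if (is.character(e)) match(e, bn$levels[[v]]) else as.integer(e)
    if (is.na(code) || code < 1 || code > bn$arities[[v]]) {
      abort(paste0("evidence category not found for node ", v))
    }
    code
  })
  names(hard_codes) <- names(hard)
  # barren-node pruning: nodes outside the ancestral closure of the query
  # and evidence marginalize to 1 and can be dropped wholesale
  needed <- unique(c(targets, names(evidence)))
  repeat {
    grown <- unique(c(needed, unlist(bn$dag$parents[needed], use.names = FALSE)))
    if (length(grown) == length(needed)) break
    needed <- grown
  }
  facs <- c(bn_factors(bn, nodes = needed),
            evidence_factors(bn, evidence[!is_hard]))
  for (v in names(hard_codes)) {
    facs <- lapply(facs, function(f) {
      if (v %in% f$vars) fac_slice(f, v, hard_codes[[v]], arities) else f
    })
  }
  elim <- setdiff(needed, c(targets, names(hard_codes)))
  while (length(elim)) {
    # greedy: eliminate the variable with the smallest combined scope
    cost <- vapply(elim, function(v) {
      scope <- unique(unlist(lapply(facs, function(f) {
        if (v %in% f$vars) f$vars else NULL
      })))
      if (is.null(scope)) 0 else prod(arities[scope])
    }, numeric(1))
    v <- elim[which.min(cost)]
    elim <- setdiff(elim, v)
    has <- vapply(facs, function(f) v %in% f$vars, TRUE)
    if (!any(has)) next
    f <- Reduce(function(a, b) fac_mult(a, b, arities), facs[has])
    facs <- c(facs[!has], list(fac_marg(f, v, arities)))
  }
  f <- Reduce(function(a, b) fac_mult(a, b, arities), facs)
  # order dims as `targets`
  if (length(f$vars) > 1 || !identical(f$vars, targets)) {
    perm <- match(targets, f$vars)
    f$tab <- aperm(array(f$tab, unname(arities[f$vars])), perm)
    f$vars <- targets
  }
  z <- sum(f$tab)
  if (z <= 0) abort("impossible evidence")
  f$tab <- f$tab / z
  f
}

#' Exact posterior of one node by variable elimination
#'
#' @param bn A `discrete_bn`.
#' @param target Node name (must not carry hard evidence).
#' @param evidence Named list: a single category (code or level label) for
#'   hard evidence, or a likelihood vector over the node's categories for
#'   soft (virtual) evidence.
#' @return Named probability vector over the target's categories.
#' @export
query <- function(bn, target, evidence = list()) {
  stopifnot(inherits(bn, "discrete_bn"), target %in% bn$dag$nodes)
  hard <- names(evidence)[vapply(evidence, function(e) length(e) == 1, TRUE)]
  if (target %in% hard) abort("target must not carry hard evidence")
  f <- ve_joint(bn, target, evidence)
  setNames(as.numeric(f$tab), bn$levels[[target]])
}

#' Negative log-likelihood of data under a fitted network, in bits
#'
#' Decomposes over families; with pseudocount-0 CPTs a zero-probability row
#' yields `+Inf` with a warning.
#'
#' @param bn A `discrete_bn`.
#' @param data Data covering all nodes (factors or integer codes).
#' @return Total `-sum(log2 P(row))` in bits.
#' @export
loglik_bits <- function(bn, data) {
  cm <- as_cat_matrix(data)
  total <- 0
  for (v in bn$dag$nodes) {
    pa <- bn$dag$parents[[v]]
    dims <- c(bn$arities[[v]], unname(bn$arities[pa]))
    idx <- cbind(cm$m[, v], cm$m[, pa, drop = FALSE])
    p <- bn$cpts[[v]][lin_index(idx, dims)]
    if (any(p == 0)) {
      warning("zero-probability observation; log-likelihood is infinite",
              call. = FALSE)
      return(Inf)
    }
    total <- total - sum(log2(p))
  }
  total
}

#' Sample observations from a discrete Bayesian network
#'
#' @param bn A `discrete_bn`.
#' @param n Number of rows.
#' @param seed RNG seed.
#' @return Data frame of factors (columns in node order).
#' @export
sample_bn <- function(bn, n, seed = 1L) {
  ord <- topo_order(bn$dag)
  out <- matrix(NA_integer_, n, length(bn$dag$nodes),
                dimnames = list(NULL, bn$dag$nodes))
  with_seed(seed, {
    for (v in ord) {
      pa <- bn$dag$parents[[v]]
      a_v <- bn$arities[[v]]
      if (!length(pa)) {
        out[, v] <- sample.int(a_v, n, replace = TRUE, prob = bn$cpts[[v]])
      } else {
        dims <- c(a_v, unname(bn$arities[pa]))
        cfg <- lin_index(cbind(1L, out[, pa, drop = FALSE]), dims)
        # cfg is the index of category 1 given the parent config; the a_v
        # categories are contiguous? no -- child is the first (fastest) dim
        for (i in seq_len(n)) {
          p <- bn$cpts[[v]][cfg[i] + (seq_len(a_v) - 1L)]
          out[i, v] <- sample.int(a_v, 1, prob = p)
        }
      }
    }
  })
  df <- as.data.frame(out)
  for (v in bn$dag$nodes) {
    df[[v]] <- factor(bn$levels[[v]][df[[v]]], levels = bn$levels[[v]])
  }
  df
}

#' Random strong-signal discrete Bayesian network (for simulations)
#'
#' Builds a random DAG over `n_nodes` nodes (uniform parent choice among
#' predecessors in a random order) and Dirichlet-ish CPTs sharpened so arcs
#' carry strong signal.
#'
#' @param n_nodes,n_arcs Graph size.
#' @param arity Number of categories per node.
#' @param strength Concentration of the CPT rows: each conditional
#'   distribution puts mass `strength` on one category and spreads the rest.
#' @param seed RNG seed.
#' @return A `discrete_bn` (with `N = 0`; it is a generator, not a fit).
#' @export
random_discrete_bn <- function(n_nodes, n_arcs, arity = 3, strength = 0.85,
                               seed = 1L) {
  nodes <- sprintf("V%02d", seq_len(n_nodes))
  with_seed(seed, {
    ord <- sample(nodes)
    pool <- expand.grid(i = seq_len(n_nodes), j = seq_len(n_nodes))
    pool <- pool[pool$i < pool$j, ]
    pick <- pool[sample.int(nrow(pool), min(n_arcs, nrow(pool))), ]
    arcs <- data.frame(parent = ord[pick$i], child = ord[pick$j])
    dag <- new_dag(nodes, arcs)
    cpts <- setNames(vector("list", n_nodes), nodes)
    levels <- setNames(rep(list(as.character(seq_len(arity))), n_nodes), nodes)
    for (v in nodes) {
      pa <- dag$parents[[v]]
      q <- prod(c(1, unname(rep(arity, length(pa)))))
      # conditional = normalized product of per-parent "channel" factors,
      # each a strong random-permutation stochastic matrix: every parent
      # has a guaranteed marginal pull on the child
      channels <- lapply(pa, function(p) {
        perm <- sample.int(arity)
        M <- matrix((1 - strength) / (arity - 1), arity, arity)
        M[cbind(perm, seq_len(arity))] <- strength
        M
      })
      block <- vapply(seq_len(q), function(cfg) {
        cat_p <- arrayInd(cfg, rep(arity, max(1, length(pa))))
        p <- rep(1, arity)
        for (pi in seq_along(pa)) p <- p * channels[[pi]][, cat_p[pi]]
        p / sum(p)
      }, numeric(arity))
      dims <- c(arity, rep(arity, length(pa)))
      cpts[[v]] <- array(block, dim = dims,
                         dimnames = setNames(rep(list(as.character(seq_len(arity))),
                                                 length(dims)), c(v, pa)))
    }
  })
  structure(
    list(dag = dag, cpts = cpts,
         arities = setNames(rep(as.integer(arity), n_nodes), nodes),
         levels = levels, N = 0L, pseudocount = 0),
    class = "discrete_bn"
  )
}
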