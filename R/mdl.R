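# MDL scoring and tabu hill-climbing structure search.
#
# MDL(B) = sc * DL_struct(B) + DL_data(B), in bits, where DL_data is the
# negative maximized log-likelihood and DL_struct counts, per node,
# log2(n) * (1 + |parents|) graph-coding bits plus (log2 N)/2 parameter-
# coding bits per free CPT parameter.  The structural coefficient sc scales
# the whole structural term: smaller sc admits denser networks.

#' Search configuration for MDL structure learning
#'
#' @param sc Structural coefficient in (0, 1]; multiplies the structural
#'   description length. Default 0.85 (midpoint of the adequate 0.7-1 range
#'   for taxa networks).
#' @param max_parents Parent cap per node (tractability), default 4.
#' @param tabu_length Iterations for which an undone move stays forbidden.
#' @param n_restarts Random restarts from perturbed optima.
#' @param max_stall Non-improving moves tolerated before stopping.
#' @param seed RNG seed (restart perturbations only; the base search is
#'   deterministic with lexicographic tie-breaking).
#' @param prior_arcs Optional tibble (parent, child) of arcs whose
#'   graph-coding bits are waived (used by structural-priors bagging).
#' @return A list of class `mdl_config`.
#' @export
mdl_config <- function(sc = 0.85, max_parents = 4L, tabu_length = 10L,
                       n_restarts = 2L, max_stall = 10L, seed = 1L,
                       prior_arcs = NULL) {
  stopifnot(sc > 0, max_parents >= 1)
  structure(list(sc = sc, max_parents = as.integer(max_parents),
                 tabu_length = as.integer(tabu_length),
                 n_restarts = as.integer(n_restarts),
                 max_stall = as.integer(max_stall), seed = as.integer(seed),
                 prior_arcs = prior_arcs),
            class = "mdl_config")
}

# data + struct description length of one family, in bits.
# waived = number of this family's parents whose graph-coding slot is free.
family_bits <- function(m, child, parents, arities, sc, waived = 0L) {
  N <- nrow(m)
  a_c <- arities[[child]]
  if (!length(parents)) {
    cnt <- tabulate(m[, child], a_c)
    data_bits <- N * log2(N) - nlog2n(cnt)
    q <- 1
  } else {
    ap <- unname(arities[parents])
    code <- m[, parents[1]]
    mult <- ap[1]
    for (j in seq_along(parents)[-1]) {
      code <- code + (m[, parents[j]] - 1L) * mult
      mult <- mult * ap[j]
    }
    q <- mult
    njc <- tabulate(code + (m[, child] - 1L) * q, q * a_c)
    nj <- tabulate(code, q)
    data_bits <- nlog2n(nj) - nlog2n(njc)
  }
  n_nodes <- ncol(m)
  struct_bits <- log2(n_nodes) * (1 + length(parents) - waived) +
    log2(N) / 2 * (a_c - 1) * q
  sc * struct_bits + data_bits
}

# cached family score; cache is an environment
family_bits_cached <- function(cache, m, child, parents, arities, sc, waived) {
  key <- paste0(child, "|", paste(sort(parents), collapse = ","))
  val <- cache[[key]]
  if (is.null(val)) {
    val <- family_bits(m, child, parents, arities, sc, waived)
    cache[[key]] <- val
  }
  val
}

#' MDL score of a DAG on categorical data
#'
#' @param dag A `dag`.
#' @param data Data frame of factors or integer code matrix.
#' @param sc Structural coefficient in (0, 1].
#' @param prior_arcs Optional (parent, child) tibble of arcs whose
#'   graph-coding bits are waived.
#' @return Score in bits (lower is better), with attributes `data_bits` and
#'   `struct_bits`.
#' @export
mdl_score <- function(dag, data, sc = 1, prior_arcs = NULL) {
  cm <- as_cat_matrix(data)
  m <- cm$m[, dag$nodes, drop = FALSE]
  arities <- cm$arities[dag$nodes]
  waive <- waived_counts(dag, prior_arcs)
  total <- 0; dtot <- 0
  for (v in dag$nodes) {
    s <- family_bits(m, v, dag$parents[[v]], arities, sc, waive[[v]])
    total <- total + s
    dtot <- dtot + family_bits(m, v, dag$parents[[v]], arities, sc = 0,
                               waive[[v]])
  }
  structure(total, data_bits = dtot, struct_bits = (total - dtot) / sc)
}

# per-node count of parents that are prior (waived) arcs
waived_counts <- function(dag, prior_arcs) {
  waive <- setNames(rep(0L, length(dag$nodes)), dag$nodes)
  if (!is.null(prior_arcs) && NROW(prior_arcs)) {
    for (i in seq_len(NROW(prior_arcs))) {
      ch <- as.character(prior_arcs[[2]][i]); p <- as.character(prior_arcs[[1]][i])
      if (ch %in% dag$nodes && p %in% dag$parents[[ch]]) {
        waive[[ch]] <- waive[[ch]] + 1L
      }
    }
  }
  waive
}

# ---- tabu hill-climbing -------------------------------------------------

# One hill-climb from a starting adjacency matrix. Deterministic.
# Returns list(adj, score, trace).  `prior` is an adjacency-shaped logical
# matrix of waived arcs.
hill_climb <- function(m, arities, sc, max_parents, tabu_length, max_stall,
                       prior, cache, adj0 = NULL, collect_trace = FALSE) {
  nodes <- colnames(m)
  n <- length(nodes)
  adj <- if (is.null(adj0)) matrix(FALSE, n, n, dimnames = list(nodes, nodes)) else adj0
  fam_score <- function(v, pset) {
    family_bits_cached(cache, m, v, pset, arities, sc, sum(prior[pset, v]))
  }
  parents_of <- function(v) nodes[adj[, v]]
  fs <- vapply(nodes, function(v) fam_score(v, parents_of(v)), numeric(1))
  # delta matrices: D_add[u,v] = change in v's family score if arc u->v added
  D_add <- matrix(NA_real_, n, n, dimnames = list(nodes, nodes))
  D_del <- matrix(NA_real_, n, n, dimnames = list(nodes, nodes))
  refresh_child <- function(v) {
    pv <- parents_of(v)
    for (u in nodes) {
      if (u == v) { D_add[u, v] <<- NA; D_del[u, v] <<- NA; next }
      if (adj[u, v]) {
        D_del[u, v] <<- fam_score(v, setdiff(pv, u)) - fs[v]
        D_add[u, v] <<- NA
      } else {
        D_add[u, v] <<- fam_score(v, c(pv, u)) - fs[v]
        D_del[u, v] <<- NA
      }
    }
  }
  for (v in nodes) refresh_child(v)
  reach_mat <- function() {
    # reach[u,v] TRUE if v reachable from u (including u itself)
    r <- diag(TRUE, n); dimnames(r) <- list(nodes, nodes)
    ord <- rev(topo_order_adj(adj, nodes))
    for (u in ord) {
      ch <- adj[u, ]
      if (any(ch)) r[u, ] <- r[u, ] | (colSums(r[ch, , drop = FALSE]) > 0)
    }
    r
  }
  best_adj <- adj; best_score <- sum(fs)
  cur_score <- best_score
  tabu <- list() # move key -> expiry iteration
  stall <- 0; iter <- 0
  trace <- if (collect_trace) list() else NULL
  repeat {
    iter <- iter + 1
    if (iter > 400) break
    reach <- reach_mat()
    np <- colSums(adj)
    # candidate deltas
    add_ok <- !adj & !t(reach) & !diag(TRUE, n) &
      matrix(np < max_parents, n, n, byrow = TRUE)
    del_ok <- adj
    # reverse u->v ok if after deleting, u not reachable from v via others
    # and u has room for a parent
    rev_ok <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
    arcs_idx <- which(adj, arr.ind = TRUE)
    if (nrow(arcs_idx)) {
      for (r_i in seq_len(nrow(arcs_idx))) {
        u <- arcs_idx[r_i, 1]; v <- arcs_idx[r_i, 2]
        if (np[u] >= max_parents) next
        adj[u, v] <- FALSE
        # new arc v->u is cyclic iff a u ~> v path remains after deletion
        ok <- !reaches_adj(adj, u, v)
        adj[u, v] <- TRUE
        rev_ok[u, v] <- ok
      }
    }
    cand <- rbind(
      if (any(add_ok)) cbind(which(add_ok, arr.ind = TRUE), type = 1L),
      if (any(del_ok)) cbind(which(del_ok, arr.ind = TRUE), type = 2L),
      if (any(rev_ok)) cbind(which(rev_ok, arr.ind = TRUE), type = 3L)
    )
    if (is.null(cand) || !nrow(cand)) break
    delta <- numeric(nrow(cand))
    for (ci in seq_len(nrow(cand))) {
      u <- cand[ci, 1]; v <- cand[ci, 2]
      delta[ci] <- switch(cand[ci, 3],
        D_add[u, v],
        D_del[u, v],
        D_del[u, v] + D_add[v, u])
    }
    # tabu filter with aspiration (move allowed if it beats the global best)
    keys <- paste0(cand[, 3], ":", nodes[cand[, 1]], ">", nodes[cand[, 2]])
    is_tabu <- vapply(keys, function(k) {
      exp <- tabu[[k]]; !is.null(exp) && exp >= iter
    }, TRUE)
    aspire <- (cur_score + delta) < best_score - 1e-9
    ok <- !is_tabu | aspire
    if (!any(ok)) break
    cand <- cand[ok, , drop = FALSE]; delta <- delta[ok]
    # lexicographic tie-break: (type, parent name, child name)
    ordk <- order(delta, cand[, 3], nodes[cand[, 1]], nodes[cand[, 2]])
    pick <- ordk[1]
    d <- delta[pick]
    if (d >= -1e-9) {
      stall <- stall + 1
      if (stall > max_stall) break
    } else stall <- 0
    u <- cand[pick, 1]; v <- cand[pick, 2]; type <- cand[pick, 3]
    un <- nodes[u]; vn <- nodes[v]
    if (type == 1L) {
      adj[u, v] <- TRUE
      tabu[[paste0("2:", un, ">", vn)]] <- iter + tabu_length
      changed <- vn
    } else if (type == 2L) {
      adj[u, v] <- FALSE
      tabu[[paste0("1:", un, ">", vn)]] <- iter + tabu_length
      changed <- vn
    } else {
      adj[u, v] <- FALSE; adj[v, u] <- TRUE
      tabu[[paste0("3:", vn, ">", un)]] <- iter + tabu_length
      changed <- c(vn, un)
    }
    for (w in changed) {
      fs[w] <- fam_score(w, parents_of(w))
      refresh_child(w)
    }
    cur_score <- sum(fs)
    if (collect_trace) {
      trace[[length(trace) + 1]] <- tibble(
        iter = iter, move = c("add", "delete", "reverse")[type],
        parent = un, child = vn, delta = d, score = cur_score)
    }
    if (cur_score < best_score - 1e-9) {
      best_score <- cur_score
      best_adj <- adj
    }
  }
  list(adj = best_adj, score = best_score,
       trace = if (collect_trace) bind_rows(trace) else NULL)
}

# topological order of an adjacency matrix (assumed acyclic)
topo_order_adj <- function(adj, nodes) {
  indeg <- colSums(adj)
  out <- character(0)
  avail <- nodes[indeg == 0]
  indeg <- setNames(indeg, nodes)
  while (length(avail)) {
    v <- sort(avail)[1]
    avail <- setdiff(avail, v)
    out <- c(out, v)
    for (ch in nodes[adj[v, ]]) {
      indeg[ch] <- indeg[ch] - 1
      if (indeg[ch] == 0) avail <- c(avail, ch)
    }
  }
  out
}

# DFS reachability on adjacency matrix: is `to` reachable from `from`?
reaches_adj <- function(adj, from, to) {
  n <- nrow(adj)
  seen <- logical(n)
  stack <- from
  while (length(stack)) {
    u <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (u == to) return(TRUE)
    if (seen[u]) next
    seen[u] <- TRUE
    stack <- c(stack, which(adj[u, ] & !seen))
  }
  FALSE
}

adj_to_dag <- function(adj, nodes) {
  idx <- which(adj, arr.ind = TRUE)
  arcs <- if (nrow(idx)) data.frame(parent = nodes[idx[, 1]],
                                    child = nodes[idx[, 2]]) else NULL
  new_dag(nodes, arcs)
}

dag_to_adj <- function(dag) {
  n <- length(dag$nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(dag$nodes, dag$nodes))
  a <- dag_arcs(dag)
  if (nrow(a)) adj[cbind(a$parent, a$child)] <- TRUE
  adj
}

#' Learn a DAG by MDL tabu search
#'
#' Greedy hill-climbing over add/delete/reverse moves minimizing the MDL
#' score, with a tabu list on recently undone moves and random restarts
#' from perturbed optima.  Deterministic given the seed; ties between
#' equal-scoring moves break lexicographically.
#'
#' @param data Data frame of factors / integer code matrix.
#' @param config An [mdl_config()].
#' @param trace Keep the per-move search trace (for score-decomposability
#'   audits)?
#' @return A `dag`; attributes `mdl` (best score) and, if requested,
#'   `trace`.
#' @export
tabu_search <- function(data, config = mdl_config(), trace = FALSE) {
  cm <- as_cat_matrix(data)
  m <- cm$m
  nodes <- colnames(m)
  n <- length(nodes)
  if (n < 2) abort("need at least 2 nodes")
  prior <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (!is.null(config$prior_arcs) && NROW(config$prior_arcs)) {
    pa <- as.data.frame(config$prior_arcs)
    prior[cbind(as.character(pa[[1]]), as.character(pa[[2]]))] <- TRUE
  }
  cache <- new.env(parent = emptyenv())
  run <- hill_climb(m, cm$arities, config$sc, config$max_parents,
                    config$tabu_length, config$max_stall, prior, cache,
                    collect_trace = trace)
  best <- run
  if (config$n_restarts > 0) {
    for (r in seq_len(config$n_restarts)) {
      adj0 <- with_seed(config$seed + r, perturb_adj(best$adj, nodes))
      run_r <- hill_climb(m, cm$arities, config$sc, config$max_parents,
                          config$tabu_length, config$max_stall, prior, cache,
                          adj0 = adj0)
      if (run_r$score < best$score - 1e-9) {
        best <- run_r
        best$trace <- NULL
      }
    }
  }
  out <- adj_to_dag(best$adj, nodes)
  attr(out, "mdl") <- best$score
  if (trace && !is.null(best$trace)) attr(out, "trace") <- best$trace
  out
}

# random perturbation for restarts: delete a few arcs, try a few additions
perturb_adj <- function(adj, nodes) {
  n <- nrow(adj)
  arcs <- which(adj, arr.ind = TRUE)
  if (nrow(arcs)) {
    drop <- sample.int(nrow(arcs), size = ceiling(nrow(arcs) / 4))
    adj[arcs[drop, , drop = FALSE]] <- FALSE
  }
  for (t in seq_len(max(2, n %/% 4))) {
    u <- sample.int(n, 1); v <- sample.int(n, 1)
    if (u != v && !adj[u, v] && !reaches_adj(adj, v, u)) adj[u, v] <- TRUE
  }
  adj
}

#' Scan the structural coefficient and report network density
#'
#' Runs one MDL search per SC value and tabulates arc counts and scores;
#' the elbow (largest second difference of the arc count) is flagged as a
#' candidate operating point.
#'
#' @param data Categorical data.
#' @param sc_grid SC values in (0, 1].
#' @param config Base [mdl_config()] (its `sc` is overridden per grid
#'   point).
#' @return Tibble (sc, n_arcs, mdl, elbow), class `sc_scan` for
#'   `autoplot()`.
#' @export
sc_scan <- function(data, sc_grid = seq(0.1, 1, by = 0.1),
                    config = mdl_config()) {
  stopifnot(all(sc_grid > 0), all(sc_grid <= 1))
  sc_grid <- sort(sc_grid)
  rows <- purrr::map(sc_grid, function(s) {
    cfg <- config
    cfg$sc <- s
    dag <- tabu_search(data, cfg)
    tibble(sc = s, n_arcs = nrow(dag_arcs(dag)),
           mdl = as.numeric(attr(dag, "mdl")))
  })
  out <- bind_rows(rows)
  out$elbow <- FALSE
  if (nrow(out) >= 3) {
    d2 <- diff(diff(out$n_arcs))
    out$elbow[which.max(abs(d2)) + 1] <- TRUE
  }
  class(out) <- c("sc_scan", class(out))
  out
}
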