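# Orientation of CI-maps: collider (v-structure) detection from separating
# sets, Meek-rule closure to a maximally oriented PDAG, extension to a DAG
# under mutual-information node orders with acyclicity repair, BIC scoring,
# and the TSF-baseline + random-restart search.

new_pdag <- function(nodes, directed, undirected) {
  structure(list(nodes = nodes,
                 directed = directed,
                 undirected = undirected),
            class = "pdag")
}

#' @export
print.pdag <- function(x, ...) {
  cat("PDAG:", length(x$nodes), "nodes,", nrow(x$directed), "directed and",
      nrow(x$undirected), "undirected edges\n")
  invisible(x)
}

# Internal adjacency-matrix codec for pdag manipulation:
# amat[i, j] == 1 & amat[j, i] == 1 : undirected i -- j
# amat[i, j] == 1 & amat[j, i] == 0 : directed   i --> j
pdag_amat <- function(pdag) {
  p <- length(pdag$nodes)
  amat <- matrix(0L, p, p, dimnames = list(pdag$nodes, pdag$nodes))
  if (nrow(pdag$undirected) > 0L) {
    for (r in seq_len(nrow(pdag$undirected))) {
      a <- pdag$undirected[r, 1L]; b <- pdag$undirected[r, 2L]
      amat[a, b] <- amat[b, a] <- 1L
    }
  }
  if (nrow(pdag$directed) > 0L) {
    for (r in seq_len(nrow(pdag$directed))) {
      amat[pdag$directed[r, 1L], pdag$directed[r, 2L]] <- 1L
    }
  }
  amat
}

amat_pdag <- function(amat) {
  nodes <- rownames(amat)
  und <- directed <- character(0)
  dfrom <- dto <- ufrom <- uto <- character(0)
  p <- length(nodes)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j || amat[i, j] == 0L) next
      if (amat[j, i] == 1L) {
        if (i < j) { ufrom <- c(ufrom, nodes[i]); uto <- c(uto, nodes[j]) }
      } else {
        dfrom <- c(dfrom, nodes[i]); dto <- c(dto, nodes[j])
      }
    }
  }
  new_pdag(nodes,
           matrix(c(dfrom, dto), ncol = 2L,
                  dimnames = list(NULL, c("from", "to"))),
           matrix(c(ufrom, uto), ncol = 2L,
                  dimnames = list(NULL, c("a", "b"))))
}

amat_acyclic <- function(amat) {
  dir <- amat == 1L & t(amat) == 0L
  nodes <- rownames(amat)
  is_acyclic(nodes, nodes[row(dir)[dir]], nodes[col(dir)[dir]])
}

#' Orient the v-structures of a CI-map
#'
#' For every unshielded triple X - Z - Y (X and Y non-adjacent), orients
#' X -> Z <- Y iff Z is not in the recorded separating set of (X, Y).
#' Triples are processed in sorted (X, Z, Y) name order and the first
#' orientation claim on an edge wins; an orientation that would close a
#' directed cycle is skipped.  All other edges remain undirected.
#'
#' @param cimap A [cimap] object with separating sets.
#' @return A `pdag` object.
#' @export
orient_v_structures <- function(cimap) {
  stopifnot(inherits(cimap, "cimap"))
  nodes <- sort(cimap$nodes)
  p <- length(nodes)
  amat <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(cimap$edges))) {
    a <- cimap$edges[r, 1L]; b <- cimap$edges[r, 2L]
    amat[a, b] <- amat[b, a] <- 1L
  }
  for (z in nodes) {
    nb <- nodes[amat[z, ] == 1L & amat[, z] == 1L]
    if (length(nb) < 2L) next
    for (x in nb) {
      for (y in nb) {
        if (x >= y) next
        if (amat[x, y] != 0L || amat[y, x] != 0L) next   # shielded
        key <- edge_key(x, y)
        sep <- cimap$sepsets[[key]]
        if (is.null(sep)) {
          stop("no separating set recorded for non-adjacent pair (", x,
               ", ", y, ")", call. = FALSE)
        }
        if (z %in% sep) next
        # claim x -> z <- y unless an opposite claim came first
        for (u in c(x, y)) {
          if (amat[u, z] == 1L && amat[z, u] == 1L) {
            amat2 <- amat; amat2[z, u] <- 0L
            if (amat_acyclic(amat2)) amat <- amat2
          }
        }
      }
    }
  }
  amat_pdag(amat)
}

#' Meek-rule closure of a PDAG
#'
#' Applies the four standard orientation rules to a fixpoint:
#' \enumerate{
#'   \item a -> b, b - c, a and c non-adjacent: orient b -> c.
#'   \item a -> b -> c, a - c: orient a -> c.
#'   \item a - b, a - c, a - d, c -> b, d -> b, c and d non-adjacent:
#'     orient a -> b.
#'   \item a - b, a - c, c -> d, d -> b, b and c non-adjacent:
#'     orient a -> b.
#' }
#' The closure is idempotent and introduces no new colliders.
#'
#' @param pdag A `pdag` object.
#' @return The maximally oriented `pdag`.
#' @export
rule_closure <- function(pdag) {
  stopifnot(inherits(pdag, "pdag"))
  amat <- pdag_amat(pdag)
  nodes <- rownames(amat)
  p <- length(nodes)
  und <- function() which(amat == 1L & t(amat) == 1L, arr.ind = TRUE)
  orient <- function(i, j) {     # i -> j, guarded against cycles
    amat2 <- amat; amat2[j, i] <- 0L
    if (amat_acyclic(amat2)) { amat <<- amat2; TRUE } else FALSE
  }
  repeat {
    changed <- FALSE
    uu <- und()
    if (nrow(uu) > 0L) {
      o <- order(nodes[uu[, 1L]], nodes[uu[, 2L]])
      uu <- uu[o, , drop = FALSE]
    }
    for (r in seq_len(nrow(uu))) {
      b <- uu[r, 1L]; c_ <- uu[r, 2L]
      if (!(amat[b, c_] == 1L && amat[c_, b] == 1L)) next
      dir_in_b <- which(amat[, b] == 1L & amat[b, ] == 0L)
      # R1: a -> b, b - c, a,c non-adjacent
      for (a in dir_in_b) {
        if (amat[a, c_] == 0L && amat[c_, a] == 0L) {
          if (orient(b, c_)) { changed <- TRUE; break }
        }
      }
      if (!(amat[b, c_] == 1L && amat[c_, b] == 1L)) next
      # R2: b -> k -> c with b - c
      mid <- which(amat[b, ] == 1L & amat[, b] == 0L &
                     amat[, c_] == 1L & amat[c_, ] == 0L)
      if (length(mid) > 0L && orient(b, c_)) { changed <- TRUE; next }
      # R3: b - c, b - d1, b - d2, d1 -> c, d2 -> c, d1,d2 non-adjacent
      nb_u <- which(amat[b, ] == 1L & amat[, b] == 1L)
      into_c <- intersect(nb_u,
                          which(amat[, c_] == 1L & amat[c_, ] == 0L))
      r3 <- FALSE
      if (length(into_c) >= 2L) {
        for (d1 in into_c) {
          for (d2 in into_c) {
            if (d1 < d2 && amat[d1, d2] == 0L && amat[d2, d1] == 0L) {
              r3 <- TRUE; break
            }
          }
          if (r3) break
        }
      }
      if (r3 && orient(b, c_)) { changed <- TRUE; next }
      # R4: b - c, b - k, k -> l, l -> c, c,k non-adjacent
      r4 <- FALSE
      for (k in nb_u) {
        if (amat[k, c_] != 0L || amat[c_, k] != 0L) next
        l_set <- which(amat[k, ] == 1L & amat[, k] == 0L &
                         amat[, c_] == 1L & amat[c_, ] == 0L)
        if (length(l_set) > 0L) { r4 <- TRUE; break }
      }
      if (r4 && orient(b, c_)) changed <- TRUE
    }
    if (!changed) break
  }
  amat_pdag(amat)
}

# Average-MI node score from per-edge weights (0 for isolated nodes).
node_mi_from_edges <- function(nodes, skel_keys, mi_weight) {
  sc <- stats::setNames(numeric(length(nodes)), nodes)
  cnt <- stats::setNames(numeric(length(nodes)), nodes)
  if (length(skel_keys) > 0L) {
    em <- edge_key_split(skel_keys)
    w <- mi_weight[skel_keys]
    w[is.na(w)] <- 0
    for (r in seq_along(skel_keys)) {
      sc[em[r, 1L]] <- sc[em[r, 1L]] + w[r]
      sc[em[r, 2L]] <- sc[em[r, 2L]] + w[r]
      cnt[em[r, 1L]] <- cnt[em[r, 1L]] + 1
      cnt[em[r, 2L]] <- cnt[em[r, 2L]] + 1
    }
  }
  ifelse(cnt > 0, sc / pmax(cnt, 1), 0)
}

#' Extend a PDAG to a fully directed acyclic graph
#'
#' Orients every remaining undirected edge by sweeping the nodes in a
#' chosen order: each node's undirected edges are directed away from it
#' towards not-yet-processed neighbours; after every orientation an
#' acyclicity check runs and reverses the edge if a directed cycle would
#' arise.  The node order is by average mutual information — ascending for
#' `"TWF"`, descending for `"TSF"` — or a seeded random permutation.
#'
#' @param pdag A `pdag` whose directed part is acyclic.
#' @param policy `"TSF"` (strongest first), `"TWF"` or `"random"`.
#' @param mi_weight Named vector of per-edge mutual information (names as in
#'   a `cimap`'s `mi` field); required for TSF/TWF.
#' @param seed Integer seed (random policy).
#' @param node_order Optional explicit node order overriding `policy`.
#' @return A list of class `dag`: `nodes`, `edges` (from/to matrix),
#'   `order_used`, `policy`.
#' @export
extend_to_dag <- function(pdag, policy = c("TSF", "TWF", "random"),
                          mi_weight = NULL, seed = NULL, node_order = NULL) {
  stopifnot(inherits(pdag, "pdag"))
  policy <- match.arg(policy)
  amat <- pdag_amat(pdag)
  nodes <- rownames(amat)
  if (!amat_acyclic(amat)) {
    stop("directed part of the PDAG is cyclic", call. = FALSE)
  }
  if (is.null(node_order)) {
    if (policy == "random") {
      node_order <- with_seed(seed, sample(nodes))
    } else {
      skel_keys <- unique(c(
        if (nrow(pdag$undirected) > 0L)
          edge_key(pdag$undirected[, 1L], pdag$undirected[, 2L]),
        if (nrow(pdag$directed) > 0L)
          edge_key(pdag$directed[, 1L], pdag$directed[, 2L])))
      if (is.null(mi_weight)) {
        stop("mi_weight is required for the ", policy, " policy",
             call. = FALSE)
      }
      sc <- node_mi_from_edges(nodes, skel_keys, mi_weight)
      node_order <- if (policy == "TWF") nodes[order(sc, nodes)] else
        nodes[order(-sc, nodes)]
    }
  } else {
    stopifnot(setequal(node_order, nodes))
  }
  processed <- character(0)
  for (v in node_order) {
    nb <- nodes[amat[v, ] == 1L & amat[, v] == 1L]
    for (u in sort(setdiff(nb, processed))) {
      amat[u, v] <- 0L                     # try v -> u
      if (!amat_acyclic(amat)) {           # reverse to u -> v
        amat[u, v] <- 1L
        amat[v, u] <- 0L
      }
    }
    processed <- c(processed, v)
  }
  res <- amat_pdag(amat)
  if (nrow(res$undirected) > 0L) {
    stop("internal error: undirected edges remain after extension",
         call. = FALSE)
  }
  structure(list(nodes = nodes, edges = res$directed,
                 order_used = node_order, policy = policy),
            class = "dag")
}

#' @export
print.dag <- function(x, ...) {
  cat("DAG:", length(x$nodes), "nodes,", nrow(x$edges), "edges",
      sprintf("(node order policy: %s)\n", x$policy %||% "given"))
  invisible(x)
}

dag_parents <- function(nodes, edges) {
  out <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) out[[v]] <- character(0)
  for (r in seq_len(nrow(edges))) {
    out[[edges[r, 2L]]] <- c(out[[edges[r, 2L]]], edges[r, 1L])
  }
  out
}

#' BIC score of a DAG structure on discrete data
#'
#' Maximum-likelihood log score with a complexity penalty:
#' sum over nodes and parent configurations of N(x, pa) * ln(N(x, pa) /
#' N(pa)) minus ln(N)/2 times the number of independent parameters
#' Dim_G = sum over nodes of (card - 1) * prod(parent cards).  Zero-count
#' configurations contribute 0 (0 * ln 0 = 0 convention), so the score is
#' always finite and non-positive; higher is better.
#'
#' @param dag A `dag` object, a `pdag` with no undirected edges, or a
#'   two-column from/to edge matrix.
#' @param data A non-empty data.frame of factors containing all DAG nodes.
#' @return Numeric BIC score (<= 0).
#' @export
bic_score <- function(dag, data) {
  if (inherits(dag, "pdag")) {
    if (nrow(dag$undirected) > 0L) {
      stop("PDAG still has undirected edges; extend it first", call. = FALSE)
    }
    nodes <- dag$nodes; edges <- dag$directed
  } else if (inherits(dag, "dag")) {
    nodes <- dag$nodes; edges <- dag$edges
  } else {
    edges <- as.matrix(dag); nodes <- names(data)
  }
  if (nrow(data) == 0L) stop("empty dataset", call. = FALSE)
  miss <- setdiff(nodes, names(data))
  if (length(miss) > 0L) {
    stop("data lacks variable(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dd <- dd_prepare(data[nodes])
  idx <- stats::setNames(seq_along(nodes), nodes)
  parents <- dag_parents(nodes, edges)
  n <- dd$n
  ll <- 0
  dim_g <- 0
  for (v in nodes) {
    pa <- parents[[v]]
    cv <- dd$cards[[idx[[v]]]]
    cpa <- prod(c(1L, dd$cards[idx[pa]]))
    dim_g <- dim_g + (cv - 1L) * cpa
    lin <- dd$X[, idx[[v]]] - 1L
    mult <- cv
    for (u in pa) {
      lin <- lin + (dd$X[, idx[[u]]] - 1L) * mult
      mult <- mult * dd$cards[[idx[[u]]]]
    }
    cnt <- tabulate(lin + 1L, nbins = cv * cpa)
    cnt <- matrix(cnt, nrow = cv)
    npa <- colSums(cnt)
    nz <- cnt > 0
    ll <- ll + sum(cnt[nz] * log(cnt[nz] / rep(npa, each = cv)[nz]))
  }
  ll - log(n) / 2 * dim_g
}

#' Orient a CI-map into the best-scoring Bayesian network structure
#'
#' Implements the CI-map-to-DAG search: the CI-map is first oriented into a
#' PDAG (v-structures plus Meek closure); the strongest-first (TSF)
#' extension provides a baseline BIC score; then `max_iter` random node
#' orders are tried and the best-scoring DAG is returned.  The returned
#' score is therefore never below the TSF baseline, and the whole procedure
#' is deterministic given `(cimap, data, max_iter, seed)`.
#'
#' @param cimap A [cimap] object.
#' @param data The discrete dataset used for scoring.
#' @param max_iter Number of random-order restarts (0 returns the TSF DAG).
#' @param seed Integer seed for the random-order stream.
#' @return A list of class `scored_dag`: `dag`, `bic`, `baseline_bic`,
#'   `order_used`, `policy`, `max_iter`.
#' @export
cimap_to_dag <- function(cimap, data, max_iter = 100, seed = NULL) {
  stopifnot(inherits(cimap, "cimap"), max_iter >= 0)
  pdag <- rule_closure(orient_v_structures(cimap))
  dag_tsf <- extend_to_dag(pdag, "TSF", mi_weight = cimap$mi)
  bic_tsf <- bic_score(dag_tsf, data)
  best <- dag_tsf
  best_bic <- bic_tsf
  cache <- new.env(parent = emptyenv())
  assign(paste(dag_tsf$edges[, 1L], dag_tsf$edges[, 2L], collapse = ";"),
         bic_tsf, envir = cache)
  nodes <- pdag$nodes
  with_seed(seed, {
    for (it in seq_len(max_iter)) {
      ord <- sample(nodes)
      dag_r <- extend_to_dag(pdag, "random", node_order = ord)
      key <- paste(dag_r$edges[, 1L], dag_r$edges[, 2L], collapse = ";")
      bic_r <- if (!is.null(cache[[key]])) cache[[key]] else {
        b <- bic_score(dag_r, data)
        assign(key, b, envir = cache)
        b
      }
      if (bic_r > best_bic) {
        best <- dag_r
        best_bic <- bic_r
      }
    }
  })
  structure(list(dag = best, bic = best_bic, baseline_bic = bic_tsf,
                 order_used = best$order_used,
                 policy = if (identical(best, dag_tsf)) "TSF" else "random",
                 max_iter = max_iter),
            class = "scored_dag")
}

#' @export
print.scored_dag <- function(x, ...) {
  cat(sprintf("Scored DAG (%d edges): BIC = %.3f (TSF baseline %.3f, %d random restarts, best order from %s)\n",
              nrow(x$dag$edges), x$bic, x$baseline_bic, x$max_iter,
              x$policy))
  invisible(x)
}
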