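# PC adjacency search producing a CI-map: weakest-first (TWF) ordering,
# level-wise conditioning, separating-set bookkeeping and the three FDR
# schedules (basic / interleaved / mini).

# Internal: coerce a discrete dataset to an integer matrix plus metadata.
dd_prepare <- function(data) {
  stopifnot(is.data.frame(data), nrow(data) >= 1L)
  vars <- names(data)
  cols <- lapply(data, function(cl) if (is.factor(cl)) cl else factor(cl))
  if (anyNA(data)) stop("dataset contains missing values", call. = FALSE)
  X <- do.call(cbind, lapply(cols, as.integer))
  colnames(X) <- vars
  cards <- vapply(cols, nlevels, integer(1))
  nobs <- vapply(seq_along(cols), function(j) length(unique(X[, j])),
                 integer(1))
  list(X = X, cards = cards, vars = vars, n = nrow(data), observed = nobs)
}

# Internal: G statistic, df and MI (bits) for columns i, j given columns S
# of a prepared dataset.  Semantically identical to
# g_statistic(contingency(...)) but avoids repeated data.frame work.
fast_ci <- function(dd, i, j, S = integer()) {
  cards <- dd$cards
  lin <- dd$X[, i] - 1L
  mult <- cards[[i]]
  lin <- lin + (dd$X[, j] - 1L) * mult
  mult <- mult * cards[[j]]
  for (s in S) {
    lin <- lin + (dd$X[, s] - 1L) * mult
    mult <- mult * cards[[s]]
  }
  counts <- tabulate(lin + 1L, nbins = mult)
  cxy <- cards[[i]] * cards[[j]]
  nslice <- mult %/% cxy
  G <- 0
  for (a in seq_len(nslice)) {
    O <- matrix(counts[((a - 1L) * cxy + 1L):(a * cxy)], nrow = cards[[i]])
    na <- sum(O)
    if (na == 0) next
    E <- outer(rowSums(O), colSums(O)) / na
    nz <- O > 0
    G <- G + 2 * sum(O[nz] * log(O[nz] / E[nz]))
  }
  G <- max(G, 0)
  df <- (cards[[i]] - 1L) * (cards[[j]] - 1L) * prod(c(1L, cards[S]))
  list(G = G, df = as.integer(df), mi = G / (2 * dd$n * log(2)))
}

#' Weakest-first node order
#'
#' Orders the variables of a discrete dataset by ascending average pairwise
#' unconditional mutual information with all other variables (ties broken by
#' variable name).  This is the order in which the PC search prunes: the
#' weakest nodes are tested first.
#'
#' @param data A data.frame of factors with at least two columns.
#' @return Character vector of variable names, weakest first.
#' @export
twf_node_order <- function(data) {
  if (ncol(data) < 2L) stop("need at least 2 variables", call. = FALSE)
  dd <- dd_prepare(data)
  p <- length(dd$vars)
  mi <- matrix(0, p, p)
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      mi[i, j] <- mi[j, i] <- fast_ci(dd, i, j)$mi
    }
  }
  avg <- rowSums(mi) / (p - 1L)
  dd$vars[order(avg, dd$vars)]
}

#' Benjamini-Hochberg discovery set over edge p-values
#'
#' Step-up rule treating dependence (small p) as the discovery: with sorted
#' p-values p_(1) <= ... <= p_(m), find the largest k with
#' p_(k) <= k * alpha / m; all edges with p-value up to p_(k) are kept as
#' discoveries, the rest are pruned.  The three FDR schedules (basic,
#' interleaved, mini) differ only in when this pass runs during the PC
#' search, not in the rule itself.
#'
#' @param p Numeric vector of per-edge p-values (NA entries are not part of
#'   the pass and are reported as kept).
#' @param alpha FDR level.
#' @param kind One of `"basic"`, `"interleaved"`, `"mini"` (recorded only;
#'   the step-up rule is shared).
#' @return Logical vector: `TRUE` for edges kept as discoveries.
#' @export
apply_fdr <- function(p, alpha, kind = c("basic", "interleaved", "mini")) {
  kind <- match.arg(kind)
  keep <- rep(TRUE, length(p))
  idx <- which(!is.na(p))
  m <- length(idx)
  if (m == 0L) return(keep)
  pv <- p[idx]
  o <- order(pv)
  ks <- which(pv[o] <= alpha * seq_len(m) / m)
  disc <- logical(m)
  if (length(ks) > 0L) disc[o[seq_len(max(ks))]] <- TRUE
  keep[idx] <- disc
  keep
}

#' Learn a conditional-independence map (PC skeleton)
#'
#' Level-wise PC adjacency search over a discrete dataset.  Starting from
#' the complete graph, at level l every remaining edge (x, y) is tested
#' against all size-l subsets of adj(x) \ y and then adj(y) \ x; an
#' independent verdict removes the edge and records the separating set.
#' Candidate edges within a level are processed by ascending unconditional
#' mutual information (weakest first) and conditioning subsets are
#' enumerated in lexicographic order of the weakest-first node order, so
#' the result does not depend on the input column order.
#'
#' Tests can be skipped (edge kept) by the FNR power threshold
#' ([fnr_max_dof()]) or by the reliability rule of thumb N/df >= 5; skipped
#' tests carry no p-value and never enter the FDR pass.
#'
#' FDR schedules: `"basic"` runs one Benjamini-Hochberg pass over the
#' surviving edges after convergence; `"interleaved"` runs a pass after
#' every level; under `"mini"` individual tests never remove an edge and
#' only the per-level FDR pass prunes.  An edge pruned by FDR records as
#' separating set the conditioning set of its weakest-evidence test
#' (maximum p-value).
#'
#' @param data A data.frame of factors; every variable must show at least
#'   two observed categories.
#' @param alpha Per-test significance level and FDR level.
#' @param fdr FDR schedule: `"basic"` (default), `"interleaved"` or
#'   `"mini"`.
#' @param fnr An [fnr_config()]; default disabled, the recommended setup.
#' @param max_level Optional cap on the conditioning-set size.
#' @return An object of class `cimap`: fields `nodes` (in weakest-first
#'   order), `edges` (two-column matrix of unordered pairs), `mi` (per-edge
#'   unconditional mutual information, bits), `sepsets` (per separated
#'   pair), `pmax` (per-edge maximum p-value seen), `node_mi` (per-node
#'   average pairwise MI), `alpha` and `policy_log`.
#' @examples
#' bn <- fixture_bn8()
#' d <- forward_sample(bn, 2000, seed = 1)
#' cm <- cimap(d)
#' cm
#' @export
cimap <- function(data, alpha = 0.05, fdr = c("basic", "interleaved", "mini"),
                  fnr = fnr_off(), max_level = Inf) {
  fdr <- match.arg(fdr)
  stopifnot(inherits(fnr, "fnr_config"), alpha > 0, alpha < 1)
  if (ncol(data) < 2L) stop("need at least 2 variables", call. = FALSE)
  dd <- dd_prepare(data)
  bad <- dd$vars[dd$observed < 2L]
  if (length(bad) > 0L) {
    stop("constant column(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  p <- length(dd$vars)
  n <- dd$n

  # order columns weakest-first so integer index order = TWF order
  mi0 <- matrix(0, p, p)
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) mi0[i, j] <- mi0[j, i] <- fast_ci(dd, i, j)$mi
  }
  avg <- rowSums(mi0) / (p - 1L)
  ord <- order(avg, dd$vars)
  dd$X <- dd$X[, ord, drop = FALSE]
  dd$cards <- dd$cards[ord]
  dd$vars <- dd$vars[ord]
  mi0 <- mi0[ord, ord]
  node_mi <- stats::setNames(avg[ord], dd$vars)

  maxdof <- if (fnr$enabled) fnr_max_dof(n, fnr) else NA_integer_
  df_skip <- function(df) {
    (fnr$enabled && df > maxdof) || (n / df < 5)
  }

  adj <- matrix(TRUE, p, p); diag(adj) <- FALSE
  pmax <- matrix(NA_real_, p, p)
  sepset <- vector("list", p * p)        # by (i-1)*p+j for i<j
  sepcand <- vector("list", p * p)
  sid <- function(i, j) (min(i, j) - 1L) * p + max(i, j)

  remove_edge <- function(i, j, S) {
    adj[i, j] <<- adj[j, i] <<- FALSE
    sepset[[sid(i, j)]] <<- dd$vars[S]
  }

  fdr_pass <- function() {
    ut <- which(upper.tri(adj) & adj, arr.ind = TRUE)
    if (nrow(ut) == 0L) return(invisible())
    pv <- pmax[ut]
    keep <- apply_fdr(pv, alpha, fdr)
    for (r in which(!keep)) {
      i <- ut[r, 1L]; j <- ut[r, 2L]
      Sc <- sepcand[[sid(i, j)]] %||% integer()
      remove_edge(i, j, Sc)
    }
    invisible()
  }

  ell <- 0L
  repeat {
    ut <- which(upper.tri(adj) & adj, arr.ind = TRUE)
    if (nrow(ut) == 0L) break
    # edges whose larger open neighbourhood can host a size-ell subset
    nb_ok <- vapply(seq_len(nrow(ut)), function(r) {
      i <- ut[r, 1L]; j <- ut[r, 2L]
      max(sum(adj[i, ]) - 1L, sum(adj[j, ]) - 1L) >= ell
    }, logical(1))
    if (!any(nb_ok) || ell > max_level) break
    edges_now <- ut[nb_ok, , drop = FALSE]
    emi <- mi0[edges_now]
    ekey <- paste(dd$vars[edges_now[, 1L]], dd$vars[edges_now[, 2L]])
    edges_now <- edges_now[order(emi, ekey), , drop = FALSE]

    for (r in seq_len(nrow(edges_now))) {
      i <- edges_now[r, 1L]; j <- edges_now[r, 2L]
      if (!adj[i, j]) next                      # removed earlier this level
      done <- FALSE
      tried <- character(0)
      for (side in list(c(i, j), c(j, i))) {
        if (done) break
        x <- side[1L]; y <- side[2L]
        cand <- setdiff(which(adj[x, ]), y)     # ascending = TWF order
        if (length(cand) < ell) next
        # all subsets skipped? check the smallest reachable df first
        min_df <- (dd$cards[[i]] - 1L) * (dd$cards[[j]] - 1L) *
          prod(c(1, sort(dd$cards[cand])[seq_len(ell)]))
        if (df_skip(min_df)) next
        for (S in subsets_of_size(cand, ell)) {
          key <- paste(sort(S), collapse = ",")
          if (key %in% tried) next
          tried <- c(tried, key)
          df <- (dd$cards[[i]] - 1L) * (dd$cards[[j]] - 1L) *
            prod(c(1L, dd$cards[S]))
          if (df_skip(df)) next
          ct <- fast_ci(dd, i, j, S)
          pv <- stats::pchisq(ct$G, ct$df, lower.tail = FALSE)
          cur <- pmax[i, j]
          if (is.na(cur) || pv > cur) {
            pmax[i, j] <- pmax[j, i] <- pv
            sepcand[[sid(i, j)]] <- S
          }
          if (pv >= alpha) {
            if (fdr == "mini") {
              done <- TRUE                       # candidate for the FDR pass
            } else {
              remove_edge(i, j, S)
              done <- TRUE
            }
            break
          }
        }
      }
    }
    if (fdr %in% c("interleaved", "mini")) fdr_pass()
    ell <- ell + 1L
  }
  if (fdr == "basic") fdr_pass()

  ut <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  keys <- if (nrow(ut) > 0L) {
    edge_key(dd$vars[ut[, 1L]], dd$vars[ut[, 2L]])
  } else character()
  o <- order(keys)
  keys <- keys[o]
  mi_e <- stats::setNames(mi0[ut, drop = FALSE][o], keys)
  seps <- list()
  pvals <- stats::setNames(rep(NA_real_, length(keys)), keys)
  if (length(keys) > 0L) pvals[] <- pmax[ut][o]
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      if (!adj[i, j] && !is.null(sepset[[sid(i, j)]])) {
        seps[[edge_key(dd$vars[i], dd$vars[j])]] <- sepset[[sid(i, j)]]
      }
    }
  }
  structure(list(
    nodes = dd$vars,
    edges = as_edge_matrix(keys),
    mi = mi_e,
    sepsets = seps,
    pmax = pvals,
    node_mi = node_mi,
    alpha = alpha,
    policy_log = list(fdr = fdr, fnr = fnr, n = n,
                      fnr_max_dof = maxdof)
  ), class = "cimap")
}

#' @rdname cimap
#' @export
learn_skeleton <- cimap

#' @export
print.cimap <- function(x, ...) {
  cat("CI-map:", length(x$nodes), "nodes,", nrow(x$edges), "edges",
      sprintf("(alpha = %g, FDR = %s, FNR %s)\n", x$alpha, x$policy_log$fdr,
              if (x$policy_log$fnr$enabled) "on" else "off"))
  if (nrow(x$edges) > 0L) {
    shown <- utils::head(seq_len(nrow(x$edges)), 12L)
    for (r in shown) {
      cat(sprintf("  %s -- %s  (MI %.4f bits)\n", x$edges[r, 1L],
                  x$edges[r, 2L], x$mi[[r]]))
    }
    if (nrow(x$edges) > 12L) cat("  ...", nrow(x$edges) - 12L, "more\n")
  }
  invisible(x)
}

#' @export
summary.cimap <- function(object, ...) {
  deg <- table(factor(c(object$edges[, 1L], object$edges[, 2L]),
                      levels = object$nodes))
  structure(list(n_nodes = length(object$nodes),
                 n_edges = nrow(object$edges),
                 degree = deg,
                 n_separated = length(object$sepsets),
                 alpha = object$alpha,
                 policy_log = object$policy_log),
            class = "summary.cimap")
}

#' @export
print.summary.cimap <- function(x, ...) {
  cat("CI-map with", x$n_nodes, "nodes and", x$n_edges, "edges;",
      x$n_separated, "separated pairs\n")
  cat("alpha =", x$alpha, "| FDR =", x$policy_log$fdr, "| FNR",
      if (x$policy_log$fnr$enabled) "enabled" else "disabled", "\n")
  cat("degrees:\n")
  print(x$degree)
  invisible(x)
}

# Adjacency helper used across modules.
cimap_adjacent <- function(cm, v) {
  e <- cm$edges
  unique(c(e[e[, 1L] == v, 2L], e[e[, 2L] == v, 1L]))
}

#' Plot a CI-map
#'
#' Draws the undirected CI-map with edge widths proportional to mutual
#' information (uses igraph when available, otherwise a circular layout in
#' base graphics).
#'
#' @param x A `cimap` object.
#' @param ... Passed to the underlying plot call.
#' @export
plot.cimap <- function(x, ...) {
  if (requireNamespace("igraph", quietly = TRUE) && nrow(x$edges) > 0L) {
    g <- igraph::graph_from_edgelist(x$edges, directed = FALSE)
    g <- g + igraph::vertices(setdiff(x$nodes, igraph::V(g)$name))
    igraph::E(g)$width <- 0.5 + 4 * x$mi / max(x$mi, 1e-12)
    igraph::plot.igraph(g, ...)
  } else {
    k <- length(x$nodes)
    th <- 2 * pi * seq_len(k) / k
    xx <- cos(th); yy <- sin(th)
    plot(xx, yy, type = "n", axes = FALSE, xlab = "", ylab = "",
         xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3), ...)
    idx <- stats::setNames(seq_len(k), x$nodes)
    for (r in seq_len(nrow(x$edges))) {
      a <- idx[[x$edges[r, 1L]]]; b <- idx[[x$edges[r, 2L]]]
      graphics::segments(xx[a], yy[a], xx[b], yy[b], col = "grey50")
    }
    graphics::text(1.15 * xx, 1.15 * yy, x$nodes, cex = 0.8)
  }
  invisible(x)
}
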