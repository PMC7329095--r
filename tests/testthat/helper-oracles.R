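# Independent oracle implementations used to cross-check the package.
# These deliberately re-derive quantities from first principles (literal
# formulas, exhaustive enumeration, graph reachability) rather than calling
# the code paths they verify.

# Literal G statistic: 2 * sum O ln(O/E), expected counts formed slice by
# slice from the marginals, zero cells contributing nothing.
oracle_g <- function(counts3d) {
  G <- 0
  for (a in seq_len(dim(counts3d)[3])) {
    O <- counts3d[, , a]
    n <- sum(O)
    if (n == 0) next
    for (i in seq_len(nrow(O))) {
      for (j in seq_len(ncol(O))) {
        if (O[i, j] > 0) {
          E <- sum(O[i, ]) * sum(O[, j]) / n
          G <- G + 2 * O[i, j] * log(O[i, j] / E)
        }
      }
    }
  }
  G
}

# Literal plug-in conditional mutual information in bits.
oracle_mi_bits <- function(counts3d) {
  N <- sum(counts3d)
  I <- 0
  for (a in seq_len(dim(counts3d)[3])) {
    O <- counts3d[, , a]
    na <- sum(O)
    if (na == 0) next
    for (i in seq_len(nrow(O))) {
      for (j in seq_len(ncol(O))) {
        if (O[i, j] > 0) {
          p_ija <- O[i, j] / N
          p_ij_a <- O[i, j] / na
          p_i_a <- sum(O[i, ]) / na
          p_j_a <- sum(O[, j]) / na
          I <- I + p_ija * log2(p_ij_a / (p_i_a * p_j_a))
        }
      }
    }
  }
  I
}

# d-separation in a bn: moralised ancestral graph reachability.
oracle_dsep <- function(bn, x, y, S = character()) {
  anc <- unique(c(x, y, S))
  repeat {
    more <- unique(unlist(bn$parents[anc], use.names = FALSE))
    if (all(more %in% anc)) break
    anc <- unique(c(anc, more))
  }
  adj <- matrix(FALSE, length(anc), length(anc), dimnames = list(anc, anc))
  for (v in anc) {
    pa <- intersect(bn$parents[[v]], anc)
    for (u in pa) adj[u, v] <- adj[v, u] <- TRUE
    if (length(pa) > 1) {                      # marry co-parents
      for (i in seq_along(pa)) {
        for (j in seq_along(pa)) {
          if (i != j) adj[pa[i], pa[j]] <- TRUE
        }
      }
    }
  }
  keep <- setdiff(anc, S)
  adj <- adj[keep, keep, drop = FALSE]
  # BFS from x
  seen <- x
  frontier <- x
  while (length(frontier) > 0) {
    nxt <- unique(unlist(lapply(frontier, function(v) keep[adj[v, ]])))
    if (y %in% nxt) return(FALSE)
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  TRUE
}

# True skeleton of a bn as sorted "a b" pair strings.
truth_pairs <- function(bn) {
  e <- bn_edges(bn)
  sort(unique(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))))
}

cimap_pairs <- function(cm) {
  if (nrow(cm$edges) == 0) return(character())
  sort(paste(cm$edges[, 1], cm$edges[, 2]))
}

# Unshielded colliders of a DAG given as a parents list: sorted strings
# "x->z<-y" with x < y.
oracle_colliders <- function(nodes, parents) {
  adj <- function(a, b) {
    b %in% parents[[a]] || a %in% parents[[b]]
  }
  out <- character()
  for (z in nodes) {
    pa <- sort(parents[[z]])
    if (length(pa) < 2) next
    for (i in seq_along(pa)) {
      for (j in seq_along(pa)) {
        if (i < j && !adj(pa[i], pa[j])) {
          out <- c(out, paste0(pa[i], "->", z, "<-", pa[j]))
        }
      }
    }
  }
  sort(out)
}

# Exhaustive maximally-oriented-graph oracle: over all acyclic orientations
# of the skeleton whose unshielded-collider set matches the sepset pattern
# (x-z-y unshielded is a collider iff z is absent from sepset(x, y)), an
# edge is directed in the PDAG iff every consistent DAG orients it the same
# way.  Returns list(directed = "a->b" strings, undirected = "a--b").
oracle_pdag <- function(nodes, skel, sepsets) {
  # skel: two-column matrix of unordered pairs; sepsets: named list keyed
  # by "x|y" with x < y.
  m <- nrow(skel)
  adj <- function(a, b) {
    any((skel[, 1] == a & skel[, 2] == b) |
          (skel[, 1] == b & skel[, 2] == a))
  }
  want_collider <- function(x, z, y) {
    key <- paste(min(x, y), max(x, y), sep = "|")
    !(z %in% sepsets[[key]])
  }
  consistent <- list()
  for (mask in 0:(2^m - 1)) {
    parents <- setNames(lapply(nodes, function(v) character()), nodes)
    for (e in seq_len(m)) {
      a <- skel[e, 1]; b <- skel[e, 2]
      if (bitwAnd(mask, bitwShiftL(1L, e - 1L)) > 0L) {
        parents[[b]] <- c(parents[[b]], a)     # a -> b
      } else {
        parents[[a]] <- c(parents[[a]], b)     # b -> a
      }
    }
    acyc <- tryCatch({
      cimapr:::topo_order(nodes, parents); TRUE
    }, error = function(e) FALSE)
    if (!acyc) next
    # check collider pattern over all unshielded triples
    ok <- TRUE
    for (z in nodes) {
      nb <- nodes[vapply(nodes, function(u) u != z && adj(u, z), logical(1))]
      if (length(nb) < 2) next
      for (x in nb) {
        for (y in nb) {
          if (x >= y || adj(x, y)) next
          is_coll <- x %in% parents[[z]] && y %in% parents[[z]]
          if (is_coll != want_collider(x, z, y)) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (!ok) break
    }
    if (ok) consistent[[length(consistent) + 1L]] <- parents
  }
  stopifnot(length(consistent) > 0)
  directed <- character(); undirected <- character()
  for (e in seq_len(m)) {
    a <- skel[e, 1]; b <- skel[e, 2]
    a_to_b <- vapply(consistent, function(p) a %in% p[[b]], logical(1))
    if (all(a_to_b)) directed <- c(directed, paste0(a, "->", b))
    else if (all(!a_to_b)) directed <- c(directed, paste0(b, "->", a))
    else undirected <- c(undirected, paste0(a, "--", b))
  }
  list(directed = sort(directed), undirected = sort(undirected))
}

# Canonical form of a pdag object for comparison with oracles.
pdag_strings <- function(pdag) {
  d <- if (nrow(pdag$directed) > 0) {
    paste0(pdag$directed[, 1], "->", pdag$directed[, 2])
  } else character()
  u <- if (nrow(pdag$undirected) > 0) {
    paste0(pmin(pdag$undirected[, 1], pdag$undirected[, 2]), "--",
           pmax(pdag$undirected[, 1], pdag$undirected[, 2]))
  } else character()
  list(directed = sort(d), undirected = sort(u))
}

# Second, batch-style implementation of the four orientation rules:
# scans all candidate configurations, collects every forced orientation,
# applies them, repeats to a fixpoint.
oracle_closure <- function(pdag) {
  amat <- cimapr:::pdag_amat(pdag)
  nodes <- rownames(amat)
  p <- length(nodes)
  und <- function(i, j) amat[i, j] == 1 && amat[j, i] == 1
  dir <- function(i, j) amat[i, j] == 1 && amat[j, i] == 0
  nonadj <- function(i, j) amat[i, j] == 0 && amat[j, i] == 0
  repeat {
    force_edges <- matrix(integer(), ncol = 2)
    for (b in seq_len(p)) {
      for (cc in seq_len(p)) {
        if (b == cc || !und(b, cc)) next
        fire <- FALSE
        for (a in seq_len(p)) {
          if (a == b || a == cc) next
          if (dir(a, b) && nonadj(a, cc)) fire <- TRUE            # R1
          if (dir(b, a) && dir(a, cc)) fire <- TRUE               # R2
        }
        for (d1 in seq_len(p)) {
          for (d2 in seq_len(p)) {
            if (d1 >= d2 || d1 %in% c(b, cc) || d2 %in% c(b, cc)) next
            if (und(b, d1) && und(b, d2) && dir(d1, cc) &&
                dir(d2, cc) && nonadj(d1, d2)) fire <- TRUE       # R3
          }
        }
        for (k in seq_len(p)) {
          if (k %in% c(b, cc) || !und(b, k) || !nonadj(k, cc)) next
          for (l in seq_len(p)) {
            if (l %in% c(b, cc, k)) next
            if (dir(k, l) && dir(l, cc)) fire <- TRUE             # R4
          }
        }
        if (fire) force_edges <- rbind(force_edges, c(b, cc))
      }
    }
    if (nrow(force_edges) == 0) break
    for (r in seq_len(nrow(force_edges))) {
      amat[force_edges[r, 2], force_edges[r, 1]] <- 0L
    }
  }
  cimapr:::amat_pdag(amat)
}

# Exact joint distribution of a small bn by full enumeration:
# data.frame of category-label combinations with a `prob` column.
oracle_joint <- function(bn) {
  grid <- expand.grid(bn$levels, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  cards <- vapply(bn$levels, length, integer(1))
  prob <- rep(1, nrow(grid))
  for (v in bn$nodes) {
    vi <- match(grid[[v]], bn$levels[[v]])
    pa <- bn$parents[[v]]
    cfg <- if (length(pa) == 0) rep(1L, nrow(grid)) else {
      idx <- do.call(cbind, lapply(pa, function(u) match(grid[[u]],
                                                         bn$levels[[u]])))
      cimapr:::cpt_config_index(idx, cards[pa])
    }
    prob <- prob * bn$cpts[[v]][cbind(cfg, vi)]
  }
  grid$prob <- prob
  grid
}

# All permutations of a character vector (exhaustive node-order oracle).
combinat_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (p in combinat_perms(x[-i])) out[[length(out) + 1L]] <- c(x[i], p)
  }
  out
}
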