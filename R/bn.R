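#' Construct a discrete Bayesian network
#'
#' A `bn` object holds a directed acyclic graph over categorical variables
#' together with one conditional probability table (CPT) per variable, i.e.
#' the factorisation P(X1,...,XN) = prod_i P(Xi | parents(Xi)).
#'
#' CPTs are stored as matrices with one row per joint parent configuration
#' and one column per child category.  Parent configurations are indexed with
#' the first parent varying fastest (see [cpt_config_index()]).
#'
#' @param levels Named list; one character vector of category labels (at
#'   least two, all distinct) per variable.  List order is the declaration
#'   order of the network.
#' @param parents Named list; one character vector of parent names per
#'   variable (may be empty).  The implied directed graph must be acyclic.
#' @param cpts Named list; for each variable a numeric matrix of dimension
#'   (number of joint parent configurations) x (number of categories), every
#'   row a probability vector.  Rows whose sum deviates from 1 by at most
#'   1e-6 are renormalised (repository files carry rounded decimals); larger
#'   deviations are an error.
#' @return An object of class `bn`.
#' @examples
#' bn <- bn_network(
#'   levels  = list(A = c("no", "yes"), B = c("no", "yes")),
#'   parents = list(A = character(), B = "A"),
#'   cpts    = list(A = matrix(c(0.6, 0.4), 1), B = rbind(c(0.9, 0.1), c(0.2, 0.8)))
#' )
#' network_stats(bn)
#' @export
bn_network <- function(levels, parents, cpts) {
  nodes <- names(levels)
  if (is.null(nodes) || anyDuplicated(nodes) || any(!nzchar(nodes))) {
    stop("variable names must be non-empty and unique", call. = FALSE)
  }
  for (v in nodes) {
    lv <- levels[[v]]
    if (length(lv) < 2L || anyDuplicated(lv)) {
      stop("variable '", v, "' needs >= 2 distinct categories", call. = FALSE)
    }
  }
  if (!setequal(names(parents), nodes) || !setequal(names(cpts), nodes)) {
    stop("'parents' and 'cpts' must be named for exactly the variables",
         call. = FALSE)
  }
  parents <- parents[nodes]
  cpts <- cpts[nodes]
  for (v in nodes) {
    bad <- setdiff(parents[[v]], nodes)
    if (length(bad) > 0L) {
      stop("unknown parent(s) of '", v, "': ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  topo_order(nodes, parents)  # errors on cycles
  cards <- vapply(levels, length, integer(1))
  for (v in nodes) {
    tab <- as.matrix(cpts[[v]])
    ncfg <- prod(cards[parents[[v]]])
    if (nrow(tab) != ncfg || ncol(tab) != cards[[v]]) {
      stop("CPT of '", v, "' must be ", ncfg, " x ", cards[[v]], call. = FALSE)
    }
    if (any(tab < 0)) stop("CPT of '", v, "' has negative entries", call. = FALSE)
    s <- rowSums(tab)
    if (any(abs(s - 1) > 1e-6)) {
      stop("CPT row of '", v, "' sums to ", format(s[which.max(abs(s - 1))]),
           " (beyond tolerance 1e-6)", call. = FALSE)
    }
    cpts[[v]] <- tab / s
  }
  structure(list(nodes = nodes, levels = levels, parents = parents,
                 cpts = cpts),
            class = "bn")
}

#' Row index of a joint parent configuration
#'
#' Maps parent category indices to the CPT row, with the first parent
#' varying fastest.
#'
#' @param idx Integer matrix (n x p) or vector of parent category indices,
#'   columns in the CPT's parent order.
#' @param cards Integer vector of parent cardinalities.
#' @return Integer vector of row indices (all 1 when there are no parents).
#' @export
cpt_config_index <- function(idx, cards) {
  if (length(cards) == 0L) {
    n <- if (is.matrix(idx)) nrow(idx) else max(1L, length(idx))
    return(rep(1L, n))
  }
  idx <- if (is.matrix(idx)) idx else matrix(idx, ncol = length(cards))
  mult <- cumprod(c(1L, cards[-length(cards)]))
  as.integer(1L + (idx - 1L) %*% mult)
}

#' @export
print.bn <- function(x, ...) {
  ne <- sum(lengths(x$parents))
  cat("Discrete Bayesian network:", length(x$nodes), "nodes,", ne, "edges\n")
  cat("Variables:", paste(utils::head(x$nodes, 8L), collapse = ", "),
      if (length(x$nodes) > 8L) "..." else "", "\n")
  invisible(x)
}

#' Directed edges of a network
#'
#' @param bn A `bn` object.
#' @return Character matrix with columns `from`, `to`.
#' @export
bn_edges <- function(bn) {
  from <- unlist(bn$parents, use.names = FALSE)
  to <- rep(bn$nodes, lengths(bn$parents))
  matrix(c(from, to), ncol = 2L, dimnames = list(NULL, c("from", "to")))
}

#' Descriptive statistics of a network
#'
#' Reports node/edge counts, the number of independent CPT parameters
#' (sum over nodes of (card - 1) times the product of parent cardinalities),
#' the average degree 2E/V, the average Markov-blanket size (parents,
#' children and co-parents of children), and the maximum in-degree.
#'
#' @param bn A `bn` object.
#' @return A list of class `network_stats`.
#' @export
network_stats <- function(bn) {
  stopifnot(inherits(bn, "bn"))
  nodes <- bn$nodes
  cards <- vapply(bn$levels, length, integer(1))
  n_edges <- sum(lengths(bn$parents))
  n_par <- sum(vapply(nodes, function(v) {
    (cards[[v]] - 1L) * prod(cards[bn$parents[[v]]])
  }, numeric(1)))
  children <- lapply(nodes, function(v) {
    nodes[vapply(nodes, function(u) v %in% bn$parents[[u]], logical(1))]
  })
  names(children) <- nodes
  mb <- vapply(nodes, function(v) {
    cop <- unlist(lapply(children[[v]], function(ch) bn$parents[[ch]]),
                  use.names = FALSE)
    length(setdiff(unique(c(bn$parents[[v]], children[[v]], cop)), v))
  }, numeric(1))
  structure(list(
    n_nodes = length(nodes),
    n_edges = n_edges,
    n_parameters = n_par,
    avg_degree = 2 * n_edges / length(nodes),
    avg_markov_blanket = mean(mb),
    max_in_degree = max(c(0L, lengths(bn$parents)))
  ), class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf(paste0("%d nodes, %d edges, %g parameters\n",
                     "average degree %.2f, average Markov blanket %.2f, ",
                     "max in-degree %d\n"),
              x$n_nodes, x$n_edges, x$n_parameters,
              x$avg_degree, x$avg_markov_blanket, x$max_in_degree))
  invisible(x)
}

#' @export
summary.bn <- function(object, ...) network_stats(object)

#' Forward (ancestral) sampling from a network
#'
#' Draws `n` complete observations by sampling each variable given its
#' parents in a topological order (Kahn order with declaration-order
#' tie-breaks, so results are reproducible across runs).
#'
#' @param bn A `bn` object.
#' @param n Number of observations (>= 1).
#' @param seed Integer seed; identical (bn, n, seed) yield identical data.
#' @return A `data.frame` of factors, one column per variable in declaration
#'   order, with factor levels equal to the network's category labels.
#' @export
forward_sample <- function(bn, n, seed = NULL) {
  stopifnot(inherits(bn, "bn"), n >= 1)
  n <- as.integer(n)
  cards <- vapply(bn$levels, length, integer(1))
  ord <- topo_order(bn$nodes, bn$parents)
  with_seed(seed, {
    cols <- vector("list", length(bn$nodes))
    names(cols) <- bn$nodes
    for (v in ord) {
      pa <- bn$parents[[v]]
      tab <- bn$cpts[[v]]
      if (length(pa) == 0L) {
        cols[[v]] <- sample.int(cards[[v]], n, replace = TRUE, prob = tab[1L, ])
      } else {
        cfg <- cpt_config_index(do.call(cbind, cols[pa]), cards[pa])
        out <- integer(n)
        for (g in unique(cfg)) {
          rows <- which(cfg == g)
          out[rows] <- sample.int(cards[[v]], length(rows), replace = TRUE,
                                  prob = tab[g, ])
        }
        cols[[v]] <- out
      }
    }
    as.data.frame(lapply(bn$nodes, function(v) {
      factor(bn$levels[[v]][cols[[v]]], levels = bn$levels[[v]])
    }), col.names = bn$nodes)
  })
}

#' @rdname forward_sample
#' @param object A `bn` object (simulate method).
#' @param nsim Number of observations.
#' @param ... Unused.
#' @export
simulate.bn <- function(object, nsim = 1, seed = NULL, ...) {
  forward_sample(object, nsim, seed)
}

#' Random fixture network
#'
#' Generates a random DAG (parents drawn only from earlier nodes in a random
#' permutation, hence acyclic by construction) with CPT rows drawn from a
#' symmetric Dirichlet distribution.  A small `concentration` yields
#' near-deterministic rows, i.e. strong dependences.
#'
#' @param n_nodes Number of variables.
#' @param max_parents Maximum in-degree (must be < n_nodes).
#' @param cardinalities Inclusive integer range `c(lo, hi)` of category
#'   counts, sampled per variable.
#' @param concentration Positive Dirichlet concentration for CPT rows.
#' @param seed Integer seed; one seed fixes structure and parameters.
#' @return A `bn` object with variables `V01`, `V02`, ...
#' @export
random_network <- function(n_nodes, max_parents, cardinalities = c(2L, 3L),
                           concentration = 1, seed = NULL) {
  stopifnot(n_nodes >= 1, max_parents < n_nodes, concentration > 0)
  lo <- as.integer(min(cardinalities)); hi <- as.integer(max(cardinalities))
  if (lo < 2L) stop("cardinalities must be >= 2", call. = FALSE)
  nodes <- sprintf("V%02d", seq_len(n_nodes))
  with_seed(seed, {
    cards <- if (lo == hi) rep(lo, n_nodes) else
      sample(seq.int(lo, hi), n_nodes, replace = TRUE)
    names(cards) <- nodes
    perm <- sample(nodes)
    parents <- stats::setNames(vector("list", n_nodes), nodes)
    for (k in seq_len(n_nodes)) {
      v <- perm[k]
      avail <- min(max_parents, k - 1L)
      npa <- if (avail == 0L) 0L else sample.int(avail + 1L, 1L) - 1L
      parents[[v]] <- if (npa == 0L) character() else
        sort(sample(perm[seq_len(k - 1L)], npa))
    }
    cpts <- lapply(nodes, function(v) {
      ncfg <- prod(cards[parents[[v]]])
      tab <- matrix(stats::rgamma(ncfg * cards[[v]], shape = concentration),
                    nrow = ncfg)
      tab / rowSums(tab)
    })
    names(cpts) <- nodes
    bn_network(lapply(cards, function(k) paste0("c", seq_len(k))),
               parents, cpts)
  })
}

#' Built-in eight-node benchmark network
#'
#' A hand-designed sparse network over eight variables (six binary, two
#' ternary) with strongly informative CPTs, used as a reproducible recovery
#' benchmark: at moderate sample sizes its skeleton is identifiable from
#' data by conditional-independence testing.
#'
#' @return A `bn` object.
#' @export
fixture_bn8 <- function() {
  b2 <- c("lo", "hi"); b3 <- c("lo", "mid", "hi")
  strong2 <- function(...) rbind(...)
  bn_network(
    levels = list(A = b2, B = b3, C = b2, D = b2, E = b3, F = b2, G = b2,
                  H = b2),
    parents = list(
      A = character(),
      B = "A",
      C = "A",
      D = c("B", "C"),
      E = "D",
      F = "D",
      G = character(),
      H = c("F", "G")
    ),
    cpts = list(
      A = matrix(c(0.45, 0.55), 1),
      B = rbind(c(0.80, 0.15, 0.05),   # A=lo
                c(0.05, 0.15, 0.80)),  # A=hi
      C = strong2(c(0.85, 0.15), c(0.10, 0.90)),
      # rows: (B,C) with B varying fastest
      D = rbind(c(0.90, 0.10),  # B=lo, C=lo
                c(0.60, 0.40),  # B=mid,C=lo
                c(0.35, 0.65),  # B=hi, C=lo
                c(0.65, 0.35),  # B=lo, C=hi
                c(0.40, 0.60),  # B=mid,C=hi
                c(0.10, 0.90)), # B=hi, C=hi
      E = rbind(c(0.75, 0.20, 0.05), c(0.05, 0.20, 0.75)),
      F = strong2(c(0.88, 0.12), c(0.15, 0.85)),
      G = matrix(c(0.5, 0.5), 1),
      H = rbind(c(0.92, 0.08),  # F=lo, G=lo
                c(0.40, 0.60),  # F=hi, G=lo
                c(0.55, 0.45),  # F=lo, G=hi
                c(0.05, 0.95))  # F=hi, G=hi
    )
  )
}
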