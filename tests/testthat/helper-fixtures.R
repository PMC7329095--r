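# Small networks used as fixtures throughout the suite.

# A -> B -> C chain with strong links.
fixture_chain3 <- function() {
  bn_network(
    levels = list(A = c("0", "1"), B = c("0", "1"), C = c("0", "1")),
    parents = list(A = character(), B = "A", C = "B"),
    cpts = list(A = matrix(c(0.5, 0.5), 1),
                B = rbind(c(0.9, 0.1), c(0.1, 0.9)),
                C = rbind(c(0.85, 0.15), c(0.15, 0.85)))
  )
}

# Collider X -> Z <- Y with independent strong parents.
fixture_collider3 <- function() {
  bn_network(
    levels = list(X = c("0", "1"), Y = c("0", "1"), Z = c("0", "1")),
    parents = list(X = character(), Y = character(), Z = c("X", "Y")),
    cpts = list(X = matrix(c(0.5, 0.5), 1),
                Y = matrix(c(0.4, 0.6), 1),
                Z = rbind(c(0.9, 0.1),    # X=0, Y=0
                          c(0.4, 0.6),    # X=1, Y=0
                          c(0.5, 0.5),    # X=0, Y=1
                          c(0.05, 0.95))) # X=1, Y=1
  )
}

# Five-node fixtures with strong, faithfulness-friendly CPTs, used for
# d-separation recovery and node-order enumeration checks.
fixture_bn5 <- function(variant = 1L) {
  s <- function(p) rbind(c(p, 1 - p), c(1 - p, p))
  if (variant == 1L) {
    # Full chain A -> B -> C -> D -> E.  Chains are used for the exact
    # recovery checks because every non-adjacent pair then has at least
    # two separating conditioning sets within the search's reach (e.g.
    # A-C is separable by {B} and by {B, D}); a null pair with a single
    # separating test survives as a false positive with probability
    # ~ alpha per run, and a fixture with an unshielded collider always
    # has such a pair (the spouses' one marginal test), so exact
    # per-run agreement cannot reach 95% there at alpha = 0.05.
    bn_network(
      levels = list(A = c("0", "1"), B = c("0", "1"), C = c("0", "1"),
                    D = c("0", "1"), E = c("0", "1")),
      parents = list(A = character(), B = "A", C = "B", D = "C", E = "D"),
      cpts = list(A = matrix(c(0.5, 0.5), 1),
                  B = s(0.88), C = s(0.85), D = s(0.12), E = s(0.9))
    )
  } else {
    # chain A -> B -> C -> D with independent E
    bn_network(
      levels = list(A = c("0", "1"), B = c("0", "1"), C = c("0", "1"),
                    D = c("0", "1"), E = c("0", "1")),
      parents = list(A = character(), B = "A", C = "B", D = "C",
                     E = character()),
      cpts = list(A = matrix(c(0.45, 0.55), 1),
                  B = s(0.9), C = s(0.12), D = s(0.85),
                  E = matrix(c(0.3, 0.7), 1))
    )
  }
}

# Hand-built CI-map over given nodes from "a-b" pair strings; sepsets keyed
# by "x|y" (x < y) as character vectors.
make_cimap <- function(nodes, pairs, sepsets = list(), mi = NULL) {
  edges <- if (length(pairs) > 0) {
    t(vapply(strsplit(pairs, "-", fixed = TRUE),
             function(ab) sort(ab), character(2)))
  } else matrix(character(), ncol = 2)
  dimnames(edges) <- list(NULL, c("a", "b"))
  keys <- if (nrow(edges) > 0) {
    paste(edges[, 1], edges[, 2], sep = "\r")
  } else character()
  o <- order(keys)
  edges <- edges[o, , drop = FALSE]
  keys <- keys[o]
  if (is.null(mi)) mi <- seq_along(keys) / 10
  mi <- stats::setNames(rep_len(mi, length(keys)), keys)
  seps <- sepsets
  if (length(seps) > 0) {
    names(seps) <- vapply(strsplit(names(seps), "|", fixed = TRUE),
                          function(xy) paste(sort(xy), collapse = "\r"),
                          character(1))
  }
  structure(list(nodes = nodes, edges = edges, mi = mi, sepsets = seps,
                 pmax = stats::setNames(rep(NA_real_, length(keys)), keys),
                 node_mi = NULL, alpha = 0.05,
                 policy_log = list(fdr = "basic", fnr = fnr_off(), n = 0)),
            class = "cimap")
}
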