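# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Counter-based seed derivation (Lehmer-style hash) so that replicate k of a
# master seed is stable no matter how many replicates are requested.
derive_seed <- function(master, counter) {
  h <- (as.double(master) %% 2147483647)
  h <- (h * 48271 + as.double(counter) * 8191 + 1) %% 2147483647
  as.integer(h)
}

# Canonical key for an unordered node pair.
edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

edge_key_split <- function(key) {
  do.call(rbind, strsplit(key, "\r", fixed = TRUE))
}

# Sorted two-column character matrix of unordered pairs.
as_edge_matrix <- function(keys) {
  if (length(keys) == 0L) {
    return(matrix(character(), ncol = 2L, dimnames = list(NULL, c("a", "b"))))
  }
  m <- edge_key_split(keys)
  dimnames(m) <- list(NULL, c("a", "b"))
  m
}

# Kahn topological order with ties broken by the order of `nodes`.
topo_order <- function(nodes, parents) {
  remaining <- nodes
  indeg <- vapply(nodes, function(v) length(parents[[v]]), integer(1))
  names(indeg) <- nodes
  out <- character(0)
  while (length(remaining) > 0L) {
    ready <- remaining[indeg[remaining] == 0L]
    if (length(ready) == 0L) {
      stop("graph is cyclic: no topological order exists", call. = FALSE)
    }
    v <- ready[1L]                      # declaration-order tie-break
    out <- c(out, v)
    remaining <- setdiff(remaining, v)
    child_of_v <- remaining[vapply(remaining, function(u) v %in% parents[[u]],
                                   logical(1))]
    indeg[child_of_v] <- indeg[child_of_v] - 1L
  }
  out
}

# Is the directed graph given by an edge list (from, to) acyclic?
is_acyclic <- function(nodes, from, to) {
  parents <- split(from, factor(to, levels = nodes))
  ok <- tryCatch({
    topo_order(nodes, parents)
    TRUE
  }, error = function(e) FALSE)
  ok
}

# Does a directed path `from` ~> `to` exist? Adjacency given as a named list
# of out-neighbours.
has_path <- function(adj_out, from, to) {
  if (from == to) return(TRUE)
  seen <- from
  frontier <- from
  while (length(frontier) > 0L) {
    nxt <- unique(unlist(adj_out[frontier], use.names = FALSE))
    if (to %in% nxt) return(TRUE)
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  FALSE
}

# All size-k subsets of `x`, enumerated in lexicographic order of the
# positions of `x` (so the ordering of `x` fixes the enumeration order).
subsets_of_size <- function(x, k) {
  if (k == 0L) return(list(character(0)))
  if (length(x) < k) return(list())
  idx <- utils::combn(length(x), k, simplify = FALSE)
  lapply(idx, function(i) x[i])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
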