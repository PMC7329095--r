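# Bootstrapped CI-maps around a target variable: association histograms,
# hierarchical filtering, and selection of the most representative map.

#' Learn CI-maps from bootstrap resamples
#'
#' Each replicate draws an N-out-of-N resample of the rows (with
#' replacement) and learns a CI-map from it.  Replicate seeds are derived
#' from the master seed by a counter-based split, so replicate k is stable
#' no matter how many replicates are requested.
#'
#' @inheritParams cimap
#' @param b Number of bootstrap replicates (>= 1).
#' @param seed Integer master seed.
#' @return A list of `b` [cimap] objects; each carries its resample row
#'   indices as attribute `"resample"`.
#' @export
bootstrap_cimaps <- function(data, b, alpha = 0.05,
                             fdr = c("basic", "interleaved", "mini"),
                             fnr = fnr_off(), seed = NULL) {
  stopifnot(b >= 1)
  fdr <- match.arg(fdr)
  n <- nrow(data)
  maps <- vector("list", b)
  for (k in seq_len(b)) {
    sk <- derive_seed(seed %||% 0L, k)
    rows <- with_seed(sk, sample.int(n, n, replace = TRUE))
    maps[[k]] <- tryCatch(
      cimap(data[rows, , drop = FALSE], alpha = alpha, fdr = fdr, fnr = fnr),
      error = function(e) {
        stop("bootstrap replicate ", k, ": ", conditionMessage(e),
             call. = FALSE)
      })
    attr(maps[[k]], "resample") <- rows
  }
  maps
}

# Nodes at shortest-path distance exactly 2 from `target` in a cimap.
second_order_nodes <- function(cm, target) {
  first <- cimap_adjacent(cm, target)
  second <- unique(unlist(lapply(first, cimap_adjacent, cm = cm),
                          use.names = FALSE))
  setdiff(second, c(first, target))
}

#' First/second-order association histogram around a target
#'
#' For each CI-map, the first-order set is the target's neighbours and the
#' second-order set the nodes at shortest-path distance exactly 2 (the two
#' sets are disjoint within a map).  Percentages count the fraction of maps
#' in which a node falls in each set.
#'
#' @param maps List of [cimap] objects sharing the target node.
#' @param target Target variable name.
#' @return A list of class `assoc_hist` with named percentage vectors
#'   `first_order` and `second_order` (all nodes except the target), and
#'   `n_maps`.
#' @export
association_histogram <- function(maps, target) {
  stopifnot(length(maps) >= 1L)
  for (cm in maps) {
    if (!target %in% cm$nodes) {
      stop("target '", target, "' absent from a CI-map", call. = FALSE)
    }
  }
  nodes <- sort(setdiff(maps[[1L]]$nodes, target))
  f <- stats::setNames(numeric(length(nodes)), nodes)
  s <- f
  for (cm in maps) {
    fo <- cimap_adjacent(cm, target)
    so <- second_order_nodes(cm, target)
    f[intersect(fo, nodes)] <- f[intersect(fo, nodes)] + 1
    s[intersect(so, nodes)] <- s[intersect(so, nodes)] + 1
  }
  structure(list(target = target,
                 first_order = 100 * f / length(maps),
                 second_order = 100 * s / length(maps),
                 n_maps = length(maps)),
            class = "assoc_hist")
}

#' @export
print.assoc_hist <- function(x, ...) {
  cat("Association histogram for target '", x$target, "' over ", x$n_maps,
      " CI-maps\n", sep = "")
  ord <- order(-x$first_order, -x$second_order)
  tab <- data.frame(node = names(x$first_order)[ord],
                    first_pct = round(unname(x$first_order)[ord], 1),
                    second_pct = round(unname(x$second_order)[ord], 1))
  print(utils::head(tab, 15L), row.names = FALSE)
  invisible(x)
}

#' Plot an association histogram
#'
#' @param x An `assoc_hist` object.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.assoc_hist <- function(x, ...) {
  ord <- order(-x$first_order)
  m <- rbind(x$first_order[ord], x$second_order[ord])
  graphics::barplot(m, beside = TRUE, names.arg = names(x$first_order)[ord],
                    legend.text = c("1st order", "2nd order"), las = 2,
                    ylab = "% of CI-maps", ...)
  invisible(x)
}

cimap_edge_signature <- function(cm) {
  paste(sort(edge_key(cm$edges[, 1L], cm$edges[, 2L])), collapse = ";")
}

#' Hierarchical filtering of bootstrapped CI-maps
#'
#' Selects the most representative map of a collection: nodes are ranked by
#' how frequently they are first-order connections of the target (then
#' second-order, up to `max_order` which is capped at 2, the deepest order
#' tallied); in rank order, and skipping nodes below the `min_freq`
#' prevalence cutoff, the collection is filtered to the maps exhibiting the
#' connection, stopping as soon as one map remains or all survivors have
#' equal edge sets.  A filter step that would empty the collection is
#' skipped.  If every candidate is below the cutoff at the first step, the
#' modal map (by exact edge-set equality) is returned with a warning.
#' Ties in frequency are broken by node name; when several maps survive all
#' criteria, the earliest replicate is returned.
#'
#' @param maps List of [cimap] objects.
#' @param target Target variable name.
#' @param min_freq Prevalence cutoff as a fraction in [0, 1); default 0.10.
#' @param max_order Deepest connection order used for filtering (>= 1).
#' @return The selected [cimap] (a member of `maps`), with attribute
#'   `"replicate"` giving its index.
#' @export
hierarchical_filter <- function(maps, target, min_freq = 0.10,
                                max_order = 2L) {
  stopifnot(length(maps) >= 1L, min_freq >= 0, min_freq < 1, max_order >= 1L)
  hist <- association_histogram(maps, target)
  ranked <- function(pct) {
    keep <- pct[pct / 100 >= min_freq & pct > 0]
    names(keep)[order(-keep, names(keep))]
  }
  orders <- list(ranked(hist$first_order))
  if (max_order >= 2L) orders <- c(orders, list(ranked(hist$second_order)))
  if (length(orders[[1L]]) == 0L) {
    warning("no first-order node reaches min_freq; returning the modal map",
            call. = FALSE)
    sig <- vapply(maps, cimap_edge_signature, character(1))
    modal <- names(sort(table(sig), decreasing = TRUE))[1L]
    k <- which(sig == modal)[1L]
    out <- maps[[k]]
    attr(out, "replicate") <- k
    return(out)
  }
  idx <- seq_along(maps)
  done <- function(ii) {
    length(ii) == 1L ||
      length(unique(vapply(maps[ii], cimap_edge_signature,
                           character(1)))) == 1L
  }
  for (ord in seq_along(orders)) {
    for (nd in orders[[ord]]) {
      if (done(idx)) break
      hit <- vapply(idx, function(k) {
        cm <- maps[[k]]
        if (ord == 1L) nd %in% cimap_adjacent(cm, target)
        else nd %in% second_order_nodes(cm, target)
      }, logical(1))
      if (any(hit)) idx <- idx[hit]        # never empty the collection
    }
    if (done(idx)) break
  }
  out <- maps[[idx[1L]]]
  attr(out, "replicate") <- idx[1L]
  out
}

#' Most representative CI-map around a target variable
#'
#' Composition of [bootstrap_cimaps()], [association_histogram()] and
#' [hierarchical_filter()]: learns `b` CI-maps from bootstrap resamples and
#' selects the map whose target-adjacent structure is the most prevalent in
#' the collection.  The intended usage has one binary target per map; with
#' several target categories, run once per binary category indicator so
#' that spurious target-target associations cannot mask feature links.
#'
#' @inheritParams bootstrap_cimaps
#' @param target Target variable (a column of `data`).
#' @param min_freq,max_order Passed to [hierarchical_filter()].
#' @return The selected [cimap], with attributes `"replicate"` (its index)
#'   and `"histogram"` (the [association_histogram()] of the collection).
#' @export
most_representative_cimap <- function(data, target, b = 400, alpha = 0.05,
                                      fdr = c("basic", "interleaved", "mini"),
                                      fnr = fnr_off(), seed = NULL,
                                      min_freq = 0.10, max_order = 2L) {
  if (!target %in% names(data)) {
    stop("target '", target, "' is not a column of data", call. = FALSE)
  }
  fdr <- match.arg(fdr)
  maps <- bootstrap_cimaps(data, b, alpha = alpha, fdr = fdr, fnr = fnr,
                           seed = seed)
  hist <- association_histogram(maps, target)
  out <- hierarchical_filter(maps, target, min_freq = min_freq,
                             max_order = max_order)
  attr(out, "histogram") <- hist
  out
}
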