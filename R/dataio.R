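# Dataset input/output, quantile discretisation with the degrees-of-freedom
# category budget, and the synthetic metabolite-table generator.

#' Read a tabular dataset from CSV
#'
#' Reads a header CSV and types each column: columns named in
#' `factor_cols` (or non-numeric columns) become factors with their labels
#' preserved verbatim; the rest stay numeric.  Missing values and duplicate
#' headers are errors.
#'
#' @param path CSV file with a header row.
#' @param factor_cols Optional character vector of columns to force to
#'   factor.
#' @return A data.frame (factors and/or numerics).
#' @export
read_table_csv <- function(path, factor_cols = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  if (anyDuplicated(names(df))) {
    stop("duplicate column header(s): ",
         paste(unique(names(df)[duplicated(names(df))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(df)) {
    bad <- which(rowSums(is.na(df)) > 0)
    cols <- names(df)[colSums(is.na(df)) > 0]
    stop("missing values in row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "",
         " (column(s): ", paste(cols, collapse = ", "), ")", call. = FALSE)
  }
  for (v in names(df)) {
    if ((!is.null(factor_cols) && v %in% factor_cols) ||
        is.character(df[[v]]) || is.logical(df[[v]])) {
      df[[v]] <- factor(df[[v]])
    }
  }
  df
}

#' Write a discrete dataset to CSV
#'
#' Cells are category labels; the header row carries variable names.
#'
#' @param data A data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Equal-frequency (quantile) discretisation
#'
#' Bins every numeric feature at its empirical k/n_categories quantiles.
#' Values tied with a cut point go to the lower bin, so the binning is
#' deterministic and monotone; bin populations differ only by the
#' tie-induced excess.  Factor columns (e.g. a binary target) pass through
#' untouched.
#'
#' @param table A data.frame with numeric feature columns (and optionally
#'   factor columns).
#' @param n_categories Number of bins (>= 2); every numeric feature must
#'   have at least this many distinct values.
#' @return A data.frame of factors; numeric columns become factors with
#'   levels `q1 < q2 < ...`.
#' @export
discretize_quantiles <- function(table, n_categories = 3L) {
  stopifnot(is.data.frame(table), n_categories >= 2L)
  out <- table
  for (v in names(table)) {
    x <- table[[v]]
    if (!is.numeric(x)) next
    if (length(unique(x)) < n_categories) {
      stop("feature '", v, "' has fewer than ", n_categories,
           " distinct values", call. = FALSE)
    }
    cuts <- stats::quantile(x, probs = seq_len(n_categories - 1L) /
                              n_categories, names = FALSE)
    cuts <- unique(cuts)
    bin <- vapply(x, function(val) sum(val > cuts), numeric(1)) + 1L
    out[[v]] <- factor(paste0("q", bin),
                       levels = paste0("q", seq_len(length(cuts) + 1L)))
  }
  out
}

#' Maximum category count under the reliability budget
#'
#' Largest number of categories c >= 2 such that the worst-case pairwise
#' unconditional test df = (c - 1)^2 — optionally inflated by `cond_vars`
#' conditioning variables of the same cardinality, df = (c - 1)^2 * c^k —
#' keeps the ratio n / df at or above `min_ratio` (the rule of thumb below
#' which the G statistic is no longer a trustworthy chi-squared).  Returns
#' 1 with a warning when even two categories fail.
#'
#' @param n Sample size.
#' @param cond_vars Number of same-cardinality conditioning variables
#'   included in the worst-case df (default 0: unconditional pairwise df).
#' @param min_ratio Reliability threshold (default 5).
#' @return Integer category budget.
#' @export
category_budget <- function(n, cond_vars = 0L, min_ratio = 5) {
  stopifnot(n >= 1, cond_vars >= 0L)
  feasible <- function(c) n / ((c - 1)^2 * c^cond_vars) >= min_ratio
  if (!feasible(2L)) {
    warning("even 2 categories fail the n/df >= ", min_ratio,
            " reliability rule at n = ", n, call. = FALSE)
    return(1L)
  }
  c <- 2L
  while (feasible(c + 1L)) c <- c + 1L
  c
}

#' Metabolite names used for synthetic spectra tables
#'
#' The clinically relevant single-voxel MRS signals: mobile lipids,
#' lactate, the two alanine signals, N-acetyl aspartate,
#' creatine/phosphocreatine, choline, taurine, glycine/myo-inositol and
#' the glutamate+glutamine group.
#'
#' @return Character vector of ten names.
#' @export
mrs_feature_names <- function() {
  c("ML", "Lac", "Ala1", "Ala2", "NAA", "PCr", "Cho", "Tau", "GlyMIns",
    "Glx")
}

#' Synthetic MRS-like feature table
#'
#' Generates a continuous feature table with a binary class column,
#' emulating a small single-voxel MRS cohort: per-subject metabolite
#' intensities whose means shift with the class, plus correlated Gaussian
#' noise.  Stands in for non-deposited clinical spectra; it reproduces the
#' dimensionality and effect structure of such data, not its spectral
#' physics.
#'
#' @param n_subjects Number of rows (default 239, a typical cohort of 217
#'   patients plus 22 controls).
#' @param n_features Number of metabolite features (named after the MRS
#'   signals when <= 10).
#' @param class_fraction Prevalence of the positive class.
#' @param effect Per-feature class shift in noise-standard-deviation units
#'   (recycled scalar or full-length vector).  Default: one dominant
#'   feature (1.5), one moderate (0.8), one weak (0.4), the rest null.
#' @param latent_corr Feature-feature noise correlation: a single
#'   exchangeable correlation in [0, 1) or a full correlation matrix.
#'   Default 0.3, a mild shared-intensity correlation.
#' @param seed Integer seed.
#' @return A data.frame: numeric features plus factor `class` with levels
#'   `neg`, `pos`.
#' @export
synth_mrs_table <- function(n_subjects = 239L, n_features = 10L,
                            class_fraction = 0.25,
                            effect = NULL, latent_corr = 0.3, seed = NULL) {
  stopifnot(n_features >= 2L, n_subjects >= 4L,
            class_fraction > 0, class_fraction < 1)
  if (is.null(effect)) {
    effect <- c(1.5, 0.8, 0.4, rep(0, max(0L, n_features - 3L)))[
      seq_len(n_features)]
  }
  if (length(effect) == 1L) effect <- rep(effect, n_features)
  if (length(effect) != n_features) {
    stop("effect must have length 1 or n_features (", n_features, "), got ",
         length(effect), call. = FALSE)
  }
  if (is.matrix(latent_corr)) {
    if (!all(dim(latent_corr) == n_features)) {
      stop("latent_corr matrix must be ", n_features, " x ", n_features,
           call. = FALSE)
    }
    R <- latent_corr
  } else {
    stopifnot(latent_corr >= 0, latent_corr < 1)
    R <- matrix(latent_corr, n_features, n_features)
    diag(R) <- 1
  }
  feats <- if (n_features <= 10L) mrs_feature_names()[seq_len(n_features)]
  else paste0("F", seq_len(n_features))
  with_seed(seed, {
    cls <- stats::rbinom(n_subjects, 1L, class_fraction)
    L <- chol(R)
    Z <- matrix(stats::rnorm(n_subjects * n_features), n_subjects) %*% L
    X <- Z + outer(cls, effect)
    df <- as.data.frame(X)
    names(df) <- feats
    df$class <- factor(ifelse(cls == 1L, "pos", "neg"),
                       levels = c("neg", "pos"))
    df
  })
}

# ---- graph exports -------------------------------------------------------

graphml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Export a CI-map or DAG to GraphML
#'
#' CI-maps are written as undirected graphs with the mutual information as
#' a `mi` edge attribute; DAGs as directed graphs.
#'
#' @param x A [cimap] or `dag` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_graphml <- function(x, path) {
  directed <- inherits(x, "dag")
  edges <- x$edges
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
    "  <key id=\"mi\" for=\"edge\" attr.name=\"mi\" attr.type=\"double\"/>",
    sprintf("  <graph edgedefault=\"%s\">",
            if (directed) "directed" else "undirected"),
    sprintf("    <node id=\"%s\"/>", graphml_escape(x$nodes)))
  for (r in seq_len(nrow(edges))) {
    mi <- if (!directed && !is.null(x$mi)) {
      sprintf("><data key=\"mi\">%.10g</data></edge>", unname(x$mi[[r]]))
    } else "/>"
    lines <- c(lines, sprintf("    <edge source=\"%s\" target=\"%s\"%s",
                              graphml_escape(edges[r, 1L]),
                              graphml_escape(edges[r, 2L]), mi))
  }
  writeLines(c(lines, "  </graph>", "</graphml>"), path)
  invisible(path)
}

#' Export a DAG to Graphviz DOT
#'
#' @param dag A `dag` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dot <- function(dag, path) {
  stopifnot(inherits(dag, "dag"))
  lines <- c("digraph G {",
             sprintf("  \"%s\";", dag$nodes),
             sprintf("  \"%s\" -> \"%s\";", dag$edges[, 1L],
                     dag$edges[, 2L]),
             "}")
  writeLines(lines, path)
  invisible(path)
}

#' JSON sidecar of a CI-map
#'
#' Serialises the separating sets, per-edge statistics and the policy log.
#'
#' @param cimap A [cimap] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cimap_json <- function(cimap, path) {
  stopifnot(inherits(cimap, "cimap"))
  seps <- lapply(cimap$sepsets, as.character)
  names(seps) <- gsub("\r", "|", names(seps), fixed = TRUE)
  mi <- as.list(cimap$mi)
  names(mi) <- gsub("\r", "|", names(mi), fixed = TRUE)
  obj <- list(
    nodes = cimap$nodes,
    edges = apply(cimap$edges, 1L, paste, collapse = "|"),
    mi = mi,
    sepsets = seps,
    alpha = cimap$alpha,
    policy = list(fdr = cimap$policy_log$fdr,
                  fnr = unclass(cimap$policy_log$fnr),
                  n = cimap$policy_log$n))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Export an association histogram to CSV
#'
#' @param hist An `assoc_hist` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_histogram_csv <- function(hist, path) {
  stopifnot(inherits(hist, "assoc_hist"))
  tab <- data.frame(node = names(hist$first_order),
                    first_order_pct = unname(hist$first_order),
                    second_order_pct = unname(hist$second_order))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CI-map from its JSON sidecar
#'
#' Reconstructs a [cimap] object written by [write_cimap_json()].
#'
#' @param path JSON file.
#' @return A `cimap` object.
#' @export
read_cimap_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- if (length(obj$edges) > 0L) {
    do.call(rbind, strsplit(unlist(obj$edges), "|", fixed = TRUE))
  } else matrix(character(), ncol = 2L)
  dimnames(edges) <- list(NULL, c("a", "b"))
  keyfix <- function(x) gsub("|", "\r", x, fixed = TRUE)
  mi <- unlist(obj$mi) %||% numeric()
  names(mi) <- keyfix(names(mi))
  seps <- lapply(obj$sepsets, as.character)
  names(seps) <- keyfix(names(seps))
  fnr <- obj$policy$fnr
  structure(list(
    nodes = unlist(obj$nodes),
    edges = edges,
    mi = mi,
    sepsets = seps,
    pmax = NULL,
    node_mi = NULL,
    alpha = obj$alpha,
    policy_log = list(fdr = obj$policy$fdr,
                      fnr = fnr_config(isTRUE(fnr$enabled), fnr$alpha,
                                       fnr$beta, fnr$w),
                      n = obj$policy$n)
  ), class = "cimap")
}
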