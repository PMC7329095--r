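# Mutual-information / G-test conditional-independence machinery.
#
# The G statistic for a pair (X, Y) given a conditioning assignment set A is
#   G = 2 * sum_{i,j,a} O_{ij|a} * ln(O_{ij|a} / E_{ij|a}),
# with E the independence-model expected counts within each conditioning
# slice.  G is asymptotically chi-squared with
#   df = (|X| - 1) * (|Y| - 1) * prod(|A_k|)
# and is linked to the plug-in conditional mutual information (in bits) by
#   G = 2 * N * ln(2) * I.

#' Contingency table of a variable pair given a conditioning set
#'
#' @param data A data.frame of factors (a discrete dataset).
#' @param x,y Names of the two tested variables (distinct).
#' @param cond Character vector of conditioning variable names (may be
#'   empty); must exclude `x` and `y`.
#' @return An object of class `ctab`: a 3-d count array (x, y, conditioning
#'   configuration) with cardinalities and total attached.
#' @export
contingency <- function(data, x, y, cond = character()) {
  vars <- c(x, y, cond)
  if (x == y) stop("x and y must differ", call. = FALSE)
  if (x %in% cond || y %in% cond) {
    stop("conditioning set must exclude x and y", call. = FALSE)
  }
  miss <- setdiff(vars, names(data))
  if (length(miss) > 0L) {
    stop("variable(s) not found in data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cols <- lapply(data[vars], function(col) {
    if (!is.factor(col)) factor(col) else col
  })
  cards <- vapply(cols, nlevels, integer(1))
  idx <- lapply(cols, as.integer)
  n <- length(idx[[1L]])
  # linear cell index: x fastest, then y, then conditioning variables
  lin <- idx[[1L]] - 1L
  mult <- cards[[1L]]
  if (length(vars) > 1L) {
    for (k in 2L:length(vars)) {
      lin <- lin + (idx[[k]] - 1L) * mult
      mult <- mult * cards[[k]]
    }
  }
  counts <- tabulate(lin + 1L, nbins = prod(cards))
  ncfg <- prod(cards[-(1:2)])
  arr <- array(counts, dim = c(cards[[1L]], cards[[2L]], max(1L, ncfg)))
  structure(list(counts = arr,
                 x_card = cards[[1L]], y_card = cards[[2L]],
                 cond_cards = if (length(cond) > 0L) cards[-(1:2)] else
                   integer(),
                 n_total = n, x = x, y = y, cond = cond),
            class = "ctab")
}

#' G statistic and degrees of freedom of a contingency table
#'
#' Cells with zero observed count contribute 0; conditioning slices with a
#' zero total are skipped.  The degrees of freedom follow the unconditional
#' formula (x_card - 1)(y_card - 1) * prod(cond_cards) and are not reduced
#' for empty slices.
#'
#' @param table A `ctab` object from [contingency()].
#' @return List with elements `G` (natural-log scale) and `df`.
#' @export
g_statistic <- function(table) {
  stopifnot(inherits(table, "ctab"))
  arr <- table$counts
  G <- 0
  for (a in seq_len(dim(arr)[3L])) {
    O <- arr[, , a, drop = FALSE]
    dim(O) <- dim(arr)[1:2]
    na <- sum(O)
    if (na == 0) next
    E <- outer(rowSums(O), colSums(O)) / na
    nz <- O > 0
    G <- G + 2 * sum(O[nz] * log(O[nz] / E[nz]))
  }
  df <- (table$x_card - 1L) * (table$y_card - 1L) *
    prod(c(1L, table$cond_cards))
  list(G = max(G, 0), df = as.integer(df))
}

#' Plug-in (conditional) mutual information in bits
#'
#' The maximum-likelihood plug-in estimate with probabilities O/N and
#' base-2 logarithms.  Satisfies `G = 2 * N * ln(2) * I` exactly.
#'
#' @param table A `ctab` object.
#' @return Mutual information in bits (non-negative).
#' @export
mutual_information <- function(table) {
  stopifnot(inherits(table, "ctab"))
  g_statistic(table)$G / (2 * table$n_total * log(2))
}

#' False-negative-reduction configuration
#'
#' Parameters of the FNR policy: an independence test is skipped (and the
#' edge kept) when its degrees of freedom exceed the largest df at which a
#' chi-squared test of level `alpha` still has power at least `1 - beta`
#' against the effect size `w` (noncentrality N * w^2).
#'
#' @param enabled Logical; `fnr_off()` is shorthand for a disabled policy.
#' @param alpha Test level in (0, 1).
#' @param beta Tolerated false-negative rate in (0, 1).
#' @param w Cohen-style effect size (> 0 when enabled).
#' @return A list of class `fnr_config`.
#' @export
fnr_config <- function(enabled = TRUE, alpha = 0.05, beta = 0.05, w = 0.25) {
  stopifnot(alpha > 0, alpha < 1, beta > 0, beta < 1)
  if (enabled && !(w > 0)) stop("effect size w must be > 0", call. = FALSE)
  structure(list(enabled = isTRUE(enabled), alpha = alpha, beta = beta,
                 w = w), class = "fnr_config")
}

#' @rdname fnr_config
#' @export
fnr_off <- function() fnr_config(enabled = FALSE, w = 0.1)

#' Maximum testable degrees of freedom under the FNR policy
#'
#' Largest `df` such that an upper-tail chi-squared test at level
#' `cfg$alpha` has power at least `1 - cfg$beta` against noncentrality
#' `n * cfg$w^2` (noncentral chi-squared power, Cohen's formulation).
#' Returns 0 when even df = 1 is underpowered, in which case every test is
#' skipped and the graph stays fully connected.
#'
#' @param n Sample size.
#' @param cfg An enabled [fnr_config()].
#' @return Integer df threshold (>= 0).
#' @export
fnr_max_dof <- function(n, cfg) {
  stopifnot(inherits(cfg, "fnr_config"), cfg$enabled, n >= 1)
  lambda <- n * cfg$w^2
  pow <- function(df) {
    stats::pchisq(stats::qchisq(1 - cfg$alpha, df), df, ncp = lambda,
                  lower.tail = FALSE)
  }
  if (pow(1) < 1 - cfg$beta) return(0L)
  # power is decreasing in df at fixed lambda: bracket then bisect
  hi <- 1
  while (pow(hi * 2) >= 1 - cfg$beta) {
    hi <- hi * 2
    if (hi > 2^40) return(as.integer(2^31 - 2))
  }
  lo <- hi; hi <- hi * 2              # pow(lo) ok, pow(hi) fails
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (pow(mid) >= 1 - cfg$beta) lo <- mid else hi <- mid
  }
  as.integer(lo)
}

#' One conditional-independence test
#'
#' Performs the G-test of X independent of Y given `cond`, unless the test
#' is skipped: (a) under an enabled FNR policy, when df exceeds
#' [fnr_max_dof()]; (b) under the reliability rule of thumb, when the ratio
#' N/df falls below 5.  A skipped test returns verdict
#' `"untested-keep-edge"`, the PC default being to keep the edge.
#'
#' @inheritParams contingency
#' @param alpha Significance level; the verdict is `"independent"` iff the
#'   upper-tail chi-squared p-value is >= `alpha`.
#' @param fnr An [fnr_config()] (use [fnr_off()] to disable).
#' @return A list of class `ci_test` with fields `g_stat`, `mi_bits`, `dof`,
#'   `p_value`, `performed`, `alpha_used`, `verdict`.
#' @export
ci_test <- function(data, x, y, cond = character(), alpha = 0.05,
                    fnr = fnr_off()) {
  tab <- contingency(data, x, y, cond)
  gs <- g_statistic(tab)
  skipped <- FALSE
  if (fnr$enabled && gs$df > fnr_max_dof(tab$n_total, fnr)) skipped <- TRUE
  if (!skipped && tab$n_total / gs$df < 5) skipped <- TRUE
  if (skipped) {
    res <- list(g_stat = gs$G, mi_bits = mutual_information(tab),
                dof = gs$df, p_value = NA_real_, performed = FALSE,
                alpha_used = alpha, verdict = "untested-keep-edge")
  } else {
    p <- stats::pchisq(gs$G, gs$df, lower.tail = FALSE)
    res <- list(g_stat = gs$G, mi_bits = mutual_information(tab),
                dof = gs$df, p_value = p, performed = TRUE,
                alpha_used = alpha,
                verdict = if (p >= alpha) "independent" else "dependent")
  }
  structure(res, class = "ci_test")
}

#' @export
print.ci_test <- function(x, ...) {
  if (x$performed) {
    cat(sprintf("G = %.4f, df = %d, p = %.4g -> %s (alpha = %g)\n",
                x$g_stat, x$dof, x$p_value, x$verdict, x$alpha_used))
  } else {
    cat(sprintf("skipped (df = %d): %s\n", x$dof, x$verdict))
  }
  invisible(x)
}
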