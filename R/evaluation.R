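# Structure-error metrics against a ground-truth network and the benchmark
# experiment drivers: FDR-policy comparison, effect-size scan, sample-size
# scan, and the node-order BIC experiment.

truth_skeleton_keys <- function(truth) {
  e <- bn_edges(truth)
  unique(edge_key(e[, 1L], e[, 2L]))
}

learned_skeleton_keys <- function(learned) {
  if (inherits(learned, "cimap")) {
    e <- learned$edges
  } else if (inherits(learned, "dag")) {
    e <- learned$edges
  } else {
    e <- as.matrix(learned)
  }
  if (nrow(e) == 0L) return(character())
  unique(edge_key(e[, 1L], e[, 2L]))
}

#' Skeleton errors of a learned graph
#'
#' False positives are learned edges absent from the truth skeleton, false
#' negatives are truth edges missing from the learned graph (both over
#' unordered pairs).
#'
#' @param learned A [cimap], `dag`, or two-column edge matrix.
#' @param truth A `bn` object over the same node set.
#' @return A list of class `skeleton_errors` with `fp`, `fn`, `total`.
#' @export
skeleton_errors <- function(learned, truth) {
  stopifnot(inherits(truth, "bn"))
  ln <- if (inherits(learned, c("cimap", "dag"))) learned$nodes else
    unique(c(as.matrix(learned)))
  if (inherits(learned, c("cimap", "dag")) && !setequal(ln, truth$nodes)) {
    stop("learned and truth node sets differ", call. = FALSE)
  }
  le <- learned_skeleton_keys(learned)
  te <- truth_skeleton_keys(truth)
  fp <- length(setdiff(le, te))
  fn <- length(setdiff(te, le))
  structure(list(fp = fp, fn = fn, total = fp + fn),
            class = "skeleton_errors")
}

#' @export
print.skeleton_errors <- function(x, ...) {
  cat(sprintf("skeleton errors: FP %d + FN %d = %d\n", x$fp, x$fn, x$total))
  invisible(x)
}

#' DAG errors of a learned directed graph
#'
#' Skeleton errors plus a direction-error count: edges present in both
#' skeletons but oriented oppositely.
#'
#' @param learned A `dag` object (or from/to edge matrix).
#' @param truth A `bn` object over the same node set.
#' @return A list of class `dag_errors` with `skeleton` and `direction`.
#' @export
dag_errors <- function(learned, truth) {
  skel <- skeleton_errors(learned, truth)
  le <- if (inherits(learned, "dag")) learned$edges else as.matrix(learned)
  te <- bn_edges(truth)
  lkey <- paste(le[, 1L], le[, 2L])
  tkey <- paste(te[, 1L], te[, 2L])
  rev_t <- paste(te[, 2L], te[, 1L])
  direction <- sum(lkey %in% rev_t & !(lkey %in% tkey))
  structure(list(skeleton = skel, direction = direction),
            class = "dag_errors")
}

#' @export
print.dag_errors <- function(x, ...) {
  cat(sprintf("DAG errors: FP %d, FN %d, direction %d\n",
              x$skeleton$fp, x$skeleton$fn, x$direction))
  invisible(x)
}

#' Compare FDR schedules on data sampled from a known network
#'
#' Draws `reps` datasets of `n` observations from `bn` and learns one
#' CI-map per dataset and FDR schedule, using the same datasets for every
#' schedule (a paired design, so schedule differences are not confounded
#' by sampling noise).  Reports per-schedule means and sample standard
#' deviations of FN, FP and total skeleton errors.
#'
#' @param bn Ground-truth `bn`.
#' @param n Observations per dataset.
#' @param reps Number of replicate datasets (>= 2 so that sd is defined).
#' @param policies Character vector of FDR schedules to compare.
#' @param fnr An [fnr_config()].
#' @param alpha Test level.
#' @param seed Master seed; replicate seeds are counter-derived.
#' @return A data.frame with one row per schedule: mean and sd of fn, fp,
#'   total.
#' @export
fdr_comparison <- function(bn, n, reps = 10,
                           policies = c("basic", "interleaved", "mini"),
                           fnr = fnr_off(), alpha = 0.05, seed = NULL) {
  stopifnot(inherits(bn, "bn"))
  if (reps < 2) stop("reps must be >= 2 for a standard deviation",
                     call. = FALSE)
  datasets <- lapply(seq_len(reps), function(k) {
    forward_sample(bn, n, seed = derive_seed(seed %||% 0L, k))
  })
  rows <- lapply(policies, function(pol) {
    errs <- vapply(datasets, function(d) {
      cm <- cimap(d, alpha = alpha, fdr = pol, fnr = fnr)
      e <- skeleton_errors(cm, bn)
      c(e$fn, e$fp, e$total)
    }, numeric(3))
    data.frame(policy = pol,
               fn_mean = mean(errs[1L, ]), fn_sd = stats::sd(errs[1L, ]),
               fp_mean = mean(errs[2L, ]), fp_sd = stats::sd(errs[2L, ]),
               total_mean = mean(errs[3L, ]),
               total_sd = stats::sd(errs[3L, ]))
  })
  do.call(rbind, rows)
}

#' Effect-size scan for the FNR policy
#'
#' For each effect size on the grid, learns CI-maps with the FNR policy at
#' that `w` over `reps` datasets and averages the skeleton errors; also
#' reports the FNR-disabled reference.  The reported `argmin` is the grid
#' value minimising the mean total error (ties broken towards the larger
#' `w`, i.e. fewer skipped tests).
#'
#' @inheritParams fdr_comparison
#' @param w_grid Numeric vector of effect sizes to scan (non-empty).
#' @param beta Tolerated false-negative rate of the FNR policy.
#' @param fdr FDR schedule used throughout.
#' @return A list of class `scan_result`: `grid`, `mean_fp`, `mean_fn`,
#'   `mean_total`, `sd_total`, `argmin`, `reference_total` (FNR off).
#' @export
effect_size_scan <- function(bn, n, w_grid, reps = 10, alpha = 0.05,
                             beta = 0.05, fdr = "basic", seed = NULL) {
  stopifnot(inherits(bn, "bn"))
  if (length(w_grid) == 0L) stop("empty effect-size grid", call. = FALSE)
  datasets <- lapply(seq_len(reps), function(k) {
    forward_sample(bn, n, seed = derive_seed(seed %||% 0L, k))
  })
  run <- function(fnr_cfg) {
    vapply(datasets, function(d) {
      e <- skeleton_errors(cimap(d, alpha = alpha, fdr = fdr, fnr = fnr_cfg),
                           bn)
      c(e$fp, e$fn, e$total)
    }, numeric(3))
  }
  ref <- run(fnr_off())
  res <- vapply(w_grid, function(w) {
    errs <- run(fnr_config(TRUE, alpha = alpha, beta = beta, w = w))
    c(mean(errs[1L, ]), mean(errs[2L, ]), mean(errs[3L, ]),
      stats::sd(errs[3L, ]))
  }, numeric(4))
  mt <- res[3L, ]
  best <- which(mt == min(mt))
  argmin <- w_grid[best[which.max(w_grid[best])]]
  structure(list(grid = w_grid, mean_fp = res[1L, ], mean_fn = res[2L, ],
                 mean_total = mt, sd_total = res[4L, ], argmin = argmin,
                 reference_total = mean(ref[3L, ])),
            class = "scan_result")
}

#' Sample-size scan of skeleton and DAG errors
#'
#' For each sample size, averages skeleton errors over `reps` datasets; DAG
#' errors are averaged from one random-order DAG per CI-map (extended with
#' the replicate's seed).
#'
#' @inheritParams effect_size_scan
#' @param sizes Numeric vector of sample sizes (non-empty).
#' @return A list of class `scan_result` with an additional
#'   `mean_dag_total` vector; `argmin` is the size minimising mean total
#'   skeleton error (ties towards the larger size).
#' @export
sample_size_scan <- function(bn, sizes, reps = 10, fnr = fnr_off(),
                             alpha = 0.05, fdr = "basic", seed = NULL) {
  stopifnot(inherits(bn, "bn"))
  if (length(sizes) == 0L) stop("empty size grid", call. = FALSE)
  res <- vapply(seq_along(sizes), function(si) {
    n <- sizes[si]
    errs <- vapply(seq_len(reps), function(k) {
      sk <- derive_seed(derive_seed(seed %||% 0L, si), k)
      d <- forward_sample(bn, n, seed = sk)
      cm <- cimap(d, alpha = alpha, fdr = fdr, fnr = fnr)
      e <- skeleton_errors(cm, bn)
      pdag <- rule_closure(orient_v_structures(cm))
      dag <- extend_to_dag(pdag, "random", seed = derive_seed(sk, 1L))
      de <- dag_errors(dag, bn)
      c(e$fp, e$fn, e$total, de$skeleton$total + de$direction)
    }, numeric(4))
    c(mean(errs[1L, ]), mean(errs[2L, ]), mean(errs[3L, ]),
      stats::sd(errs[3L, ]), mean(errs[4L, ]))
  }, numeric(5))
  mt <- res[3L, ]
  best <- which(mt == min(mt))
  argmin <- sizes[best[which.max(sizes[best])]]
  structure(list(grid = sizes, mean_fp = res[1L, ], mean_fn = res[2L, ],
                 mean_total = mt, sd_total = res[4L, ],
                 mean_dag_total = res[5L, ], argmin = argmin),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  tab <- data.frame(grid = x$grid, mean_fp = x$mean_fp, mean_fn = x$mean_fn,
                    mean_total = x$mean_total, sd_total = x$sd_total)
  if (!is.null(x$mean_dag_total)) tab$mean_dag_total <- x$mean_dag_total
  print(tab, row.names = FALSE)
  cat("argmin:", x$argmin, "\n")
  if (!is.null(x$reference_total)) {
    cat("FNR-disabled reference mean total:", x$reference_total, "\n")
  }
  invisible(x)
}

#' Node-order experiment for DAG scoring
#'
#' For each of `n_datasets` samples of `n_obs` observations from `bn`,
#' learns a CI-map, orients it, and records the BIC score of the TSF and
#' TWF extensions plus the best and worst of k random-order extensions for
#' each k in `random_set_sizes` (with k = 1, worst equals best).
#'
#' @inheritParams fdr_comparison
#' @param n_datasets Number of replicate datasets.
#' @param n_obs Observations per dataset.
#' @param random_set_sizes Integer vector of random-order set sizes.
#' @return A data.frame with one row per dataset: `tsf`, `twf`, and
#'   `best_k`/`worst_k` columns per set size.
#' @export
node_order_experiment <- function(bn, n_datasets, n_obs,
                                  random_set_sizes = c(1, 25, 100),
                                  alpha = 0.05, fdr = "basic",
                                  fnr = fnr_off(), seed = NULL) {
  stopifnot(inherits(bn, "bn"))
  kmax <- max(random_set_sizes)
  rows <- lapply(seq_len(n_datasets), function(dset) {
    sk <- derive_seed(seed %||% 0L, dset)
    d <- forward_sample(bn, n_obs, seed = sk)
    cm <- cimap(d, alpha = alpha, fdr = fdr, fnr = fnr)
    pdag <- rule_closure(orient_v_structures(cm))
    tsf <- bic_score(extend_to_dag(pdag, "TSF", mi_weight = cm$mi), d)
    twf <- bic_score(extend_to_dag(pdag, "TWF", mi_weight = cm$mi), d)
    rnd <- vapply(seq_len(kmax), function(it) {
      dag <- extend_to_dag(pdag, "random", seed = derive_seed(sk, 1000L + it))
      bic_score(dag, d)
    }, numeric(1))
    out <- data.frame(dataset = dset, tsf = tsf, twf = twf)
    for (k in random_set_sizes) {
      out[[paste0("best_", k)]] <- max(rnd[seq_len(k)])
      out[[paste0("worst_", k)]] <- min(rnd[seq_len(k)])
    }
    out
  })
  do.call(rbind, rows)
}
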