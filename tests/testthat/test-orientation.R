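test_that("v-structure detection follows the sepset rule", {
  # A - B - C with sepset(A, C) = {B}: no orientation
  cm1 <- make_cimap(c("A", "B", "C"), c("A-B", "B-C"),
                    sepsets = list("A|C" = "B"))
  p1 <- orient_v_structures(cm1)
  expect_equal(nrow(p1$directed), 0)
  expect_equal(nrow(p1$undirected), 2)

  # sepset(A, C) empty: collider A -> B <- C
  cm2 <- make_cimap(c("A", "B", "C"), c("A-B", "B-C"),
                    sepsets = list("A|C" = character()))
  p2 <- orient_v_structures(cm2)
  expect_setequal(paste0(p2$directed[, 1], "->", p2$directed[, 2]),
                  c("A->B", "C->B"))

  # a required sepset that was never recorded is a structural error
  cm3 <- make_cimap(c("A", "B", "C"), c("A-B", "B-C"))
  expect_error(orient_v_structures(cm3), "no separating set")
})

test_that("PDAGs equal the exhaustive-enumeration oracle on small fixtures", {
  fixtures <- list(
    list(nodes = c("A", "B", "C"), pairs = c("A-B", "B-C"),
         seps = list("A|C" = character())),
    list(nodes = c("A", "B", "C"), pairs = c("A-B", "B-C"),
         seps = list("A|C" = "B")),
    # star with one collider pair
    list(nodes = c("A", "B", "C", "D"), pairs = c("A-D", "B-D", "C-D"),
         seps = list("A|B" = character(), "A|C" = "D", "B|C" = "D")),
    # square A-B, B-C, C-D, D-A with colliders at B and D
    # (a 4-cycle skeleton always has at least one collider in any DAG)
    list(nodes = c("A", "B", "C", "D"),
         pairs = c("A-B", "B-C", "C-D", "A-D"),
         seps = list("A|C" = character(), "B|D" = c("A", "C"))),
    # path with collider at one end plus pendant
    list(nodes = c("A", "B", "C", "D"), pairs = c("A-B", "C-B", "B-D"),
         seps = list("A|C" = character(), "A|D" = "B", "C|D" = "B")),
    # triangle plus pendant: no unshielded triples inside the triangle
    list(nodes = c("A", "B", "C", "D"),
         pairs = c("A-B", "B-C", "A-C", "C-D"),
         seps = list("A|D" = "C", "B|D" = "C"))
  )
  for (f in fixtures) {
    cm <- make_cimap(f$nodes, f$pairs, sepsets = f$seps)
    got <- pdag_strings(rule_closure(orient_v_structures(cm)))
    want <- oracle_pdag(f$nodes, cm$edges, stats::setNames(
      f$seps, gsub("|", "|", names(f$seps), fixed = TRUE)))
    expect_equal(got$directed, want$directed,
                 info = paste(f$pairs, collapse = " "))
    expect_equal(got$undirected, want$undirected,
                 info = paste(f$pairs, collapse = " "))
  }
})

test_that("rule closure applies the textbook first rule and is idempotent", {
  # A -> B, B - C, A and C non-adjacent => B -> C
  pd <- cimapr:::new_pdag(
    c("A", "B", "C"),
    matrix(c("A", "B"), 1, dimnames = list(NULL, c("from", "to"))),
    matrix(c("B", "C"), 1, dimnames = list(NULL, c("a", "b"))))
  cl <- rule_closure(pd)
  expect_setequal(paste0(cl$directed[, 1], "->", cl$directed[, 2]),
                  c("A->B", "B->C"))

  # no directed edges: closure is the identity
  pd2 <- cimapr:::new_pdag(
    c("A", "B", "C"),
    matrix(character(), ncol = 2, dimnames = list(NULL, c("from", "to"))),
    matrix(c("A", "B", "B", "C"), 2, byrow = TRUE,
           dimnames = list(NULL, c("a", "b"))))
  expect_equal(pdag_strings(rule_closure(pd2)), pdag_strings(pd2))
})

test_that("closure agrees with an independent batch implementation", {
  set.seed(41)
  for (r in 1:40) {
    bn <- random_network(6, 3, c(2, 2), seed = r)
    # consistent PDAG: true skeleton plus the DAG's own colliders
    nodes <- sort(bn$nodes)
    e <- bn_edges(bn)
    coll <- oracle_colliders(bn$nodes, bn$parents)
    dir_e <- unique(unlist(lapply(coll, function(s) {
      parts <- strsplit(s, "->|<-")[[1]]    # x, z, y
      c(paste(parts[1], parts[2]), paste(parts[3], parts[2]))
    })))
    all_pairs <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    dmat <- if (length(dir_e) > 0) {
      do.call(rbind, strsplit(dir_e, " "))
    } else matrix(character(), ncol = 2)
    dkeys <- if (nrow(dmat) > 0) {
      paste(pmin(dmat[, 1], dmat[, 2]), pmax(dmat[, 1], dmat[, 2]))
    } else character()
    ukeys <- setdiff(all_pairs, dkeys)
    umat <- if (length(ukeys) > 0) do.call(rbind, strsplit(ukeys, " ")) else
      matrix(character(), ncol = 2)
    pd <- cimapr:::new_pdag(nodes,
                            `dimnames<-`(dmat, list(NULL, c("from", "to"))),
                            `dimnames<-`(umat, list(NULL, c("a", "b"))))
    got <- pdag_strings(rule_closure(pd))
    want <- pdag_strings(oracle_closure(pd))
    expect_equal(got, want, info = paste("seed", r))
    # idempotence
    expect_equal(pdag_strings(rule_closure(rule_closure(pd))), got)
  }
})

test_that("extension orients every edge, preserves structure, stays acyclic", {
  # fully directed input is returned unchanged
  pd <- cimapr:::new_pdag(
    c("A", "B"),
    matrix(c("A", "B"), 1, dimnames = list(NULL, c("from", "to"))),
    matrix(character(), ncol = 2, dimnames = list(NULL, c("a", "b"))))
  dag <- extend_to_dag(pd, "random", seed = 1)
  expect_equal(paste0(dag$edges[, 1], "->", dag$edges[, 2]), "A->B")

  # undirected triangle: always an acyclic orientation, for all 6 orders
  tri <- cimapr:::new_pdag(
    c("A", "B", "C"),
    matrix(character(), ncol = 2, dimnames = list(NULL, c("from", "to"))),
    matrix(c("A", "B", "B", "C", "A", "C"), 3, byrow = TRUE,
           dimnames = list(NULL, c("a", "b"))))
  perms <- list(c("A","B","C"), c("A","C","B"), c("B","A","C"),
                c("B","C","A"), c("C","A","B"), c("C","B","A"))
  for (ord in perms) {
    dag <- extend_to_dag(tri, "random", node_order = ord)
    expect_equal(nrow(dag$edges), 3)
    expect_true(cimapr:::is_acyclic(dag$nodes, dag$edges[, 1],
                                    dag$edges[, 2]))
  }

  # 100-seed sweep on a learned PDAG: acyclic, skeleton preserved,
  # directed edges of the PDAG respected
  d <- forward_sample(fixture_bn8(), 4000, seed = 9)
  cm <- cimap(d)
  pdag <- rule_closure(orient_v_structures(cm))
  skel <- sort(paste(pmin(cm$edges[, 1], cm$edges[, 2]),
                     pmax(cm$edges[, 1], cm$edges[, 2])))
  pre <- paste0(pdag$directed[, 1], "->", pdag$directed[, 2])
  for (s in 1:100) {
    dag <- extend_to_dag(pdag, "random", seed = s)
    expect_true(cimapr:::is_acyclic(dag$nodes, dag$edges[, 1],
                                    dag$edges[, 2]))
    got_skel <- sort(paste(pmin(dag$edges[, 1], dag$edges[, 2]),
                           pmax(dag$edges[, 1], dag$edges[, 2])))
    expect_equal(got_skel, skel)
    expect_true(all(pre %in% paste0(dag$edges[, 1], "->", dag$edges[, 2])))
  }
})

test_that("BIC matches closed forms and is equal across equivalent DAGs", {
  # single binary node, all rows identical: 0 - ln(100)/2 * 1
  d1 <- data.frame(A = factor(rep("x", 100), levels = c("x", "y")))
  e0 <- matrix(character(), ncol = 2)
  expect_equal(bic_score(e0, d1), -log(100) / 2, tolerance = 1e-12)
  expect_error(bic_score(e0, d1[0, , drop = FALSE]), "empty")

  # two binary nodes, 8 rows; closed forms expanded by hand from counts
  d2 <- data.frame(A = factor(c(0, 0, 0, 0, 1, 1, 1, 1)),
                   B = factor(c(0, 0, 1, 1, 0, 1, 1, 1)))
  # no edge: ll = sum_v sum_c n_c ln(n_c / 8); dims = 2
  ll_A <- 4 * log(4 / 8) + 4 * log(4 / 8)
  ll_B <- 3 * log(3 / 8) + 5 * log(5 / 8)
  expect_equal(bic_score(e0[0, , drop = FALSE], d2), ll_A + ll_B - log(8),
               tolerance = 1e-12)
  # edge A -> B: ll_B|A = 2ln(2/4)+2ln(2/4)+1ln(1/4)+3ln(3/4); dims = 1+2
  eAB <- matrix(c("A", "B"), 1)
  llBA <- 2 * log(2 / 4) + 2 * log(2 / 4) + 1 * log(1 / 4) + 3 * log(3 / 4)
  expect_equal(bic_score(eAB, d2), ll_A + llBA - log(8) / 2 * 3,
               tolerance = 1e-12)
  # reversal scores identically (same skeleton, no colliders)
  expect_equal(bic_score(matrix(c("B", "A"), 1), d2), bic_score(eAB, d2),
               tolerance = 1e-12)

  # chain forward and backward: identical goodness-of-fit
  d3 <- forward_sample(fixture_chain3(), 500, seed = 10)
  fwd <- matrix(c("A", "B", "B", "C"), 2, byrow = TRUE)
  bwd <- matrix(c("C", "B", "B", "A"), 2, byrow = TRUE)
  expect_equal(bic_score(fwd, d3), bic_score(bwd, d3), tolerance = 1e-9)
  expect_lte(bic_score(fwd, d3), 0)
})

test_that("all DAGs in an equivalence class score identically", {
  # random extensions may create extra colliders (different equivalence
  # classes), but two extensions with the same skeleton AND the same
  # collider set must score the same
  bn <- fixture_bn5(2)                     # chain + isolated node
  d <- forward_sample(bn, 1000, seed = 11)
  cm <- cimap(d)
  pdag <- rule_closure(orient_v_structures(cm))
  dags <- lapply(1:40, function(s) extend_to_dag(pdag, "random", seed = s))
  coll_key <- vapply(dags, function(g) {
    paste(oracle_colliders(g$nodes, cimapr:::dag_parents(g$nodes, g$edges)),
          collapse = ";")
  }, character(1))
  scores <- vapply(dags, bic_score, numeric(1), data = d)
  expect_gt(length(unique(coll_key)), 1)     # classes actually differ
  for (k in unique(coll_key)) {
    s <- scores[coll_key == k]
    expect_lt(max(s) - min(s), 1e-9)
  }
  # and scores differ across classes for at least one pair (the penalty
  # is shared, the fit is not)
  cls_means <- tapply(scores, coll_key, mean)
  expect_gt(max(cls_means) - min(cls_means), 1e-9)
})

test_that("cimap_to_dag honours its search contract", {
  d <- forward_sample(fixture_bn5(1), 2000, seed = 12)
  cm <- cimap(d)

  # max_iter = 0 is exactly the TSF extension
  s0 <- cimap_to_dag(cm, d, max_iter = 0)
  pdag <- rule_closure(orient_v_structures(cm))
  tsf <- extend_to_dag(pdag, "TSF", mi_weight = cm$mi)
  expect_equal(s0$bic, bic_score(tsf, d))
  expect_identical(s0$dag$edges, tsf$edges)

  # the best score never falls below the TSF baseline, and is monotone
  # in max_iter for a fixed seed stream
  prev <- -Inf
  for (k in c(0, 5, 20, 60)) {
    sk <- cimap_to_dag(cm, d, max_iter = k, seed = 13)
    expect_gte(sk$bic, sk$baseline_bic)
    expect_gte(sk$bic, prev)
    prev <- sk$bic
  }
  # determinism
  expect_equal(cimap_to_dag(cm, d, max_iter = 30, seed = 14)$bic,
               cimap_to_dag(cm, d, max_iter = 30, seed = 14)$bic)

  # exhaustive node-order enumeration on 5 nodes
  perms <- combinat_perms(cm$nodes)
  best_exhaustive <- max(vapply(perms, function(ord) {
    bic_score(extend_to_dag(pdag, "random", node_order = ord), d)
  }, numeric(1)))
  s_big <- cimap_to_dag(cm, d, max_iter = 2000, seed = 15)
  expect_equal(s_big$bic, best_exhaustive, tolerance = 1e-9)
})
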