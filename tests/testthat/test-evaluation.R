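test_that("MCC arithmetic matches its closed form, including the zero convention", {
  expect_equal(mcc_score(3, 3, 0, 0), 1)
  expect_equal(mcc_score(2, 2, 1, 1), 1 / 3)
  # all four denominator factors are 1 here, so the closed form gives -1
  expect_equal(mcc_score(0, 0, 1, 1), -1)
  expect_equal(mcc_score(0, 3, 0, 0), 0)   # zero factor in the denominator
  # total disagreement on a balanced 2x2
  expect_equal(mcc_score(0, 0, 2, 2), -1)
  expect_equal(mcc_score(1, 0, 1, 1), -0.5)
  expect_gte(mcc_score(5, 5, 1, 1), -1)
})

test_that("a perfect clustering scores 1 everywhere", {
  ref <- reference_pathway(c("A", "B", "C", "D"), c("x", "x", "y", "y"))
  pred <- c(A = "c1", B = "c1", C = "c2", D = "c2")
  rep <- evaluate_clustering(pred, ref)
  expect_equal(rep$per_gene$mcc, rep(1, 4))
  expect_equal(rep$overall, 1)
})

test_that("noise genes form one extra reference cluster and counts match brute force", {
  # reference {A,B},{C}; noise D merged by the prediction into {A,B}
  ref <- reference_pathway(c("A", "B", "C"), c("x", "x", "y"))
  pred <- c(A = "c1", B = "c1", C = "c2", D = "c1")
  rep <- evaluate_clustering(pred, ref, noise_genes = "D")
  full_ref <- c(A = "x", B = "x", C = "y", D = ".noise")
  oracle <- oracle_pair_counts(full_ref, pred)
  got <- rep$per_gene[match(oracle$gene, rep$per_gene$gene), ]
  expect_equal(got$tp, oracle$tp)
  expect_equal(got$tn, oracle$tn)
  expect_equal(got$fp, oracle$fp)
  expect_equal(got$fn, oracle$fn)
  # counts always total n - 1 per gene
  expect_equal(got$tp + got$tn + got$fp + got$fn, rep_len(3L, 4))
  expect_equal(rep$overall, mean(rep$per_cluster$avg_mcc))
})

test_that("splitting a reference pair yields a false negative for both members", {
  ref <- reference_pathway(c("A", "B", "C"), c("x", "x", "y"))
  pred <- c(A = "c1", B = "c2", C = "c3")  # all singletons
  rep <- evaluate_clustering(pred, ref)
  ab <- rep$per_gene[rep$per_gene$gene %in% c("A", "B"), ]
  expect_equal(ab$fn, c(1L, 1L))
  expect_equal(ab$tp, c(0L, 0L))
})

test_that("pair counts are invariant to cluster relabeling and match brute force on random partitions", {
  set.seed(41)
  genes <- sprintf("g%02d", 1:10)
  for (rep_i in 1:10) {
    ref <- reference_pathway(genes, sample(c("r1", "r2", "r3"), 10, replace = TRUE))
    pred <- stats::setNames(sample(c("p1", "p2", "p3"), 10, replace = TRUE), genes)
    r1 <- evaluate_clustering(pred, ref)
    oracle <- oracle_pair_counts(stats::setNames(ref$cluster, ref$gene), pred)
    expect_equal(r1$per_gene[, c("tp", "tn", "fp", "fn")],
                 oracle[, c("tp", "tn", "fp", "fn")],
                 ignore_attr = TRUE)
    expect_true(all(rowSums(r1$per_gene[, c("tp", "tn", "fp", "fn")]) == 9L))
    # relabeling the prediction changes nothing
    relab <- stats::setNames(paste0("z", pred), genes)
    expect_equal(evaluate_clustering(relab, ref)$per_gene, r1$per_gene)
  }
})

test_that("evaluating a gene missing from reference + noise errors", {
  ref <- reference_pathway(c("A", "B"), c("x", "x"))
  expect_error(evaluate_clustering(c(A = "c1"), ref), "missing gene")
  expect_error(evaluate_clustering(c(A = "c1", B = "c1", Z = "c9"), ref),
               "outside reference")
})

test_that("random partitions of planted blocks score near zero on average", {
  ref <- reference_pathway(sprintf("g%02d", 1:12), rep(c("a", "b", "c"), each = 4))
  set.seed(42)
  means <- replicate(200, {
    pred <- stats::setNames(sample(c("p1", "p2", "p3"), 12, replace = TRUE),
                            ref$gene)
    evaluate_clustering(pred, ref)$overall
  })
  expect_lt(abs(mean(means)), 0.15)
})

test_that("noise-gene counts follow round-half-up of fraction times pathway size", {
  ref10 <- reference_pathway(sprintf("p%02d", 1:10), rep("x", 10))
  pool <- sprintf("q%02d", 1:30)
  picked <- inject_noise_genes(ref10, pool, fraction = 0.5, seed = 4)
  expect_equal(length(picked), 5L)                       # 10 * 50% = 5
  expect_true(all(picked %in% pool))
  expect_identical(picked, inject_noise_genes(ref10, pool, fraction = 0.5, seed = 4))
  expect_false(identical(picked,
                         inject_noise_genes(ref10, pool, fraction = 0.5, seed = 5)))

  ref3 <- reference_pathway(c("a", "b", "c"), c("x", "x", "y"))
  expect_equal(length(inject_noise_genes(ref3, pool, fraction = 0.5, seed = 1)), 2L)
  expect_error(inject_noise_genes(ref10, pool[1:3], fraction = 0.5, seed = 1),
               "short by 2")
  expect_error(inject_noise_genes(ref10, ref10$gene, fraction = 0.5, seed = 1),
               "disjoint")
})

test_that("EC-matched noise respects the first two EC levels", {
  ref <- reference_pathway(c("ARO8", "ARO9"), c("amt", "amt"),
                           ec = c("2.6.1.28", "2.6.1.27"))
  pool <- c("CAND1", "CAND2", "CAND3")
  pool_ec <- c(CAND1 = "2.6.1.1", CAND2 = "1.1.1.1", CAND3 = "2.6.3.9")
  picked <- inject_noise_genes(ref, pool, pool_ec, fraction = 0.5,
                               mode = "ec_matched", seed = 2)
  expect_equal(length(picked), 1L)
  expect_true(picked %in% c("CAND1", "CAND3"))  # 2.6.x.x only, never 1.1.x.x
  expect_identical(picked,
                   inject_noise_genes(ref, pool, pool_ec, fraction = 0.5,
                                      mode = "ec_matched", seed = 2))
  expect_error(inject_noise_genes(ref, c("ONLY1"), c(ONLY1 = "1.1.1.1"),
                                  fraction = 0.5, mode = "ec_matched", seed = 1),
               "eligible")
  expect_error(inject_noise_genes(ref, pool, NULL, fraction = 0.5,
                                  mode = "ec_matched", seed = 1), "EC numbers")
})

test_that("term-pair sampling is seeded, distinct, and honours the Wang threshold", {
  spec <- fixture_spec(n_terms = 40, seed = 43)
  ont <- simulate_ontology(spec)
  plain <- sample_term_pairs(ont, 10, "BPO", seed = 9)
  expect_equal(nrow(plain), 10L)
  expect_equal(nrow(unique(plain)), 10L)
  expect_true(all(plain$a != plain$b))
  expect_identical(plain, sample_term_pairs(ont, 10, "BPO", seed = 9))

  thr <- sample_term_pairs(ont, 8, "BPO", min_wang_sim = 0.5, seed = 9)
  wang <- gogo_config(method = "WANG")
  recheck <- mapply(function(a, b) term_similarity(ont, a, b, wang),
                    thr$a, thr$b)
  expect_true(all(recheck >= 0.5))
  expect_equal(unname(recheck), thr$wang_sim, tolerance = 1e-12)

  # an unattainable threshold exhausts the attempt budget with a diagnostic
  expect_error(sample_term_pairs(ont, 5, "BPO", min_wang_sim = 1.0, seed = 9,
                                 max_attempts = 300), "acceptance rate")
})

test_that("sibling pairs share a parent and sit at the requested depth", {
  spec <- fixture_spec(n_terms = 50, seed = 44)
  ont <- simulate_ontology(spec)
  depths <- go_depths(ont, "BPO")
  for (d in 1:2) {
    got <- tryCatch(sample_sibling_pairs(ont, d, 3, "BPO", seed = 5),
                    error = function(e) e)
    if (inherits(got, "error")) next
    for (r in seq_len(nrow(got))) {
      a <- got$a[r]; b <- got$b[r]
      expect_equal(unname(depths[a]), d)
      expect_equal(unname(depths[b]), d)
      expect_gt(length(intersect(go_parents(ont, a)$parent,
                                 go_parents(ont, b)$parent)), 0L)
    }
  }
  # two children of the root are a sibling pair at depth 1
  tiny <- parse_obo(c("format-version: 1.2", "",
    "[Term]", "id: GO:1", "name: r", "namespace: biological_process", "",
    "[Term]", "id: GO:2", "name: a", "namespace: biological_process", "is_a: GO:1", "",
    "[Term]", "id: GO:3", "name: b", "namespace: biological_process", "is_a: GO:1"))
  p <- sample_sibling_pairs(tiny, 1, 1, "BPO", seed = 1)
  expect_setequal(c(p$a, p$b), c("GO:2", "GO:3"))
  expect_error(sample_sibling_pairs(tiny, 1, 5, "BPO", seed = 1), "available")
})

test_that("method correlation matrices match direct moment computation", {
  pairs <- data.frame(a = c("t1", "t2", "t3", "t4"), b = c("u1", "u2", "u3", "u4"),
                      stringsAsFactors = FALSE)
  base <- c(t1 = 0.1, t2 = 0.4, t3 = 0.7, t4 = 0.9)
  f1 <- function(a, b) base[[a]]
  f2 <- function(a, b) 2 * base[[a]] + 1     # affine transform: correlation 1
  f3 <- function(a, b) 1 - base[[a]]         # reversed: correlation -1
  m <- method_correlation_matrix(pairs, list(one = f1, two = f2, rev = f3))
  expect_equal(unname(diag(m)), rep(1, 3))
  expect_equal(m["one", "two"], 1)
  expect_equal(m["one", "rev"], -1)
  expect_equal(m, t(m))
  # zero-variance method flagged
  f0 <- function(a, b) 0.5
  expect_warning(m0 <- method_correlation_matrix(pairs, list(one = f1, flat = f0)),
                 "zero variance")
  expect_true(is.na(m0["one", "flat"]))
})
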