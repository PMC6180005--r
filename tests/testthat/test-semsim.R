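test_that("children are counted over the configured relations in the full graph", {
  ont <- parse_obo(mixed_obo)
  # bp root GO:0000100 has is_a children 101, 103 and part_of child 102
  expect_equal(children_count(ont, "GO:0000100", "is_a"), 2L)
  expect_equal(children_count(ont, "GO:0000100", c("is_a", "part_of")), 3L)
  expect_equal(children_count(ont, "GO:0000102", c("is_a", "part_of")), 0L)
  # a term that is both is_a and part_of child would still count once
  expect_equal(children_count(ont, "GO:0000101",
                              c("is_a", "part_of", "regulates")), 2L)
})

test_that("edge weights follow 1/(c + nc) + d and the Wang constants", {
  chain <- parse_obo(chain_obo)
  cfg <- gogo_config()
  expect_equal(edge_weight(chain, "GO:0000002", "is_a", cfg), 1 / 1.67 + 0.4,
               tolerance = 1e-12)

  # nc = 9 part_of example: build a star with 9 children
  star <- parse_obo(c("format-version: 1.2", "",
    "[Term]", "id: GO:0000020", "name: hub", "namespace: biological_process",
    unlist(lapply(1:9, function(i) {
      c("", "[Term]", paste0("id: GO:00000", 20 + i), paste0("name: c", i),
        "namespace: biological_process", "relationship: part_of GO:0000020")
    }))))
  expect_equal(edge_weight(star, "GO:0000020", "part_of", gogo_config()),
               1 / 9.67 + 0.3, tolerance = 1e-12)

  wang <- gogo_config(method = "WANG")
  expect_equal(edge_weight(chain, "GO:0000002", "is_a", wang), 0.8)
})

test_that("c below 0.67 is rejected unless explicitly unsafe, and bad weights error", {
  expect_error(gogo_config(c = 0.5), ">= 0.67")
  cfg <- gogo_config(c = 0.5, unsafe_c = TRUE)
  chain <- parse_obo(chain_obo)
  # nc = 1, d = 0.4: w = 1/(0.5+1) + 0.4 = 1.0667 > 1 must be caught
  expect_error(edge_weight(chain, "GO:0000002", "is_a", cfg), "outside")
  # the boundary configuration c = 0.67, nc = 1 is legal (w ~ 0.9988)
  expect_lte(edge_weight(chain, "GO:0000002", "is_a", gogo_config()), 1)
})

test_that("S-values on the chain equal the path product and sum to the semantic value", {
  chain <- parse_obo(chain_obo)
  g <- ancestor_graph(chain, "GO:0000003")
  w <- 1 / 1.67 + 0.4
  expect_equal(unname(g$s_values["GO:0000003"]), 1)
  expect_equal(unname(g$s_values["GO:0000002"]), w, tolerance = 1e-12)
  expect_equal(unname(g$s_values["GO:0000001"]), w^2, tolerance = 1e-12)
  expect_equal(semantic_value(g), 1 + w + w^2, tolerance = 1e-12)

  root <- ancestor_graph(chain, "GO:0000001")
  expect_equal(root$nodes, "GO:0000001")
  expect_equal(semantic_value(root), 1)
})

test_that("the diamond takes the maximum over path products", {
  ont <- parse_obo(diamond_obo)
  g <- ancestor_graph(ont, "GO:0000010")
  wB <- 1 / (0.67 + 2) + 0.4   # B has children A and X
  wC <- 1 / (0.67 + 1) + 0.4   # C has child A only
  wD <- 1 / (0.67 + 2) + 0.4   # D has children B and C
  expect_equal(unname(g$s_values["GO:0000011"]), wB, tolerance = 1e-12)
  expect_equal(unname(g$s_values["GO:0000012"]), wC, tolerance = 1e-12)
  expect_equal(unname(g$s_values["GO:0000013"]), max(wD * wB, wD * wC),
               tolerance = 1e-12)
  o <- oracle_s_values(ont, "GO:0000010")
  expect_equal(g$s_values[sort(names(g$s_values))], o[sort(names(o))],
               tolerance = 1e-12)
})

test_that("term similarity is symmetric, 1 on the diagonal, and in range", {
  spec <- fixture_spec(n_terms = 40, seed = 11)
  ont <- simulate_ontology(spec)
  ids <- ont$terms$id
  set.seed(11)
  cfgs <- list(gogo_config(),
               gogo_config(relations = c("is_a", "part_of", "regulates")),
               gogo_config(method = "WANG"))
  for (cfg in cfgs) {
    cache <- new_semsim_cache()
    for (rep in 1:15) {
      p <- sample(ids, 2L)
      sab <- term_similarity(ont, p[1], p[2], cfg, cache)
      sba <- term_similarity(ont, p[2], p[1], cfg, cache)
      expect_identical(sab, sba)
      expect_gte(sab, 0); expect_lte(sab, 1)
      # single root: every pair shares at least the root ancestor
      expect_gt(sab, 0)
      expect_equal(term_similarity(ont, p[1], p[1], cfg, cache), 1)
    }
  }
})

test_that("cross-namespace pairs error without the cross-namespace flag", {
  ont <- parse_obo(mixed_obo)
  expect_error(term_similarity(ont, "GO:0000102", "GO:0000151"),
               "different namespaces")
})

test_that("dynamic-programming S-values match exhaustive path enumeration", {
  # many random DAGs, each checked node-by-node against the path oracle
  for (s in 1:60) {
    spec <- fixture_spec(n_terms = sample(5:30, 1), max_depth = sample(3:6, 1),
                         extra_parent_prob = 0.4, seed = 1000 + s)
    ont <- simulate_ontology(spec)
    target <- sample(ont$terms$id, 1L)
    for (cfg in list(gogo_config(), gogo_config(method = "WANG"))) {
      g <- ancestor_graph(ont, target, cfg)
      o <- oracle_s_values(ont, target, cfg)
      expect_equal(g$s_values[sort(names(g$s_values))], o[sort(names(o))],
                   tolerance = 1e-12)
    }
  }
})

test_that("similarity matches the full brute-force evaluation on random fixtures", {
  for (s in 1:10) {
    spec <- fixture_spec(n_terms = 20, extra_parent_prob = 0.4, seed = 2000 + s)
    ont <- simulate_ontology(spec)
    set.seed(s)
    p <- sample(ont$terms$id, 2L)
    expect_equal(term_similarity(ont, p[1], p[2]),
                 oracle_term_similarity(ont, p[1], p[2]), tolerance = 1e-12)
  }
})

test_that("inflating an ancestor's children count lowers similarity through it", {
  # siblings under mid, with extra children attachable to mid
  make_ont <- function(extra) {
    lines <- c("format-version: 1.2", "",
      "[Term]", "id: GO:0000300", "name: root", "namespace: biological_process", "",
      "[Term]", "id: GO:0000301", "name: mid", "namespace: biological_process",
      "is_a: GO:0000300", "",
      "[Term]", "id: GO:0000302", "name: s1", "namespace: biological_process",
      "is_a: GO:0000301", "",
      "[Term]", "id: GO:0000303", "name: s2", "namespace: biological_process",
      "is_a: GO:0000301")
    for (i in seq_len(extra)) {
      lines <- c(lines, "", "[Term]", sprintf("id: GO:00004%02d", i),
                 sprintf("name: extra%d", i), "namespace: biological_process",
                 "is_a: GO:0000301")
    }
    parse_obo(lines)
  }
  sims <- vapply(c(0, 5, 28), function(extra) {
    term_similarity(make_ont(extra), "GO:0000302", "GO:0000303")
  }, numeric(1))
  expect_true(all(diff(sims) < 0))
  # Wang's fixed weights cannot tell these settings apart
  wang <- vapply(c(0, 5, 28), function(extra) {
    term_similarity(make_ont(extra), "GO:0000302", "GO:0000303",
                    gogo_config(method = "WANG"))
  }, numeric(1))
  expect_equal(diff(wang), c(0, 0), tolerance = 1e-12)
})

test_that("the memoising cache does not change results", {
  spec <- fixture_spec(n_terms = 25, seed = 5)
  ont <- simulate_ontology(spec)
  ids <- ont$terms$id[c(3, 10, 17, 24)]
  cache <- new_semsim_cache()
  for (i in 1:3) for (j in 4:2) {
    expect_identical(term_similarity(ont, ids[i], ids[j], cache = cache),
                     term_similarity(ont, ids[i], ids[j]))
  }
})

test_that("term similarity matrices are symmetric with unit diagonal", {
  spec <- fixture_spec(n_terms = 20, seed = 6)
  ont <- simulate_ontology(spec)
  m <- term_sim_matrix(ont, ont$terms$id[c(2, 7, 11, 19)])
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 4))
  expect_true(all(m >= 0 & m <= 1))
})
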