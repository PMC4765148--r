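# OBO parsing, DAG distances and hierarchical (HIB) mapping.

test_that("OBO parsing builds the expected DAG and drops obsolete terms", {
  expect_warning(dag <- read_obo(toy_obo_lines()), "obsolete")
  expect_identical(sort(dag$ids),
                   c("GO:0000001", "GO:0000002", "GO:0000003",
                     "GO:0000005", "GO:0000006"))
  expect_identical(attr(dag, "n_obsolete"), 1L)
  # edges: child -> parent, by id
  i3 <- dag$index[["GO:0000003"]]
  expect_setequal(dag$ids[dag$parents[[i3]]],
                  c("GO:0000002", "GO:0000001"))
  expect_setequal(dag$edge_type[[i3]], c("is_a", "part_of"))
  expect_setequal(dag$roots, c("GO:0000001", "GO:0000005"))
  expect_identical(unname(dag$namespace[dag$index[["GO:0000006"]]]), "BP")
})

test_that("cyclic or namespace-broken OBO input is rejected", {
  cyc <- c("[Term]", "id: GO:0000001", "namespace: cellular_component",
           "is_a: GO:0000002", "",
           "[Term]", "id: GO:0000002", "namespace: cellular_component",
           "is_a: GO:0000001")
  expect_error(read_obo(cyc), "cycle")
  nons <- c("[Term]", "id: GO:0000001")
  expect_error(read_obo(nons), "namespace")
  cross <- c("[Term]", "id: GO:0000001", "namespace: cellular_component",
             "", "[Term]", "id: GO:0000002",
             "namespace: biological_process", "is_a: GO:0000001")
  expect_error(read_obo(cross), "taxonomies")
})

test_that("DAG distances: identity, cross-taxonomy, and BFS agreement", {
  suppressWarnings(dag <- read_obo(toy_obo_lines()))
  expect_identical(dag_distance(dag, "GO:0000003", "GO:0000003"), 0L)
  expect_identical(dag_distance(dag, "GO:0000003", "GO:0000002"), 1L)
  # part_of shortcut: leafA -> rootA directly
  expect_identical(dag_distance(dag, "GO:0000003", "GO:0000001"), 1L)
  # restricted to is_a only, the path goes through midA
  expect_identical(dag_distance(dag, "GO:0000003", "GO:0000001",
                                edge_types = "is_a"), 2L)
  expect_identical(dag_distance(dag, "GO:0000003", "GO:0000006"), Inf)
  expect_error(dag_distance(dag, "GO:0000003", "GO:9999999"), "not in the DAG")
})

test_that("distances on random toy DAGs match the BFS oracle", {
  for (seed in 1:4) {
    toy <- make_toy_dag(depth = 3, branching = 2, extra_edge_prob = 0.3,
                        seed = seed)
    dag <- toy$dag
    # flatten edges for the oracle
    ef <- character(0); et <- character(0)
    for (i in seq_along(dag$ids)) {
      for (p in dag$parents[[i]]) {
        ef <- c(ef, dag$ids[i]); et <- c(et, dag$ids[p])
      }
    }
    set.seed(100 + seed)
    for (rep in 1:8) {
      ab <- sample(dag$ids, 2)
      got <- dag_distance(dag, ab[1], ab[2])
      ns <- dag$namespace[dag$index[ab]]
      want <- if (ns[1] != ns[2]) Inf else {
        oracle_bfs_distance(ef, et, ab[1], ab[2])
      }
      expect_equal(as.numeric(got), as.numeric(want))
    }
  }
})

test_that("toy DAG generator: sizes, acyclicity, pure-tree distances", {
  toy <- make_toy_dag(depth = 1, branching = 2, seed = 1)
  expect_identical(sum(toy$dag$namespace == "CC"), 3L)  # root + 2 children
  expect_length(toy$dag$ids, 9L)
  # constructor runs Kahn's algorithm, so construction implies acyclicity;
  # check a pure tree's distances equal tree distances (siblings at 2)
  tree <- make_toy_dag(depth = 2, branching = 2, extra_edge_prob = 0,
                       seed = 2)$dag
  root_cc <- tree$roots[tree$namespace[tree$index[tree$roots]] == "CC"]
  kids <- tree$ids[vapply(seq_along(tree$ids), function(i) {
    any(tree$parents[[i]] == tree$index[[root_cc]])
  }, TRUE)]
  expect_identical(dag_distance(tree, kids[1], kids[2]), 2L)
  expect_identical(dag_distance(tree, kids[1], root_cc), 1L)
  # annotation db is valid and non-empty
  expect_s3_class(toy$db, "annotation_db")
  expect_gt(length(toy$db), 0L)
})

test_that("hib_params validates the decay contract", {
  p <- hib_params()
  expect_identical(p$decay(0), 1)
  expect_identical(p$decay(2), 0.25)
  expect_error(hib_params(max_distance = -1), ">= 0")
  expect_error(hib_params(decay = function(d) 2^d), "non-increasing")
  expect_error(hib_params(decay = function(d) 0.5 * 2^(-d)), "w\\(0\\)")
})

test_that("HIB mapping: identity contribution, chain decay, null signal", {
  chain <- c("[Term]", "id: GO:0000001", "namespace: cellular_component",
             "", "[Term]", "id: GO:0000002",
             "namespace: cellular_component", "is_a: GO:0000001",
             "", "[Term]", "id: GO:0000003",
             "namespace: cellular_component", "is_a: GO:0000002")
  dag <- read_obo(chain)
  # G = E with count 2: at least f * w(0) = 2
  v <- map_to_essential(c("GO:0000001" = 2L), "GO:0000001", dag)
  expect_gte(unname(v[["GO:0000001"]]), 2)
  # chain A<-B<-C, essential {A}, annotated {C:3}, w(d)=2^-d, D=3 -> 0.75
  v <- map_to_essential(c("GO:0000003" = 3L), "GO:0000001", dag,
                        hib_params(max_distance = 3))
  expect_equal(unname(v[["GO:0000001"]]), 3 * 0.25)
  # beyond reach: null vector plus the null-feature-vector signal
  expect_warning(
    v0 <- map_to_essential(c("GO:0000003" = 1L), "GO:0000001", dag,
                           hib_params(max_distance = 1)),
    class = "sparseloc_null_feature_vector")
  expect_true(all(v0 == 0))
})

test_that("HIB additivity, distance dominance, and D = 0 reduction", {
  toy <- make_toy_dag(depth = 3, branching = 2, extra_edge_prob = 0.2,
                      seed = 5)
  dag <- toy$dag
  set.seed(50)
  cc_terms <- dag$ids[dag$namespace == "CC"]
  essential <- sample(cc_terms, 3)
  ms1 <- stats::setNames(c(2L, 1L), sample(cc_terms, 2))
  ms2 <- stats::setNames(c(1L, 3L), sample(cc_terms, 2))
  merged <- merge_two <- tapply(c(ms1, ms2), names(c(ms1, ms2)), sum)
  merged <- stats::setNames(as.integer(merge_two), names(merge_two))
  pars <- hib_params(max_distance = 4)
  va <- suppressWarnings(map_to_essential(ms1, essential, dag, pars))
  vb <- suppressWarnings(map_to_essential(ms2, essential, dag, pars))
  vm <- suppressWarnings(map_to_essential(merged, essential, dag, pars))
  expect_equal(vm, va + vb, tolerance = 1e-12)
  # increasing D never decreases any entry
  for (D in 0:3) {
    v_small <- suppressWarnings(
      map_to_essential(ms1, essential, dag, hib_params(max_distance = D)))
    v_big <- suppressWarnings(
      map_to_essential(ms1, essential, dag, hib_params(max_distance = D + 1)))
    expect_true(all(v_big >= v_small - 1e-12))
  }
  # D = 0 equals the plain projection restricted to essential terms
  v0 <- suppressWarnings(
    map_to_essential(ms1, essential, dag, hib_params(max_distance = 0)))
  plain <- stats::setNames(numeric(3), essential)
  hit <- intersect(names(ms1), essential)
  plain[hit] <- ms1[hit]
  expect_equal(v0, plain)
})

test_that("nearest_only assigns contributions to the closest essential term", {
  chain <- c("[Term]", "id: GO:0000001", "namespace: cellular_component",
             "", "[Term]", "id: GO:0000002",
             "namespace: cellular_component", "is_a: GO:0000001",
             "", "[Term]", "id: GO:0000003",
             "namespace: cellular_component", "is_a: GO:0000002")
  dag <- read_obo(chain)
  ess <- c("GO:0000001", "GO:0000002")
  v_all <- map_to_essential(c("GO:0000003" = 2L), ess, dag)
  expect_equal(unname(v_all), c(2 * 0.25, 2 * 0.5))
  v_near <- map_to_essential(c("GO:0000003" = 2L), ess, dag,
                             hib_params(nearest_only = TRUE))
  expect_equal(unname(v_near), c(0, 2 * 0.5))
})
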