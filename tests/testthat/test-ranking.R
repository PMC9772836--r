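toy_paths <- function(kg = toy_kg_a()) kg_shortest_paths(kg, "n1", "n4")

test_that("path-degree product matches hand arithmetic on the toy graph", {
  kg <- toy_kg_a()
  paths <- toy_paths(kg)
  expect_identical(score_pdp(paths[[1]], kg, w = 1), 1 / 12)
  expect_identical(score_pdp(paths[[2]], kg, w = 1), 1 / 16)

  one_edge <- kg_shortest_paths(kg, "n1", "n2")[[1]]
  for (w in c(0.1, 0.4, 1, 3)) expect_identical(score_pdp(one_edge, kg, w), 1)
  zero_len <- kg_shortest_paths(kg, "n1", "n1")[[1]]
  expect_identical(score_pdp(zero_len, kg), 1)
})

test_that("PDP ranking selects the hub-avoiding path for every w", {
  kg <- toy_kg_a()
  for (w in c(0.1, 0.4, 1, 3)) {
    rp <- rank_paths(toy_paths(kg), "pdp", kg = kg, w = w)
    expect_identical(selected_path(rp)$nodes, c("n1", "n2", "n3", "n4"))
  }
})

test_that("PDP ordering is invariant under the damping exponent", {
  n_checked <- 0
  for (seed in c(1, 2, 6)) {
    kg <- small_random_kg(seed, n = 12, m = 28)
    tied <- find_tied_pair(kg)
    if (is.null(tied)) next
    n_checked <- n_checked + 1
    orders <- lapply(c(0.1, 0.4, 1, 3), function(w) {
      vapply(rank_paths(tied$paths, "pdp", kg = kg, w = w)$paths,
             path_seq_string, "")
    })
    for (o in orders[-1]) expect_identical(o, orders[[1]])
  }
  expect_gte(n_checked, 2)
})

test_that("raising one intermediate's degree strictly lowers PDP", {
  nodes <- tibble::tibble(id = c("s", "m", "t", paste0("x", 1:3)),
                          label = "")
  edges <- tibble::tibble(subject = c("s", "m"), predicate = "p",
                          object = c("m", "t"))
  base <- knowledge_graph(nodes, edges)
  p <- kg_shortest_paths(base, "s", "t")[[1]]
  low <- score_pdp(p, base, w = 0.4)
  heavier <- knowledge_graph(nodes, dplyr::bind_rows(
    edges, tibble::tibble(subject = "m", predicate = "p",
                          object = c("x1", "x2", "x3"))))
  expect_lt(score_pdp(kg_shortest_paths(heavier, "s", "t")[[1]],
                      heavier, w = 0.4), low)
})

test_that("cosine similarity behaves on canonical vectors and rejects zeros", {
  expect_equal(cosine_similarity(c(1, 0), c(1, 0)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 0), c(-1, 0)), -1)
  expect_error(cosine_similarity(c(0, 0), c(1, 0)),
               class = "kg_undefined_similarity")
  expect_error(cosine_similarity(c(1, 0), c(1, 0, 0)), "dimension")
})

test_that("CS path scores match the injected-table hand computation", {
  kg <- toy_kg_a()
  paths <- toy_paths(kg)
  emb <- toy_cs_table()
  expect_equal(score_cs(paths[[1]], emb, "n4"), 1)
  expect_equal(score_cs(paths[[2]], emb, "n4"), -1)
  rp <- rank_paths(paths, "cs", embeddings = emb, target = "n4")
  expect_identical(selected_path(rp)$nodes, c("n1", "n2", "n3", "n4"))

  zero_len <- kg_shortest_paths(kg, "n4", "n4")[[1]]
  expect_identical(score_cs(zero_len, emb, "n4"), 0)
  expect_error(score_cs(paths[[1]], fixed_embeddings(list(n4 = c(1, 0))), "n4"),
               "n1", class = "kg_missing_embedding")
})

test_that("identical embeddings score every length-L path as L", {
  kg <- small_random_kg(5)
  ids <- kg_nodes(kg)$id
  emb <- fixed_embeddings(setNames(rep(list(c(0.3, 0.7)), length(ids)), ids))
  tied <- find_tied_pair(kg)
  expect_false(is.null(tied))
  for (p in tied$paths) expect_equal(score_cs(p, emb, tied$target), p$length)
  # ranking degenerates to the deterministic tie-break
  rp <- rank_paths(tied$paths, "cs", embeddings = emb, target = tied$target)
  keys <- vapply(tied$paths, path_seq_string, "")
  expect_identical(vapply(rp$paths, path_seq_string, ""), sort(keys))
})

test_that("edge constraints keep, drop, relax and error as specified", {
  kg <- toy_kg_a()
  variants <- purrr::list_flatten(purrr::map(toy_paths(kg),
                                             expand_edge_variants, kg = kg))

  hard <- apply_edge_constraints(variants,
                                 edge_constraint(prohibit = "only_in_taxon"))
  expect_false(hard$relaxed)
  expect_length(hard$paths, 1)
  expect_identical(hard$paths[[1]]$nodes, c("n1", "n2", "n3", "n4"))

  all_gone_soft <- apply_edge_constraints(
    variants, edge_constraint(prohibit = c("interacts_with", "only_in_taxon"),
                              soft = TRUE))
  expect_true(all_gone_soft$relaxed)
  expect_identical(all_gone_soft$paths, variants)

  all_gone_hard <- apply_edge_constraints(
    variants, edge_constraint(prohibit = c("interacts_with", "only_in_taxon")))
  expect_false(all_gone_hard$relaxed)
  expect_length(all_gone_hard$paths, 0)

  noop <- apply_edge_constraints(variants, edge_constraint())
  expect_identical(noop$paths, variants)
  expect_false(noop$relaxed)

  required <- apply_edge_constraints(variants,
                                     edge_constraint(require = "only_in_taxon"))
  expect_true(all(vapply(required$paths, function(p)
    any(p$edges$predicate == "only_in_taxon"), TRUE)))

  expect_error(edge_constraint(require = "a", prohibit = "a"))
  expect_error(
    rank_paths(variants, "pdp", kg = kg,
               constraint = edge_constraint(prohibit = c("interacts_with",
                                                         "only_in_taxon"))),
    class = "kg_no_path_after_constraint")
})

test_that("with soft constraints no survivor ever carries a prohibited edge unless relaxed", {
  for (seed in 1:20) {
    kg <- small_random_kg(seed)
    ids <- kg_nodes(kg)$id
    withr::with_seed(seed, pair <- sample(ids, 2))
    paths <- kg_shortest_paths(kg, pair[1], pair[2], max_paths = 500)
    if (length(paths) == 0) next
    variants <- purrr::list_flatten(purrr::map(paths, expand_edge_variants,
                                               kg = kg))
    res <- apply_edge_constraints(variants,
                                  edge_constraint(prohibit = "only_in_taxon",
                                                  soft = TRUE))
    if (!res$relaxed) {
      expect_true(all(vapply(res$paths, function(p)
        !any(p$edges$predicate == "only_in_taxon"), TRUE)))
    } else {
      expect_identical(res$paths, variants)
    }
  }
})

test_that("rank_paths ordering equals a brute-force sort of oracle scores", {
  for (seed in 1:15) {
    kg <- small_random_kg(seed, n = 10, m = 24)
    ids <- kg_nodes(kg)$id
    withr::with_seed(seed + 500, {
      pair <- sample(ids, 2)
      emb <- fixed_embeddings(setNames(
        lapply(ids, function(i) stats::rnorm(4)), ids))
    })
    paths <- kg_shortest_paths(kg, pair[1], pair[2], max_paths = 500)
    if (length(paths) == 0) next

    for (action in c("pdp", "cs")) {
      rp <- rank_paths(paths, action, kg = kg, w = 0.4, embeddings = emb,
                       target = pair[2])
      want_scores <- vapply(paths, function(p) {
        if (action == "pdp") oracle_pdp(p, kg, 0.4)
        else oracle_cs(p, emb, pair[2])
      }, 0)
      keys <- vapply(paths, path_seq_string, "")
      want <- keys[order(-want_scores, keys)]
      expect_identical(vapply(rp$paths, path_seq_string, ""), want)
      expect_equal(rp$scores, sort(want_scores, decreasing = TRUE))
    }
  }
})

test_that("CS and PDP rank the same path set as permutations of each other", {
  kg <- small_random_kg(23, n = 12, m = 25)
  ids <- kg_nodes(kg)$id
  withr::with_seed(23, {
    emb <- fixed_embeddings(setNames(lapply(ids, function(i) stats::rnorm(4)),
                                     ids))
  })
  tied <- find_tied_pair(kg)
  expect_false(is.null(tied))
  paths <- tied$paths
  rp_pdp <- rank_paths(paths, "pdp", kg = kg)
  rp_cs <- rank_paths(paths, "cs", embeddings = emb, target = tied$target)
  expect_setequal(vapply(rp_pdp$paths, path_seq_string, ""),
                  vapply(rp_cs$paths, path_seq_string, ""))
  p <- plot_rank_comparison(rp_pdp, rp_cs)
  expect_s3_class(p, "ggplot")
})

test_that("single-path input is selected regardless of action", {
  kg <- toy_kg_a()
  p <- kg_shortest_paths(kg, "n1", "n2")
  emb <- fixed_embeddings(list(n1 = c(1, 0), n2 = c(0, 1)))
  for (spec in list(list(action = "pdp"), list(action = "cs"))) {
    rp <- rank_paths(p, spec$action, kg = kg, embeddings = emb, target = "n2")
    expect_identical(selected_path(rp)$nodes, c("n1", "n2"))
  }
})

test_that("tidy and glance summarize a ranking", {
  kg <- toy_kg_a()
  rp <- rank_paths(toy_paths(kg), "pdp", kg = kg, w = 1)
  tb <- tidy(rp)
  expect_identical(tb$rank, 1:2)
  expect_identical(tb$selected, c(TRUE, FALSE))
  expect_equal(tb$score, c(1 / 12, 1 / 16))
  g <- glance(rp)
  expect_identical(g$n_paths, 2L)
  expect_identical(g$selected, "n1 -> n2 -> n3 -> n4")
  expect_s3_class(autoplot(rp), "ggplot")
})
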