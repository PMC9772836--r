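test_that("toy graph round-trips through both TSV dialects", {
  kg <- toy_kg_a()
  for (dialect in list(dialect_kgx(), dialect_pheknowlator())) {
    dir <- withr::local_tempdir()
    paths <- write_kg(kg, file.path(dir, "toy"), dialect)
    kg2 <- read_kg(paths[["nodes"]], paths[["edges"]], dialect)
    expect_identical(nrow(kg_nodes(kg2)), 8L)
    expect_identical(kg_edges(kg2), kg_edges(kg))
    expect_identical(kg_nodes(kg2)$id, kg_nodes(kg)$id)
    expect_identical(kg_nodes(kg2)$label, kg_nodes(kg)$label)
    if (identical(dialect$name, "kgx")) {
      expect_identical(kg_nodes(kg2)$category, kg_nodes(kg)$category)
    }
  }
})

test_that("random fixtures round-trip and the two dialects parse identically", {
  for (seed in 1:20) {
    kg <- small_random_kg(seed, n = 10, m = 18)
    dir <- withr::local_tempdir()
    pk <- write_kg(kg, file.path(dir, "pk"), dialect_pheknowlator())
    kx <- write_kg(kg, file.path(dir, "kx"), dialect_kgx())
    kg_pk <- read_kg(pk[["nodes"]], pk[["edges"]], dialect_pheknowlator())
    kg_kx <- read_kg(kx[["nodes"]], kx[["edges"]], dialect_kgx())
    # fixture categories are CURIE prefixes, so they survive both dialects
    expect_identical(kg_nodes(kg_pk), kg_nodes(kg))
    expect_identical(kg_edges(kg_pk), kg_edges(kg))
    expect_identical(kg_nodes(kg_kx), kg_nodes(kg_pk))
    expect_identical(kg_edges(kg_kx), kg_edges(kg_pk))
  }
})

test_that("degenerate and malformed inputs are handled per contract", {
  dir <- withr::local_tempdir()
  nodes <- file.path(dir, "nodes.tsv")
  edges <- file.path(dir, "edges.tsv")

  writeLines("a\tsolo", nodes)
  writeLines(character(), edges)
  kg <- read_kg(nodes, edges, dialect_pheknowlator())
  expect_identical(nrow(kg_nodes(kg)), 1L)
  expect_identical(nrow(kg_edges(kg)), 0L)

  writeLines("a\tp\tnX", edges)
  expect_warning(kg2 <- read_kg(nodes, edges, dialect_pheknowlator()),
                 "placeholder")
  expect_true("nX" %in% kg_nodes(kg2)$id)
  expect_identical(kg_nodes(kg2)$label[kg_nodes(kg2)$id == "nX"], "")

  writeLines(c("a\tp\tb", "a\tp"), edges)
  expect_error(read_kg(nodes, edges, dialect_pheknowlator()),
               "line 2", class = "kg_parse_error")

  expect_error(read_kg(file.path(dir, "nope.tsv"), edges,
                       dialect_pheknowlator()),
               class = "kg_io_error")

  writeLines(c("id\tname", "a\tA"), nodes)
  writeLines(c("subject\tpredicate\tobject", "a\tp\ta"), edges)
  expect_error(read_kg(nodes, edges, dialect_kgx()),
               "category", class = "kg_dialect_error")
})

test_that("dialect construction enforces required role mappings", {
  expect_error(kg_dialect("x", list(id = "id"),
                          list(subject = "s", predicate = "p", object = "o")),
               class = "kg_dialect_error")
  expect_error(kg_dialect("x", list(id = "id", label = "lab"),
                          list(subject = "s", object = "o")),
               class = "kg_dialect_error")
})

test_that("tab characters inside fields are rejected rather than quoted", {
  kg <- knowledge_graph(tibble::tibble(id = "a", label = "has\ttab"))
  dir <- withr::local_tempdir()
  expect_error(write_kg(kg, file.path(dir, "bad"), dialect_kgx()),
               class = "kg_io_error")
})

test_that("subgraph SIF output has one row per edge", {
  kg <- toy_kg_a()
  rp <- rank_paths(kg_shortest_paths(kg, "n1", "n3"), "pdp", kg = kg)
  sg <- paths_to_subgraph(kg, list(rp), input_ids = c("n1", "n3"))
  dir <- withr::local_tempdir()
  files <- write_subgraph(sg, file.path(dir, "sg"), formats = "sif")
  rows <- readLines(files[["sif"]])
  expect_length(rows, 2)
  expect_true(all(grepl("^\\S+\t\\S+\t\\S+$", rows)))
})

test_that("GraphML subgraph export round-trips including isolated augmented nodes", {
  kg <- toy_kg_a()
  rp <- rank_paths(kg_shortest_paths(kg, "n1", "n4"), "pdp", kg = kg, w = 1)
  sg <- paths_to_subgraph(kg, list(rp), input_ids = c("n1", "n4"))
  # graft an isolated augmented node to exercise the SIF warning too
  sg_iso <- kg_subgraph(
    dplyr::bind_rows(sg$nodes,
                     tibble::tibble(id = "n8", label = "orphan",
                                    category = "class",
                                    provenance = "augmented")),
    sg$edges, sg$pair_index)
  dir <- withr::local_tempdir()
  expect_warning(write_subgraph(sg_iso, file.path(dir, "sg"),
                                formats = c("graphml", "sif")),
                 "isolated")
  back <- read_subgraph_graphml(file.path(dir, "sg.graphml"))
  expect_setequal(back$nodes$id, sg_iso$nodes$id)
  o <- match(sg_iso$nodes$id, back$nodes$id)
  expect_identical(back$nodes$label[o], sg_iso$nodes$label)
  expect_identical(back$nodes$category[o], sg_iso$nodes$category)
  expect_identical(back$nodes$provenance[o], sg_iso$nodes$provenance)
  expect_identical(back$nodes$provenance[back$nodes$id == "n8"], "augmented")
  expect_setequal(paste(back$edges$subject, back$edges$predicate,
                        back$edges$object),
                  paste(sg_iso$edges$subject, sg_iso$edges$predicate,
                        sg_iso$edges$object))
})

test_that("GraphML round-trips for random fixture subgraphs", {
  for (seed in 1:20) {
    kg <- small_random_kg(seed, n = 10, m = 18)
    sg <- kg_subgraph(
      dplyr::mutate(kg_nodes(kg), provenance = "input"),
      dplyr::mutate(kg_edges(kg), provenance = "path"))
    dir <- withr::local_tempdir()
    write_subgraph(sg, file.path(dir, "sg"), formats = "graphml")
    back <- read_subgraph_graphml(file.path(dir, "sg.graphml"))
    expect_setequal(back$nodes$id, sg$nodes$id)
    expect_setequal(paste(back$edges$subject, back$edges$predicate,
                          back$edges$object),
                    paste(sg$edges$subject, sg$edges$predicate,
                          sg$edges$object))
  }
})

test_that("path report lists every (pair, path) row and flags selection", {
  kg <- toy_kg_a()
  rp <- rank_paths(kg_shortest_paths(kg, "n1", "n4"), "pdp", kg = kg, w = 1)
  dir <- withr::local_tempdir()
  out <- file.path(dir, "report.tsv")
  write_path_report(list(rp), out)
  tab <- readr::read_tsv(out, show_col_types = FALSE)
  expect_identical(nrow(tab), 2L)
  expect_identical(sum(tab$selected), 1L)
  expect_identical(tab$path[tab$selected], "n1 -> n2 -> n3 -> n4")

  # empty input: header-only file
  write_path_report(list(), out)
  expect_identical(nrow(readr::read_tsv(out, show_col_types = FALSE)), 0L)

  # disconnected pair: single NONE row with empty rank
  none <- structure(list(pair = c(source = "n7", target = "n8"),
                         action = "pdp", w = 1, paths = list(),
                         scores = double(), relaxed = FALSE),
                    class = "ranked_paths")
  write_path_report(list(none), out)
  tab <- readr::read_tsv(out, show_col_types = FALSE)
  expect_identical(tab$path, "NONE")
  expect_true(is.na(tab$rank))
})
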