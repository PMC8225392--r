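test_that("read_connectome round-trips the toy tables and sums parallel edges", {
  conn <- read_connectome(extdata("toy_neurons.tsv"),
                          extdata("toy_chemical.tsv"),
                          extdata("toy_electrical.tsv"))
  expect_equal(nrow(conn$neurons), 7)
  expect_equal(nrow(conn$chemical), 5)
  expect_equal(nrow(conn$electrical), 2)

  tmp <- withr::local_tempdir()
  p <- file.path(tmp, c("n.tsv", "c.tsv", "e.tsv"))
  write_connectome(conn, p[1], p[2], p[3])
  back <- read_connectome(p[1], p[2], p[3])
  expect_equal(back, conn)

  # duplicate parallel rows sum into one edge
  dup <- connectome(data.frame(id = c("A", "B"), class = c("a", "b")),
                    chemical = data.frame(pre = c("A", "A"),
                                          post = c("B", "B"),
                                          weight = c(1, 2)))
  expect_equal(nrow(dup$chemical), 1)
  expect_equal(dup$chemical$weight, 3L)
})

test_that("edge validation errors name the offending row or neuron", {
  neurons <- data.frame(id = c("A", "B"), class = c("a", "b"))
  expect_error(
    connectome(neurons, chemical = data.frame(pre = "A", post = "XYZ",
                                              weight = 1)),
    "XYZ")
  expect_error(
    connectome(neurons, chemical = data.frame(pre = "A", post = "B",
                                              weight = 0)),
    "positive integer")
  expect_error(
    connectome(neurons, chemical = data.frame(pre = "A", post = "B",
                                              weight = 1.5)),
    "positive integer")
})

test_that("electrical edges are canonicalized regardless of input order", {
  neurons <- data.frame(id = c("A", "B"), class = c("a", "b"))
  c1 <- connectome(neurons, electrical = data.frame(a = "A", b = "B", weight = 2))
  c2 <- connectome(neurons, electrical = data.frame(a = "B", b = "A", weight = 2))
  expect_equal(c1, c2)
  expect_equal(c1$electrical$a, "A")
})

test_that("restrict_to_somatic drops pharyngeal neurons with their edges and is idempotent", {
  conn <- read_connectome(extdata("toy_neurons.tsv"),
                          extdata("toy_chemical.tsv"),
                          extdata("toy_electrical.tsv"))
  som <- restrict_to_somatic(conn)
  expect_equal(nrow(som$neurons), 6)
  expect_false("M1" %in% c(som$chemical$pre, som$chemical$post))
  expect_equal(nrow(som$chemical), 4)   # M1 -> AVAL removed
  expect_equal(restrict_to_somatic(som), som)

  all_ph <- connectome(data.frame(id = "M1", class = "M1", pharyngeal = TRUE))
  expect_equal(nrow(restrict_to_somatic(all_ph)$neurons), 0)

  none_ph <- toy4()
  expect_equal(restrict_to_somatic(none_ph), none_ph)
})

test_that("contact map dialects agree, enforce symmetry and reject unknown neurons", {
  ids <- c("A", "B", "C")
  tmp <- withr::local_tempdir()
  el <- file.path(tmp, "contacts_edges.tsv")
  writeLines(c("a\tb", "A\tB"), el)
  m1 <- read_contact_map(el, ids)
  expect_true(m1$adjacency["A", "B"] && m1$adjacency["B", "A"])
  expect_equal(sum(m1$adjacency), 2)

  mx <- file.path(tmp, "contacts_matrix.tsv")
  write_contact_map(m1, mx, dialect = "matrix")
  expect_equal(read_contact_map(mx, ids), m1)

  empty <- file.path(tmp, "contacts_empty.tsv")
  writeLines("a\tb", empty)
  m0 <- read_contact_map(empty, ids)
  expect_false(any(m0$adjacency))
  expect_equal(dim(m0$adjacency), c(3, 3))

  bad <- file.path(tmp, "asym.tsv")
  writeLines(c("neuron\tA\tB", "A\t0\t1", "B\t0\t0"), bad)
  expect_error(read_contact_map(bad, ids), "asymmetric")
  writeLines(c("a\tb", "A\tZZ"), el)
  expect_error(read_contact_map(el, ids), "ZZ")
})

test_that("expression readers handle wide and long formats with the stated error contracts", {
  tmp <- withr::local_tempdir()
  wide <- file.path(tmp, "wide.tsv")
  writeLines(c("gene\tA\tB\tC", "g1\t0\t1\t0", "g2\t1\t1\t0"), wide)
  e <- read_expression(wide)
  expect_equal(unname(e$values["g2", ]), c(1, 1, 0))

  long <- file.path(tmp, "long.tsv")
  writeLines(c("gene\tneuron\tvalue", "g1\tA\t1", "g1\tB\t0"), long)
  el <- read_expression(long)
  expect_equal(unname(el$values["g1", c("A", "B")]), c(1, 0))

  writeLines(c("gene\tA", "g1\t-1"), wide)
  expect_error(read_expression(wide), "negative")
  writeLines(c("gene\tneuron\tvalue", "g1\tA\t1", "g1\tA\t2"), long)
  expect_error(read_expression(long), "duplicate")

  ww <- file.path(tmp, "roundtrip.tsv")
  write_expression(e, ww)
  expect_equal(read_expression(ww), e)
})

test_that("write -> read is the identity on randomly generated datasets", {
  for (s in 1:3) {
    cfg <- synthetic_config(n_classes = 8, class_size = 2,
                            n_background_genes = 5, seed = 400 + s)
    gen <- generate_connectome(cfg)
    expr <- generate_expression(cfg, gen$truth)
    tmp <- withr::local_tempdir()
    p <- file.path(tmp, c("n.tsv", "c.tsv", "e.tsv", "m.tsv", "x.tsv"))
    write_connectome(gen$connectome, p[1], p[2], p[3])
    expect_equal(read_connectome(p[1], p[2], p[3]), gen$connectome)
    write_contact_map(gen$contacts, p[4], dialect = "edges")
    expect_equal(read_contact_map(p[4], gen$contacts$neuron_ids),
                 gen$contacts)
    write_expression(expr, p[5])
    expect_equal(read_expression(p[5]), expr)
  }
})

test_that("annotated network export writes GraphML that round-trips the topology", {
  conn <- toy4()
  tmp <- withr::local_tempdir()
  prefix <- file.path(tmp, "net")
  paths <- export_annotated_network(
    conn,
    node_attrs = data.frame(id = c("A", "B"),
                            neurotransmitter = c("glu", "ach")),
    edge_attrs = data.frame(from = "D", to = "C", strength = 9),
    out_prefix = prefix)
  txt <- readLines(paths["graphml"])
  expect_true(any(grepl("neurotransmitter", txt)))
  expect_true(file.exists(paths["nodes"]))

  g <- igraph::read_graph(paths["graphml"], format = "graphml")
  back <- connectome_from_igraph(g)
  expect_equal(back$chemical, conn$chemical)
  expect_equal(back$electrical, conn$electrical)
  expect_setequal(back$neurons$id, conn$neurons$id)

  # electrical attr keyed (D, C) attached to the canonical (C, D) edge
  ed <- igraph::as_data_frame(g, what = "edges")
  expect_equal(ed$strength[ed$type == "electrical"], 9)

  expect_warning(
    export_annotated_network(conn,
                             node_attrs = data.frame(id = "NOPE", x = 1),
                             out_prefix = file.path(tmp, "net2")),
    "unknown node")
})
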