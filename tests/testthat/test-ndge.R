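# neurons A..D in distinct classes; chemical A->B; contacts A-B, A-C
pairs_fixture <- function() {
  conn <- connectome(data.frame(id = c("A", "B", "C"),
                                class = c("a", "b", "c")),
                     chemical = data.frame(pre = "A", post = "B", weight = 1))
  m <- matrix(FALSE, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  m["A", "B"] <- m["B", "A"] <- TRUE
  m["A", "C"] <- m["C", "A"] <- TRUE
  list(conn = conn, contacts = contact_map(c("A", "B", "C"), m))
}

test_that("pair_sets partitions contact pairs into disjoint synaptic/non-synaptic sets", {
  f <- pairs_fixture()
  ps <- pair_sets(f$conn, f$contacts)
  expect_equal(unname(ps$synaptic), cbind("A", "B"))
  expect_equal(unname(ps$nonsynaptic), cbind("A", "C"))

  # synaptic pair without declared contact stays synaptic, with a warning
  no_contact <- contact_map(c("A", "B", "C"),
                            matrix(c(F, F, T, F, F, F, T, F, F), 3))
  expect_warning(ps2 <- pair_sets(f$conn, no_contact), "lack declared")
  expect_equal(unname(ps2$synaptic), cbind("A", "B"))

  empty <- contact_map(c("A", "B", "C"))
  expect_error(pair_sets(f$conn, empty), "no contacts")
})

test_that("homomeric mean and the log-fold statistic match hand enumeration", {
  ids <- c("A", "B", "C")
  expr <- toy_expression(c("all", "none", "ab"), ids,
                         list(all = ids, ab = c("A", "B")))
  prs <- rbind(c("A", "B"), c("A", "C"))
  expect_equal(homomeric_mean(expr, "all", prs), 1.0)
  expect_equal(homomeric_mean(expr, "none", prs), 0.0)
  expect_equal(homomeric_mean(expr, "ab", prs), 0.5)
  expect_error(homomeric_mean(expr, "ab", prs[0, , drop = FALSE]), "empty")

  syn <- rbind(c("A", "B"))
  non <- rbind(c("A", "C"))
  expect_equal(ndge_statistic(expr, "all", syn, non), 0.0)
  expect_equal(ndge_statistic(expr, "none", syn, non), 0.0)
  # expressed in all synaptic endpoints, absent from non-synaptic partners:
  # log(1 + eps) - log(eps)
  conn4 <- connectome(data.frame(id = c("A", "B", "C", "D"),
                                 class = letters[1:4]),
                      chemical = data.frame(pre = "A", post = "B", weight = 1))
  e4 <- toy_expression("g", c("A", "B", "C", "D"), list(g = c("A", "B")))
  expect_equal(ndge_statistic(e4, "g", rbind(c("A", "B")), rbind(c("C", "D")),
                              pseudocount = 1e-6),
               log(1 + 1e-6) - log(1e-6), tolerance = 1e-12)
  expect_equal(ndge_statistic(e4, "g", rbind(c("A", "B")), rbind(c("C", "D"))),
               13.8155, tolerance = 1e-4)

  # invariant to neuron relabelling
  perm <- c(A = "W", B = "X", C = "Y", D = "Z")
  e4p <- toy_expression("g", unname(perm), list(g = c("W", "X")))
  expect_equal(ndge_statistic(e4p, "g", rbind(c("W", "X")), rbind(c("Y", "Z"))),
               ndge_statistic(e4, "g", rbind(c("A", "B")), rbind(c("C", "D"))))
})

test_that("rewiring preserves degrees, avoids duplicates and respects contact", {
  # frozen graph: the contact mask equals the edge pairs, so no swap is legal
  f <- pairs_fixture()
  froz_contacts <- contact_map(c("A", "B", "C"),
                               matrix(c(F, T, F, T, F, F, F, F, F), 3))
  rw <- rewire_connectome(f$conn, froz_contacts, attempts = 500, seed = 1)
  expect_equal(rw$chemical, f$conn$chemical)

  cfg <- synthetic_config(n_classes = 10, class_size = 2, p_contact = 1,
                          p_chem_given_contact = 0.2,
                          p_elec_given_contact = 0.1, seed = 77)
  gen <- generate_connectome(cfg)
  conn <- gen$connectome
  n_edges <- nrow(conn$chemical) + nrow(conn$electrical)
  rw <- rewire_connectome(conn, gen$contacts, attempts = 10 * n_edges, seed = 5)

  deg <- function(x) as.vector(table(factor(x, levels = neuron_ids(conn))))
  expect_equal(deg(rw$chemical$pre), deg(conn$chemical$pre))
  expect_equal(deg(rw$chemical$post), deg(conn$chemical$post))
  expect_equal(deg(c(rw$electrical$a, rw$electrical$b)),
               deg(c(conn$electrical$a, conn$electrical$b)))
  expect_false(any(rw$chemical$pre == rw$chemical$post))
  expect_false(anyDuplicated(paste(rw$chemical$pre, rw$chemical$post)) > 0)

  # with swaps accepted, the edge set moves: Jaccard < 1
  key <- function(c) paste(c$chemical$pre, c$chemical$post)
  jac <- length(intersect(key(rw), key(conn))) /
    length(union(key(rw), key(conn)))
  expect_lt(jac, 1)
  expect_gt(sum(attr(rw, "accepted_swaps")), 0)

  # deterministic given seed
  rw2 <- rewire_connectome(conn, gen$contacts, attempts = 10 * n_edges, seed = 5)
  expect_equal(rw2$chemical, rw$chemical)
  expect_equal(rw2$electrical, rw$electrical)
})

test_that("null ensemble is reproducible and matches the single-rewire path", {
  cfg <- synthetic_config(n_classes = 8, class_size = 2, seed = 31)
  gen <- generate_connectome(cfg)
  ncfg <- ndge_config(n_rewires = 5, seed = 9)
  ens1 <- build_null_ensemble(gen$connectome, gen$contacts, ncfg)
  ens2 <- build_null_ensemble(gen$connectome, gen$contacts, ncfg)
  expect_equal(ens1$replicates, ens2$replicates)
  expect_equal(length(ens1$replicates), 5)

  # the fast kernel path equals rewire_connectome() for the same derived seed
  ids <- neuron_ids(gen$connectome)
  n_edges <- sum(gen$connectome$chemical$pre != gen$connectome$chemical$post) +
    nrow(gen$connectome$electrical)
  attempts <- ceiling(ncfg$swap_attempts_factor * n_edges)
  set.seed(ncfg$seed)
  rep_seeds <- sample.int(2147483646L, ncfg$n_rewires)
  rw1 <- rewire_connectome(gen$connectome, gen$contacts, attempts, rep_seeds[1])
  expect_setequal(
    circuitenrich:::pair_codes(ens1$replicates[[1]], length(ids)),
    circuitenrich:::pair_codes(
      circuitenrich:::synaptic_pair_idx(rw1, ids, TRUE), length(ids)))
})

test_that("empirical p-values follow the add-one rule and never reach zero", {
  expect_equal(empirical_pvalue(10, rep(0, 999)), 1 / 1000)
  expect_equal(empirical_pvalue(-1, rep(0, 10)), 1.0)
  nulls <- seq_len(999)
  expect_equal(empirical_pvalue(500, nulls), (1 + 500) / 1000)
  expect_error(empirical_pvalue(1, numeric(0)), "empty")
})

test_that("run_ndge flags a planted homomeric gene and is bitwise reproducible", {
  cfg <- small_planted_config(seed = 55)
  gen <- generate_connectome(cfg)
  expr <- generate_expression(cfg, gen$truth)
  ncfg <- ndge_config(n_rewires = 500, seed = 21)
  res <- run_ndge(gen$connectome, gen$contacts, expr, config = ncfg)
  planted <- res[res$gene == "planted", ]
  expect_true(planted$significant)
  expect_equal(planted$pvalue, min(res$pvalue))
  expect_true(all(res$pvalue >= 1 / (ncfg$n_rewires + 1)))

  res2 <- run_ndge(gen$connectome, gen$contacts, expr, config = ncfg)
  expect_identical(res, res2)

  vol <- volcano_table(res)
  expect_equal(vol$neg_log10_p, -log10(res$pvalue))

  # empty gene list and all-zero genes
  expect_equal(nrow(run_ndge(gen$connectome, gen$contacts, expr,
                             genes = character(0), config = ncfg)), 0)
  zeros <- toy_expression(c("z", "planted"), expr$neurons,
                          list(planted = gen$truth$planted$planted$neurons))
  rz <- run_ndge(gen$connectome, gen$contacts, zeros, genes = "z",
                 config = ndge_config(n_rewires = 20, seed = 2))
  expect_false(rz$significant)

  # a connectome whose edges cover every contact pair cannot be analysed
  ids3 <- c("A", "B", "C")
  covered <- connectome(data.frame(id = ids3, class = letters[1:3]),
                        chemical = data.frame(pre = "A", post = "B", weight = 1))
  one_pair <- contact_map(ids3, matrix(c(F, T, F, T, F, F, F, F, F), 3))
  ex3 <- toy_expression("g", ids3, list(g = "A"))
  expect_error(run_ndge(covered, one_pair, ex3,
                        config = ndge_config(n_rewires = 5, seed = 1)),
               "non-synaptic")
})
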