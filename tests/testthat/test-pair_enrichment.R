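test_that("pair universe enumerates ordered cross-class pairs", {
  u <- build_pair_universe(names(ava_ash_classes), ava_ash_classes,
                           "exclude_same_class")
  expect_equal(u$n, 4)
  got <- paste(u$pairs$i, u$pairs$j)
  expect_setequal(got, c("AVAL ASHL", "ASHL AVAL", "AVAR ASHL", "ASHL AVAR"))

  expect_equal(build_pair_universe("AVAL", ava_ash_classes)$n, 0)

  m <- 6
  cls <- setNames(letters[1:m], LETTERS[1:m])
  expect_equal(build_pair_universe(LETTERS[1:m], cls)$n, m * (m - 1))
  expect_error(build_pair_universe(c("A", "Z"), cls), "Z")
})

test_that("connection orientation: chemical counts one way, electrical both ways", {
  conn <- toy4()
  expect_true(is_connected(conn, "A", "B"))
  expect_false(is_connected(conn, "B", "A"))
  expect_true(is_connected(conn, "C", "D"))
  expect_true(is_connected(conn, "D", "C"))
  expect_false(is_connected(conn, "A", "C"))
  expect_error(is_connected(conn, "A", "A"), "self")
  expect_error(is_connected(conn, "A", "Z"), "Z")
})

test_that("connection probability is an exact pair-count ratio, invariant to storage order", {
  conn <- toy4()
  u <- build_pair_universe(neuron_ids(conn),
                           setNames(conn$neurons$class, conn$neurons$id))
  # successes: A>B, B>C chemical; C-D electrical in both orders -> 4 of 12
  expect_equal(connection_probability(conn, u), 4 / 12)

  shuffled <- connectome(conn$neurons[c(3, 1, 4, 2), ],
                         conn$chemical[c(2, 1), ],
                         conn$electrical)
  expect_equal(connection_probability(shuffled, u), 4 / 12)

  none <- connectome(conn$neurons)
  expect_equal(connection_probability(none, u), 0)
})

test_that("binomial mass and tail match the closed-form values", {
  expect_equal(binomial_pmf(2, 4, 0.5), 0.375)
  expect_equal(binomial_pmf(0, 5, 0), 1.0)
  oracle <- factorial(10) / (factorial(3) * factorial(7)) * 0.1^3 * 0.9^7
  expect_equal(binomial_pmf(3, 10, 0.1), oracle, tolerance = 1e-12)
  expect_equal(binomial_pmf(3, 10, 0.1), 0.05739563, tolerance = 1e-7)

  expect_equal(binomial_upper_tail(0, 7, 0.3), 1.0)
  expect_equal(binomial_upper_tail(2, 2, 0.5), 0.25)
  expect_equal(binomial_upper_tail(3, 10, 0.1),
               sum(sapply(3:10, binomial_pmf, n = 10, p = 0.1)),
               tolerance = 1e-12)
  expect_equal(binomial_upper_tail(3, 10, 0.1), 0.07019083, tolerance = 1e-7)
  expect_error(binomial_pmf(5, 4, 0.5), "k > n")
})

test_that("binomial identities hold across n and p", {
  for (n in c(3, 50, 500)) {
    for (p in c(0, 0.1, 0.5, 0.9, 1)) {
      expect_equal(sum(binomial_pmf(0:n, n, p)), 1, tolerance = 1e-12)
      k <- 0:(n - 1)
      expect_equal(binomial_upper_tail(k, n, p) -
                     binomial_upper_tail(k + 1, n, p),
                   binomial_pmf(k, n, p), tolerance = 1e-12)
    }
  }
  # large n stays finite and positive in the far tail
  expect_gt(binomial_upper_tail(500, 1e5, 1e-3), 0)
})

test_that("per-gene test: self-consistency, degeneracy, and the k = n closed form", {
  conn <- toy4()
  expr <- toy_expression(c("all", "one", "none"), neuron_ids(conn),
                         list(all = c("A", "B", "C", "D"), one = "A"))
  r_all <- tf_connectivity_test(conn, expr, "all")
  expect_equal(r_all$k_successes / r_all$n_trials, r_all$p_success)

  for (g in c("one", "none")) {
    r <- tf_connectivity_test(conn, expr, g)
    expect_false(r$testable)
    expect_equal(r$n_trials, 0L)
    expect_equal(r$pvalue_tail, 1)
  }
  expect_error(tf_connectivity_test(conn, expr, "missing"), "absent")

  # planted clique: gene in 4 mutually connected cross-class neurons
  ids <- LETTERS[1:4]
  clique <- connectome(
    data.frame(id = ids, class = letters[1:4]),
    chemical = expand.grid(pre = ids, post = ids,
                           stringsAsFactors = FALSE) |>
      subset(pre != post) |> transform(weight = 1))
  ex <- toy_expression("g", ids, list(g = ids))
  r <- tf_connectivity_test(clique, ex, "g", p_success = 0.05)
  expect_equal(r$n_trials, 12L)
  expect_equal(r$k_successes, 12L)
  expect_equal(r$pvalue_tail, 0.05^12, tolerance = 1e-12)
})

test_that("BH adjustment matches the step-up formula and its edge cases", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_fdr(rep(0.2, 3)), rep(0.2, 3))
  expect_equal(bh_fdr(0.037), 0.037)
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(11)
  for (i in 1:5) {
    p <- runif(sample(2:20, 1))
    q <- bh_fdr(p)
    o <- order(p)
    manual <- rev(cummin(rev(p[o] * length(p) / seq_along(p))))
    expect_equal(q[o], pmin(1, manual), tolerance = 1e-12)
    expect_true(all(q >= p))
  }
})

test_that("family screen: q-values over testable genes only, planted gene ranks first", {
  conn <- toy4()
  expr <- toy_expression(c("g1", "g2"), neuron_ids(conn),
                         list(g1 = c("A", "B", "C", "D")))
  one <- test_gene_family(conn, expr, "g1")
  expect_equal(one$qvalue, one$pvalue_tail)

  res <- test_gene_family(conn, expr, c("g1", "g2"))
  expect_false(res$testable[res$gene == "g2"])
  expect_equal(res$qvalue[res$gene == "g2"], 1)

  only_untestable <- test_gene_family(conn, expr, "g2")
  expect_equal(only_untestable$qvalue, 1)
  expect_error(test_gene_family(conn, expr, character(0)), "empty gene list")

  for (s in 1:5) {
    cfg <- small_planted_config(seed = 600 + s)
    gen <- generate_connectome(cfg)
    ex <- generate_expression(cfg, gen$truth)
    r <- test_gene_family(gen$connectome, ex, ex$genes)
    expect_equal(r$gene[which.min(r$qvalue)], "planted")
  }
})

test_that("success counts over random expression sets follow the binomial law", {
  # full contact, chemical-only, one neuron per class: the ordered pairs of a
  # random 6-neuron expression set are then i.i.d. Bernoulli(p_chem), so k is
  # exactly binomial and the empirical law must match the pmf
  n_sims <- 400
  kk <- integer(n_sims)
  cfg0 <- synthetic_config(n_classes = 10, class_size = 1, p_contact = 1,
                           p_chem_given_contact = 0.1,
                           p_elec_given_contact = 0, n_background_genes = 0)
  for (s in seq_len(n_sims)) {
    cfg <- cfg0; cfg$seed <- 3000 + s
    gen <- generate_connectome(cfg)
    conn <- gen$connectome
    set.seed(cfg$seed)
    on <- sample(neuron_ids(conn), 6)
    ex <- toy_expression("g", neuron_ids(conn), list(g = on))
    r <- tf_connectivity_test(conn, ex, "g", p_success = 0.1)
    expect_equal(r$n_trials, 30L)
    kk[s] <- r$k_successes
  }
  for (k0 in 2:4) {
    freq <- mean(kk == k0)
    expected <- binomial_pmf(k0, 30, 0.1)
    se <- sqrt(expected * (1 - expected) / n_sims)
    expect_lt(abs(freq - expected), 3 * se)
  }
})
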