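test_that("similarity matrix is symmetric 0/1 with zero diagonal", {
  sp <- paste0("SP", 1:3)
  rel <- make_relations(list(c("SP1", "SP2")))
  m <- build_matrix(rel, sp)
  expect_identical(sum(m), 2L)
  expect_identical(m, t(m))
  expect_identical(diag(m), setNames(rep(0L, 3), sp))

  expect_identical(sum(build_matrix(make_relations(list()), sp)), 0L)

  k4 <- build_matrix(make_relations(combn(paste0("SP", 1:4), 2,
                                          simplify = FALSE)),
                     paste0("SP", 1:4))
  expect_identical(unname(rowSums(k4)), rep(3, 4))

  expect_error(build_matrix(make_relations(list(c("SP1", "SP9"))), sp),
               "SP9")
})

test_that("primer summary computes the coverage estimators", {
  # 10 evaluated, 8 detected, 5 with at least one relation
  sp <- paste0("SP", 1:8)
  rel <- make_relations(list(c("SP1", "SP2"), c("SP2", "SP3"),
                             c("SP4", "SP5")))
  s <- summarize_primer(build_matrix(rel, sp), 10, "P1")
  expect_identical(s$SC, 80)
  expect_identical(s$SC_ASI97, 50)
  expect_identical(s$SC_NASI97, 30)
  expect_identical(s$non_SC, 20)
  expect_identical(s$n_asi97, 3L)
  expect_identical(s$max_asi97_per_species, 2L)
  expect_equal(s$mean_asi97_per_species, 6 / 5)

  # zero matrix: everything detected counts as no-similarity coverage
  s0 <- summarize_primer(build_matrix(make_relations(list()), sp), 10)
  expect_identical(s0$SC_NASI97, s0$SC)
  expect_identical(s0$SC, 80)
  expect_identical(s0$mean_asi97_per_species, 0)

  # 4-clique among 4 of 4
  k4 <- build_matrix(make_relations(combn(paste0("SP", 1:4), 2,
                                          simplify = FALSE)),
                     paste0("SP", 1:4))
  s4 <- summarize_primer(k4, 4)
  expect_identical(s4$n_asi97, 6L)
  expect_identical(s4$max_asi97_per_species, 3L)

  expect_error(summarize_primer(k4, 0), "positive")
  expect_error(summarize_primer(k4, 3), "smaller")
})

test_that("coverage identities hold on random similarity structures", {
  set.seed(101)
  for (i in 1:20) {
    n_total <- sample(5:40, 1L)
    n_det <- sample(0:n_total, 1L)
    sp <- if (n_det) paste0("SP", seq_len(n_det)) else character()
    pairs <- if (n_det >= 2) combn(sp, 2, simplify = FALSE) else list()
    pairs <- pairs[runif(length(pairs)) < 0.2]
    s <- summarize_primer(build_matrix(make_relations(pairs), sp),
                          max(n_total, 1L))
    expect_equal(s$SC_ASI97 + s$SC_NASI97, s$SC, tolerance = 1e-12)
    expect_equal(s$SC + s$non_SC, 100, tolerance = 1e-12)
    expect_identical(s$n_asi97, length(pairs))
    # rounding to two decimals preserves the identities to within 0.01
    expect_lt(abs(round(s$SC_ASI97, 2) + round(s$SC_NASI97, 2) -
                    round(s$SC, 2)), 0.011)
  }
})

test_that("pair frequency counts primer pairs per species pair", {
  rels <- list(
    A = make_relations(list(c("SP1", "SP2"), c("SP3", "SP4")), "A"),
    B = make_relations(list(c("SP1", "SP2")), "B"),
    C = make_relations(list(c("SP1", "SP2")), "C"),
    D = make_relations(list(), "D"),
    E = make_relations(list(c("SP3", "SP4")), "E")
  )
  pf <- pair_frequency(rels)
  expect_identical(pf$frequency$frequency[pf$frequency$species_a == "SP1"], 3L)
  expect_identical(pf$frequency$frequency[pf$frequency$species_a == "SP3"], 2L)
  expect_identical(nrow(pf$long), 5L)
  expect_identical(max(pf$frequency$frequency), length(rels) - 2L)

  empty <- pair_frequency(list(A = make_relations(list())))
  expect_identical(nrow(empty$frequency), 0L)

  # a pair present under every primer reaches frequency = n primers
  all20 <- setNames(lapply(1:20, function(i) {
    make_relations(list(c("SP1", "SP2")), paste0("P", i))
  }), paste0("P", 1:20))
  expect_identical(pair_frequency(all20)$frequency$frequency, 20L)
})

test_that("cross-rank tallies classify relations by shared lineage labels", {
  labels <- paste0("SP", 1:6)
  lin <- data.frame(
    species_label = labels,
    genus = c("GenA", "GenA", "GenB", "GenB", "GenC", "GenD"),
    family = c("Fam1", "Fam1", "Fam1", "Fam1", "Fam2", "Fam3"),
    order = "Ord1", class = "Cls1",
    stringsAsFactors = FALSE
  )
  rel <- make_relations(list(c("SP1", "SP2"),   # same genus
                             c("SP3", "SP4"),   # same genus
                             c("SP1", "SP3"),   # cross genus, same family
                             c("SP5", "SP6")))  # cross genus, cross family
  g <- cross_rank_tally(rel, lin, "genus")
  expect_identical(g$n_cross_rank, 2L)
  expect_identical(g$n_same_rank, 2L)
  expect_identical(g$percent_cross, 50)
  f <- cross_rank_tally(rel, lin, "family")
  expect_identical(f$n_cross_rank, 1L)
  expect_identical(cross_rank_tally(rel, lin, "order")$n_cross_rank, 0L)

  expect_error(cross_rank_tally(make_relations(list(c("SP1", "SP9"))), lin,
                                "genus"), "SP9")
})

test_that("cross-rank counts are monotone from class up to genus", {
  set.seed(103)
  for (i in 1:10) {
    n <- sample(6:20, 1L)
    labels <- paste0("SP", seq_len(n))
    lin <- make_lineages(labels, genus = sample(1:6, n, replace = TRUE))
    pairs <- combn(labels, 2, simplify = FALSE)
    rel <- make_relations(pairs[runif(length(pairs)) < 0.3])
    if (!nrow(rel)) next
    counts <- vapply(c("class", "order", "family", "genus"), function(r) {
      cross_rank_tally(rel, lin, r)$n_cross_rank
    }, integer(1L))
    expect_true(all(diff(counts) >= 0L))
  }
})
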