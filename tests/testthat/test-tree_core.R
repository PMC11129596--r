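test_that("parse_tree recovers ages, tips and sampled ancestors", {
  tr <- fixture_tree3()
  expect_equal(n_taxa(tr), 3)
  expect_equal(root_age(tr), 2)
  expect_equal(unname(tip_ages(tr)), c(0, 0, 0))
  expect_equal(count_sampled_ancestors(tr), 0)

  sa <- fixture_sa_tree()
  expect_equal(count_sampled_ancestors(sa), 1)
  expect_true(sa$sa[match("F", sa$phy$tip.label)])
  expect_equal(unname(tip_ages(sa, "F")), 1)

  expect_error(parse_tree("((A:1,B:1):1,C:2"), "parse error")
  expect_error(parse_tree("((A:1,B:-1):1,C:2);"), "negative branch length")
})

test_that("BEAST-style metadata comments are honoured for age/rate keys", {
  tr <- parse_tree("((A[&rate=2.0]:1,B:1)[&posterior=0.9]:1,C[&age=0.5]:1.5);")
  expect_equal(tr$rates[match("A", tr$phy$tip.label)], 2)
  expect_equal(unname(tip_ages(tr, "C")), 0.5)
  expect_equal(root_age(tr), 2)
})

test_that("serialization round-trips topology, ages and flags", {
  for (i in 1:15) {
    tr <- random_fbd_tree(7000 + i, lo = 2, hi = 12)
    for (dialect in c("newick", "nexus")) {
      tr2 <- parse_tree(write_tree(tr, dialect = dialect), dialect = dialect)
      expect_setequal(taxa_labels(tr2), taxa_labels(tr))
      labs <- taxa_labels(tr)
      expect_equal(phylo_vcv(tr2)[labs, labs], phylo_vcv(tr),
                   tolerance = 1e-9)
      expect_equal(count_sampled_ancestors(tr2), count_sampled_ancestors(tr))
      # parse(write(parse(s))) == parse(s)
      s2 <- write_tree(tr2, dialect = dialect)
      expect_equal(phylo_vcv(parse_tree(s2, dialect = dialect))[labs, labs],
                   phylo_vcv(tr), tolerance = 1e-9)
    }
  }
})

test_that("tip-date sidecar anchors heterochronous ages", {
  td <- data.frame(taxon = c("A", "B"), age = c(2, 1))
  tr <- parse_tree("((A:1,B:2):1,C:3);", tip_dates = td)
  # A and B pin the root at age 4; C's age then follows from its depth
  expect_equal(unname(tip_ages(tr, c("A", "B", "C"))), c(2, 1, 1))
  expect_equal(root_age(tr), 4)
  expect_error(parse_tree("((A:1,B:2):1,C:3);",
                          tip_dates = data.frame(taxon = c("A", "B"),
                                                 age = c(2, 3))),
               "inconsistent")
})

test_that("phylo_vcv matches hand values and is linear in c_m", {
  tr <- fixture_tree3()
  Tm <- phylo_vcv(tr)
  expect_equal(unname(Tm), rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 2)))
  expect_equal(phylo_vcv(tr, c_m = 2), 2 * Tm)
})

test_that("phylo_vcv equals the explicit path-walk oracle", {
  for (i in 1:12) {
    tr <- random_fbd_tree(31 + i, lo = 3, hi = 10)
    tr$rates[] <- exp(stats::rnorm(length(tr$rates), 0, 0.3))
    cm <- runif(1, 0.5, 2)
    expect_equal(phylo_vcv(tr, cm), oracle_phylo_vcv(tr, cm),
                 tolerance = 1e-10)
  }
})

test_that("phylo_vcv is PSD and monotone in pendant-edge length", {
  for (i in 1:50) {
    tr <- random_fbd_tree(900 + i, lo = 2, hi = 12)
    ev <- eigen(phylo_vcv(tr), symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
  }
  Tm1 <- phylo_vcv(fixture_tree3())
  Tm2 <- phylo_vcv(parse_tree("((A:1.0,B:1.0):1.0,C:2.5);"))
  expect_equal(Tm2["C", "C"] - Tm1["C", "C"], 0.5)
  expect_equal(Tm2[rownames(Tm1) != "C", ], Tm1[rownames(Tm1) != "C", ])
})

test_that("shared_path_length agrees with the covariance contract", {
  tr <- fixture_tree3()
  expect_equal(shared_path_length(tr, "A", "B"), 1)
  expect_equal(shared_path_length(tr, "A", "C"), 0)
  expect_equal(shared_path_length(tr, "A", "A"), 2)
  expect_error(shared_path_length(tr, "A", "Z"), "unknown taxon")
})

test_that("prune_taxa removes tips, keeps ages, matches sub-block of T", {
  tr <- fixture_tree3()
  pr <- prune_taxa(tr, "C")
  expect_setequal(taxa_labels(pr), c("A", "B"))
  expect_equal(root_age(pr), 1)
  expect_identical(prune_taxa(tr, character(0)), tr)
  expect_error(prune_taxa(tr, c("A", "B")), "fewer than 2")

  for (i in 1:10) {
    tr <- random_fbd_tree(1200 + i, lo = 4, hi = 12)
    ages <- tip_ages(tr)
    fossils <- names(ages)[ages > 0]
    keep <- setdiff(names(ages), fossils)
    if (length(keep) < 2 || length(fossils) == 0) next
    sub <- prune_taxa(tr, fossils)
    want <- phylo_vcv(tr)[taxa_labels(sub), taxa_labels(sub)]
    # pruning reroots at the survivors' MRCA: the shared root-ward offset
    # (the smallest shared path in the sub-block) drops from every entry
    off <- min(want[row(want) != col(want)])
    expect_equal(phylo_vcv(sub), want - off, tolerance = 1e-9)
  }
})

test_that("mcc_tree picks the credible topology and matches clade counts", {
  t1 <- fixture_tree3()                          # ((A,B),C)
  t2 <- parse_tree("((A:1.0,C:1.0):1.0,B:2.0);") # ((A,C),B)
  res <- mcc_tree(list(t1, t1, t1), burnin_fraction = 0)
  expect_true(all(res$clade_support$support == 1))
  res2 <- mcc_tree(list(t1, t1, t2), burnin_fraction = 0)
  expect_true("A|B" %in% res2$node_ages$clade)
  expect_error(mcc_tree(list(), 0), "empty")

  # bipartition-count oracle over a posterior-like sample
  trees <- lapply(1:40, function(i) {
    if (i %% 3 == 0) t2 else t1
  })
  res3 <- mcc_tree(trees, burnin_fraction = 0)
  oracle <- oracle_clade_freqs(trees)
  for (j in seq_len(nrow(res3$clade_support))) {
    key <- res3$clade_support$clade[j]
    expect_equal(res3$clade_support$support[j], unname(oracle[key]))
  }
  # node-age HPD annotation covers the observed ages
  expect_true(all(res3$node_ages$hpd_low <= res3$node_ages$mean_age + 1e-12))
})

test_that("clade_constraint validates labels", {
  expect_error(clade_constraint(character(0)), "non-empty")
  cc <- clade_constraint(c("A", "B"), fixed_subtopology = TRUE)
  expect_true(cc$fixed_subtopology)
})
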