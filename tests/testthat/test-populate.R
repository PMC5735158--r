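test_that("per-level abstract minima drop weakly mentioned pairs", {
  tax <- tiny_tax()
  counts <- scp_counts(data.frame(
    gene = c("g1", "g2", "g3", "g4", "g5", "g6"),
    scp_id = c("C1.a.x", "C1.a.x", "C1.a.x.i", "C1", "C1", "C1.a"),
    count = c(1, 2, 1, 3, 4, 2)))
  out <- as.data.frame(apply_abstract_minimum(counts, tax))
  key <- paste(out$gene, out$scp_id)
  expect_false("g1 C1.a.x" %in% key)  # level-3 needs 2
  expect_true("g2 C1.a.x" %in% key)
  expect_true("g3 C1.a.x.i" %in% key) # level-4 needs 1
  expect_false("g4 C1" %in% key)      # level-1 needs 4
  expect_true("g5 C1" %in% key)
  expect_false("g6 C1.a" %in% key)    # level-2 needs 3
  empty <- scp_counts(data.frame(gene = character(), scp_id = character(),
                                 count = numeric()))
  expect_equal(nrow(apply_abstract_minimum(empty, tax)), 0L)
  bad <- scp_counts(data.frame(gene = "g", scp_id = "NOPE", count = 5))
  expect_error(apply_abstract_minimum(bad, tax), "missing from taxonomy")
})

test_that("validation adjustments remove M pairs and penalize S pairs", {
  counts <- scp_counts(data.frame(
    gene = c("g1", "g2", "g3"), scp_id = c("S1", "S1", "S1"),
    count = c(7, 100, 12)))
  labels <- validation_labels(data.frame(
    gene = c("g1", "g2", "g4"), scp_id = c("S1", "S1", "S9"),
    label = c("M", "S", "T")))
  expect_warning(out <- apply_validation_adjustments(counts, labels),
                 "not present")
  df <- as.data.frame(out)
  expect_false("g1" %in% df$gene)
  expect_equal(df$count[df$gene == "g2"], 34)  # 66% reduction
  expect_equal(df$count[df$gene == "g3"], 12)  # unlabeled untouched
})

test_that("per-SCP normalization hits the level target exactly", {
  tax <- tiny_tax()
  counts <- scp_counts(data.frame(
    gene = c("g1", "g2", "g3"),
    scp_id = c("C1.a.x", "C1.a.x", "C1.a"),
    count = c(2, 2, 3000)))
  nc <- as.data.frame(normalize_scp_counts(counts, tax))
  expect_equal(sort(nc$norm[nc$scp_id == "C1.a.x"]), c(500, 500))
  expect_equal(nc$norm[nc$scp_id == "C1.a"], 3000)
  sums <- tapply(nc$norm, nc$scp_id, sum)
  expect_equal(as.numeric(sums[c("C1.a", "C1.a.x")]), c(3000, 1000),
               tolerance = 1e-6)
})

test_that("enrichment p-values are symmetric for identical siblings and 1 at zero counts", {
  tax <- tiny_tax()
  counts <- scp_counts(data.frame(
    gene = rep(c("g1", "g2", "g3"), 2),
    scp_id = rep(c("C1.a.x", "C1.a.y"), each = 3),
    count = rep(c(8, 4, 2), 2)))
  nc <- normalize_scp_counts(counts, tax)
  pv <- gene_pvalues(nc, tax, "children_set", "C1.a")
  for (g in c("g1", "g2", "g3")) {
    ps <- pv$p[pv$gene == g]
    expect_equal(ps[1], ps[2])
  }
  # a pair whose normalized count rounds to zero is unenriched (p = 1)
  tiny <- scp_counts(data.frame(
    gene = c("g1", "g2", "g1"), scp_id = c("C1.a.x", "C1.a.y", "C1.a.y"),
    count = c(1000, 1000, 0.3)))
  pv2 <- gene_pvalues(normalize_scp_counts(tiny, tax), tax,
                      "children_set", "C1.a")
  expect_equal(pv2$p[pv2$gene == "g1" & pv2$scp_id == "C1.a.y"], 1)
  # same-level background must contain more than one populated SCP
  solo <- scp_counts(data.frame(gene = "g1", scp_id = "C1.a.x", count = 5))
  expect_error(gene_pvalues(normalize_scp_counts(solo, tax), tax,
                            "same_level", 3), "more than one")
})

test_that("raising a gene's count in one SCP never worsens its p there", {
  tax <- tiny_tax()
  last <- Inf
  for (cnt in c(2, 5, 10, 20, 40, 80)) {
    counts <- scp_counts(data.frame(
      gene = c("g1", "g2", "g1", "g2"),
      scp_id = c("C1.a.x", "C1.a.x", "C1.a.y", "C1.a.y"),
      count = c(cnt, 10, 5, 10)))
    pv <- gene_pvalues(normalize_scp_counts(counts, tax), tax,
                       "children_set", "C1.a")
    p <- pv$p[pv$gene == "g1" & pv$scp_id == "C1.a.x"]
    expect_lte(p, last + 1e-12)
    last <- p
  }
})

test_that("competitive filtering keeps selective SCPs and reinstates T pairs", {
  tax <- tiny_tax()
  # gX selective for C1.a.x; gU symmetric across the children set
  # (both sibling totals equal, so gU's normalized counts are identical)
  counts <- scp_counts(data.frame(
    gene = c("gX", "gX", "gU", "gU", "f1", "f2"),
    scp_id = c("C1.a.x", "C1.a.y", "C1.a.x", "C1.a.y", "C1.a.x", "C1.a.y"),
    count = c(40, 2, 10, 10, 30, 68)))
  out <- enrich_and_filter(counts, tax, 3, "children_set")
  df <- as.data.frame(out)
  expect_true("gX" %in% df$gene[df$scp_id == "C1.a.x"])
  expect_false("gX" %in% df$gene[df$scp_id == "C1.a.y"])
  # the uniform gene has no informative gap: kept in both siblings
  expect_equal(sum(df$gene == "gU"), 2L)
  # a T label shields the weak association from the gap filter
  labels <- validation_labels(data.frame(gene = "gX", scp_id = "C1.a.y",
                                         label = "T"))
  out2 <- as.data.frame(enrich_and_filter(counts, tax, 3, "children_set",
                                          labels = labels))
  row <- out2[out2$gene == "gX" & out2$scp_id == "C1.a.y", ]
  expect_equal(nrow(row), 1L)
  expect_equal(row$origin, "reinstated")
})

test_that("inheritance gates level-1 and level-4 candidates", {
  tax <- tiny_tax()
  ref <- assoc_from_sets(list(`C1.a` = c("g1", "g2"),
                              `C1.a.x` = c("g1", "g3"),
                              `C1.b.x` = "g4"))
  counts <- scp_counts(data.frame(
    gene = c("g1", "g9", "g1", "g9", "g3"),
    scp_id = c("C1", "C1", "C1.a.x.i", "C1.a.x.i", "C2.a.x"),
    count = c(10, 10, 3, 3, 3)))
  l1 <- as.data.frame(inherit_filter(counts, tax, 1, ref))
  expect_equal(l1$gene, "g1")           # g9 in no child/grandchild
  expect_equal(unique(l1$origin), "inherited")
  l4 <- as.data.frame(inherit_filter(counts, tax, 4, ref))
  expect_equal(l4$gene, "g1")           # g9 absent from the L3 parent
  # a level-4 SCP whose parent is empty loses all candidates
  ref2 <- assoc_from_sets(list(`C1.b.x` = "g4"))
  expect_equal(nrow(inherit_filter(counts, tax, 4, ref2)), 0L)
})

test_that("upward propagation makes ancestors supersets of their children", {
  tax <- tiny_tax()
  tab <- assoc_from_sets(list(`C1.a.x` = c("g1", "g2"),
                              `C1.b.x` = "g3",
                              `C1.a` = "g1",
                              `C1` = character(0)))
  out <- propagate_upward(as.data.frame(tab), tax)
  sets <- split(out$gene, out$scp_id)
  expect_setequal(sets[["C1.a"]], c("g1", "g2"))
  expect_setequal(sets[["C1"]], c("g1", "g2", "g3"))
  expect_equal(sum(out$gene == "g1" & out$scp_id == "C1.a"), 1L)  # no dupes
  added <- out[out$origin == "propagated", ]
  expect_true(all(paste(added$gene, added$scp_id) %in%
                  c("g2 C1.a", "g1 C1", "g2 C1", "g3 C1.b", "g3 C1")))
})

test_that("ranking uses p, then count, then symbol", {
  df <- data.frame(
    gene = c("b", "a", "c", "solo"),
    scp_id = c("S", "S", "S", "T"),
    p_children_set = c(1e-2, 1e-5, 1e-2, 0.5),
    adjusted_count = c(10, 1, 3, 1))
  out <- rank_genes(df)
  s <- out[out$scp_id == "S", ]
  expect_equal(s$gene[order(s$rank)], c("a", "b", "c"))
  expect_equal(out$rank[out$scp_id == "T"], 1L)
})

test_that("populate is deterministic and respects the hierarchy invariants", {
  spec <- fixture_spec(n_level1 = 2, children_per_node = c(l1 = 2, l2 = 2,
                                                           l3 = 2),
                       n_genes = 60, abstracts_per_scp = 120, seed = 5)
  fx <- generate_taxonomy(spec)
  counts <- simulate_counts(fx$truth, fx$taxonomy, spec)
  t1 <- populate(counts, fx$taxonomy)
  t2 <- populate(counts, fx$taxonomy)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  tax <- fx$taxonomy
  lv <- tax$level[match(t1$scp_id, tax$scp_id)]
  sets <- split(t1$gene, t1$scp_id)
  # every level-4 gene is in its level-3 parent
  for (s in unique(t1$scp_id[lv == 4])) {
    par <- query_relatives(tax, s, "parent")
    expect_true(all(sets[[s]] %in% sets[[par]]), info = s)
  }
  # every level-3 gene is in its level-2 parent and level-1 grandparent
  for (s in unique(t1$scp_id[lv == 3])) {
    anc <- scp_ancestors(tax, s)
    for (a in anc[tax$level[match(anc, tax$scp_id)] %in% 1:2])
      expect_true(all(sets[[s]] %in% sets[[a]]), info = paste(s, a))
  }
  # ranks are gapless within each SCP
  for (s in names(sets))
    expect_setequal(t1$rank[t1$scp_id == s], seq_along(sets[[s]]))
})

test_that("F-labeled pairs vanish from the final table but survive the LOO regime", {
  spec <- fixture_spec(n_level1 = 2, children_per_node = c(l1 = 2, l2 = 2,
                                                           l3 = 0),
                       n_genes = 40, abstracts_per_scp = 120, seed = 6)
  fx <- generate_taxonomy(spec)
  counts <- simulate_counts(fx$truth, fx$taxonomy, spec)
  base <- populate(counts, fx$taxonomy, levels = 3, propagate = FALSE)
  pick <- as.data.frame(base)[1, ]
  labels <- validation_labels(data.frame(gene = pick$gene,
                                         scp_id = pick$scp_id, label = "F"))
  full <- populate(counts, fx$taxonomy, labels, levels = 3,
                   propagate = FALSE, label_mode = "full")
  expect_false(any(full$gene == pick$gene & full$scp_id == pick$scp_id))
  loo <- populate(counts, fx$taxonomy, labels, levels = 3,
                  propagate = FALSE, label_mode = "no_fp_removal")
  expect_true(any(loo$gene == pick$gene & loo$scp_id == pick$scp_id))
})
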