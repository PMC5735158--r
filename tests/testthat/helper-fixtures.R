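# Small taxonomy builders used across tests.

tiny_tax <- function() {
  scp_taxonomy(data.frame(
    scp_id = c("ROOT", "C1", "C2",
               "C1.a", "C1.b", "C2.a",
               "C1.a.x", "C1.a.y", "C1.b.x", "C2.a.x",
               "C1.a.x.i"),
    name = c("cell", "cytoskeleton", "metabolism",
             "actin", "microtubule", "glycolysis",
             "polymerization", "branching", "mt dynamics", "payoff",
             "nucleation"),
    level = c(0, 1, 1, 2, 2, 2, 3, 3, 3, 3, 4),
    parent_id = c(NA, "ROOT", "ROOT", "C1", "C1", "C2",
                  "C1.a", "C1.a", "C1.b", "C2.a", "C1.a.x"),
    stringsAsFactors = FALSE))
}

# Associations table from explicit gene sets (list scp_id -> genes).
assoc_from_sets <- function(sets, origin = "enriched") {
  sets <- sets[lengths(sets) > 0]
  df <- do.call(rbind, lapply(names(sets), function(s)
    data.frame(gene = sets[[s]], scp_id = s, origin = origin,
               stringsAsFactors = FALSE)))
  scp_associations(df)
}

# Count table from a dense matrix (genes x SCPs).
counts_from_matrix <- function(m, totals = NULL) {
  idx <- which(m > 0, arr.ind = TRUE)
  scp_counts(data.frame(gene = rownames(m)[idx[, 1]],
                        scp_id = colnames(m)[idx[, 2]],
                        count = m[idx], stringsAsFactors = FALSE),
             totals)
}

# The default leave-one-out study fixture: 64 level-3 SCPs, 800 genes,
# 200 abstracts per SCP, six disjoint planted leakage pairs at the
# related-mention rate.
loo_study_fixture <- function(seed = 101) {
  base <- fixture_spec(n_level1 = 4, children_per_node = c(l1 = 4, l2 = 4,
                                                           l3 = 0),
                       n_genes = 800, abstracts_per_scp = 200, seed = seed)
  fx <- generate_taxonomy(base)
  l3 <- fx$taxonomy$scp_id[fx$taxonomy$level == 3]
  picked <- with_seed_test(seed, sample(l3, 12))
  leak <- data.frame(from = picked[1:6], to = picked[7:12],
                     stringsAsFactors = FALSE)
  spec <- fixture_spec(n_level1 = 4, children_per_node = c(l1 = 4, l2 = 4,
                                                           l3 = 0),
                       n_genes = 800, abstracts_per_scp = 200,
                       leakage_edges = leak, seed = seed)
  counts <- simulate_counts(fx$truth, fx$taxonomy, spec)
  list(spec = spec, taxonomy = fx$taxonomy, truth = fx$truth,
       counts = counts, leak = leak)
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

level3_precision_recall <- function(table, tax, truth) {
  lv <- tax$level[match(table$scp_id, tax$scp_id)]
  pred <- paste(table$gene[lv == 3], table$scp_id[lv == 3])
  tru <- paste(truth$gene, truth$scp_id)
  c(precision = mean(pred %in% tru), recall = mean(tru %in% pred))
}
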