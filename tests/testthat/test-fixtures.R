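test_that("generated taxonomies have the prescribed regular shape", {
  spec <- fixture_spec(n_level1 = 4, children_per_node = c(l1 = 2, l2 = 2,
                                                           l3 = 0),
                       n_genes = 50, seed = 1)
  fx <- generate_taxonomy(spec)
  s <- summary(fx$taxonomy)
  expect_equal(s$n_scps, c(1L, 4L, 8L, 16L, 0L))
  expect_equal(attr(s, "total"), 29L)
  # every gene gets exactly one primary level-3 SCP
  expect_equal(nrow(fx$truth), 50L)
  expect_true(all(fx$truth$scp_id %in%
                  fx$taxonomy$scp_id[fx$taxonomy$level == 3]))
})

test_that("generators are pure functions of spec and seed", {
  spec <- fixture_spec(n_level1 = 2, children_per_node = c(l1 = 2, l2 = 2,
                                                           l3 = 0),
                       n_genes = 30, seed = 3)
  a <- generate_taxonomy(spec); b <- generate_taxonomy(spec)
  expect_identical(a, b)
  ca <- simulate_counts(a$truth, a$taxonomy, spec)
  cb <- simulate_counts(b$truth, b$taxonomy, spec)
  expect_identical(as.data.frame(ca), as.data.frame(cb))
  spec2 <- fixture_spec(n_level1 = 2, children_per_node = c(l1 = 2, l2 = 2,
                                                            l3 = 0),
                        n_genes = 30, seed = 4)
  expect_false(identical(generate_taxonomy(spec2)$truth$scp_id,
                         a$truth$scp_id))
  # generators restore the caller's RNG state
  set.seed(123); before <- .Random.seed
  invisible(simulate_counts(a$truth, a$taxonomy, spec))
  expect_identical(.Random.seed, before)
})

test_that("counts respect the mention model bounds and moments", {
  spec <- fixture_spec(n_level1 = 2, children_per_node = c(l1 = 2, l2 = 2,
                                                           l3 = 0),
                       n_genes = 40, abstracts_per_scp = 100,
                       p_background = 0, p_related = 1e-6,
                       gene_rate_sd = 0, seed = 5)
  fx <- generate_taxonomy(spec)
  counts <- simulate_counts(fx$truth, fx$taxonomy, spec)
  df <- as.data.frame(counts)
  expect_true(all(df$count <= 100))
  l3 <- df[scptools:::scp_level(fx$taxonomy, df$scp_id) == 3, ]
  # with zero background, every level-3 count sits on a member pair
  key_truth <- paste(fx$truth$gene, fx$truth$scp_id)
  expect_true(all(paste(l3$gene, l3$scp_id) %in% key_truth))
  # mean member count across seeds stays within 3 sigma of n*p
  means <- vapply(1:30, function(s) {
    sp <- fixture_spec(n_level1 = 2, children_per_node = c(l1 = 2, l2 = 2,
                                                           l3 = 0),
                      n_genes = 40, abstracts_per_scp = 100,
                      gene_rate_sd = 0, seed = 100 + s)
    f <- generate_taxonomy(sp)
    cc <- as.data.frame(simulate_counts(f$truth, f$taxonomy, sp))
    k <- paste(cc$gene, cc$scp_id) %in% paste(f$truth$gene, f$truth$scp_id)
    mean(cc$count[k])
  }, numeric(1))
  n <- 100; p <- 0.1
  se <- sqrt(n * p * (1 - p) / (40 * 30))
  expect_lt(abs(mean(means) - n * p), 3 * se + 0.2)
})

test_that("perturbation lists have the requested composition", {
  spec <- fixture_spec(n_level1 = 2, children_per_node = c(l1 = 2, l2 = 2,
                                                           l3 = 0),
                       n_genes = 64, seed = 6)
  fx <- generate_taxonomy(spec)
  targets <- unique(fx$truth$scp_id)[1:2]
  pl <- simulate_perturbation(fx$truth, targets, n_from_each = 3,
                              n_noise = 4, seed = 9)
  expect_equal(nrow(pl), 10L)
  expect_false(anyDuplicated(pl$gene) > 0)
  expect_equal(sum(pl$origin == "noise"), 4L)
  members <- pl[pl$origin != "noise", ]
  expect_true(all(paste(members$gene, members$origin) %in%
                  paste(fx$truth$gene, fx$truth$scp_id)))
  noise_free <- simulate_perturbation(fx$truth, targets, 3, 0, seed = 9)
  expect_true(all(noise_free$origin %in% targets))
})

test_that("expression blocks reach the requested correlation regimes", {
  spec1 <- fixture_spec(n_level1 = 2, children_per_node = c(l1 = 2, l2 = 2,
                                                            l3 = 0),
                        n_genes = 32, rho = 1, n_tissues = 20, seed = 7)
  fx <- generate_taxonomy(spec1)
  expr <- simulate_expression(fx$truth, spec1)
  pr <- pairwise_pearson(expr)
  grp <- partition_pairs(pr, scp_associations(fx$truth), fx$taxonomy, 3)
  expect_true(all(abs(grp$shared$r - 1) < 1e-9))
  spec0 <- fixture_spec(n_level1 = 2, children_per_node = c(l1 = 2, l2 = 2,
                                                            l3 = 0),
                        n_genes = 32, rho = 0, n_tissues = 30, seed = 7)
  mean_r <- mean(vapply(1:10, function(s) {
    sp <- fixture_spec(n_level1 = 2, children_per_node = c(l1 = 2, l2 = 2,
                                                           l3 = 0),
                       n_genes = 32, rho = 0, n_tissues = 30,
                       seed = 200 + s)
    f <- generate_taxonomy(sp)
    e <- simulate_expression(f$truth, sp)
    p <- pairwise_pearson(e)
    g <- partition_pairs(p, scp_associations(f$truth), f$taxonomy, 3)
    mean(g$shared$r)
  }, numeric(1)))
  expect_lt(abs(mean_r), 0.1)
})

test_that("simulated labels mirror the truth and drive the pipeline", {
  spec <- fixture_spec(n_level1 = 2, children_per_node = c(l1 = 2, l2 = 2,
                                                           l3 = 0),
                       n_genes = 30, abstracts_per_scp = 100, seed = 8)
  fx <- generate_taxonomy(spec)
  counts <- simulate_counts(fx$truth, fx$taxonomy, spec)
  df <- as.data.frame(counts)
  lv3 <- df[scptools:::scp_level(fx$taxonomy, df$scp_id) == 3, ]
  labels <- simulate_validation_labels(fx$truth, lv3, fx$taxonomy,
                                       fp_rate = 0, seed = 10)
  truthy <- paste(fx$truth$gene, fx$truth$scp_id)
  expect_true(all((paste(labels$gene, labels$scp_id) %in% truthy) ==
                  (labels$label == "T")))
  # an all-M labeling wipes the adjusted count matrix
  all_m <- validation_labels(transform(as.data.frame(labels), label = "M"))
  adj <- suppressWarnings(
    apply_validation_adjustments(scp_counts(lv3), all_m))
  expect_equal(nrow(adj), 0L)
  # S-labeled pairs lose 66% of their counts on the way in
  one <- lv3[1, ]
  s_lab <- validation_labels(data.frame(gene = one$gene,
                                        scp_id = one$scp_id, label = "S"))
  adj2 <- suppressWarnings(apply_validation_adjustments(scp_counts(lv3),
                                                        s_lab))
  expect_equal(adj2$count[adj2$gene == one$gene &
                          adj2$scp_id == one$scp_id], one$count * 0.34)
})
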