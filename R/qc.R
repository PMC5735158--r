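#' Child-parent gene overlap (internal consistency)
#'
#' For every level-3 SCP with at least one gene, the percentage of its
#' genes also associated with its annotated level-2 parent. Because the
#' question is whether parent and child were populated consistently by two
#' independent enrichment runs, the table must NOT contain propagated rows
#' (which would trivially give 100%).
#'
#' @param table `scp_associations` built without upward propagation.
#' @param tax `scp_taxonomy`.
#' @return data.frame (`scp_id`, `parent_id`, `n_genes`, `overlap_pct`)
#'   with summary `mean`, `sd`, `median` attributes (also returned by
#'   `attr(x, "summary")`).
#' @export
child_parent_overlap <- function(table, tax) {
  if (any(table$origin == "propagated", na.rm = TRUE))
    stop("table contains propagated rows; rebuild with propagate = FALSE",
         call. = FALSE)
  lv <- scp_level(tax, table$scp_id)
  kids <- unique(table$scp_id[lv == 3L])
  res <- lapply(sort(kids), function(s) {
    g <- table$gene[table$scp_id == s]
    par <- query_relatives(tax, s, "parent")
    pg <- table$gene[table$scp_id == par]
    data.frame(scp_id = s, parent_id = par, n_genes = length(g),
               overlap_pct = 100 * mean(g %in% pg),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "summary") <- c(mean = mean(out$overlap_pct),
                            sd = stats::sd(out$overlap_pct),
                            median = stats::median(out$overlap_pct))
  out
}

#' Best-matching level-2 parent of each level-3 SCP
#'
#' For every populated level-3 SCP, finds the level-2 SCP sharing the most
#' genes with it. The child is `matched` when the unique argmax is its
#' annotated parent, `tied` when several level-2 SCPs attain the maximum
#' and the annotated parent is among them, and `mismatched` otherwise.
#' Children with zero genes are excluded.
#'
#' @inheritParams child_parent_overlap
#' @return data.frame per child (`scp_id`, `parent_id`, `best_scp`,
#'   `best_shared`, `status`); class counts in attribute `"counts"`.
#' @export
best_matching_parent <- function(table, tax) {
  lv <- scp_level(tax, table$scp_id)
  l2 <- sort(unique(table$scp_id[lv == 2L]))
  kids <- sort(unique(table$scp_id[lv == 3L]))
  l2_genes <- lapply(l2, function(s) table$gene[table$scp_id == s])
  names(l2_genes) <- l2
  res <- lapply(kids, function(s) {
    g <- table$gene[table$scp_id == s]
    if (!length(g)) return(NULL)
    shared <- vapply(l2_genes, function(pg) sum(g %in% pg), numeric(1))
    mx <- max(shared)
    best <- l2[shared == mx]
    par <- query_relatives(tax, s, "parent")
    status <- if (length(best) == 1L && best == par) "matched"
      else if (length(best) > 1L && par %in% best) "tied"
      else "mismatched"
    data.frame(scp_id = s, parent_id = par,
               best_scp = paste(best, collapse = ";"), best_shared = mx,
               status = status, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  cnt <- table(factor(out$status,
                      levels = c("matched", "tied", "mismatched")))
  attr(out, "counts") <- stats::setNames(as.integer(cnt), names(cnt))
  out
}

#' Coverage of parent genes by the union of children
#'
#' For every level-2 parent SCP, the fraction of its genes present in at
#' least one of its level-3 children. Run on the propagated table (after
#' the upward propagation step), mirroring the published analysis.
#'
#' @inheritParams child_parent_overlap
#' @param table `scp_associations` (propagation included).
#' @return data.frame (`parent_id`, `n_genes`, `coverage_pct`) with a
#'   `"summary"` attribute (mean coverage).
#' @export
parent_coverage_by_children <- function(table, tax) {
  lv <- scp_level(tax, table$scp_id)
  parents <- sort(unique(table$scp_id[lv == 2L]))
  res <- lapply(parents, function(p) {
    pg <- table$gene[table$scp_id == p]
    if (!length(pg)) return(NULL)
    kids <- query_relatives(tax, p, "children")
    kg <- unique(table$gene[table$scp_id %in% kids])
    data.frame(parent_id = p, n_genes = length(pg),
               coverage_pct = 100 * mean(pg %in% kg),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "summary") <- c(mean = mean(out$coverage_pct))
  out
}

#' Sequential removal of children SCPs
#'
#' For one level-2 parent, removes every subset of its level-3 children in
#' turn, re-populates the remaining level-3 SCPs (manual validation
#' skipped), and records how many parent genes remain covered by the union
#' of the remaining children. If the children describe mutually exclusive
#' sub-functions the overlap decreases steadily with the number removed.
#' Parents with more than `max_enumerate` children get `n_sample` random
#' subsets per removal size instead of the full enumeration.
#'
#' @param parent_id a level-2 SCP id.
#' @param counts raw [scp_counts].
#' @param tax `scp_taxonomy`.
#' @param cfg [population_config()].
#' @param baseline_table optional precomputed level-2 population (defaults
#'   to populating level 2 from `counts` without labels).
#' @param max_enumerate largest family size enumerated exhaustively.
#' @param n_sample subsets sampled per removal size above that.
#' @param seed seed for subset sampling.
#' @return data.frame (`n_removed`, `removed`, `overlap`) where `removed`
#'   is a `;`-joined subset signature and `overlap` the number of parent
#'   genes covered by the remaining children.
#' @export
sequential_child_removal <- function(parent_id, counts, tax,
                                     cfg = population_config(),
                                     baseline_table = NULL,
                                     max_enumerate = 12, n_sample = 20,
                                     seed = 1L) {
  kids <- query_relatives(tax, parent_id, "children")
  if (!length(kids)) stop("parent has no children", call. = FALSE)
  if (is.null(baseline_table))
    baseline_table <- populate(counts, tax, labels = NULL, cfg,
                               levels = 2L, propagate = FALSE)
  pg <- unique(baseline_table$gene[baseline_table$scp_id == parent_id])

  subsets <- if (length(kids) <= max_enumerate) {
    unlist(lapply(0:length(kids), function(k)
      utils::combn(kids, k, simplify = FALSE)), recursive = FALSE)
  } else {
    with_seed(seed, {
      c(list(character()),
        unlist(lapply(seq_along(kids), function(k) {
          if (k == length(kids)) return(list(kids))
          unique(lapply(seq_len(n_sample), function(i)
            sort(sample(kids, k))))
        }), recursive = FALSE))
    })
  }

  res <- lapply(subsets, function(rm) {
    sub <- as.data.frame(counts)
    sub <- sub[!sub$scp_id %in% rm, , drop = FALSE]
    tab3 <- populate(scp_counts(sub, attr(counts, "scp_totals")), tax,
                     labels = NULL, cfg, levels = 3L, propagate = FALSE)
    remaining <- setdiff(kids, rm)
    kg <- unique(tab3$gene[tab3$scp_id %in% remaining])
    data.frame(n_removed = length(rm),
               removed = paste(sort(rm), collapse = ";"),
               overlap = sum(pg %in% kg), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
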