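#' Configuration of the SCP population pipeline
#'
#' Defaults follow the published pipeline: a gene must be mentioned in at
#' least 4/3/2/1 abstracts of a level-1/2/3/4 SCP abstract set; per-SCP
#' mention counts are normalized to a total of 3000 articles for level-1/2
#' SCPs and 1000 for level-3/4 SCPs before each Fisher test; counts of
#' pairs labeled as belonging to a sibling SCP (label S) are decreased by
#' 66%, i.e. multiplied by 0.34.
#'
#' @param min_abstracts_by_level named numeric, minimum abstract count per
#'   taxonomy level.
#' @param norm_total_by_level named numeric, per-SCP normalization target by
#'   level.
#' @param sibling_penalty_factor fraction of the count retained for
#'   S-labeled pairs, in (0, 1).
#' @return list of class `population_config`.
#' @export
population_config <- function(min_abstracts_by_level = c(`1` = 4, `2` = 3,
                                                         `3` = 2, `4` = 1),
                              norm_total_by_level = c(`1` = 3000, `2` = 3000,
                                                      `3` = 1000, `4` = 1000),
                              sibling_penalty_factor = 0.34) {
  if (any(norm_total_by_level <= 0))
    stop("normalization totals must be positive", call. = FALSE)
  if (sibling_penalty_factor <= 0 || sibling_penalty_factor >= 1)
    stop("sibling_penalty_factor must be in (0, 1)", call. = FALSE)
  structure(list(min_abstracts_by_level = min_abstracts_by_level,
                 norm_total_by_level = norm_total_by_level,
                 sibling_penalty_factor = sibling_penalty_factor),
            class = "population_config")
}

#' Manual validation labels
#'
#' @param df data.frame with columns `gene`, `scp_id`, `label`; labels come
#'   from the 4-letter alphabet T (true positive), F (false positive),
#'   M (misinterpreted non-gene term), S (belongs to a sibling SCP).
#' @return validated data.frame of class `validation_labels`.
#' @export
validation_labels <- function(df) {
  stopifnot(all(c("gene", "scp_id", "label") %in% names(df)))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$gene <- as.character(df$gene); df$scp_id <- as.character(df$scp_id)
  df$label <- as.character(df$label)
  bad <- setdiff(unique(df$label), c("T", "F", "M", "S"))
  if (length(bad))
    stop("labels must be T/F/M/S; found: ", paste(bad, collapse = ", "),
         call. = FALSE)
  key <- paste(df$gene, df$scp_id, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate labeled pair", call. = FALSE)
  rownames(df) <- NULL
  structure(df, class = c("validation_labels", "data.frame"))
}

#' @rdname validation_labels
#' @param path TSV with columns gene, scp_id, label.
#' @export
load_labels <- function(path) validation_labels(read_tsv_base(path))

label_lookup <- function(labels, gene, scp_id) {
  if (is.null(labels) || !nrow(labels)) return(rep("unlabeled", length(gene)))
  m <- match(paste(gene, scp_id, sep = "\r"),
             paste(labels$gene, labels$scp_id, sep = "\r"))
  out <- labels$label[m]
  out[is.na(out)] <- "unlabeled"
  out
}

scp_level <- function(tax, ids) tax$level[match(ids, tax$scp_id)]

#' Remove pairs below the per-level abstract minimum
#'
#' @param counts an [scp_counts] table.
#' @param tax `scp_taxonomy`; every SCP in `counts` must be present.
#' @param cfg a [population_config()].
#' @return filtered `scp_counts`.
#' @export
apply_abstract_minimum <- function(counts, tax, cfg = population_config()) {
  stopifnot(inherits(counts, "scp_counts"))
  lv <- scp_level(tax, counts$scp_id)
  if (anyNA(lv))
    stop("SCP(s) missing from taxonomy: ",
         paste(unique(counts$scp_id[is.na(lv)]), collapse = ", "),
         call. = FALSE)
  thr <- cfg$min_abstracts_by_level[as.character(lv)]
  thr[is.na(thr)] <- 1
  keep <- counts$count >= thr
  scp_counts(as.data.frame(counts)[keep, , drop = FALSE],
             attr(counts, "scp_totals"))
}

#' Apply manual-validation adjustments to mention counts
#'
#' Pairs labeled M (gene hit caused by a misinterpreted non-gene term) are
#' removed. Counts of pairs labeled S (gene belongs to a sibling SCP) are
#' multiplied by the sibling penalty factor and kept fractional. T and F
#' labels are untouched at this stage; unknown labeled pairs are ignored
#' with a warning.
#'
#' @inheritParams apply_abstract_minimum
#' @param labels a [validation_labels] table (or NULL).
#' @return adjusted `scp_counts`.
#' @export
apply_validation_adjustments <- function(counts, labels,
                                         cfg = population_config()) {
  stopifnot(inherits(counts, "scp_counts"))
  if (is.null(labels) || !nrow(labels)) return(counts)
  known <- paste(labels$gene, labels$scp_id, sep = "\r") %in%
    paste(counts$gene, counts$scp_id, sep = "\r")
  if (any(!known))
    warning(sum(!known), " labeled pair(s) not present in counts; ignored",
            call. = FALSE)
  lab <- label_lookup(labels, counts$gene, counts$scp_id)
  df <- as.data.frame(counts)
  df$count[lab == "S"] <- df$count[lab == "S"] * cfg$sibling_penalty_factor
  df <- df[lab != "M", , drop = FALSE]
  scp_counts(df, attr(counts, "scp_totals"))
}

#' Normalize per-SCP mention counts to a fixed article total
#'
#' Within each SCP, counts are scaled so that the per-SCP sum equals the
#' level's normalization target (3000 for levels 1-2, 1000 for levels 3-4
#' by default). Adds a `norm` column; SCPs with zero total are dropped and
#' reported in attribute `"empty_scps"`.
#'
#' @inheritParams apply_abstract_minimum
#' @param scps optional subset of SCP ids to normalize over (defaults to
#'   all SCPs present).
#' @return `scp_counts` with a `norm` column.
#' @export
normalize_scp_counts <- function(counts, tax, cfg = population_config(),
                                 scps = NULL) {
  stopifnot(inherits(counts, "scp_counts"))
  df <- as.data.frame(counts)
  if (!is.null(scps)) df <- df[df$scp_id %in% scps, , drop = FALSE]
  if (!nrow(df)) {
    df$norm <- numeric(0)
    out <- scp_counts(df, attr(counts, "scp_totals"))
    attr(out, "empty_scps") <- character()
    return(out)
  }
  lv <- scp_level(tax, df$scp_id)
  if (anyNA(lv)) stop("SCP(s) missing from taxonomy", call. = FALSE)
  target <- cfg$norm_total_by_level[as.character(lv)]
  sums <- rowsum(df$count, df$scp_id)
  tot <- sums[match(df$scp_id, rownames(sums)), 1L]
  empty <- unique(df$scp_id[tot <= 0])
  df <- df[tot > 0, , drop = FALSE]
  target <- target[tot > 0]; tot <- tot[tot > 0]
  df$norm <- df$count * target / tot
  out <- scp_counts(df, attr(counts, "scp_totals"))
  attr(out, "empty_scps") <- empty
  out
}

#' Competitive enrichment p-values for gene-SCP pairs
#'
#' For every (gene, SCP) pair within a background scope, computes the
#' one-sided Fisher probability that the gene's normalized article count in
#' that SCP (or a higher one) arose by chance given the gene's counts over
#' the background SCPs. The contingency table is built on the normalized
#' scale: `a` = rounded normalized count in the SCP, `a + b` = the SCP's
#' normalization target, `c` = rounded sum of the gene's normalized counts
#' over the other background SCPs, `c + d` = (number of background SCPs -
#' 1) x target.
#'
#' @inheritParams apply_abstract_minimum
#' @param background `"same_level"` (background = all SCPs of a level) or
#'   `"children_set"` (background = one set of siblings).
#' @param scope the level number (for `same_level`) or the parent SCP id
#'   (for `children_set`).
#' @return data.frame with columns `gene`, `scp_id`, `p`.
#' @export
gene_pvalues <- function(counts, tax,
                         background = c("same_level", "children_set"),
                         scope, cfg = population_config()) {
  background <- match.arg(background)
  df <- as.data.frame(counts)
  if (is.null(df$norm))
    stop("counts must be normalized first (see normalize_scp_counts)",
         call. = FALSE)
  bg_scps <- if (background == "same_level") {
    tax$scp_id[tax$level == as.integer(scope)]
  } else {
    query_relatives(tax, as.character(scope), "children")
  }
  df <- df[df$scp_id %in% bg_scps, , drop = FALSE]
  n_bg <- length(unique(df$scp_id))
  if (background == "same_level" && n_bg <= 1L)
    stop("same_level background needs more than one populated SCP",
         call. = FALSE)
  if (!nrow(df))
    return(data.frame(gene = character(), scp_id = character(),
                      p = numeric()))
  lv <- scp_level(tax, df$scp_id)
  target <- cfg$norm_total_by_level[as.character(lv)]
  gene_tot <- rowsum(df$norm, df$gene)
  tot <- gene_tot[match(df$gene, rownames(gene_tot)), 1L]
  a <- round(df$norm)
  b <- pmax(round(target) - a, 0)
  cc <- pmax(round(tot - df$norm), 0)
  d <- pmax((n_bg - 1) * round(target) - cc, 0)
  data.frame(gene = df$gene, scp_id = df$scp_id,
             # clamp underflowed p-values into (0, 1]
             p = pmax(fisher_upper_tail(a, b, cc, d), .Machine$double.xmin),
             stringsAsFactors = FALSE)
}

# Gap-filter a (gene, scp_id, p) table per gene; returns logical keep vector
# aligned with rows of pv.
gap_keep <- function(pv) {
  if (!nrow(pv)) return(logical(0))
  keep <- logical(nrow(pv))
  idx <- split(seq_len(nrow(pv)), pv$gene)
  for (rows in idx) {
    kept <- largest_gap_filter(stats::setNames(neglog10(pv$p[rows]),
                                               pv$scp_id[rows]))
    keep[rows] <- pv$scp_id[rows] %in% kept
  }
  keep
}

#' One competitive enrichment round with largest-gap removal
#'
#' Normalizes counts over the requested scope, computes per-gene Fisher
#' p-values against the background, and removes for every gene the SCP
#' associations below its largest -log10(p) gap. Pairs manually labeled T
#' are never removed: if the gap filter would drop them they are reinstated
#' (origin `"reinstated"`).
#'
#' @inheritParams apply_abstract_minimum
#' @param level taxonomy level whose SCPs are being populated.
#' @param background_kind `"same_level"` or `"children_set"`.
#' @param labels optional [validation_labels].
#' @return `scp_counts` restricted to surviving pairs, with columns `norm`,
#'   the p-value column (`p_same_level` or `p_children_set`) and `origin`.
#' @export
enrich_and_filter <- function(counts, tax, level,
                              background_kind = c("same_level",
                                                  "children_set"),
                              cfg = population_config(), labels = NULL) {
  background_kind <- match.arg(background_kind)
  level <- as.integer(level)
  level_scps <- tax$scp_id[tax$level == level]
  sub <- as.data.frame(counts)
  sub <- sub[sub$scp_id %in% level_scps, , drop = FALSE]
  sub$norm <- NULL
  nc <- normalize_scp_counts(scp_counts(sub, attr(counts, "scp_totals")),
                             tax, cfg)
  df <- as.data.frame(nc)
  if (!nrow(df)) {
    df$p <- numeric(0); df$origin <- character(0)
    names(df)[names(df) == "p"] <-
      if (background_kind == "same_level") "p_same_level" else "p_children_set"
    return(scp_counts(df, attr(counts, "scp_totals")))
  }

  if (background_kind == "same_level") {
    pv <- gene_pvalues(nc, tax, "same_level", level, cfg)
    keep <- gap_keep(pv)
  } else {
    parents <- unique(tax$parent_id[match(unique(df$scp_id), tax$scp_id)])
    pv_list <- lapply(sort(parents), function(p)
      gene_pvalues(nc, tax, "children_set", p, cfg))
    pv <- do.call(rbind, pv_list)
    keep <- unlist(lapply(pv_list, gap_keep), use.names = FALSE)
  }
  m <- match(paste(df$gene, df$scp_id, sep = "\r"),
             paste(pv$gene, pv$scp_id, sep = "\r"))
  df$p <- pv$p[m]
  row_keep <- keep[m]
  lab <- label_lookup(labels, df$gene, df$scp_id)
  reinstate <- !row_keep & lab == "T"
  df$origin <- ifelse(reinstate, "reinstated",
                      if (!is.null(df$origin)) df$origin else "enriched")
  df <- df[row_keep | reinstate, , drop = FALSE]
  names(df)[names(df) == "p"] <-
    if (background_kind == "same_level") "p_same_level" else "p_children_set"
  scp_counts(df, attr(counts, "scp_totals"))
}

#' Inheritance filter for level-1 and level-4 SCPs
#'
#' Replaces the same-level enrichment for the outer levels: a level-1
#' candidate gene is kept only if it is part of at least one of the SCP's
#' level-2 children or level-3 grandchildren in the populated reference;
#' a level-4 candidate is kept only if it is part of its level-3 parent.
#' Surviving rows carry origin `"inherited"`.
#'
#' @inheritParams apply_abstract_minimum
#' @param level 1 or 4.
#' @param reference populated associations for levels 2-3 (post manual
#'   validation).
#' @return filtered `scp_counts`.
#' @export
inherit_filter <- function(counts, tax, level, reference) {
  level <- as.integer(level)
  if (!level %in% c(1L, 4L)) stop("level must be 1 or 4", call. = FALSE)
  ref_lv <- scp_level(tax, reference$scp_id)
  if (!any(ref_lv %in% c(2L, 3L)))
    stop("reference must contain populated level-2/3 SCPs", call. = FALSE)
  df <- as.data.frame(counts)
  df <- df[scp_level(tax, df$scp_id) == level, , drop = FALSE]
  if (!nrow(df)) return(scp_counts(df, attr(counts, "scp_totals")))
  keep <- vapply(seq_len(nrow(df)), function(i) {
    s <- df$scp_id[i]
    allowed <- if (level == 1L) {
      kids <- query_relatives(tax, s, "children")
      gkids <- query_relatives(tax, s, "grandchildren")
      reference$gene[reference$scp_id %in% c(kids, gkids)]
    } else {
      reference$gene[reference$scp_id %in% query_relatives(tax, s, "parent")]
    }
    df$gene[i] %in% allowed
  }, logical(1))
  df <- df[keep, , drop = FALSE]
  df$origin <- rep("inherited", nrow(df))
  scp_counts(df, attr(counts, "scp_totals"))
}

#' Remove manually identified false positives
#'
#' @param table `scp_associations` or `scp_counts`-like data.frame.
#' @param labels [validation_labels].
#' @return table without F-labeled pairs.
#' @export
remove_false_positives <- function(table, labels) {
  if (is.null(labels) || !nrow(labels)) return(table)
  lab <- label_lookup(labels, table$gene, table$scp_id)
  out <- table[lab != "F", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Propagate genes upward through the hierarchy
#'
#' Adds every level-3 gene to its level-2 parent and level-1 grandparent
#' and every level-2 gene to its level-1 parent, where not already present.
#' Added rows carry origin `"propagated"` and no literature evidence of
#' their own.
#'
#' @param table data.frame of associations (gene, scp_id, ...).
#' @param tax `scp_taxonomy`.
#' @return table with propagated rows appended.
#' @export
propagate_upward <- function(table, tax) {
  df <- as.data.frame(table)
  lv <- scp_level(tax, df$scp_id)
  add <- list()
  push <- function(genes, scp, lab) {
    if (!length(genes)) return()
    add[[length(add) + 1L]] <<- data.frame(
      gene = genes, scp_id = scp, raw_count = NA_real_,
      adjusted_count = NA_real_, norm_count = NA_real_,
      p_same_level = NA_real_, p_children_set = NA_real_,
      label = lab, origin = "propagated", stringsAsFactors = FALSE)
  }
  existing <- paste(df$gene, df$scp_id, sep = "\r")
  # level-3 genes -> level-2 parent and level-1 grandparent
  l3 <- df[lv == 3L, , drop = FALSE]
  for (s in unique(l3$scp_id)) {
    anc <- scp_ancestors(tax, s)
    anc <- anc[scp_level(tax, anc) %in% c(1L, 2L)]
    genes_s <- l3[l3$scp_id == s, , drop = FALSE]
    for (a in anc) {
      new <- genes_s[!(paste(genes_s$gene, a, sep = "\r") %in% existing), ,
                     drop = FALSE]
      if (nrow(new)) {
        push(new$gene, a, new$label)
        existing <- c(existing, paste(new$gene, a, sep = "\r"))
      }
    }
  }
  # level-2 genes (incl. freshly propagated) -> level-1 parent
  l2_pairs <- rbind(
    df[lv == 2L, c("gene", "scp_id"), drop = FALSE],
    do.call(rbind, lapply(add, function(x)
      x[scp_level(tax, x$scp_id) == 2L, c("gene", "scp_id"), drop = FALSE])))
  if (!is.null(l2_pairs) && nrow(l2_pairs)) {
    for (s in unique(l2_pairs$scp_id)) {
      par <- query_relatives(tax, s, "parent")
      if (!length(par)) next
      g <- unique(l2_pairs$gene[l2_pairs$scp_id == s])
      new <- g[!(paste(g, par, sep = "\r") %in% existing)]
      if (length(new)) {
        push(new, par, "unlabeled")
        existing <- c(existing, paste(new, par, sep = "\r"))
      }
    }
  }
  if (length(add)) {
    extra <- do.call(rbind, add)
    common <- intersect(names(df), names(extra))
    for (nm in setdiff(names(df), names(extra))) extra[[nm]] <- NA
    df <- rbind(df[names(df)], extra[names(df)])
  }
  rownames(df) <- NULL
  df
}

#' Rank genes within each SCP
#'
#' Genes are ranked 1..N within each SCP by ascending children-set p-value,
#' ties by descending adjusted count, remaining ties alphabetically.
#' Rows without a children-set p-value (propagated rows) sort last.
#'
#' @param table data.frame of associations.
#' @return same table with a gapless integer `rank` column.
#' @export
rank_genes <- function(table) {
  df <- as.data.frame(table)
  p <- df$p_children_set
  p[is.na(p)] <- Inf
  cnt <- df$adjusted_count
  cnt[is.na(cnt)] <- -Inf
  o <- stable_order(df$scp_id, p, -cnt, df$gene)
  df <- df[o, , drop = FALSE]
  df$rank <- stats::ave(seq_len(nrow(df)), df$scp_id, FUN = seq_along)
  rownames(df) <- NULL
  df
}

#' Populate an SCP taxonomy with genes from literature mention counts
#'
#' Runs the full population pipeline: per-level abstract minimum,
#' manual-validation adjustments, then for levels 2 and 3 a same-level
#' competitive enrichment followed by a children-set enrichment (each with
#' per-SCP normalization and per-gene largest-gap removal); levels 1 and 4
#' are instead seeded by inheritance from the populated levels 2-3 and then
#' pass the children-set enrichment. Finally F-labeled pairs are removed,
#' level-3/2 genes are propagated upward, and genes are ranked within SCPs.
#' Deterministic given its inputs.
#'
#' @param counts an [scp_counts] table of raw abstract counts.
#' @param tax `scp_taxonomy`.
#' @param labels optional [validation_labels].
#' @param cfg a [population_config()].
#' @param levels taxonomy levels to populate (default 1:4; level-3-only
#'   runs are used by the leave-one-out relationship inference).
#' @param label_mode `"full"` applies all label rules; with
#'   `"no_fp_removal"` only misinterpreted-term (M) removals apply and
#'   F-labeled pairs are kept (the label regime of the leave-one-out runs).
#' @param propagate add level-3/2 genes to their ancestors (skipped
#'   automatically when levels 1-2 are not populated).
#' @return an [scp_associations] table.
#' @export
populate <- function(counts, tax, labels = NULL, cfg = population_config(),
                     levels = 1:4, label_mode = c("full", "no_fp_removal"),
                     propagate = TRUE) {
  stopifnot(inherits(counts, "scp_counts"), inherits(tax, "scp_taxonomy"))
  label_mode <- match.arg(label_mode)
  levels <- sort(unique(as.integer(levels)))

  raw <- as.data.frame(counts)
  raw_key <- paste(raw$gene, raw$scp_id, sep = "\r")
  thr <- apply_abstract_minimum(counts, tax, cfg)
  adj <- suppressWarnings(apply_validation_adjustments(thr, labels, cfg))

  run_level23 <- function(level) {
    s1 <- enrich_and_filter(adj, tax, level, "same_level", cfg, labels)
    s2 <- enrich_and_filter(s1, tax, level, "children_set", cfg, labels)
    df2 <- as.data.frame(s2)
    m <- match(paste(df2$gene, df2$scp_id, sep = "\r"),
               paste(s1$gene, s1$scp_id, sep = "\r"))
    df2$p_same_level <- s1$p_same_level[m]
    df2
  }

  parts <- list()
  for (lv in intersect(levels, 2:3))
    parts[[as.character(lv)]] <- run_level23(lv)

  ref23 <- do.call(rbind, unname(parts))
  if (label_mode == "full" && !is.null(ref23))
    ref23 <- remove_false_positives(ref23, labels)

  for (lv in intersect(levels, c(1L, 4L))) {
    if (is.null(ref23) || !nrow(ref23)) {
      parts[[as.character(lv)]] <- NULL
      next
    }
    inh <- inherit_filter(adj, tax, lv, ref23)
    s2 <- enrich_and_filter(inh, tax, lv, "children_set", cfg, labels)
    df2 <- as.data.frame(s2)
    if (nrow(df2)) {
      df2$p_same_level <- NA_real_
      df2$origin[df2$origin == "enriched"] <- "inherited"
    } else df2$p_same_level <- numeric(0)
    parts[[as.character(lv)]] <- df2
  }

  parts <- Filter(function(x) !is.null(x) && nrow(x) > 0, parts)
  if (!length(parts)) {
    return(scp_associations(data.frame(gene = character(),
                                       scp_id = character())))
  }
  all_cols <- c("gene", "scp_id", "count", "norm", "p_same_level",
                "p_children_set", "origin")
  tab <- do.call(rbind, lapply(unname(parts), function(x) x[all_cols]))

  tab$label <- label_lookup(labels, tab$gene, tab$scp_id)
  if (label_mode == "full")
    tab <- remove_false_positives(tab, labels)

  names(tab)[names(tab) == "count"] <- "adjusted_count"
  names(tab)[names(tab) == "norm"] <- "norm_count"
  tab$raw_count <- raw$count[match(paste(tab$gene, tab$scp_id, sep = "\r"),
                                   raw_key)]

  if (propagate && any(c(1L, 2L) %in% levels))
    tab <- propagate_upward(tab, tax)
  tab$label <- label_lookup(labels, tab$gene, tab$scp_id)
  tab <- rank_genes(tab)
  scp_associations(tab)
}
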