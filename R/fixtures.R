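#' Specification for synthetic SCP fixtures
#'
#' Describes a regular synthetic taxonomy (a root, `n_level1` level-1 SCPs,
#' a fixed number of children per node down to level 3, optionally level 4)
#' together with a generative model of the literature: every gene has one
#' primary level-3 SCP; an abstract of an SCP's article set mentions a gene
#' with probability `p_member` if the SCP is the gene's primary process
#' (or an ancestor of it), `p_related` if the pair is a planted leakage
#' edge (literature spill-over such as cargo proteins discussed in
#' endocytosis abstracts), and `p_background` otherwise. Membership
#' mention rates must dominate: `p_member > p_related > p_background`.
#'
#' @param n_level1 number of level-1 SCPs.
#' @param children_per_node named vector: children per level-1 node
#'   (`l1`), per level-2 node (`l2`) and optionally per level-3 node
#'   (`l3`, giving level-4 SCPs; 0 for none).
#' @param n_genes number of genes.
#' @param abstracts_per_scp abstracts in each SCP-specific article set.
#' @param p_member,p_related,p_background mean per-abstract mention
#'   probabilities.
#' @param gene_rate_sd sigma of the per-gene lognormal mention-rate
#'   multiplier (mean 1). Literature mention counts are heavy-tailed
#'   across genes: well-studied genes are cited more often everywhere.
#'   The multiplier scales a gene's mention probability in every SCP, so
#'   it cancels in the within-gene competitive enrichment but produces
#'   realistic interleaving of within-SCP ranks. 0 disables it.
#' @param leakage_edges data.frame (`from`, `to`, optional `rate`) of
#'   planted directed literature leakage between level-3 SCPs: genes
#'   primary in `from` are mentioned in `to`'s abstracts at `rate`
#'   (default `p_related`).
#' @param rho latent within-SCP expression correlation in [0, 1].
#' @param n_tissues number of tissues for the expression fixture.
#' @param seed mandatory RNG seed; every generator is a pure function of
#'   (spec, seed).
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_level1 = 4, children_per_node = c(l1 = 2, l2 = 2,
                                                             l3 = 0),
                         n_genes = 100, abstracts_per_scp = 100,
                         p_member = 0.10, p_related = 0.03,
                         p_background = 0.002, gene_rate_sd = 0.8,
                         leakage_edges = NULL, rho = 0.5, n_tissues = 30,
                         seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  probs <- c(p_member, p_related, p_background)
  if (any(probs < 0 | probs > 1))
    stop("mention probabilities must be in [0, 1]", call. = FALSE)
  if (!(p_member > p_related && p_related > p_background))
    stop("need p_member > p_related > p_background", call. = FALSE)
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]", call. = FALSE)
  if (!is.null(leakage_edges))
    stopifnot(all(c("from", "to") %in% names(leakage_edges)))
  if (gene_rate_sd < 0) stop("gene_rate_sd must be >= 0", call. = FALSE)
  structure(list(n_level1 = n_level1, children_per_node = children_per_node,
                 n_genes = n_genes, abstracts_per_scp = abstracts_per_scp,
                 p_member = p_member, p_related = p_related,
                 p_background = p_background, gene_rate_sd = gene_rate_sd,
                 leakage_edges = leakage_edges,
                 rho = rho, n_tissues = n_tissues, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic taxonomy and gene-membership truth
#'
#' Builds the regular taxonomy described by the spec and assigns every
#' gene a primary level-3 SCP (round-robin over a seeded permutation, so
#' level-3 set sizes are balanced). The truth table is the reference for
#' precision/recall of the population pipeline.
#'
#' @param spec a [fixture_spec()].
#' @return list with `taxonomy` (an `scp_taxonomy`; level-1 SCPs carry a
#'   `signaling` class tag on the last branch so edge-exclusion rules are
#'   exercisable) and `truth` (data.frame `gene`, `scp_id` of the primary
#'   level-3 SCP).
#' @export
generate_taxonomy <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  cpn <- spec$children_per_node
  rows <- list(data.frame(scp_id = "SCP0000", name = "Whole cell function",
                          level = 0L, parent_id = NA_character_,
                          class_tags = "", stringsAsFactors = FALSE))
  mk <- function(n, prefix) sprintf("%s%03d", prefix, seq_len(n))
  l1 <- mk(spec$n_level1, "L1-")
  rows[[2]] <- data.frame(scp_id = l1, name = paste("Process", l1),
                          level = 1L, parent_id = "SCP0000",
                          class_tags = ifelse(seq_along(l1) == length(l1),
                                              "signaling", ""),
                          stringsAsFactors = FALSE)
  l2 <- character(); l2p <- character()
  for (p in l1) {
    ids <- sprintf("%s.%d", sub("L1-", "L2-", p), seq_len(cpn[["l1"]]))
    l2 <- c(l2, ids); l2p <- c(l2p, rep(p, length(ids)))
  }
  rows[[3]] <- data.frame(scp_id = l2, name = paste("Process", l2),
                          level = 2L, parent_id = l2p, class_tags = "",
                          stringsAsFactors = FALSE)
  l3 <- character(); l3p <- character()
  for (p in l2) {
    ids <- sprintf("%s.%d", sub("L2-", "L3-", p), seq_len(cpn[["l2"]]))
    l3 <- c(l3, ids); l3p <- c(l3p, rep(p, length(ids)))
  }
  rows[[4]] <- data.frame(scp_id = l3, name = paste("Process", l3),
                          level = 3L, parent_id = l3p, class_tags = "",
                          stringsAsFactors = FALSE)
  n4 <- if (!is.na(cpn["l3"])) cpn[["l3"]] else 0
  if (n4 > 0) {
    l4 <- character(); l4p <- character()
    for (p in l3) {
      ids <- sprintf("%s.%d", sub("L3-", "L4-", p), seq_len(n4))
      l4 <- c(l4, ids); l4p <- c(l4p, rep(p, length(ids)))
    }
    rows[[5]] <- data.frame(scp_id = l4, name = paste("Process", l4),
                            level = 4L, parent_id = l4p, class_tags = "",
                            stringsAsFactors = FALSE)
  }
  tax <- scp_taxonomy(do.call(rbind, rows))
  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  truth <- with_seed(spec$seed, {
    assign_to <- rep(sample(l3), length.out = spec$n_genes)
    data.frame(gene = genes, scp_id = assign_to, stringsAsFactors = FALSE)
  })
  list(taxonomy = tax, truth = truth)
}

#' Synthetic taxonomy with a prescribed per-level profile
#'
#' Builds a structurally valid taxonomy with exactly the requested number
#' of SCPs at each level (plus the level-0 root), assigning parents
#' round-robin so every node has a parent one level up. Node names are
#' synthetic placeholders; the tree is a stand-in for summary-level
#' structural analyses, not a biological annotation.
#'
#' @param profile named integer vector `c(l1 = ..., l2 = ..., l3 = ...,
#'   l4 = ...)`; `l4` may be 0.
#' @return an `scp_taxonomy`.
#' @export
level_profile_taxonomy <- function(profile) {
  stopifnot(all(c("l1", "l2", "l3") %in% names(profile)))
  n <- c(profile[["l1"]], profile[["l2"]], profile[["l3"]],
         if (!is.na(profile["l4"])) profile[["l4"]] else 0L)
  ids <- lapply(seq_along(n), function(l) sprintf("L%d-%04d", l, seq_len(n[l])))
  rows <- list(data.frame(scp_id = "ROOT", name = "Whole cell function",
                          level = 0L, parent_id = NA_character_,
                          stringsAsFactors = FALSE))
  parents <- "ROOT"
  for (l in seq_along(n)) {
    if (n[l] == 0L) next
    rows[[l + 1L]] <- data.frame(
      scp_id = ids[[l]], name = paste("Synthetic process", ids[[l]]),
      level = l, parent_id = rep(parents, length.out = n[l]),
      stringsAsFactors = FALSE)
    parents <- ids[[l]]
  }
  scp_taxonomy(do.call(rbind, rows))
}

# Genes whose primary level-3 SCP equals `scp` or descends from it. Level-4
# SCPs deterministically split their level-3 parent's members round-robin,
# emulating more detailed sub-processes.
member_genes_of <- function(truth, tax, scp) {
  lv <- scp_level(tax, scp)
  if (lv == 3L) return(truth$gene[truth$scp_id == scp])
  if (lv == 4L) {
    par <- query_relatives(tax, scp, "parent")
    sibs <- sort(query_relatives(tax, par, "children"))
    pos <- match(scp, sibs)
    pg <- sort(truth$gene[truth$scp_id == par])
    return(pg[(seq_along(pg) - 1L) %% length(sibs) + 1L == pos])
  }
  desc <- query_relatives(tax, scp, "children")
  repeat {
    lower <- tax$scp_id[!is.na(tax$parent_id) & tax$parent_id %in% desc]
    if (!length(setdiff(lower, desc))) break
    desc <- union(desc, lower)
  }
  l3 <- desc[scp_level(tax, desc) == 3L]
  truth$gene[truth$scp_id %in% l3]
}

#' Simulate literature mention counts with planted membership
#'
#' For every SCP at levels 1-4 (level 1-2 member sets are the union over
#' descendant level-3 SCPs), draws the number of abstracts mentioning each
#' gene as `Binomial(abstracts_per_scp, p)` with the mention probability
#' determined by membership, planted leakage, or background. The binomial
#' keeps counts bounded by the abstract-set size, as document-level
#' counting requires.
#'
#' @param truth membership truth from [generate_taxonomy()].
#' @param tax the matching `scp_taxonomy`.
#' @param spec the [fixture_spec()].
#' @return an [scp_counts] table (zero counts omitted) with per-SCP
#'   abstract totals.
#' @export
simulate_counts <- function(truth, tax, spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  scps <- tax$scp_id[tax$level >= 1L]
  genes <- unique(truth$gene)
  leak <- spec$leakage_edges
  with_seed(spec$seed + 1L, {
    sd <- spec$gene_rate_sd %||% 0
    fame <- if (sd > 0)
      exp(stats::rnorm(length(genes), -sd^2 / 2, sd)) else rep(1, length(genes))
    out <- vector("list", length(scps))
    for (si in seq_along(scps)) {
      s <- scps[si]
      p <- rep(spec$p_background, length(genes))
      members <- member_genes_of(truth, tax, s)
      p[genes %in% members] <- spec$p_member
      if (!is.null(leak)) {
        lk <- leak[leak$to == s, , drop = FALSE]
        if (nrow(lk)) {
          for (j in seq_len(nrow(lk))) {
            src_genes <- truth$gene[truth$scp_id == lk$from[j]]
            rate <- if (!is.null(lk$rate)) lk$rate[j] else spec$p_related
            idx <- genes %in% src_genes & !(genes %in% members)
            p[idx] <- rate
          }
        }
      }
      cnt <- stats::rbinom(length(genes), spec$abstracts_per_scp,
                           pmin(1, p * fame))
      nz <- cnt > 0
      out[[si]] <- data.frame(gene = genes[nz], scp_id = s,
                              count = as.numeric(cnt[nz]),
                              stringsAsFactors = FALSE)
    }
    totals <- stats::setNames(rep(as.numeric(spec$abstracts_per_scp),
                                  length(scps)), scps)
    scp_counts(do.call(rbind, out), totals)
  })
}

#' Sample a perturbed gene list from target SCPs
#'
#' Emulates an experimental hit list: `n_from_each` member genes sampled
#' without replacement from every target SCP, plus `n_noise` genes drawn
#' from the remaining gene universe.
#'
#' @param truth membership truth table.
#' @param target_scps level-3 SCP ids to draw members from.
#' @param n_from_each members sampled per target.
#' @param n_noise number of unrelated genes added.
#' @param seed RNG seed.
#' @return data.frame `gene`, `origin` (target SCP id or `"noise"`).
#' @export
simulate_perturbation <- function(truth, target_scps, n_from_each,
                                  n_noise = 0, seed) {
  with_seed(seed, {
    picks <- lapply(target_scps, function(s) {
      pool <- truth$gene[truth$scp_id == s]
      if (length(pool) < n_from_each)
        stop("SCP ", s, " has fewer than ", n_from_each, " member genes",
             call. = FALSE)
      data.frame(gene = sample(pool, n_from_each), origin = s,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, picks)
    if (n_noise > 0) {
      pool <- setdiff(truth$gene, out$gene)
      out <- rbind(out, data.frame(gene = sample(pool, n_noise),
                                   origin = "noise",
                                   stringsAsFactors = FALSE))
    }
    out
  })
}

#' Simulate a tissue expression matrix with within-SCP correlation
#'
#' Each level-3 SCP receives a latent standard-normal tissue profile;
#' member genes mix the latent profile with independent noise so that the
#' expected correlation of two genes sharing an SCP is `rho`, and 0 for
#' genes of different SCPs. Values are shifted to an RPKM-like non-negative
#' scale (offset 8, truncated at 0), which leaves Pearson correlations
#' essentially untouched.
#'
#' @inheritParams simulate_counts
#' @return numeric matrix genes x tissues.
#' @export
simulate_expression <- function(truth, spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed + 2L, {
    scps <- unique(truth$scp_id)
    latent <- matrix(stats::rnorm(length(scps) * spec$n_tissues),
                     nrow = length(scps),
                     dimnames = list(scps, NULL))
    noise <- matrix(stats::rnorm(nrow(truth) * spec$n_tissues),
                    nrow = nrow(truth))
    z <- sqrt(spec$rho) * latent[truth$scp_id, , drop = FALSE] +
      sqrt(1 - spec$rho) * noise
    expr <- pmax(z + 8, 0)
    rownames(expr) <- truth$gene
    colnames(expr) <- sprintf("tissue_%02d", seq_len(spec$n_tissues))
    expr
  })
}

#' Simulate manual-validation labels against the truth
#'
#' Labels every populated (gene, SCP) pair T when the SCP is the gene's
#' primary level-3 SCP (or an ancestor of it) and F otherwise; with
#' probability `fp_rate` a pair's verdict is flipped (mislabeling).
#' Optionally, planted sibling confusions are labeled S and planted
#' dictionary confusions M instead of F.
#'
#' @param truth membership truth table.
#' @param table data.frame of candidate pairs (`gene`, `scp_id`).
#' @param tax the `scp_taxonomy` (for ancestor-aware truth at levels 1-2).
#' @param fp_rate mislabeling probability.
#' @param seed RNG seed.
#' @param sibling_pairs,misinterpreted_pairs optional data.frames
#'   (`gene`, `scp_id`) labeled S / M.
#' @return a [validation_labels] table.
#' @export
simulate_validation_labels <- function(truth, table, tax, fp_rate = 0,
                                       seed, sibling_pairs = NULL,
                                       misinterpreted_pairs = NULL) {
  with_seed(seed, {
    is_true <- vapply(seq_len(nrow(table)), function(i)
      table$gene[i] %in% member_genes_of(truth, tax, table$scp_id[i]),
      logical(1))
    flip <- stats::runif(nrow(table)) < fp_rate
    verdict <- ifelse(xor(is_true, flip), "T", "F")
    out <- data.frame(gene = table$gene, scp_id = table$scp_id,
                      label = verdict, stringsAsFactors = FALSE)
    overlay <- function(out, pairs, lab) {
      if (is.null(pairs) || !nrow(pairs)) return(out)
      k <- paste(out$gene, out$scp_id, sep = "\r")
      pk <- paste(pairs$gene, pairs$scp_id, sep = "\r")
      out$label[k %in% pk] <- lab
      new <- !(pk %in% k)
      if (any(new))
        out <- rbind(out, data.frame(gene = pairs$gene[new],
                                     scp_id = pairs$scp_id[new],
                                     label = lab, stringsAsFactors = FALSE))
      out
    }
    out <- overlay(out, sibling_pairs, "S")
    out <- overlay(out, misinterpreted_pairs, "M")
    validation_labels(out)
  })
}
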