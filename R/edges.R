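#' Re-populate level-3 SCPs with one SCP left out
#'
#' Removes one level-3 SCP from the count matrix and re-runs the level-3
#' population. Label handling is restricted to the leave-one-out regime:
#' only misinterpreted-term (M) removals apply; other false-positive labels
#' are kept (count adjustments for S and T-reinstatement still apply).
#'
#' @param scp_id the level-3 SCP to leave out.
#' @param counts raw [scp_counts].
#' @param tax `scp_taxonomy`.
#' @param labels optional [validation_labels].
#' @param cfg [population_config()].
#' @return an [scp_associations] table over the remaining level-3 SCPs.
#' @export
repopulate_without <- function(scp_id, counts, tax, labels = NULL,
                               cfg = population_config()) {
  if (scp_level(tax, scp_id) != 3L)
    stop(scp_id, " is not a level-3 SCP", call. = FALSE)
  sub <- as.data.frame(counts)
  sub <- sub[sub$scp_id != scp_id, , drop = FALSE]
  populate(scp_counts(sub, attr(counts, "scp_totals")), tax, labels, cfg,
           levels = 3L, label_mode = "no_fp_removal", propagate = FALSE)
}

#' Score the competition between a removed SCP and the remaining SCPs
#'
#' For each remaining level-3 SCP, member genes of the removed SCP are
#' checked in the re-populated ontology: a member that newly appears in a
#' remaining SCP of baseline size N enters at notional prior rank N + 1;
#' a member already present contributes its rank improvement. Improvements
#' (numeric rank value decreasing) are summed and normalized by the SCP's
#' size before removal; worsened ranks contribute zero. Edges with zero
#' score are dropped.
#'
#' @param removed_scp id of the left-out SCP.
#' @param baseline reference `scp_associations` (all SCPs present).
#' @param alternative `scp_associations` from [repopulate_without()].
#' @param members genes considered members of the removed SCP (the
#'   manually validated members; for unlabeled corpora the baseline gene
#'   set of the removed SCP).
#' @return data.frame (`removed_scp`, `remaining_scp`, `score`,
#'   `contributing_genes`).
#' @export
score_competition <- function(removed_scp, baseline, alternative, members) {
  rem <- setdiff(unique(c(baseline$scp_id, alternative$scp_id)), removed_scp)
  out <- lapply(sort(rem), function(r) {
    base_r <- baseline[baseline$scp_id == r, , drop = FALSE]
    alt_r <- alternative[alternative$scp_id == r, , drop = FALSE]
    n_before <- nrow(base_r)
    if (n_before == 0L) return(NULL)  # size normalization undefined
    m <- members[members %in% alt_r$gene]
    if (!length(m)) return(NULL)
    rank_after <- alt_r$rank[match(m, alt_r$gene)]
    rank_before <- base_r$rank[match(m, base_r$gene)]
    rank_before[is.na(rank_before)] <- n_before + 1L
    delta <- pmax(0, rank_before - rank_after)
    if (sum(delta) <= 0) return(NULL)
    data.frame(removed_scp = removed_scp, remaining_scp = r,
               score = sum(delta) / n_before,
               contributing_genes = paste(sort(m[delta > 0]),
                                          collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(removed_scp = character(), remaining_scp = character(),
                      score = numeric(), contributing_genes = character(),
                      stringsAsFactors = FALSE)
  out
}

#' Infer weighted level-3 SCP-SCP relationships by leave-one-out
#'
#' Removes one level-3 SCP at a time, re-populates the remaining level-3
#' SCPs, and scores how strongly each remaining SCP absorbs the removed
#' SCP's member genes ([score_competition()]). The union over all removals
#' is the weighted directed relationship list. Deterministic given inputs.
#'
#' @inheritParams repopulate_without
#' @param scps optional subset of level-3 SCPs to leave out (defaults to
#'   all populated level-3 SCPs).
#' @return data.frame of class `scp_edges`.
#' @export
infer_scp_edges <- function(counts, tax, labels = NULL,
                            cfg = population_config(), scps = NULL) {
  baseline <- populate(counts, tax, labels, cfg, levels = 3L,
                       label_mode = "no_fp_removal", propagate = FALSE)
  if (is.null(scps))
    scps <- sort(unique(baseline$scp_id))
  validated <- if (!is.null(labels) && nrow(labels))
    labels[labels$label == "T", , drop = FALSE] else NULL
  res <- lapply(scps, function(s) {
    alt <- repopulate_without(s, counts, tax, labels, cfg)
    members <- if (!is.null(validated)) {
      validated$gene[validated$scp_id == s]
    } else baseline$gene[baseline$scp_id == s]
    if (!length(members)) return(NULL)
    score_competition(s, baseline, alt, members)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(removed_scp = character(), remaining_scp = character(),
                      score = numeric(), contributing_genes = character(),
                      stringsAsFactors = FALSE)
  structure(out[stable_order(-out$score, out$removed_scp,
                             out$remaining_scp), , drop = FALSE],
            class = c("scp_edges", "data.frame"))
}

#' Keep the top fraction of inferred edges
#'
#' Edges whose two endpoints both carry an excluded class tag (by default
#' `signaling`, whose relationships mostly reflect shared genes rather
#' than functional coupling) are dropped first; the remainder is sorted by
#' decreasing score and the top `ceiling(q * N)` kept, including all edges
#' tied with the cutoff score.
#'
#' @param edges an `scp_edges` data.frame.
#' @param q fraction in [0, 1].
#' @param tax `scp_taxonomy` (needed when `exclude_tags` is non-empty).
#' @param exclude_tags class tags defining excluded endpoint pairs.
#' @return filtered `scp_edges`.
#' @export
top_fraction <- function(edges, q, tax = NULL, exclude_tags = "signaling") {
  stopifnot(q >= 0, q <= 1)
  df <- as.data.frame(edges)
  if (length(exclude_tags) && !is.null(tax) && nrow(df)) {
    both <- vapply(seq_len(nrow(df)), function(i)
      any(vapply(exclude_tags, function(tg)
        has_class_tag(tax, df$removed_scp[i], tg) &&
          has_class_tag(tax, df$remaining_scp[i], tg), logical(1))),
      logical(1))
    df <- df[!both, , drop = FALSE]
  }
  if (!nrow(df) || q == 0)
    return(structure(df[0, , drop = FALSE],
                     class = c("scp_edges", "data.frame")))
  df <- df[stable_order(-df$score, df$removed_scp, df$remaining_scp), ,
           drop = FALSE]
  k <- ceiling(q * nrow(df))
  cutoff <- df$score[k]
  out <- df[df$score >= cutoff, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("scp_edges", "data.frame"))
}

#' @export
print.scp_edges <- function(x, ...) {
  cat(sprintf("inferred SCP-SCP relationships: %d edges between %d SCPs\n",
              nrow(x), length(unique(c(x$removed_scp, x$remaining_scp)))))
  invisible(x)
}

#' Write / read inferred edges as TSV
#'
#' @param edges `scp_edges`.
#' @param path TSV path.
#' @export
save_edges <- function(edges, path) {
  write_tsv_base(as.data.frame(edges), path)
}

#' @rdname save_edges
#' @export
load_edges <- function(path) {
  df <- read_tsv_base(path)
  stopifnot(all(c("removed_scp", "remaining_scp", "score") %in% names(df)))
  if (is.null(df$contributing_genes)) df$contributing_genes <- ""
  structure(df, class = c("scp_edges", "data.frame"))
}

# Collapse directed edges to undirected pairs, keeping the max score of the
# two directions.
undirect_edges <- function(edges) {
  if (!nrow(edges))
    return(data.frame(a = character(), b = character(), score = numeric()))
  a <- pmin(edges$removed_scp, edges$remaining_scp)
  b <- pmax(edges$removed_scp, edges$remaining_scp)
  key <- paste(a, b, sep = "\r")
  sc <- tapply(edges$score, key, max)
  parts <- strsplit(names(sc), "\r", fixed = TRUE)
  data.frame(a = vapply(parts, `[`, "", 1L), b = vapply(parts, `[`, "", 2L),
             score = as.numeric(sc), stringsAsFactors = FALSE)
}
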