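#' Standard Fisher gene-set enrichment
#'
#' One-sided Fisher exact test of a query gene list against every gene set
#' over a fixed universe: for a set S, the 2x2 table is (|query ∩ S|,
#' |query \\ S|, |S \\ query|, rest of universe) and the upper tail is
#' tested. Results are sorted by ascending p-value with gapless ranks.
#'
#' @param query_genes character vector of query genes.
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()] or [gene_sets_by_level()]).
#' @param universe gene universe; must contain every gene set. Defaults to
#'   the union of all gene sets.
#' @param adjust multiple-testing adjustment passed to
#'   [stats::p.adjust()] (default `"none"`: targets are ranked by raw
#'   p-value; `"BH"` available as an option).
#' @return data.frame of class `scp_enrichment` (`target`, `p`, `p_adj`,
#'   `n_set`, `n_overlap`, `overlap_genes`, `rank`).
#' @export
standard_enrichment <- function(query_genes, gene_sets, universe = NULL,
                                adjust = "none") {
  if (!length(query_genes)) stop("empty query gene list", call. = FALSE)
  if (is.null(universe)) universe <- unique(unlist(gene_sets))
  query <- unique(intersect(query_genes, universe))
  if (!length(query))
    stop("query genes are disjoint from the universe", call. = FALSE)
  n_u <- length(universe)
  res <- lapply(names(gene_sets), function(nm) {
    set <- unique(intersect(gene_sets[[nm]], universe))
    ov <- intersect(query, set)
    a <- length(ov)
    b <- length(query) - a
    cc <- length(set) - a
    d <- n_u - a - b - cc
    data.frame(target = nm, p = fisher_upper_tail(a, b, cc, d),
               n_set = length(set), n_overlap = a,
               overlap_genes = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = adjust)
  out <- out[stable_order(out$p, out$target), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out[c("target", "p", "p_adj", "n_set", "n_overlap",
                  "overlap_genes", "rank")],
            class = c("scp_enrichment", "data.frame"))
}

#' @export
print.scp_enrichment <- function(x, n = 10, ...) {
  cat(sprintf("enrichment over %d targets; top %d:\n", nrow(x),
              min(n, nrow(x))))
  print.data.frame(utils::head(as.data.frame(x)[c("rank", "target", "p",
                                                  "n_overlap", "n_set")], n),
                   row.names = FALSE)
  invisible(x)
}

#' Gene sets per taxonomy level from a populated ontology
#'
#' @param table `scp_associations`.
#' @param tax `scp_taxonomy`.
#' @param level taxonomy level.
#' @return named list of gene vectors, names are SCP ids.
#' @export
gene_sets_by_level <- function(table, tax, level) {
  lv <- scp_level(tax, table$scp_id)
  sub <- table[lv == level, , drop = FALSE]
  split(sub$gene, sub$scp_id)
}

#' Build merged SCP units from edge-connected level-3 SCPs
#'
#' Candidate SCPs are the level-3 SCPs containing at least one perturbed
#' gene. All pairs connected by a selected edge and all triples of
#' candidates whose induced subgraph is connected (paths and triangles
#' both qualify) become SCP units; a unit's gene set is the union of its
#' members' sets. Output is independent of edge order.
#'
#' @param perturbed character vector of experimentally perturbed genes.
#' @param level3_sets named list of level-3 gene sets.
#' @param edges_topq `scp_edges` already restricted by [top_fraction()].
#' @param max_size maximal unit size (2 or 3; default 3).
#' @return named list of unit gene sets; each element carries attribute
#'   `"members"`. Unit names join member ids with `"+"`.
#' @export
build_units <- function(perturbed, level3_sets, edges_topq, max_size = 3) {
  stopifnot(max_size %in% 2:3)
  cand <- names(level3_sets)[vapply(level3_sets, function(g)
    any(perturbed %in% g), logical(1))]
  if (!length(cand) || !nrow(edges_topq))
    return(structure(list(), names = character()))
  und <- undirect_edges(edges_topq)
  und <- und[und$a %in% cand & und$b %in% cand, , drop = FALSE]
  units <- list()
  add_unit <- function(members) {
    members <- sort(members)
    nm <- paste(members, collapse = "+")
    if (!is.null(units[[nm]])) return()
    gs <- sort(unique(unlist(level3_sets[members])))
    attr(gs, "members") <- members
    units[[nm]] <<- gs
  }
  for (i in seq_len(nrow(und))) add_unit(c(und$a[i], und$b[i]))
  if (max_size >= 3 && nrow(und)) {
    adj <- lapply(stats::setNames(cand, cand), function(x)
      unique(c(und$b[und$a == x], und$a[und$b == x])))
    cand3 <- sort(unique(c(und$a, und$b)))
    if (length(cand3) >= 3) {
      trip <- utils::combn(cand3, 3, simplify = FALSE)
      for (t in trip) {
        deg <- vapply(t, function(x) sum(t %in% adj[[x]]), numeric(1))
        # induced subgraph on 3 nodes is connected iff it has >= 2 edges
        if (sum(deg) / 2 >= 2) add_unit(t)
      }
    }
  }
  if (!length(units)) return(structure(list(), names = character()))
  units[order(names(units))]
}

#' Dynamic enrichment over level-3 SCPs plus context-specific units
#'
#' Extends the level-3 gene-set collection with merged SCP units built
#' from the top-`q` inferred relationships ([build_units()]) and re-runs
#' the standard Fisher enrichment over the extended collection. With no
#' edges (or `q = 0`) this reduces exactly to [standard_enrichment()].
#'
#' @param query_genes perturbed gene list.
#' @param table populated `scp_associations`.
#' @param tax `scp_taxonomy`.
#' @param edges full `scp_edges` from [infer_scp_edges()].
#' @param q top fraction of edges used for unit building (default 0.25).
#' @param max_size maximal unit size (default 3).
#' @param top_k number of top results reported by downstream network
#'   extraction (default 5).
#' @param universe enrichment universe; defaults to all genes associated
#'   with any level-3 SCP.
#' @param adjust see [standard_enrichment()].
#' @return `scp_enrichment` with attributes `"units"` (the unit list) and
#'   `"top_k"`.
#' @export
dynamic_enrichment <- function(query_genes, table, tax, edges,
                               q = 0.25, max_size = 3, top_k = 5,
                               universe = NULL, adjust = "none") {
  sets <- gene_sets_by_level(table, tax, 3)
  topq <- top_fraction(edges, q, tax)
  units <- build_units(query_genes, sets, topq, max_size)
  all_sets <- c(sets, units)
  if (is.null(universe)) universe <- unique(unlist(sets))
  out <- standard_enrichment(query_genes, all_sets, universe, adjust)
  attr(out, "units") <- units
  attr(out, "top_k") <- top_k
  out
}

#' Extract the context network of the top enrichment results
#'
#' Collects every level-3 SCP appearing among the top-`k` results (as a
#' singleton or as a unit member), connects them using all inferred
#' relationships (signaling-signaling pairs still excluded), and returns
#' the largest connected component, decorated with the annotated level-2
#' parents and level-1 grandparents of its members. Ties between equally
#' large components are broken toward the component containing the
#' best-ranked (lowest p) result.
#'
#' @param top_results an `scp_enrichment` (typically from
#'   [dynamic_enrichment()]); its first `top_k` rows are used.
#' @param all_edges full `scp_edges`.
#' @param tax `scp_taxonomy`.
#' @param top_k how many top results to use (defaults to the result's
#'   `"top_k"` attribute, else 5).
#' @return list with `nodes` (data.frame `scp_id`, `level`, `role` in
#'   `member`/`ancestor`) and `edges` (undirected, within members).
#' @export
extract_context_network <- function(top_results, all_edges, tax,
                                    top_k = NULL) {
  if (!nrow(top_results)) stop("empty top results", call. = FALSE)
  top_k <- top_k %||% attr(top_results, "top_k") %||% 5
  top <- utils::head(top_results, top_k)
  units <- attr(top_results, "units")
  members <- unique(unlist(lapply(top$target, function(t) {
    if (!is.null(units[[t]])) attr(units[[t]], "members")
    else strsplit(t, "+", fixed = TRUE)[[1L]]
  })))
  members <- members[members %in% tax$scp_id]
  und <- undirect_edges(top_fraction(all_edges, 1, tax))
  und <- und[und$a %in% members & und$b %in% members, , drop = FALSE]

  g <- igraph::graph_from_data_frame(
    und[c("a", "b")], directed = FALSE,
    vertices = data.frame(name = members))
  comp <- igraph::components(g)
  sizes <- comp$csize
  best_of <- function(scps) {
    # best (lowest) rank among top results touching these SCPs
    r <- vapply(seq_len(nrow(top)), function(i) {
      t <- top$target[i]
      ms <- if (!is.null(units[[t]])) attr(units[[t]], "members") else t
      if (any(ms %in% scps)) i else NA_integer_
    }, integer(1))
    suppressWarnings(min(r, na.rm = TRUE))
  }
  big <- which(sizes == max(sizes))
  if (length(big) > 1L) {
    scores <- vapply(big, function(ci)
      best_of(names(comp$membership)[comp$membership == ci]), numeric(1))
    big <- big[which.min(scores)]
  }
  keep <- names(comp$membership)[comp$membership == big]
  anc <- unique(unlist(lapply(keep, function(s) {
    a <- scp_ancestors(tax, s)
    a[scp_level(tax, a) %in% c(1L, 2L)]
  })))
  nodes <- rbind(
    data.frame(scp_id = sort(keep), level = scp_level(tax, sort(keep)),
               role = "member", stringsAsFactors = FALSE),
    data.frame(scp_id = sort(anc), level = scp_level(tax, sort(anc)),
               role = "ancestor", stringsAsFactors = FALSE))
  eo <- und[und$a %in% keep & und$b %in% keep, , drop = FALSE]
  rownames(eo) <- NULL
  list(nodes = nodes, edges = eo)
}
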