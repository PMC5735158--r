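#' Read a GCT expression matrix
#'
#' GCT: line 1 a version tag (`#1.2`), line 2 `n_rows<TAB>n_cols`, then a
#' TSV with `Name`, `Description` and one column per sample. Duplicate
#' gene symbols collapse to the row with the highest median expression;
#' rows with missing values are dropped.
#'
#' @param path GCT (or plain TSV with gene-symbol first column) file.
#' @return numeric matrix genes x samples.
#' @export
read_gct <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  skip <- if (startsWith(first, "#1.")) 2L else 0L
  df <- utils::read.delim(path, skip = skip, stringsAsFactors = FALSE,
                          check.names = FALSE)
  has_desc <- tolower(names(df)[2]) %in% c("description", "desc")
  genes <- as.character(df[[1L]])
  vals <- as.matrix(df[, (if (has_desc) 3L else 2L):ncol(df), drop = FALSE])
  mode(vals) <- "numeric"
  ok <- stats::complete.cases(vals)
  vals <- vals[ok, , drop = FALSE]; genes <- genes[ok]
  if (anyDuplicated(genes)) {
    med <- apply(vals, 1L, stats::median)
    o <- stable_order(genes, -med)
    keep <- o[!duplicated(genes[o])]
    vals <- vals[keep, , drop = FALSE]; genes <- genes[keep]
  }
  rownames(vals) <- genes
  vals
}

#' Pairwise Pearson correlation between genes
#'
#' Correlations of row profiles across tissues. Genes with zero variance
#' are excluded (with a message) since their correlation is undefined.
#'
#' @param expr numeric matrix genes x tissues (at least 3 tissues).
#' @param genes optional subset of row names.
#' @return data.frame (`gene1`, `gene2`, `r`) over unordered pairs with
#'   `gene1 < gene2`.
#' @export
pairwise_pearson <- function(expr, genes = NULL) {
  if (!is.null(genes)) expr <- expr[rownames(expr) %in% genes, , drop = FALSE]
  if (ncol(expr) < 3L) stop("need at least 3 tissues", call. = FALSE)
  v <- apply(expr, 1L, stats::var)
  if (any(v == 0)) {
    message("excluding ", sum(v == 0), " zero-variance gene(s)")
    expr <- expr[v > 0, , drop = FALSE]
  }
  if (nrow(expr) < 2L) stop("fewer than 2 usable genes", call. = FALSE)
  cm <- stats::cor(t(expr))
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  out <- data.frame(gene1 = rownames(cm)[idx[, 1L]],
                    gene2 = rownames(cm)[idx[, 2L]],
                    r = cm[idx], stringsAsFactors = FALSE)
  swap <- out$gene1 > out$gene2
  tmp <- out$gene1[swap]; out$gene1[swap] <- out$gene2[swap]
  out$gene2[swap] <- tmp
  out[stable_order(out$gene1, out$gene2), , drop = FALSE]
}

#' Partition gene pairs by shared SCP membership
#'
#' Only pairs where BOTH genes are associated with at least one SCP of the
#' requested level are considered; of those, a pair is `shared` when the
#' two genes have at least one common SCP at that level and `nonshared`
#' otherwise. The two groups are disjoint and exhaust the considered
#' pairs.
#'
#' @param pairs data.frame (`gene1`, `gene2`, `r`) from
#'   [pairwise_pearson()].
#' @param table `scp_associations`.
#' @param tax `scp_taxonomy`.
#' @param level taxonomy level (the published analysis focuses on 3).
#' @return list with data.frames `shared` and `nonshared`.
#' @export
partition_pairs <- function(pairs, table, tax, level = 3) {
  lv <- scp_level(tax, table$scp_id)
  sub <- table[lv == level, , drop = FALSE]
  scps_of <- split(sub$scp_id, sub$gene)
  annotated <- names(scps_of)
  consider <- pairs$gene1 %in% annotated & pairs$gene2 %in% annotated
  pr <- pairs[consider, , drop = FALSE]
  shared <- vapply(seq_len(nrow(pr)), function(i)
    length(intersect(scps_of[[pr$gene1[i]]], scps_of[[pr$gene2[i]]])) > 0,
    logical(1))
  list(shared = pr[shared, , drop = FALSE],
       nonshared = pr[!shared, , drop = FALSE])
}

#' Two-sample Kolmogorov-Smirnov test (two-sided)
#'
#' D is the supremum distance between the two empirical CDFs; the p-value
#' comes from the standard two-sample distribution (exact where
#' [stats::ks.test()] supports it, asymptotic otherwise).
#'
#' @param g1,g2 numeric samples.
#' @return list with `statistic` (D) and `p.value`.
#' @export
ks_two_sample <- function(g1, g2) {
  ht <- suppressWarnings(stats::ks.test(g1, g2, alternative = "two.sided"))
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Co-expression support for SCP membership at one level
#'
#' Computes all pairwise correlations, partitions pairs into shared /
#' nonshared SCP membership and compares the two correlation
#' distributions with the two-sided KS test. Histogram data (both groups
#' normalized to 100%) are returned for plotting.
#'
#' @param expr genes x tissues matrix.
#' @param table `scp_associations`.
#' @param tax `scp_taxonomy`.
#' @param level taxonomy level (default 3).
#' @param breaks histogram breaks over [-1, 1].
#' @return list: `ks` (statistic, p.value), group sizes, and `histogram`
#'   data.frame (`mid`, `shared_pct`, `nonshared_pct`).
#' @export
coexpression_test <- function(expr, table, tax, level = 3,
                              breaks = seq(-1, 1, by = 0.1)) {
  pairs <- pairwise_pearson(expr)
  grp <- partition_pairs(pairs, table, tax, level)
  if (!nrow(grp$shared) || !nrow(grp$nonshared))
    stop("need non-empty shared and nonshared groups", call. = FALSE)
  ks <- ks_two_sample(grp$shared$r, grp$nonshared$r)
  h1 <- graphics::hist(grp$shared$r, breaks = breaks, plot = FALSE)
  h2 <- graphics::hist(grp$nonshared$r, breaks = breaks, plot = FALSE)
  hist_df <- data.frame(mid = h1$mids,
                        shared_pct = 100 * h1$counts / sum(h1$counts),
                        nonshared_pct = 100 * h2$counts / sum(h2$counts))
  list(ks = ks, n_shared = nrow(grp$shared),
       n_nonshared = nrow(grp$nonshared), histogram = hist_df)
}
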