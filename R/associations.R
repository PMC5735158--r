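#' Gene-SCP association tables
#'
#' The populated ontology is a table of gene-SCP associations. Each row
#' carries the literature evidence (`raw_count` abstracts mentioning the
#' gene, `adjusted_count` after validation adjustments, `norm_count` after
#' per-SCP normalization), the two competitive enrichment p-values
#' (`p_same_level`, `p_children_set`), the within-SCP `rank`, the manual
#' validation `label` (T true positive, F false positive, M misinterpreted
#' term, S belongs-to-sibling, or `unlabeled`) and an `origin` flag saying
#' how the row entered the ontology (`enriched`, `inherited`, `propagated`
#' or `reinstated`).
#'
#' @param df data.frame with at least `gene` and `scp_id`; missing evidence
#'   columns are filled with `NA`.
#' @return object of class `scp_associations` (a data.frame).
#' @export
scp_associations <- function(df) {
  if (!all(c("gene", "scp_id") %in% names(df)))
    stop("association table needs columns gene and scp_id", call. = FALSE)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$gene <- as.character(df$gene)
  df$scp_id <- as.character(df$scp_id)
  defaults <- list(raw_count = NA_real_, adjusted_count = NA_real_,
                   norm_count = NA_real_, p_same_level = NA_real_,
                   p_children_set = NA_real_, rank = NA_integer_,
                   label = "unlabeled", origin = "enriched")
  for (nm in names(defaults))
    if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  df$rank <- as.integer(df$rank)
  df$label[is.na(df$label) | df$label == ""] <- "unlabeled"
  bad <- setdiff(unique(df$label), c("T", "F", "M", "S", "unlabeled"))
  if (length(bad))
    stop("malformed label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  key <- paste(df$gene, df$scp_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (gene, scp_id) pair(s): ",
         paste(unique(sub("\r", "/", key[duplicated(key)])), collapse = ", "),
         call. = FALSE)
  for (p in c("p_same_level", "p_children_set")) {
    bad <- !is.na(df[[p]]) & (df[[p]] <= 0 | df[[p]] > 1)
    if (any(bad))
      stop(p, " outside (0, 1]: rows ", paste(which(bad), collapse = ", "),
           call. = FALSE)
  }
  # ranks, where present, must be gapless 1..N within each SCP
  if (any(!is.na(df$rank))) {
    sp <- split(df$rank, df$scp_id)
    for (s in names(sp)) {
      r <- sp[[s]]
      if (all(is.na(r))) next
      if (anyNA(r) || !identical(sort(r), seq_along(r)))
        stop("ranks within SCP ", s, " are not gapless 1..N", call. = FALSE)
    }
  }
  df <- df[c("gene", "scp_id", "raw_count", "adjusted_count", "norm_count",
             "p_same_level", "p_children_set", "rank", "label", "origin")]
  rownames(df) <- NULL
  structure(df, class = c("scp_associations", "data.frame"))
}

#' @export
print.scp_associations <- function(x, ...) {
  cat(sprintf("gene-SCP associations: %d rows, %d genes, %d SCPs\n",
              nrow(x), length(unique(x$gene)), length(unique(x$scp_id))))
  invisible(x)
}

#' @export
summary.scp_associations <- function(object, tax = NULL, ...) {
  if (is.null(tax)) {
    return(data.frame(n_associations = nrow(object),
                      n_genes = length(unique(object$gene)),
                      n_scps = length(unique(object$scp_id))))
  }
  lv <- tax$level[match(object$scp_id, tax$scp_id)]
  per <- tapply(object$gene, object$scp_id, length)
  per_lv <- tax$level[match(names(per), tax$scp_id)]
  out <- do.call(rbind, lapply(sort(unique(lv)), function(l) {
    data.frame(level = l,
               n_scps = sum(per_lv == l),
               n_associations = sum(lv == l),
               mean_genes_per_scp = mean(per[per_lv == l]),
               sd_genes_per_scp = stats::sd(per[per_lv == l]))
  }))
  attr(out, "n_genes") <- length(unique(object$gene))
  attr(out, "n_associations") <- nrow(object)
  out
}

#' Read / write gene-SCP association tables
#'
#' Tab-separated, one row per (gene, SCP) pair; round-trips all fields.
#' Uniqueness and rank-gap invariants are re-checked on load.
#'
#' @param path file path.
#' @return `load_associations`: an `scp_associations` table.
#' @export
load_associations <- function(path) {
  df <- read_tsv_base(path)
  for (nm in c("raw_count", "adjusted_count", "norm_count",
               "p_same_level", "p_children_set"))
    if (!is.null(df[[nm]])) df[[nm]] <- as.numeric(df[[nm]])
  scp_associations(df)
}

#' @rdname load_associations
#' @param table an `scp_associations` table.
#' @param header_lines optional provenance comment lines written with `# `.
#' @export
save_associations <- function(table, path, header_lines = character()) {
  stopifnot(inherits(table, "scp_associations"))
  write_tsv_base(as.data.frame(table), path, header_lines)
}

#' Export one taxonomy level as GMT gene sets
#'
#' Standard GMT: one line per gene set -- set name, TAB, description (here
#' the SCP id), TAB, tab-separated gene symbols. Genes are ordered by their
#' within-SCP rank (then alphabetically where ranks are missing).
#'
#' @param table `scp_associations`.
#' @param tax `scp_taxonomy`.
#' @param level taxonomy level 1-4 to export.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
export_gmt <- function(table, tax, level, path) {
  stopifnot(inherits(table, "scp_associations"), inherits(tax, "scp_taxonomy"))
  if (!level %in% 1:4) stop("level must be in 1..4", call. = FALSE)
  scps <- tax$scp_id[tax$level == level]
  tab <- table[table$scp_id %in% scps, , drop = FALSE]
  if (!nrow(tab))
    stop("no populated SCPs at level ", level, call. = FALSE)
  lines <- vapply(sort(unique(tab$scp_id)), function(s) {
    rows <- tab[tab$scp_id == s, , drop = FALSE]
    o <- stable_order(ifelse(is.na(rows$rank), .Machine$integer.max, rows$rank),
                      rows$gene)
    nm <- tax$name[match(s, tax$scp_id)]
    paste(c(nm, s, rows$gene[o]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' @param path GMT file.
#' @return named list of character vectors (names are set names); each
#'   element carries the description in attribute `"description"`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stop("malformed GMT line (needs name, description, >=1 gene): ", ln,
           call. = FALSE)
    genes <- parts[-(1:2)]
    genes <- genes[nzchar(genes)]
    attr(genes, "description") <- parts[2L]
    out[[parts[1L]]] <- genes
  }
  out
}
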