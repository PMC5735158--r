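#' Literature mention counts per gene and SCP
#'
#' Thin container for the gene x SCP abstract-count table produced by
#' [count_gene_mentions()] (or by [simulate_counts()]): one row per
#' (gene, SCP) pair with a positive `count`, plus the per-SCP total number
#' of abstracts as attribute `"scp_totals"`.
#'
#' @param df data.frame with columns `gene`, `scp_id`, `count`.
#' @param scp_totals named numeric vector, total abstracts per SCP; must
#'   cover every SCP present in `df`.
#' @return object of class `scp_counts`.
#' @export
scp_counts <- function(df, scp_totals = NULL) {
  stopifnot(all(c("gene", "scp_id", "count") %in% names(df)))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$gene <- as.character(df$gene)
  df$scp_id <- as.character(df$scp_id)
  df$count <- as.numeric(df$count)
  if (any(df$count < 0)) stop("counts must be non-negative", call. = FALSE)
  key <- paste(df$gene, df$scp_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (gene, scp_id) count rows", call. = FALSE)
  if (!is.null(scp_totals)) {
    bad <- df$count > scp_totals[df$scp_id] + 1e-9
    bad[is.na(bad)] <- FALSE
    if (any(bad))
      stop("count exceeds SCP abstract total for pair(s): ",
           paste(utils::head(paste(df$gene[bad], df$scp_id[bad]), 5),
                 collapse = ", "), call. = FALSE)
  }
  df <- df[stable_order(df$scp_id, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, scp_totals = scp_totals,
            class = c("scp_counts", "data.frame"))
}

#' @export
print.scp_counts <- function(x, ...) {
  cat(sprintf("mention counts: %d (gene, SCP) pairs, %d genes, %d SCPs\n",
              nrow(x), length(unique(x$gene)), length(unique(x$scp_id))))
  invisible(x)
}

#' Read a term dictionary
#'
#' TSV with columns `term`, `entity_id`, `entity_class`. Terms belong to one
#' of eight biological entity classes (genes and proteins, protein domains,
#' metabolites, diseases, drugs, sub-cellular structures, sub-cellular
#' processes, confounding terms). A term may map to several genes
#' (ambiguous synonyms); non-gene entries for a term suppress its gene
#' reading during matching.
#'
#' @param path TSV file.
#' @return data.frame of dictionary entries.
#' @export
load_dictionary <- function(path) {
  df <- read_tsv_base(path)
  validate_dictionary(df)
}

validate_dictionary <- function(entries) {
  stopifnot(all(c("term", "entity_id", "entity_class") %in% names(entries)))
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  entries$term <- as.character(entries$term)
  entries$entity_id <- as.character(entries$entity_id)
  entries$entity_class <- as.character(entries$entity_class)
  if (any(!nzchar(entries$term)))
    stop("empty dictionary term", call. = FALSE)
  entries
}

GENE_CLASS <- "genes and proteins"

tokenize_text <- function(text) {
  # split on non-alphanumeric characters, keeping internal hyphens
  m <- gregexpr("[A-Za-z0-9]+(?:-[A-Za-z0-9]+)*", text, perl = TRUE)
  regmatches(text, m)[[1L]]
}

term_key <- function(term) {
  paste(tolower(tokenize_text(term)), collapse = " ")
}

#' Compile a dictionary into a token-sequence matcher
#'
#' Matching is exact at token boundaries, case-insensitive, and greedy:
#' at each text position the longest dictionary term wins and consumes its
#' tokens, so longer terms shadow shorter ones. Terms that also belong to a
#' non-gene entity class (e.g. confounding terms, sub-cellular processes)
#' suppress the gene reading of the identical term, which removes false
#' positive gene hits caused by misinterpreted abbreviations.
#'
#' @param entries dictionary data.frame (see [load_dictionary()]).
#' @param stop_terms optional character vector of terms whose gene reading
#'   is always suppressed (e.g. all-lowercase common-word synonyms).
#' @return object of class `scp_matcher`.
#' @export
compile_matcher <- function(entries, stop_terms = NULL) {
  entries <- validate_dictionary(entries)
  if (!nrow(entries)) stop("empty dictionary", call. = FALSE)
  keys <- vapply(entries$term, term_key, character(1), USE.NAMES = FALSE)
  keep <- nzchar(keys)
  entries <- entries[keep, , drop = FALSE]
  keys <- keys[keep]
  lens <- vapply(strsplit(keys, " ", fixed = TRUE), length, integer(1))

  env <- new.env(parent = emptyenv(), size = max(16L, nrow(entries)))
  for (i in seq_len(nrow(entries))) {
    hit <- env[[keys[i]]]
    env[[keys[i]]] <- rbind(hit, data.frame(entity_id = entries$entity_id[i],
                                            entity_class = entries$entity_class[i],
                                            stringsAsFactors = FALSE))
  }
  suppressed <- unique(c(
    keys[entries$entity_class != GENE_CLASS],
    if (!is.null(stop_terms))
      vapply(stop_terms, term_key, character(1), USE.NAMES = FALSE)))
  structure(list(table = env, max_len = max(lens),
                 suppressed = suppressed),
            class = "scp_matcher")
}

#' Match dictionary terms in a text
#'
#' @param matcher an `scp_matcher`.
#' @param text character scalar (e.g. title + abstract concatenation).
#' @return data.frame of hits (`term_key`, `entity_id`, `entity_class`);
#'   gene hits suppressed by non-gene readings are excluded.
#' @export
match_terms <- function(matcher, text) {
  stopifnot(inherits(matcher, "scp_matcher"))
  toks <- tolower(tokenize_text(text))
  n <- length(toks)
  hits <- list()
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    for (len in seq(min(matcher$max_len, n - i + 1L), 1L)) {
      key <- paste(toks[i:(i + len - 1L)], collapse = " ")
      entry <- matcher$table[[key]]
      if (!is.null(entry)) {
        ent <- entry
        if (key %in% matcher$suppressed)
          ent <- ent[ent$entity_class != GENE_CLASS, , drop = FALSE]
        if (nrow(ent))
          hits[[length(hits) + 1L]] <- cbind(term_key = key, ent)
        i <- i + len
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  if (!length(hits))
    return(data.frame(term_key = character(), entity_id = character(),
                      entity_class = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Gene hits of a matcher in a text
#'
#' @inheritParams match_terms
#' @return character vector of distinct gene symbols mentioned in `text`.
#' @export
match_genes <- function(matcher, text) {
  h <- match_terms(matcher, text)
  sort(unique(h$entity_id[h$entity_class == GENE_CLASS]))
}

#' Count per-SCP abstracts mentioning each gene
#'
#' For every SCP-specific abstract set, counts the number of distinct
#' documents whose title + abstract text mentions each gene at least once.
#' Mention multiplicity within a document does not matter: counting is
#' binarized per document.
#'
#' @param abstracts data.frame with columns `doc_id`, `scp_id` and either
#'   `text` or both `title` and `abstract`; (doc_id, scp_id) pairs must be
#'   unique (the same document may appear in several SCP sets).
#' @param matcher an `scp_matcher`.
#' @return an [scp_counts] table; attribute `"scp_totals"` holds the number
#'   of abstracts per SCP.
#' @export
count_gene_mentions <- function(abstracts, matcher) {
  abstracts <- as.data.frame(abstracts, stringsAsFactors = FALSE)
  if (is.null(abstracts$text)) {
    stopifnot(all(c("title", "abstract") %in% names(abstracts)))
    abstracts$text <- paste(abstracts$title, abstracts$abstract)
  }
  stopifnot(all(c("doc_id", "scp_id") %in% names(abstracts)))
  key <- paste(abstracts$doc_id, abstracts$scp_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (doc_id, scp_id) abstract records", call. = FALSE)

  totals <- tapply(abstracts$doc_id, abstracts$scp_id,
                   function(d) length(unique(d)))
  totals <- stats::setNames(as.numeric(totals), names(totals))

  per_doc <- lapply(seq_len(nrow(abstracts)), function(i)
    match_genes(matcher, abstracts$text[i]))
  nhit <- lengths(per_doc)
  if (!any(nhit > 0)) {
    return(scp_counts(data.frame(gene = character(), scp_id = character(),
                                 count = numeric()), totals))
  }
  long <- data.frame(
    gene = unlist(per_doc[nhit > 0]),
    scp_id = rep(abstracts$scp_id[nhit > 0], nhit[nhit > 0]),
    stringsAsFactors = FALSE)
  agg <- stats::aggregate(list(count = rep(1, nrow(long))),
                          by = long[c("gene", "scp_id")], FUN = sum)
  scp_counts(agg, totals)
}

#' Read abstract records
#'
#' `read_abstracts_jsonl()` reads JSON-lines records with fields `doc_id`,
#' `scp_id`, `title`, `abstract`. `read_abstracts_medline()` reads a
#' MEDLINE-format file (PMID/TI/AB tags with continuation lines) belonging
#' to one SCP's abstract set.
#'
#' @param path input file.
#' @return data.frame with columns `doc_id`, `scp_id`, `title`, `abstract`.
#' @export
read_abstracts_jsonl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON)
  data.frame(doc_id = vapply(recs, function(r) as.character(r$doc_id), ""),
             scp_id = vapply(recs, function(r) as.character(r$scp_id), ""),
             title = vapply(recs, function(r) as.character(r$title %||% ""), ""),
             abstract = vapply(recs, function(r) as.character(r$abstract %||% ""), ""),
             stringsAsFactors = FALSE)
}

#' @rdname read_abstracts_jsonl
#' @param scp_id the SCP whose abstract set the MEDLINE file holds.
#' @export
read_abstracts_medline <- function(path, scp_id) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  recs <- list()
  cur <- list(); field <- NULL
  flush <- function(cur) {
    if (is.null(cur$PMID)) return(NULL)
    data.frame(doc_id = cur$PMID, scp_id = scp_id,
               title = cur$TI %||% "", abstract = cur$AB %||% "",
               stringsAsFactors = FALSE)
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) {
      r <- flush(cur); if (!is.null(r)) recs[[length(recs) + 1L]] <- r
      cur <- list(); field <- NULL
      next
    }
    if (grepl("^[A-Z]{1,4}\\s*-", ln)) {
      field <- trimws(sub("-.*$", "", ln))
      val <- trimws(sub("^[A-Z]{1,4}\\s*-\\s*", "", ln))
      cur[[field]] <- paste(c(cur[[field]], val), collapse = " ")
    } else if (!is.null(field) && grepl("^\\s", ln)) {
      cur[[field]] <- paste(cur[[field]], trimws(ln))
    }
  }
  r <- flush(cur); if (!is.null(r)) recs[[length(recs) + 1L]] <- r
  if (!length(recs))
    return(data.frame(doc_id = character(), scp_id = character(),
                      title = character(), abstract = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, recs)
}

#' Write / read mention-count tables
#'
#' TSV with columns `gene`, `scp_id`, `count`; per-SCP abstract totals go to
#' a companion TSV (`scp_id`, `total_abstracts`).
#'
#' @param counts an [scp_counts] table.
#' @param path counts TSV path; totals are written to
#'   `paste0(path, ".totals")` when present.
#' @export
save_counts <- function(counts, path) {
  stopifnot(inherits(counts, "scp_counts"))
  write_tsv_base(as.data.frame(counts), path)
  tot <- attr(counts, "scp_totals")
  if (!is.null(tot))
    write_tsv_base(data.frame(scp_id = names(tot), total_abstracts = tot),
                   paste0(path, ".totals"))
  invisible(path)
}

#' @rdname save_counts
#' @export
load_counts <- function(path) {
  df <- read_tsv_base(path)
  tot <- NULL
  tp <- paste0(path, ".totals")
  if (file.exists(tp)) {
    t <- read_tsv_base(tp)
    tot <- stats::setNames(as.numeric(t$total_abstracts), t$scp_id)
  }
  scp_counts(df, tot)
}
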