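#' Construct and validate an SCP taxonomy
#'
#' A taxonomy is a rooted tree of subcellular processes (SCPs) with five
#' levels: a single level-0 root describing overall cell function, level-1
#' SCPs akin to textbook chapters, down to level-4 SCPs describing the most
#' detailed processes. Every non-root node has exactly one parent whose
#' level is one less than its own.
#'
#' @param df data.frame with columns `scp_id`, `name`, `level`, `parent_id`
#'   and optionally `class_tags` (semicolon-separated labels such as
#'   `"signaling"`, used by edge-exclusion rules). The root's `parent_id`
#'   must be empty or `NA`.
#' @return An object of class `scp_taxonomy`: the validated data.frame plus
#'   precomputed child indices.
#' @examples
#' tax <- scp_taxonomy(data.frame(
#'   scp_id = c("R", "A", "B"), name = c("root", "a", "b"),
#'   level = c(0L, 1L, 1L), parent_id = c(NA, "R", "R")))
#' query_relatives(tax, "R", "children")
#' @seealso [load_taxonomy()], [query_relatives()]
#' @export
scp_taxonomy <- function(df) {
  req <- c("scp_id", "name", "level", "parent_id")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("taxonomy is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$scp_id <- as.character(df$scp_id)
  df$name <- as.character(df$name)
  df$level <- as.integer(df$level)
  df$parent_id <- as.character(df$parent_id)
  df$parent_id[!is.na(df$parent_id) & df$parent_id == ""] <- NA_character_
  if (is.null(df$class_tags)) df$class_tags <- ""
  df$class_tags <- ifelse(is.na(df$class_tags), "", as.character(df$class_tags))

  dup <- df$scp_id[duplicated(df$scp_id)]
  if (length(dup))
    stop("duplicate scp_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (any(is.na(df$level) | df$level < 0L | df$level > 4L))
    stop("levels must be integers in 0..4; offending rows: ",
         paste(df$scp_id[is.na(df$level) | df$level < 0 | df$level > 4],
               collapse = ", "), call. = FALSE)

  roots <- df$scp_id[df$level == 0L & is.na(df$parent_id)]
  if (length(roots) != 1L)
    stop("taxonomy must have exactly one level-0 root without parent; found ",
         length(roots), call. = FALSE)
  bad_root <- df$scp_id[df$level == 0L & !is.na(df$parent_id)]
  if (length(bad_root))
    stop("level-0 node with a parent: ", paste(bad_root, collapse = ", "),
         call. = FALSE)
  orphan <- df$scp_id[df$level > 0L & is.na(df$parent_id)]
  if (length(orphan))
    stop("non-root node without parent: ", paste(orphan, collapse = ", "),
         call. = FALSE)

  idx <- match(df$parent_id, df$scp_id)
  missing_parent <- df$level > 0L & is.na(idx)
  if (any(missing_parent))
    stop("missing parent for node(s): ",
         paste(sprintf("%s (parent %s)", df$scp_id[missing_parent],
                       df$parent_id[missing_parent]), collapse = ", "),
         call. = FALSE)
  nonroot <- df$level > 0L
  mism <- nonroot & df$level != df$level[idx] + 1L
  if (any(mism))
    stop("level mismatch (child level must be parent level + 1): ",
         paste(sprintf("%s (level %d, parent %s level %d)",
                       df$scp_id[mism], df$level[mism],
                       df$parent_id[mism], df$level[idx][mism]),
               collapse = ", "), call. = FALSE)

  rownames(df) <- NULL
  structure(df, class = c("scp_taxonomy", "data.frame"))
}

#' Read an SCP taxonomy from a TSV file
#'
#' The dialect is UTF-8 tab-separated with a header line and columns
#' `scp_id`, `name`, `level`, `parent_id`, `class_tags` (semicolon-separated,
#' may be empty). Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return `scp_taxonomy` object; all structural invariants are checked.
#' @export
load_taxonomy <- function(path) {
  scp_taxonomy(read_tsv_base(path))
}

#' @rdname load_taxonomy
#' @param tax a `scp_taxonomy`.
#' @export
write_taxonomy <- function(tax, path) {
  stopifnot(inherits(tax, "scp_taxonomy"))
  df <- as.data.frame(tax)
  df$parent_id[is.na(df$parent_id)] <- ""
  write_tsv_base(df, path)
}

#' @export
print.scp_taxonomy <- function(x, ...) {
  tab <- table(factor(x$level, levels = 0:4))
  cat(sprintf("SCP taxonomy: %d SCPs (%s)\n", nrow(x),
              paste(sprintf("level %s: %d", names(tab), as.integer(tab)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
summary.scp_taxonomy <- function(object, ...) {
  tab <- table(factor(object$level, levels = 0:4))
  out <- data.frame(level = 0:4, n_scps = as.integer(tab))
  attr(out, "total") <- nrow(object)
  out
}

taxonomy_root <- function(tax) tax$scp_id[tax$level == 0L][1L]

#' Query hierarchical relatives of an SCP
#'
#' @param tax a `scp_taxonomy`.
#' @param scp_id a node identifier present in `tax`.
#' @param relation one of `"parent"`, `"children"`, `"siblings"`
#'   (same children set, excluding the query node), `"grandchildren"` or
#'   `"level_members"` (all other SCPs at the node's level).
#' @return character vector of SCP ids (possibly empty).
#' @export
query_relatives <- function(tax, scp_id,
                            relation = c("parent", "children", "siblings",
                                         "grandchildren", "level_members")) {
  stopifnot(inherits(tax, "scp_taxonomy"))
  relation <- match.arg(relation)
  i <- match(scp_id, tax$scp_id)
  if (is.na(i)) stop("unknown scp_id: ", scp_id, call. = FALSE)
  switch(relation,
    parent = {
      p <- tax$parent_id[i]
      if (is.na(p)) character() else p
    },
    children = sort(tax$scp_id[!is.na(tax$parent_id) & tax$parent_id == scp_id]),
    siblings = {
      p <- tax$parent_id[i]
      if (is.na(p)) return(character())
      sib <- tax$scp_id[!is.na(tax$parent_id) & tax$parent_id == p]
      sort(setdiff(sib, scp_id))
    },
    grandchildren = {
      kids <- tax$scp_id[!is.na(tax$parent_id) & tax$parent_id == scp_id]
      sort(tax$scp_id[!is.na(tax$parent_id) & tax$parent_id %in% kids])
    },
    level_members = {
      lv <- tax$level[i]
      sort(setdiff(tax$scp_id[tax$level == lv], scp_id))
    })
}

#' Ancestors of an SCP up to the root
#'
#' @inheritParams query_relatives
#' @return character vector of ancestor ids ordered parent-first.
#' @export
scp_ancestors <- function(tax, scp_id) {
  stopifnot(inherits(tax, "scp_taxonomy"))
  i <- match(scp_id, tax$scp_id)
  if (is.na(i)) stop("unknown scp_id: ", scp_id, call. = FALSE)
  out <- character()
  p <- tax$parent_id[i]
  while (!is.na(p)) {
    out <- c(out, p)
    p <- tax$parent_id[match(p, tax$scp_id)]
  }
  out
}

# Effective class tags of a node: its own tags when present, otherwise the
# tags of its level-1 ancestor (tags such as "signaling" are typically
# annotated once per level-1 branch and inherited downward).
effective_tags <- function(tax, scp_id) {
  i <- match(scp_id, tax$scp_id)
  if (is.na(i)) stop("unknown scp_id: ", scp_id, call. = FALSE)
  own <- tax$class_tags[i]
  if (nzchar(own)) return(strsplit(own, ";", fixed = TRUE)[[1L]])
  anc <- c(scp_id, scp_ancestors(tax, scp_id))
  lv1 <- anc[tax$level[match(anc, tax$scp_id)] == 1L]
  if (!length(lv1)) return(character())
  tg <- tax$class_tags[match(lv1[1L], tax$scp_id)]
  if (nzchar(tg)) strsplit(tg, ";", fixed = TRUE)[[1L]] else character()
}

#' Does an SCP carry a class tag (directly or inherited)?
#'
#' @inheritParams query_relatives
#' @param tag a single tag, e.g. `"signaling"`.
#' @return logical scalar.
#' @export
has_class_tag <- function(tax, scp_id, tag) {
  tag %in% effective_tags(tax, scp_id)
}
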