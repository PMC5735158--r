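# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so generators stay pure functions of (spec, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single non-missing number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

read_tsv_base <- function(path, ...) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

write_tsv_base <- function(df, path, header_lines = character()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header_lines))
    writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable order helper: always breaks ties on the extra keys so outputs are
# reproducible across platforms and input orderings.
stable_order <- function(...) do.call(order, list(..., method = "radix"))
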