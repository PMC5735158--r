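# Independent brute-force oracles used to freeze expected values.

# Upper-tail hypergeometric probability by full enumeration over all 2x2
# tables with the observed margins, using only choose().
enum_upper_tail <- function(a, b, c, d) {
  m <- a + c   # items of the first kind (gene-mentioning articles)
  n <- b + d   # items of the second kind
  k <- a + b   # draws (articles in the SCP set)
  xs <- max(0, k - n):min(k, m)
  probs <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  sum(probs[xs >= a])
}

# Exhaustive largest-gap cut: evaluates the gap at every cut position of
# the descending-sorted value list and keeps everything above the first
# maximal gap; no cut when all gaps are zero.
gap_cut_oracle <- function(values) {
  o <- order(-values, names(values), method = "radix")
  s <- values[o]
  n <- length(s)
  if (n == 1L) return(names(s))
  best_gap <- -Inf; best_cut <- 0L
  for (cut in 1:(n - 1L)) {
    gap <- s[cut] - s[cut + 1L]
    if (gap > best_gap) { best_gap <- gap; best_cut <- cut }
  }
  if (best_gap <= 0) return(names(s))
  names(s)[seq_len(best_cut)]
}

# Naive greedy longest-match scan for the dictionary matcher: tokenizes by
# the same rule, then at each position tries every dictionary term by
# direct token comparison, longest first.
matcher_oracle <- function(entries, text, gene_class = "genes and proteins") {
  toks <- tolower(regmatches(text,
    gregexpr("[A-Za-z0-9]+(?:-[A-Za-z0-9]+)*", text, perl = TRUE))[[1L]])
  term_toks <- lapply(entries$term, function(t)
    tolower(regmatches(t,
      gregexpr("[A-Za-z0-9]+(?:-[A-Za-z0-9]+)*", t, perl = TRUE))[[1L]]))
  keys <- vapply(term_toks, paste, "", collapse = " ")
  suppressed <- unique(keys[entries$entity_class != gene_class])
  genes <- character()
  i <- 1L
  while (i <= length(toks)) {
    lens <- sort(unique(lengths(term_toks)), decreasing = TRUE)
    hit_len <- 0L
    for (L in lens) {
      if (i + L - 1L > length(toks)) next
      window <- paste(toks[i:(i + L - 1L)], collapse = " ")
      idx <- which(keys == window)
      if (length(idx)) {
        if (!(window %in% suppressed))
          genes <- c(genes, entries$entity_id[idx][
            entries$entity_class[idx] == gene_class])
        hit_len <- L
        break
      }
    }
    i <- i + max(hit_len, 1L)
  }
  sort(unique(genes))
}

# Two-sample KS statistic by direct ECDF sweep over the pooled support.
ks_D_oracle <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# All 2x2 tables with grand total at most `max_total`.
all_tables_upto <- function(max_total) {
  g <- expand.grid(a = 0:max_total, b = 0:max_total, c = 0:max_total)
  g <- g[g$a + g$b + g$c <= max_total, ]
  do.call(rbind, lapply(0:max_total, function(n) {
    s <- g[g$a + g$b + g$c <= n, ]
    data.frame(a = s$a, b = s$b, c = s$c, d = n - s$a - s$b - s$c)
  }))
}
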