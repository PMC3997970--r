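# Independent oracles: character-by-character reference implementations,
# deliberately naive (no shared code with the package internals).

# base-wise complement without chartr
oracle_complement <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(strsplit(x, ""), function(cs) paste(map[cs], collapse = ""),
         character(1))
}

oracle_revcomp <- function(x) {
  vapply(strsplit(x, ""), function(cs) {
    map <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(map[cs]), collapse = "")
  }, character(1))
}

# 0-based starts where `query` matches `seq_chars` exactly; query char "N"
# matches any of ACGT; any non-ACGT genome char never matches
oracle_starts <- function(seq_chars, query) {
  q <- strsplit(query, "")[[1]]
  k <- length(q)
  n <- length(seq_chars)
  if (k == 0 || k > n) {
    return(integer())
  }
  out <- integer()
  for (s in 0:(n - k)) {
    w <- seq_chars[(s + 1):(s + k)]
    ok <- all(w %in% c("A", "C", "G", "T")) &
      all(q == "N" | q == w)
    if (ok) out <- c(out, s)
  }
  out
}

oracle_drop_overlaps <- function(starts, width) {
  keep <- integer()
  last_end <- -1
  for (s in starts) {
    if (s >= last_end) {
      keep <- c(keep, s)
      last_end <- s + width
    }
  }
  keep
}

# full reference scan with the package's coordinate and strand conventions
oracle_scan <- function(genome, query, strand = "forward",
                        overlapping = TRUE) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  queries <- c("+" = query)
  if (strand == "both") {
    queries <- c(queries, "-" = oracle_revcomp(query))
  }
  rows <- list()
  for (rec in names(genome)) {
    cs <- strsplit(genome[[rec]], "")[[1]]
    for (st in names(queries)) {
      starts <- oracle_starts(cs, queries[[st]])
      if (!overlapping) {
        starts <- oracle_drop_overlaps(starts, nchar(query))
      }
      if (length(starts)) {
        rows[[length(rows) + 1]] <- data.frame(
          record = rec, start = starts, end = starts + nchar(query),
          strand = st, stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(record = character(), start = integer(), end = integer(),
               strand = character(), stringsAsFactors = FALSE)
  }
  out[order(out$record, out$start, out$strand), , drop = FALSE]
}

random_genome_chr <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# selection-sort ranking oracle: repeatedly pick the largest remaining count,
# earliest row first on ties
oracle_rank_order <- function(counts) {
  remaining <- seq_along(counts)
  order_out <- integer()
  while (length(remaining)) {
    best <- remaining[which.max(counts[remaining])]
    order_out <- c(order_out, best)
    remaining <- setdiff(remaining, best)
  }
  order_out
}
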