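# Independent oracles used to cross-check the implementation.

PSI <- "Ψ"
AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# pattern -> PCRE with lookahead for overlapping matches
pattern_regex <- function(pat) {
  paste0(vapply(pat$elements, function(el) {
    if (length(el$allowed) == 1L) el$allowed
    else sprintf("[%s]", paste(el$allowed, collapse = ""))
  }, character(1L)), collapse = "")
}

oracle_scan <- function(seq, pat) {
  rx <- sprintf("(?=%s)", pattern_regex(pat))
  m <- gregexpr(rx, seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(integer())
  as.integer(m)
}

# set-union composition oracle: covered positions from qualifying windows,
# contiguous blocks, boundary adjustment, core/min_run filters
oracle_composition <- function(seq, classes, window, min_fraction,
                               core = NULL, min_run = 0L) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  if (window > n) return(list())
  member <- ch %in% classes
  covered <- rep(FALSE, n)
  for (i in seq_len(n - window + 1L)) {
    if (mean(member[i:(i + window - 1L)]) >= min_fraction) {
      covered[i:(i + window - 1L)] <- TRUE
    }
  }
  if (!any(covered)) return(list())
  blocks <- split(which(covered), cumsum(c(1L, diff(which(covered)) != 1L)))
  out <- list()
  for (b in blocks) {
    s <- min(b); e <- max(b)
    while (s <= e && !member[s]) s <- s + 1L
    while (e >= s && !member[e]) e <- e - 1L
    if (s > e) next
    while (s > 1L && member[s - 1L]) s <- s - 1L
    while (e < n && member[e + 1L]) e <- e + 1L
    if (min_run > 0L && (e - s + 1L) < min_run) next
    if (!is.null(core)) {
      pos <- oracle_scan(seq, core)
      plen <- length(core$elements)
      if (!length(pos) || !any(pos >= s & (pos + plen - 1L) <= e)) next
    }
    out[[length(out) + 1L]] <- list(start = s, end = e,
                                    score = mean(member[s:e]))
  }
  out
}

# brute-force parsimony minimum by enumerating internal-node labelings;
# unknown tips contribute no cost (they can always copy their parent)
oracle_parsimony <- function(tree, tip_states) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  st <- tip_states[tree$tip.label]
  edge <- tree$edge
  best <- Inf
  for (code in 0:(2^nint - 1L)) {
    internal <- as.integer(intToBits(code))[seq_len(nint)]
    lab <- c(rep(NA_integer_, ntip), internal)
    lab[seq_len(ntip)] <- ifelse(is.na(st), NA_integer_, as.integer(st))
    cost <- 0L
    for (k in seq_len(nrow(edge))) {
      a <- lab[edge[k, 1L]]; b <- lab[edge[k, 2L]]
      if (!is.na(b) && a != b) cost <- cost + 1L
    }
    if (cost < best) best <- cost
  }
  best
}

random_pattern_source <- function(max_len = 6L) {
  n <- sample(2:max_len, 1L)
  parts <- vapply(seq_len(n), function(i) {
    kind <- sample(c("fixed", "wild", "psi", "alt"), 1L,
                   prob = c(0.5, 0.2, 0.1, 0.2))
    switch(kind,
      fixed = sample(AA, 1L),
      wild = "x",
      psi = PSI,
      alt = { p <- sample(AA, 2L); sprintf("(%s/%s)", p[1L], p[2L]) })
  }, character(1L))
  paste(parts, collapse = "")
}

random_seq <- function(len, alphabet = AA) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# minimal hand-built region for classifier rule tests
fake_region <- function(hint, hits, raw = NULL) {
  if (is.null(raw)) {
    raw <- hits
    raw$passed_window <- rep(TRUE, nrow(hits))
  }
  structure(list(sequence_id = "fake", isoform_hint = hint, seq = "",
                 hits = hits, raw_hits = raw, flags = character()),
            class = "ecr_region")
}

fake_hits <- function(ids, starts = NULL, variants = NULL) {
  n <- length(ids)
  if (!n) {
    return(data.frame(motif_id = character(), start = integer(),
                      end = integer(), match = character(),
                      score = numeric(), variant = character(),
                      stringsAsFactors = FALSE))
  }
  if (is.null(starts)) starts <- seq(1L, by = 20L, length.out = n)
  if (is.null(variants)) variants <- rep("canonical", n)
  data.frame(motif_id = ids, start = as.integer(starts),
             end = as.integer(starts) + 3L,
             match = "XXXX", score = 1.0, variant = variants,
             stringsAsFactors = FALSE)
}
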