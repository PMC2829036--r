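# Degenerate consensus-pattern grammar.
#
# The printed motif notation uses four element kinds:
#   * a fixed residue, e.g. K
#   * the wildcard x (any canonical residue, never a gap)
#   * the class symbol Ψ (large hydrophobic residue)
#   * a two-residue alternation written (X/Y)
# A compiled pattern is a list of elements, each a list(kind, allowed),
# where `allowed` is the set of residues the element accepts.

#' Compile a printed degenerate consensus string
#'
#' Parses motif notation such as `"ΨKxE"`, `"K(K/R)x(K/R)"` or
#' `"(D/E)(D/E)W"` into a compiled pattern usable with [scan_pattern()].
#' `x` is a wildcard matching any canonical residue; `Ψ` matches the
#' large-hydrophobic class (see [residue_classes()]); `(X/Y)` matches
#' either residue of the alternation.
#'
#' @param source printed consensus string.
#' @param classes named list of residue classes; `classes$PSI` defines the
#'   membership of `Ψ`.
#' @return An object of class `ecr_pattern`: a list with elements
#'   `elements` (compiled element list), `source` (the input string) and
#'   `canonical` (canonical re-rendering; alternations sorted
#'   alphabetically).
#' @examples
#' p <- compile_pattern("K(K/R)x(K/R)")
#' length(p$elements)
#' @export
compile_pattern <- function(source, classes = residue_classes()) {
  if (length(source) != 1L || !is.character(source) || is.na(source) ||
      !nzchar(source)) {
    stop_input("pattern source must be a non-empty string")
  }
  chars <- strsplit(source, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  elements <- list()
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      # alternation (X/Y)
      if (i + 4L > n || chars[i + 2L] != "/" || chars[i + 4L] != ")") {
        stop_input(sprintf(
          "malformed alternation starting at position %d of '%s'", i, source))
      }
      a <- toupper(chars[i + 1L]); b <- toupper(chars[i + 3L])
      for (r in c(a, b)) {
        if (!(r %in% AA_ALPHABET)) {
          stop_input(sprintf(
            "non-amino-acid symbol '%s' in alternation at position %d of '%s'",
            r, i, source))
        }
      }
      if (a == b) {
        stop_input(sprintf(
          "degenerate alternation (%s/%s) at position %d of '%s'",
          a, b, i, source))
      }
      elements[[length(elements) + 1L]] <-
        list(kind = "alt", allowed = c(a, b))
      i <- i + 5L
    } else if (ch == "x") {
      elements[[length(elements) + 1L]] <-
        list(kind = "wild", allowed = AA_ALPHABET)
      i <- i + 1L
    } else if (ch == PSI_CHAR) {
      elements[[length(elements) + 1L]] <-
        list(kind = "class", allowed = classes$PSI, class = "PSI")
      i <- i + 1L
    } else if (toupper(ch) %in% AA_ALPHABET) {
      elements[[length(elements) + 1L]] <-
        list(kind = "fixed", allowed = toupper(ch))
      i <- i + 1L
    } else {
      stop_input(sprintf(
        "unknown symbol '%s' at position %d of '%s'", ch, i, source))
    }
  }
  if (length(elements) < 2L) {
    stop_input(sprintf("pattern '%s' has fewer than 2 elements", source))
  }
  structure(list(elements = elements, source = source,
                 canonical = render_elements(elements)),
            class = "ecr_pattern")
}

# canonical rendering: alternations alphabetical, Ψ kept as Ψ, wildcard x
render_elements <- function(elements) {
  paste(vapply(elements, function(el) {
    switch(el$kind,
      fixed = el$allowed,
      wild  = "x",
      class = PSI_CHAR,
      alt   = sprintf("(%s/%s)", sort(el$allowed)[1L], sort(el$allowed)[2L]))
  }, character(1L)), collapse = "")
}

#' Render a compiled pattern in canonical form
#' @param pat an `ecr_pattern`.
#' @return Canonical consensus string (alternations sorted alphabetically).
#' @export
render_pattern <- function(pat) {
  stopifnot(inherits(pat, "ecr_pattern"))
  pat$canonical
}

#' @export
print.ecr_pattern <- function(x, ...) {
  cat("<ecr_pattern> ", x$source, " (canonical: ", x$canonical, ", ",
      length(x$elements), " elements)\n", sep = "")
  invisible(x)
}

pattern_length <- function(pat) length(pat$elements)

#' Scan a sequence with a compiled degenerate pattern
#'
#' Returns all (possibly overlapping) matches, sorted by start.
#' Coordinates are 1-based inclusive.
#'
#' @param seq amino-acid string (no gaps).
#' @param pat an `ecr_pattern` from [compile_pattern()].
#' @return data.frame with columns `start`, `end`, `match`.
#' @examples
#' scan_pattern("GLKSEG", compile_pattern("ΨKxE"))
#' @export
scan_pattern <- function(seq, pat) {
  stopifnot(inherits(pat, "ecr_pattern"))
  chars <- check_sequence(seq)
  m <- pattern_length(pat)
  n <- length(chars)
  if (n < m) return(empty_hits())
  ok <- rep(TRUE, n - m + 1L)
  for (j in seq_len(m)) {
    ok <- ok & (chars[seq.int(j, n - m + j)] %in% pat$elements[[j]]$allowed)
  }
  starts <- which(ok)
  if (!length(starts)) return(empty_hits())
  data.frame(start = starts, end = starts + m - 1L,
             match = vapply(starts, function(s)
               paste(chars[s:(s + m - 1L)], collapse = ""), character(1L)),
             stringsAsFactors = FALSE)
}

empty_hits <- function() {
  data.frame(start = integer(), end = integer(), match = character(),
             stringsAsFactors = FALSE)
}

# Scan for >= min_repeats consecutive (abutting) matches of a short unit
# pattern; used for the D(T/S)S repeat signature. Each maximal chain is one
# hit spanning all chained units.
scan_repeats <- function(seq, pat, min_repeats = 2L) {
  unit <- pattern_length(pat)
  hits <- scan_pattern(seq, pat)
  if (!nrow(hits)) return(empty_hits())
  starts <- hits$start
  out <- empty_hits()
  i <- 1L
  chars <- check_sequence(seq)
  while (i <= length(starts)) {
    j <- i
    while (j + 1L <= length(starts) && starts[j + 1L] == starts[j] + unit) {
      j <- j + 1L
    }
    nrep <- j - i + 1L
    if (nrep >= min_repeats) {
      s <- starts[i]; e <- starts[j] + unit - 1L
      out <- rbind(out, data.frame(
        start = s, end = e,
        match = paste(chars[s:e], collapse = ""),
        stringsAsFactors = FALSE))
    }
    i <- j + 1L
  }
  out
}

#' Realize one instance of a degenerate pattern
#'
#' Deterministic rule used by the synthetic generator: alternations take
#' their first printed alternative, `Ψ` becomes L, and wildcards are drawn
#' uniformly from `wildcard_alphabet`.
#'
#' @param pat an `ecr_pattern`.
#' @param wildcard_alphabet residues the wildcard may take.
#' @return Single realized amino-acid string.
#' @export
realize_pattern <- function(pat, wildcard_alphabet = c("G", "N", "Q")) {
  stopifnot(inherits(pat, "ecr_pattern"))
  paste(vapply(pat$elements, function(el) {
    switch(el$kind,
      fixed = el$allowed,
      alt   = el$allowed[1L],     # first printed alternative
      class = "L",
      wild  = sample(wildcard_alphabet, 1L))
  }, character(1L)), collapse = "")
}

#' Sample aligned instances of a degenerate pattern
#'
#' Generates `n` equal-length realizations for consensus-recovery tests.
#' In `"balanced"` mode (default) alternation and class columns cycle
#' round-robin through their members and wildcards cycle through
#' `wildcard_alphabet`, so column frequencies are as even as `n` allows;
#' `"random"` mode draws uniformly.
#'
#' @param pat an `ecr_pattern`.
#' @param n number of instances (>= 1).
#' @param mode `"balanced"` or `"random"`.
#' @param wildcard_alphabet residues a wildcard column may take.
#' @return Character vector of `n` strings, all of pattern length.
#' @export
sample_pattern_instances <- function(pat, n,
                                     mode = c("balanced", "random"),
                                     wildcard_alphabet = c("G", "N", "Q")) {
  stopifnot(inherits(pat, "ecr_pattern"), n >= 1L)
  mode <- match.arg(mode)
  cols <- lapply(pat$elements, function(el) {
    choices <- if (el$kind == "wild") wildcard_alphabet else el$allowed
    if (length(choices) == 1L) {
      rep(choices, n)
    } else if (mode == "balanced") {
      choices[((seq_len(n) - 1L) %% length(choices)) + 1L]
    } else {
      sample(choices, n, replace = TRUE)
    }
  })
  mat <- do.call(cbind, cols)
  apply(mat, 1L, paste, collapse = "")
}
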