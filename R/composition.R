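# Compositional-window scanner for low-complexity / biased motifs
# (S-rich, DL-rich). A region qualifies when every length-`window`
# subwindow inside it keeps the class fraction at or above `min_fraction`.

#' Scan for compositionally biased regions
#'
#' Finds maximal runs in which every length-`window` subwindow has a
#' fraction of `classes` members of at least `min_fraction`. Qualifying
#' window spans are merged, and each merged run is adjusted to class-member
#' boundaries (trimmed inward past non-members, then extended outward over
#' contiguous members). If `core` is given (hybrid mode, e.g. the S-rich
#' motif's EV(T/S)SS core), runs lacking a core match are discarded. Each
#' hit's score is its overall class fraction over the reported span.
#'
#' @param seq amino-acid string (no gaps).
#' @param classes character vector of residues counting as class members
#'   (e.g. `class_members("ACIDIC", "BULKY")` for the DL-rich motif).
#' @param window subwindow length (>= 3).
#' @param min_fraction minimum member fraction per subwindow, in (0, 1].
#' @param core optional `ecr_pattern`; hits must contain a core match.
#' @param min_run minimum reported run length (0 disables).
#' @return data.frame with columns `start`, `end`, `match`, `score`
#'   (class fraction over the span). Sequences shorter than `window`
#'   return zero hits.
#' @examples
#' cls <- class_members("ACIDIC", "BULKY")
#' scan_composition("DIGEVDLDFWDLDL", cls, window = 10, min_fraction = 0.8)
#' @export
scan_composition <- function(seq, classes, window, min_fraction,
                             core = NULL, min_run = 0L) {
  if (!(min_fraction > 0 && min_fraction <= 1)) {
    stop_config("min_fraction must be in (0, 1]")
  }
  if (window < 3L) stop_config("window must be >= 3")
  chars <- check_sequence(seq)
  n <- length(chars)
  if (window > n) return(empty_comp_hits())
  member <- chars %in% classes
  # fraction per window start, via cumulative sum
  cs <- c(0L, cumsum(member))
  starts <- seq_len(n - window + 1L)
  frac <- (cs[starts + window] - cs[starts]) / window
  ok <- frac >= min_fraction
  if (!any(ok)) return(empty_comp_hits())
  # blocks of consecutive qualifying window starts -> intervals
  runs <- rle(ok)
  ends_idx <- cumsum(runs$lengths)
  begs_idx <- ends_idx - runs$lengths + 1L
  iv <- cbind(start = begs_idx[runs$values],
              end   = ends_idx[runs$values] + window - 1L)
  # merge overlapping/adjacent intervals
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  merged <- list()
  cur <- iv[1L, ]
  if (nrow(iv) > 1L) for (k in 2L:nrow(iv)) {
    if (iv[k, 1L] <= cur[2L] + 1L) {
      cur[2L] <- max(cur[2L], iv[k, 2L])
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- iv[k, ]
    }
  }
  merged[[length(merged) + 1L]] <- cur
  out <- empty_comp_hits()
  for (run in merged) {
    s <- run[[1L]]; e <- run[[2L]]
    # trim inward to class members
    while (s <= e && !member[s]) s <- s + 1L
    while (e >= s && !member[e]) e <- e - 1L
    if (s > e) next
    # extend outward over contiguous members
    while (s > 1L && member[s - 1L]) s <- s - 1L
    while (e < n && member[e + 1L]) e <- e + 1L
    if (min_run > 0L && (e - s + 1L) < min_run) next
    if (!is.null(core)) {
      ch <- scan_pattern(seq, core)
      if (!nrow(ch) || !any(ch$start >= s & ch$end <= e)) next
    }
    out <- rbind(out, data.frame(
      start = as.integer(s), end = as.integer(e),
      match = paste(chars[s:e], collapse = ""),
      score = mean(member[s:e]),
      stringsAsFactors = FALSE))
  }
  out
}

empty_comp_hits <- function() {
  data.frame(start = integer(), end = integer(), match = character(),
             score = numeric(), stringsAsFactors = FALSE)
}

#' Union of named residue classes
#'
#' @param ... names of classes from [residue_classes()].
#' @param classes the class list to draw from.
#' @return Sorted character vector of member residues.
#' @examples
#' class_members("ACIDIC", "NEUTRAL_POLAR")
#' @export
class_members <- function(..., classes = residue_classes()) {
  class_union(c(...), classes = classes)
}
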