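# Consensus strings and information-content profiles from alignments of
# motif instances (re-implementation of the logo/consensus computation the
# original analysis obtained from an alignment viewer).

#' Per-position information content of a residue frequency vector
#'
#' Computed as `log2(20) - H`, where `H` is the Shannon entropy of the
#' column in bits. No small-sample correction is applied.
#'
#' @param freqs numeric vector of residue frequencies summing to 1.
#' @return Information content in bits, in `[0, log2(20)]`.
#' @examples
#' information_content(c(W = 1))           # ~4.322 bits
#' information_content(c(D = 0.5, E = 0.5))
#' @export
information_content <- function(freqs) {
  if (any(freqs < 0)) stop_input("negative frequency")
  s <- sum(freqs)
  if (abs(s - 1) > 1e-6) stop_input("frequencies must sum to 1")
  p <- freqs[freqs > 0]
  h <- -sum(p * log2(p))
  log2(20) - h
}

#' Build a consensus profile from an alignment of motif instances
#'
#' Per aligned column: the frequency vector over the residues present
#' (gaps tracked separately), and a consensus symbol -- a fixed residue
#' when its frequency reaches `single_threshold`; otherwise an
#' alternation `(X/Y)` when the two most frequent residues jointly reach
#' `class_threshold` (if `require_class = TRUE`, X and Y must also share a
#' catalog class); otherwise `x`. Columns with gap fraction above 0.5 are
#' dropped from the consensus string. Alternations are written
#' alphabetically (the canonical form; the printed notation uses both
#' orders, e.g. (D/E) and (E/D), for the same element).
#'
#' @param alignment character vector of equal-length amino-acid strings;
#'   `-` gaps permitted.
#' @param single_threshold minimum frequency to emit a fixed residue.
#' @param class_threshold minimum joint frequency of the top two residues
#'   to emit an alternation.
#' @param require_class if TRUE, an alternation is only emitted when both
#'   residues belong to one catalog class.
#' @param classes residue class list used when `require_class = TRUE`.
#' @return Object of class `ecr_profile`: list with `freqs` (20 x L
#'   matrix of per-column residue frequencies over non-gap residues),
#'   `gap_fraction` (length-L), `info_bits` (length-L), `consensus`
#'   (string) and `n` (number of rows).
#' @examples
#' build_consensus(c("NGYSSP", "NGYSSP", "NGYSSP"))$consensus
#' @export
build_consensus <- function(alignment, single_threshold = 0.6,
                            class_threshold = 0.8, require_class = FALSE,
                            classes = residue_classes()) {
  if (length(alignment) < 2L) stop_input("alignment needs >= 2 rows")
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L) {
    stop_input("alignment rows have unequal lengths")
  }
  L <- lens[1L]
  rows <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
  bad <- !(rows %in% c(AA_ALPHABET, "-"))
  if (any(bad)) {
    stop_input(sprintf("illegal symbol '%s' in alignment",
                       rows[which(bad)[1L]]))
  }
  freqs <- matrix(0, nrow = length(AA_ALPHABET), ncol = L,
                  dimnames = list(AA_ALPHABET, NULL))
  gap_fraction <- numeric(L)
  info_bits <- numeric(L)
  symbols <- character(L)
  for (j in seq_len(L)) {
    col <- rows[, j]
    gap_fraction[j] <- mean(col == "-")
    res <- col[col != "-"]
    if (!length(res)) {
      info_bits[j] <- NA_real_
      symbols[j] <- NA_character_
      next
    }
    f <- table(factor(res, levels = AA_ALPHABET)) / length(res)
    freqs[, j] <- as.numeric(f)
    info_bits[j] <- information_content(as.numeric(f))
    symbols[j] <- consensus_symbol(f, single_threshold, class_threshold,
                                   require_class, classes)
  }
  consensus <- paste(symbols[gap_fraction <= 0.5 & !is.na(symbols)],
                     collapse = "")
  structure(list(freqs = freqs, gap_fraction = gap_fraction,
                 info_bits = info_bits, consensus = consensus,
                 n = length(alignment)),
            class = "ecr_profile")
}

consensus_symbol <- function(f, single_threshold, class_threshold,
                             require_class, classes) {
  ord <- order(-as.numeric(f), names(f))   # frequency desc, alpha tiebreak
  top1 <- names(f)[ord[1L]]
  if (f[[ord[1L]]] >= single_threshold) return(top1)
  top2 <- names(f)[ord[2L]]
  joint <- f[[ord[1L]]] + f[[ord[2L]]]
  if (f[[ord[2L]]] > 0 && joint >= class_threshold) {
    share <- any(vapply(classes, function(cl) all(c(top1, top2) %in% cl),
                        logical(1L)))
    if (!require_class || share) {
      pair <- sort(c(top1, top2))
      return(sprintf("(%s/%s)", pair[1L], pair[2L]))
    }
  }
  "x"
}

#' @export
print.ecr_profile <- function(x, ...) {
  cat(sprintf("<ecr_profile> %d columns from %d rows\nconsensus: %s\n",
              ncol(x$freqs), x$n, x$consensus))
  invisible(x)
}

#' Plot an information-content profile (text logo)
#'
#' Draws stacked residue letters scaled by their share of the column's
#' information content -- the standard sequence-logo representation.
#'
#' @param x an `ecr_profile`.
#' @param ... passed to [graphics::plot.default()].
#' @return Invisibly, `x`.
#' @export
plot.ecr_profile <- function(x, ...) {
  L <- ncol(x$freqs)
  graphics::plot(NULL, xlim = c(0.5, L + 0.5), ylim = c(0, log2(20)),
                 xlab = "position", ylab = "bits", xaxs = "i", ...)
  cols <- c(ACIDIC = "red3", BASIC = "blue3", NEUTRAL_POLAR = "darkgreen")
  classes <- residue_classes()
  for (j in seq_len(L)) {
    f <- x$freqs[, j]
    keep <- f > 0
    if (!any(keep) || is.na(x$info_bits[j])) next
    heights <- f[keep] * x$info_bits[j]
    ord <- order(heights)
    y0 <- 0
    for (k in ord) {
      r <- names(heights)[k]
      col <- if (r %in% classes$ACIDIC) cols[["ACIDIC"]]
             else if (r %in% classes$BASIC) cols[["BASIC"]]
             else if (r %in% classes$NEUTRAL_POLAR) cols[["NEUTRAL_POLAR"]]
             else "grey30"
      graphics::text(j, y0 + heights[k] / 2, r, col = col,
                     cex = 0.4 + 2.2 * heights[k] / log2(20))
      y0 <- y0 + heights[k]
    }
  }
  invisible(x)
}

#' Compare a compositional motif against acidic-activator style patterns
#'
#' Utility for DL-rich / acidic-activation-domain comparisons: reports,
#' for two sequences, the positions of acidic and bulky-hydrophobic
#' residues and a simple class-identity fraction over the shorter length
#' (the fraction of aligned positions whose residues fall in the same
#' class: acidic, bulky hydrophobic, or other).
#'
#' @param a,b amino-acid strings (e.g. a DL-rich consensus instance and an
#'   acidic activation domain).
#' @param classes residue class list.
#' @return List with `class_string_a`, `class_string_b` (`A` = acidic,
#'   `H` = bulky hydrophobic, `.` = other) and `class_identity`.
#' @export
compare_acidic_activator <- function(a, b, classes = residue_classes()) {
  to_cls <- function(s) {
    ch <- check_sequence(s)
    out <- rep(".", length(ch))
    out[ch %in% classes$ACIDIC] <- "A"
    out[ch %in% classes$BULKY] <- "H"
    out
  }
  ca <- to_cls(a); cb <- to_cls(b)
  n <- min(length(ca), length(cb))
  list(class_string_a = paste(ca, collapse = ""),
       class_string_b = paste(cb, collapse = ""),
       class_identity = mean(ca[seq_len(n)] == cb[seq_len(n)]))
}
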