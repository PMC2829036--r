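# Whole-catalog annotation of one isoform-specific-region sequence.

#' Annotate an isoform-specific region with the microdomain catalog
#'
#' Scans the sequence with every catalog motif and assembles an ordered,
#' architecture-checked annotation. Position-restricted motifs are only
#' reported inside their terminal window (N-terminal 25 residues by
#' default; 10 for KRRW / TxxΨW / YRLN; the A-box inside the last 40).
#' KRRW is additionally accepted when it starts within
#' `krrw_adjacency_gap` residues after a reported LQTVPRVPVAGV /
#' LAVPRVPVAGV signature, since the type-4/5 B1 architectures place that
#' signature (and, in type 5, an N-terminal extension) before KRRW. SP is
#' reported only when an SP dipeptide lies strictly between the retained
#' S-rich end and DL-rich start. At most one hit per motif class is
#' retained (best score, then leftmost); the unfiltered hit list is kept
#' in `raw_hits`.
#'
#' @param seq amino-acid string, length >= 10 after gap stripping.
#'   Lowercase is uppercased; non-canonical residues are rejected.
#' @param isoform_hint `"A"`, `"B1"` or `"unknown"`; governs the expected
#'   motif set and ordering used for architecture flags only -- every
#'   motif is scanned regardless.
#' @param sequence_id identifier carried into reports.
#' @param catalog an `ecr_catalog`.
#' @param config an [ecr_config()] list.
#' @return Object of class `ecr_region` with fields `sequence_id`,
#'   `isoform_hint`, `seq`, `hits` (one row per retained motif:
#'   `motif_id`, `start`, `end`, `match`, `score`, `variant`), `raw_hits`
#'   and `flags` (see [check_architecture()]).
#' @export
detect_microdomains <- function(seq, isoform_hint = c("unknown", "A", "B1"),
                                sequence_id = "seq1",
                                catalog = default_catalog(),
                                config = ecr_config()) {
  isoform_hint <- match.arg(isoform_hint)
  if (length(seq) != 1L || !is.character(seq) || is.na(seq) || !nzchar(seq)) {
    stop_input("empty sequence")
  }
  seq <- gsub("-", "", toupper(seq), fixed = TRUE)
  if (!nzchar(seq)) stop_input("all-gap sequence")
  chars <- check_sequence(seq)
  n <- length(chars)
  if (n < 10L) stop_input(sprintf("sequence '%s' shorter than 10 residues",
                                  sequence_id))

  raw <- data.frame(motif_id = character(), start = integer(),
                    end = integer(), match = character(), score = numeric(),
                    variant = character(), stringsAsFactors = FALSE)
  add <- function(raw, id, hits, variant, score = NULL) {
    if (!nrow(hits)) return(raw)
    rbind(raw, data.frame(
      motif_id = id, start = hits$start, end = hits$end, match = hits$match,
      score = if (is.null(score)) hits$score else score,
      variant = variant, stringsAsFactors = FALSE))
  }

  for (def in catalog) {
    id <- def$motif_id
    if (id == "SP") next                      # contextual; handled below
    if (id == "SRICH") {
      found <- FALSE
      for (v in def$variants) {
        ch <- scan_composition(seq, def$composition$classes,
                               config$srich_window,
                               config$srich_min_fraction,
                               core = v$pattern)
        if (nrow(ch)) found <- TRUE
        raw <- add(raw, id, ch, v$variant)
      }
      if (!found) {
        # no composition run carries a core: fall back to a bare core
        # match extended over contiguous class members (covers the
        # shortened/fused type-2' S-rich motif)
        member <- chars %in% def$composition$classes
        for (v in def$variants) {
          ch <- scan_pattern(seq, v$pattern)
          if (!nrow(ch)) next
          spans <- lapply(seq_len(nrow(ch)), function(k) {
            s <- ch$start[k]; e <- ch$end[k]
            while (s > 1L && member[s - 1L]) s <- s - 1L
            while (e < n && member[e + 1L]) e <- e + 1L
            c(s, e)
          })
          ch2 <- data.frame(
            start = vapply(spans, `[`, integer(1L), 1L),
            end = vapply(spans, `[`, integer(1L), 2L),
            stringsAsFactors = FALSE)
          ch2$match <- substring(seq, ch2$start, ch2$end)
          ch2$score <- vapply(seq_len(nrow(ch2)), function(k)
            mean(member[ch2$start[k]:ch2$end[k]]), numeric(1L))
          raw <- add(raw, id, ch2, v$variant)
        }
      }
    } else if (id == "DLRICH") {
      comp <- scan_composition(seq, def$composition$classes,
                               config$dlrich_window,
                               config$dlrich_min_fraction,
                               min_run = config$dlrich_min_run)
      raw <- add(raw, id, comp, "canonical")
      for (v in def$variants) {
        if (identical(v$variant, "modified")) {
          raw <- add(raw, id, scan_pattern(seq, v$pattern), "modified",
                     score = 1.0)
        }
      }
    } else if (def$mode == "repeat") {
      for (v in def$variants) {
        raw <- add(raw, id, scan_repeats(seq, v$pattern, def$min_repeats),
                   v$variant, score = 1.0)
      }
    } else {
      for (v in def$variants) {
        raw <- add(raw, id, scan_pattern(seq, v$pattern), v$variant,
                   score = 1.0)
      }
    }
  }

  # positional (terminal-window) restrictions
  keep <- rep(TRUE, nrow(raw))
  for (def in catalog) {
    sel <- raw$motif_id == def$motif_id
    if (!any(sel) || def$terminus == "none") next
    w <- def$terminal_window
    if (is.na(w)) {
      w <- if (def$terminus == "n_terminal") config$n_terminal_window
           else config$c_terminal_window
    }
    if (def$terminus == "n_terminal") {
      keep[sel] <- keep[sel] & raw$start[sel] <= w
    } else {
      keep[sel] <- keep[sel] & raw$start[sel] >= max(1L, n - w + 1L)
    }
  }
  raw$passed_window <- keep

  pick_best <- function(df) {
    df <- df[df$passed_window, , drop = FALSE]
    if (!nrow(df)) return(NULL)
    df[order(-df$score, df$start), , drop = FALSE][1L, , drop = FALSE]
  }

  # KRRW adjacency exemption: accepted right after a retained signature hit
  prv <- pick_best(raw[raw$motif_id == "PRVPVAGV", , drop = FALSE])
  if (!is.null(prv)) {
    sel <- raw$motif_id == "KRRW" & !raw$passed_window
    gap <- raw$start[sel] - prv$end - 1L
    raw$passed_window[sel][gap >= 0L & gap <= config$krrw_adjacency_gap] <- TRUE
  }

  hits <- do.call(rbind, Filter(Negate(is.null), lapply(
    unique(raw$motif_id), function(id)
      pick_best(raw[raw$motif_id == id, , drop = FALSE]))))
  if (is.null(hits)) {
    hits <- raw[0L, , drop = FALSE]
  }

  # SP residues: a single SP dipeptide strictly between S-rich and DL-rich
  if ("SP" %in% names(catalog)) {
    sr <- hits[hits$motif_id == "SRICH", , drop = FALSE]
    dl <- hits[hits$motif_id == "DLRICH", , drop = FALSE]
    if (nrow(sr) && nrow(dl) && dl$start > sr$end + 2L) {
      sp_at <- which(chars == "S" & c(chars[-1L], "") == "P")
      sp_at <- sp_at[sp_at > sr$end & (sp_at + 1L) < dl$start]
      if (length(sp_at)) {
        sp_hit <- data.frame(motif_id = "SP", start = sp_at[1L],
                             end = sp_at[1L] + 1L, match = "SP", score = 1.0,
                             variant = "canonical", passed_window = TRUE,
                             stringsAsFactors = FALSE)
        hits <- rbind(hits, sp_hit)
        raw <- rbind(raw, sp_hit)
      }
    }
  }

  hits <- hits[order(hits$start, hits$motif_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits$passed_window <- NULL
  region <- structure(list(sequence_id = sequence_id,
                           isoform_hint = isoform_hint, seq = seq,
                           hits = hits, raw_hits = raw,
                           flags = character()),
                      class = "ecr_region")
  region$flags <- check_architecture(region)
  region
}

# expected left-to-right ranks; equal rank = mutually unordered
ARCH_RANK <- list(
  A  = c(DLKHE = 1, PSIAYRG = 2, DTS_REPEATS = 1, YRLN = 1, SUMO = 3,
         NLS = 4, NLS_VARIANT = 4, DDW = 5, ABOX = 6),
  B1 = c(PRVPVAGV = 1, KRRW = 2, TXXPSIW = 2, SRICH = 3, SP = 4, DLRICH = 5)
)

EXPECTED_MOTIFS <- list(A = c("SUMO", "NLS", "DDW", "ABOX"),
                        B1 = c("SRICH", "SP", "DLRICH"))

#' Check architecture of an annotated region
#'
#' Produces a deterministic list of violation flags: `out_of_order(X,Y)`
#' when motif X is expected before motif Y but found after it,
#' `missing(X)` when an expected motif for the hinted isoform is absent
#' (A expects SUMO, NLS, (D/E)(D/E)W and the A-box; B1 expects the
#' S-rich, SP and DL-rich motifs), and `duplicate(X)` when several
#' non-overlapping candidate hits of one class passed the positional
#' filters. The expected A order is N-terminal signatures < SUMO < NLS <
#' DDW < A-box; the B1 order is signature/(K/R)RRW/TxxΨW < S-rich < SP <
#' DL-rich.
#'
#' @param region an `ecr_region`.
#' @return Character vector of flags (empty when the architecture holds).
#' @export
check_architecture <- function(region) {
  stopifnot(inherits(region, "ecr_region"))
  flags <- character()
  hint <- region$isoform_hint
  ranks <- if (hint %in% names(ARCH_RANK)) ARCH_RANK[[hint]]
           else c(ARCH_RANK$A, ARCH_RANK$B1[setdiff(names(ARCH_RANK$B1),
                                                    names(ARCH_RANK$A))])
  h <- region$hits
  h <- h[h$motif_id %in% names(ranks), , drop = FALSE]
  if (nrow(h) > 1L) {
    h <- h[order(h$start), , drop = FALSE]
    for (i in seq_len(nrow(h) - 1L)) {
      for (j in (i + 1L):nrow(h)) {
        ri <- ranks[[h$motif_id[i]]]; rj <- ranks[[h$motif_id[j]]]
        if (ri > rj) {
          flags <- c(flags, sprintf("out_of_order(%s,%s)",
                                    h$motif_id[j], h$motif_id[i]))
        }
      }
    }
  }
  if (hint %in% names(EXPECTED_MOTIFS)) {
    expected <- EXPECTED_MOTIFS[[hint]]
    found <- region$hits$motif_id
    if ("NLS_VARIANT" %in% found) found <- c(found, "NLS")
    for (m in setdiff(expected, found)) {
      flags <- c(flags, sprintf("missing(%s)", m))
    }
  }
  raw <- region$raw_hits
  raw <- raw[raw$passed_window & raw$motif_id != "SP", , drop = FALSE]
  for (id in unique(raw$motif_id)) {
    sub <- raw[raw$motif_id == id, , drop = FALSE]
    if (nrow(sub) > 1L) {
      sub <- sub[order(sub$start), , drop = FALSE]
      if (any(sub$start[-1L] > sub$end[-nrow(sub)])) {
        flags <- c(flags, sprintf("duplicate(%s)", id))
      }
    }
  }
  unique(flags)
}

#' @export
print.ecr_region <- function(x, ...) {
  cat(sprintf("<ecr_region> %s (hint %s, %d aa): %d motif hit(s)\n",
              x$sequence_id, x$isoform_hint, nchar(x$seq), nrow(x$hits)))
  if (nrow(x$hits)) print(x$hits, row.names = FALSE)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
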