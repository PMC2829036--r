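# Ground-truthed synthetic exemplars of the 12 structural-type
# architectures, assembled from the printed per-type consensus sequences
# joined by neutral linkers.

motif_part <- function(id, source) list(kind = "motif", id = id,
                                        source = source)
linker_part <- function(min, max) list(kind = "linker",
                                       range = c(min, max))
sp_linker_part <- function(min, max, offset = 5L) {
  # `offset` keeps the SP dipeptide at least that many residues past the
  # S-rich motif: a compositional window bridging the S-rich tail can
  # otherwise absorb the serine (window 8, fraction 0.6 admits up to 4
  # residues of neutral spacer). Type-2', whose shortened S-rich motif is
  # matched at core level only, may place SP closer.
  list(kind = "sp_linker", range = c(min, max), offset = offset)
}
extension_part <- function(min, max) list(kind = "extension",
                                          range = c(min, max))

#' Structural-type templates of the synthetic generator
#'
#' One template per published architecture. Motif segments instantiate
#' the printed per-type consensus sequences (A-box, S-rich, DL-rich and
#' N-terminal signature consensi); linker segments draw from the neutral
#' alphabet (default \{G, N, Q\}, disjoint from every motif class) with the
#' stated length ranges; the S-rich to DL-rich linker carries the SP
#' dipeptide. Length choices: generic inter-motif linkers 2-8 residues;
#' S-rich/DL-rich gap 10-30 for type-1 B1 (the long-linker architecture),
#' 8-14 for type-2, 4-5 for type-2' (at or under the fusion threshold),
#' 6-12 for the holometabolan types; the type-5 B1 N-terminal extension
#' is 15-22 residues (over the classifier's 15-residue minimum while
#' keeping the signature inside the 25-residue N-terminal window).
#'
#' @return Named list of templates; each has `label`, `isoform` and
#'   `parts`.
#' @export
ecr_templates <- function() {
  list(
    "A1" = list(label = "A1", isoform = "A", parts = list(
      linker_part(2, 6),
      motif_part("SUMO", "ΨKxE"), linker_part(3, 8),
      motif_part("NLS", "K(K/R)x(K/R)"), linker_part(3, 8),
      motif_part("DDW", "(D/E)(D/E)W"), linker_part(3, 8),
      motif_part("ABOX", "NGxSPSxxSSYDxxYSP"), linker_part(0, 3))),
    "A2" = list(label = "A2", isoform = "A", parts = list(
      motif_part("DLKHE", "DLKHE"), linker_part(1, 3),
      motif_part("PSIAYRG", "ΨAYRG"), linker_part(3, 8),
      motif_part("SUMO", "ΨKxE"), linker_part(3, 8),
      motif_part("NLS", "K(K/R)x(K/R)"), linker_part(3, 8),
      motif_part("DDW", "(D/E)(D/E)W"), linker_part(3, 8),
      motif_part("ABOX", "NGYSSP(M/L)SSGSYDPYSP"), linker_part(0, 3))),
    "A3" = list(label = "A3", isoform = "A", parts = list(
      linker_part(4, 10),
      motif_part("DDW", "(D/E)(D/E)W"), linker_part(3, 8),
      motif_part("ABOX", "NGxPSPTMSSMSYDPYSP"), linker_part(0, 3))),
    "A4" = list(label = "A4", isoform = "A", parts = list(
      motif_part("DTS_REPEATS", "D(T/S)SD(T/S)SD(T/S)S"), linker_part(3, 8),
      motif_part("SUMO", "ΨKxE"), linker_part(3, 8),
      motif_part("NLS", "K(K/R)x(K/R)"), linker_part(3, 8),
      motif_part("DDW", "(D/E)(D/E)W"), linker_part(3, 8),
      motif_part("ABOX", "NGYASPMS(T/S)GSYDPYSP"), linker_part(0, 3))),
    "A5" = list(label = "A5", isoform = "A", parts = list(
      motif_part("YRLN", "YRLN"), linker_part(2, 5),
      motif_part("SUMO", "ΨKxE"), linker_part(3, 8),
      motif_part("NLS", "K(K/R)x(K/R)"), linker_part(3, 8),
      motif_part("DDW", "(D/E)(D/E)W"), linker_part(3, 8),
      motif_part("ABOX", "NGYASPMSAGSYDPYSPNG"), linker_part(0, 3))),
    "B1-1" = list(label = "B1-1", isoform = "B1", parts = list(
      linker_part(2, 6),
      motif_part("SRICH", "GDExSxEVSSSS"), sp_linker_part(10, 30),
      motif_part("DLRICH", "DIGEVDLDFWDLDL"), linker_part(0, 5))),
    "B1-2" = list(label = "B1-2", isoform = "B1", parts = list(
      linker_part(0, 4),
      motif_part("TXXPSIW", "TxxΨW"), linker_part(3, 8),
      motif_part("SRICH", "GxESSPEVTSSS"), sp_linker_part(8, 14),
      motif_part("DLRICH", "DIGEVDLEFWDLDL"), linker_part(0, 5))),
    "B1-2'" = list(label = "B1-2'", isoform = "B1", parts = list(
      linker_part(0, 4),
      motif_part("TXXPSIW", "TxxΨW"), linker_part(3, 8),
      motif_part("SRICH", "EDxxxQVSSS"), sp_linker_part(4, 5, offset = 2L),
      motif_part("DLRICH", "EVDLELWDLGL"), linker_part(0, 5))),
    "B1-3" = list(label = "B1-3", isoform = "B1", parts = list(
      linker_part(0, 3),
      motif_part("KRRW", "(K/R)RRW"), linker_part(2, 6),
      motif_part("SRICH", "EESSSEVTSSS"), sp_linker_part(6, 12),
      motif_part("DLRICH", "DIGDVDLEFWDLDL"), linker_part(0, 5))),
    "B1-4" = list(label = "B1-4", isoform = "B1", parts = list(
      linker_part(0, 2),
      motif_part("PRVPVAGV", "LQTVPRVPVAGV"), linker_part(0, 2),
      motif_part("KRRW", "(K/R)RRW"), linker_part(2, 6),
      motif_part("SRICH", "ESSPEVSSS"), sp_linker_part(6, 12),
      motif_part("DLRICH", "EDLQLWDLDL"), linker_part(0, 5))),
    "B1-5" = list(label = "B1-5", isoform = "B1", parts = list(
      extension_part(15, 22),
      motif_part("PRVPVAGV", "LAVPRVPVAGV"), linker_part(0, 2),
      motif_part("KRRW", "(K/R)RRW"), linker_part(2, 6),
      motif_part("SRICH", "ESSPEVSSS"), sp_linker_part(6, 12),
      motif_part("DLRICH", "EDLQLWDLDL"), linker_part(0, 5))),
    "B1-6" = list(label = "B1-6", isoform = "B1", parts = list(
      linker_part(0, 3),
      motif_part("KRRW", "(K/R)RRW"), linker_part(2, 6),
      motif_part("SRICH", "EESSSEVTSSS"), sp_linker_part(6, 12),
      motif_part("DLRICH", "(D/E)Y(C/G)(E/D)LWxxxxD"), linker_part(0, 5)))
  )
}

#' Generate one ground-truthed exemplar sequence
#'
#' Motif instances are realized from their printed consensus
#' (alternations take the first printed alternative, `Ψ` becomes L,
#' wildcards draw from the linker alphabet), joined by neutral linkers,
#' then mutated: each motif-instance residue is substituted with
#' probability `noise_rate` by a uniformly drawn different canonical
#' residue. Linkers are never mutated (they are random already) and
#' substitutions never create gaps. The same seed gives byte-identical
#' output; the global RNG state is left untouched.
#'
#' @param template a structural-type label (see [ecr_templates()]).
#' @param noise_rate per-residue substitution probability within motif
#'   instances, in `[0, 0.5]`.
#' @param seed integer seed.
#' @param linker_alphabet residues used for linkers and wildcards;
#'   the default \{G, N, Q\} lies outside every motif class.
#' @return List with `sequence`, `ground_truth` (data.frame: `motif_id`,
#'   `start`, `end`, `instance` -- the pre-noise instance), `label`,
#'   `isoform`.
#' @examples
#' ex <- make_exemplar("B1-3", noise_rate = 0, seed = 1)
#' ex$ground_truth
#' @export
make_exemplar <- function(template, noise_rate = 0, seed = 1,
                          linker_alphabet = c("G", "N", "Q")) {
  templates <- ecr_templates()
  if (!template %in% names(templates)) {
    stop_input(sprintf("unknown template '%s'", template))
  }
  if (!(noise_rate >= 0 && noise_rate <= 0.5)) {
    stop_config("noise_rate must be in [0, 0.5]")
  }
  tpl <- templates[[template]]
  withr::with_seed(as.integer(seed), {
    pieces <- character()
    gt <- data.frame(motif_id = character(), start = integer(),
                     end = integer(), instance = character(),
                     stringsAsFactors = FALSE)
    pos <- 1L
    motif_mask <- logical()
    for (part in tpl$parts) {
      if (part$kind == "motif") {
        inst <- realize_pattern(compile_pattern(part$source),
                                wildcard_alphabet = linker_alphabet)
        gt <- rbind(gt, data.frame(
          motif_id = part$id, start = pos,
          end = pos + nchar(inst) - 1L, instance = inst,
          stringsAsFactors = FALSE))
        pieces <- c(pieces, inst)
        motif_mask <- c(motif_mask, rep(TRUE, nchar(inst)))
        pos <- pos + nchar(inst)
      } else {
        len <- if (part$range[1L] == part$range[2L]) part$range[1L]
               else sample(part$range[1L]:part$range[2L], 1L)
        chars <- if (len > 0L) sample(linker_alphabet, len, replace = TRUE)
                 else character()
        mask <- rep(FALSE, len)
        if (part$kind == "sp_linker") {
          lo <- part$offset; hi <- len - 1L
          stopifnot(lo <= hi)
          at <- if (lo == hi) lo else sample(lo:hi, 1L)
          chars[at] <- "S"; chars[at + 1L] <- "P"
          mask[c(at, at + 1L)] <- TRUE
          gt <- rbind(gt, data.frame(
            motif_id = "SP", start = pos + at - 1L, end = pos + at,
            instance = "SP", stringsAsFactors = FALSE))
        }
        pieces <- c(pieces, paste(chars, collapse = ""))
        motif_mask <- c(motif_mask, mask)
        pos <- pos + len
      }
    }
    seq <- paste(pieces, collapse = "")
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    if (noise_rate > 0) {
      hit <- which(motif_mask & stats::runif(length(chars)) < noise_rate)
      for (i in hit) {
        chars[i] <- sample(setdiff(AA_ALPHABET, chars[i]), 1L)
      }
      seq <- paste(chars, collapse = "")
    }
    # self-consistency: ground truth must index the emitted sequence
    stopifnot(all(gt$end <= nchar(seq)))
    if (noise_rate == 0) {
      stopifnot(identical(substring(seq, gt$start, gt$end), gt$instance))
    }
    list(sequence = seq, ground_truth = gt, label = tpl$label,
         isoform = tpl$isoform)
  })
}

#' Generate a panel of exemplars with files cross-referenced by id
#'
#' @param templates character vector of template labels.
#' @param replicates exemplars per template (0 gives empty, valid
#'   outputs).
#' @param noise_rate passed to [make_exemplar()].
#' @param seed master seed; per-sequence seeds are derived from it.
#' @param out_prefix optional path prefix; when given, writes
#'   `<prefix>.fasta`, `<prefix>_truth.gff3` and `<prefix>_labels.tsv`.
#' @param linker_alphabet see [make_exemplar()].
#' @return List with `sequences` (named character vector),
#'   `ground_truth` (data.frame with `sequence_id` column) and `labels`
#'   (data.frame: `sequence_id`, `isoform`, `label`).
#' @export
make_panel <- function(templates, replicates = 1L, noise_rate = 0,
                       seed = 1L, out_prefix = NULL,
                       linker_alphabet = c("G", "N", "Q")) {
  if (!length(templates)) stop_input("templates must be non-empty")
  n <- length(templates) * replicates
  seeds <- withr::with_seed(as.integer(seed),
                            sample.int(.Machine$integer.max, max(n, 1L)))
  seqs <- character()
  gt_all <- data.frame()
  labels <- data.frame(sequence_id = character(), isoform = character(),
                       label = character(), stringsAsFactors = FALSE)
  k <- 0L
  for (tpl in templates) {
    for (rep_i in seq_len(replicates)) {
      k <- k + 1L
      ex <- make_exemplar(tpl, noise_rate = noise_rate, seed = seeds[k],
                          linker_alphabet = linker_alphabet)
      id <- sprintf("%s_rep%02d", gsub("'", "p", tpl, fixed = TRUE), rep_i)
      seqs[id] <- ex$sequence
      if (nrow(ex$ground_truth)) {
        gt_all <- rbind(gt_all, cbind(sequence_id = id, ex$ground_truth,
                                      stringsAsFactors = FALSE))
      }
      labels <- rbind(labels, data.frame(
        sequence_id = id, isoform = ex$isoform, label = ex$label,
        stringsAsFactors = FALSE))
    }
  }
  if (!nrow(gt_all)) {
    gt_all <- data.frame(sequence_id = character(), motif_id = character(),
                         start = integer(), end = integer(),
                         instance = character(), stringsAsFactors = FALSE)
  }
  out <- list(sequences = seqs, ground_truth = gt_all, labels = labels)
  if (!is.null(out_prefix)) {
    write_fasta(seqs, paste0(out_prefix, ".fasta"))
    gff <- gt_all
    names(gff)[names(gff) == "instance"] <- "match"
    gff$score <- rep(1.0, nrow(gff))
    gff$variant <- rep("truth", nrow(gff))
    write_gff3(gff, paste0(out_prefix, "_truth.gff3"))
    utils::write.table(labels, paste0(out_prefix, "_labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
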