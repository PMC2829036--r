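# Readers/writers: FASTA in, GFF3 + TSV out, Newick via ape.

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @param mode `"ungapped"` strips alignment gaps (`-`) for annotation
#'   input; `"aligned"` keeps them for consensus building.
#' @return Named character vector of sequences, order preserved.
#'   Duplicate ids, empty files and illegal residues are errors naming
#'   the offending record.
#' @export
read_sequences <- function(path, mode = c("ungapped", "aligned")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop_input(sprintf("FASTA not found: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop_input(sprintf(
                    "cannot parse FASTA %s: %s", path, conditionMessage(e))))
  if (!length(set)) stop_input(sprintf("FASTA %s contains no records", path))
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop_input(sprintf("duplicate sequence id '%s' in %s", dup[1L], path))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (mode == "ungapped") seqs <- gsub("-", "", seqs, fixed = TRUE)
  for (i in seq_along(seqs)) {
    probe <- if (mode == "aligned") gsub("-", "", seqs[[i]], fixed = TRUE)
             else seqs[[i]]
    if (nzchar(probe)) {
      tryCatch(check_sequence(probe, what = sprintf("record '%s'", ids[i])),
               ecr_input_error = function(e) stop_input(conditionMessage(e)))
    }
  }
  seqs
}

write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# hits: data.frame with sequence_id, motif_id, start, end, score, variant
write_gff3 <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(hits)) {
    lines <- sprintf(
      "%s\tecrmotifs\tpolypeptide_motif\t%d\t%d\t%s\t.\t.\tID=%s;motif_id=%s;variant=%s",
      hits$sequence_id, hits$start, hits$end,
      formatC(hits$score, format = "fg", digits = 6),
      sprintf("%s.%s.%d", hits$sequence_id, hits$motif_id, hits$start),
      hits$motif_id, hits$variant)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write annotations as GFF3 and TSV
#'
#' One `polypeptide_motif` feature per retained motif hit, 1-based
#' inclusive coordinates, score column carrying the hit score and the
#' motif id in the attributes; the TSV mirrors the same rows.
#'
#' @param regions list of `ecr_region` objects (or a single one).
#' @param gff_path,tsv_path output paths (either may be NULL to skip).
#' @return Invisibly, the combined hits data.frame.
#' @export
write_annotations <- function(regions, gff_path = NULL, tsv_path = NULL) {
  if (inherits(regions, "ecr_region")) regions <- list(regions)
  rows <- lapply(regions, function(r) {
    if (!nrow(r$hits)) return(NULL)
    cbind(sequence_id = r$sequence_id, r$hits, stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(hits)) {
    hits <- data.frame(sequence_id = character(), motif_id = character(),
                       start = integer(), end = integer(),
                       match = character(), score = numeric(),
                       variant = character(), stringsAsFactors = FALSE)
  }
  if (!is.null(gff_path)) write_gff3(hits, gff_path)
  if (!is.null(tsv_path)) {
    utils::write.table(
      hits[, c("sequence_id", "motif_id", "start", "end", "score")],
      tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(hits)
}

#' Read motif annotations back from GFF3
#'
#' Lossless round trip for (`sequence_id`, `motif_id`, `start`, `end`,
#' `score`) of files written by [write_annotations()] or any GFF3 with a
#' `motif_id` attribute.
#'
#' @param path GFF3 file.
#' @return data.frame with columns `sequence_id`, `motif_id`, `start`,
#'   `end`, `score`, `variant`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("GFF3 not found: %s", path))
  lines <- readLines(path)
  if (!length(lines) || !grepl("^##gff-version", lines[1L])) {
    stop_input(sprintf("%s lacks a ##gff-version pragma", path))
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(body)) {
    return(data.frame(sequence_id = character(), motif_id = character(),
                      start = integer(), end = integer(), score = numeric(),
                      variant = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) != 9L)) {
    stop_input(sprintf("malformed GFF3 line in %s", path))
  }
  attr_field <- function(attrs, key) {
    m <- regmatches(attrs, regexec(sprintf("(?:^|;)%s=([^;]*)", key), attrs))
    vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_,
           character(1L))
  }
  attrs <- vapply(parts, `[`, character(1L), 9L)
  data.frame(
    sequence_id = vapply(parts, `[`, character(1L), 1L),
    motif_id = attr_field(attrs, "motif_id"),
    start = as.integer(vapply(parts, `[`, character(1L), 4L)),
    end = as.integer(vapply(parts, `[`, character(1L), 5L)),
    score = as.numeric(vapply(parts, `[`, character(1L), 6L)),
    variant = attr_field(attrs, "variant"),
    stringsAsFactors = FALSE)
}

#' Annotate every record of a FASTA file
#'
#' @param path FASTA of isoform-specific-region sequences.
#' @param isoform_hint `"A"`, `"B1"` or `"unknown"`.
#' @param catalog,config see [detect_microdomains()].
#' @return Named list of `ecr_region` objects.
#' @export
annotate_fasta <- function(path, isoform_hint = "unknown",
                           catalog = default_catalog(),
                           config = ecr_config()) {
  seqs <- read_sequences(path, mode = "ungapped")
  out <- lapply(seq_along(seqs), function(i)
    detect_microdomains(seqs[[i]], isoform_hint,
                        sequence_id = names(seqs)[i],
                        catalog = catalog, config = config))
  names(out) <- names(seqs)
  out
}

#' Classify every record of a FASTA file
#'
#' @inheritParams annotate_fasta
#' @param isoform `"A"` or `"B1"`.
#' @param taxa optional data.frame with columns `sequence_id`, `taxon`
#'   (or a path to such a TSV).
#' @return data.frame: `sequence_id`, `isoform`, `label`,
#'   `missing_motifs`, `notes`.
#' @export
classify_fasta <- function(path, isoform, taxa = NULL,
                           catalog = default_catalog(),
                           config = ecr_config()) {
  if (!isoform %in% c("A", "B1")) {
    stop_config("isoform must be 'A' or 'B1'")
  }
  if (is.character(taxa) && length(taxa) == 1L) {
    taxa <- utils::read.delim(taxa, stringsAsFactors = FALSE)
  }
  regions <- annotate_fasta(path, isoform_hint = isoform,
                            catalog = catalog, config = config)
  rows <- lapply(regions, function(r) {
    taxon <- NULL
    if (!is.null(taxa)) {
      m <- match(r$sequence_id, taxa$sequence_id)
      if (!is.na(m)) taxon <- taxa$taxon[m]
    }
    call <- classify_region(r, taxon = taxon, config = config)
    data.frame(sequence_id = r$sequence_id, isoform = isoform,
               label = call$label,
               missing_motifs = paste(call$missing_motifs, collapse = ","),
               notes = paste(call$notes, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
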