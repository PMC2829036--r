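# Microdomain catalog: one definition per motif id, possibly with several
# per-structural-type pattern variants. The shipped catalog lives in
# inst/extdata/motif_catalog.tsv and is human-editable.

#' Read a microdomain catalog from a TSV config
#'
#' The TSV has one row per pattern variant with columns `motif_id`,
#' `isoform`, `structural_type`, `mode` (pattern / composition / hybrid /
#' repeat / context), `pattern` (printed consensus notation), `classes`
#' (`+`-joined class names for composition rules), `window`,
#' `min_fraction`, `min_run`, `min_repeats`, `terminus` (none /
#' n_terminal / c_terminal), `terminal_window` and `variant`. Missing
#' values are written `.`.
#'
#' @param path TSV file; defaults to the catalog shipped with the package.
#' @param classes residue class list used to compile `Ψ` and composition
#'   rules.
#' @return An object of class `ecr_catalog`: a list of definitions, one
#'   per motif id, each with fields `motif_id`, `isoform`, `mode`,
#'   `variants` (compiled patterns with variant tags), `composition`
#'   (classes/window/min_fraction/min_run or NULL), `min_repeats`,
#'   `terminus`, `terminal_window`.
#' @export
read_catalog <- function(path = system.file("extdata", "motif_catalog.tsv",
                                            package = "ecrmotifs"),
                         classes = residue_classes()) {
  if (!file.exists(path)) stop_input(sprintf("catalog file not found: %s", path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8", na.strings = ".")
  needed <- c("motif_id", "isoform", "structural_type", "mode", "pattern",
              "classes", "window", "min_fraction", "min_run", "min_repeats",
              "terminus", "terminal_window", "variant")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    stop_config(sprintf("catalog is missing column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  defs <- list()
  for (id in unique(tab$motif_id)) {
    rows <- tab[tab$motif_id == id, , drop = FALSE]
    mode <- rows$mode[1L]
    def <- list(motif_id = id, isoform = rows$isoform[1L], mode = mode,
                variants = list(), composition = NULL,
                min_repeats = NA_integer_,
                terminus = ifelse(is.na(rows$terminus[1L]), "none",
                                  rows$terminus[1L]),
                terminal_window = rows$terminal_window[1L])
    for (k in seq_len(nrow(rows))) {
      r <- rows[k, ]
      if (!is.na(r$pattern) && r$mode != "context") {
        def$variants[[length(def$variants) + 1L]] <- list(
          pattern = compile_pattern(r$pattern, classes = classes),
          variant = r$variant,
          structural_type = r$structural_type,
          mode = r$mode)
      }
      if (!is.na(r$classes)) {
        comp_classes <- strsplit(r$classes, "+", fixed = TRUE)[[1L]]
        def$composition <- list(
          classes = class_union(comp_classes, classes = classes),
          class_names = comp_classes,
          window = as.integer(r$window),
          min_fraction = as.numeric(r$min_fraction),
          min_run = ifelse(is.na(r$min_run), 0L, as.integer(r$min_run)))
      }
      if (!is.na(r$min_repeats)) def$min_repeats <- as.integer(r$min_repeats)
    }
    defs[[id]] <- def
  }
  structure(defs, class = "ecr_catalog")
}

#' Default microdomain catalog
#'
#' The full catalog of EcR isoform-specific-region microdomains: the
#' SUMOylation motif ΨKxE, the monopartite NLS K(K/R)x(K/R) and its KxxR
#' variant, the (D/E)(D/E)W residues, five per-type A-box consensi, the
#' N-terminal signatures DLKHE / ΨAYRG / D(T/S)S repeats / YRLN, the B1
#' motifs (K/R)RRW, TxxΨW, LQTVPRVPVAGV / LAVPRVPVAGV, the hybrid S-rich
#' rule (acidic + neutral-polar composition with an EV(T/S)SS or QVSSS
#' core), the DL-rich composition rule (acidic + bulky hydrophobic) with
#' its modified pattern variant, and the contextual SP residues.
#'
#' @param classes residue class list.
#' @return An `ecr_catalog`.
#' @export
default_catalog <- function(classes = residue_classes()) {
  read_catalog(classes = classes)
}

#' @export
print.ecr_catalog <- function(x, ...) {
  cat("<ecr_catalog> with", length(x), "microdomain definitions:\n")
  for (d in x) {
    pats <- vapply(d$variants, function(v) v$pattern$source, character(1L))
    cat(sprintf("  %-12s %-3s %-11s %s\n", d$motif_id, d$isoform, d$mode,
                paste(pats, collapse = " | ")))
  }
  invisible(x)
}

#' Pipeline configuration defaults
#'
#' Central collection of tunable parameters: terminal windows for
#' position-restricted motifs (N-terminal 25 residues; 10 for the
#' strictly terminal KRRW / TxxΨW / YRLN; C-terminal 40 for the A-box),
#' composition thresholds for the S-rich (window 8, fraction 0.6) and
#' DL-rich (window 10, fraction 0.8, minimum run 8) motifs, classifier
#' thresholds (type-5 B1 extension >= 15 residues; type-2' fusion gap <= 5;
#' KRRW-after-signature adjacency gap <= 3), and consensus thresholds
#' (single residue 0.6; alternation 0.8).
#'
#' @param ... overrides as `name = value`; unknown names are rejected.
#' @return Named list of configuration values.
#' @examples
#' ecr_config(fusion_gap = 3)
#' @export
ecr_config <- function(...) {
  cfg <- list(
    n_terminal_window = 25L,
    n_terminal_window_strict = 10L,
    c_terminal_window = 40L,
    srich_window = 8L,
    srich_min_fraction = 0.6,
    dlrich_window = 10L,
    dlrich_min_fraction = 0.8,
    dlrich_min_run = 8L,
    extension_min = 15L,
    fusion_gap = 5L,
    krrw_adjacency_gap = 3L,
    single_threshold = 0.6,
    class_threshold = 0.8,
    require_class = FALSE
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad) || is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
      stop_config(sprintf("unknown config key(s): %s",
                          paste(bad, collapse = ", ")))
    }
    cfg[names(overrides)] <- overrides
  }
  cfg
}
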