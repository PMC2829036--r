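#' @keywords internal
"_PACKAGE"

# 20 canonical amino acids, one-letter codes
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Greek capital psi, used throughout the printed motif notation for
# "large hydrophobic residue"
PSI_CHAR <- "Ψ"

#' Named amino-acid residue classes used by the motif grammar
#'
#' The motif catalog is written over a handful of named alphabet subsets:
#' `ACIDIC` (D, E) and `NEUTRAL_POLAR` (S, T) compose the S-rich motif;
#' `ACIDIC` plus `BULKY` (W, A, F, I, L, M, V -- the aromatic/bulky
#' hydrophobic residues) compose the DL-rich motif; `BASIC` (K, R) appears
#' in the (K/R)RRW motif; `PSI` is the "large hydrophobic" class written as
#' the Greek letter psi in degenerate consensus strings. The membership of
#' `PSI` is a package choice (F, I, L, M, V, W, Y): the notation's source
#' never enumerates it, and "large" excludes A and G. It can be overridden
#' by passing a modified class list wherever a `classes` argument is
#' accepted.
#'
#' @return Named list of character vectors, each a subset of the 20
#'   canonical one-letter codes.
#' @examples
#' residue_classes()$ACIDIC
#' @export
residue_classes <- function() {
  list(
    ACIDIC        = c("D", "E"),
    NEUTRAL_POLAR = c("S", "T"),
    BULKY         = c("W", "A", "F", "I", "L", "M", "V"),
    BASIC         = c("K", "R"),
    PSI           = c("F", "I", "L", "M", "V", "W", "Y")
  )
}

# union of named classes, e.g. class_union(c("ACIDIC","BULKY"))
class_union <- function(names, classes = residue_classes()) {
  bad <- setdiff(names, names(classes))
  if (length(bad)) {
    stop_config(sprintf("unknown residue class(es): %s",
                        paste(bad, collapse = ", ")))
  }
  sort(unique(unlist(classes[names], use.names = FALSE)))
}

# Validate an amino-acid sequence string; returns uppercased character
# vector of residues. Gaps are never accepted here -- callers strip them.
check_sequence <- function(seq, what = "sequence") {
  if (length(seq) != 1L || !is.character(seq) || is.na(seq)) {
    stop_input(sprintf("%s must be a single character string", what))
  }
  if (!nzchar(seq)) stop_input(sprintf("%s is empty", what))
  chars <- toupper(strsplit(seq, "", fixed = TRUE)[[1L]])
  bad <- which(!(chars %in% AA_ALPHABET))
  if (length(bad)) {
    stop_input(sprintf(
      "non-canonical residue '%s' at position %d of %s",
      chars[bad[1L]], bad[1L], what))
  }
  chars
}

# condition helpers -- CLI maps these onto exit codes 2 (input) / 3 (config)
stop_input <- function(msg) {
  stop(structure(class = c("ecr_input_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1L))))
}

stop_config <- function(msg) {
  stop(structure(class = c("ecr_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1L))))
}
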