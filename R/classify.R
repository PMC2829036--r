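# Rule-based structural-type classification from microdomain inventories.

new_type_call <- function(label, missing_motifs = character(),
                          notes = character(), taxon_used = FALSE) {
  structure(list(label = label, missing_motifs = missing_motifs,
                 notes = notes, taxon_used = taxon_used),
            class = "ecr_type_call")
}

#' @export
print.ecr_type_call <- function(x, ...) {
  cat(sprintf("<ecr_type_call> %s", x$label))
  if (length(x$missing_motifs))
    cat(" | missing:", paste(x$missing_motifs, collapse = ","))
  if (length(x$notes)) cat(" |", paste(x$notes, collapse = "; "))
  cat("\n")
  invisible(x)
}

region_inventory <- function(region) unique(region$hits$motif_id)

#' Classify an A isoform-specific region into structural types A1-A5
#'
#' Decision rules, evaluated in fixed priority order on the retained motif
#' inventory: (1) (D/E)(D/E)W and A-box present while both the
#' SUMOylation motif and the NLS are absent -> A3 (the heteropteran
#' architecture lacking the N-terminal half); (2) D(T/S)S repeats with the
#' common scaffold -> A4 (Hymenoptera/Mecoptera); (3) N-terminal YRLN with
#' the scaffold -> A5 (Diptera); (4) DLKHE or ΨAYRG with the scaffold ->
#' A2 (direct-developing insects and most holometabolans; the NLS may be
#' absent, noted as the lepidopteran variant); (5) full scaffold
#' (SUMOylation motif, NLS or its KxxR variant, (D/E)(D/E)W, A-box) -> A1.
#' If taxon metadata names Diptera where rule 5 would fire, the call is
#' upgraded to A5 with a note (the Drosophila group lost the YRLN
#' residues). Anything else is `unclassified`.
#'
#' @param region an `ecr_region` with isoform hint A (hint B1 is an error).
#' @param taxon optional taxon name (insect order or subgroup).
#' @param config an [ecr_config()] list.
#' @return An `ecr_type_call` with fields `label`, `missing_motifs`,
#'   `notes`, `taxon_used`.
#' @export
classify_a_region <- function(region, taxon = NULL, config = ecr_config()) {
  stopifnot(inherits(region, "ecr_region"))
  if (identical(region$isoform_hint, "B1")) {
    stop_input("classify_a_region given a region annotated with hint B1")
  }
  inv <- region_inventory(region)
  has <- function(...) all(c(...) %in% inv)
  nls_ok <- has("NLS") || has("NLS_VARIANT")
  scaffold <- has("SUMO") && nls_ok && has("DDW") && has("ABOX")
  taxon <- if (is.null(taxon) || is.na(taxon)) "" else as.character(taxon)

  if (has("DDW", "ABOX") && !has("SUMO") && !nls_ok) {
    return(new_type_call("A3"))
  }
  if (has("DTS_REPEATS") && scaffold) {
    notes <- character(); used <- FALSE
    if (!has("NLS") && has("NLS_VARIANT")) {
      notes <- "NLS modified (KxxR variant)"
      if (grepl("hymenoptera", taxon, ignore.case = TRUE)) used <- TRUE
    }
    return(new_type_call("A4", notes = notes, taxon_used = used))
  }
  if (has("YRLN") && scaffold) {
    return(new_type_call("A5"))
  }
  if ((has("DLKHE") || has("PSIAYRG")) &&
      has("SUMO", "DDW", "ABOX")) {
    notes <- if (!nls_ok)
      "NLS absent - consistent with Lepidoptera type-2 variant"
    else character()
    return(new_type_call("A2", notes = notes))
  }
  if (scaffold) {
    if (grepl("diptera", taxon, ignore.case = TRUE) &&
        !grepl("lepidoptera", taxon, ignore.case = TRUE)) {
      return(new_type_call(
        "A5", notes = "YRLN absent - Drosophila-group loss (Diptera)",
        taxon_used = TRUE))
    }
    return(new_type_call("A1"))
  }
  new_type_call("unclassified",
                missing_motifs = setdiff(c("SUMO", "NLS", "DDW", "ABOX"),
                                         c(inv, if (nls_ok) "NLS")))
}

#' Classify a B1 isoform-specific region into structural types B1-1..B1-6
#' and B1-2'
#'
#' Decision rules in fixed priority order: (1) with the holometabolan
#' (K/R)RRW motif -- (1a) an LQTVPRVPVAGV / LAVPRVPVAGV signature ending
#' within `krrw_adjacency_gap` residues before KRRW gives B1-5 when the
#' signature is preceded by an N-terminal extension of at least
#' `extension_min` residues (sawflies, Mecoptera), otherwise B1-4
#' (aculeate Hymenoptera); (1b) a DL-rich motif matched only by the
#' modified pattern (D/E)Y(C/G)(E/D)LWxxxxD gives B1-6 (Diptera,
#' Lepidoptera, Trichoptera); (1c) otherwise B1-3. (2) Without KRRW but
#' with the N-terminal TxxΨW sequence: an S-rich/DL-rich gap of at most
#' `fusion_gap` residues, or an S-rich core matched by the QVSSS variant,
#' gives B1-2' (Heteroptera), otherwise B1-2 (other Polyneoptera /
#' Paraneoptera). (3) S-rich and DL-rich alone give B1-1 (non-insect
#' arthropods, non-neopteran insects); absent SP residues are noted (the
#' heteropteran exception). Rules only fire when the type's minimal motif
#' set is present; anything else is `unclassified`.
#'
#' @inheritParams classify_a_region
#' @return An `ecr_type_call`.
#' @export
classify_b1_region <- function(region, taxon = NULL, config = ecr_config()) {
  stopifnot(inherits(region, "ecr_region"))
  if (identical(region$isoform_hint, "A")) {
    stop_input("classify_b1_region given a region annotated with hint A")
  }
  inv <- region_inventory(region)
  has <- function(...) all(c(...) %in% inv)
  hits <- region$hits
  get1 <- function(id) hits[hits$motif_id == id, , drop = FALSE]
  core3 <- has("SRICH") && has("DLRICH")

  if (has("KRRW")) {
    krrw <- get1("KRRW")
    if (has("PRVPVAGV")) {
      prv <- get1("PRVPVAGV")
      gap <- krrw$start - prv$end - 1L
      if (gap >= 0L && gap <= config$krrw_adjacency_gap && core3) {
        extension <- prv$start - 1L
        label <- if (extension >= config$extension_min) "B1-5" else "B1-4"
        return(new_type_call(label))
      }
    }
    raw_dl <- region$raw_hits[region$raw_hits$motif_id == "DLRICH" &
                                region$raw_hits$passed_window, , drop = FALSE]
    modified_only <- any(raw_dl$variant == "modified") &&
      !any(raw_dl$variant == "canonical")
    if (modified_only && has("SRICH")) {
      return(new_type_call("B1-6"))
    }
    if (core3) {
      return(new_type_call("B1-3"))
    }
    return(new_type_call(
      "unclassified",
      missing_motifs = setdiff(c("SRICH", "DLRICH"), inv),
      notes = "KRRW present but core motifs incomplete"))
  }
  if (has("TXXPSIW") && core3) {
    sr <- get1("SRICH"); dl <- get1("DLRICH")
    gap <- dl$start - sr$end - 1L
    if (gap <= config$fusion_gap || identical(sr$variant, "QVSSS")) {
      return(new_type_call("B1-2'"))
    }
    return(new_type_call("B1-2"))
  }
  if (core3) {
    notes <- if (!has("SP"))
      "SP residues absent - heteropteran exception" else character()
    return(new_type_call("B1-1", notes = notes))
  }
  new_type_call("unclassified",
                missing_motifs = setdiff(c("SRICH", "SP", "DLRICH"), inv))
}

#' Classify an annotated region according to its isoform hint
#'
#' @param region an `ecr_region` with hint `"A"` or `"B1"`.
#' @param taxon optional taxon name.
#' @param config an [ecr_config()] list.
#' @return An `ecr_type_call`.
#' @export
classify_region <- function(region, taxon = NULL, config = ecr_config()) {
  switch(region$isoform_hint,
    A  = classify_a_region(region, taxon, config),
    B1 = classify_b1_region(region, taxon, config),
    stop_input("classify_region requires an isoform hint of 'A' or 'B1'"))
}

#' Motif inventory of a structural type
#'
#' Expands a structural-type label into its defining microdomain set, for
#' use as presence/absence characters in the parsimony module.
#'
#' @param label one of `A1`..`A5`, `B1-1`..`B1-6`, `B1-2'`.
#' @return Character vector of motif ids.
#' @export
type_inventory <- function(label) {
  a_scaffold <- c("SUMO", "NLS", "DDW", "ABOX")
  b_core <- c("SRICH", "SP", "DLRICH")
  inv <- switch(label,
    "A1" = a_scaffold,
    "A2" = c("DLKHE", "PSIAYRG", a_scaffold),
    "A3" = c("DDW", "ABOX"),
    "A4" = c("DTS_REPEATS", a_scaffold),
    "A5" = c("YRLN", a_scaffold),
    "B1-1" = b_core,
    "B1-2" = c("TXXPSIW", b_core),
    "B1-2'" = c("TXXPSIW", b_core),
    "B1-3" = c("KRRW", b_core),
    "B1-4" = c("PRVPVAGV", "KRRW", b_core),
    "B1-5" = c("PRVPVAGV", "KRRW", b_core),
    "B1-6" = c("KRRW", b_core),
    stop_input(sprintf("unknown structural type label '%s'", label)))
  inv
}
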