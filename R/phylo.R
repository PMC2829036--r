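# Fitch parsimony reconstruction of motif presence/absence over a rooted
# taxon tree, with gain/loss assignment per branch.

#' Bundled insect-subgroup cladogram
#'
#' A rooted order-level cladogram of the arthropod/insect subgroups used
#' in the motif-evolution models (Crustacea outgroup; Apterygota;
#' Paleoptera; Polyneoptera; Paraneoptera split into Psocodea and
#' Heteroptera; Holometabola with Hymenoptera basal, then
#' Coleoptera+Neuropterida, Trichoptera+Lepidoptera and
#' Mecoptera+Diptera). Users may supply any Newick tree instead.
#'
#' @return An [ape::read.tree()] `phylo` object.
#' @export
ecr_subgroup_tree <- function() {
  ape::read.tree(system.file("extdata", "insect_subgroups.nwk",
                             package = "ecrmotifs"))
}

#' Read a taxon-by-motif presence/absence table
#'
#' TSV with a `taxon` column and one 0/1 column per motif; `?` or `NA`
#' mark unknown states.
#'
#' @param path TSV file.
#' @return data.frame with rownames = taxa and integer 0/1/NA columns.
#' @export
read_state_table <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("state table not found: %s", path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("?", "NA"))
  if (!"taxon" %in% names(tab)) stop_input("state table needs a 'taxon' column")
  if (anyDuplicated(tab$taxon)) stop_input("duplicate taxon in state table")
  rownames(tab) <- tab$taxon
  tab$taxon <- NULL
  for (j in seq_along(tab)) tab[[j]] <- as.integer(tab[[j]])
  bad <- !(unlist(tab) %in% c(0L, 1L, NA))
  if (any(bad, na.rm = TRUE)) stop_input("states must be 0, 1 or ?")
  tab
}

#' Expand structural-type labels into motif presence/absence states
#'
#' @param labels named character vector: taxon -> structural-type label.
#' @param motifs motif ids to score; default = union over all labels.
#' @return data.frame of 0/1 states, rows = taxa.
#' @export
states_from_types <- function(labels, motifs = NULL) {
  invs <- lapply(labels, type_inventory)
  if (is.null(motifs)) motifs <- sort(unique(unlist(invs)))
  out <- do.call(rbind, lapply(invs, function(iv)
    as.integer(motifs %in% iv)))
  out <- as.data.frame(out)
  names(out) <- motifs
  rownames(out) <- names(labels)
  out
}

prepare_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop_input("tree must be an ape 'phylo' object")
  if (!ape::is.rooted(tree)) stop_input("tree must be rooted")
  if (!ape::is.binary(tree)) {
    # deterministic resolution of polytomies (no randomisation)
    tree <- ape::multi2di(tree, random = FALSE)
  }
  tree
}

#' Fitch parsimony reconstruction for one presence/absence character
#'
#' Classic unordered two-state Fitch parsimony on a rooted tree:
#' bottom-up state sets per node and the minimum number of state changes.
#' Polytomies are resolved deterministically ([ape::multi2di()] with
#' `random = FALSE`). Tips absent from `tip_states` are an error in
#' strict mode, otherwise treated as unknown (state set \{0, 1\}).
#'
#' @param tree rooted `phylo` tree.
#' @param tip_states named vector (names = tip labels) with values 0, 1
#'   or NA (unknown).
#' @param strict error on tips missing from `tip_states`?
#' @return Object of class `ecr_fitch`: list with `tree` (the possibly
#'   re-resolved tree), `sets` (node x 2 logical matrix, columns
#'   `state0`/`state1`, rows in ape node order), `changes` (minimum
#'   change count) and `tip_states`.
#' @examples
#' tr <- ape::read.tree(text = "((a,b),(c,d));")
#' fitch_reconstruct(tr, c(a = 1, b = 1, c = 0, d = 0))$changes
#' @export
fitch_reconstruct <- function(tree, tip_states, strict = FALSE) {
  tree <- prepare_tree(tree)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  missing_tips <- setdiff(tree$tip.label, names(tip_states))
  if (length(missing_tips)) {
    if (strict) {
      stop_input(sprintf("tip(s) missing from state table: %s",
                         paste(missing_tips, collapse = ", ")))
    }
    tip_states[missing_tips] <- NA
  }
  st <- tip_states[tree$tip.label]
  if (sum(!is.na(st)) < 2L) stop_input("need >= 2 tips with known state")
  if (!all(st %in% c(0, 1, NA))) stop_input("tip states must be 0, 1 or NA")

  sets <- matrix(FALSE, nrow = nnode, ncol = 2L,
                 dimnames = list(NULL, c("state0", "state1")))
  sets[seq_len(ntip), 1L] <- is.na(st) | st == 0
  sets[seq_len(ntip), 2L] <- is.na(st) | st == 1

  edge <- tree$edge
  po <- ape::reorder.phylo(tree, "postorder")$edge
  changes <- 0L
  # process internal nodes child-first
  for (node in unique(po[, 1L])) {
    kids <- edge[edge[, 1L] == node, 2L]
    inter <- rep(TRUE, 2L)
    for (k in kids) inter <- inter & sets[k, ]
    if (any(inter)) {
      sets[node, ] <- inter
    } else {
      uni <- rep(FALSE, 2L)
      for (k in kids) uni <- uni | sets[k, ]
      sets[node, ] <- uni
      changes <- changes + 1L
    }
  }
  structure(list(tree = tree, sets = sets, changes = changes,
                 tip_states = st),
            class = "ecr_fitch")
}

#' @export
print.ecr_fitch <- function(x, ...) {
  cat(sprintf("<ecr_fitch> %d tips, minimum changes: %d\n",
              length(x$tree$tip.label), x$changes))
  invisible(x)
}

#' Assign gains and losses to branches of a Fitch reconstruction
#'
#' Resolves ambiguous node sets top-down: the root takes the state chosen
#' by `root_state_policy` (`"absent"`, the default, prefers state 0 when
#' the root set is ambiguous -- pushing gains toward later branches;
#' `"present"` prefers 1; `"fitch"` is an alias for `"absent"`), and every
#' other node takes its parent's state when that state is in its set.
#' Each state-changing branch is labelled a gain (0 to 1) or a loss
#' (1 to 0); gains + losses always equals the Fitch minimum change count.
#'
#' @param fit an `ecr_fitch` from [fitch_reconstruct()], or a tree (then
#'   `tip_states` must be supplied and the reconstruction is run first).
#' @param tip_states optional, see above.
#' @param root_state_policy `"absent"`, `"present"` or `"fitch"`.
#' @return List with `gains`, `losses`, `root_state`, `node_states`
#'   (resolved 0/1 per node, ape order), `events` (data.frame: `node`
#'   label or id, `parent`, `from`, `to`, `event`) and `tree` with node
#'   labels set to the resolved states (an annotated Newick can be
#'   written with [ape::write.tree()]).
#' @export
count_gain_loss <- function(fit, tip_states = NULL,
                            root_state_policy = c("absent", "present",
                                                  "fitch")) {
  root_state_policy <- match.arg(root_state_policy)
  if (!inherits(fit, "ecr_fitch")) {
    fit <- fitch_reconstruct(fit, tip_states)
  }
  tree <- fit$tree
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  states <- integer(nnode)
  pick <- function(set, prefer) {
    if (set[prefer + 1L]) prefer else (1L - prefer)
  }
  prefer_root <- if (root_state_policy == "present") 1L else 0L
  states[root] <- pick(fit$sets[root, ], prefer_root)
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  for (k in seq_len(nrow(pre))) {
    par <- pre[k, 1L]; child <- pre[k, 2L]
    states[child] <- pick(fit$sets[child, ], states[par])
  }
  pe <- pre[states[pre[, 1L]] != states[pre[, 2L]], , drop = FALSE]
  lab <- function(node) {
    if (node <= ntip) tree$tip.label[node] else sprintf("node%d", node)
  }
  events <- data.frame(
    node = vapply(pe[, 2L], lab, character(1L)),
    parent = vapply(pe[, 1L], lab, character(1L)),
    from = states[pe[, 1L]], to = states[pe[, 2L]],
    stringsAsFactors = FALSE)
  events$event <- ifelse(events$to == 1L, "gain", "loss")
  annotated <- tree
  annotated$node.label <- sprintf("state%d", states[(ntip + 1L):nnode])
  list(gains = sum(events$event == "gain"),
       losses = sum(events$event == "loss"),
       root_state = states[root],
       node_states = states,
       events = events,
       tree = annotated)
}

#' Dollo parsimony count for a single-origin motif
#'
#' Assumes the motif is gained exactly once (on the branch to the most
#' recent common ancestor of the tips carrying it) and counts the losses
#' needed to explain absent tips inside that clade -- appropriate for
#' motifs whose complexity makes repeated independent gain implausible.
#'
#' @param tree rooted `phylo`.
#' @param tip_states named 0/1/NA vector.
#' @return List with `gains` (0 or 1), `losses` and `origin` (node id of
#'   the gain, NA when the motif is absent everywhere).
#' @export
dollo_count <- function(tree, tip_states) {
  tree <- prepare_tree(tree)
  ntip <- length(tree$tip.label)
  st <- tip_states[tree$tip.label]
  present <- which(!is.na(st) & st == 1)
  if (!length(present)) {
    return(list(gains = 0L, losses = 0L, origin = NA_integer_))
  }
  origin <- if (length(present) == 1L) present
            else ape::getMRCA(tree, present)
  # all-absent status per node (over known tips), child-first
  nnode <- ntip + tree$Nnode
  allabs <- rep(NA, nnode)
  hasknown <- rep(FALSE, nnode)
  allabs[seq_len(ntip)] <- !is.na(st) & st == 0
  hasknown[seq_len(ntip)] <- !is.na(st)
  po <- ape::reorder.phylo(tree, "postorder")$edge
  edge <- tree$edge
  for (node in unique(po[, 1L])) {
    kids <- edge[edge[, 1L] == node, 2L]
    known_kids <- kids[hasknown[kids]]
    hasknown[node] <- length(known_kids) > 0L
    allabs[node] <- hasknown[node] && all(allabs[known_kids])
  }
  # losses = maximal all-absent clades strictly inside the origin clade
  in_clade <- rep(FALSE, nnode)
  in_clade[origin] <- TRUE
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  for (k in seq_len(nrow(pre))) {
    if (in_clade[pre[k, 1L]]) in_clade[pre[k, 2L]] <- TRUE
  }
  losses <- 0L
  for (k in seq_len(nrow(pre))) {
    par <- pre[k, 1L]; child <- pre[k, 2L]
    if (in_clade[child] && child != origin &&
        hasknown[child] && isTRUE(allabs[child]) &&
        !(hasknown[par] && isTRUE(allabs[par]))) {
      losses <- losses + 1L
    }
  }
  list(gains = 1L, losses = losses, origin = origin)
}
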