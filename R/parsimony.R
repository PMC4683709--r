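## parsimony: Dollo reconstruction of intron presence/absence on a fixed,
## rooted species tree. Each intron site is gained at most once (at the most
## recent common ancestor of all tips carrying it) and may be lost on any
## number of branches below; the reconstruction minimises the total number
## of presence/absence changes under that single-gain constraint.

#' Default five-taxon species tree
#'
#' `(((("DDB","DPU"),"PPA"),"DFA"),"EHI")` — the focal pair of social
#' amoebae (DDB, DPU), two nearer outgroups (PPA, DFA) and a distant
#' outgroup (EHI).
#'
#' @param text optional alternative newick string.
#' @return a rooted [ape] `phylo` object.
#' @export
default_species_tree <- function(
    text = "((((DDB,DPU),PPA),DFA),EHI);") {
  tr <- ape::read.tree(text = text)
  if (any(duplicated(tr$tip.label))) stop("duplicate tip labels")
  tr
}

## children of each node as a list indexed by node number
tree_children <- function(tree) {
  n_nodes <- max(tree$edge)
  ch <- vector("list", n_nodes)
  for (i in seq_len(nrow(tree$edge))) {
    ch[[tree$edge[i, 1]]] <- c(ch[[tree$edge[i, 1]]], tree$edge[i, 2])
  }
  ch
}

## tips (labels) under each node
tips_under <- function(tree) {
  ntip <- length(tree$tip.label)
  ch <- tree_children(tree)
  n_nodes <- max(tree$edge)
  out <- vector("list", n_nodes)
  rec <- function(v) {
    if (v <= ntip) {
      out[[v]] <<- tree$tip.label[v]
    } else {
      for (c in ch[[v]]) rec(c)
      out[[v]] <<- unlist(lapply(ch[[v]], function(c) out[[c]]))
    }
  }
  rec(ntip + 1L)
  out
}

## label an edge by the tip set below it, e.g. "DPU" or "DDB+DPU"
edge_label <- function(tipset) paste(sort(tipset), collapse = "+")

#' Dollo parsimony reconstruction of one presence/absence profile
#'
#' The single origin is placed at the most recent common ancestor of all
#' tips where the intron is present; losses are the minimal set of edges
#' below that origin whose removal explains every tip where it is absent.
#' `unknown` tips are uninformative: they never force a loss by themselves
#' and never block one.
#'
#' @param profile named character vector over tip labels with values in
#'   `present`, `absent`, `unknown`.
#' @param tree rooted `phylo`; defaults to [default_species_tree()].
#' @return data.frame of events: columns `event` (`gain`/`loss`), `branch`
#'   (edge label = tip set below the edge, "root" for an origin at the
#'   root), `species` (affected tips, "+"-joined).
#' @export
dollo_reconstruct <- function(profile, tree = default_species_tree()) {
  stopifnot(all(names(profile) %in% tree$tip.label))
  state <- stats::setNames(rep("unknown", length(tree$tip.label)),
                           tree$tip.label)
  state[names(profile)] <- profile
  if (!any(state == "present")) stop("all-absent profile: no intron site")

  ntip <- length(tree$tip.label)
  ch <- tree_children(tree)
  below <- tips_under(tree)
  root <- ntip + 1L

  ## origin = MRCA of present tips: descend from the root while a single
  ## child still covers all present tips
  present_tips <- names(state)[state == "present"]
  v <- root
  repeat {
    nxt <- NA_integer_
    for (c in ch[[v]]) if (all(present_tips %in% below[[c]])) nxt <- c
    if (is.na(nxt)) break
    v <- nxt
  }
  origin <- v

  events <- list()
  push <- function(event, node) {
    events[[length(events) + 1L]] <<- data.frame(
      event = event, branch = edge_label(below[[node]]),
      species = edge_label(below[[node]]))
  }
  ev_gain <- data.frame(
    event = "gain",
    branch = if (origin == root) "root" else edge_label(below[[origin]]),
    species = edge_label(below[[origin]]))
  events[[1L]] <- ev_gain

  ## minimal loss edges: cut the edge into any maximal subtree that holds at
  ## least one known-absent tip and no known-present tip
  count_losses <- function(v) {
    st <- state[below[[v]]]
    if (!any(st == "present")) {
      if (any(st == "absent")) push("loss", v)
      return(invisible())
    }
    if (v <= ntip) return(invisible())
    for (c in ch[[v]]) count_losses(c)
  }
  if (origin <= ntip) {
    ## single present tip: nothing below to lose
  } else {
    for (c in ch[[origin]]) count_losses(c)
  }
  do.call(rbind, events)
}

#' Loss calls on focal terminal branches
#'
#' Runs [dollo_reconstruct()] over a table of site profiles and collects
#' losses that fall on the requested terminal branches (by default the two
#' focal species).
#'
#' @param profiles data.frame with a `site_id` column plus one column per
#'   tip label, values in `present`/`absent`/`unknown`.
#' @param tree rooted `phylo`.
#' @param focal character vector of tip labels whose terminal-branch losses
#'   are collected.
#' @return data.frame `site_id`, `species` (one row per terminal loss).
#' @export
loss_calls <- function(profiles, tree = default_species_tree(),
                       focal = c("DDB", "DPU")) {
  tips <- tree$tip.label
  out <- list()
  for (i in seq_len(nrow(profiles))) {
    prof <- stats::setNames(
      as.character(unlist(profiles[i, tips, drop = TRUE])), tips)
    ev <- dollo_reconstruct(prof, tree)
    losses <- ev[ev$event == "loss" & ev$branch %in% focal, , drop = FALSE]
    if (nrow(losses) > 0L) {
      out[[length(out) + 1L]] <- data.frame(
        site_id = profiles$site_id[i], species = losses$branch)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(site_id = character(), species = character()))
  }
  do.call(rbind, out)
}

#' Putative intron-gain calls
#'
#' A gain is called for a focal species iff the intron is present in exactly
#' that species and its absence is positively confirmed (state `absent`,
#' not `unknown`) in all other taxa of the tree. This deliberately stricter
#' criterion than plain Dollo placement guards against recurrent-loss sites
#' masquerading as gains when few outgroups are available.
#'
#' @param profiles as in [loss_calls()].
#' @param tree rooted `phylo`.
#' @return data.frame `site_id`, `species`.
#' @export
putative_gain_calls <- function(profiles, tree = default_species_tree()) {
  tips <- tree$tip.label
  out <- list()
  for (i in seq_len(nrow(profiles))) {
    st <- stats::setNames(
      as.character(unlist(profiles[i, tips, drop = TRUE])), tips)
    pres <- names(st)[st == "present"]
    if (length(pres) == 1L && all(st[setdiff(tips, pres)] == "absent")) {
      out[[length(out) + 1L]] <- data.frame(site_id = profiles$site_id[i],
                                            species = pres)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(site_id = character(), species = character()))
  }
  do.call(rbind, out)
}
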