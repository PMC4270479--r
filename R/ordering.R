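# Parsimony-based ordering of the focal substitutions on a fixed rooted
# phylogeny. The tree is an ape "phylo" as read from Newick; the character
# matrix scores each tip with a single amino-acid letter per focal site.
# The tree is used as rooted in the file — no re-rooting.

# children of every node, from the edge matrix
child_list <- function(tree) {
  n_all <- ape::Ntip(tree) + tree$Nnode
  ch <- vector("list", n_all)
  for (e in seq_len(nrow(tree$edge)))
    ch[[tree$edge[e, 1L]]] <- c(ch[[tree$edge[e, 1L]]], tree$edge[e, 2L])
  ch
}

#' Fitch small parsimony for one site
#'
#' Standard two-pass Fitch reconstruction on a rooted tree: a bottom-up
#' pass building preliminary state sets (intersection when non-empty,
#' otherwise union, counting one change; multifurcations are handled by
#' the state-frequency generalisation), then a top-down pass resolving
#' final state sets. Multi-state sites use full set arithmetic — no
#' binarization.
#'
#' @param tree a rooted `ape::phylo`.
#' @param characters matrix or data frame of single-letter states, rows
#'   named by taxon, columns by site label.
#' @param site column name (or index) of the site to reconstruct.
#' @return list with `score` (minimum number of state changes), `prelim`
#'   and `final` (lists of character state sets indexed like the tree's
#'   nodes: tips `1..Ntip`, then internal nodes).
#' @export
fitch_parsimony <- function(tree, characters, site) {
  stopifnot(inherits(tree, "phylo"))
  characters <- as.matrix(characters)
  tips <- tree$tip.label
  if (!all(tips %in% rownames(characters)))
    stop("unscored tip(s): ",
         paste(setdiff(tips, rownames(characters)), collapse = ", "))
  states <- as.character(characters[tips, site])
  if (anyNA(states) || any(!nzchar(states)))
    stop("missing state at site ", site)
  ntip <- ape::Ntip(tree)
  n_all <- ntip + tree$Nnode
  ch <- child_list(tree)
  prelim <- vector("list", n_all)
  by_union <- logical(n_all)
  prelim[seq_len(ntip)] <- as.list(states)
  score <- 0L
  # parents in order of first appearance in the postorder edge list:
  # every node comes after all of its descendants
  post <- unique(ape::reorder.phylo(tree, "postorder")$edge[, 1L])
  for (u in post) {
    kids <- ch[[u]]
    tab <- table(unlist(prelim[kids]))
    k <- max(tab)
    prelim[[u]] <- sort(names(tab)[tab == k])
    by_union[u] <- k < length(kids)   # no state shared by all children
    score <- score + (length(kids) - k)
  }
  # top-down resolution (Fitch's second-pass rules)
  root <- ntip + 1L
  final <- vector("list", n_all)
  final[[root]] <- prelim[[root]]
  pre <- rev(post)                    # parents before children
  for (u in pre) {
    for (v in ch[[u]]) {
      if (v <= ntip) { final[[v]] <- prelim[[v]]; next }
      if (all(final[[u]] %in% prelim[[v]])) {
        final[[v]] <- final[[u]]
      } else if (by_union[v]) {
        final[[v]] <- sort(union(prelim[[v]], final[[u]]))
      } else {
        kid_union <- sort(unique(unlist(prelim[ch[[v]]])))
        final[[v]] <- sort(union(prelim[[v]],
                                 intersect(final[[u]], kid_union)))
      }
    }
  }
  list(score = score, prelim = prelim, final = final)
}

#' Place focal substitutions on the root-to-tip path of one lineage
#'
#' For each focal site whose state differs between the resolved root state
#' and the focal tip, identifies the candidate branch(es) on the
#' root-to-tip path where the derived state arose under the Fitch
#' reconstruction. When the reconstruction is ambiguous the full candidate
#' set is reported — no silent accelerated/delayed choice is made. Sites
#' whose root reconstruction already contains the tip state are excluded
#' (no change required on the focal path) and listed in `excluded`.
#'
#' @inheritParams fitch_parsimony
#' @param focal_tip tip label of the lineage of interest.
#' @param sites site labels to place; default all columns of `characters`.
#' @return object of class `"substitution_placement"`: list with
#'   `path` (node indices root to tip), `placements` (per changed site: the
#'   ancestral and derived states and the candidate branch positions, 1 =
#'   branch leaving the root), and `excluded` (sites with no required
#'   change, with a note).
#' @export
place_substitutions <- function(tree, characters, focal_tip,
                                sites = colnames(characters)) {
  stopifnot(inherits(tree, "phylo"))
  characters <- as.matrix(characters)
  tip_idx <- match(focal_tip, tree$tip.label)
  if (is.na(tip_idx)) stop("focal tip not in tree: ", focal_tip)
  root <- ape::Ntip(tree) + 1L
  path <- ape::nodepath(tree, root, tip_idx)
  placements <- list()
  excluded <- character(0)
  for (s in sites) {
    fp <- fitch_parsimony(tree, characters, s)
    F <- fp$final[path]
    t_state <- as.character(characters[focal_tip, s])
    if (t_state %in% F[[1L]]) {
      excluded <- c(excluded,
                    structure(sprintf("root state set {%s} already contains %s; no change required on focal path",
                                      paste(F[[1L]], collapse = ","), t_state),
                              names = s))
      next
    }
    cand <- integer(0)
    for (i in seq_len(length(path) - 1L)) {
      gains <- t_state %in% F[[i + 1L]]
      loses <- any(F[[i]] != t_state)
      if (gains && loses) cand <- c(cand, i)
    }
    placements[[s]] <- list(
      site = s,
      from = setdiff(F[[1L]], t_state),
      to = t_state,
      branches = cand
    )
  }
  structure(list(path = path, placements = placements, excluded = excluded,
                 tree = tree, focal_tip = focal_tip),
            class = "substitution_placement")
}

#' @export
print.substitution_placement <- function(x, ...) {
  cat(sprintf("substitutions on the %s lineage (%d branches):\n",
              x$focal_tip, length(x$path) - 1L))
  for (p in x$placements)
    cat(sprintf("  %s: %s -> %s on branch%s %s\n", p$site,
                paste(p$from, collapse = "/"), p$to,
                if (length(p$branches) > 1L) "es" else "",
                paste(p$branches, collapse = ",")))
  if (length(x$excluded))
    cat("  excluded:", paste(names(x$excluded), collapse = ", "), "\n")
  invisible(x)
}

#' Branch-wise partial orders implied by a substitution placement
#'
#' Groups the placed sites by branch (root-most group first). Sites with a
#' unique candidate branch yield a single partial order; ambiguous sites
#' multiply out into every consistent assignment, all of which are
#' returned.
#'
#' @param placement a [place_substitutions()] result.
#' @return list of partial orders; each is a list of character vectors of
#'   site labels, ordered root-most first.
#' @export
partial_orders <- function(placement) {
  stopifnot(inherits(placement, "substitution_placement"))
  pl <- placement$placements
  if (!length(pl)) return(list())
  cand <- lapply(pl, `[[`, "branches")
  grid <- expand.grid(cand, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  names(grid) <- vapply(pl, `[[`, character(1L), "site")
  out <- lapply(seq_len(nrow(grid)), function(i) {
    assign <- unlist(grid[i, , drop = FALSE])
    branches <- sort(unique(assign))
    lapply(branches, function(b) names(assign)[assign == b])
  })
  unique(out)
}

#' Count and enumerate linear extensions of a branch-wise partial order
#'
#' Mutations within a group occurred on one branch in unknown order;
#' groups occurred strictly in sequence. The consistent total orderings
#' are the concatenations of within-group permutations, so their count is
#' the product of the group-size factorials.
#'
#' @param partial_order list of disjoint character vectors, root-most
#'   group first.
#' @param enumerate logical; also return the orderings themselves.
#' @return list with `count` and (when `enumerate = TRUE`) `orderings`, a
#'   character matrix with one ordering per row.
#' @examples
#' linear_extensions(list(c("a", "b"), "c", c("d", "e")))$count  # 4
#' @export
linear_extensions <- function(partial_order, enumerate = FALSE) {
  flat <- unlist(partial_order)
  if (anyDuplicated(flat)) stop("groups must be disjoint")
  count <- prod(factorial(lengths(partial_order)))
  out <- list(count = count)
  if (enumerate) {
    M <- matrix(character(0), 1L, 0L)
    for (g in partial_order) {
      gp <- permutations(seq_along(g))
      gp <- matrix(g[gp], nrow(gp), ncol(gp))
      M <- do.call(rbind, lapply(seq_len(nrow(M)), function(i)
        cbind(matrix(M[i, ], nrow(gp), ncol(M), byrow = TRUE), gp,
              deparse.level = 0L)))
    }
    out$orderings <- M
  }
  out
}
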