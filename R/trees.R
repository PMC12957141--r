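## Tree preparation: Newick I/O and the algorithms applied to host and
## parasite phylogenies before any diversity computation. Trees are ape
## "phylo" objects throughout; an optional root.edge carries the depth of a
## pruned subtree's stem so that evolutionary periods keep their full-tree
## context.

#' Read a Newick tree
#'
#' Parses a single Newick string into an [ape::phylo] object. Branch lengths
#' absent from the string default to 1, the convention used when a tree is
#' assembled from taxonomic topology alone and no length information exists.
#'
#' @param text A Newick string (terminated by `;`).
#' @return A rooted `phylo` object with unique, non-empty tip labels.
#' @examples
#' tr <- readNewick("((A:1,B:1):1,C:2);")
#' treeHeight(tr)
#' @export
readNewick <- function(text) {
  stopIfNot(is.character(text) && length(text) == 1L, "'text' must be a single string")
  text <- trimws(text)
  checkNewickSyntax(text)
  tr <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("Newick parse error: input could not be interpreted as a tree", call. = FALSE)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip label(s): ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(tr$tip.label)))
    stop("empty tip label in Newick input", call. = FALSE)
  if (is.null(tr$edge.length)) {
    tr$edge.length <- rep(1, nrow(tr$edge))
  } else if (anyNA(tr$edge.length)) {
    tr$edge.length[is.na(tr$edge.length)] <- 1
  }
  if (any(tr$edge.length < 0))
    stop("negative branch length in Newick input", call. = FALSE)
  tr
}

## Balanced-parenthesis pre-check so parse errors carry a position.
checkNewickSyntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse error at position ", i, ": unmatched ')'", call. = FALSE)
    }
  }
  if (depth > 0L)
    stop("Newick parse error at position ", nchar(text),
         ": ", depth, " unclosed '('", call. = FALSE)
  if (!grepl(";\\s*$", text))
    stop("Newick parse error at position ", nchar(text),
         ": missing terminating ';'", call. = FALSE)
  invisible(TRUE)
}

#' Write a tree as Newick
#'
#' @param tree A `phylo` object.
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string (invisibly when written to a file).
#' @export
writeNewick <- function(tree, file = NULL, digits = 12) {
  txt <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Read a sample of Newick trees (one per line)
#'
#' @param path File with one Newick tree per line.
#' @return A list of `phylo` objects.
#' @export
readTreeSample <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, readNewick)
}

#' Height of a tree
#'
#' Maximum root-to-tip path length, excluding any stem (`root.edge`) unless
#' requested.
#'
#' @param tree A `phylo` object.
#' @param includeRootEdge Add the stem length (`tree$root.edge`), if present.
#' @return A single number.
#' @export
treeHeight <- function(tree, includeRootEdge = FALSE) {
  h <- max(ape::node.depth.edgelength(tree))
  if (includeRootEdge) h <- h + (tree$root.edge %||% 0)
  h
}

#' Is a tree ultrametric?
#'
#' All root-to-tip path lengths equal within a relative tolerance.
#'
#' @param tree A `phylo` object.
#' @param tol Relative tolerance on the spread of tip depths.
#' @return Logical.
#' @export
isUltrametric <- function(tree, tol = 1e-8) {
  nd <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  h <- max(nd)
  if (h == 0) return(TRUE)
  (h - min(nd)) / h <= tol
}

#' Node ages of an ultrametric tree
#'
#' Tips have age 0; the root has the maximal age (the tree height); the age of
#' a parent equals the age of any child plus that child's branch length.
#'
#' @param tree An ultrametric `phylo` object.
#' @param tol Relative ultrametricity tolerance.
#' @return Named numeric vector over all nodes (tips first, then internal
#'   nodes; internal nodes are named by their node labels when present,
#'   otherwise `node<k>`).
#' @export
nodeAges <- function(tree, tol = 1e-8) {
  if (!isUltrametric(tree, tol))
    stop("tree is not ultrametric; node ages are undefined", call. = FALSE)
  nd <- ape::node.depth.edgelength(tree)
  h <- max(nd[seq_len(ape::Ntip(tree))])
  ages <- pmax(h - nd, 0)
  nlab <- tree$node.label
  if (is.null(nlab) || any(!nzchar(nlab)))
    nlab <- paste0("node", ape::Ntip(tree) + seq_len(tree$Nnode))
  names(ages) <- c(tree$tip.label, nlab)
  ages
}

#' Ultrametrize a tree by extending terminal branches
#'
#' Each terminal branch is extended by the difference between the maximal
#' root-to-tip depth and its tip's depth; internal branches are unchanged.
#' Idempotent.
#'
#' @param tree A rooted `phylo` object with branch lengths.
#' @return An ultrametric `phylo` object.
#' @export
forceUltrametricExtend <- function(tree) {
  stopIfNot(!is.null(tree$edge.length), "tree has no branch lengths")
  nd <- ape::node.depth.edgelength(tree)
  ntip <- ape::Ntip(tree)
  h <- max(nd[seq_len(ntip)])
  term <- tree$edge[, 2] <= ntip
  tipOfEdge <- tree$edge[term, 2]
  tree$edge.length[term] <- tree$edge.length[term] + (h - nd[tipOfEdge])
  tree
}

#' Resolve polytomies into a binary tree
#'
#' Multifurcations are replaced by randomly ordered binary splits joined by
#' zero-length branches, so all pairwise tip path lengths (and hence
#' ultrametricity) are preserved exactly.
#'
#' @param tree A rooted `phylo` object.
#' @param seed Integer seed controlling the randomized split order.
#' @return A strictly bifurcating `phylo` object.
#' @export
resolvePolytomies <- function(tree, seed = 1L) {
  if (ape::is.binary(tree)) return(tree)
  withSeed(seed, ape::multi2di(tree, random = TRUE))
}

## Map each edge of a rooted tree to the sorted set of tip labels below it.
cladeSets <- function(tree) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  below <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  keys <- character(nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge)))
    keys[e] <- paste(sort(below[[tree$edge[e, 2]]]), collapse = "\x1f")
  keys
}

#' Majority-rule consensus with averaged edge lengths
#'
#' Builds the majority-rule (>50%) consensus topology of a sample of rooted
#' trees on one tip set and assigns to each retained edge the mean length of
#' that edge over the trees containing the corresponding clade.
#'
#' @param trees A list (or `multiPhylo`) of rooted `phylo` objects with
#'   identical tip sets.
#' @return A `phylo` object with edge lengths.
#' @export
consensusWithEdges <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  stopIfNot(length(trees) >= 1L, "need at least one tree")
  tips <- sort(trees[[1]]$tip.label)
  for (tr in trees)
    if (!identical(sort(tr$tip.label), tips))
      stop("trees have different tip sets", call. = FALSE)
  if (length(trees) == 1L) return(trees[[1]])
  class(trees) <- "multiPhylo"
  cons <- ape::consensus(trees, p = 0.5, rooted = TRUE)
  # mean edge length per clade over the trees that contain it
  acc <- new.env(parent = emptyenv())
  for (tr in trees) {
    keys <- cladeSets(tr)
    for (e in seq_along(keys)) {
      cur <- get0(keys[e], envir = acc, ifnotfound = c(0, 0))
      assign(keys[e], cur + c(tr$edge.length[e], 1), envir = acc)
    }
  }
  ckeys <- cladeSets(cons)
  el <- numeric(length(ckeys))
  for (e in seq_along(ckeys)) {
    cur <- get0(ckeys[e], envir = acc, ifnotfound = NULL)
    if (is.null(cur))
      stop("consensus clade not found in any input tree", call. = FALSE)
    el[e] <- cur[1] / cur[2]
  }
  cons$edge.length <- el
  cons
}

#' Convert a taxonomic rank table to a quasi-phylogenetic tree
#'
#' Builds the four-level rank tree (family, subfamily, genus, species) with
#' every edge of length 1, used as a proxy phylogeny when no molecular tree
#' exists. Two congeneric species sit at cophenetic distance 2, two species
#' sharing only a subfamily at 4, only a family at 6, and members of
#' different families at 8. Single-child rank nodes are retained, so the tree
#' is ultrametric with height 4 by construction.
#'
#' @param taxonomy Data frame with character columns `species`, `genus`,
#'   `subfamily`, `family`.
#' @return An ultrametric `phylo` object of height 4 with labelled internal
#'   nodes.
#' @export
taxonomyToTree <- function(taxonomy) {
  need <- c("species", "genus", "subfamily", "family")
  stopIfNot(all(need %in% names(taxonomy)),
            "taxonomy must have columns species, genus, subfamily, family")
  tt <- as.data.frame(lapply(taxonomy[need], as.character),
                      stringsAsFactors = FALSE)
  if (anyNA(tt) || any(!nzchar(unlist(tt))))
    stop("taxonomy table has missing rank assignments", call. = FALSE)
  if (anyDuplicated(tt$species))
    stop("duplicate species in taxonomy table", call. = FALSE)
  # consistent nesting: each genus in one subfamily, each subfamily in one family
  gmap <- unique(tt[c("genus", "subfamily")])
  if (anyDuplicated(gmap$genus))
    stop("inconsistent taxonomy: genus assigned to multiple subfamilies: ",
         paste(gmap$genus[duplicated(gmap$genus)], collapse = ", "), call. = FALSE)
  smap <- unique(tt[c("subfamily", "family")])
  if (anyDuplicated(smap$subfamily))
    stop("inconsistent taxonomy: subfamily assigned to multiple families: ",
         paste(smap$subfamily[duplicated(smap$subfamily)], collapse = ", "),
         call. = FALSE)

  nsp <- nrow(tt)
  fams <- unique(tt$family)
  subf <- unique(tt$subfamily)
  gens <- unique(tt$genus)
  # node ids: tips 1..nsp, root nsp+1, then families, subfamilies, genera
  rootId <- nsp + 1L
  famId <- stats::setNames(rootId + seq_along(fams), fams)
  subId <- stats::setNames(rootId + length(fams) + seq_along(subf), subf)
  genId <- stats::setNames(rootId + length(fams) + length(subf) + seq_along(gens), gens)
  edges <- rbind(
    cbind(rootId, famId[fams]),
    cbind(famId[smap$family], subId[smap$subfamily]),
    cbind(subId[gmap$subfamily], genId[gmap$genus]),
    cbind(genId[tt$genus], seq_len(nsp))
  )
  tr <- structure(list(
    edge = unname(edges),
    edge.length = rep(1, nrow(edges)),
    tip.label = tt$species,
    node.label = c("root", fams, subf, gens),
    Nnode = 1L + length(fams) + length(subf) + length(gens)
  ), class = "phylo", order = "cladewise")
  tr
}

#' Prune a tree to a tip subset, keeping full-tree depth
#'
#' Returns the induced subtree on `tips` with unbranched paths collapsed
#' (lengths summed). The distance from the original root down to the subtree
#' is kept as the stem (`root.edge`), so tip ages relative to the full tree's
#' root are preserved. This matters for phylogenetic niche breadth: an
#' assemblage of two congeners in a deep tree must keep the deep-time context
#' in which it is a single lineage.
#'
#' @param tree A rooted `phylo` object.
#' @param tips Character vector of tip labels to keep (non-empty subset).
#' @return A `phylo` object whose height including `root.edge` equals the
#'   original height spanned by the retained tips.
#' @export
pruneKeepDepth <- function(tree, tips) {
  tips <- unique(as.character(tips))
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown))
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  stopIfNot(length(tips) >= 1L, "need at least one tip")
  base <- tree$root.edge %||% 0
  if (length(tips) == ape::Ntip(tree)) return(tree)
  nd <- ape::node.depth.edgelength(tree)
  if (length(tips) == 1L) {
    depth <- nd[match(tips, tree$tip.label)]
    out <- structure(list(
      edge = matrix(c(2L, 1L), 1, 2),
      edge.length = depth,
      tip.label = tips,
      Nnode = 1L
    ), class = "phylo", order = "cladewise")
    if (base > 0) out$root.edge <- base
    return(out)
  }
  mrca <- ape::getMRCA(tree, tips)
  stem <- nd[mrca]
  out <- ape::keep.tip(tree, tips)
  if (stem + base > 0) out$root.edge <- stem + base
  out
}
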