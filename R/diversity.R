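## The two niche-breadth statistics: Rao's quadratic functional diversity Q
## and tree-slicing phylogenetic diversity D_P of a parasite's host
## assemblage.

#' Rao's quadratic diversity of a host assemblage
#'
#' With presence/absence data each of the S hosts gets weight 1/S and
#' \deqn{Q = \frac{1}{S^2}\sum_i \sum_j d_{ij}.}
#' Q is 0 for a single host and bounded above by \eqn{(S-1)/S} when all
#' dissimilarities are at their maximum of 1.
#'
#' @param hosts Character vector of host labels (the assemblage).
#' @param d Symmetric dissimilarity matrix with host labels as dimnames,
#'   e.g. from [gowerMatrix()].
#' @return A single number in \[0, (S-1)/S\].
#' @examples
#' d <- matrix(1, 4, 4) - diag(4)
#' dimnames(d) <- list(letters[1:4], letters[1:4])
#' raoQ(letters[1:4], d)  # 0.75
#' @export
raoQ <- function(hosts, d) {
  hosts <- unique(as.character(hosts))
  stopIfNot(length(hosts) >= 1L, "assemblage must contain at least one host")
  missing <- setdiff(hosts, rownames(d))
  if (length(missing))
    stop("host(s) missing from the dissimilarity matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  S <- length(hosts)
  sum(d[hosts, hosts, drop = FALSE]) / S^2
}

#' Tree-slicing phylogenetic diversity of a host assemblage
#'
#' The ultrametric tree is segmented at its node ages into evolutionary
#' periods. Within each period the number of distinct lineages ancestral to
#' the assemblage's hosts is counted (lineage richness, evaluated at the
#' period midpoint, where it is constant). The period diversities are then
#' averaged over the tree height with weights proportional to period
#' duration:
#' \deqn{D_P = \sum_k \frac{t_k - t_{k-1}}{T} D_k.}
#' \eqn{D_P} is 1 for a single host, equals S on a star tree, and
#' approaches 1 for a pair of close relatives in a deep tree. If the tree
#' carries a stem (`root.edge`, e.g. from [pruneKeepDepth()]), the stem
#' segment counts as one lineage and the height T includes it, so depth
#' context from a larger tree is preserved.
#'
#' @param hosts Character vector of host tip labels.
#' @param tree An ultrametric `phylo` object whose tips include `hosts`.
#' @param weighting `"duration"` (default) weights each period by its length;
#'   `"equal"` takes the unweighted mean over periods.
#' @param tol Relative ultrametricity tolerance.
#' @return A single number in \[1, S\].
#' @examples
#' tr <- readNewick("((A:1,B:1):1,C:2);")
#' phyloDP(c("A", "B", "C"), tr)  # 2.5
#' @export
phyloDP <- function(hosts, tree, weighting = c("duration", "equal"), tol = 1e-8) {
  weighting <- match.arg(weighting)
  hosts <- unique(as.character(hosts))
  stopIfNot(length(hosts) >= 1L, "assemblage must contain at least one host")
  unknown <- setdiff(hosts, tree$tip.label)
  if (length(unknown))
    stop("host(s) not in the tree: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!isUltrametric(tree, tol))
    stop("tree is not ultrametric", call. = FALSE)

  ntip <- ape::Ntip(tree)
  nd <- ape::node.depth.edgelength(tree)
  H <- max(nd[seq_len(ntip)])
  stem <- tree$root.edge %||% 0
  Tfull <- H + stem
  if (Tfull <= 0) return(1)
  age <- pmax(H - nd, 0)
  age[seq_len(ntip)] <- 0  # ultrametric within tol: snap tips to zero

  # which nodes have at least one assemblage host below them
  hasHost <- logical(ntip + tree$Nnode)
  hasHost[match(hosts, tree$tip.label)] <- TRUE
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    if (hasHost[ch]) hasHost[p] <- TRUE
  }

  # period boundaries: distinct node ages (zero-length edges collapse), plus stem
  bounds <- sort(unique(c(0, age[-seq_len(ntip)], Tfull)))
  keep <- c(TRUE, diff(bounds) > tol * max(Tfull, 1))
  bounds <- bounds[keep]
  if (length(bounds) < 2L) return(1)
  mids <- (bounds[-1] + bounds[-length(bounds)]) / 2
  lens <- diff(bounds)

  aChild <- age[tree$edge[, 2]]
  aParent <- age[tree$edge[, 1]]
  anc <- hasHost[tree$edge[, 2]]
  Dk <- vapply(mids, function(m) {
    k <- sum(anc & aChild < m & m < aParent)
    if (m > age[ntip + 1L]) k <- k + 1L  # stem segment above the root
    max(k, 1L)
  }, numeric(1))
  if (weighting == "duration") sum(lens * Dk) / Tfull else mean(Dk)
}

#' Niche-breadth table for all parasites at both scales
#'
#' Computes, for every parasite, one record per region it occurs in plus one
#' continental record (host set = union over regions), each with host count
#' S, phylogenetic niche breadth D_P and functional niche breadth Q. D_P is
#' computed on the host tree pruned to the relevant scale's host pool with
#' the full-tree depth retained (see [pruneKeepDepth()]).
#'
#' @param inc An [IncidenceSet-class] (use the result of [applyFilters()] to
#'   honour the host-count filtering rules at each scale).
#' @param tree Ultrametric host phylogeny covering all hosts.
#' @param d Host dissimilarity matrix from [gowerMatrix()].
#' @param weighting Passed to [phyloDP()].
#' @return data.frame with columns `parasite`, `scale` (region name or
#'   `"continental"`), `S`, `DP`, `Q`.
#' @export
nicheBreadthTable <- function(inc, tree, d, weighting = "duration") {
  regRec <- regionalRecords(inc)
  conRec <- continentalRecords(inc)
  allHosts <- unique(c(regRec$host, conRec$host))
  unknown <- setdiff(allHosts, tree$tip.label)
  if (length(unknown))
    stop("host(s) missing from the host tree: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  unknown <- setdiff(allHosts, rownames(d))
  if (length(unknown))
    stop("host(s) missing from the dissimilarity matrix: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  rows <- list()
  oneScale <- function(records, scaleName) {
    if (!nrow(records)) return(NULL)
    pool <- unique(records$host)
    poolTree <- pruneKeepDepth(tree, pool)
    hostSets <- lapply(split(records$host, records$parasite), unique)
    data.frame(
      parasite = names(hostSets),
      scale = scaleName,
      S = vapply(hostSets, length, integer(1)),
      DP = vapply(hostSets, phyloDP, numeric(1),
                  tree = poolTree, weighting = weighting),
      Q = vapply(hostSets, raoQ, numeric(1), d = d),
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  for (rg in sort(unique(regRec$region)))
    rows[[length(rows) + 1L]] <- oneScale(regRec[regRec$region == rg, ], rg)
  rows[[length(rows) + 1L]] <- oneScale(conRec, "continental")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
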