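# Independent brute-force oracles and small fixture builders used across the
# test files. Every oracle is written directly from the defining formula and
# shares no code with the package internals it checks.

# Gower dissimilarity by an explicit double loop over species pairs.
gowerBrute <- function(df, types, weights = NULL) {
  n <- nrow(df)
  if (is.null(weights)) weights <- stats::setNames(rep(1, ncol(df)), names(df))
  rng <- lapply(names(df), function(cn) {
    if (types[[cn]] %in% c("quantitative", "ordinal"))
      diff(range(df[[cn]], na.rm = TRUE)) else NA_real_
  })
  names(rng) <- names(df)
  d <- matrix(0, n, n, dimnames = list(rownames(df), rownames(df)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- 0; den <- 0
    for (cn in names(df)) {
      xi <- df[[cn]][i]; xj <- df[[cn]][j]
      if (is.na(xi) || is.na(xj)) next
      if (types[[cn]] %in% c("quantitative", "ordinal")) {
        if (rng[[cn]] == 0) next
        s <- abs(xi - xj) / rng[[cn]]
      } else {
        lev <- unique(stats::na.omit(as.character(df[[cn]])))
        if (length(lev) < 2) next
        s <- as.numeric(as.character(xi) != as.character(xj))
      }
      num <- num + weights[[cn]] * s
      den <- den + weights[[cn]]
    }
    d[i, j] <- num / den
  }
  d
}

# Rao's Q by the explicit double sum.
raoBrute <- function(hosts, d) {
  S <- length(hosts)
  acc <- 0
  for (a in hosts) for (b in hosts) acc <- acc + d[a, b]
  acc / S^2
}

# Brownian covariance by summing shared root-path edges for every tip pair.
vcvBrute <- function(tree) {
  nt <- ape::Ntip(tree)
  rootPath <- function(tip) {
    # edge indices from tip up to the root
    path <- integer(0)
    node <- tip
    repeat {
      e <- which(tree$edge[, 2] == node)
      if (!length(e)) break
      path <- c(path, e)
      node <- tree$edge[e, 1]
    }
    path
  }
  paths <- lapply(seq_len(nt), rootPath)
  V <- matrix(0, nt, nt, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    shared <- intersect(paths[[i]], paths[[j]])
    V[i, j] <- sum(tree$edge.length[shared])
  }
  V + (if (is.null(tree$root.edge)) 0 else tree$root.edge)
}

# All-pairs tip path-length matrix by brute force over root paths.
copheneticBrute <- function(tree) {
  V <- vcvBrute(tree)
  D <- outer(diag(V), diag(V), "+") - 2 * V
  D
}

# Closed-form REML for the BALANCED one-way random-intercept model
# (expected mean squares; the REML solution when the estimate is interior).
remlBalanced <- function(y, g) {
  g <- as.character(g)
  k <- length(unique(g))
  n0 <- length(y) / k
  gm <- tapply(y, g, mean)
  msb <- n0 * sum((gm - mean(y))^2) / (k - 1)
  msw <- sum((y - gm[g])^2) / (length(y) - k)
  list(sigma2Between = max(0, (msb - msw) / n0), sigma2Within = msw)
}

# GLS estimate by the explicit-inverse textbook formula.
glsBrute <- function(y, X, V) {
  Vi <- solve(V)
  solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi %*% y
}

# Lineage count of `hosts` at time `age` above the tips, walking each host
# tip towards the root and recording which edge spans that age (independent
# of the package's edge-sweep implementation).
lineagesAtAge <- function(tree, hosts, age) {
  nd <- ape::node.depth.edgelength(tree)
  H <- max(nd[seq_len(ape::Ntip(tree))])
  nodeAge <- H - nd
  hit <- character(0)
  for (h in hosts) {
    node <- match(h, tree$tip.label)
    repeat {
      e <- which(tree$edge[, 2] == node)
      if (!length(e)) { hit <- c(hit, "stem"); break }
      par <- tree$edge[e, 1]
      if (nodeAge[node] <= age && age < nodeAge[par]) {
        hit <- c(hit, as.character(e)); break
      }
      node <- par
    }
  }
  length(unique(hit))
}

# D_P by integrating brute-force lineage counts over a fine grid (valid
# because counts are piecewise constant between node ages).
dpBrute <- function(tree, hosts, nGrid = 20000) {
  stopifnot(is.null(tree$root.edge))
  nd <- ape::node.depth.edgelength(tree)
  H <- max(nd[seq_len(ape::Ntip(tree))])
  mids <- (seq_len(nGrid) - 0.5) * H / nGrid
  mean(vapply(mids, function(m) lineagesAtAge(tree, hosts, m), numeric(1)))
}

# Small random ultrametric tree for property tests.
randUltraTree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rcoal(n)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

# Toy incidence records used by the pipeline tests.
toyRecords <- function() {
  rbind(
    data.frame(region = "R1", parasite = "p1", host = c("A", "B", "C"),
               abundance = c(1, 2, 3)),
    data.frame(region = "R1", parasite = "p2", host = c("A", "B"),
               abundance = c(5, 1)),
    data.frame(region = "R2", parasite = "p1", host = c("B", "C", "D"),
               abundance = c(2, 1, 4)),
    data.frame(region = "R2", parasite = "p2", host = c("C", "D"),
               abundance = c(2, 2)),
    data.frame(region = "R2", parasite = "p3", host = c("A", "B"),
               abundance = c(1, 1))
  )
}
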