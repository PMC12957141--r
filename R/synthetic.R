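## Synthetic survey-data generator: produces host/parasite trees, mixed-type
## host traits, region-structured incidence records with tunable
## phylogenetic clustering of each parasite's hosts, and parasite
## abundance/body-size variables with known log-log links to niche breadth,
## so every stage of the pipeline is testable without any external dataset.

#' Default simulation configuration
#'
#' Returns the named list of generator settings. Sizes are desk-scale
#' stand-ins for a multi-region ectoparasite survey; the dependence
#' parameters are chosen to reproduce the statistical structure such data
#' exhibit (weak within-species repeatability of regional niche breadth, a
#' positive continental abundance-breadth slope on the log-log scale,
#' phylogenetic signal in species-level residuals).
#'
#' @param ... Overrides of the defaults.
#' @return Named list.
#' @export
simulationConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    nHosts = 40L,        # host species in the pool
    nParasites = 60L,    # parasite species
    nRegions = 15L,      # survey regions
    birthRate = 1,       # pure-birth rate for both trees (height rescaled to 1)
    nQuantTraits = 7L, nOrdinalTraits = 1L,
    nCategoricalTraits = 3L, nBinaryTraits = 2L,   # 13 traits total
    theta = 8,           # phylogenetic concentration of host choice
    targetICC = 0.12,    # within-species repeatability of regional breadth
    meanHosts = 6,       # typical per-region host-set size
    sizeLogSD = 0.5,     # total SD of log host-set size
    pRegion = 0.4,       # chance a parasite is recorded in a region
    aCA = 0, bCA = 0.3, sdCA = 0.3,     # log CA = aCA + bCA * log DP + eps
    aBS = 0, bBS = -0.2, sdBS = 0.2,    # log BS = aBS + bBS * log DP + eps
    lambdaResid = 0.5    # Pagel lambda of the parasite-level residuals
  )
  override <- list(...)
  for (nm in names(override)) cfg[[nm]] <- override[[nm]]
  stopIfNot(cfg$nHosts >= 5 && cfg$nParasites >= 4 && cfg$nRegions >= 2,
            "counts below minimum viable sizes")
  stopIfNot(cfg$theta >= 0 && cfg$sdCA >= 0 && cfg$sdBS >= 0,
            "theta and noise SDs must be non-negative")
  stopIfNot(cfg$targetICC >= 0 && cfg$targetICC < 1,
            "targetICC must lie in [0, 1)")
  cfg
}

#' Simulate an ultrametric pure-birth host tree
#'
#' @param cfg From [simulationConfig()].
#' @return Ultrametric `phylo` with `cfg$nHosts` tips, height 1, tip labels
#'   `H001`, `H002`, ...
#' @export
simulateHostTree <- function(cfg = simulationConfig()) {
  tr <- withSeed(cfg$seed,
                 ape::rphylo(cfg$nHosts, birth = cfg$birthRate, death = 0))
  tr$edge.length <- tr$edge.length / treeHeight(tr)
  tr$tip.label <- sprintf("H%03d", seq_len(cfg$nHosts))
  tr
}

simulateParasiteTree <- function(cfg = simulationConfig()) {
  tr <- withSeed(childSeed(cfg$seed, 101),
                 ape::rphylo(cfg$nParasites, birth = cfg$birthRate, death = 0))
  tr$edge.length <- tr$edge.length / treeHeight(tr)
  tr$tip.label <- sprintf("P%03d", seq_len(cfg$nParasites))
  tr
}

#' Simulate mixed-type host traits on a tree
#'
#' Quantitative traits evolve by unit-rate Brownian motion; categorical and
#' binary traits by a symmetric Markov switching process (rate 1); each
#' ordinal trait discretizes a Brownian trait into 5 ranks.
#'
#' @param tree Host tree.
#' @param cfg From [simulationConfig()].
#' @return A [TraitTable-class].
#' @export
simulateTraits <- function(tree, cfg = simulationConfig()) {
  withSeed(childSeed(cfg$seed, 102), {
    n <- ape::Ntip(tree)
    cols <- list(); types <- character()
    for (i in seq_len(cfg$nQuantTraits)) {
      nm <- paste0("q", i)
      cols[[nm]] <- ape::rTraitCont(tree, model = "BM", sigma = 1)
      types[nm] <- "quantitative"
    }
    for (i in seq_len(cfg$nOrdinalTraits)) {
      nm <- paste0("ord", i)
      z <- ape::rTraitCont(tree, model = "BM", sigma = 1)
      cols[[nm]] <- as.integer(cut(z, breaks = stats::quantile(
        z, probs = seq(0, 1, length.out = 6)), include.lowest = TRUE))
      types[nm] <- "ordinal"
    }
    for (i in seq_len(cfg$nCategoricalTraits)) {
      nm <- paste0("cat", i)
      cols[[nm]] <- paste0("lvl", as.character(
        ape::rTraitDisc(tree, model = "ER", k = 3, rate = 1)))
      types[nm] <- "categorical"
    }
    for (i in seq_len(cfg$nBinaryTraits)) {
      nm <- paste0("bin", i)
      cols[[nm]] <- c("no", "yes")[as.integer(
        ape::rTraitDisc(tree, model = "ER", k = 2, rate = 1))]
      types[nm] <- "binary"
    }
    df <- as.data.frame(cols, stringsAsFactors = FALSE)
    rownames(df) <- tree$tip.label
    traitTable(df, types)
  })
}

## Draw the incidence records at a fixed between/within split of the
## log-size variance; the core used both by the pilot calibration and the
## final draw.
drawIncidence <- function(tree, cfg, fBetween, seed) {
  withSeed(seed, {
    hosts <- tree$tip.label
    nH <- length(hosts)
    D <- ape::cophenetic.phylo(tree)
    nP <- cfg$nParasites; nR <- cfg$nRegions
    par <- sprintf("P%03d", seq_len(nP))
    # region host faunas: each region holds a random subset of the pool
    pools <- lapply(seq_len(nR), function(r)
      sample(hosts, max(5L, round(stats::runif(1, 0.55, 0.9) * nH))))
    focal <- sample(hosts, nP, replace = TRUE)
    # fBetween splits the species-persistent vs region-local share of the
    # within-species structure: the log host-set size variance, and the
    # chance that the focal host is retained (vs shifted) in a region
    tauB <- sqrt(fBetween) * cfg$sizeLogSD
    tauW <- sqrt(1 - fBetween) * cfg$sizeLogSD
    pShift <- 1 - fBetween
    u <- stats::rnorm(nP, 0, tauB)
    baseAb <- stats::rnorm(nP, 0, 0.5)  # parasite-specific log abundance level
    recs <- list()
    for (i in seq_len(nP)) {
      inRegions <- stats::runif(nR) < cfg$pRegion
      if (!any(inRegions)) inRegions[sample.int(nR, 1)] <- TRUE
      for (r in which(inRegions)) {
        pool <- pools[[r]]
        fr <- if (stats::runif(1) < pShift || !(focal[i] %in% pool)) {
          sample(pool, 1)  # regional host shift
        } else focal[i]
        w <- exp(-cfg$theta * D[fr, pool])
        s <- round(exp(log(cfg$meanHosts) + u[i] + stats::rnorm(1, 0, tauW)))
        s <- max(3L, min(as.integer(s), length(pool)))
        hs <- sample(pool, s, prob = w)
        recs[[length(recs) + 1L]] <- data.frame(
          region = sprintf("R%02d", r), parasite = par[i], host = hs,
          abundance = stats::rlnorm(s, meanlog = baseAb[i], sdlog = 0.5),
          stringsAsFactors = FALSE)
      }
    }
    list(records = do.call(rbind, recs), focal = stats::setNames(focal, par))
  })
}

#' Simulate region-structured incidence records
#'
#' Each parasite receives a focal host; its per-region host sets are drawn
#' with weights proportional to \eqn{\exp(-\theta \cdot} patristic distance
#' to the focal host\eqn{)}, so `theta` tunes how tightly hosts cluster on
#' the tree. Host-set sizes vary between and within parasites; the split of
#' that variation is calibrated by a pilot pass so that the realized
#' intra-class correlation of regional D_P approximates `cfg$targetICC`.
#' Positive abundances are attached from a lognormal with parasite-specific
#' median.
#'
#' @param tree Host tree from [simulateHostTree()].
#' @param cfg From [simulationConfig()].
#' @return List with `incidence` (an [IncidenceSet-class]) and `truth`
#'   (focal hosts, theta, target ICC, calibrated variance split, realized
#'   pilot ICC).
#' @export
simulateIncidence <- function(tree, cfg = simulationConfig()) {
  pilotICC <- function(f) {
    dr <- drawIncidence(tree, cfg, f, childSeed(cfg$seed, 103))
    inc <- incidenceSet(dr$records)
    nb <- nicheBreadthTable(inc, tree, NULL_DISS(tree$tip.label))
    reg <- nb[nb$scale != "continental", , drop = FALSE]
    ok <- names(which(table(reg$parasite) >= 2))
    reg <- reg[reg$parasite %in% ok, , drop = FALSE]
    iccPoint(reg$DP, reg$parasite)
  }
  grid <- seq(0.05, 0.95, by = 0.15)
  realized <- vapply(grid, pilotICC, numeric(1))
  f <- grid[which.min(abs(realized - cfg$targetICC))]
  dr <- drawIncidence(tree, cfg, f, childSeed(cfg$seed, 104))
  list(incidence = incidenceSet(dr$records),
       truth = list(theta = cfg$theta, focalHosts = dr$focal,
                    targetICC = cfg$targetICC, fBetween = f,
                    pilotICC = realized[which.min(abs(realized - cfg$targetICC))]))
}

## Trivial all-ones dissimilarity used only inside the pilot (Q is not
## calibrated; only DP matters there).
NULL_DISS <- function(labels) {
  d <- matrix(1, length(labels), length(labels),
              dimnames = list(labels, labels))
  diag(d) <- 0
  d
}

#' Simulate parasite abundance and body size with known links to breadth
#'
#' Generates \eqn{\log CA = a_{CA} + b_{CA} \log D_P^{cont} + \epsilon} and
#' \eqn{\log BS = a_{BS} + b_{BS} \log D_P^{cont} + \epsilon'}, with the
#' residuals drawn from a multivariate normal whose covariance is the
#' lambda-transformed Brownian structure of the parasite tree. Male and
#' female sizes are reported at 0.9 and 1.1 times the species size, so the
#' derived size (median of the sex averages) recovers it.
#'
#' @param tree Parasite tree.
#' @param nb Niche-breadth table containing continental records for the
#'   parasites (e.g. from [nicheBreadthTable()]).
#' @param cfg From [simulationConfig()].
#' @return List with `traits` (data.frame for the regression suites) and
#'   `truth` (the generating intercepts, slopes, lambda and SDs).
#' @export
simulateParasiteResponses <- function(tree, nb, cfg = simulationConfig()) {
  con <- nb[nb$scale == "continental", , drop = FALSE]
  con <- con[con$parasite %in% tree$tip.label, , drop = FALSE]
  stopIfNot(nrow(con) >= 4, "need continental breadth for at least 4 parasites")
  tr <- ape::keep.tip(tree, con$parasite)
  con <- con[match(tr$tip.label, con$parasite), , drop = FALSE]
  V <- transformCov(tr, lambda = cfg$lambdaResid)
  V <- V / max(diag(V))
  L <- t(chol(V))
  withSeed(childSeed(cfg$seed, 105), {
    n <- nrow(con)
    x <- log(con$DP)
    logCA <- cfg$aCA + cfg$bCA * x + cfg$sdCA * as.numeric(L %*% stats::rnorm(n))
    logBS <- cfg$aBS + cfg$bBS * x + cfg$sdBS * as.numeric(L %*% stats::rnorm(n))
    bs <- exp(logBS)
    traits <- parasiteTraits(con$parasite, abundance = exp(logCA),
                             maleSize = 0.9 * bs, femaleSize = 1.1 * bs)
    list(traits = traits,
         truth = list(aCA = cfg$aCA, bCA = cfg$bCA, sdCA = cfg$sdCA,
                      aBS = cfg$aBS, bBS = cfg$bBS, sdBS = cfg$sdBS,
                      lambda = cfg$lambdaResid))
  })
}

#' Simulate a complete study bundle
#'
#' Host tree, host traits, parasite tree, incidence records and parasite
#' traits, with the ground truth of every generated dependence. The bundle
#' feeds [runAll()] directly.
#'
#' @param cfg From [simulationConfig()].
#' @return List with components `hostTree`, `hostTraits`, `parasiteTree`,
#'   `incidence`, `parasiteTraits`, `truth`, `config`.
#' @export
simulateStudy <- function(cfg = simulationConfig()) {
  hostTree <- simulateHostTree(cfg)
  hostTraits <- simulateTraits(hostTree, cfg)
  parasiteTree <- simulateParasiteTree(cfg)
  sim <- simulateIncidence(hostTree, cfg)
  gd <- gowerMatrix(hostTraits)
  nb <- nicheBreadthTable(sim$incidence, hostTree, gd)
  resp <- simulateParasiteResponses(parasiteTree, nb, cfg)
  list(hostTree = hostTree, hostTraits = hostTraits,
       parasiteTree = parasiteTree, incidence = sim$incidence,
       parasiteTraits = resp$traits,
       truth = c(sim$truth, resp$truth), config = cfg)
}

#' Write a simulated study bundle to a directory
#'
#' Writes the trees as Newick, the tables as CSV, and the configuration and
#' ground truth as JSON, i.e. exactly the input bundle [runAll()] accepts
#' from disk.
#'
#' @param study From [simulateStudy()].
#' @param dir Output directory (created if needed).
#' @return Invisible character vector of the files written.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    hostTree = file.path(dir, "host_tree.nwk"),
    parasiteTree = file.path(dir, "parasite_tree.nwk"),
    hostTraits = file.path(dir, "host_traits.csv"),
    hostTraitSchema = file.path(dir, "host_trait_schema.csv"),
    incidence = file.path(dir, "incidence.csv"),
    parasiteTraits = file.path(dir, "parasite_traits.csv"),
    config = file.path(dir, "config.json"),
    truth = file.path(dir, "ground_truth.json"))
  writeNewick(study$hostTree, paths["hostTree"])
  writeNewick(study$parasiteTree, paths["parasiteTree"])
  td <- study$hostTraits@data
  utils::write.csv(cbind(species = rownames(td), td), paths["hostTraits"],
                   row.names = FALSE)
  utils::write.csv(
    data.frame(trait = names(study$hostTraits@types),
               type = unname(study$hostTraits@types),
               weight = unname(study$hostTraits@weights)),
    paths["hostTraitSchema"], row.names = FALSE)
  utils::write.csv(study$incidence@records, paths["incidence"], row.names = FALSE)
  utils::write.csv(study$parasiteTraits, paths["parasiteTraits"],
                   row.names = FALSE)
  jsonlite::write_json(study$config, paths["config"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  truth <- study$truth
  truth$focalHosts <- as.list(truth$focalHosts)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}
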