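## Data ingestion, filtering rules, characteristic abundance / body size
## derivation, and orchestration of the regional and continental analysis
## suites.

#' IncidenceSet: region-structured host-parasite records
#'
#' Long-format records of parasite occurrences on hosts per survey region,
#' with optional mean abundances. Presence is `abundance > 0`, or the record
#' itself when abundance is missing.
#'
#' @slot records data.frame with columns `region`, `parasite`, `host`, and
#'   optionally `abundance`.
#' @export
setClass("IncidenceSet",
  representation(records = "data.frame"),
  validity = function(object) {
    df <- object@records
    msg <- character()
    need <- c("region", "parasite", "host")
    if (!all(need %in% names(df)))
      msg <- c(msg, "records need columns region, parasite, host")
    else {
      if (any(!nzchar(df$region)) || anyNA(df$region))
        msg <- c(msg, "region names must be non-empty")
      if (anyDuplicated(df[c("region", "parasite", "host")]))
        msg <- c(msg, "duplicate (region, parasite, host) rows")
    }
    if (length(msg)) msg else TRUE
  })

#' FilterConfig: the dataset filtering rules
#'
#' @slot excludedHosts Host species removed before any tally (default: the
#'   commensal ubiquitous rodents *Rattus rattus*, *Rattus norvegicus*,
#'   *Mus musculus*).
#' @slot excludedParasites Parasite species removed (default: the ubiquitous
#'   fleas *Xenopsylla cheopis*, *Nosopsyllus fasciatus*).
#' @slot minHosts Minimum hosts per parasite at a scale (default 3, i.e.
#'   parasites recorded on one or two hosts are dropped).
#' @slot minParasitesPerRegion Minimum parasites for a region to enter the
#'   regional regression suites (default 8).
#' @slot minRegionsRepeatability Minimum regions per parasite for the ICC
#'   analysis (default 2).
#' @slot minRegionsHostPool Minimum regions per parasite for the host-pool
#'   regressions (default 8).
#' @export
setClass("FilterConfig",
  representation(excludedHosts = "character", excludedParasites = "character",
                 minHosts = "integer", minParasitesPerRegion = "integer",
                 minRegionsRepeatability = "integer",
                 minRegionsHostPool = "integer"),
  validity = function(object) {
    if (any(c(object@minHosts, object@minParasitesPerRegion,
              object@minRegionsRepeatability, object@minRegionsHostPool) < 1L))
      "thresholds must be positive integers" else TRUE
  })

#' @rdname FilterConfig-class
#' @param excludedHosts,excludedParasites Species removed outright.
#' @param minHosts,minParasitesPerRegion,minRegionsRepeatability,minRegionsHostPool
#'   Positive integer thresholds; see the class documentation.
#' @return A [FilterConfig-class].
#' @export
filterConfig <- function(excludedHosts = c("Rattus rattus", "Rattus norvegicus",
                                           "Mus musculus"),
                         excludedParasites = c("Xenopsylla cheopis",
                                               "Nosopsyllus fasciatus"),
                         minHosts = 3L, minParasitesPerRegion = 8L,
                         minRegionsRepeatability = 2L, minRegionsHostPool = 8L) {
  methods::new("FilterConfig", excludedHosts = excludedHosts,
               excludedParasites = excludedParasites,
               minHosts = as.integer(minHosts),
               minParasitesPerRegion = as.integer(minParasitesPerRegion),
               minRegionsRepeatability = as.integer(minRegionsRepeatability),
               minRegionsHostPool = as.integer(minRegionsHostPool))
}

#' FilteredIncidence: an IncidenceSet with the filtering rules applied
#'
#' Holds the exclusion-filtered records plus the per-scale record subsets:
#' the minimum-host rule is applied within each region for the regional
#' records and on the pooled data for the continental records,
#' independently.
#'
#' @slot regional Records passing the per-region minimum-host rule.
#' @slot continental Records of parasites passing the pooled rule.
#' @slot report Counts removed by each rule.
#' @slot config The [FilterConfig-class] used.
#' @export
setClass("FilteredIncidence", contains = "IncidenceSet",
  representation(regional = "data.frame", continental = "data.frame",
                 report = "list", config = "FilterConfig"))

#' Construct an IncidenceSet
#'
#' @param records data.frame with columns `region`, `parasite`, `host` and
#'   optionally `abundance` (mean individuals per host individual).
#' @return An [IncidenceSet-class].
#' @export
incidenceSet <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!"abundance" %in% names(records)) records$abundance <- NA_real_
  for (cn in c("region", "parasite", "host"))
    records[[cn]] <- as.character(records[[cn]])
  # drop explicit-absence rows (abundance == 0): presence means abundance > 0
  pres <- is.na(records$abundance) | records$abundance > 0
  methods::new("IncidenceSet", records = records[pres, , drop = FALSE])
}

#' Read an incidence CSV (region, parasite, host, abundance)
#' @param path CSV path.
#' @return An [IncidenceSet-class].
#' @export
readIncidence <- function(path)
  incidenceSet(utils::read.csv(path, stringsAsFactors = FALSE))

#' @export
setMethod("show", "IncidenceSet", function(object) {
  df <- object@records
  cat(class(object), ":", nrow(df), "records |",
      length(unique(df$parasite)), "parasites x",
      length(unique(df$host)), "hosts in",
      length(unique(df$region)), "regions\n")
})

#' Region names of an IncidenceSet
#' @param x An [IncidenceSet-class].
#' @return Character vector.
#' @export
regions <- function(x) sort(unique(x@records$region))

#' Parasite species of an IncidenceSet
#' @param x An [IncidenceSet-class].
#' @return Character vector.
#' @export
parasites <- function(x) sort(unique(x@records$parasite))

#' Host species of an IncidenceSet
#' @param x An [IncidenceSet-class].
#' @return Character vector.
#' @export
hostSpecies <- function(x) sort(unique(x@records$host))

## Records entering regional / continental computations. For a raw
## IncidenceSet both scales use all records; a FilteredIncidence carries the
## per-scale filtered subsets.
regionalRecords <- function(x) {
  if (methods::is(x, "FilteredIncidence")) x@regional else x@records
}
continentalRecords <- function(x) {
  if (methods::is(x, "FilteredIncidence")) x@continental else x@records
}

#' Binary parasite-by-host matrix for one region
#' @param x An [IncidenceSet-class].
#' @param region Region name.
#' @return 0/1 matrix, parasites in rows, hosts in columns.
#' @export
regionalMatrix <- function(x, region) {
  df <- regionalRecords(x)
  df <- df[df$region == region, , drop = FALSE]
  stopIfNot(nrow(df) > 0, paste0("no records for region '", region, "'"))
  1 * (table(df$parasite, df$host) > 0)
}

#' Pooled continental parasite-by-host matrix
#' @param x An [IncidenceSet-class].
#' @return 0/1 matrix, parasites in rows, hosts in columns.
#' @export
continentalMatrix <- function(x) {
  df <- continentalRecords(x)
  1 * (table(df$parasite, df$host) > 0)
}

#' Apply the dataset filtering rules
#'
#' Removes the configured commensal hosts and ubiquitous parasites, then
#' drops every parasite recorded on fewer than `minHosts` host species —
#' applied within each region for the regional record set and on the pooled
#' records for the continental record set, independently. Idempotent.
#'
#' @param x An [IncidenceSet-class].
#' @param config A [FilterConfig-class].
#' @return A [FilteredIncidence-class]; see [filterReport()].
#' @export
applyFilters <- function(x, config = filterConfig()) {
  df <- x@records
  hostDrop <- df$host %in% config@excludedHosts
  parDrop <- df$parasite %in% config@excludedParasites
  df2 <- df[!(hostDrop | parDrop), , drop = FALSE]

  hostCount <- function(d, by) {
    key <- interaction(d[by], drop = TRUE)
    cnt <- tapply(d$host, key, function(h) length(unique(h)))
    cnt[match(key, names(cnt))]
  }
  keepReg <- hostCount(df2, c("region", "parasite")) >= config@minHosts
  keepCon <- hostCount(df2, "parasite") >= config@minHosts
  regional <- df2[keepReg, , drop = FALSE]
  continental <- df2[keepCon, , drop = FALSE]
  report <- list(
    hostExclusionRows = sum(hostDrop),
    parasiteExclusionRows = sum(parDrop & !hostDrop),
    regionalPairsDropped = length(unique(interaction(
      df2$region[!keepReg], df2$parasite[!keepReg], drop = TRUE))),
    continentalParasitesDropped = length(unique(df2$parasite[!keepCon]))
  )
  if (nrow(regional) == 0 && nrow(continental) == 0)
    warning("filtering removed every record", call. = FALSE)
  methods::new("FilteredIncidence", records = df2, regional = regional,
               continental = continental, report = report, config = config)
}

#' Filter report of a FilteredIncidence
#' @param x A [FilteredIncidence-class].
#' @return Named list of counts removed per rule.
#' @export
filterReport <- function(x) x@report

#' Principal host and characteristic abundance
#'
#' For each parasite, abundances are first averaged per host species across
#' regions; the principal host is the host with the maximal mean, and the
#' characteristic abundance is that maximum. Ties are broken towards the
#' lexicographically first host (reported via a message).
#'
#' @param x An [IncidenceSet-class] whose records carry abundances.
#' @return data.frame with columns `parasite`, `principalHost`,
#'   `characteristicAbundance`.
#' @export
characteristicAbundance <- function(x) {
  df <- x@records
  df <- df[!is.na(df$abundance), , drop = FALSE]
  out <- lapply(split(df, df$parasite), function(d) {
    if (!nrow(d) || all(d$abundance == 0))
      stop("no positive abundance records for parasite '", d$parasite[1], "'",
           call. = FALSE)
    hostMean <- tapply(d$abundance, d$host, mean)
    hostMean <- hostMean[order(names(hostMean))]
    best <- which(hostMean == max(hostMean))
    if (length(best) > 1)
      message("characteristicAbundance: tie for parasite '", d$parasite[1],
              "'; keeping lexicographically first host")
    data.frame(parasite = d$parasite[1],
               principalHost = names(hostMean)[best[1]],
               characteristicAbundance = unname(hostMean[best[1]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Parasite trait table with derived body size
#'
#' Body size of a species is the median of its average male and average
#' female sizes (i.e. their midpoint, reflecting female-biased size
#' dimorphism).
#'
#' @param parasite Parasite species labels.
#' @param abundance Characteristic abundances (> 0 where present).
#' @param maleSize,femaleSize Average body sizes per sex (mm).
#' @return data.frame with a derived `bodySize` column.
#' @export
parasiteTraits <- function(parasite, abundance = NA_real_,
                           maleSize = NA_real_, femaleSize = NA_real_) {
  stopIfNot(all(is.na(abundance) | abundance > 0),
            "characteristic abundance must be positive")
  stopIfNot(all(is.na(maleSize) | maleSize > 0) &&
              all(is.na(femaleSize) | femaleSize > 0),
            "body sizes must be positive")
  data.frame(parasite = as.character(parasite), abundance = abundance,
             maleSize = maleSize, femaleSize = femaleSize,
             bodySize = apply(cbind(maleSize, femaleSize), 1, stats::median),
             stringsAsFactors = FALSE)
}

## ---- regression suites -----------------------------------------------------

## One log-log (or raw) PGLS row for a set of taxa.
fitSuiteModel <- function(df, tree, response, predictor, label,
                          logScale = TRUE, alpha = 0.05, seed = 1L,
                          minTaxa = 4L, logfun = log) {
  d <- df[is.finite(df[[response]]) & is.finite(df[[predictor]]), , drop = FALSE]
  if (logScale) {
    pos <- d[[response]] > 0 & d[[predictor]] > 0
    d <- d[pos, , drop = FALSE]
    d$.y <- logfun(d[[response]]); d$.x <- logfun(d[[predictor]])
  } else {
    d$.y <- d[[response]]; d$.x <- d[[predictor]]
  }
  d <- d[d$parasite %in% tree$tip.label, , drop = FALSE]
  if (nrow(d) < minTaxa) {
    message("suite: '", label, "' skipped (only ", nrow(d), " matched taxa)")
    return(NULL)
  }
  rownames(d) <- d$parasite
  if (stats::sd(d$.x) == 0) {
    message("suite: '", label, "' skipped (constant predictor)")
    return(NULL)
  }
  fit <- pgls(.y ~ .x, d, tree, seed = seed)
  fit <- maybeDropIntercept(fit, alpha)
  cf <- fit@coefficients
  hasInt <- "(Intercept)" %in% rownames(cf)
  data.frame(
    label = label, response = response, predictor = predictor,
    n = fit@n,
    intercept = if (hasInt) cf["(Intercept)", "Estimate"] else NA_real_,
    slope = cf[".x", "Estimate"], slopeSE = cf[".x", "SE"],
    slopeP = cf[".x", "p"],
    lambda = fit@lambda, kappa = fit@kappa, delta = fit@delta,
    R2 = fit@R2, F = fit@Fstat, modelP = fit@pModel,
    interceptDropped = !hasInt,
    stringsAsFactors = FALSE)
}

#' Abundance vs niche breadth regression suite
#'
#' PGLS of log characteristic abundance (response) on log phylogenetic
#' (D_P) and log functional (Q) niche breadth, per region (for regions with
#' at least `minParasitesPerRegion` parasites) or continentally.
#'
#' @param nb Niche-breadth table from [nicheBreadthTable()].
#' @param traits Parasite trait table ([parasiteTraits()] or equivalent with
#'   columns `parasite`, `abundance`).
#' @param tree Parasite phylogeny (or quasi-phylogeny).
#' @param scale `"regional"` or `"continental"`.
#' @param config A [FilterConfig-class] (supplies the region census rule).
#' @param alpha Intercept-retention threshold (see [maybeDropIntercept()]).
#' @param seed Seed for the PGLS optimizer starts.
#' @return data.frame, one row per fitted model (columns: label = region or
#'   "continental", response, predictor, n, coefficients, transform
#'   parameters, R2, F, modelP).
#' @export
runAbundanceSuite <- function(nb, traits, tree, scale = c("continental", "regional"),
                              config = filterConfig(), alpha = 0.05, seed = 1L) {
  scale <- match.arg(scale)
  dat <- merge(nb, traits[c("parasite", "abundance")], by = "parasite")
  rows <- list()
  doOne <- function(d, label) {
    for (metric in c("DP", "Q"))
      rows[[length(rows) + 1L]] <<- fitSuiteModel(
        d, tree, response = "abundance", predictor = metric,
        label = label, seed = seed, alpha = alpha)
  }
  if (scale == "continental") {
    doOne(dat[dat$scale == "continental", , drop = FALSE], "continental")
  } else {
    reg <- dat[dat$scale != "continental", , drop = FALSE]
    for (rg in sort(unique(reg$scale))) {
      d <- reg[reg$scale == rg, , drop = FALSE]
      if (length(unique(d$parasite)) < config@minParasitesPerRegion) next
      doOne(d, rg)
    }
  }
  collectRows(rows)
}

#' Body size vs niche breadth regression suite
#'
#' PGLS of log niche breadth (D_P or Q; response) on log body size
#' (explanatory), per qualifying region or continentally.
#'
#' @inheritParams runAbundanceSuite
#' @return data.frame as in [runAbundanceSuite()].
#' @export
runBodySizeSuite <- function(nb, traits, tree, scale = c("continental", "regional"),
                             config = filterConfig(), alpha = 0.05, seed = 1L) {
  scale <- match.arg(scale)
  dat <- merge(nb, traits[c("parasite", "bodySize")], by = "parasite")
  rows <- list()
  doOne <- function(d, label) {
    for (metric in c("DP", "Q"))
      rows[[length(rows) + 1L]] <<- fitSuiteModel(
        d, tree, response = metric, predictor = "bodySize",
        label = label, seed = seed, alpha = alpha)
  }
  if (scale == "continental") {
    doOne(dat[dat$scale == "continental", , drop = FALSE], "continental")
  } else {
    reg <- dat[dat$scale != "continental", , drop = FALSE]
    for (rg in sort(unique(reg$scale))) {
      d <- reg[reg$scale == rg, , drop = FALSE]
      if (length(unique(d$parasite)) < config@minParasitesPerRegion) next
      doOne(d, rg)
    }
  }
  collectRows(rows)
}

collectRows <- function(rows) {
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    warning("no models could be fitted", call. = FALSE)
    return(data.frame())
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean-regional vs continental niche breadth comparison
#'
#' For each parasite occurring in at least `minRegions` regions, its mean
#' regional D_P (and Q) is regressed on its continental D_P (Q) by PGLS on
#' the raw metric scale.
#'
#' @param nb Niche-breadth table from [nicheBreadthTable()].
#' @param tree Parasite phylogeny.
#' @param minRegions Minimum regions per parasite (default 2).
#' @param alpha,seed As in [runAbundanceSuite()].
#' @return data.frame, one row per metric.
#' @export
runScaleComparison <- function(nb, tree, minRegions = 2L, alpha = 0.05,
                               seed = 1L) {
  reg <- nb[nb$scale != "continental", , drop = FALSE]
  con <- nb[nb$scale == "continental", , drop = FALSE]
  nReg <- table(reg$parasite)
  keep <- names(nReg)[nReg >= minRegions]
  if (!length(keep)) {
    warning("no parasite occurs in at least ", minRegions, " regions",
            call. = FALSE)
    return(data.frame())
  }
  rows <- list()
  for (metric in c("DP", "Q")) {
    mReg <- tapply(reg[[metric]][reg$parasite %in% keep],
                   reg$parasite[reg$parasite %in% keep], mean)
    d <- data.frame(parasite = names(mReg),
                    meanRegional = as.numeric(mReg),
                    continental = con[[metric]][match(names(mReg), con$parasite)],
                    stringsAsFactors = FALSE)
    d <- d[is.finite(d$continental), , drop = FALSE]
    rows[[length(rows) + 1L]] <- fitSuiteModel(
      d, tree, response = "meanRegional", predictor = "continental",
      label = paste0("mean regional ", metric, " ~ continental ", metric),
      logScale = FALSE, alpha = alpha, seed = seed)
  }
  collectRows(rows)
}

#' Regional niche breadth vs host-pool diversity, per parasite
#'
#' For every parasite recorded in at least `minRegions` regions, ordinary
#' least squares of its log regional D_P (Q) across regions on the log
#' regional host-pool diversity — the D_P (Q) of all hosts recorded in that
#' region. These are within-species regressions across regions, so no
#' cross-species phylogenetic covariance applies and plain least squares is
#' used, with the same intercept-retention convention.
#'
#' @param inc A [FilteredIncidence-class] (or [IncidenceSet-class]).
#' @param tree Ultrametric host tree.
#' @param d Host Gower dissimilarity matrix.
#' @param nb Niche-breadth table from [nicheBreadthTable()].
#' @param minRegions Minimum regions per parasite (default 8).
#' @param alpha Intercept-retention threshold.
#' @return data.frame, one row per (parasite, metric) with slope, R2, F, P.
#' @export
runHostPoolSuite <- function(inc, tree, d, nb, minRegions = 8L, alpha = 0.05) {
  rec <- if (methods::is(inc, "FilteredIncidence")) inc@records else inc@records
  pools <- split(rec$host, rec$region)
  poolDiv <- data.frame(
    region = names(pools),
    DPh = vapply(pools, function(h) {
      h <- unique(h)
      phyloDP(h, pruneKeepDepth(tree, unique(h)))
    }, numeric(1)),
    Qh = vapply(pools, function(h) raoQ(unique(h), d), numeric(1)),
    stringsAsFactors = FALSE)

  reg <- nb[nb$scale != "continental", , drop = FALSE]
  nReg <- table(reg$parasite)
  keep <- names(nReg)[nReg >= minRegions]
  rows <- list()
  for (sp in keep) {
    dsp <- reg[reg$parasite == sp, , drop = FALSE]
    dsp <- merge(dsp, poolDiv, by.x = "scale", by.y = "region")
    for (metric in c("DP", "Q")) {
      pred <- if (metric == "DP") "DPh" else "Qh"
      ok <- dsp[[metric]] > 0 & dsp[[pred]] > 0
      dd <- dsp[ok, , drop = FALSE]
      if (nrow(dd) < 3L) {
        message("host-pool suite: '", sp, "' / ", metric,
                " skipped (too few usable regions)")
        next
      }
      x <- log(dd[[pred]]); y <- log(dd[[metric]])
      if (stats::sd(x) == 0) {
        message("host-pool suite: '", sp, "' / ", metric,
                " skipped (host-pool diversity constant across regions)")
        next
      }
      fit <- stats::lm(y ~ x)
      sm <- summary(fit)
      if (sm$coefficients["(Intercept)", 4] >= alpha) {
        fit <- stats::lm(y ~ x - 1)
        sm <- summary(fit)
        interceptDropped <- TRUE
        intercept <- NA_real_
      } else {
        interceptDropped <- FALSE
        intercept <- sm$coefficients["(Intercept)", 1]
      }
      fr <- sm$fstatistic
      rows[[length(rows) + 1L]] <- data.frame(
        parasite = sp, metric = metric, nRegions = nrow(dd),
        intercept = intercept,
        slope = sm$coefficients["x", 1], slopeSE = sm$coefficients["x", 2],
        slopeP = sm$coefficients["x", 4],
        R2 = sm$r.squared,
        F = unname(fr[1]),
        modelP = stats::pf(fr[1], fr[2], fr[3], lower.tail = FALSE),
        interceptDropped = interceptDropped,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    warning("host-pool suite: no parasite qualifies", call. = FALSE)
    return(data.frame())
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## ---- orchestration ---------------------------------------------------------

#' Run the full analysis
#'
#' Executes the whole pipeline: filtering, niche-breadth tables, ICC
#' repeatability, the abundance and body-size regression suites at both
#' scales, the scale comparison, and the host-pool regressions. Writes the
#' seven output tables, a run log and a machine-readable manifest into
#' `outDir` when given.
#'
#' @param config Named list with components `hostTree`, `parasiteTree`
#'   (`phylo` objects or Newick paths), `hostTraits` (a
#'   [TraitTable-class], or a path plus `hostTraitSchema`), `incidence` (an
#'   [IncidenceSet-class] or CSV path), `parasiteTraits` (data.frame or CSV
#'   path with columns `parasite`, `abundance`, `maleSize`, `femaleSize`),
#'   and optionally `filters` (a [FilterConfig-class]), `nBoot`, `alpha`,
#'   `seed`, `outDir`.
#' @return Invisible list with all result tables, the filter report and the
#'   manifest.
#' @export
runAll <- function(config) {
  need <- c("hostTree", "parasiteTree", "hostTraits", "incidence",
            "parasiteTraits")
  missing <- need[!vapply(need, function(nm) !is.null(config[[nm]]), logical(1))]
  if (length(missing))
    stop("config is missing component(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  seed <- config$seed %||% 1L
  nBoot <- config$nBoot %||% 1000L
  alpha <- config$alpha %||% 0.05
  fc <- config$filters %||% filterConfig()
  logLines <- character()
  note <- function(...) {
    line <- paste0(...)
    logLines <<- c(logLines, line)
    message(line)
  }

  hostTree <- if (is.character(config$hostTree))
    readNewick(readLines(config$hostTree)[1]) else config$hostTree
  parasiteTree <- if (is.character(config$parasiteTree))
    readNewick(readLines(config$parasiteTree)[1]) else config$parasiteTree
  hostTraits <- if (is.character(config$hostTraits))
    readTraitTable(config$hostTraits, config$hostTraitSchema) else config$hostTraits
  inc <- if (is.character(config$incidence))
    readIncidence(config$incidence) else config$incidence
  ptr <- if (is.character(config$parasiteTraits))
    utils::read.csv(config$parasiteTraits, stringsAsFactors = FALSE)
  else config$parasiteTraits
  if (!"bodySize" %in% names(ptr) &&
      all(c("maleSize", "femaleSize") %in% names(ptr)))
    ptr$bodySize <- (ptr$maleSize + ptr$femaleSize) / 2
  if (!"abundance" %in% names(ptr)) ptr$abundance <- NA_real_
  if (!"bodySize" %in% names(ptr)) ptr$bodySize <- NA_real_

  note("filtering incidence records")
  filt <- applyFilters(inc, fc)
  note("  report: ", paste(names(filt@report), unlist(filt@report),
                           sep = "=", collapse = ", "))
  note("computing Gower dissimilarities and niche-breadth tables")
  gd <- gowerMatrix(hostTraits)
  nb <- nicheBreadthTable(filt, hostTree, gd)

  note("estimating repeatability (ICC), ", nBoot, " bootstrap iterations")
  reg <- nb[nb$scale != "continental", , drop = FALSE]
  nRegPer <- table(reg$parasite)
  keep <- names(nRegPer)[nRegPer >= fc@minRegionsRepeatability]
  iccTab <- do.call(rbind, lapply(c("DP", "Q"), function(metric) {
    sub <- reg[reg$parasite %in% keep, , drop = FALSE]
    res <- icc(sub[[metric]], sub$parasite, nBoot = nBoot,
               seed = childSeed(seed, match(metric, c("DP", "Q"))))
    data.frame(metric = metric, nSpecies = length(keep),
               ICC = res@R, SE = res@se, CI2.5 = res@ci[1], CI97.5 = res@ci[2],
               P = res@p, stringsAsFactors = FALSE)
  }))

  note("regression suites")
  t2 <- runAbundanceSuite(nb, ptr, parasiteTree, "regional", fc, alpha,
                          seed = childSeed(seed, 11))
  t3 <- runAbundanceSuite(nb, ptr, parasiteTree, "continental", fc, alpha,
                          seed = childSeed(seed, 12))
  t4 <- runBodySizeSuite(nb, ptr, parasiteTree, "regional", fc, alpha,
                         seed = childSeed(seed, 13))
  t5 <- runBodySizeSuite(nb, ptr, parasiteTree, "continental", fc, alpha,
                         seed = childSeed(seed, 14))
  t6 <- runScaleComparison(nb, parasiteTree, fc@minRegionsRepeatability,
                           alpha, seed = childSeed(seed, 15))
  t7 <- runHostPoolSuite(filt, hostTree, gd, nb, fc@minRegionsHostPool, alpha)

  manifest <- list(
    package = "hostNiche",
    version = as.character(utils::packageVersion("hostNiche")),
    seed = seed, nBoot = nBoot, alpha = alpha,
    nRecords = nrow(inc@records),
    nParasites = length(parasites(inc)), nHosts = length(hostSpecies(inc)),
    nRegions = length(regions(inc)),
    filterReport = filt@report,
    filterConfig = list(
      excludedHosts = fc@excludedHosts, excludedParasites = fc@excludedParasites,
      minHosts = fc@minHosts, minParasitesPerRegion = fc@minParasitesPerRegion,
      minRegionsRepeatability = fc@minRegionsRepeatability,
      minRegionsHostPool = fc@minRegionsHostPool),
    conventions = list(log = "natural", periodWeighting = "duration",
                       pglsOptimized = "lambda", interceptRule = alpha)
  )
  results <- list(nicheBreadth = nb, T1_icc = iccTab,
                  T2_regional_abundance = t2, T3_continental_abundance = t3,
                  T4_regional_bodysize = t4, T5_continental_bodysize = t5,
                  T6_scale_comparison = t6, T7_hostpool = t7,
                  filterReport = filt@report, manifest = manifest)

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("T1_icc", "T2_regional_abundance", "T3_continental_abundance",
                 "T4_regional_bodysize", "T5_continental_bodysize",
                 "T6_scale_comparison", "T7_hostpool"))
      utils::write.csv(results[[nm]], file.path(config$outDir,
                                                paste0(nm, ".csv")),
                       row.names = FALSE)
    utils::write.csv(nb, file.path(config$outDir, "niche_breadth.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    writeLines(logLines, file.path(config$outDir, "run.log"))
  }
  invisible(results)
}
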