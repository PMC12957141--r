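## Host trait tables of mixed type and the Gower dissimilarity feeding
## functional niche breadth.

TRAIT_TYPES <- c("quantitative", "ordinal", "categorical", "binary")

#' TraitTable: species-by-trait data of mixed type
#'
#' Holds a species-by-trait table where every trait carries a type tag
#' (`quantitative`, `ordinal`, `categorical`, `binary`) and an optional
#' weight. Quantitative and ordinal traits must be numeric (ordinal values
#' are integer ranks); categorical and binary traits are stored as character.
#' Missing values are allowed and handled downstream by pairwise deletion.
#'
#' @slot data data.frame with species as row names and one column per trait.
#' @slot types Named character vector of type tags, one per column.
#' @slot weights Named numeric vector of positive Gower weights.
#' @export
setClass("TraitTable",
  representation(data = "data.frame", types = "character", weights = "numeric"),
  validity = function(object) {
    msg <- character()
    df <- object@data
    if (is.null(rownames(df)) || anyDuplicated(rownames(df)))
      msg <- c(msg, "species row names must be present and unique")
    if (!identical(sort(names(object@types)), sort(colnames(df))))
      msg <- c(msg, "types must be named by the trait columns")
    if (!all(object@types %in% TRAIT_TYPES))
      msg <- c(msg, paste("trait types must be one of:",
                          paste(TRAIT_TYPES, collapse = ", ")))
    if (!identical(sort(names(object@weights)), sort(colnames(df))) ||
        any(object@weights <= 0))
      msg <- c(msg, "weights must be positive and named by the trait columns")
    for (cn in colnames(df)) {
      ty <- object@types[[cn]]
      if (is.na(ty)) next
      if (ty %in% c("quantitative", "ordinal") && !is.numeric(df[[cn]]))
        msg <- c(msg, paste0("trait '", cn, "' tagged ", ty, " must be numeric"))
      if (ty %in% c("categorical", "binary") && is.numeric(df[[cn]]))
        msg <- c(msg, paste0("trait '", cn, "' tagged ", ty,
                             " must be character/factor"))
      if (ty == "binary") {
        lev <- unique(stats::na.omit(as.character(df[[cn]])))
        if (length(lev) > 2)
          msg <- c(msg, paste0("binary trait '", cn, "' has >2 levels"))
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a TraitTable
#'
#' @param data data.frame of trait values with species as row names (or a
#'   `species` column, which is moved to row names).
#' @param types Named character vector mapping each trait column to one of
#'   `quantitative`, `ordinal`, `categorical`, `binary`.
#' @param weights Optional named numeric vector of Gower weights (default 1).
#' @return A [TraitTable-class] object.
#' @examples
#' tt <- traitTable(
#'   data.frame(mass = c(5, 10), fossorial = c("yes", "no"),
#'              row.names = c("sp1", "sp2")),
#'   types = c(mass = "quantitative", fossorial = "binary"))
#' gowerMatrix(tt)
#' @export
traitTable <- function(data, types, weights = NULL) {
  if ("species" %in% names(data) && is.character(data$species)) {
    rownames(data) <- data$species
    data$species <- NULL
  }
  for (cn in names(data))
    if (is.factor(data[[cn]]) || is.logical(data[[cn]]))
      data[[cn]] <- as.character(data[[cn]])
  if (is.null(weights)) weights <- stats::setNames(rep(1, ncol(data)), names(data))
  methods::new("TraitTable", data = data, types = types[names(data)],
               weights = weights[names(data)])
}

#' Read a trait table with its type schema
#'
#' The CSV's first column must be `species`; the schema CSV maps each trait
#' column to a type tag and an optional weight (columns `trait`, `type`,
#' optionally `weight`). A schema for the 13 ecomorphological host traits
#' used for small-mammal hosts ships with the package
#' (`system.file("extdata/host_trait_schema.csv", package = "hostNiche")`).
#'
#' @param path CSV of trait values.
#' @param schemaPath CSV schema mapping trait columns to types.
#' @return A [TraitTable-class] object.
#' @export
readTraitTable <- function(path, schemaPath) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopIfNot(names(df)[1] == "species", "first column of the trait CSV must be 'species'")
  schema <- utils::read.csv(schemaPath, stringsAsFactors = FALSE)
  stopIfNot(all(c("trait", "type") %in% names(schema)),
            "schema must have columns 'trait' and 'type'")
  missingTraits <- setdiff(setdiff(names(df), "species"), schema$trait)
  if (length(missingTraits))
    stop("schema does not cover trait column(s): ",
         paste(missingTraits, collapse = ", "), call. = FALSE)
  types <- stats::setNames(schema$type, schema$trait)
  w <- if ("weight" %in% names(schema)) {
    schema$weight[is.na(schema$weight)] <- 1
    stats::setNames(schema$weight, schema$trait)
  } else NULL
  keep <- intersect(names(types), names(df))
  traitTable(df, types[keep], if (is.null(w)) NULL else w[keep])
}

#' @export
setMethod("show", "TraitTable", function(object) {
  cat("TraitTable:", nrow(object@data), "species x", ncol(object@data), "traits\n")
  tab <- table(factor(object@types, levels = TRAIT_TYPES))
  cat(" ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
  nmiss <- sum(is.na(object@data))
  if (nmiss > 0) cat("  missing values:", nmiss, "\n")
})

#' Species names of a TraitTable
#' @param x A [TraitTable-class].
#' @return Character vector.
#' @export
speciesNames <- function(x) rownames(x@data)

#' Trait type tags of a TraitTable
#' @param x A [TraitTable-class].
#' @return Named character vector.
#' @export
traitTypes <- function(x) x@types

#' Natural-log transform quantitative trait columns
#'
#' @param x A [TraitTable-class].
#' @param columns Character vector of quantitative columns with strictly
#'   positive values.
#' @return A [TraitTable-class] with the named columns replaced by their
#'   natural logarithms.
#' @export
logTransformColumns <- function(x, columns) {
  df <- x@data
  for (cn in columns) {
    stopIfNot(cn %in% names(df), paste0("unknown trait column '", cn, "'"))
    stopIfNot(x@types[[cn]] == "quantitative",
              paste0("trait '", cn, "' is not quantitative"))
    bad <- which(!is.na(df[[cn]]) & df[[cn]] <= 0)
    if (length(bad))
      stop("non-positive value in column '", cn, "' for species: ",
           paste(rownames(df)[bad], collapse = ", "), call. = FALSE)
    df[[cn]] <- log(df[[cn]])
  }
  methods::new("TraitTable", data = df, types = x@types, weights = x@weights)
}

#' Gower dissimilarity matrix for mixed-type traits
#'
#' Computes the Gower coefficient
#' \deqn{d_{ij} = \sum_k w_k \delta_{ijk} s_{ijk} / \sum_k w_k \delta_{ijk}}
#' where for quantitative and ordinal traits \eqn{s_{ijk} = |x_{ik} -
#' x_{jk}| / \mathrm{range}_k} (ordinal traits compared on their integer
#' ranks), for categorical and binary traits \eqn{s_{ijk}} is 0 on a match
#' and 1 on a mismatch, and \eqn{\delta_{ijk} = 1} only when both values are
#' observed and the trait is not constant over the table. Missing values are
#' handled by pairwise deletion with denominator renormalization; constant
#' traits are excluded with a warning.
#'
#' @param x A [TraitTable-class] with at least two species.
#' @param ordinal How to compare ordinal traits: `"ranks"` (rank difference
#'   scaled by rank range; the default) or `"mismatch"` (0/1 like a
#'   categorical trait).
#' @return Symmetric numeric matrix in \[0, 1\] with zero diagonal, dimnames
#'   the species labels.
#' @export
gowerMatrix <- function(x, ordinal = c("ranks", "mismatch")) {
  ordinal <- match.arg(ordinal)
  df <- x@data
  n <- nrow(df)
  stopIfNot(n >= 2, "need at least two species")
  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  for (cn in names(df)) {
    ty <- x@types[[cn]]
    w <- x@weights[[cn]]
    v <- df[[cn]]
    obs <- !is.na(v)
    both <- outer(obs, obs, "&")
    if (ty == "quantitative" || (ty == "ordinal" && ordinal == "ranks")) {
      rng <- diff(range(v[obs]))
      if (!is.finite(rng) || rng == 0) {
        warning("trait '", cn, "' is constant over the table; excluded from Gower",
                call. = FALSE)
        next
      }
      vv <- ifelse(obs, v, 0)
      s <- abs(outer(vv, vv, "-")) / rng
    } else {
      vc <- as.character(v)
      nlev <- length(unique(vc[obs]))
      if (nlev < 2) {
        warning("trait '", cn, "' is constant over the table; excluded from Gower",
                call. = FALSE)
        next
      }
      vv <- ifelse(obs, vc, "\x1fNA")
      s <- (outer(vv, vv, "!=")) * 1
    }
    num <- num + w * s * both
    den <- den + w * both
  }
  bad <- which(den == 0 & upper.tri(den), arr.ind = TRUE)
  if (nrow(bad))
    stop("species pair with no jointly observed trait: ",
         rownames(df)[bad[1, 1]], " / ", rownames(df)[bad[1, 2]], call. = FALSE)
  d <- num / den
  diag(d) <- 0
  dimnames(d) <- list(rownames(df), rownames(df))
  d
}
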