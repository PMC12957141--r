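## Phylogenetic generalized least squares with Pagel's lambda, kappa and
## delta transforms optimized by maximum likelihood. The GLS core whitens
## through the Cholesky factor of the phylogenetic covariance (no explicit
## inverse); transform parameters are profiled by bounded multi-start
## optimization.

#' PglsFit: a fitted phylogenetic regression
#'
#' @slot coefficients Matrix with columns `Estimate`, `SE`, `t`, `p`.
#' @slot lambda,kappa,delta Transform parameters of the fit.
#' @slot optimized Which transform parameters were free.
#' @slot boundary TRUE when an optimized parameter ended at a bound.
#' @slot sigma2 Residual variance scale.
#' @slot logLik Log-likelihood (ML or REML per `method`).
#' @slot method `"ML"` or `"REML"`.
#' @slot R2 Coefficient of determination in the whitened space against the
#'   GLS intercept-only null.
#' @slot Fstat,dfF F statistic and its degrees of freedom.
#' @slot pModel Model p-value from the F test.
#' @slot n Number of taxa.
#' @slot formula Model formula as character.
#' @slot alternative Other intercept variant retained by
#'   [maybeDropIntercept()] (empty list otherwise).
#' @slot model Internal refit context (response, design, tree).
#' @export
setClass("PglsFit",
  representation(coefficients = "matrix", lambda = "numeric", kappa = "numeric",
                 delta = "numeric", optimized = "character", boundary = "logical",
                 sigma2 = "numeric", logLik = "numeric", method = "character",
                 R2 = "numeric", Fstat = "numeric", dfF = "numeric",
                 pModel = "numeric", n = "integer", formula = "character",
                 alternative = "list", model = "list"),
  validity = function(object) {
    msg <- character()
    if (object@lambda < -1e-9 || object@lambda > 1 + 1e-9)
      msg <- c(msg, "lambda must lie in [0, 1]")
    if (object@R2 > 1 + 1e-9) msg <- c(msg, "R2 cannot exceed 1")
    if (length(msg)) msg else TRUE
  })

#' @export
setMethod("show", "PglsFit", function(object) {
  cat("PGLS fit:", object@formula, "  (n =", object@n, ")\n")
  stats::printCoefmat(object@coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("lambda = %.3f, kappa = %.3f, delta = %.3f%s%s\n",
              object@lambda, object@kappa, object@delta,
              if (length(object@optimized))
                paste0("  [ML-optimized: ", paste(object@optimized, collapse = ","), "]")
              else "  [fixed]",
              if (object@boundary) "  (boundary)" else ""))
  cat(sprintf("R2 = %.3f, F(%g, %g) = %.3f, P = %s, logLik(%s) = %.3f\n",
              object@R2, object@dfF[1], object@dfF[2], object@Fstat,
              format.pval(object@pModel, digits = 3), object@method, object@logLik))
})

#' Coefficients of a PGLS fit
#' @param object A [PglsFit-class].
#' @param ... Ignored.
#' @return Coefficient matrix.
#' @export
setMethod("coef", "PglsFit", function(object, ...) object@coefficients)

#' Brownian-motion covariance of a tree
#'
#' \eqn{V_{ij}} is the shared root-to-MRCA path length of tips i and j;
#' diagonals are root-to-tip depths. Any stem (`root.edge`) is shared by all
#' tips and added throughout.
#'
#' @param tree A rooted `phylo` object with branch lengths.
#' @param taxa Optional taxa ordering; must match the tip set.
#' @return Symmetric covariance matrix with tip labels as dimnames.
#' @export
brownianCov <- function(tree, taxa = NULL) {
  V <- ape::vcv(tree)
  V <- V + (tree$root.edge %||% 0)
  if (!is.null(taxa)) {
    if (!setequal(taxa, rownames(V)) || length(taxa) != nrow(V))
      stop("taxa do not match the tree's tips", call. = FALSE)
    V <- V[taxa, taxa]
  }
  V
}

#' Pagel-transformed phylogenetic covariance
#'
#' Applies, in order: kappa (each branch length \eqn{b \to b^\kappa}, with
#' \eqn{0^0 := 0}, then the covariance is rebuilt), delta (element-wise
#' \eqn{V \to V^\delta}, rescaled so the maximal diagonal is preserved;
#' requires an ultrametric tree), and lambda (off-diagonal elements
#' multiplied by \eqn{\lambda}).
#'
#' @param tree A rooted `phylo` object.
#' @param lambda Phylogenetic signal scaling, in \[0, 1\].
#' @param kappa Branch-length power, \eqn{\ge 0}.
#' @param delta Node-depth power, \eqn{> 0}.
#' @return Symmetric positive-definite covariance matrix.
#' @export
transformCov <- function(tree, lambda = 1, kappa = 1, delta = 1) {
  stopIfNot(lambda >= 0 && lambda <= 1, "lambda must lie in [0, 1]")
  stopIfNot(kappa >= 0, "kappa must be non-negative")
  stopIfNot(delta > 0, "delta must be positive")
  if (kappa != 1) {
    el <- tree$edge.length
    tree$edge.length <- ifelse(el == 0, 0, el^kappa)  # 0^0 := 0
    if (!is.null(tree$root.edge))
      tree$root.edge <- if (tree$root.edge == 0) 0 else tree$root.edge^kappa
  }
  V <- brownianCov(tree)
  if (delta != 1) {
    if (!isUltrametric(tree, tol = 1e-6))
      stop("delta transform requires an ultrametric tree", call. = FALSE)
    T0 <- max(diag(V))
    if (T0 > 0) V <- V^delta * (T0 / T0^delta)
  }
  if (lambda != 1) {
    D <- diag(V)
    V <- V * lambda
    diag(V) <- D
  }
  ok <- tryCatch({ chol(V); TRUE }, error = function(e) FALSE)
  if (!ok) {
    jit <- 1e-10 * mean(diag(V))
    ok <- tryCatch({ chol(V + jit * diag(nrow(V))); TRUE },
                   error = function(e) FALSE)
    if (!ok)
      stop("transformed covariance is not positive definite; ",
           "tighten the transform bounds", call. = FALSE)
    V <- V + jit * diag(nrow(V))
  }
  V
}

## GLS at a fixed covariance, by Cholesky whitening.
## y, X in tip order; V their covariance up to the scalar sigma2.
glsCore <- function(y, X, V, method = c("ML", "REML")) {
  method <- match.arg(method)
  n <- length(y)
  p <- ncol(X)
  R <- chol(V)
  z <- backsolve(R, y, transpose = TRUE)
  W <- backsolve(R, X, transpose = TRUE)
  qrW <- qr(W)
  if (qrW$rank < p) stop("singular design matrix", call. = FALSE)
  beta <- qr.coef(qrW, z)
  r <- z - W %*% beta
  RSS <- sum(r^2)
  sigma2 <- RSS / (n - p)
  XtX_inv <- chol2inv(qr.R(qrW))
  se <- sqrt(sigma2 * diag(XtX_inv))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  logdetV <- 2 * sum(log(diag(R)))
  ll <- if (method == "ML") {
    -0.5 * (n * (log(2 * pi) + log(RSS / n) + 1) + logdetV)
  } else {
    -0.5 * ((n - p) * (log(2 * pi) + log(RSS / (n - p)) + 1) + logdetV +
              determinant(crossprod(W), logarithm = TRUE)$modulus[1])
  }
  # null model: GLS intercept-only fit in the same whitened space
  one <- backsolve(R, rep(1, n), transpose = TRUE)
  mu0 <- sum(one * z) / sum(one^2)
  TSS <- sum((z - mu0 * one)^2)
  hasInt <- any(apply(X, 2, function(cc) all(cc == 1)))
  q <- if (hasInt) p - 1L else p
  Fstat <- if (q > 0) ((TSS - RSS) / q) / (RSS / (n - p)) else NA_real_
  pModel <- if (q > 0) stats::pf(Fstat, q, n - p, lower.tail = FALSE) else NA_real_
  cf <- cbind(Estimate = as.numeric(beta), SE = se,
              t = as.numeric(tval), p = as.numeric(pval))
  rownames(cf) <- colnames(X)
  list(coefficients = cf, sigma2 = sigma2, logLik = ll,
       R2 = 1 - RSS / TSS, Fstat = Fstat, dfF = c(q, n - p), pModel = pModel,
       residualsWhitened = as.numeric(r), designWhitened = W, method = method)
}

#' GLS fit at a fixed phylogenetic covariance
#'
#' Estimates \eqn{\hat\beta = (X'V^{-1}X)^{-1}X'V^{-1}y} through Cholesky
#' whitening, with \eqn{R^2} and the model F test computed in the whitened
#' space against the GLS intercept-only null.
#'
#' @param y Response vector (tip order of `V`).
#' @param X Design matrix (include an intercept column of ones if wanted).
#' @param V Positive-definite covariance matrix.
#' @param method Likelihood reported: `"ML"` (default) or `"REML"`.
#' @return List with coefficient table, `sigma2`, `logLik`, `R2`, `Fstat`,
#'   `dfF`, `pModel`, and whitened residuals/design.
#' @export
glsFit <- function(y, X, V, method = "ML") {
  stopIfNot(length(y) == nrow(X) && nrow(X) == nrow(V),
            "y, X and V must agree in size")
  glsCore(y, as.matrix(X), V, method)
}

#' Phylogenetic GLS with ML-optimized Pagel transforms
#'
#' Fits `formula` to `data` under the Brownian covariance of `tree`
#' transformed by Pagel's lambda, kappa and delta. The transform parameters
#' named in `optimize` are estimated by profile maximum likelihood with
#' bounded multi-start optimization (both bounds, the midpoint, and two
#' seeded random starts); the others are fixed at 1. Rows of `data` are
#' matched to tree tips by row name, and the tree is pruned to the taxa
#' present.
#'
#' @param formula Model formula, e.g. `log(CA) ~ log(DP)`.
#' @param data data.frame with taxa as row names.
#' @param tree Rooted `phylo` object covering the taxa.
#' @param optimize Character subset of `c("lambda", "kappa", "delta")`;
#'   defaults to `"lambda"`. Use `character(0)` for a pure Brownian fit.
#' @param bounds Named list of c(lower, upper) per parameter.
#' @param method Likelihood reported for the final fit (`"ML"` default; the
#'   transform profile always uses ML).
#' @param seed Seed for the random optimizer starts.
#' @return A [PglsFit-class] object.
#' @export
pgls <- function(formula, data, tree,
                 optimize = "lambda",
                 bounds = list(lambda = c(0, 1), kappa = c(1e-6, 3),
                               delta = c(1e-6, 3)),
                 method = "ML", seed = 1L) {
  stopIfNot(all(optimize %in% c("lambda", "kappa", "delta")),
            "optimize must be a subset of lambda, kappa, delta")
  taxa <- rownames(data)
  stopIfNot(!is.null(taxa), "data must have taxa as row names")
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown))
    stop("taxa missing from the tree: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (length(taxa) < ape::Ntip(tree)) tree <- ape::keep.tip(tree, taxa)
  ord <- tree$tip.label
  data <- data[ord, , drop = FALSE]
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- length(y); p <- ncol(X)
  stopIfNot(n >= p + 2, "too few taxa for the number of predictors")

  defBounds <- list(lambda = c(0, 1), kappa = c(1e-6, 3), delta = c(1e-6, 3))
  for (nm in names(defBounds)) bounds[[nm]] <- bounds[[nm]] %||% defBounds[[nm]]

  fixed <- c(lambda = 1, kappa = 1, delta = 1)
  covAt <- function(par) {
    pp <- fixed; pp[optimize] <- par
    transformCov(tree, lambda = pp[["lambda"]], kappa = pp[["kappa"]],
                 delta = pp[["delta"]])
  }
  fitAt <- function(par, meth = "ML")
    glsCore(y, X, covAt(par), meth)

  if (length(optimize) == 0L) {
    best <- list(par = numeric(0))
    core <- fitAt(numeric(0), method)
    bnd <- FALSE
    pp <- fixed
  } else {
    lo <- vapply(optimize, function(nm) bounds[[nm]][1], numeric(1))
    hi <- vapply(optimize, function(nm) bounds[[nm]][2], numeric(1))
    k <- length(optimize)
    starts <- withSeed(seed, {
      rnd <- matrix(stats::runif(2 * k, min = lo, max = hi), nrow = k)
      cbind(lo, hi, (lo + hi) / 2, rnd)
    })
    objective <- function(par) {
      val <- tryCatch(fitAt(par)$logLik, error = function(e) NA_real_)
      # degenerate perfect fits give +Inf loglik: treat as flat, not an error
      if (is.na(val) || val == -Inf) 1e10 else if (val == Inf) -1e9 else -val
    }
    best <- NULL
    diagList <- list()
    for (s in seq_len(ncol(starts))) {
      res <- tryCatch(
        stats::optim(starts[, s], objective, method = "L-BFGS-B",
                     lower = lo, upper = hi,
                     control = list(factr = 1e7)),
        error = function(e) NULL)
      diagList[[s]] <- res
      if (!is.null(res) && res$value < 1e9 &&
          (is.null(best) || res$value < best$value)) best <- res
    }
    if (is.null(best))
      stop("transform-parameter optimization failed from all starts; ",
           "diagnostics: ",
           paste(vapply(diagList, function(d) if (is.null(d)) "error" else
             paste0("value=", signif(d$value, 6)), character(1)),
             collapse = "; "), call. = FALSE)
    pp <- fixed; pp[optimize] <- best$par
    bnd <- any(abs(best$par - lo) < 1e-4 * (hi - lo)) ||
           any(abs(best$par - hi) < 1e-4 * (hi - lo))
    core <- fitAt(best$par, method)
  }

  methods::new("PglsFit",
    coefficients = core$coefficients,
    lambda = unname(pp[["lambda"]]), kappa = unname(pp[["kappa"]]),
    delta = unname(pp[["delta"]]),
    optimized = as.character(optimize), boundary = bnd,
    sigma2 = core$sigma2, logLik = core$logLik, method = core$method,
    R2 = core$R2, Fstat = core$Fstat, dfF = core$dfF, pModel = core$pModel,
    n = as.integer(n), formula = deparse(formula),
    alternative = list(),
    model = list(formula = formula, data = data, tree = tree,
                 optimize = optimize, bounds = bounds, method = method,
                 seed = seed))
}

#' Report a through-origin model when the intercept is not supported
#'
#' If the fitted intercept's p-value is at or above `alpha`, the model is
#' refitted through the origin and the origin fit is reported, with the
#' intercept fit retained in the `alternative` slot (and vice versa). This
#' mirrors the common reporting convention in which regressions whose
#' intercept is indistinguishable from zero are quoted without one.
#'
#' @param fit A [PglsFit-class] from [pgls()] with an intercept.
#' @param alpha Significance threshold for keeping the intercept.
#' @return A [PglsFit-class]; slot `alternative` holds the other variant.
#' @export
maybeDropIntercept <- function(fit, alpha = 0.05) {
  cf <- fit@coefficients
  if (!"(Intercept)" %in% rownames(cf)) return(fit)
  pInt <- cf["(Intercept)", "p"]
  # NaN p (zero-variance degenerate fits) counts as unsupported
  if (!is.na(pInt) && pInt < alpha) return(fit)
  m <- fit@model
  f0 <- stats::update(m$formula, . ~ . - 1)
  fit0 <- pgls(f0, m$data, m$tree, optimize = m$optimize, bounds = m$bounds,
               method = m$method, seed = m$seed)
  fit0@alternative <- list(withIntercept = fit)
  fit0
}
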