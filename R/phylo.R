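#' Conditional error probability of an observed p-value
#'
#' Converts a p-value into the (Bayesian-derived) probability that a
#' rejection of the null at that p is a false discovery:
#' \deqn{\alpha(p) = \left(1 + [-e\,p\,\ln p]^{-1}\right)^{-1}.}
#' At `p = 0.05` the false-discovery probability is already about 29%,
#' which motivates demanding p-values near 0.001 (where it drops to 1.84%)
#' before declaring groups definitively different.  The function is
#' monotone increasing on (0, 1/e), equals 1/2 at `p = 1/e`, and decreases
#' beyond.
#'
#' @param p P-value(s), strictly between 0 and 1.
#' @return `alpha(p)` (vectorized).
#' @examples
#' conditional_error_probability(0.05)   # ~0.289
#' conditional_error_probability(0.001)  # ~0.0184
#' @export
conditional_error_probability <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("p must lie strictly between 0 and 1", call. = FALSE)
  q <- -exp(1) * p * log(p)
  1 / (1 + 1 / q)
}

#' Time-calibrate a tree from tip occurrence dates
#'
#' Assigns branch lengths (in Myr) to a topology using per-tip first and
#' last appearance dates (Ma).  The calibration is a deliberately simple,
#' reproducible scheme: each tip sits at its first-appearance date (FAD);
#' each internal node is placed at
#' `max(oldest descendant FAD + padding, oldest child age + epsilon)`,
#' which keeps every node at least `padding` older than any descendant
#' occurrence and every branch at least `epsilon` long.  Polytomies
#' (including same-species hard polytomies) are resolved arbitrarily with
#' `epsilon`-length internal branches, which preserves near-equal pairwise
#' covariances among their tips while keeping the covariance matrix
#' invertible.  A topology that already carries positive branch lengths can
#' be passed with `occurrences = NULL` to bypass calibration.
#'
#' @param topology An `ape` `phylo` object or path to a Newick file.
#' @param occurrences Data frame with columns `tip`, `fad_ma`, `lad_ma`
#'   (first/last appearance, Ma; `fad_ma >= lad_ma`), one row per tip; or
#'   `NULL` to accept existing branch lengths.
#' @param padding Minimum gap (Myr) between a node and the oldest
#'   occurrence below it (default 1).
#' @param epsilon Minimum branch length (Myr); default
#'   `max(0.001 * FAD span, 1e-3)`.
#' @return A `phylo` tree with positive branch lengths in Myr and an
#'   attribute `ages` (node ages in Ma, tips first).
#' @export
calibrate_tree <- function(topology, occurrences, padding = 1,
                           epsilon = NULL) {
  tree <- if (is.character(topology)) ape::read.tree(topology) else topology
  if (!inherits(tree, "phylo"))
    stop("topology must be a phylo object or a Newick file path",
         call. = FALSE)
  if (is.null(occurrences)) {
    if (is.null(tree$edge.length) || any(tree$edge.length <= 0))
      stop("tree without occurrence dates must already carry positive ",
           "branch lengths", call. = FALSE)
    return(tree)
  }
  need <- c("tip", "fad_ma", "lad_ma")
  miss <- setdiff(need, names(occurrences))
  if (length(miss))
    stop("occurrence table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  missing_tips <- setdiff(tree$tip.label, occurrences$tip)
  if (length(missing_tips))
    stop("no occurrence dates for tip(s): ",
         paste(missing_tips, collapse = ", "), call. = FALSE)
  occ <- occurrences[match(tree$tip.label, occurrences$tip), ]
  if (any(occ$fad_ma < occ$lad_ma))
    stop("first appearance (fad_ma) must not postdate last appearance ",
         "(lad_ma) for tip ",
         occ$tip[which(occ$fad_ma < occ$lad_ma)[1L]], call. = FALSE)

  if (!ape::is.binary(tree))
    tree <- ape::multi2di(tree, random = FALSE)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  if (is.null(epsilon))
    epsilon <- max(0.001 * diff(range(occ$fad_ma)), 1e-3)
  if (epsilon <= 0 || padding <= 0)
    stop("padding and epsilon must be positive", call. = FALSE)

  ages <- numeric(ntip + nnode)
  ages[seq_len(ntip)] <- occ$fad_ma
  oldest_fad <- ages  # propagated clade-wise below
  ## postorder over internal nodes: children always precede parents
  edge <- tree$edge
  for (e in ape::postorder(tree)) {
    parent <- edge[e, 1L]
    child <- edge[e, 2L]
    oldest_fad[parent] <- max(oldest_fad[parent], oldest_fad[child])
    ages[parent] <- max(ages[parent], ages[child] + epsilon,
                        oldest_fad[child] + padding)
  }
  ## second sweep so siblings processed later still lift the node
  for (e in rev(seq_len(nrow(edge)))) {
    ## ensure parent older than each child by >= epsilon
    parent <- edge[e, 1L]; child <- edge[e, 2L]
    if (ages[parent] < ages[child] + epsilon)
      ages[parent] <- ages[child] + epsilon
  }
  tree$edge.length <- ages[edge[, 1L]] - ages[edge[, 2L]]
  attr(tree, "ages") <- ages
  tree
}

#' Brownian-motion covariance of tree tips with Pagel's lambda transform
#'
#' Expected trait covariance under Brownian motion on a tree: `V[i, j]` is
#' the shared root-to-MRCA path length of tips i and j, `V[i, i]` the
#' root-to-tip path length.  Pagel's lambda multiplies the off-diagonal
#' entries by `lambda` while leaving the diagonal untouched: `lambda = 0`
#' gives independent tips, `lambda = 1` plain Brownian motion.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param lambda Signal parameter in \[0, 1\].
#' @return Tip-by-tip covariance matrix (rows/columns in
#'   `tree$tip.label` order).
#' @export
bm_covariance <- function(tree, lambda = 1) {
  if (!is.finite(lambda) || lambda < 0 || lambda > 1)
    stop("lambda must lie in [0, 1]", call. = FALSE)
  V <- ape::vcv(tree)
  d <- diag(V)
  V <- V * lambda
  diag(V) <- d
  V
}

## whitened GLS core: returns estimates and the ML log-likelihood
.gls_core <- function(y, X, V) {
  R <- chol(V)
  wy <- backsolve(R, y, transpose = TRUE)
  wX <- backsolve(R, X, transpose = TRUE)
  fit <- stats::lm.fit(wX, wy)
  rss <- sum(fit$residuals^2)
  n <- length(y)
  logdet <- 2 * sum(log(diag(R)))
  sigma2_ml <- rss / n
  ll <- -0.5 * (n * log(2 * pi * sigma2_ml) + logdet + n)
  xtx_inv <- chol2inv(qr.R(fit$qr))
  list(beta = fit$coefficients, rss = rss, logdet = logdet,
       logLik = ll, xtx_inv = xtx_inv, rank = fit$rank)
}

#' Maximum-likelihood estimate of Pagel's lambda for one trait
#'
#' Profiles the Brownian-motion likelihood of a single trait over the
#' lambda transform of the tree covariance (mean and rate maximized
#' analytically; lambda by bounded scalar optimization on \[0, 1\] with
#' tolerance `tol`).  Endpoint likelihoods are checked so boundary maxima
#' (`lambda` of exactly 0 or 1) are returned exactly.
#'
#' @param x Named numeric vector of trait values (names must match the
#'   tree's tip labels).
#' @param tree A `phylo` tree with branch lengths.
#' @param tol Convergence tolerance of the scalar optimization
#'   (default 1e-8).
#' @return List with `lambda`, `logLik` (at the optimum), and `logLik0` /
#'   `logLik1` (at the boundaries).  A constant trait has no defined
#'   lambda; `NA` is returned with a warning.
#' @export
estimate_lambda <- function(x, tree, tol = 1e-8) {
  if (length(x) < 4L)
    stop("at least 4 tips are required to estimate lambda", call. = FALSE)
  x <- x[tree$tip.label]
  if (anyNA(x))
    stop("trait values missing for some tips (or names do not match tip ",
         "labels)", call. = FALSE)
  if (stats::var(x) == 0) {
    warning("trait is constant across tips; lambda is undefined",
            call. = FALSE)
    return(list(lambda = NA_real_, logLik = NA_real_,
                logLik0 = NA_real_, logLik1 = NA_real_))
  }
  V <- ape::vcv(tree)
  d <- diag(V)
  X <- matrix(1, length(x), 1L)
  ll <- function(lam) {
    Vl <- V * lam
    diag(Vl) <- d
    .gls_core(x, X, Vl)$logLik
  }
  opt <- stats::optimize(ll, c(0, 1), maximum = TRUE, tol = tol)
  cand <- c(`0` = ll(0), opt = opt$objective, `1` = ll(1))
  lams <- c(0, opt$maximum, 1)
  best <- which.max(cand)
  list(lambda = lams[best], logLik = unname(cand[best]),
       logLik0 = unname(cand[1L]), logLik1 = unname(cand[3L]))
}

#' Phylogenetic generalized least squares regression
#'
#' Fits `y ~ x` by GLS with error covariance proportional to the
#' lambda-transformed Brownian-motion structure of the tree:
#' `beta = (X' V^-1 X)^-1 X' V^-1 y`.  Lambda is either estimated by
#' maximum likelihood jointly with the regression (`lambda = "ml"`) or held
#' fixed.  Per-tip 95% confidence and prediction intervals are computed
#' under the same covariance (the prediction variance at tip i adds
#' `sigma2 * V[i, i]`), so points lying at or above the upper prediction
#' limit can be flagged.
#'
#' @param y Named numeric response (e.g. log10 agility).
#' @param x Named numeric covariate (e.g. log10 body mass), or a matrix /
#'   data frame of covariates with rows matching tips.
#' @param tree A `phylo` tree with branch lengths.
#' @param lambda `"ml"` (default) or a fixed value in \[0, 1\].
#' @param conf_level Level for the confidence and prediction intervals
#'   (default 0.95).
#' @return An object of class `pgls_result`: list with `coefficients`
#'   (intercept and slopes), `se`, `lambda`, `sigma2` (rate, residual
#'   mean square per unit covariance), `r_squared_gls` (on the whitened
#'   scale, relative to a GLS intercept-only fit), `r_squared_raw` (ordinary
#'   scale), `logLik`, `df_residual`, and a per-tip data frame `intervals`
#'   (`fitted`, `ci_lwr`, `ci_upr`, `pi_lwr`, `pi_upr`, `at_or_above_pi`).
#' @export
pgls_fit <- function(y, x, tree, lambda = "ml", conf_level = 0.95) {
  tips <- tree$tip.label
  n <- length(tips)
  y <- y[tips]
  if (anyNA(y))
    stop("response missing for some tips", call. = FALSE)
  if (is.null(dim(x))) {
    x <- x[tips]
    X <- cbind(intercept = 1, x = as.numeric(x))
  } else {
    x <- as.matrix(x)[tips, , drop = FALSE]
    X <- cbind(intercept = 1, x)
  }
  if (anyNA(X))
    stop("covariate missing for some tips", call. = FALSE)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient", call. = FALSE)

  V <- ape::vcv(tree)
  d <- diag(V)
  make_V <- function(lam) { Vl <- V * lam; diag(Vl) <- d; Vl }

  if (identical(lambda, "ml")) {
    ll <- function(lam) .gls_core(y, X, make_V(lam))$logLik
    opt <- stats::optimize(ll, c(0, 1), maximum = TRUE, tol = 1e-8)
    cand <- c(ll(0), opt$objective, ll(1))
    lambda_hat <- c(0, opt$maximum, 1)[which.max(cand)]
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
      stop("lambda must be \"ml\" or a value in [0, 1]", call. = FALSE)
    lambda_hat <- lambda
  }
  Vl <- make_V(lambda_hat)
  core <- .gls_core(y, X, Vl)
  p <- ncol(X)
  df <- n - p
  sigma2 <- core$rss / df
  se <- sqrt(sigma2 * diag(core$xtx_inv))
  fitted <- drop(X %*% core$beta)

  null_core <- .gls_core(y, matrix(1, n, 1L), Vl)
  r2_gls <- 1 - core$rss / null_core$rss
  r2_raw <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)

  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
  var_fit <- sigma2 * rowSums((X %*% core$xtx_inv) * X)
  ci_half <- tcrit * sqrt(var_fit)
  pi_half <- tcrit * sqrt(var_fit + sigma2 * d)
  intervals <- data.frame(
    tip = tips, y = as.numeric(y), fitted = fitted,
    ci_lwr = fitted - ci_half, ci_upr = fitted + ci_half,
    pi_lwr = fitted - pi_half, pi_upr = fitted + pi_half,
    at_or_above_pi = as.numeric(y) >= fitted + pi_half,
    stringsAsFactors = FALSE)

  structure(list(coefficients = stats::setNames(core$beta, colnames(X)),
                 se = stats::setNames(se, colnames(X)),
                 lambda = lambda_hat, sigma2 = sigma2,
                 r_squared_gls = r2_gls, r_squared_raw = r2_raw,
                 logLik = core$logLik, df_residual = df,
                 conf_level = conf_level, intervals = intervals),
            class = "pgls_result")
}

#' @export
print.pgls_result <- function(x, ...) {
  cat("Phylogenetic GLS fit (lambda = ",
      format(x$lambda, digits = 4), ")\n", sep = "")
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = x$se)
  print(round(tab, 5))
  cat("R^2 (GLS): ", format(x$r_squared_gls, digits = 4),
      "   R^2 (raw): ", format(x$r_squared_raw, digits = 4),
      "   residual df: ", x$df_residual, "\n", sep = "")
  invisible(x)
}

#' Default grade comparisons for the agility analysis
#'
#' The three grade-wise hypotheses tested on the canonical grouping of
#' specimens into adult tyrannosaurids, juvenile tyrannosaurids, and other
#' theropods: (1) any difference among the three groups; (2) juveniles
#' versus adult tyrannosaurids (with other theropods always kept as their
#' own grade); (3) all tyrannosaurids versus other theropods.  Each
#' comparison is a reduced-versus-full pair of grade assignments; `NULL`
#' means a single common grade.
#'
#' @param levels Character vector of the three group labels in the order
#'   adult, juvenile, other.
#' @return Named list of comparisons usable by [phyl_ancova()].
#' @export
default_agility_comparisons <- function(levels = c("tyrannosaurid_adult",
                                                   "tyrannosaurid_juvenile",
                                                   "other")) {
  stopifnot(length(levels) == 3L)
  adult <- levels[1L]; juv <- levels[2L]; other <- levels[3L]
  tyr_vs_other <- stats::setNames(c("tyr", "tyr", "other"),
                                  c(adult, juv, other))
  identity_map <- stats::setNames(levels, levels)
  list(
    among_groups = list(reduced = NULL, full = identity_map),
    juvenile_vs_adult = list(reduced = tyr_vs_other, full = identity_map),
    tyrannosaurs_vs_others = list(reduced = NULL, full = tyr_vs_other))
}

#' Grade-wise phylogenetic ANCOVA
#'
#' Tests whether groups of tips occupy distinct grades (intercept offsets,
#' optionally also slopes) on the `y ~ x` phylogenetic regression, using
#' nested-model F-tests on covariance-whitened residuals while preserving
#' the whole-sample phylogenetic covariance.  For each comparison a reduced
#' and a full grade assignment are fitted by GLS under one shared lambda
#' (estimated once on the pooled single-grade model, so nested models are
#' compared like with like) and
#' `F = ((RSS_red - RSS_full) / ddf) / (RSS_full / df_full)`.
#' The conditional error probability `alpha(p)` of each p-value is appended.
#'
#' @inheritParams pgls_fit
#' @param groups Named character/factor assigning every tip to exactly one
#'   group.
#' @param comparisons Named list of comparisons, each a list with elements
#'   `reduced` and `full`; each element is either `NULL` (single common
#'   grade) or a named map from group level to grade label.  Defaults to
#'   [default_agility_comparisons()] when the groups carry the canonical
#'   three levels, otherwise to a single among-groups comparison.
#' @param lambda `"ml"` (shared ML estimate from the pooled model) or a
#'   fixed value in \[0, 1\].
#' @param grade_model `"intercept"` (default: grades differ in intercept
#'   only) or `"intercept_slope"` (grades free in slope too).
#' @return A data frame with one row per comparison: `comparison`, `F`,
#'   `df1`, `df2`, `p`, `alpha_p`; attribute `lambda` records the shared
#'   lambda used.
#' @export
phyl_ancova <- function(y, x, tree, groups, comparisons = NULL,
                        lambda = "ml",
                        grade_model = c("intercept", "intercept_slope")) {
  grade_model <- match.arg(grade_model)
  tips <- tree$tip.label
  n <- length(tips)
  y <- y[tips]
  x <- x[tips]
  groups <- as.character(groups[tips])
  if (anyNA(y) || anyNA(x) || anyNA(groups))
    stop("y, x and groups must cover every tip", call. = FALSE)

  canonical <- c("tyrannosaurid_adult", "tyrannosaurid_juvenile", "other")
  if (is.null(comparisons)) {
    comparisons <- if (setequal(unique(groups), canonical))
      default_agility_comparisons(canonical)
    else {
      ids <- sort(unique(groups))
      list(among_groups = list(reduced = NULL,
                               full = stats::setNames(ids, ids)))
    }
  }

  V <- ape::vcv(tree)
  d <- diag(V)
  make_V <- function(lam) { Vl <- V * lam; diag(Vl) <- d; Vl }
  X_pooled <- cbind(1, x)
  if (identical(lambda, "ml")) {
    ll <- function(lam) .gls_core(y, X_pooled, make_V(lam))$logLik
    opt <- stats::optimize(ll, c(0, 1), maximum = TRUE, tol = 1e-8)
    cand <- c(ll(0), opt$objective, ll(1))
    lambda <- c(0, opt$maximum, 1)[which.max(cand)]
  } else if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
    stop("lambda must be \"ml\" or a value in [0, 1]", call. = FALSE)
  Vl <- make_V(lambda)

  design <- function(map) {
    if (is.null(map)) return(X_pooled)
    grade <- map[groups]
    if (anyNA(grade))
      stop("grade map does not cover group(s): ",
           paste(setdiff(unique(groups), names(map)), collapse = ", "),
           call. = FALSE)
    counts <- table(grade)
    if (any(counts < 2L))
      stop("grade '", names(counts)[which(counts < 2L)[1L]],
           "' has fewer than 2 tips; insufficient data", call. = FALSE)
    if (length(counts) == 1L) return(X_pooled)  # single grade
    G <- stats::model.matrix(~ 0 + factor(grade))
    if (grade_model == "intercept") cbind(G, x) else cbind(G, G * x)
  }

  rows <- lapply(names(comparisons), function(nm) {
    cmp <- comparisons[[nm]]
    Xr <- design(cmp$reduced)
    Xf <- design(cmp$full)
    fr <- .gls_core(y, Xr, Vl)
    ff <- .gls_core(y, Xf, Vl)
    df1 <- ff$rank - fr$rank
    df2 <- n - ff$rank
    if (df1 <= 0L) {
      Fv <- 0; pv <- 1
    } else {
      Fv <- max(0, (fr$rss - ff$rss) / df1 / (ff$rss / df2))
      pv <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
    }
    alpha <- if (pv > 0 && pv < 1) conditional_error_probability(pv)
             else NA_real_
    data.frame(comparison = nm, F = Fv, df1 = df1, df2 = df2,
               p = pv, alpha_p = alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "lambda") <- lambda
  out
}
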