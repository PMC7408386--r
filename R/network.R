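# Shrinkage-based Gaussian graphical model estimation.
#
# The estimator follows the shrinkage partial-correlation approach used for
# small-n-large-p omics data: (1) the sample correlation matrix is shrunk
# toward the identity with an analytically chosen intensity lambda*; (2)
# partial correlations are obtained from the standardized negative inverse;
# (3) edge significance comes from fitting the null density
# f0(r; kappa) ~ (1 - r^2)^((kappa-3)/2) to the observed off-diagonal
# partial correlations (kappa plays the role of the effective degrees of
# freedom), with tail-area p-values and Benjamini-Hochberg selection.

#' Shrinkage estimate of the correlation matrix
#'
#' Computes the sample correlation matrix R and shrinks it toward the
#' identity: `R* = lambda I + (1 - lambda) R`, with the analytic intensity
#' `lambda* = sum Var(r_ij) / sum r_ij^2` (sums over i != j, clipped to
#' \[0, 1\]), where `Var(r_ij)` is the unbiased empirical variance of the
#' standardized cross-products. `R*` is positive definite whenever
#' `lambda > 0`.
#'
#' @param X Numeric n-by-p data matrix, n >= 3, p >= 2; constant columns
#'   are rejected.
#' @param lambda Optional fixed shrinkage intensity overriding the analytic
#'   choice (e.g. 0 for the raw sample correlation).
#' @return List with components `R` (shrunken p-by-p correlation matrix)
#'   and `lambda`.
#' @export
shrinkage_correlation <- function(X, lambda = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(n >= 3, p >= 2)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(X)[which(sds == 0)[1]] %||% which(sds == 0)[1]
    stop("constant column (zero variance): glycan ", bad)
  }
  Z <- scale(X)                      # centered, sd with denominator n-1
  R <- crossprod(Z) / (n - 1)
  diag(R) <- 1
  if (is.null(lambda)) {
    # Var-hat(r_ij) = n / (n-1)^3 * sum_k (w_kij - wbar_ij)^2,
    # w_kij = z_ki * z_kj
    W1 <- crossprod(Z) / n                       # mean of w over k
    W2 <- crossprod(Z^2) / n                     # mean of w^2 over k
    Vr <- n / (n - 1)^3 * n * (W2 - W1^2)
    off <- upper.tri(R)
    denom <- sum(R[off]^2)
    lambda <- if (denom == 0) 1 else sum(Vr[off]) / denom
    lambda <- min(1, max(0, lambda))
  } else {
    stopifnot(lambda >= 0, lambda <= 1)
  }
  Rs <- (1 - lambda) * R
  diag(Rs) <- 1
  dimnames(Rs) <- list(colnames(X), colnames(X))
  list(R = Rs, lambda = lambda)
}

#' Partial correlations from a correlation matrix
#'
#' Standardized negative inverse: with `Omega = R^{-1}`,
#' `pcor_ij = -Omega_ij / sqrt(Omega_ii * Omega_jj)`, diagonal one.
#'
#' @param R Positive definite correlation matrix.
#' @return Symmetric partial-correlation matrix with unit diagonal.
#' @export
partial_correlations <- function(R) {
  ch <- tryCatch(chol(R), error = function(e)
    stop("correlation matrix is not positive definite"))
  Om <- chol2inv(ch)
  D <- sqrt(diag(Om))
  P <- -Om / tcrossprod(D)
  diag(P) <- 1
  P <- (P + t(P)) / 2
  dimnames(P) <- dimnames(R)
  P
}

null_loglik <- function(kappa, r, log_trunc = NULL) {
  # f0(r; kappa) = (1 - r^2)^((kappa-3)/2) / Beta(1/2, (kappa-1)/2)
  ll <- sum((kappa - 3) / 2 * log1p(-r^2)) -
    length(r) * lbeta(0.5, (kappa - 1) / 2)
  if (!is.null(log_trunc)) ll <- ll - length(r) * log_trunc(kappa)
  ll
}

#' Fit the empirical null of partial correlations
#'
#' Fits the null density `f0(r; kappa) ~ (1 - r^2)^((kappa-3)/2)` to the
#' observed off-diagonal partial correlations by maximum likelihood.
#' Under the null-majority assumption only a minority of coefficients are
#' real edges, so the plain MLE is robustified by iterative tail
#' exclusion: after an initial fit on all values, values beyond the fitted
#' null's upper `alpha` tail (`P(|R| >= c) = alpha` under `f0`) are set
#' aside and `kappa` is refit by a truncated likelihood on the central
#' region (the truncation probability enters the likelihood, so the
#' estimate stays consistent for the null component while true edges in
#' the far tail are ignored). A few iterations suffice; `alpha = 0`
#' disables the robustification.
#'
#' @param r Numeric vector of (off-diagonal) partial correlations,
#'   length >= 10.
#' @param alpha Null tail mass excluded per iteration (default 0.05).
#' @param max_iter Maximum exclusion iterations (default 10).
#' @param kappa_max Upper bound for kappa (default 1e7); hitting it flags a
#'   degenerate fit (e.g. all values zero) with a warning.
#' @return Estimated `kappa` (> 3).
#' @export
estimate_kappa <- function(r, alpha = 0.05, max_iter = 10, kappa_max = 1e7) {
  r <- r[!is.na(r)]
  stopifnot(length(r) >= 10, all(abs(r) <= 1), alpha >= 0, alpha < 0.5)
  if (all(r == 0)) {
    warning("all partial correlations are zero: kappa is degenerate ",
            "(returning upper bound)")
    return(kappa_max)
  }
  fit_one <- function(rfit, log_trunc = NULL) {
    # optimize over u = log(kappa - 3) for a well-scaled search
    obj <- function(u) -null_loglik(3 + exp(u), rfit, log_trunc)
    opt <- stats::optimize(obj, interval = c(log(1e-2), log(kappa_max - 3)))
    3 + exp(opt$minimum)
  }
  kappa <- fit_one(r)
  if (alpha > 0) {
    for (it in seq_len(max_iter)) {
      # exclusion threshold at the fitted null's upper alpha tail:
      # r^2 ~ Beta(1/2, (kappa-1)/2) under f0
      cut <- sqrt(stats::qbeta(1 - alpha, 0.5, (kappa - 1) / 2))
      rfit <- r[abs(r) <= cut]
      if (length(rfit) < 10 || all(rfit == 0)) break
      log_trunc <- function(k)
        stats::pbeta(cut^2, 0.5, (k - 1) / 2, log.p = TRUE)
      knew <- fit_one(rfit, log_trunc)
      if (abs(log(knew - 3 + 1e-12) - log(kappa - 3 + 1e-12)) < 1e-4) {
        kappa <- knew
        break
      }
      kappa <- knew
    }
  }
  if (kappa > 0.99 * kappa_max)
    warning("kappa at upper bound: null fit is degenerate")
  kappa
}

#' Edge p-values for partial correlations
#'
#' Two-sided tail-area p-values per unordered pair. Method
#' `"null_density"` uses the fitted empirical null: under `f0(r; kappa)`,
#' `r^2 ~ Beta(1/2, (kappa-1)/2)`, so `P(|R| >= |r|)` has an
#' incomplete-beta closed form. Method `"fisher_z"` uses
#' `z = atanh(r) * sqrt(df - 3)` with a normal tail.
#'
#' @param pcor Partial-correlation matrix (or numeric vector).
#' @param kappa Null parameter (> 3), required for `"null_density"`.
#' @param method `"null_density"` (default) or `"fisher_z"`.
#' @param df Effective degrees of freedom for `"fisher_z"` (> 3).
#' @return Object of the same shape as `pcor` with p-values in \[0, 1\]
#'   (matrix input: symmetric, diagonal `NA`).
#' @export
edge_pvalues <- function(pcor, kappa = NULL,
                         method = c("null_density", "fisher_z"), df = NULL) {
  method <- match.arg(method)
  r <- if (is.matrix(pcor)) pcor[row(pcor) != col(pcor)] else pcor
  p <- if (method == "null_density") {
    stopifnot(!is.null(kappa), kappa > 3)
    stats::pbeta(r^2, 0.5, (kappa - 1) / 2, lower.tail = FALSE)
  } else {
    stopifnot(!is.null(df), df > 3)
    2 * stats::pnorm(-abs(atanh(r)) * sqrt(df - 3))
  }
  if (!is.matrix(pcor)) return(p)
  out <- pcor
  out[row(out) != col(out)] <- p
  diag(out) <- NA_real_
  out
}

#' Benjamini-Hochberg edge selection
#'
#' Standard BH step-up over all p(p-1)/2 unordered pairs at FDR level `q`.
#'
#' @param pvals Symmetric p-value matrix (diagonal ignored).
#' @param q FDR level (default 0.01).
#' @return Two-column character (or integer, if unnamed) matrix of selected
#'   unordered pairs.
#' @export
bh_select <- function(pvals, q = 0.01) {
  stopifnot(is.matrix(pvals), nrow(pvals) == ncol(pvals), q > 0, q < 1)
  ut <- which(upper.tri(pvals), arr.ind = TRUE)
  p <- pvals[upper.tri(pvals)]
  sel <- which(stats::p.adjust(p, method = "BH") <= q)
  nm <- colnames(pvals)
  if (is.null(nm)) {
    cbind(ut[sel, 1], ut[sel, 2])
  } else {
    canonical_edges(nm[ut[sel, 1]], nm[ut[sel, 2]])
  }
}

#' Fit a Gaussian graphical model by shrinkage partial correlations
#'
#' The core estimator: shrinks the sample correlation toward the identity
#' ([shrinkage_correlation()]), converts to partial correlations
#' ([partial_correlations()]), fits the empirical null
#' ([estimate_kappa()]), computes tail-area edge p-values
#' ([edge_pvalues()]), and selects edges by BH at FDR `q`
#' ([bh_select()]). Deterministic given its input; invariant to the order
#' of samples.
#'
#' @param d A [glycomics_dataset()] (complete-case) or numeric
#'   samples-by-glycans matrix with at least 3 samples.
#' @param q FDR level for edge selection (default 0.01).
#' @param method Significance method, see [edge_pvalues()].
#' @param lambda Optional fixed shrinkage intensity (see
#'   [shrinkage_correlation()]).
#' @param alpha Robustification parameter of the null fit, see
#'   [estimate_kappa()].
#' @return An object of class `"ggm"`: list with `pcor`, `lambda`, `kappa`,
#'   `pvals`, `edges` (two-column matrix), `q`, `method`, `n`, `p`,
#'   `nodes`.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(300), 100, 3)
#' X[, 2] <- X[, 2] + X[, 1]
#' fit <- infer_ggm(X, q = 0.05)
#' fit
#' @export
infer_ggm <- function(d, q = 0.01, method = c("null_density", "fisher_z"),
                      lambda = NULL, alpha = 0.05) {
  method <- match.arg(method)
  X <- abund(d)
  check_complete(X, "infer_ggm")
  stopifnot(nrow(X) >= 3)
  # the empirical-null fit needs a usable number of pairs; tiny networks
  # fall back to the Fisher-z test
  if (method == "null_density" && choose(ncol(X), 2) < 10)
    method <- "fisher_z"
  sc <- shrinkage_correlation(X, lambda = lambda)
  P <- partial_correlations(sc$R)
  kappa <- if (method == "null_density") {
    suppressWarnings(estimate_kappa(P[upper.tri(P)], alpha = alpha))
  } else NA_real_
  pv <- edge_pvalues(P, kappa = kappa, method = method,
                     df = nrow(X) - (ncol(X) - 2))
  edges <- bh_select(pv, q = q)
  structure(list(pcor = P, lambda = sc$lambda, kappa = kappa, pvals = pv,
                 edges = edges, q = q, method = method,
                 n = nrow(X), p = ncol(X),
                 nodes = colnames(X) %||% as.character(seq_len(ncol(X)))),
            class = "ggm")
}

#' @export
print.ggm <- function(x, ...) {
  cat(sprintf("<GGM> %d nodes, %d edges at FDR %g (n = %d)\n",
              x$p, nrow(x$edges), x$q, x$n))
  cat(sprintf("  shrinkage lambda = %.4f%s\n", x$lambda,
              if (is.finite(x$kappa))
                sprintf(", null kappa = %.1f", x$kappa) else ""))
  invisible(x)
}

#' @export
summary.ggm <- function(object, ...) {
  off <- object$pcor[upper.tri(object$pcor)]
  structure(list(ggm = object,
                 pcor_range = range(off),
                 n_edges = nrow(object$edges),
                 n_pairs = length(off)),
            class = "summary.ggm")
}

#' @export
print.summary.ggm <- function(x, ...) {
  print(x$ggm)
  cat(sprintf("  partial correlations in [%.3f, %.3f]; %d of %d pairs selected\n",
              x$pcor_range[1], x$pcor_range[2], x$n_edges, x$n_pairs))
  invisible(x)
}

#' @export
coef.ggm <- function(object, ...) object$pcor

#' Edge table of a fitted GGM
#'
#' @param x A `"ggm"` object.
#' @param all Include non-selected pairs (default `FALSE`).
#' @param ... Unused.
#' @return Data.frame with columns node1, node2, pcor, p, selected.
#' @export
as.data.frame.ggm <- function(x, all = FALSE, ...) {
  ut <- which(upper.tri(x$pcor), arr.ind = TRUE)
  nm <- x$nodes
  df <- data.frame(node1 = pmin(nm[ut[, 1]], nm[ut[, 2]]),
                   node2 = pmax(nm[ut[, 1]], nm[ut[, 2]]),
                   pcor = x$pcor[ut], p = x$pvals[ut],
                   stringsAsFactors = FALSE)
  df$selected <- edge_keys(cbind(df$node1, df$node2)) %in% edge_keys(x$edges)
  if (!all) df <- df[df$selected, , drop = FALSE]
  df[order(df$p), ]
}

#' Plot a fitted GGM
#'
#' Draws the FDR-selected edge set as an undirected graph (via igraph);
#' edge width scales with |partial correlation|.
#'
#' @param x A `"ggm"` object.
#' @param ... Passed to `igraph::plot.igraph`.
#' @export
plot.ggm <- function(x, ...) {
  df <- as.data.frame(x)
  g <- igraph::graph_from_data_frame(df[, c("node1", "node2")],
                                     directed = FALSE, vertices = x$nodes)
  w <- abs(df$pcor)
  igraph::plot.igraph(g, edge.width = 1 + 4 * w / max(w, 0.01),
                      vertex.size = 6, vertex.label.cex = 0.6, ...)
  invisible(x)
}

#' Simulate data from a fitted GGM
#'
#' Draws multivariate normal samples with the fitted (shrunken) correlation
#' matrix — useful for parametric-bootstrap checks.
#'
#' @param object A `"ggm"` object.
#' @param nsim Number of samples.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return Numeric `nsim`-by-p matrix.
#' @export
simulate.ggm <- function(object, nsim = object$n, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  # reconstruct the shrunken correlation from pcor is lossy; use pcor's
  # implied precision instead: Omega with unit partial variances
  P <- object$pcor
  Om <- -P
  diag(Om) <- 1
  S <- stats::cov2cor(solve(Om))
  X <- MASS::mvrnorm(nsim, mu = rep(0, object$p), Sigma = S)
  colnames(X) <- object$nodes
  X
}

#' Export a GGM as edge-list and matrix TSVs
#'
#' @param x A `"ggm"` object.
#' @param edge_path TSV path for the per-pair table (node1, node2, pcor, p,
#'   selected).
#' @param matrix_path Optional TSV path for the full partial-correlation
#'   matrix.
#' @return Invisibly, `x`.
#' @export
write_ggm <- function(x, edge_path, matrix_path = NULL) {
  utils::write.table(as.data.frame(x, all = TRUE), edge_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(matrix_path))
    utils::write.table(data.frame(node = x$nodes, x$pcor,
                                  check.names = FALSE),
                       matrix_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(x)
}
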