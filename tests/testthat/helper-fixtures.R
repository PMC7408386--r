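# Shared fixtures: all synthetic, generated in code.

# random strictly positive abundance matrix (log-normal)
rand_pos_matrix <- function(n, p, seed = 1, meanlog = 0, sdlog = 1) {
  set.seed(seed)
  m <- matrix(exp(rnorm(n * p, meanlog, sdlog)), n, p,
              dimnames = list(paste0("S", 1:n), paste0("G", 1:p)))
  m
}

igg1_panel <- function() {
  pan <- igg_glycoforms()
  pan[pan$subclass == "IgG1", ]
}

igg1_pathway <- function() build_igg_fc_pathway(igg1_panel())

# small LC-ESI-MS-shaped dataset (50 glycans, 20/20/10 subclasses)
lc_dataset <- function(n = 40, seed = 1, sigma_d = 0, sigma = 0.5) {
  pw <- build_igg_fc_pathway(igg_glycoforms())
  cfg <- simulation_config(pw, n = n, rho = 0.3, sigma = sigma,
                           sigma_d = sigma_d, seed = seed)
  d <- apply_artifacts(sample_abundances(cfg), cfg)
  d$platform <- "lc-esi-ms"
  d$glycan_meta <- data.frame(subclass = igg_glycoforms()$subclass,
                              row.names = colnames(d$abundance))
  d
}

# abundance matrix stripped of audit attributes, for comparisons
abundmat <- function(d) {
  m <- if (inherits(d, "glycomics_dataset")) d$abundance else d
  attr(m, "dilution") <- NULL
  m
}

# brute-force oracle for single-step enzymatic edges: explicit field
# comparison over all pairs
brute_force_edges <- function(comps) {
  ids <- names(comps)
  out <- matrix(character(), ncol = 2)
  fields <- c("hexose", "hexnac", "fucose", "neuac")
  for (i in seq_along(comps)) for (j in seq_along(comps)) {
    if (i >= j) next
    diffs <- vapply(fields, function(f)
      abs(comps[[i]][[f]] - comps[[j]][[f]]), numeric(1))
    if (sum(diffs == 0) == 3 && sum(diffs == 1) == 1)
      out <- rbind(out, sort(c(ids[i], ids[j])))
  }
  if (nrow(out)) out[order(out[, 1], out[, 2]), , drop = FALSE] else out
}

random_composition_panel <- function(p, seed) {
  set.seed(seed)
  comps <- list()
  while (length(comps) < p) {
    cc <- c(sample(0:6, 1), sample(0:6, 1), sample(0:2, 1), sample(0:3, 1))
    if (sum(cc) == 0) next
    key <- sprintf("H%dN%dF%dS%d", cc[1], cc[2], cc[3], cc[4])
    if (key %in% names(comps)) next
    comps[[key]] <- glycan_composition(cc[1], cc[2], cc[3], cc[4], label = key)
  }
  comps
}

# pairwise Schur-complement (residual-covariance) oracle for partial
# correlation of (i, j) given all other variables
pcor_schur_oracle <- function(R, i, j) {
  rest <- setdiff(seq_len(nrow(R)), c(i, j))
  if (length(rest) == 0) return(R[i, j])
  S <- R[c(i, j), c(i, j)] -
    R[c(i, j), rest, drop = FALSE] %*%
    solve(R[rest, rest, drop = FALSE], R[rest, c(i, j), drop = FALSE])
  S[1, 2] / sqrt(S[1, 1] * S[2, 2])
}

random_pd_correlation <- function(p, seed) {
  set.seed(seed)
  A <- matrix(rnorm(p * (p + 3)), p + 3, p)
  stats::cov2cor(crossprod(A) / (p + 3))
}

edge_key_set <- function(edges) {
  if (nrow(edges) == 0) return(character())
  paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]), sep = "|")
}

# exhaustive hypergeometric tail oracle via explicit binomial coefficients
fisher_greater_oracle <- function(tp, fp, fn, tn) {
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn); tn <- unname(tn)
  M <- tp + fp + fn + tn; K <- tp + fn; n <- tp + fp
  ks <- max(0, n - (M - K)):min(K, n)
  tot <- 0
  for (i in ks[ks >= tp]) tot <- tot + choose(K, i) * choose(M - K, n - i)
  tot / choose(M, n)
}
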