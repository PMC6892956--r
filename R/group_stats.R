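# Vectorized two-sample Welch t over the columns of a subjects x variables
# matrix, given a logical group indicator.  One code path serves both the
# observed statistic and the permutation null (cross-checked against
# stats::t.test in the tests).
welch_t_cols <- function(X, in_a) {
  na <- sum(in_a); nb <- sum(!in_a)
  ma <- colMeans(X[in_a, , drop = FALSE])
  mb <- colMeans(X[!in_a, , drop = FALSE])
  va <- colSums(sweep(X[in_a, , drop = FALSE], 2, ma)^2) / (na - 1)
  vb <- colSums(sweep(X[!in_a, , drop = FALSE], 2, mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df)
}

perm_p_value <- function(observed, null_stats, tails) {
  B <- length(null_stats)
  hits <- switch(tails,
                 two = sum(abs(null_stats) >= abs(observed)),
                 greater = sum(null_stats >= observed),
                 less = sum(null_stats <= observed))
  (1 + hits) / (1 + B)   # add-one estimator: never exactly 0
}

#' Permutation test result
#' @param observed_stat observed test statistic.
#' @param null_stats vector of B permutation statistics.
#' @param p_value permutation p (add-one convention).
#' @param seed RNG seed used.
#' @param tails `"two"`, `"greater"` or `"less"`.
#' @export
permutation_result <- function(observed_stat, null_stats, p_value, seed, tails) {
  stopifnot(p_value > 0, p_value <= 1)
  structure(list(observed_stat = observed_stat, null_stats = null_stats,
                 p_value = p_value, B = length(null_stats), seed = seed,
                 tails = tails),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> stat = %.4g, p = %.4g (B = %d, %s-tailed)\n",
              x$observed_stat, x$p_value, x$B, x$tails))
  invisible(x)
}

#' Residualize subject-level values against covariates
#'
#' Removes the least-squares projection onto `[1, covariates]`; residuals
#' are orthogonal to every covariate column.  Collinear covariates fall
#' back to the pseudo-inverse with a warning.
#'
#' @param values numeric vector or subjects x variables matrix.
#' @param covariates subjects x covariates numeric matrix or data.frame.
#' @return residuals with the shape of `values`.
#' @export
residualize_covariates <- function(values, covariates) {
  v <- as.matrix(values)
  Z <- cbind(1, as.matrix(covariates))
  if (anyNA(Z)) nvf_stop("nvf_validation_error", "covariates must be complete")
  if (nrow(v) != nrow(Z)) nvf_stop("nvf_validation_error", "row count mismatch")
  if (nrow(Z) <= ncol(Z)) {
    nvf_stop("nvf_validation_error", "need n_subjects > n_covariates + 1")
  }
  qr_ <- qr(Z)
  if (qr_$rank < ncol(Z)) {
    warning("collinear covariates; using pseudo-inverse")
    s <- svd(Z)
    pos <- s$d > max(s$d) * 1e-10
    U <- s$u[, pos, drop = FALSE]
    res <- v - U %*% crossprod(U, v)
  } else {
    res <- v - Z %*% qr.coef(qr_, v)[seq_len(ncol(Z)), , drop = FALSE]
  }
  if (is.null(dim(values))) drop(res) else res
}

#' Permutation test for a group difference in means
#'
#' Observed statistic: Welch t between the groups.  The null is built by
#' randomly reassigning subjects to groups (sizes preserved) B times; p
#' follows the add-one convention `(1 + #extreme) / (1 + B)`.
#'
#' @param group_a,group_b numeric vectors of per-subject scalars.
#' @param B number of permutations (default 1000).
#' @param seed RNG seed.
#' @param tails `"two"` (default), `"greater"` or `"less"`.
#' @return a `permutation_result`.
#' @export
permutation_mean_diff <- function(group_a, group_b, B = 1000, seed = 1,
                                  tails = c("two", "greater", "less")) {
  tails <- match.arg(tails)
  if (!length(group_a) || !length(group_b)) {
    nvf_stop("nvf_validation_error", "both groups must be non-empty")
  }
  pooled <- c(group_a, group_b)
  if (var(pooled) == 0) nvf_stop("nvf_validation_error", "zero pooled variance")
  na <- length(group_a)
  in_a <- c(rep(TRUE, na), rep(FALSE, length(group_b)))
  X <- matrix(pooled, ncol = 1)
  observed <- welch_t_cols(X, in_a)$t
  old <- get0(".Random.seed", globalenv())
  set.seed(seed)
  null_stats <- vapply(seq_len(B), function(b) {
    welch_t_cols(X, sample(in_a))$t
  }, 0)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  permutation_result(observed, null_stats,
                     perm_p_value(observed, null_stats, tails), seed, tails)
}

# stack the upper triangles of per-subject connectivity matrices into a
# subjects x edges matrix (Fisher z applied to correlation metrics first)
stack_edges <- function(matrices) {
  cm1 <- matrices[[1]]
  ut <- upper.tri(cm1$values)
  vals <- t(vapply(matrices, function(cm) {
    v <- cm$values
    if (cm$metric == "pearson_r") {
      off <- row(v) != col(v)
      v[off] <- atanh(pmin(pmax(v[off], -(1 - 1e-7)), 1 - 1e-7))
    }
    v[ut]
  }, numeric(sum(ut))))
  idx <- which(ut, arr.ind = TRUE)
  list(X = vals, i = idx[, 1], j = idx[, 2], labels = cm1$labels, n = nrow(cm1$values))
}

#' Edgewise two-sample t maps over connectivity matrices
#'
#' Per off-diagonal entry, a two-sample Welch t across subjects (computed on
#' Fisher-z values when the metric is `pearson_r`, raw values for SL) with
#' two-tailed parametric p.  Edges with zero variance in both groups are
#' returned as `NA` and logged.
#'
#' @param matrices_a,matrices_b lists of `connectivity_matrix` sharing labels.
#' @return list with symmetric `t` and `p` matrices (`NA` diagonal).
#' @export
edgewise_t <- function(matrices_a, matrices_b) {
  if (length(matrices_a) < 2 || length(matrices_b) < 2) {
    nvf_stop("nvf_validation_error", "need >= 2 subjects per group")
  }
  if (!identical(matrices_a[[1]]$labels, matrices_b[[1]]$labels)) {
    nvf_stop("nvf_validation_error", "matrices do not share labels")
  }
  sa <- stack_edges(matrices_a); sb <- stack_edges(matrices_b)
  X <- rbind(sa$X, sb$X)
  in_a <- c(rep(TRUE, nrow(sa$X)), rep(FALSE, nrow(sb$X)))
  wt <- welch_t_cols(X, in_a)
  degenerate <- !is.finite(wt$t)
  if (any(degenerate)) {
    message(sum(degenerate), " edge(s) with zero variance in both groups masked")
  }
  p_edge <- 2 * pt(abs(wt$t), wt$df, lower.tail = FALSE)
  n <- sa$n
  tmat <- matrix(NA_real_, n, n, dimnames = list(sa$labels, sa$labels))
  pmat <- tmat
  tmat[cbind(sa$i, sa$j)] <- ifelse(degenerate, NA, wt$t)
  pmat[cbind(sa$i, sa$j)] <- ifelse(degenerate, NA, p_edge)
  tmat[lower.tri(tmat)] <- t(tmat)[lower.tri(tmat)]
  pmat[lower.tri(pmat)] <- t(pmat)[lower.tri(pmat)]
  list(t = tmat, p = pmat)
}

# cluster supra-threshold edges: two edges are adjacent iff they share an
# electrode, i.e. clusters are the connected components of the graph whose
# edge set is the supra-threshold set.  Returns the summed |t| of the
# heaviest cluster and (optionally) the component membership.
max_cluster_mass <- function(i, j, tvals, n, detail = FALSE) {
  if (!length(i)) {
    return(if (detail) list(mass = 0, clusters = list(), masses = numeric()) else 0)
  }
  g <- igraph::graph_from_edgelist(cbind(i, j), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  cl_of_edge <- comp[i]
  masses <- tapply(abs(tvals), cl_of_edge, sum)
  if (!detail) return(max(masses))
  ids <- names(sort(masses, decreasing = TRUE))
  clusters <- lapply(ids, function(id) which(cl_of_edge == as.integer(id)))
  list(mass = max(masses), clusters = clusters,
       masses = as.numeric(masses[ids]))
}

#' Cluster-based permutation test over an electrode-pair network
#'
#' Edges with uncorrected Welch p below `forming_alpha` are clustered by
#' shared electrode endpoints; each cluster's mass is its summed |t|.  The
#' null distribution is the maximum cluster mass over `B` random relabelings
#' of subjects, giving family-wise-corrected cluster p-values.
#'
#' @inheritParams edgewise_t
#' @param forming_alpha cluster-forming threshold on uncorrected p (default
#'   0.05).
#' @param B permutations (default 1000).
#' @param seed RNG seed.
#' @return a `cluster_result`: `clusters` (lists of edge index pairs),
#'   `cluster_mass`, `cluster_p`, `edge_t`, `edge_p`, `null_max_mass`.
#' @export
cbpt <- function(matrices_a, matrices_b, forming_alpha = 0.05, B = 1000,
                 seed = 1) {
  sa <- stack_edges(matrices_a); sb <- stack_edges(matrices_b)
  X <- rbind(sa$X, sb$X)
  in_a <- c(rep(TRUE, nrow(sa$X)), rep(FALSE, nrow(sb$X)))
  obs <- welch_t_cols(X, in_a)
  p_edge <- 2 * pt(abs(obs$t), obs$df, lower.tail = FALSE)
  supra <- which(is.finite(obs$t) & p_edge < forming_alpha)
  detail <- max_cluster_mass(sa$i[supra], sa$j[supra], obs$t[supra], sa$n,
                             detail = TRUE)

  old <- get0(".Random.seed", globalenv())
  set.seed(seed)
  null_max <- vapply(seq_len(B), function(b) {
    lab <- sample(in_a)
    wt <- welch_t_cols(X, lab)
    pp <- 2 * pt(abs(wt$t), wt$df, lower.tail = FALSE)
    s <- which(is.finite(wt$t) & pp < forming_alpha)
    max_cluster_mass(sa$i[s], sa$j[s], wt$t[s], sa$n)
  }, 0)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())

  clusters <- lapply(detail$clusters, function(edge_sel) {
    cbind(i = sa$i[supra][edge_sel], j = sa$j[supra][edge_sel])
  })
  cluster_p <- vapply(detail$masses, function(m) perm_p_value(m, null_max, "greater"), 0)

  n <- sa$n
  tmat <- matrix(NA_real_, n, n, dimnames = list(sa$labels, sa$labels))
  pmat <- tmat
  tmat[cbind(sa$i, sa$j)] <- obs$t
  pmat[cbind(sa$i, sa$j)] <- p_edge
  tmat[lower.tri(tmat)] <- t(tmat)[lower.tri(tmat)]
  pmat[lower.tri(pmat)] <- t(pmat)[lower.tri(pmat)]

  structure(list(clusters = clusters, cluster_mass = detail$masses,
                 cluster_p = cluster_p, edge_t = tmat, edge_p = pmat,
                 null_max_mass = null_max, labels = sa$labels,
                 forming_alpha = forming_alpha, B = B, seed = seed,
                 adjacency_rule = "edges adjacent iff they share an electrode endpoint"),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s); ", length(x$clusters)))
  if (length(x$clusters)) {
    cat(sprintf("largest mass %.3g (p = %.4g)\n", x$cluster_mass[1], x$cluster_p[1]))
  } else cat("no supra-threshold edges\n")
  invisible(x)
}
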