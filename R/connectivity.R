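#' Symmetric pairwise connectivity matrix
#'
#' @param values n x n symmetric numeric matrix.
#' @param metric one of `"sl"`, `"pearson_r"`, `"fisher_z"`.
#' @param labels channel/electrode labels.
#' @param band optional band name.
#' @export
connectivity_matrix <- function(values, metric = c("sl", "pearson_r", "fisher_z"),
                                labels, band = NULL) {
  metric <- match.arg(metric)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) nvf_stop("nvf_validation_error", "matrix not square")
  if (length(labels) != nrow(values)) nvf_stop("nvf_validation_error", "label count mismatch")
  if (max(abs(values - t(values))) > 1e-12) {
    nvf_stop("nvf_validation_error", "matrix not symmetric")
  }
  if (anyNA(values)) nvf_stop("nvf_validation_error", "undefined entries forbidden")
  if (metric %in% c("sl", "pearson_r") && max(abs(diag(values) - 1)) > 1e-12) {
    nvf_stop("nvf_validation_error", "diagonal must be 1 for metric ", metric)
  }
  if (metric == "sl" && (min(values) < -1e-12)) {
    nvf_stop("nvf_validation_error", "SL entries must be non-negative")
  }
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, metric = metric, labels = as.character(labels),
                 band = band),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s %dx%d%s\n", x$metric, nrow(x$values),
              ncol(x$values), if (is.null(x$band)) "" else paste0(" [", x$band, "]")))
  invisible(x)
}

#' Pearson connectivity over hemodynamic time courses
#'
#' Correlation matrix across channels of the chosen chromophore, with
#' excluded channels dropped.  Zero-variance channels are auto-excluded
#' (with a message) rather than producing undefined correlations.
#'
#' @param h a `hemodynamic_series`.
#' @param chromophore `"hbo"` or `"hb"`.
#' @return a `connectivity_matrix` with `metric = "pearson_r"`.
#' @export
pearson_matrix <- function(h, chromophore = c("hbo", "hb")) {
  chromophore <- match.arg(chromophore)
  x <- h[[chromophore]]
  keep <- !(h$channel_labels %in% h$excluded_channels)
  sds <- apply(x, 1, sd)
  flat <- sds == 0 & keep
  if (any(flat)) {
    message("zero-variance channel(s) excluded: ",
            paste(h$channel_labels[flat], collapse = ", "))
    keep <- keep & !flat
  }
  if (sum(keep) < 2) nvf_stop("nvf_validation_error", "need >= 2 usable channels")
  if (ncol(x) < 3) nvf_stop("nvf_validation_error", "need >= 3 time samples")
  r <- cor(t(x[keep, , drop = FALSE]))
  diag(r) <- 1
  r <- (r + t(r)) / 2
  connectivity_matrix(r, metric = "pearson_r", labels = h$channel_labels[keep])
}

#' Fisher z-transformation of a correlation matrix
#'
#' `z = atanh(r)` elementwise off-diagonal; |r| is clipped to `1 - 1e-7`
#' with a warning before transforming.  The diagonal is carried as 0 and is
#' excluded from all downstream statistics.
#'
#' @param cm a `connectivity_matrix` with `metric = "pearson_r"`.
#' @return a `connectivity_matrix` with `metric = "fisher_z"`.
#' @export
fisher_z <- function(cm) {
  stopifnot(cm$metric == "pearson_r")
  r <- cm$values
  off <- row(r) != col(r)
  if (any(abs(r[off]) >= 1)) {
    warning("correlations at |r| >= 1 clipped before atanh")
    r[off] <- pmin(pmax(r[off], -(1 - 1e-7)), 1 - 1e-7)
  }
  z <- r
  z[off] <- atanh(r[off])
  diag(z) <- 0
  connectivity_matrix(z, metric = "fisher_z", labels = cm$labels, band = cm$band)
}

#' Threshold a connectivity matrix at its top fraction of connections
#'
#' The threshold `r_T` is the value such that `k = ceiling(fraction *
#' n(n-1)/2)` off-diagonal pairs of the *reference* matrix are `>= r_T`
#' (the reference defaults to `cm` itself; passing the control-group mean
#' matrix applies a control-derived threshold to both groups).  Edges of
#' `cm` with weight `>= r_T` are retained; ties at `r_T` are all kept.
#'
#' @param cm matrix to threshold.
#' @param fraction top fraction of connections, in (0, 1].
#' @param reference optional `connectivity_matrix` from which `r_T` is
#'   derived.
#' @return a `network_graph`.
#' @export
threshold_top_fraction <- function(cm, fraction = 0.05, reference = NULL) {
  if (!(fraction > 0 && fraction <= 1)) {
    nvf_stop("nvf_parameter_error", "fraction must lie in (0, 1]")
  }
  ref <- if (is.null(reference)) cm else reference
  rv <- ref$values[upper.tri(ref$values)]
  k <- ceiling(fraction * length(rv))
  if (k == 0) nvf_stop("nvf_parameter_error", "fraction yields no edges")
  r_T <- sort(rv, decreasing = TRUE)[k]
  ut <- which(upper.tri(cm$values), arr.ind = TRUE)
  w <- cm$values[ut]
  keep <- w >= r_T
  edges <- data.frame(i = ut[keep, 1], j = ut[keep, 2], weight = w[keep])
  edges <- edges[order(-edges$weight), ]
  rownames(edges) <- NULL
  network_graph(labels = cm$labels, edges = edges, threshold_value = r_T,
                threshold_rule = sprintf("top %.3g%% of %s connections%s",
                                         100 * fraction, ref$metric,
                                         if (is.null(reference)) "" else " (external reference)"),
                degree_strength = degree_strength(cm))
}

#' Degree strength of each node
#'
#' `sigma_i` = mean connectivity of node i with every other node, computed
#' on the full (unthresholded) matrix.
#' @param cm a `connectivity_matrix`.
#' @return named numeric vector.
#' @export
degree_strength <- function(cm) {
  n <- nrow(cm$values)
  if (n < 2) nvf_stop("nvf_validation_error", "need >= 2 nodes")
  v <- cm$values
  diag(v) <- 0
  s <- rowSums(v) / (n - 1)
  names(s) <- cm$labels
  s
}

#' Thresholded network graph
#' @param labels node labels.
#' @param edges data.frame with columns `i`, `j` (node indices, i < j) and
#'   `weight`.
#' @param threshold_value the applied threshold `r_T`.
#' @param threshold_rule human-readable description.
#' @param degree_strength per-node mean connectivity (full matrix).
#' @export
network_graph <- function(labels, edges, threshold_value, threshold_rule,
                          degree_strength) {
  stopifnot(all(edges$i < edges$j), length(degree_strength) == length(labels))
  structure(list(labels = as.character(labels), edges = edges,
                 threshold_value = threshold_value,
                 threshold_rule = threshold_rule,
                 degree_strength = degree_strength),
            class = "network_graph")
}

#' @export
print.network_graph <- function(x, ...) {
  cat(sprintf("<network_graph> %d nodes, %d edges, r_T = %.4g (%s)\n",
              length(x$labels), nrow(x$edges), x$threshold_value, x$threshold_rule))
  invisible(x)
}
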