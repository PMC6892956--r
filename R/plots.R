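# Best-effort base-graphics rendering of a pipeline run: matrix heat maps,
# 2-D sensor-layout connectivity (display threshold only), degree-strength
# bars with s.e.m., fusion-pattern topographies on the flat montage.

plot_matrix_heatmap <- function(cm, main = "") {
  n <- nrow(cm$values)
  image(seq_len(n), seq_len(n), t(cm$values[n:1, , drop = FALSE]),
        col = hcl.colors(64, "RdBu", rev = TRUE), axes = FALSE,
        xlab = "", ylab = "", main = main)
  axis(1, at = seq_len(n), labels = cm$labels, las = 2, cex.axis = 0.5)
  axis(2, at = seq_len(n), labels = rev(cm$labels), las = 2, cex.axis = 0.5)
}

# flat (x, y) sensor layout from montage MNI coordinates
montage_xy <- function(montage, labels) {
  i <- match(labels, montage$label)
  cbind(x = montage$x[i], y = montage$y[i])
}

plot_sensor_network <- function(cm, montage, threshold, main = "") {
  xy <- montage_xy(montage, cm$labels)
  plot(xy[, 1], xy[, 2], pch = 16, cex = 0.8, axes = FALSE, xlab = "",
       ylab = "", main = main, asp = 1)
  ut <- which(upper.tri(cm$values) & cm$values > threshold, arr.ind = TRUE)
  if (nrow(ut)) {
    segments(xy[ut[, 1], 1], xy[ut[, 1], 2], xy[ut[, 2], 1], xy[ut[, 2], 2],
             col = "darkgreen")
  }
  title(sub = sprintf("display threshold > %.2f (visualization only)", threshold))
}

plot_degree_strength <- function(sigma_by_group, main = "degree strength") {
  means <- vapply(sigma_by_group, colMeans, numeric(ncol(sigma_by_group[[1]])))
  sems <- vapply(sigma_by_group, function(m) apply(m, 2, sd) / sqrt(nrow(m)),
                 numeric(ncol(sigma_by_group[[1]])))
  bp <- barplot(t(means), beside = TRUE, las = 2, main = main,
                legend.text = names(sigma_by_group), ylab = "mean r",
                ylim = range(0, means + sems, means - sems))
  arrows(bp, t(means) - t(sems), bp, t(means) + t(sems), angle = 90, code = 3,
         length = 0.02)
}

plot_pattern_topo <- function(pattern, labels, montage, main = "") {
  xy <- montage_xy(montage, labels)
  sc <- (pattern - min(pattern)) / max(diff(range(pattern)), 1e-12)
  cols <- hcl.colors(64, "RdBu", rev = TRUE)[pmax(1, ceiling(sc * 64))]
  plot(xy[, 1], xy[, 2], pch = 21, bg = cols, cex = 2.2, axes = FALSE,
       xlab = "", ylab = "", main = main, asp = 1)
}

#' Render a figure report for a pipeline run
#'
#' Writes one multi-page PDF: SL display-threshold sensor networks, group
#' connectivity heat maps, per-channel degree strength with standard errors,
#' and the fusion activation patterns on the flat montage.  All thresholds
#' here are display-only.
#'
#' @param res result of [run_pipeline()].
#' @param path output PDF path.
#' @param sl_display_threshold edge display threshold for the SL network
#'   view (default 0.8).
#' @return `path`, invisibly.
#' @export
render_report <- function(res, path = "nvfusion_report.pdf",
                          sl_display_threshold = 0.8) {
  montage <- res$config$montage
  pdf(path, width = 8, height = 8)
  on.exit(dev.off())
  for (g in c("A", "B")) {
    plot_matrix_heatmap(res$group_mean_r[[g]],
                        main = paste("HbO connectivity, group", g))
  }
  bn <- res$feature_selection$band
  if (bn %in% names(res$sl_matrices) && !is.null(montage)) {
    groups <- res$groups
    for (g in c("A", "B")) {
      vals <- Reduce(`+`, lapply(res$sl_matrices[[bn]][groups == g],
                                 `[[`, "values")) / sum(groups == g)
      diag(vals) <- 1
      cm <- connectivity_matrix(vals, "sl", res$sl_matrices[[bn]][[1]]$labels)
      if (all(cm$labels %in% montage$label)) {
        plot_sensor_network(cm, montage, sl_display_threshold,
                            main = sprintf("%s SL network, group %s", bn, g))
      }
    }
  }
  sig <- list(A = res$degree_strength[res$groups == "A", , drop = FALSE],
              B = res$degree_strength[res$groups == "B", , drop = FALSE])
  colnames(sig$A) <- colnames(sig$B) <- res$group_mean_r$A$labels
  plot_degree_strength(sig)
  if (length(res$fusion) && !is.null(montage)) {
    for (g in names(res$fusion)) {
      f <- res$fusion[[g]]
      if (all(f$fits[[1]]$eeg_labels %in% montage$label)) {
        plot_pattern_topo(f$mean_a_eeg, f$fits[[1]]$eeg_labels, montage,
                          main = paste("EEG activation pattern, group", g))
      }
    }
  }
  invisible(path)
}
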