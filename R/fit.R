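#' Fit the transcriptional-wave trend model to a time-course experiment
#'
#' The central fitting function. For one stimulated condition contrasted
#' against the untreated baseline it runs the full chain: TMM
#' normalization, the mean-expression filter, method-of-moments common NB
#' dispersion, per-timepoint log2 fold changes with the conditioned NB
#' exact test and BH FDR, and the nine-class combined-trend classification
#' with its partition summary, plus a PCA summary of all samples.
#'
#' @param counts genes x samples integer count matrix, or a `"wave_sim"`
#'   object (in which case `design` is taken from it).
#' @param design data.frame with columns sample_id, condition, time_h,
#'   replicate.
#' @param condition the stimulated condition to contrast against baseline.
#' @param baseline_condition,baseline_time the untreated reference group.
#' @param times_h the early and late post-stimulus timepoints.
#' @param tau trend threshold in log2 units.
#' @param q_max FDR threshold used by the filtered gene lists.
#' @param min_tmm expression filter threshold (mean TMM-CPM, strict `>`)
#'   over the baseline and contrasted groups.
#' @param pseudocount pseudocount for fold changes.
#' @param dispersion optional fixed NB dispersion phi; estimated from all
#'   replicate groups when `NULL`.
#'
#' @return An object of class `"wave_fit"`: a list with `norm`
#'   (`"wave_expr"`), `expressed` (gene ids passing the filter), `de`
#'   (`"wave_de"` table over the expressed genes), `trends` (named factor),
#'   `partition` (`"wave_partition"`), `pca` (`"wave_pca"`), `dispersion`,
#'   and the call/threshold metadata. Methods: `print`, `summary`, `coef`
#'   (log2 fold-change matrix), `plot`.
#' @seealso [monotonic_de_genes()], [slow_kinetic_genes()], [top_induced()]
#' @export
#' @examples
#' sim <- simulate_experiment(n_genes = 300, seed = 7)
#' fit <- wave_fit(sim, condition = "bzATP_LPS")
#' summary(fit)
wave_fit <- function(counts, design = NULL, condition = "bzATP_LPS",
                     baseline_condition = "NT", baseline_time = 0,
                     times_h = c(3, 8), tau = 0.5, q_max = 0.05,
                     min_tmm = 10, pseudocount = 0.25, dispersion = NULL) {
  if (inherits(counts, "wave_sim")) {
    design <- counts$design
    counts <- counts$counts
  }
  if (is.null(design))
    stop("'design' is required when 'counts' is a plain matrix", call. = FALSE)
  counts <- .as_count_matrix(counts)
  sim <- structure(list(counts = counts, design = design), class = "wave_sim")

  norm <- normalize_tmm(counts, design)
  base_s <- group_samples(design, baseline_condition, baseline_time)
  grp_s <- unlist(lapply(times_h, function(t)
    group_samples(design, condition, t)))
  expressed <- filter_expressed(norm, c(base_s, grp_s), min_tmm)
  if (!length(expressed))
    stop(sprintf("no genes pass the >%g mean-TMM expression filter", min_tmm),
         call. = FALSE)

  disp <- if (is.null(dispersion)) {
    all_groups <- split(design$sample_id,
                        interaction(design$condition, design$time_h,
                                    drop = TRUE))
    estimate_common_dispersion(counts, all_groups,
                               lib_sizes = norm$lib_sizes * norm$factors)
  } else if (inherits(dispersion, "wave_dispersion")) dispersion
  else structure(list(phi = dispersion, method = "fixed", n_groups = NA),
                 class = "wave_dispersion")

  de <- de_table(sim, norm, condition,
                 baseline_condition = baseline_condition,
                 baseline_time = baseline_time, times_h = times_h,
                 genes = expressed, dispersion = disp,
                 pseudocount = pseudocount)
  fc1 <- de[[sprintf("log2fc_%gh", times_h[1])]]
  fc2 <- de[[sprintf("log2fc_%gh", times_h[2])]]
  trends <- combined_trend(fc1, fc2, tau)
  names(trends) <- de$gene_id

  structure(list(norm = norm, expressed = expressed, de = de,
                 trends = trends, partition = partition_summary(trends),
                 pca = pca_variance(norm),
                 dispersion = disp, condition = condition,
                 baseline = c(baseline_condition, baseline_time),
                 times_h = times_h,
                 thresholds = c(tau = tau, q_max = q_max, min_tmm = min_tmm,
                                pseudocount = pseudocount),
                 design = design, call = match.call()),
            class = "wave_fit")
}

#' @export
print.wave_fit <- function(x, ...) {
  cat("Transcriptional-wave trend fit\n")
  cat(sprintf("  contrast: %s (%g h, %g h) vs %s (%g h)\n",
              x$condition, x$times_h[1], x$times_h[2],
              x$baseline[1], as.numeric(x$baseline[2])))
  cat(sprintf("  %d samples, %d expressed genes (mean TMM > %g), phi = %.4g\n",
              ncol(x$norm$expr), length(x$expressed),
              x$thresholds["min_tmm"], x$dispersion$phi))
  tab <- x$partition$table
  cat(sprintf("  trends: %s\n",
              paste(sprintf("%s %d", tab$trend, tab$count), collapse = ", ")))
  invisible(x)
}

#' @export
summary.wave_fit <- function(object, ...) {
  mono <- monotonic_de_genes(object$trends, object$de,
                             q_max = object$thresholds["q_max"],
                             min_mean_tmm = object$thresholds["min_tmm"])
  structure(list(fit = object, monotonic = mono), class = "summary.wave_fit")
}

#' @export
print.summary.wave_fit <- function(x, ...) {
  print(x$fit)
  print(x$fit$partition)
  cat(sprintf("Monotonic DE genes (q < %g, mean TMM > %g): %d Up-Up, %d Down-Down\n",
              x$fit$thresholds["q_max"], x$fit$thresholds["min_tmm"],
              nrow(x$monotonic$up), nrow(x$monotonic$down)))
  vf <- x$fit$pca$var_frac
  if (length(vf) >= 2)
    cat(sprintf("PCA: PC1+PC2 explain %.1f%% of variance\n",
                100 * sum(vf[1:2])))
  invisible(x)
}

#' @export
coef.wave_fit <- function(object, ...) {
  de <- object$de
  cols <- grep("^log2fc_", names(de), value = TRUE)
  m <- as.matrix(de[, cols])
  rownames(m) <- de$gene_id
  m
}

#' Plot a fitted wave model
#'
#' Scatter of the early versus late log2 fold change for every expressed
#' gene, colored by combined trend, with the `tau` decision boundaries.
#'
#' @param x a `"wave_fit"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.wave_fit <- function(x, ...) {
  fc <- coef(x)
  tau <- x$thresholds["tau"]
  cols <- stats::setNames(grDevices::hcl.colors(9, "Dark 3"), COMBINED_TRENDS)
  graphics::plot(fc[, 1], fc[, 2], col = cols[as.character(x$trends)],
                 pch = 16, cex = 0.5,
                 xlab = sprintf("log2 FC (%g h vs baseline)", x$times_h[1]),
                 ylab = sprintf("log2 FC (%g h vs baseline)", x$times_h[2]),
                 main = sprintf("Combined expression trends (%s)", x$condition),
                 ...)
  graphics::abline(v = c(-tau, tau), lty = 2, col = "grey40")
  graphics::abline(a = tau, b = 1, lty = 3, col = "grey40")
  graphics::abline(a = -tau, b = 1, lty = 3, col = "grey40")
  graphics::legend("topleft", legend = names(cols), col = cols, pch = 16,
                   cex = 0.6, bty = "n")
  invisible(x)
}

#' PCA summary of an expression matrix
#'
#' Samples are projected by principal components of `log2(TMM + 1)`
#' expression with genes centered (not scaled). Reports the per-component
#' variance fractions and the sample coordinates on the leading
#' components.
#'
#' @param expr a `"wave_expr"` object or TMM-CPM matrix.
#' @param n_components number of leading components to report.
#' @return a list of class `"wave_pca"`: `var_frac`, `coords` (samples x
#'   components), `sdev`.
#' @export
pca_variance <- function(expr, n_components = 2) {
  mat <- .as_expr_matrix(expr)
  if (ncol(mat) < n_components)
    stop(sprintf("need at least %d samples for %d components",
                 n_components, n_components), call. = FALSE)
  lg <- t(log2(mat + 1))           # samples x genes
  lg <- scale(lg, center = TRUE, scale = FALSE)
  total <- sum(lg^2)
  if (total < 1e-12) {
    warning("all samples identical; variance fractions reported as 0")
    k <- n_components
    return(structure(list(var_frac = rep(0, k),
                          coords = matrix(0, nrow(lg), k,
                                          dimnames = list(rownames(lg),
                                                          paste0("PC", 1:k))),
                          sdev = rep(0, k)),
                     class = "wave_pca"))
  }
  pc <- stats::prcomp(lg, center = FALSE, scale. = FALSE)
  k <- min(n_components, length(pc$sdev))
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(var_frac = var_frac[seq_len(k)],
                 coords = pc$x[, seq_len(k), drop = FALSE],
                 sdev = pc$sdev[seq_len(k)]),
            class = "wave_pca")
}

#' @export
print.wave_pca <- function(x, ...) {
  cat(sprintf("PCA: %s\n",
              paste(sprintf("PC%d %.1f%%", seq_along(x$var_frac),
                            100 * x$var_frac), collapse = ", ")))
  invisible(x)
}
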