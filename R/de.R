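#' Per-gene log2 fold change between two sample groups
#'
#' `log2((mean_a + pseudocount) / (mean_b + pseudocount))`, with means taken
#' over TMM-CPM values. The pseudocount keeps the log finite when a group is
#' unexpressed.
#'
#' @param expr a `"wave_expr"` object or TMM-CPM matrix.
#' @param samples_a,samples_b sample ids of the two groups (a vs b).
#' @param pseudocount added to both group means before the ratio.
#' @return named numeric vector of log2 fold changes (a over b).
#' @export
group_fold_change <- function(expr, samples_a, samples_b, pseudocount = 0.25) {
  mat <- .as_expr_matrix(expr)
  .check_samples(mat, samples_a); .check_samples(mat, samples_b)
  ma <- rowMeans(mat[, samples_a, drop = FALSE])
  mb <- rowMeans(mat[, samples_b, drop = FALSE])
  log2((ma + pseudocount) / (mb + pseudocount))
}

#' Method-of-moments common negative-binomial dispersion
#'
#' For every gene and replicate group, the moment estimate
#' `(variance - mean) / mean^2` of the NB dispersion phi is computed; the
#' finite per-gene estimates are averaged across genes and groups and the
#' average is floored at 0 (Poisson-like data can produce a negative
#' moment average).
#'
#' When `lib_sizes` are supplied, counts are first rescaled to their
#' geometric-mean library size so that sequencing-depth variation between
#' replicates is not mistaken for biological overdispersion — the same
#' equalization [nb_exact_test()] applies.
#'
#' @param counts genes x samples count matrix or `"wave_sim"`.
#' @param groups list of character vectors of sample ids; groups with fewer
#'   than 2 replicates are ignored.
#' @param lib_sizes optional named effective library sizes used to equalize
#'   depth before estimation.
#' @return a list of class `"wave_dispersion"`: `phi`, `method`, `n_groups`.
#' @export
estimate_common_dispersion <- function(counts, groups, lib_sizes = NULL) {
  counts <- .as_count_matrix(counts)
  if (!is.null(lib_sizes)) {
    lib_sizes <- lib_sizes[colnames(counts)]
    if (any(!is.finite(lib_sizes)) || any(lib_sizes <= 0))
      stop("effective library sizes must be positive", call. = FALSE)
    target <- exp(mean(log(lib_sizes)))
    counts <- sweep(counts, 2, target / lib_sizes, "*")
  }
  if (!is.list(groups)) groups <- list(groups)
  groups <- Filter(function(g) length(g) >= 2, groups)
  if (!length(groups))
    stop("need at least one group with >= 2 replicates", call. = FALSE)
  ests <- unlist(lapply(groups, function(g) {
    .check_samples(counts, g)
    sub <- counts[, g, drop = FALSE]
    m <- rowMeans(sub)
    v <- apply(sub, 1, stats::var)
    e <- (v - m) / m^2
    e[is.finite(e)]
  }))
  phi <- max(0, mean(ests))
  structure(list(phi = phi, method = "moments-common", n_groups = length(groups)),
            class = "wave_dispersion")
}

#' @export
print.wave_dispersion <- function(x, ...) {
  cat(sprintf("Common NB dispersion (method of moments): phi = %.4g (%d groups)\n",
              x$phi, x$n_groups))
  invisible(x)
}

#' Conditioned negative-binomial exact test
#'
#' Two-group per-gene test of equal means. Counts are first equalized to the
#' geometric mean of the effective library sizes (deterministic scaling,
#' rounded to integers). For each gene the per-group sums `(a, b)` are then
#' exchangeable NB sums under the null; conditioning on the total `t = a+b`,
#' the probability of each split `(x, t-x)` is proportional to
#' `dnbinom(x, size = n_a/phi, mu) * dnbinom(t-x, size = n_b/phi, mu)`.
#' The two-sided p-value sums the probabilities of all splits whose
#' probability does not exceed that of the observed split (probability
#' ordering), capped at 1. At `phi = 0` the conditional law is exactly
#' binomial `(t, n_a/(n_a+n_b))`.
#'
#' @param counts genes x samples raw count matrix or `"wave_sim"`.
#' @param samples_a,samples_b sample ids of the two groups.
#' @param dispersion a `"wave_dispersion"` object or a single phi >= 0.
#' @param lib_sizes optional named effective library sizes (e.g. library
#'   size times TMM factor); defaults to column sums.
#' @return named vector of two-sided p-values in (0, 1].
#' @export
nb_exact_test <- function(counts, samples_a, samples_b, dispersion,
                          lib_sizes = NULL) {
  counts <- .as_count_matrix(counts)
  if (inherits(dispersion, "wave_dispersion")) dispersion <- dispersion$phi
  if (!is.numeric(dispersion) || length(dispersion) != 1 || dispersion < 0)
    stop("'dispersion' must be a single phi >= 0", call. = FALSE)
  if (!length(samples_a) || !length(samples_b))
    stop("both groups must be non-empty", call. = FALSE)
  .check_samples(counts, samples_a); .check_samples(counts, samples_b)
  sel <- c(samples_a, samples_b)
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)[sel]
  lib_sizes <- lib_sizes[sel]
  if (any(!is.finite(lib_sizes)) || any(lib_sizes <= 0))
    stop("effective library sizes must be positive", call. = FALSE)

  # equalize library sizes to their geometric mean, then round
  target <- exp(mean(log(lib_sizes)))
  adj <- round(sweep(counts[, sel, drop = FALSE], 2, target / lib_sizes, "*"))
  na <- length(samples_a); nb <- length(samples_b)
  a <- rowSums(adj[, samples_a, drop = FALSE])
  b <- rowSums(adj[, samples_b, drop = FALSE])
  p <- vapply(seq_along(a), function(i)
    .exact_split_p(a[i], a[i] + b[i], na, nb, dispersion), numeric(1))
  names(p) <- rownames(counts)
  p
}

# two-sided conditional p for observed group-A sum `a` out of total `t`
.exact_split_p <- function(a, t, na, nb, phi) {
  if (t == 0) return(1)
  if (phi <= 0) {
    lp <- stats::dbinom(0:t, t, na / (na + nb), log = TRUE)
    obs <- lp[a + 1]
    return(min(1, sum(exp(lp[lp <= obs + 1e-12]))))
  }
  mu <- t / (na + nb)           # per-replicate mean under the null
  ra <- na / phi; rb <- nb / phi
  x <- 0:t
  if (t > 200000) {             # window: mass outside is < 1e-15
    ca <- t * na / (na + nb)
    sd <- sqrt(na * mu * (1 + phi * mu))
    x <- max(0, floor(ca - 50 * sd)):min(t, ceiling(ca + 50 * sd))
    x <- sort(unique(c(x, a)))
  }
  lp <- stats::dnbinom(x, size = ra, mu = na * mu, log = TRUE) +
    stats::dnbinom(t - x, size = rb, mu = nb * mu, log = TRUE)
  norm <- max(lp) + log(sum(exp(lp - max(lp))))
  lp <- lp - norm
  obs <- lp[match(a, x)]
  min(1, sum(exp(lp[lp <= obs + 1e-12])))
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1 and mapped back to the
#' input order.
#'
#' @param p vector of raw p-values in \[0, 1\].
#' @return vector of q-values, same order and names as `p`.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
bh_fdr <- function(p) {
  bad <- which(!is.finite(p) | p < 0 | p > 1)
  if (length(bad))
    stop(sprintf("p-values outside [0, 1] at index %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  m <- length(p)
  if (!m) return(numeric(0))
  ord <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[ord] * m / seq_len(m)))))
  q <- numeric(m)
  q[ord] <- q_sorted
  names(q) <- names(p)
  q
}

#' Differential expression table for a two-timepoint contrast
#'
#' For one stimulated condition against the untreated baseline, computes per
#' gene the log2 fold change, the conditioned NB exact-test p-value and the
#' BH q-value at each timepoint, plus the mean TMM-CPM over the filter
#' groups.
#'
#' @param sim a `"wave_sim"` (counts + design) object.
#' @param norm the matching `"wave_expr"` from [normalize_tmm()].
#' @param condition stimulated condition to contrast against baseline.
#' @param baseline_condition,baseline_time the untreated group.
#' @param times_h the two post-stimulus timepoints.
#' @param genes optional gene subset (e.g. from [filter_expressed()]).
#' @param dispersion optional `"wave_dispersion"`; estimated from all
#'   replicate groups when `NULL`.
#' @param pseudocount pseudocount for fold changes.
#' @return data.frame of class `"wave_de"`: gene_id, mean_tmm, log2fc_3h,
#'   p_3h, q_3h, log2fc_8h, p_8h, q_8h (columns named after `times_h`).
#' @export
de_table <- function(sim, norm, condition,
                     baseline_condition = "NT", baseline_time = 0,
                     times_h = c(3, 8), genes = NULL, dispersion = NULL,
                     pseudocount = 0.25) {
  stopifnot(inherits(norm, "wave_expr"))
  design <- sim$design
  counts <- .as_count_matrix(sim)
  base_s <- group_samples(design, baseline_condition, baseline_time)
  grp_s <- lapply(times_h, function(t) group_samples(design, condition, t))
  eff_lib <- norm$lib_sizes * norm$factors
  if (is.null(dispersion)) {
    all_groups <- split(design$sample_id,
                        interaction(design$condition, design$time_h, drop = TRUE))
    dispersion <- estimate_common_dispersion(counts, all_groups,
                                             lib_sizes = eff_lib)
  }
  if (is.null(genes)) genes <- rownames(counts)
  expr <- norm$expr[genes, , drop = FALSE]
  cnt <- counts[genes, , drop = FALSE]

  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  out$mean_tmm <- rowMeans(expr[, c(base_s, unlist(grp_s)), drop = FALSE])
  for (k in seq_along(times_h)) {
    fc <- group_fold_change(expr, grp_s[[k]], base_s, pseudocount)
    p <- nb_exact_test(cnt, grp_s[[k]], base_s, dispersion,
                       lib_sizes = eff_lib)
    tt <- times_h[k]
    out[[sprintf("log2fc_%gh", tt)]] <- unname(fc)
    out[[sprintf("p_%gh", tt)]] <- unname(p)
    out[[sprintf("q_%gh", tt)]] <- unname(bh_fdr(p))
  }
  attr(out, "condition") <- condition
  attr(out, "dispersion") <- if (inherits(dispersion, "wave_dispersion"))
    dispersion$phi else dispersion
  class(out) <- c("wave_de", "data.frame")
  out
}

.check_samples <- function(mat, samples) {
  miss <- setdiff(samples, colnames(mat))
  if (length(miss))
    stop(sprintf("unknown sample(s): %s; available: %s",
                 paste(miss, collapse = ", "),
                 paste(utils::head(colnames(mat), 20), collapse = ", ")),
         call. = FALSE)
  invisible(TRUE)
}
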