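#' The nine combined expression trends
#' @keywords internal
COMBINED_TRENDS <- c("Up-Up", "Up-Same", "Up-Down",
                     "Same-Up", "Same-Same", "Same-Down",
                     "Down-Up", "Down-Same", "Down-Down")

.check_finite <- function(x, what) {
  if (any(!is.finite(x)))
    stop(sprintf("non-finite %s at index %s", what,
                 paste(which(!is.finite(x)), collapse = ", ")), call. = FALSE)
  invisible(x)
}

#' Expression trend at the early timepoint
#'
#' A gene is Up when its early log2 fold change versus baseline exceeds
#' `tau`, Down when it is below `-tau`, and Same otherwise. Values exactly
#' on a boundary are Same, so the 'Same' band is the closed interval
#' `[-tau, tau]` (with the default tau = 0.5 log2 units, fold changes
#' bounded by about 50% count as unchanged).
#'
#' @param log2fc_3h log2 fold change at the early timepoint vs baseline
#'   (vectorized).
#' @param tau trend threshold in log2 units (> 0).
#' @return character vector in `{"Up", "Same", "Down"}`.
#' @export
trend_at_3h <- function(log2fc_3h, tau = 0.5) {
  stopifnot(is.numeric(tau), length(tau) == 1, tau > 0)
  .check_finite(log2fc_3h, "log2 fold change (3 h)")
  ifelse(log2fc_3h > tau, "Up", ifelse(log2fc_3h < -tau, "Down", "Same"))
}

#' Expression trend at the late timepoint, relative to the early one
#'
#' Both fold changes are measured against the same untreated baseline; the
#' late trend thresholds their difference: Up when
#' `log2fc_8h - log2fc_3h > tau`, Down when `< -tau`, Same otherwise
#' (boundaries inclusive into Same). Because
#' `log2fc_8h - log2fc_3h = log2(expr_8h/expr_3h)` up to the shared
#' pseudocount, this is identical to thresholding the 8 h-vs-3 h fold
#' change directly.
#'
#' @param log2fc_3h,log2fc_8h log2 fold changes vs baseline (vectorized).
#' @inheritParams trend_at_3h
#' @return character vector in `{"Up", "Same", "Down"}`.
#' @export
trend_at_8h <- function(log2fc_3h, log2fc_8h, tau = 0.5) {
  stopifnot(is.numeric(tau), length(tau) == 1, tau > 0)
  .check_finite(log2fc_3h, "log2 fold change (3 h)")
  .check_finite(log2fc_8h, "log2 fold change (8 h)")
  d <- log2fc_8h - log2fc_3h
  ifelse(d > tau, "Up", ifelse(d < -tau, "Down", "Same"))
}

#' Combined nine-class expression trend
#'
#' Concatenates the early and late trend labels into one of nine combined
#' trends (`"Up-Up"`, `"Up-Same"`, ..., `"Down-Down"`). The map is total:
#' every finite pair of fold changes receives exactly one label.
#'
#' @inheritParams trend_at_8h
#' @return factor with the nine combined-trend levels.
#' @export
#' @examples
#' combined_trend(c(0.6, 0.6, 0), c(1.2, 0.6, 0))
combined_trend <- function(log2fc_3h, log2fc_8h, tau = 0.5) {
  t1 <- trend_at_3h(log2fc_3h, tau)
  t2 <- trend_at_8h(log2fc_3h, log2fc_8h, tau)
  factor(paste(t1, t2, sep = "-"), levels = COMBINED_TRENDS)
}

#' Tabulate a combined-trend partition
#'
#' Counts and fractions of genes per combined trend, plus the early-label
#' marginals (total Up at 3 h = sum over Up-*, etc.).
#'
#' @param trends factor (or character) of combined trends per gene.
#' @return a list of class `"wave_partition"`: `table` (data.frame trend,
#'   count, fraction), `marginal_3h`, `n`.
#' @export
partition_summary <- function(trends) {
  if (!length(trends))
    stop("empty trend vector", call. = FALSE)
  trends <- factor(as.character(trends), levels = COMBINED_TRENDS)
  if (any(is.na(trends)))
    stop("unknown trend labels present", call. = FALSE)
  counts <- table(trends)
  tab <- data.frame(trend = names(counts), count = as.integer(counts),
                    fraction = as.numeric(counts) / length(trends),
                    stringsAsFactors = FALSE)
  first <- sub("-.*$", "", tab$trend)
  marg <- vapply(c("Up", "Same", "Down"),
                 function(l) sum(tab$count[first == l]), integer(1))
  structure(list(table = tab, marginal_3h = marg, n = length(trends)),
            class = "wave_partition")
}

#' @export
print.wave_partition <- function(x, ...) {
  cat(sprintf("Combined-trend partition of %d genes\n", x$n))
  tab <- x$table
  tab$fraction <- sprintf("%.1f%%", 100 * tab$fraction)
  print(tab, row.names = FALSE)
  cat(sprintf("At 3 h: %d Up, %d Same, %d Down\n",
              x$marginal_3h["Up"], x$marginal_3h["Same"],
              x$marginal_3h["Down"]))
  invisible(x)
}

#' Filtered monotonic DE gene lists
#'
#' Genes whose combined trend is Up-Up or Down-Down and that pass the
#' significance (`q < q_max`, strict) and expression (`mean TMM >
#' min_mean_tmm`, strict) filters. By default the q filter applies at both
#' timepoints; set `both_timepoints = FALSE` to require it at either.
#' Lists are sorted by the binding (larger) q-value, ascending.
#'
#' @param trends combined trends named by gene, or a `"wave_fit"` object.
#' @param de a `"wave_de"` table covering the same genes.
#' @param q_max FDR threshold (strict `<`).
#' @param min_mean_tmm expression threshold (strict `>`).
#' @param both_timepoints require `q < q_max` at both timepoints.
#' @return list with data.frames `up` (Up-Up) and `down` (Down-Down).
#' @export
monotonic_de_genes <- function(trends, de, q_max = 0.05, min_mean_tmm = 10,
                               both_timepoints = TRUE) {
  x <- .trend_de_frame(trends, de)
  q1 <- x$de[[grep("^q_", names(x$de), value = TRUE)[1]]]
  q2 <- x$de[[grep("^q_", names(x$de), value = TRUE)[2]]]
  qbind <- pmax(q1, q2)
  sig <- if (both_timepoints) q1 < q_max & q2 < q_max
         else q1 < q_max | q2 < q_max
  pass <- sig & x$de$mean_tmm > min_mean_tmm
  pick <- function(label) {
    rows <- x$de[x$trends == label & pass, , drop = FALSE]
    rows[order(qbind[x$trends == label & pass]), , drop = FALSE]
  }
  list(up = pick("Up-Up"), down = pick("Down-Down"))
}

#' Slow-kinetic DE genes (changed only at the late timepoint)
#'
#' Genes labeled Same at 3 h and Up or Down at 8 h, passing a strict late
#' FDR filter and the expression filter.
#'
#' @inheritParams monotonic_de_genes
#' @param q_max strict FDR threshold on the late timepoint.
#' @return data.frame of passing genes, sorted by late q ascending, with a
#'   `direction` column.
#' @export
slow_kinetic_genes <- function(trends, de, q_max = 1e-10, min_mean_tmm = 10) {
  x <- .trend_de_frame(trends, de)
  q2 <- x$de[[grep("^q_", names(x$de), value = TRUE)[2]]]
  slow <- x$trends %in% c("Same-Up", "Same-Down")
  pass <- slow & q2 < q_max & x$de$mean_tmm > min_mean_tmm
  rows <- x$de[pass, , drop = FALSE]
  rows$direction <- ifelse(x$trends[pass] == "Same-Up", "up", "down")
  rows[order(q2[pass]), , drop = FALSE]
}

# align a trend vector (or wave_fit) with a DE table; error on mismatch
.trend_de_frame <- function(trends, de) {
  if (inherits(trends, "wave_fit")) {
    if (missing(de)) de <- trends$de
    trends <- trends$trends
  }
  stopifnot(is.data.frame(de), "gene_id" %in% names(de))
  tr <- as.character(trends)
  if (is.null(names(trends)) && length(tr) == nrow(de)) {
    names(tr) <- de$gene_id
  } else {
    names(tr) <- names(trends)
  }
  if (!setequal(names(tr), de$gene_id))
    stop("trend labels and DE table cover different gene sets", call. = FALSE)
  list(trends = unname(tr[de$gene_id]), de = de)
}
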