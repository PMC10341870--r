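#' Choose the TMM reference sample
#'
#' Picks the sample whose 75th-percentile count fraction (upper quartile of
#' counts divided by library size) is closest to the mean of that quantity
#' across samples; ties are broken by column order.
#'
#' @param counts genes x samples count matrix.
#' @return the reference sample id (column name), with the column index as
#'   attribute `"index"`.
#' @export
tmm_reference_sample <- function(counts) {
  counts <- .as_count_matrix(counts)
  if (ncol(counts) < 2)
    stop("need at least 2 samples to normalize", call. = FALSE)
  lib <- colSums(counts)
  zero <- lib <= 0
  if (any(zero))
    stop(sprintf("sample(s) with all-zero counts: %s",
                 paste(colnames(counts)[zero], collapse = ", ")),
         call. = FALSE)
  uq <- apply(counts, 2, stats::quantile, probs = 0.75) / lib
  ref <- which.min(abs(uq - mean(uq)))  # which.min keeps the first tie
  structure(colnames(counts)[ref], index = unname(ref))
}

#' TMM scaling factor for one sample against a reference
#'
#' Doubly trimmed, precision-weighted mean of per-gene log ratios. With
#' library sizes N and counts y, each gene contributes
#' `M_g = log2((y_gs/N_s)/(y_gr/N_r))` and
#' `A_g = 0.5 * log2((y_gs/N_s) * (y_gr/N_r))`; genes with a zero count in
#' either sample are excluded, the top and bottom `trim_m` of genes by M and
#' `trim_a` by A are trimmed, and the factor is
#' `2^(sum(w_g M_g) / sum(w_g))` with inverse-variance weights
#' `w_g = (N_s - y_gs)/(N_s y_gs) + (N_r - y_gr)/(N_r y_gr)` (delta-method
#' precision of M under binomial sampling, used as given).
#'
#' @param counts genes x samples count matrix.
#' @param sample,reference sample ids or column indices.
#' @param trim_m fraction trimmed from each end by M (log ratio).
#' @param trim_a fraction trimmed from each end by A (mean abundance).
#' @return a positive scaling factor; 1 when `sample == reference`.
#' @export
tmm_factor <- function(counts, sample, reference,
                       trim_m = 0.30, trim_a = 0.05) {
  counts <- .as_count_matrix(counts)
  s <- .col_index(counts, sample)
  r <- .col_index(counts, reference)
  if (s == r) return(1)
  ys <- as.numeric(counts[, s]); yr <- as.numeric(counts[, r])
  ns <- sum(ys); nr <- sum(yr)
  keep <- ys > 0 & yr > 0
  ys <- ys[keep]; yr <- yr[keep]
  if (!length(ys))
    stop("no genes expressed in both samples; cannot estimate a factor",
         call. = FALSE)
  m <- log2((ys / ns) / (yr / nr))
  a <- 0.5 * log2((ys / ns) * (yr / nr))
  # degenerate but valid: identical composition
  if (max(abs(m)) < 1e-10) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m, ties.method = "first")
  ra <- rank(a, ties.method = "first")
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(keep2))
    stop("no genes survive trimming; use smaller 'trim_m'/'trim_a'",
         call. = FALSE)
  w <- (ns - ys) / (ns * ys) + (nr - yr) / (nr * yr)
  f <- 2^(sum((m / w)[keep2]) / sum((1 / w)[keep2]))
  unname(f)
}

#' TMM-normalize a count matrix
#'
#' Computes per-sample TMM scaling factors against an automatically chosen
#' reference, rescales them to geometric mean 1, and returns expression in
#' TMM-scaled counts-per-million ("TMM" units):
#' `expr_gs = count_gs / (library_size_s * factor_s) * 1e6`.
#'
#' @param counts genes x samples count matrix, or a `"wave_sim"` object.
#' @param design optional design data.frame carried through to the result.
#' @inheritParams tmm_factor
#' @return a list of class `"wave_expr"`: `expr` (TMM-CPM matrix), `factors`
#'   (named, geometric mean 1), `lib_sizes`, `reference_sample`, `design`.
#' @export
#' @examples
#' sim <- simulate_experiment(n_genes = 500, seed = 1)
#' norm <- normalize_tmm(sim)
#' round(norm$factors, 3)
normalize_tmm <- function(counts, design = NULL,
                          trim_m = 0.30, trim_a = 0.05) {
  if (inherits(counts, "wave_sim")) {
    design <- counts$design
    counts <- counts$counts
  }
  counts <- .as_count_matrix(counts)
  ref <- tmm_reference_sample(counts)
  f <- vapply(seq_len(ncol(counts)), function(j)
    tmm_factor(counts, j, attr(ref, "index"), trim_m, trim_a), numeric(1))
  f <- f / exp(mean(log(f)))  # geometric mean 1
  names(f) <- colnames(counts)
  lib <- colSums(counts)
  expr <- sweep(counts, 2, lib * f, "/") * 1e6
  structure(list(expr = expr, factors = f, lib_sizes = lib,
                 reference_sample = as.character(ref), design = design),
            class = "wave_expr")
}

#' @export
print.wave_expr <- function(x, ...) {
  cat(sprintf("TMM-normalized expression: %d genes x %d samples\n",
              nrow(x$expr), ncol(x$expr)))
  cat(sprintf("Reference sample: %s\n", x$reference_sample))
  cat("Scaling factors:\n")
  print(round(x$factors, 4))
  invisible(x)
}

#' Filter genes by minimum mean expression
#'
#' Keeps genes whose mean TMM-CPM across the given samples strictly exceeds
#' `min_mean_tmm` (the ">10 TMM" expression filter; the averaging set is
#' conventionally the union of the baseline and treated groups).
#'
#' @param expr a `"wave_expr"` object or a TMM-CPM matrix.
#' @param samples character vector (or list of vectors, taken as a union)
#'   of sample ids to average over.
#' @param min_mean_tmm threshold (strict `>`).
#' @return character vector of retained gene ids.
#' @export
filter_expressed <- function(expr, samples, min_mean_tmm = 10) {
  mat <- .as_expr_matrix(expr)
  if (is.list(samples)) samples <- unique(unlist(samples))
  if (!length(samples))
    stop("'samples' must name at least one sample", call. = FALSE)
  miss <- setdiff(samples, colnames(mat))
  if (length(miss))
    stop(sprintf("unknown sample(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  keep <- rowMeans(mat[, samples, drop = FALSE]) > min_mean_tmm
  rownames(mat)[keep]
}

# --- internal helpers -------------------------------------------------------

.as_count_matrix <- function(counts) {
  if (inherits(counts, "wave_sim")) counts <- counts$counts
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("S%d", seq_len(ncol(counts)))
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and nonnegative", call. = FALSE)
  counts
}

.as_expr_matrix <- function(expr) {
  if (inherits(expr, "wave_expr")) expr$expr else as.matrix(expr)
}

.col_index <- function(mat, x) {
  if (is.character(x)) {
    j <- match(x, colnames(mat))
    if (is.na(j))
      stop(sprintf("unknown sample '%s'", x), call. = FALSE)
    j
  } else as.integer(x)
}
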