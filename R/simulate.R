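#' Trend classes the simulator can plant
#'
#' The nine planted classes mirror the nine combined expression trends:
#' a transient wave (`up_down`, and its mirror `down_up`), a sustained
#' induction or repression (`up_same`, `down_same`), monotone change
#' (`up_up`, `down_down`), slow kinetics (`same_up`, `same_down`) and
#' `flat` (no effect).
#'
#' @keywords internal
TREND_CLASSES <- c("flat", "up_down", "up_same", "up_up", "down_down",
                   "down_same", "down_up", "same_up", "same_down")

# planted (log2fc at 3 h, log2fc at 8 h) per class, in units of the effect size e
.class_effects <- function(e) {
  rbind(flat      = c(0, 0),
        up_down   = c(e, 0),
        up_same   = c(e, e),
        up_up     = c(e, 2 * e),
        down_down = c(-e, -2 * e),
        down_same = c(-e, -e),
        down_up   = c(-e, 0),
        same_up   = c(0, e),
        same_down = c(0, -e))
}

#' Default biotype mix for simulated annotation
#'
#' Protein-coding majority with a small non-coding complement (lncRNA,
#' antisense, processed pseudogenes, TEC, sno/snRNA, miRNA), echoing the
#' composition of an expressed-gene catalogue from bulk poly(A)+ RNA-seq
#' of murine cells.
#'
#' @export
default_biotype_fractions <- function() {
  c(protein_coding = 0.897, lncRNA = 0.030, antisense = 0.025,
    processed_pseudogene = 0.022, TEC = 0.012, snoRNA = 0.006,
    snRNA = 0.005, miRNA = 0.003)
}

#' Default planted trend-class fractions
#'
#' A large flat majority with small wave classes, as expected when most of
#' the transcriptome is unchanged by the stimulus.
#'
#' @export
default_class_fractions <- function() {
  c(flat = 0.90, up_down = 0.02, up_same = 0.01, up_up = 0.015,
    down_down = 0.015, down_same = 0.01, down_up = 0.01,
    same_up = 0.01, same_down = 0.01)
}

# deterministic largest-remainder apportionment of n items to fractions
largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    # ties broken by position, stable
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

.check_fractions <- function(x, field) {
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop(sprintf("'%s' must be a named numeric vector", field), call. = FALSE)
  if (any(x < 0) || abs(sum(x) - 1) > 1e-9)
    stop(sprintf("'%s' must be nonnegative and sum to 1 (got sum %.12g)",
                 field, sum(x)), call. = FALSE)
  invisible(x)
}

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(expr)
}

#' Simulate a stimulus-response RNA-seq time-course experiment
#'
#' Draws a genes-by-samples negative-binomial count matrix for a five-group
#' design (untreated baseline at 0 h plus two stimulated conditions sampled
#' at 3 h and 8 h, each with biological replicates) and plants known
#' expression-trend classes with configurable effect sizes, so that every
#' downstream stage (normalization, differential expression, trend
#' classification, biotype partition) can be validated against ground truth.
#'
#' Counts for gene g in sample s are drawn from
#' \code{NB(mean = base_g * depth_s * 2^planted_log2fc, dispersion = phi)}
#' where the planted log2 fold change depends on the gene's class and the
#' sample's timepoint, and is applied identically in both stimulated
#' conditions. Replicate-to-replicate variation comes only from the NB draw.
#' Class and biotype counts are apportioned deterministically by
#' largest-remainder rounding; biotype labels are then shuffled across genes
#' (seeded) so biotype and trend class are independent.
#'
#' @param n_genes number of genes.
#' @param class_fractions named fractions over the planted trend classes
#'   (must sum to 1); see [default_class_fractions()].
#' @param baseline_mean_log_range range (log10) of per-gene baseline mean
#'   counts, drawn uniformly, then rescaled so the expected column sum is
#'   `library_size_mean`.
#' @param effect_size_log2 magnitude of the planted log2 fold change for the
#'   wave classes.
#' @param dispersion negative-binomial dispersion phi (variance =
#'   mean + phi * mean^2); 0 gives Poisson counts.
#' @param replicates_per_group biological replicates per group (>= 2).
#' @param library_size_mean expected library size (column sum) per sample.
#' @param library_size_cv coefficient of variation of the per-sample
#'   sequencing depth.
#' @param library_sizes optional explicit per-sample expected library sizes
#'   (length = 5 * replicates_per_group); overrides mean/cv.
#' @param biotype_fractions named fractions over gene biotypes (sum to 1);
#'   see [default_biotype_fractions()].
#' @param conditions names of the three design conditions (baseline, first
#'   stimulus, combined stimulus).
#' @param times_h the two post-stimulus timepoints, in hours.
#' @param seed integer seed; the draw is deterministic given the seed.
#'
#' @return A list of class `"wave_sim"` with elements `counts` (integer
#'   matrix, genes x samples), `design` (data.frame: sample_id, condition,
#'   time_h, replicate) and `truth` (data.frame: gene_id, planted_class,
#'   planted_log2fc_3h, planted_log2fc_8h, biotype).
#' @export
#' @examples
#' sim <- simulate_experiment(n_genes = 200, seed = 1)
#' table(sim$truth$planted_class)
simulate_experiment <- function(n_genes = 10000,
                                class_fractions = default_class_fractions(),
                                baseline_mean_log_range = c(0.5, 3.5),
                                effect_size_log2 = 2.0,
                                dispersion = 0.05,
                                replicates_per_group = 3,
                                library_size_mean = 3e6,
                                library_size_cv = 0.2,
                                library_sizes = NULL,
                                biotype_fractions = default_biotype_fractions(),
                                conditions = c("NT", "bzATP", "bzATP_LPS"),
                                times_h = c(3, 8),
                                seed = NULL) {
  if (!is.numeric(n_genes) || length(n_genes) != 1 || n_genes < 1)
    stop("'n_genes' must be a positive integer", call. = FALSE)
  .check_fractions(class_fractions, "class_fractions")
  if (!all(names(class_fractions) %in% TREND_CLASSES))
    stop(sprintf("'class_fractions' has unknown classes: %s",
                 paste(setdiff(names(class_fractions), TREND_CLASSES),
                       collapse = ", ")), call. = FALSE)
  .check_fractions(biotype_fractions, "biotype_fractions")
  if (!is.numeric(dispersion) || length(dispersion) != 1 || dispersion < 0)
    stop("'dispersion' must be a single nonnegative number", call. = FALSE)
  if (replicates_per_group < 2)
    stop("'replicates_per_group' must be >= 2", call. = FALSE)
  if (length(baseline_mean_log_range) != 2 ||
      diff(baseline_mean_log_range) < 0)
    stop("'baseline_mean_log_range' must be an increasing pair", call. = FALSE)
  if (library_size_mean <= 0)
    stop("'library_size_mean' must be positive", call. = FALSE)
  if (library_size_cv < 0)
    stop("'library_size_cv' must be nonnegative", call. = FALSE)
  if (length(conditions) != 3 || length(times_h) != 2)
    stop("'conditions' must name 3 conditions and 'times_h' 2 timepoints",
         call. = FALSE)

  n_genes <- as.integer(n_genes)
  reps <- as.integer(replicates_per_group)
  n_samples <- 5L * reps
  if (!is.null(library_sizes) && length(library_sizes) != n_samples)
    stop(sprintf("'library_sizes' must have length %d (5 groups x %d replicates)",
                 n_samples, reps), call. = FALSE)

  # design: baseline at t=0, both stimulated conditions at each timepoint
  groups <- data.frame(
    condition = c(conditions[1], rep(conditions[2], 2), rep(conditions[3], 2)),
    time_h = c(0, times_h, times_h),
    stringsAsFactors = FALSE)
  design <- groups[rep(seq_len(5), each = reps), , drop = FALSE]
  design$replicate <- rep(seq_len(reps), times = 5)
  design$sample_id <- sprintf("%s_%gh_r%d", design$condition, design$time_h,
                              design$replicate)
  design <- design[, c("sample_id", "condition", "time_h", "replicate")]
  rownames(design) <- NULL

  # deterministic class allocation, in gene order
  n_per_class <- largest_remainder(n_genes, class_fractions)
  planted <- rep(names(n_per_class), times = n_per_class)
  eff <- .class_effects(effect_size_log2)
  fc3 <- eff[planted, 1]
  fc8 <- eff[planted, 2]

  gene_ids <- sprintf("G%0*d", nchar(n_genes) + 1L, seq_len(n_genes))

  .with_seed(seed, {
    # baseline means, rescaled to the target expected library size
    base <- 10^stats::runif(n_genes, baseline_mean_log_range[1],
                            baseline_mean_log_range[2])
    base <- base * library_size_mean / sum(base)

    # per-sample sequencing depth factors
    if (is.null(library_sizes)) {
      sizes <- stats::rnorm(n_samples, library_size_mean,
                            library_size_cv * library_size_mean)
      sizes <- pmax(sizes, 0.1 * library_size_mean)
    } else {
      sizes <- as.numeric(library_sizes)
    }
    depth <- sizes / library_size_mean

    # per-sample planted log2 fold change (stimulated samples only)
    fc_of_sample <- function(i) {
      if (design$condition[i] == conditions[1]) return(rep(0, n_genes))
      if (design$time_h[i] == times_h[1]) fc3 else fc8
    }
    counts <- matrix(0L, n_genes, n_samples,
                     dimnames = list(gene_ids, design$sample_id))
    for (i in seq_len(n_samples)) {
      mu <- base * depth[i] * 2^fc_of_sample(i)
      counts[, i] <- if (dispersion > 0)
        stats::rnbinom(n_genes, size = 1 / dispersion, mu = mu)
      else
        stats::rpois(n_genes, mu)
    }
    storage.mode(counts) <- "integer"

    # biotypes: exact counts, shuffled so biotype is independent of class
    n_per_bt <- largest_remainder(n_genes, biotype_fractions)
    biotype <- sample(rep(names(n_per_bt), times = n_per_bt))

    truth <- data.frame(gene_id = gene_ids, planted_class = planted,
                        planted_log2fc_3h = unname(fc3),
                        planted_log2fc_8h = unname(fc8),
                        biotype = biotype, stringsAsFactors = FALSE)
    structure(list(counts = counts, design = design, truth = truth),
              class = "wave_sim")
  })
}

#' @export
print.wave_sim <- function(x, ...) {
  cat(sprintf("Simulated time-course experiment: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("Groups:\n")
  print(table(condition = x$design$condition, time_h = x$design$time_h))
  cat("Planted classes:\n")
  print(table(x$truth$planted_class))
  invisible(x)
}

#' Write a simulated experiment as plain-text fixture files
#'
#' Emits a counts TSV (gene_id plus one column per sample), a sample sheet
#' CSV, a truth TSV, and a minimal GENCODE-dialect GTF whose `gene_type`
#' attributes match the planted biotypes. The files round-trip through
#' [read_counts()], [read_truth()] and [load_gene_biotypes()].
#'
#' @param sim a `"wave_sim"` object from [simulate_experiment()].
#' @param outdir output directory (created if missing).
#' @return invisibly, a named character vector of the written paths.
#' @export
write_fixture <- function(sim, outdir) {
  stopifnot(inherits(sim, "wave_sim"))
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create output directory '%s'", outdir), call. = FALSE)
  paths <- c(counts = file.path(outdir, "counts.tsv"),
             samples = file.path(outdir, "samples.csv"),
             truth = file.path(outdir, "truth.tsv"),
             gtf = file.path(outdir, "genes.gtf"))

  cnt <- data.frame(gene_id = rownames(sim$counts), sim$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(cnt, paths["counts"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(sim$design, paths["samples"], row.names = FALSE,
                   quote = FALSE)
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  n <- nrow(sim$truth)
  start <- seq_len(n) * 10000L
  gtf <- sprintf(
    'chr1\tsynthetic\tgene\t%d\t%d\t.\t+\t.\tgene_id "%s"; gene_name "%s"; gene_type "%s";',
    start, start + 999L, sim$truth$gene_id, sim$truth$gene_id,
    sim$truth$biotype)
  writeLines(c("##description: synthetic annotation stub", gtf), paths["gtf"])
  invisible(paths)
}

#' Read a counts TSV and sample sheet CSV
#'
#' @param counts_file TSV with a `gene_id` column followed by one integer
#'   column per sample.
#' @param samples_file CSV with columns sample_id, condition, time_h,
#'   replicate.
#' @return a `"wave_sim"`-shaped list with `counts` and `design` (no truth).
#' @export
read_counts <- function(counts_file, samples_file) {
  if (!file.exists(counts_file))
    stop(sprintf("counts file not found: '%s'", counts_file), call. = FALSE)
  if (!file.exists(samples_file))
    stop(sprintf("sample sheet not found: '%s'", samples_file), call. = FALSE)
  tab <- utils::read.delim(counts_file, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(tab) == 0)
    stop(sprintf("counts file '%s' contains no genes", counts_file),
         call. = FALSE)
  if (!"gene_id" %in% names(tab))
    stop(sprintf("counts file '%s' lacks a 'gene_id' column", counts_file),
         call. = FALSE)
  counts <- as.matrix(tab[, setdiff(names(tab), "gene_id"), drop = FALSE])
  rownames(counts) <- tab$gene_id
  storage.mode(counts) <- "integer"
  if (any(is.na(counts)) || any(counts < 0))
    stop(sprintf("counts file '%s' has missing or negative entries",
                 counts_file), call. = FALSE)
  design <- utils::read.csv(samples_file, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "time_h", "replicate")
  if (!all(need %in% names(design)))
    stop(sprintf("sample sheet '%s' must have columns %s", samples_file,
                 paste(need, collapse = ", ")), call. = FALSE)
  missing <- setdiff(colnames(counts), design$sample_id)
  if (length(missing))
    stop(sprintf("samples without a design entry: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
  rownames(design) <- NULL
  structure(list(counts = counts, design = design, truth = NULL),
            class = "wave_sim")
}

#' Read a planted-truth TSV written by [write_fixture()]
#' @param truth_file path to truth.tsv.
#' @return data.frame with gene_id, planted_class, planted log2 fold changes
#'   and biotype.
#' @export
read_truth <- function(truth_file) {
  if (!file.exists(truth_file))
    stop(sprintf("truth file not found: '%s'", truth_file), call. = FALSE)
  utils::read.delim(truth_file, stringsAsFactors = FALSE)
}

#' Resolve the sample ids of a (condition, time) group
#'
#' @param design design data.frame (sample_id, condition, time_h, replicate).
#' @param condition condition name.
#' @param time_h timepoint in hours.
#' @return character vector of sample ids.
#' @export
group_samples <- function(design, condition, time_h) {
  ids <- design$sample_id[design$condition == condition &
                            design$time_h == time_h]
  if (!length(ids))
    stop(sprintf("no samples for group (%s, %g h); available groups: %s",
                 condition, time_h,
                 paste(unique(sprintf("(%s, %g h)", design$condition,
                                      design$time_h)), collapse = ", ")),
         call. = FALSE)
  ids
}
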