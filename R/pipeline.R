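#' Run the full wave-analysis pipeline from files
#'
#' Loads a counts TSV and sample sheet, fits the trend model for each
#' requested condition, and writes every stage output as TSV plus a JSON
#' run manifest (package version, thresholds, input checksums). Outputs are
#' deterministic: running twice on the same inputs gives byte-identical
#' TSVs.
#'
#' @param counts_file counts TSV (gene_id + one column per sample).
#' @param samples_file sample sheet CSV (sample_id, condition, time_h,
#'   replicate).
#' @param out_dir output directory (created if needed).
#' @param gtf_file optional GENCODE-dialect GTF for the biotype stages.
#' @param genesets_file optional two-column TSV (set_name, gene_symbol).
#' @param conditions stimulated conditions to contrast against baseline.
#' @param baseline_condition,baseline_time the untreated group.
#' @param times_h early and late timepoints.
#' @param tau,q_max,min_tmm,pseudocount model thresholds (see
#'   [wave_fit()]).
#' @param ncrna_min_tmm,ncrna_min_fold abundant-DE-ncRNA filter (see
#'   [de_ncrna()]).
#' @return invisibly, a list with the fits and the manifest.
#' @export
run_pipeline <- function(counts_file, samples_file, out_dir,
                         gtf_file = NULL, genesets_file = NULL,
                         conditions = c("bzATP", "bzATP_LPS"),
                         baseline_condition = "NT", baseline_time = 0,
                         times_h = c(3, 8), tau = 0.5, q_max = 0.05,
                         min_tmm = 10, pseudocount = 0.25,
                         ncrna_min_tmm = 25, ncrna_min_fold = 2) {
  stage <- "load"
  res <- tryCatch({
    dat <- read_counts(counts_file, samples_file)
    conditions <- intersect(conditions, unique(dat$design$condition))
    if (!length(conditions))
      stop("no requested condition present in the sample sheet", call. = FALSE)
    if (!dir.exists(out_dir))
      dir.create(out_dir, recursive = TRUE)

    stage <- "normalize"
    norm <- normalize_tmm(dat)
    .write_tsv(data.frame(sample_id = names(norm$factors),
                          lib_size = unname(norm$lib_sizes),
                          tmm_factor = unname(norm$factors)),
               file.path(out_dir, "tmm_factors.tsv"))
    .write_tsv(data.frame(gene_id = rownames(norm$expr),
                          round(norm$expr, 4), check.names = FALSE),
               file.path(out_dir, "expression_tmm.tsv"))

    stage <- "pca"
    pca <- pca_variance(norm)
    .write_tsv(data.frame(sample_id = rownames(pca$coords),
                          round(pca$coords, 4),
                          check.names = FALSE),
               file.path(out_dir, "pca_coordinates.tsv"))

    ann <- NULL
    if (!is.null(gtf_file)) {
      stage <- "annotation"
      ann <- load_gene_biotypes(gtf_file)
    }
    sets <- if (!is.null(genesets_file)) {
      stage <- "genesets"
      read_gene_sets(genesets_file)
    }

    fits <- list()
    for (cond in conditions) {
      stage <- sprintf("fit (%s)", cond)
      fit <- wave_fit(dat$counts, dat$design, condition = cond,
                      baseline_condition = baseline_condition,
                      baseline_time = baseline_time, times_h = times_h,
                      tau = tau, q_max = q_max, min_tmm = min_tmm,
                      pseudocount = pseudocount)
      fits[[cond]] <- fit
      de_out <- fit$de
      de_out$trend <- as.character(fit$trends[de_out$gene_id])
      .write_tsv(.round_num(de_out, 6),
                 file.path(out_dir, sprintf("de_trends_%s.tsv", cond)))
      .write_tsv(.round_num(fit$partition$table, 6),
                 file.path(out_dir, sprintf("trend_partition_%s.tsv", cond)))

      stage <- sprintf("genesets (%s)", cond)
      if (!is.null(sets)) {
        shares <- do.call(rbind, lapply(names(sets), function(nm) {
          do.call(rbind, lapply(times_h, function(t) {
            row <- geneset_share(fit$norm, sets[[nm]],
                                 group_samples(fit$design, cond, t),
                                 set_name = nm)
            row$condition <- cond; row$time_h <- t
            row
          }))
        }))
        .write_tsv(.round_num(shares, 4),
                   file.path(out_dir, sprintf("geneset_shares_%s.tsv", cond)))
      }

      stage <- sprintf("biotypes (%s)", cond)
      if (!is.null(ann)) {
        part <- partition_by_biotype(fit$expressed, ann, expr = fit$norm,
                                     samples = colnames(fit$norm$expr))
        .write_tsv(.round_num(part$table, 4),
                   file.path(out_dir, sprintf("biotype_partition_%s.tsv", cond)))
        nc <- de_ncrna(fit$de, ann, min_tmm = ncrna_min_tmm,
                       min_fold = ncrna_min_fold, q_max = q_max)
        .write_tsv(.round_num(nc, 6),
                   file.path(out_dir, sprintf("ncrna_de_%s.tsv", cond)))
      }
    }

    stage <- "manifest"
    inputs <- c(counts = counts_file, samples = samples_file,
                gtf = gtf_file, genesets = genesets_file)
    manifest <- list(
      package = "txwaves",
      version = as.character(utils::packageVersion("txwaves")),
      thresholds = list(tau = tau, q_max = q_max, min_tmm = min_tmm,
                        pseudocount = pseudocount,
                        ncrna_min_tmm = ncrna_min_tmm,
                        ncrna_min_fold = ncrna_min_fold),
      contrast = list(conditions = conditions,
                      baseline = baseline_condition,
                      baseline_time = baseline_time, times_h = times_h),
      dispersion_phi = vapply(fits, function(f) f$dispersion$phi, numeric(1)),
      pca_var_frac = pca$var_frac,
      inputs = as.list(unname(tools::md5sum(unlist(inputs)))))
    names(manifest$inputs) <- names(inputs)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(fits = fits, manifest = manifest, pca = pca)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.round_num <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, digits))
  df
}
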