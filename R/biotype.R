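#' Load gene biotypes from a GENCODE-dialect GTF
#'
#' Parses gene-level records and returns one annotation row per gene from
#' the `gene_id`, `gene_name` and `gene_type` attributes. The attribute
#' parser tolerates real-world dialect variation: optional quotes, variable
#' spacing, and trailing semicolons. Unknown biotypes are preserved
#' verbatim.
#'
#' @param gtf path to a GTF file with `gene` feature records.
#' @return data.frame: gene_id, symbol, biotype (one row per gene).
#' @export
load_gene_biotypes <- function(gtf) {
  if (!file.exists(gtf))
    stop(sprintf("GTF file not found: '%s'", gtf), call. = FALSE)
  lines <- readLines(gtf)
  is_comment <- startsWith(lines, "#")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  feature <- vapply(fields, function(f) if (length(f) >= 3) f[3] else NA_character_,
                    character(1))
  gene_rows <- which(!is_comment & !is.na(feature) & feature == "gene")
  if (!length(gene_rows))
    stop(sprintf("no gene-level records found in '%s'", gtf), call. = FALSE)

  get_attr <- function(attrs, key) {
    # key "value"; or key value; — quotes and spacing optional
    m <- regmatches(attrs, regexec(sprintf('(^|;)\\s*%s\\s+"?([^";]*)"?\\s*(;|$)', key),
                                   attrs))[[1]]
    if (length(m) < 3) NA_character_ else m[3]
  }
  rows <- lapply(gene_rows, function(i) {
    f <- fields[[i]]
    if (length(f) < 9)
      stop(sprintf("malformed GTF record at line %d of '%s' (fewer than 9 fields)",
                   i, gtf), call. = FALSE)
    gid <- get_attr(f[9], "gene_id")
    gtype <- get_attr(f[9], "gene_type")
    if (is.na(gid) || !nzchar(gid))
      stop(sprintf("missing gene_id attribute at line %d of '%s'", i, gtf),
           call. = FALSE)
    if (is.na(gtype) || !nzchar(gtype))
      stop(sprintf("missing gene_type attribute at line %d of '%s'", i, gtf),
           call. = FALSE)
    sym <- get_attr(f[9], "gene_name")
    c(gid, if (is.na(sym) || !nzchar(sym)) gid else sym, gtype)
  })
  ann <- data.frame(gene_id = vapply(rows, `[`, "", 1),
                    symbol = vapply(rows, `[`, "", 2),
                    biotype = vapply(rows, `[`, "", 3),
                    stringsAsFactors = FALSE)
  dup <- ann[duplicated(ann$gene_id) | duplicated(ann$gene_id, fromLast = TRUE), ]
  if (nrow(dup)) {
    conflict <- tapply(dup$biotype, dup$gene_id,
                       function(b) length(unique(b)) > 1)
    if (any(conflict))
      stop(sprintf("conflicting biotypes for duplicated gene_id(s): %s",
                   paste(names(conflict)[conflict], collapse = ", ")),
           call. = FALSE)
    ann <- ann[!duplicated(ann$gene_id), , drop = FALSE]
  }
  rownames(ann) <- NULL
  ann
}

#' Partition expressed genes into coding and non-coding biotypes
#'
#' Tallies expressed genes by biotype (coding = `protein_coding` exactly;
#' every other biotype counts as non-coding) and, when an expression matrix
#' is supplied, the abundance share of each biotype (percentage of the
#' summed TMM-CPM). Warns when annotation covers < 95% of the expressed
#' genes.
#'
#' @param expressed_genes character vector of expressed gene ids.
#' @param annotations data.frame from [load_gene_biotypes()].
#' @param expr optional `"wave_expr"` or TMM-CPM matrix for abundance
#'   shares.
#' @param samples sample ids used for the abundance means (required with
#'   `expr`).
#' @return a list of class `"wave_biotypes"`: `table` (biotype, count,
#'   coding flag, and abundance_share when computable), `n_coding`,
#'   `n_noncoding`, `n_unannotated`.
#' @export
partition_by_biotype <- function(expressed_genes, annotations, expr = NULL,
                                 samples = NULL) {
  if (!length(expressed_genes))
    stop("no expressed genes supplied", call. = FALSE)
  idx <- match(expressed_genes, annotations$gene_id)
  if (all(is.na(idx)))
    stop("none of the expressed genes are annotated", call. = FALSE)
  n_un <- sum(is.na(idx))
  if (n_un > 0.05 * length(expressed_genes))
    warning(sprintf("annotation covers only %.1f%% of expressed genes",
                    100 * (1 - n_un / length(expressed_genes))))
  genes <- expressed_genes[!is.na(idx)]
  bt <- annotations$biotype[idx[!is.na(idx)]]
  counts <- sort(table(bt), decreasing = TRUE)
  tab <- data.frame(biotype = names(counts), count = as.integer(counts),
                    coding = names(counts) == "protein_coding",
                    stringsAsFactors = FALSE)
  if (!is.null(expr)) {
    if (is.null(samples))
      stop("'samples' is required when 'expr' is supplied", call. = FALSE)
    mat <- .as_expr_matrix(expr)
    .check_samples(mat, samples)
    present <- genes %in% rownames(mat)
    m <- rowMeans(mat[genes[present], samples, drop = FALSE])
    tot <- tapply(m, bt[present], sum)
    share <- 100 * tot / sum(tot)
    tab$abundance_share <- as.numeric(share[tab$biotype])
    tab$abundance_share[is.na(tab$abundance_share)] <- 0
  }
  structure(list(table = tab,
                 n_coding = sum(tab$count[tab$coding]),
                 n_noncoding = sum(tab$count[!tab$coding]),
                 n_unannotated = n_un),
            class = "wave_biotypes")
}

#' @export
print.wave_biotypes <- function(x, ...) {
  cat(sprintf("Biotype partition: %d coding, %d non-coding (%d unannotated)\n",
              x$n_coding, x$n_noncoding, x$n_unannotated))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Abundant differentially expressed non-coding genes
#'
#' Applies the abundant-DE-ncRNA filter: non-coding genes with mean TMM-CPM
#' strictly above `min_tmm`, an absolute late fold change of at least
#' `min_fold` (non-strict: exactly two-fold qualifies), and late
#' `q < q_max`. Genes are labeled up or down by the sign of the fold
#' change.
#'
#' @param de a `"wave_de"` table.
#' @param annotations data.frame from [load_gene_biotypes()].
#' @param min_tmm abundance threshold on `mean_tmm` (strict `>`).
#' @param min_fold minimum linear fold change at the late timepoint
#'   (non-strict `>=`).
#' @param q_max late FDR threshold (strict `<`).
#' @return data.frame of passing non-coding genes with `biotype` and
#'   `direction` columns, sorted by late q.
#' @export
de_ncrna <- function(de, annotations, min_tmm = 25, min_fold = 2,
                     q_max = 0.05) {
  stopifnot(is.data.frame(de))
  idx <- match(de$gene_id, annotations$gene_id)
  if (all(is.na(idx)))
    stop("DE table and annotation share no genes", call. = FALSE)
  bt <- annotations$biotype[idx]
  fc_col <- utils::tail(grep("^log2fc_", names(de), value = TRUE), 1)
  q_col <- utils::tail(grep("^q_", names(de), value = TRUE), 1)
  noncoding <- !is.na(bt) & bt != "protein_coding"
  pass <- noncoding &
    de$mean_tmm > min_tmm &
    abs(de[[fc_col]]) >= log2(min_fold) &
    de[[q_col]] < q_max
  out <- de[pass, , drop = FALSE]
  out$biotype <- bt[pass]
  out$direction <- ifelse(out[[fc_col]] > 0, "up", "down")
  out <- out[order(out[[q_col]]), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}
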