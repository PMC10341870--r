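#' Within-set expression shares of a gene set in one group
#'
#' Treats the summed TMM-CPM of the set as 100% and reports each member's
#' share in the given sample group, e.g. how much of the interleukin-gene
#' transcript pool one interleukin accounts for before and after
#' stimulation. Members absent from the matrix get share 0 with a warning.
#'
#' @param expr a `"wave_expr"` object or TMM-CPM matrix.
#' @param members character vector of member gene ids (unique).
#' @param samples sample ids of the group to summarize (replicate means).
#' @param set_name optional label carried into the output.
#' @return data.frame: gene_id, mean_tmm, share (percent; sums to 100).
#' @export
geneset_share <- function(expr, members, samples, set_name = "set") {
  mat <- .as_expr_matrix(expr)
  if (!length(members))
    stop("gene set is empty", call. = FALSE)
  if (anyDuplicated(members))
    stop("gene set members must be unique", call. = FALSE)
  .check_samples(mat, samples)
  present <- members %in% rownames(mat)
  if (!any(present))
    stop(sprintf("no member of gene set '%s' is present in the matrix",
                 set_name), call. = FALSE)
  if (!all(present))
    warning(sprintf("gene set '%s': %d member(s) absent from the matrix (share 0): %s",
                    set_name, sum(!present),
                    paste(members[!present], collapse = ", ")))
  m <- numeric(length(members))
  names(m) <- members
  m[present] <- rowMeans(mat[members[present], samples, drop = FALSE])
  total <- sum(m)
  share <- if (total > 0) 100 * m / total else rep(0, length(m))
  data.frame(set = set_name, gene_id = members, mean_tmm = unname(m),
             share = unname(share), stringsAsFactors = FALSE)
}

#' Fraction of a transcript pool contributed by one gene
#'
#' `100 * meanTMM_gene / sum(meanTMM over the universe)` for one sample
#' group; e.g. the percentage of all coding transcripts contributed by Tnf.
#'
#' @inheritParams geneset_share
#' @param gene gene id (must be in the matrix).
#' @param universe gene ids defining the pool (non-empty).
#' @return a single percentage.
#' @export
transcript_fraction <- function(expr, gene, universe, samples) {
  mat <- .as_expr_matrix(expr)
  if (!gene %in% rownames(mat))
    stop(sprintf("gene '%s' not found in the expression matrix", gene),
         call. = FALSE)
  if (!length(universe))
    stop("'universe' must be non-empty", call. = FALSE)
  .check_samples(mat, samples)
  universe <- intersect(universe, rownames(mat))
  g <- mean(mat[gene, samples])
  tot <- sum(rowMeans(mat[universe, samples, drop = FALSE]))
  if (tot <= 0) return(0)
  100 * g / tot
}

#' Top induced genes by linear fold change
#'
#' Ranks genes passing the expression filter by descending linear fold
#' ratio (2^log2fc) at the chosen timepoint; ties are broken by gene id.
#'
#' @param de a `"wave_de"` table.
#' @param n number of genes to return.
#' @param min_mean_tmm expression filter (strict `>`); `-Inf` disables.
#' @param time_h which timepoint's fold change to rank by (default the
#'   later one in the table).
#' @return data.frame: gene_id, mean_tmm, log2fc, fold — sorted by
#'   descending fold.
#' @export
top_induced <- function(de, n = 25, min_mean_tmm = 10, time_h = NULL) {
  stopifnot(is.data.frame(de))
  if (!is.numeric(n) || length(n) != 1 || n <= 0)
    stop("'n' must be a positive integer", call. = FALSE)
  fc_cols <- grep("^log2fc_", names(de), value = TRUE)
  col <- if (is.null(time_h)) fc_cols[length(fc_cols)]
         else sprintf("log2fc_%gh", time_h)
  if (!col %in% names(de))
    stop(sprintf("no fold-change column '%s' in the DE table", col),
         call. = FALSE)
  keep <- de$mean_tmm > min_mean_tmm
  sub <- de[keep, , drop = FALSE]
  ord <- order(-sub[[col]], sub$gene_id)
  sub <- sub[ord, , drop = FALSE]
  sub <- utils::head(sub, n)
  data.frame(gene_id = sub$gene_id, mean_tmm = sub$mean_tmm,
             log2fc = sub[[col]], fold = 2^sub[[col]],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read named gene sets from a two-column TSV
#'
#' @param path TSV with columns `set_name` and `gene_symbol` (header
#'   required).
#' @return named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path))
    stop(sprintf("gene-set file not found: '%s'", path), call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("set_name", "gene_symbol") %in% names(tab)))
    stop(sprintf("'%s' must have columns set_name and gene_symbol", path),
         call. = FALSE)
  if (nrow(tab) == 0)
    stop(sprintf("gene-set file '%s' is empty", path), call. = FALSE)
  lapply(split(tab$gene_symbol, tab$set_name), unique)
}
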