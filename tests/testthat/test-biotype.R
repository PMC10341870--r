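write_gtf <- function(lines) {
  path <- tempfile(fileext = ".gtf")
  writeLines(lines, path)
  path
}

gene_line <- function(id, type, name = id, attrs = NULL) {
  a <- if (is.null(attrs))
    sprintf('gene_id "%s"; gene_name "%s"; gene_type "%s";', id, name, type)
  else attrs
  sprintf("chr1\tsrc\tgene\t1\t100\t.\t+\t.\t%s", a)
}

test_that("a clean GTF stub round-trips ids, symbols and biotypes", {
  path <- write_gtf(c("#comment",
                      gene_line("G1", "protein_coding", "Tnf"),
                      gene_line("G2", "lncRNA", "Morrbid"),
                      "chr1\tsrc\texon\t1\t50\t.\t+\t.\tgene_id \"G1\";"))
  ann <- load_gene_biotypes(path)
  expect_identical(ann$gene_id, c("G1", "G2"))
  expect_identical(ann$symbol, c("Tnf", "Morrbid"))
  expect_identical(ann$biotype, c("protein_coding", "lncRNA"))
})

test_that("dialect variants parse identically to the clean form", {
  variants <- c(
    'gene_id "G1"; gene_name "Tnf"; gene_type "lncRNA";',
    'gene_id "G1";gene_name "Tnf";gene_type "lncRNA"',       # no spaces/final ;
    'gene_id "G1" ;  gene_name "Tnf" ; gene_type "lncRNA" ;',# extra spaces
    'gene_id G1; gene_name Tnf; gene_type lncRNA;',          # unquoted
    'gene_type "lncRNA"; gene_id "G1"; gene_name "Tnf";;')   # reordered, ;;
  for (a in variants) {
    ann <- load_gene_biotypes(write_gtf(gene_line("G1", "x", attrs = a)))
    expect_identical(ann$gene_id, "G1", info = a)
    expect_identical(ann$symbol, "Tnf", info = a)
    expect_identical(ann$biotype, "lncRNA", info = a)
  }
})

test_that("parsing agrees with the rtracklayer reference on a fuzzed stub", {
  sim <- simulate_experiment(n_genes = 60, seed = 44)
  out <- file.path(tempdir(), "gtf-oracle")
  paths <- write_fixture(sim, out)
  ours <- load_gene_biotypes(paths["gtf"])
  gr <- rtracklayer::import(paths["gtf"], format = "gtf")
  gr <- gr[gr$type == "gene"]
  expect_identical(ours$gene_id, gr$gene_id)
  expect_identical(ours$biotype, gr$gene_type)
  unlink(out, recursive = TRUE)
})

test_that("malformed annotation fails loudly with a location", {
  no_gene <- write_gtf("chr1\tsrc\ttranscript\t1\t100\t.\t+\t.\tgene_id \"G1\";")
  expect_error(load_gene_biotypes(no_gene), "no gene-level records")
  missing_type <- write_gtf(c(gene_line("G1", "lncRNA"),
                              gene_line("G2", "x", attrs = 'gene_id "G2";')))
  expect_error(load_gene_biotypes(missing_type), "gene_type.*line 2")
  conflict <- write_gtf(c(gene_line("G1", "lncRNA"),
                          gene_line("G1", "protein_coding")))
  expect_error(load_gene_biotypes(conflict), "conflicting biotypes")
  # duplicates with a consistent biotype are tolerated
  dup_ok <- write_gtf(c(gene_line("G1", "lncRNA"), gene_line("G1", "lncRNA")))
  expect_identical(nrow(load_gene_biotypes(dup_ok)), 1L)
})

test_that("biotype partition tallies coding vs non-coding exactly", {
  ann <- data.frame(gene_id = paste0("G", 1:1000),
                    symbol = paste0("G", 1:1000),
                    biotype = rep(c("protein_coding", "lncRNA"),
                                  times = c(900, 100)))
  part <- partition_by_biotype(ann$gene_id, ann)
  expect_identical(part$n_coding, 900L)
  expect_identical(part$n_noncoding, 100L)
  expect_identical(part$n_coding + part$n_noncoding, 1000L)
  # all coding -> zero non-coding
  part2 <- partition_by_biotype(ann$gene_id[1:900], ann)
  expect_identical(part2$n_noncoding, 0L)
  # order invariance
  part3 <- partition_by_biotype(rev(ann$gene_id), ann)
  expect_identical(part3$table, part$table)
  expect_warning(partition_by_biotype(c(ann$gene_id[1:10], "unknown1",
                                        "unknown2"), ann),
                 "covers only")
  expect_error(partition_by_biotype(c("u1", "u2"), ann), "none of")
})

test_that("abundance shares per biotype sum to 100%", {
  sim <- simulate_experiment(n_genes = 400, seed = 10)
  norm <- normalize_tmm(sim)
  ann <- data.frame(gene_id = sim$truth$gene_id, symbol = sim$truth$gene_id,
                    biotype = sim$truth$biotype)
  part <- partition_by_biotype(rownames(norm$expr), ann, expr = norm,
                               samples = colnames(norm$expr))
  expect_equal(sum(part$table$abundance_share), 100, tolerance = 1e-9)
})

test_that("abundant-DE-ncRNA filter applies its thresholds exactly", {
  de <- data.frame(gene_id = c("c1", "n1", "n2", "n3", "n4"),
                   mean_tmm = c(100, 100, 100, 25, 100),
                   log2fc_3h = 0, p_3h = 0.5, q_3h = 0.5,
                   log2fc_8h = c(3, 1, -1, 3, 0.9),
                   p_8h = 1e-6, q_8h = c(1e-5, 1e-5, 1e-5, 1e-5, 1e-5))
  ann <- data.frame(gene_id = de$gene_id, symbol = de$gene_id,
                    biotype = c("protein_coding", "lncRNA", "antisense",
                                "lncRNA", "TEC"))
  got <- de_ncrna(de, ann)
  # c1 is coding; n3 fails the strict >25 TMM; n4 is below 2-fold;
  # n1 sits exactly at 2-fold and is included (non-strict)
  expect_identical(sort(got$gene_id), c("n1", "n2"))
  expect_identical(got$direction[got$gene_id == "n1"], "up")
  expect_identical(got$direction[got$gene_id == "n2"], "down")
  # coding-only input -> empty
  expect_identical(nrow(de_ncrna(de[1, ], ann)), 0L)
  # raising thresholds never adds genes
  tighter <- de_ncrna(de, ann, min_tmm = 50, min_fold = 4)
  expect_true(all(tighter$gene_id %in% got$gene_id))
})

test_that("planted non-coding waves are recovered with correct directions", {
  sim <- shared_sim()
  fit <- shared_fit()
  ann <- data.frame(gene_id = sim$truth$gene_id, symbol = sim$truth$gene_id,
                    biotype = sim$truth$biotype)
  got <- de_ncrna(fit$de, ann, min_tmm = 25, min_fold = 2, q_max = 0.05)
  truth <- sim$truth[match(got$gene_id, sim$truth$gene_id), ]
  expect_true(all(truth$biotype != "protein_coding"))
  up_classes <- c("up_same", "up_up", "same_up")
  down_classes <- c("down_same", "down_down", "same_down")
  expect_true(all(got$direction[truth$planted_class %in% up_classes] == "up"))
  expect_true(all(got$direction[truth$planted_class %in% down_classes] == "down"))
  # strongly planted abundant ncRNAs should be found
  cand <- sim$truth$gene_id[sim$truth$biotype != "protein_coding" &
                              sim$truth$planted_class %in%
                                c(up_classes, down_classes)]
  cand <- intersect(cand, fit$de$gene_id[fit$de$mean_tmm > 50])
  expect_gt(mean(cand %in% got$gene_id), 0.8)
})
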