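test_that("simulated genomes hit their GC target and are seed-deterministic", {
  g1 <- simulate_genome("spX", "genX", length = 50000L, gc = 0.30,
                        n_core_genes = 10L, gene_len = 500L,
                        accessory_len = 3000L, seed = 5)
  gc_frac <- mean(strsplit(g1$seq, "")[[1]] %in% c("G", "C"))
  expect_equal(gc_frac, 0.30, tolerance = 0.01)
  g2 <- simulate_genome("spX", "genX", length = 50000L, gc = 0.30,
                        n_core_genes = 10L, gene_len = 500L,
                        accessory_len = 3000L, seed = 5)
  expect_identical(g1$seq, g2$seq)
  expect_error(simulate_genome("s", "g", length = 1000L, n_core_genes = 10L,
                               gene_len = 500L), "too short")
})

test_that("reads are exact substrings without errors and hit the base budget", {
  taxon <- tiny_taxa(1)[[1]]
  reads <- simulate_reads(taxon, coverage = 2, error_rate = 0, seed = 7)
  expect_equal(sum(nchar(reads$seq)), 2 * nchar(taxon$seq), tolerance = 150)
  found <- vapply(reads$seq[1:50], function(s) {
    stringi::stri_detect_fixed(taxon$seq, s) ||
      stringi::stri_detect_fixed(taxon$seq, revcomp(s))
  }, logical(1))
  expect_true(all(found))
  expect_true(all(phred_scores(reads$qual[1:5])[[1]] == 40L))
})

test_that("plasmid reads appear at copy-number proportional rates", {
  taxon <- tiny_taxa(1, genome_length = 20000L, n_core_genes = 5L)[[1]]
  taxon <- add_plasmid(taxon, length = 1000L, copy_number = 10L, seed = 8)
  reads <- simulate_reads(taxon, coverage = 30, error_rate = 0, seed = 9)
  from_plasmid <- vapply(reads$seq, function(s) {
    stringi::stri_detect_fixed(taxon$plasmids$seq[1], s) ||
      stringi::stri_detect_fixed(taxon$plasmids$seq[1], revcomp(s))
  }, logical(1))
  # plasmid weight: 1000 * 10 of 30000 total
  expect_equal(mean(from_plasmid), 1 / 3, tolerance = 0.03)
})

test_that("mixtures hold the requested contaminant share", {
  taxa <- tiny_taxa(2)
  a <- simulate_reads(taxa[[1]], 60, seed = 10)
  b <- simulate_reads(taxa[[2]], 30, seed = 11)
  mx <- mix_reads(a, b, 0.2, total_reads = 10000, seed = 12)
  expect_equal(sum(mx$origin == "contaminant"), 2000)
  expect_equal(nrow(mx), 10000)
  pure <- mix_reads(a, NULL, 0, total_reads = 5000, seed = 13)
  expect_true(all(pure$origin == "subject"))
  expect_error(mix_reads(a[1:10, ], b, 0.2, total_reads = 10000), "subject")
})

test_that("pseudo-assembly tiles pure genomes and gates contaminant content", {
  taxa <- tiny_taxa(2)
  subj <- taxa[[1]]
  contigs <- pseudo_assemble(subj, seed = 14)
  expect_identical(paste(contigs$seq, collapse = ""), subj$seq)

  # 5% of 50x is below the 10x assembly threshold: no contaminant trace
  low <- pseudo_assemble(subj, taxa[[2]], ratio = 0.05, coverage = 50, seed = 15)
  expect_false(any(grepl("_c_", low$id)))
  high <- pseudo_assemble(subj, taxa[[2]], ratio = 0.30, coverage = 50, seed = 16)
  expect_true(any(grepl("ctg_c_", high$id)))

  # same-genus contaminants contribute only their divergent gene copies
  rel <- simulate_relative(subj, 4, seed = 17)
  intra <- pseudo_assemble(subj, rel, ratio = 0.30, coverage = 50, seed = 18)
  dup_ids <- grep("ctg_dup_", intra$id, value = TRUE)
  expect_length(dup_ids, 4)
  expect_setequal(sub("ctg_dup_", "", dup_ids), rel$changed_loci)
})

test_that("isolate variants differ only in the accessory segment", {
  subj <- tiny_taxa(1, genome_length = 40000L)[[1]]
  iso <- simulate_isolate(subj, seed = 19)
  expect_equal(gene_seqs(iso), gene_seqs(subj))
  expect_false(identical(iso$seq, subj$seq))
  # accessory GC variation moves whole-genome GC only slightly
  expect_equal(assembly_stats(as_contigs(iso))$gc_percent,
               assembly_stats(as_contigs(subj))$gc_percent, tolerance = 1)
})

test_that("panel runs are deterministic and have the expected design size", {
  taxa <- tiny_taxa(2)
  args <- list(taxa = taxa, distances = 4L, ratios = 0.1, replicates = 1L,
               metrics = c("assembly", "typing"), seed = 77)
  tbl1 <- do.call(run_panel, args)
  tbl2 <- do.call(run_panel, args)
  expect_equal(tbl1, tbl2)
  # per subject: 1 self + 1 intergenus + 1 intragenus
  expect_equal(nrow(tbl1), 2 * 3)
  expect_setequal(unique(tbl1$kind), c("self", "intergenus", "intragenus"))
  # a full design multiplies out genera x contaminants x ratios x replicates
  tbl3 <- run_panel(taxa, distances = c(0L, 4L), ratios = c(0.1, 0.3),
                    replicates = 2L, metrics = "assembly", seed = 78)
  expect_equal(sum(tbl3$kind == "self"), 2 * 2)
  expect_equal(sum(tbl3$kind == "intergenus"), 2 * 1 * 2 * 2)
  expect_equal(sum(tbl3$kind == "intragenus"), 2 * 2 * 2 * 2)
})

test_that("sensitivity tables split flags by kind and group", {
  tbl <- tibble::tibble(
    subject = "spA", genus = "genA",
    kind = c("self", "intergenus", "intergenus", "intragenus", "intragenus"),
    relatedness = c(NA, NA, NA, "close", "distant"),
    ratio = c(0, 0.1, 0.3, 0.1, 0.3), replicate = 1L,
    gc_percent = c(40, 40, 47, 40, 40),
    mlst_duplicated = c(0, 0, 0, 0, 1))
  thr <- tibble::tibble(taxon = c("spA", "global"), rank = c("species", "global"),
                        metric = c("gc_percent", "mlst_duplicated"),
                        low = c(39, NA), high = c(41, 0),
                        critical = FALSE)
  sens <- sensitivity_table(tbl, thr)
  gc_inter <- sens[sens$metric == "gc_percent" & sens$kind == "intergenus", ]
  expect_equal(gc_inter$value, 0.5)
  mlst_dist <- sens[sens$metric == "mlst_duplicated" & sens$group == "distant", ]
  expect_equal(mlst_dist$value, 1)
  self_rows <- sens[sens$kind == "self", ]
  expect_true(all(self_rows$measure == "specificity" & self_rows$value == 1))
  # a metric that flags everything: sensitivity 1, specificity 0
  tbl$always <- c(10, 10, 10, 10, 10)
  thr2 <- dplyr::bind_rows(thr, tibble::tibble(
    taxon = "spA", rank = "species", metric = "always",
    low = 99, high = NA, critical = FALSE))
  sens2 <- sensitivity_table(tbl, thr2)
  always <- sens2[sens2$metric == "always", ]
  expect_true(all(always$value[always$measure == "sensitivity"] == 1))
  expect_true(all(always$value[always$measure == "specificity"] == 0))
})
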