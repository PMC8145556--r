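make_mini_scheme <- function() {
  withr::with_seed(51, {
    alleles <- list(
      adk = stats::setNames(c(random_dna_test(300), random_dna_test(300)),
                            c("adk_1", "adk_2")),
      gyrB = stats::setNames(c(random_dna_test(300), random_dna_test(300)),
                             c("gyrB_1", "gyrB_2")))
    profiles <- tibble::tibble(ST = c(1L, 21L), adk = c(1L, 2L), gyrB = c(1L, 2L))
    new_scheme(alleles, profiles, "mlst")
  })
}

test_that("allele calling finds exact matches on both strands, including mixtures", {
  sch <- make_mini_scheme()
  a1 <- sch$alleles$adk[["adk_1"]]
  g2 <- sch$alleles$gyrB[["gyrB_2"]]
  contigs <- tibble::tibble(
    id = c("c1", "c2"),
    seq = c(paste0("AAAA", a1, "TTTT"), paste0("GG", revcomp(g2), "CC")))
  calls <- call_alleles(contigs, sch)
  expect_equal(calls$alleles[[1]], "adk_1")
  expect_equal(calls$alleles[[2]], "gyrB_2")

  mixed <- tibble::tibble(id = "c", seq = paste0(a1, "NN", sch$alleles$adk[["adk_2"]]))
  calls2 <- call_alleles(mixed, sch)
  expect_setequal(calls2$alleles[[1]], c("adk_1", "adk_2"))
  expect_equal(duplicated_alleles(calls2)$duplicated_loci, 1L)
  expect_true(duplicated_alleles(calls2)$contaminated)
})

test_that("sequence types require one allele per locus and a profile match", {
  sch <- make_mini_scheme()
  both2 <- tibble::tibble(id = "c", seq = paste0(sch$alleles$adk[["adk_2"]], "NN",
                                                 sch$alleles$gyrB[["gyrB_2"]]))
  expect_equal(sequence_type(call_alleles(both2, sch), sch), "21")
  # a duplicated locus or a missing locus yields no ST
  dup <- tibble::tibble(id = "c", seq = paste0(sch$alleles$adk[["adk_1"]], "NN",
                                               sch$alleles$adk[["adk_2"]], "NN",
                                               sch$alleles$gyrB[["gyrB_1"]]))
  expect_equal(sequence_type(call_alleles(dup, sch), sch), "unknown")
  missing <- tibble::tibble(id = "c", seq = sch$alleles$adk[["adk_1"]])
  expect_equal(sequence_type(call_alleles(missing, sch), sch), "unknown")
})

test_that("core scheme construction keeps single-copy near-universal loci", {
  withr::local_seed(53)
  genes <- tibble::tibble(id = sprintf("g%02d", 1:10),
                          seq = vapply(1:10, function(i) random_dna_test(400),
                                       character(1)))
  spacer <- function() random_dna_test(200)
  genome_of <- function(gene_seqs) {
    paste(c(rbind(vapply(seq_along(gene_seqs), function(i) spacer(), character(1)),
                  gene_seqs)), collapse = "")
  }
  genomes <- purrr::map_dfr(1:5, function(g) {
    tibble::tibble(label = paste0("G", g), seq = genome_of(genes$seq))
  })
  sch <- build_core_scheme(genes, genomes)
  expect_s3_class(sch, "scheme")
  expect_equal(sch$loci, genes$id)
  # a gene duplicated in one of five genomes (beyond the 5% tolerance) is dropped
  genomes_dup <- genomes
  genomes_dup$seq[1] <- paste0(genomes_dup$seq[1], spacer(), genes$seq[3])
  sch_dup <- build_core_scheme(genes, genomes_dup)
  expect_false("g03" %in% sch_dup$loci)
  expect_equal(setdiff(genes$id, sch_dup$loci), "g03")
  # locus set invariant under genome order permutation
  sch_perm <- build_core_scheme(genes, genomes[c(3, 1, 5, 2, 4) * 1, ])
  expect_equal(sch_perm$loci, sch$loci)
  # near-exact variants (>= 90% identity) become numbered alleles
  var <- genes$seq[1]
  substr(var, 10, 10) <- ifelse(substr(var, 10, 10) == "A", "C", "A")
  genomes_var <- genomes
  genomes_var$seq[2] <- genome_of(c(var, genes$seq[-1]))
  sch_var <- build_core_scheme(genes, genomes_var)
  expect_length(sch_var$alleles$g01, 2)
})

test_that("allele distance is a metric and ignores missing loci", {
  pa <- c(l1 = "l1_1", l2 = "l2_2", l3 = "l3_3", l4 = NA)
  pb <- c(l1 = "l1_1", l2 = "l2_2", l3 = "l3_4", l4 = "l4_5")
  expect_equal(allele_distance(pa, pa), 0)
  expect_equal(allele_distance(pa, pb), 1)
  expect_error(allele_distance(c(l1 = NA_character_), c(l1 = NA_character_)),
               "comparable")
  withr::local_seed(54)
  loci <- paste0("l", 1:8)
  rand_prof <- function() stats::setNames(paste0(loci, "_", sample(3, 8, TRUE)), loci)
  for (i in 1:50) {
    x <- rand_prof(); y <- rand_prof(); z <- rand_prof()
    expect_equal(allele_distance(x, y), allele_distance(y, x))
    expect_lte(allele_distance(x, z),
               allele_distance(x, y) + allele_distance(y, z))
    expect_equal(allele_distance(x, x), 0)
  }
})

test_that("relatedness categories follow the allele-distance bins", {
  expect_equal(categorize_relatedness(TRUE, 0), "close")
  expect_equal(categorize_relatedness(FALSE, 4), "intermediate")
  expect_equal(categorize_relatedness(FALSE, 7), "distant")
  expect_equal(categorize_relatedness(FALSE, 9), "distant")
  expect_equal(categorize_relatedness(FALSE, 1), "intermediate")
})

test_that("relatives recover their target allele distance exactly", {
  taxon <- tiny_taxa(1)[[1]]
  for (d in c(0L, 2L, 4L, 6L, 7L, 10L)) {
    for (s in 1:3) {
      rel <- simulate_relative(taxon, d, seed = 100 * s + d)
      sch <- panel_scheme(taxon, list(rel))$core
      pa <- allele_profile(call_alleles(as_contigs(taxon), sch))
      pb <- allele_profile(call_alleles(as_contigs(rel), sch))
      expect_equal(allele_distance(pa, pb), d, label = sprintf("AD %d seed %d", d, s))
    }
  }
  expect_equal(categorize_relatedness(TRUE, 0), "close")
})

test_that("core-gene assessment measures completeness and duplication", {
  taxon <- tiny_taxa(1)[[1]]
  sch <- panel_scheme(taxon)$core
  full <- core_gene_assessment(as_contigs(taxon), sch)
  expect_equal(full$unique_fraction, 100)
  expect_equal(full$duplicated_count, 0L)
  expect_false(full$contamination_warning)

  # remove two of ten loci
  genes <- taxon$genes
  cut <- tibble::tibble(id = "c", seq = paste0(
    substr(taxon$seq, 1, genes$start[3]),
    substr(taxon$seq, genes$end[4] + 1, nchar(taxon$seq))))
  partial <- core_gene_assessment(cut, sch)
  expect_equal(partial$unique_fraction, 80)

  # duplicating one locus warns only above one duplicated locus
  dup1 <- tibble::tibble(id = c("c", "extra"),
                         seq = c(taxon$seq, gene_seqs(taxon)$seq[1]))
  a1 <- core_gene_assessment(dup1, sch)
  expect_equal(a1$duplicated_count, 1L)
  expect_false(a1$contamination_warning)
  dup2 <- tibble::tibble(id = c("c", "e1", "e2"),
                         seq = c(taxon$seq, gene_seqs(taxon)$seq[1:2]))
  a2 <- core_gene_assessment(dup2, sch)
  expect_equal(a2$duplicated_count, 2L)
  expect_true(a2$contamination_warning)
})

test_that("pure samples never show duplicated alleles", {
  taxa <- tiny_taxa(2)
  for (taxon in taxa) {
    sch <- panel_scheme(taxon)$mlst
    for (s in 1:10) {
      contigs <- pseudo_assemble(taxon, seed = 300 + s)
      expect_equal(duplicated_alleles(call_alleles(contigs, sch))$duplicated_loci, 0L)
    }
  }
})
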