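test_that("baiting assigns reads to the locus with most shared k-mers", {
  taxon <- tiny_taxa(1)[[1]]
  sch <- panel_scheme(taxon)$core
  g <- taxon$genes
  reads <- tibble::tibble(
    id = c("from_g1", "intergenic", "chimera"),
    seq = c(substr(taxon$seq, g$start[1] + 51, g$start[1] + 200),
            substr(taxon$seq, g$end[1] + 51, g$end[1] + 200),
            paste0(substr(taxon$seq, g$start[2] + 1, g$start[2] + 100),
                   substr(taxon$seq, g$start[3] + 1, g$start[3] + 50))))
  baited <- bait_reads(reads, sch)
  expect_equal(baited$locus[baited$id == "from_g1"], g$locus[1])
  expect_false("intergenic" %in% baited$id)
  expect_equal(baited$locus[baited$id == "chimera"], g$locus[2])
})

test_that("pileups place reads ungapped and record substitutions", {
  taxon <- tiny_taxa(1)[[1]]
  sch <- panel_scheme(taxon)$core
  locus1 <- sch$alleles[[1]][[1]]
  tile <- function(off) substr(locus1, off + 1, off + 150)
  reads <- tibble::tibble(id = sprintf("t%02d", 0:9),
                          seq = vapply(0:9 * 35, tile, character(1)),
                          qual = strrep(phred_encode(40L), 150))
  baited <- bait_reads(reads, sch)
  piles <- pileup(baited, sch)
  expect_true(all(piles$depth == pmax(piles$A, piles$C, piles$G, piles$T)))

  # one read with a substitution at (0-based) site 5
  mut <- tile(0)
  orig <- substr(mut, 6, 6)
  substr(mut, 6, 6) <- setdiff(c("A", "C", "G", "T"), orig)[1]
  reads2 <- dplyr::bind_rows(reads, tibble::tibble(
    id = "mut", seq = mut, qual = strrep(phred_encode(40L), 150)))
  piles2 <- pileup(bait_reads(reads2, sch), sch)
  site <- piles2[piles2$pos == 5 & piles2$locus == sch$loci[1], ]
  expect_equal(site$depth - pmax(site$A, site$C, site$G, site$T), 1)

  expect_equal(nrow(pileup(baited[0, ], sch)), 0)
})

test_that("contaminating SNV sites require depth and dual support", {
  mk <- function(A, C) tibble::tibble(locus = "l", pos = 0L, depth = A + C,
                                      A = A, C = C, G = 0L, T = 0L)
  expect_equal(contaminating_snvs(mk(40L, 10L))$n_snvs, 1L)
  expect_equal(contaminating_snvs(mk(49L, 1L))$n_snvs, 0L)   # minor reads < 2
  expect_equal(contaminating_snvs(mk(5L, 3L))$n_snvs, 0L)    # depth < 10
  expect_equal(contaminating_snvs(mk(96L, 4L))$n_snvs, 0L)   # fraction < 5%
})

test_that("contamination calls combine SNV count and multiallelic loci", {
  sites <- function(n, loci) tibble::tibble(
    locus = loci, pos = seq_len(n), depth = 50L,
    A = 40L, C = 10L, G = 0L, T = 0L)
  s1 <- contaminating_snvs(sites(2, c("l1", "l2")))
  expect_false(contamination_call(s1)$contaminated)          # 2 SNVs, no locus twice
  s2 <- contaminating_snvs(sites(3, c("l1", "l2", "l3")))
  expect_true(contamination_call(s2)$contaminated)           # cutoff reached
  s3 <- contaminating_snvs(sites(2, c("l1", "l1")))
  expect_true(contamination_call(s3)$contaminated)           # multiallelic locus
  expect_equal(contamination_call(s2)$est_contamination_percent, 20)
  empty <- contaminating_snvs(sites(0, character(0)))
  expect_true(is.na(contamination_call(empty)$est_contamination_percent))
})

test_that("distant intragenus mixtures are detected across ratios and ADs", {
  taxon <- tiny_taxa(1)[[1]]
  rel4 <- simulate_relative(taxon, 4, seed = 71)
  rel10 <- simulate_relative(taxon, 10, seed = 72)
  sch <- panel_scheme(taxon, list(rel4, rel10))$core
  pool <- simulate_reads(taxon, 50, seed = 73)
  cpool4 <- simulate_reads(rel4, 25, seed = 74)
  cpool10 <- simulate_reads(rel10, 25, seed = 75)
  n_by_ratio <- vapply(c(0.1, 0.2, 0.3), function(r) {
    detect_contamination(mix_reads(pool, cpool10, r, seed = 76), sch)$n_snvs
  }, numeric(1))
  expect_true(all(diff(n_by_ratio) >= 0))   # monotone in mixing ratio
  cc <- detect_contamination(mix_reads(pool, cpool10, 0.2, seed = 77), sch)
  expect_true(cc$contaminated)
  n_ad4 <- detect_contamination(mix_reads(pool, cpool4, 0.2, seed = 78), sch)$n_snvs
  expect_lte(n_ad4, n_by_ratio[2])          # monotone in allele distance

  # larger schemes detect at least as many SNVs
  sub_sch <- new_scheme(sch$alleles[1:5], NULL, "core")
  mx <- mix_reads(pool, cpool10, 0.2, seed = 79)
  expect_gte(detect_contamination(mx, sch)$n_snvs,
             detect_contamination(mx, sub_sch)$n_snvs)
})

test_that("contamination ratio is recovered within ten points", {
  taxon <- tiny_taxa(1)[[1]]
  rel <- simulate_relative(taxon, 10, seed = 81)
  sch <- panel_scheme(taxon, list(rel))$core
  pool <- simulate_reads(taxon, 50, seed = 82)
  cpool <- simulate_reads(rel, 25, seed = 83)
  dev <- vapply(c(0.1, 0.2, 0.3), function(r) {
    cc <- detect_contamination(mix_reads(pool, cpool, r, seed = round(100 * r)), sch)
    abs(cc$est_contamination_percent - 100 * r)
  }, numeric(1))
  expect_lte(mean(dev), 10)
})

test_that("pure samples carry no contaminating SNVs", {
  taxa <- tiny_taxa(2)
  schemes <- lapply(taxa, function(t) panel_scheme(t)$core)
  for (i in 1:10) {
    t_i <- (i - 1L) %% length(taxa) + 1L
    reads <- simulate_reads(taxa[[t_i]], 50, seed = 9000 + i)
    cc <- detect_contamination(reads, schemes[[t_i]])
    expect_false(cc$contaminated, label = sprintf("pure run %d", i))
  }
})
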