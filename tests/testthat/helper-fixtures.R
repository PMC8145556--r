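# Shared fixtures: small synthetic taxa and indexes built in code.

# A compact panel: `n` genera of 30 kb with 10 core genes of 500 bp.
tiny_taxa <- function(n = 2L, seed = 11L, genome_length = 30000L,
                      n_core_genes = 10L, gene_len = 500L) {
  panel_taxa(seed = seed, n_genera = n,
             gc_targets = seq(0.3, 0.6, length.out = max(2, n)),
             genome_length = genome_length, n_core_genes = n_core_genes,
             gene_len = gene_len)
}

tiny_index <- function(taxa) {
  genomes <- purrr::map_dfr(taxa, function(t) {
    dplyr::bind_rows(tibble::tibble(label = t$species, seq = t$seq),
                     tibble::tibble(label = t$plasmids$label,
                                    seq = t$plasmids$seq))
  })
  taxonomy <- purrr::map_dfr(taxa, function(t) {
    tibble::tibble(label = t$species, species = t$species, genus = t$genus)
  })
  build_kmer_index(genomes, taxonomy)
}

# One genome as a single 'contig' table, for whole-genome allele profiling.
as_contigs <- function(taxon) {
  tibble::tibble(id = taxon$species, seq = taxon$seq)
}

# Independent brute-force N50: the largest length L attained by a contig such
# that contigs of length >= L hold at least half the total.
n50_oracle <- function(lens) {
  total <- sum(lens)
  for (L in sort(unique(lens), decreasing = TRUE)) {
    if (sum(lens[lens >= L]) >= total / 2) return(L)
  }
}

random_dna_test <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

contigs_of_lengths <- function(lens) {
  tibble::tibble(id = sprintf("c%03d", seq_along(lens)),
                 seq = strrep("A", lens))
}
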