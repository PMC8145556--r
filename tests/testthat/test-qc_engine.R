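test_that("species thresholds are interpolated quantiles with a sample floor", {
  tbl <- tibble::tibble(sample = sprintf("s%03d", 1:100),
                        species = "spX", genus = "genX",
                        m_const = 7, m_range = 1:100)
  thr <- derive_species_thresholds(tbl, min_n = 100)
  const <- thr[thr$metric == "m_const", ]
  expect_equal(c(const$low, const$high), c(7, 7))
  rng <- thr[thr$metric == "m_range", ]
  expect_equal(c(rng$low, rng$high), c(5.95, 95.05))
  # quantile oracle: manual linear interpolation at p = 0.05 over 1..100
  expect_equal(rng$low, 1 + 0.05 * 99)
  expect_equal(nrow(derive_species_thresholds(tbl[1:99, ], min_n = 100)), 0)
  expect_error(derive_species_thresholds(tbl[0, ]), "empty")
})

test_that("genus thresholds span their member species", {
  sp <- tibble::tibble(taxon = c("s1", "s2"), rank = "species",
                       genus = "g", metric = "assembly_length",
                       low = c(4.5, 4.7), high = c(5.0, 5.3), n = 100)
  g <- derive_genus_thresholds(sp)
  expect_equal(c(g$low, g$high), c(4.5, 5.3))
  one <- derive_genus_thresholds(sp[1, ])
  expect_equal(c(one$low, one$high), c(4.5, 5.0))
  # containment property on random species ranges
  withr::local_seed(91)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    lows <- runif(k); highs <- lows + runif(k)
    sp_i <- tibble::tibble(taxon = paste0("s", 1:k), rank = "species",
                           genus = "g", metric = "m", low = lows, high = highs,
                           n = 100)
    g_i <- derive_genus_thresholds(sp_i)
    expect_true(all(g_i$low <= lows & g_i$high >= highs))
  }
})

test_that("metric evaluation against the bundled thresholds matches the rules", {
  thr <- default_thresholds()
  ec <- resolve_thresholds(thr, species = "Escherichia coli")
  ctg <- ec[ec$metric == "n_contigs", ]
  expect_equal(evaluate_metric(700, ctg$low, ctg$high, ctg$critical), "warn")
  se <- resolve_thresholds(thr, species = "Salmonella enterica")
  al <- se[se$metric == "assembly_length", ]
  expect_equal(evaluate_metric(3.0e6, al$low, al$high, al$critical), "fail")
  expect_equal(evaluate_metric(NA, al$low, al$high, al$critical), "not-assessed")
  # genus fallback
  campy <- resolve_thresholds(thr, species = "Campylobacter jejuni",
                              genus = "Campylobacter")
  gcr <- campy[campy$metric == "gc_percent", ]
  expect_equal(evaluate_metric(30.4, gcr$low, gcr$high, gcr$critical), "pass")
  # warn band nested in the fail range
  expect_equal(evaluate_metric(4.6e6, al$low, al$high, TRUE,
                               warn_low = 4.7e6, warn_high = 5.0e6), "warn")
})

test_that("combined taxonomy status follows the dual-classification rule", {
  expect_equal(combined_taxonomy_status(0.80, 0.82), "fail")
  expect_equal(combined_taxonomy_status(0.89, 0.99), "warn")
  expect_equal(combined_taxonomy_status(0.99, 0.99), "pass")
  expect_equal(combined_taxonomy_status(NA, 0.80), "fail")
  expect_equal(combined_taxonomy_status(0.99, NA), "pass")
  expect_equal(combined_taxonomy_status(NA, NA), "not-assessed")
})

test_that("verdicts aggregate statuses with critical precedence", {
  st <- function(...) tibble::tibble(
    metric = c("q30_fraction", "n50", "snv_contamination"),
    status = c(...), critical = c(TRUE, FALSE, TRUE))
  expect_equal(qc_verdict(st("pass", "pass", "pass")), "pass")
  expect_equal(qc_verdict(st("pass", "warn", "pass")), "warning")
  expect_equal(qc_verdict(st("pass", "pass", "fail")), "fail")
  expect_equal(qc_verdict(st("not-assessed", "pass", "pass")), "pass")
})

test_that("worsening a metric never improves the verdict", {
  withr::local_seed(92)
  rank <- c(pass = 1L, warning = 2L, fail = 3L)
  thr <- tibble::tibble(metric = paste0("m", 1:5),
                        low = runif(5, 0, 0.4), high = runif(5, 0.6, 1),
                        critical = c(TRUE, TRUE, FALSE, FALSE, TRUE))
  verdict_of <- function(values) {
    qc_verdict(tibble::tibble(
      metric = thr$metric,
      status = mapply(evaluate_metric, values, thr$low, thr$high, thr$critical),
      critical = thr$critical))
  }
  for (i in 1:100) {
    v <- runif(5, -0.2, 1.2)
    j <- sample(5, 1)
    worse <- v
    # push the metric further from the centre of its range
    centre <- (thr$low[j] + thr$high[j]) / 2
    worse[j] <- v[j] + sign(v[j] - centre) * runif(1, 0, 0.5)
    expect_gte(rank[[verdict_of(worse)]], rank[[verdict_of(v)]],
               label = sprintf("case %d", i))
  }
})

test_that("report filtering prunes exactly the omitted branches and is idempotent", {
  statuses <- tibble::tibble(metric = "q30_fraction", status = "pass",
                             critical = TRUE)
  rep <- assemble_report("s1", list(q30_fraction = 0.95), statuses,
                         pipeline = list(classification = list(fraction = 0.99),
                                         read_qc = list(n_reads = 5)))
  ident <- report_schema(rep)
  expect_equal(filter_report(rep, ident), rep)

  pruned_schema <- ident
  pruned_schema$pipeline$classification <- NULL
  flt <- filter_report(rep, pruned_schema)
  expect_false("classification" %in% names(flt$pipeline))
  expect_true("read_qc" %in% names(flt$pipeline))
  expect_equal(filter_report(flt, pruned_schema), flt)
  expect_equal(nrow(validate_report(flt)), 0)
})

test_that("a batch records failed samples and reuses cached reports", {
  taxa <- tiny_taxa(2)
  idx <- tiny_index(taxa)
  schemes <- panel_scheme(taxa[[1]])
  dir <- withr::local_tempdir()
  outdir <- file.path(dir, "out")

  good1_fq <- file.path(dir, "g1.fastq")
  write_fastq(simulate_reads(taxa[[1]], 8, seed = 101), good1_fq)
  good1_fa <- file.path(dir, "g1.fasta")
  write_fasta(pseudo_assemble(taxa[[1]], seed = 102), good1_fa)
  good2_fa <- file.path(dir, "g2.fasta")
  write_fasta(pseudo_assemble(taxa[[2]], seed = 103), good2_fa)
  bad_fa <- file.path(dir, "bad.fasta")
  write_fasta(tibble::tibble(id = "short", seq = strrep("ACGT", 30)), bad_fa)

  sheet_path <- file.path(dir, "sheet.tsv")
  writeLines(c("sample\tfq1\tfq2\tassembly",
               paste0("good1\tg1.fastq\t\tg1.fasta"),
               paste0("good2\t\t\tg2.fasta"),
               paste0("bad\t\t\tbad.fasta")), sheet_path)
  sheet <- read_samplesheet(sheet_path)

  refs <- purrr::map_dfr(taxa, function(t) {
    tibble::tibble(label = t$species, species = t$species, genus = t$genus,
                   seq = t$seq)
  })
  cfg <- qc_config(index = idx, references = refs, mlst_scheme = schemes$mlst,
                   core_scheme = schemes$core, outdir = outdir)
  res <- run_batch(sheet, cfg)
  expect_length(res$reports, 2)
  expect_equal(res$failed$sample, "bad")
  expect_equal(res$failed$module, "assembly")
  expect_match(res$failed$reason, "no assembly")
  expect_equal(nrow(res$summary), 2)
  expect_true(file.exists(file.path(outdir, "summary.tsv")))
  expect_true(file.exists(file.path(outdir, "report.html")))

  # reads-dependent metrics of the assembly-only sample are not assessed
  st2 <- res$reports$good2$sample$assessment$statuses
  expect_equal(st2$q30_fraction, "not-assessed")
  expect_equal(st2$snv_contamination, "not-assessed")

  # the rerun serves unchanged samples from cache
  res2 <- run_batch(sheet, cfg)
  expect_setequal(res2$reused, c("good1", "good2"))
  expect_equal(res2$summary, res$summary, tolerance = 1e-9)
})

test_that("tidy and glance summarise a report", {
  statuses <- tibble::tibble(metric = c("q30_fraction", "n50"),
                             status = c("pass", "warn"),
                             critical = c(TRUE, FALSE))
  rep <- assemble_report("s1", list(q30_fraction = 0.93, n50 = 1e4), statuses)
  td <- tidy(rep)
  expect_equal(td$metric, c("q30_fraction", "n50"))
  expect_equal(td$value, c(0.93, 1e4))
  gl <- glance(rep)
  expect_equal(gl$verdict, "warning")
  expect_equal(gl$n_warn, 1)
})
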