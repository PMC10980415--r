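test_that("generation is fully deterministic under a fixed seed", {
  cfg <- sim_config(seed = 91)
  t1 <- simulate_genome(cfg)
  t2 <- simulate_genome(cfg)
  expect_identical(as.character(t1$genome), as.character(t2$genome))
  expect_identical(t1$site, t2$site)
  expect_identical(t1$editing, t2$editing)
  e1 <- simulate_end_counts(t1, seed = 92)
  e2 <- simulate_end_counts(t2, seed = 92)
  expect_identical(e1$wt$counts, e2$wt$counts)
  expect_identical(e1$mutant$counts, e2$mutant$counts)
  j1 <- simulate_junctions_and_editing(t1, seed = 93)
  j2 <- simulate_junctions_and_editing(t2, seed = 93)
  expect_identical(j1, j2)
  c1 <- simulate_clones(t1, n = 10, seed = 94)
  c2 <- simulate_clones(t2, n = 10, seed = 94)
  expect_identical(as.character(c1$clones), as.character(c2$clones))
  expect_identical(c1$ends, c2$ends)
})

test_that("the planted site honours its mismatch budget constructively", {
  for (seed in c(95, 96)) {
    tr <- simulate_genome(sim_config(seed = seed, site_mismatches = 5))
    q <- chartr("U", "T", tr$perfect_target)
    in_hits <- function(hits) {
      any(hits$start == tr$site$start & hits$end == tr$site$end &
            hits$strand == tr$site$strand)
    }
    expect_true(in_hits(fuzzy_scan(tr$genome, q, 5)))
    expect_false(in_hits(fuzzy_scan(tr$genome, q, 4)))
    # and the planted hit carries exactly the configured distance
    h5 <- fuzzy_scan(tr$genome, q, 5)
    planted <- h5[h5$start == tr$site$start & h5$strand == "-", ]
    expect_equal(planted$mismatches, 5)
  }
  # zero-mismatch config: the scaffold reads the site as all-perfect
  tr0 <- simulate_genome(sim_config(seed = 97, site_mismatches = 0))
  bp <- predict_binding(tr0$scaffold, tr0$site$rna, tr0$code)
  expect_equal(unname(bp$counts["perfect"]), length(tr0$scaffold))
})

test_that("redesigning the scaffold against the planted site removes mismatches", {
  tr <- simulate_genome(sim_config(seed = 98))
  pre <- predict_binding(tr$scaffold, tr$site$rna, tr$code)
  expect_gt(unname(pre$counts["mismatch"]), 0)
  rd <- redesign(tr$scaffold, tr$site$rna, tr$code)
  expect_lte(nrow(rd$changes), tr$site$mismatches)
  expect_equal(unname(rd$predicted_post$counts["mismatch"]), 0)
})

test_that("the degenerate noise limit yields the exact expected point mass", {
  cfg <- sim_config(seed = 99, cleaved_fraction = 1, dispersion = 0)
  tr <- simulate_genome(cfg)
  ec <- simulate_end_counts(tr)
  b <- tr$boundary$genome_downstream
  expect_equal(unname(ec$mutant$counts[b, 1]), round(ec$expected$mutant[b]))
  expect_true(all(ec$mutant$counts[, 1] == round(ec$expected$mutant)))
  expect_true(all(ec$wt$counts[, 2] == round(ec$expected$wt)))
  # the point mass is cleaved_fraction x peak_scale x gene depth
  gene_bg <- cfg$depth * 1.5  # planted gene abundance
  expect_equal(ec$expected$mutant[b] - ec$expected$wt[b],
               cfg$cleaved_fraction * cfg$peak_scale * gene_bg)
})

test_that("junction and editing draws follow their planted parameters", {
  tr <- simulate_genome(sim_config(seed = 100, splicing_wt = 1.0))
  ev <- simulate_junctions_and_editing(tr, depth = 100, seed = 101)
  wt <- ev$introns[ev$introns$genotype == "wt", ]
  expect_true(all(wt$spliced == 100))  # planted fraction 1: all spliced
  expect_true(all(ev$introns$spliced + ev$introns$unspliced == 100))
  # deep draws concentrate near the planted rates
  tr2 <- simulate_genome(sim_config(seed = 102))
  deep <- simulate_junctions_and_editing(tr2, depth = 10000, seed = 103)
  ed <- deep$editing
  for (s in unique(ed$site)) {
    truth_rate <- tr2$editing$rate_wt[tr2$editing$site == s]
    est <- with(ed[ed$site == s & ed$genotype == "wt", ],
                mean(editing_rate(edited, unedited)))
    expect_lte(abs(est - truth_rate), 0.01)
  }
})

test_that("a written synthetic dataset re-analyzes to its recorded truth", {
  dir <- tempfile()
  tr <- simulate_genome(sim_config(seed = 104))
  set.seed(105)
  write_synthetic_data(tr, dir)
  genome <- read_genome(file.path(dir, "genome.fasta"))
  expect_identical(as.character(genome), as.character(tr$genome))
  models <- read_transcript_models_gff3(file.path(dir, "annotation.gff3"))
  expect_setequal(names(models), names(tr$models))
  for (g in names(models)) {
    expect_equal(models[[g]]$cds_start, tr$models[[g]]$cds_start)
    expect_equal(models[[g]]$utr5, tr$models[[g]]$utr5)
  }
  expect_identical(models$nadC$introns$trans, TRUE)
  # end counts round-trip into profiles
  profs <- read_end_counts_tsv(file.path(dir, "end_counts.tsv"),
                               tr$config$genome_length, "-")
  expect_setequal(names(profs), c("wt", "mutant"))
  expect_equal(ncol(profs$wt$counts), tr$config$replicates)
  # the full pipeline on files alone recovers the recorded boundary
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  clones <- read_fasta(file.path(dir, "clones.fasta"))
  mapped <- suppressMessages(map_clone_ends(clones, genome, models$atpB))
  cc <- call_consensus(mapped[mapped$status == "ok", ], models$atpB,
                       site_3prime = truth$site$start)
  expect_equal(unname(cc$boundary["downstream"]),
               truth$boundary$genome_downstream)
  unlink(dir, recursive = TRUE)
})
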