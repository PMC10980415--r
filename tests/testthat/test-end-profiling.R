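test_that("count_ends places 5' termini by strand and conserves records", {
  aln <- data.frame(strand = c("+", "+", "+", "-", "+", "-"),
                    start = c(100, 100, 100, 90, NA, 5),
                    end = c(130, 130, 130, 110, 40, 2000))
  res <- count_ends(aln, "+", 1000)
  expect_equal(res$counts[100], 3)
  expect_equal(sum(res$counts), 3)
  expect_equal(res$n_skipped, 1)   # the NA forward record
  expect_equal(res$n_used + res$n_skipped, 4)
  rev <- count_ends(aln, "-", 1000)
  expect_equal(rev$counts[110], 1) # reverse-strand 5' end is the rightmost base
  expect_equal(rev$n_skipped, 1)   # the out-of-range reverse record
})

test_that("simulated SAM round-trips through count_ends", {
  tr <- simulate_genome(sim_config(seed = 51))
  dir <- tempfile()
  dir.create(dir)
  ec <- simulate_end_counts(tr, replicates = 1, sam_dir = dir, seed = 52)
  aln <- read_sam_ends(ec$sam_files[1])
  res <- count_ends(aln, "-", tr$config$genome_length)
  expect_identical(res$counts, as.integer(ec$wt$counts[, 1]))
  expect_equal(res$n_used, sum(ec$wt$counts[, 1]))
  unlink(dir, recursive = TRUE)
})

test_that("normalization maps uniform profiles to 1 and spikes to h/pseudocount", {
  prof <- end_profile(rep(7, 600), "+")
  nz <- smooth_normalize(prof, smooth_window = 5, background_window = 201,
                         pseudocount = 0)
  expect_true(all(abs(nz$values - 1) < 1e-12))
  h <- 40
  spike <- numeric(600); spike[300] <- h
  sp <- end_profile(spike, "+")
  nsp <- smooth_normalize(sp, smooth_window = 1, background_window = 201,
                          pseudocount = 0.5)
  expect_equal(unname(nsp$values[300, 1]), h / 0.5)
})

test_that("a planted spike stays the argmax after normalization", {
  set.seed(61)
  for (rep in 1:10) {
    n <- 2000
    counts <- rpois(n, 20)
    pos <- sample(200:1800, 1)
    counts[pos] <- counts[pos] + 500
    prof <- end_profile(counts, "-")
    for (w in list(c(1, 51), c(5, 201), c(9, 301))) {
      nz <- smooth_normalize(prof, w[1], w[2])
      # localization is exact at single-nucleotide resolution and bounded by
      # the half-window once smoothing spreads the point mass
      expect_lte(abs(which.max(nz$values[, 1]) - pos), (w[1] - 1) / 2)
    }
  }
})

test_that("normalization is scale-equivariant up to the pseudocount", {
  set.seed(62)
  counts <- rpois(1000, 15) + 1
  p1 <- end_profile(counts, "+", library_sizes = 1e4)
  p2 <- end_profile(2 * counts, "+", library_sizes = 1e4)
  n1 <- smooth_normalize(p1, 5, 101, pseudocount = 0)
  n2 <- smooth_normalize(p2, 5, 101, pseudocount = 0)
  expect_equal(n1$values, n2$values, tolerance = 1e-12)
  # with a pseudocount the profiles differ, but only mildly
  n1p <- smooth_normalize(p1, 5, 101, pseudocount = 0.5)
  n2p <- smooth_normalize(p2, 5, 101, pseudocount = 0.5)
  expect_false(isTRUE(all.equal(n1p$values, n2p$values)))
  expect_true(max(abs(n1p$values - n2p$values)) < 0.1)
})

test_that("genotype comparison flags constructed signals and only those", {
  set.seed(63)
  base <- matrix(rnorm(500 * 3, mean = 10, sd = 0.3), ncol = 3)
  mk <- function(values, genotype) {
    structure(list(values = values, strand = "+", genotype = genotype,
                   genome_length = nrow(values), smooth_window = 1L,
                   background_window = 101L, pseudocount = 0.5),
              class = "normalized_profile")
  }
  # identical replicate sets: no calls at any alpha
  pc0 <- compare_genotypes(mk(base, "a"), mk(base, "b"), floor = 0)
  expect_true(all(pc0$p == 1))
  expect_false(any(pc0$significant))
  # one position tripled in b: top call
  tweaked <- base
  tweaked[250, ] <- 3 * base[250, ]
  pc1 <- compare_genotypes(mk(base, "a"), mk(tweaked, "b"), floor = 0)
  expect_equal(pc1$coord[1], 250)
  expect_identical(pc1$direction[1], "up_in_b")
  expect_true(pc1$padj[1] < 0.01)
  # symmetry under genotype swap: t negates
  pc2 <- compare_genotypes(mk(tweaked, "b"), mk(base, "a"), floor = 0)
  m1 <- pc1[order(pc1$coord), ]
  m2 <- pc2[order(pc2$coord), ]
  expect_equal(m2$t, -m1$t, tolerance = 1e-12)
  expect_equal(m2$p, m1$p, tolerance = 1e-12)
  expect_error(
    compare_genotypes(mk(base[, 1, drop = FALSE], "a"), mk(base, "b")),
    class = "pprcleave_input_error")
})

test_that("per-position t matches the textbook statistic", {
  set.seed(64)
  a <- matrix(rnorm(30, 5), ncol = 3)
  b <- matrix(rnorm(40, 6), ncol = 4)
  mk <- function(values, g) {
    structure(list(values = values, strand = "+", genotype = g,
                   genome_length = nrow(values), smooth_window = 1L,
                   background_window = 101L, pseudocount = 0.5),
              class = "normalized_profile")
  }
  pc <- compare_genotypes(mk(a, "a"), mk(b, "b"), floor = 0)
  pc <- pc[order(pc$coord), ]
  for (i in seq_len(10)) {
    # oracle computes a (b vs a) statistic from first principles
    expect_equal(pc$t[i], -oracle_t_equal_var(a[i, ], b[i, ]),
                 tolerance = 1e-12)
    tt <- t.test(b[i, ], a[i, ], var.equal = TRUE)
    expect_equal(pc$p[i], tt$p.value, tolerance = 1e-12)
  }
})

test_that("cleavage-site detection ranks the gained peak first", {
  # low-dispersion fixture isolates the ranking logic from replicate noise
  tr <- simulate_genome(sim_config(seed = 71, dispersion = 0.01))
  ec <- simulate_end_counts(tr, seed = 72)
  na <- smooth_normalize(ec$wt, smooth_window = 1)
  nb <- smooth_normalize(ec$mutant, smooth_window = 1)
  sites <- call_cleavage_sites(compare_genotypes(na, nb))
  expect_gt(nrow(sites), 0)
  expect_equal(sites$coord[1], tr$boundary$genome_downstream)
})
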