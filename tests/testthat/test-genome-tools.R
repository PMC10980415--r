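test_that("transcript models enforce their invariants", {
  m <- transcript_model("g", "+", 101, 160, utr5 = 10, utr3 = 5)
  expect_equal(m$cds_length, 60)
  expect_equal(m$tx_length, 75)
  expect_equal(m$tx_start, 91)
  expect_equal(m$tx_end, 165)
  r <- transcript_model("g", "-", 260, 201, utr5 = 7, utr3 = 12)
  expect_equal(r$tx_start, 267)
  expect_equal(r$tx_end, 189)
  expect_error(transcript_model("g", "+", 160, 101),
               class = "pprcleave_input_error")
  expect_error(transcript_model("g", "-", 201, 260),
               class = "pprcleave_input_error")
  expect_error(
    transcript_model("g", "+", 101, 160,
                     introns = data.frame(start = 300, end = 320)),
    class = "pprcleave_input_error")
})

test_that("CDS coordinate mapping matches the strand arithmetic", {
  # reverse-strand gene with its CDS 5' end at 68621: position +1330 falls on
  # 67292, and the last codon base (1524) on 67098
  atp1 <- transcript_model("atp1", "-", 68621, 67098, utr5 = 363, utr3 = 157)
  expect_equal(cds_to_genome(atp1, 1330), 67292)
  expect_equal(cds_to_genome(atp1, 1524), 67098)
  expect_equal(cds_to_genome(atp1, 1), 68621)
  expect_equal(genome_to_cds(atp1, 67292), 1330)
  fwd <- transcript_model("f", "+", 1000, 1999)
  expect_equal(cds_to_genome(fwd, 1), 1000)
  expect_equal(cds_to_genome(fwd, 500), 1499)
  expect_error(cds_to_genome(fwd, 0), class = "pprcleave_input_error")
  expect_error(cds_to_genome(fwd, 1001), class = "pprcleave_input_error")
  expect_error(genome_to_cds(fwd, 999), class = "pprcleave_input_error")
})

test_that("genome<->CDS round trip holds exhaustively on toy models", {
  for (m in toy_models()) {
    p <- seq_len(m$cds_length)
    expect_identical(genome_to_cds(m, cds_to_genome(m, p)), p)
    coords <- if (m$strand == "+") m$cds_start:m$cds_end else
      m$cds_start:m$cds_end
    expect_identical(cds_to_genome(m, genome_to_cds(m, coords)),
                     as.integer(coords))
  }
})

test_that("fuzzy_scan finds literal and strand-specific matches", {
  hits <- fuzzy_scan("TTTTAAAATTTT", "AAAA", 0, both_strands = FALSE)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 5)
  expect_equal(hits$end, 8)
  # reverse complement of AAAA is TTTT, absent from genome AAAA
  hits2 <- fuzzy_scan("AAAA", "AAAA", 0, both_strands = TRUE)
  expect_equal(nrow(hits2), 1)
  expect_equal(hits2$strand, "+")
  # IUPAC degeneracy matches its base set at zero cost
  hits3 <- fuzzy_scan("ACGTACGT", "ANGT", 0, both_strands = FALSE)
  expect_equal(hits3$start, c(1, 5))
  expect_error(fuzzy_scan("ACGJ", "ACG", 0), class = "pprcleave_input_error")
})

test_that("fuzzy_scan equals the brute-force Hamming oracle", {
  set.seed(101)
  for (rep in 1:25) {
    g <- random_genome_string(500)
    q <- random_genome_string(16)
    k <- sample(0:5, 1)
    got <- fuzzy_scan(g, q, k, both_strands = TRUE)
    want <- oracle_scan(g, q, k, both_strands = TRUE)
    got_key <- sort(paste(got$start, got$strand, got$mismatches))
    want_key <- sort(paste(want$start, want$strand, want$mismatches))
    expect_identical(got_key, want_key)
  }
})

test_that("fuzzy_scan hits are monotone in the mismatch budget", {
  set.seed(5)
  g <- random_genome_string(800)
  q <- random_genome_string(12)
  prev <- character(0)
  for (k in 0:4) {
    hits <- fuzzy_scan(g, q, k)
    key <- paste(hits$start, hits$strand)
    expect_true(all(prev %in% key))
    expect_true(all(hits$mismatches <= k))
    prev <- key
  }
})

test_that("circular scanning admits wrapped windows only when flagged", {
  g <- "CGTAAAATTTTAC"  # ...TAC + CGT... wraps into TACCGT
  expect_equal(nrow(fuzzy_scan(g, "TACCGT", 0, both_strands = FALSE)), 0)
  hits <- fuzzy_scan(g, "TACCGT", 0, both_strands = FALSE, circular = TRUE)
  expect_equal(hits$start, 11)
  expect_equal(hits$end, 3)
})

test_that("fragment sizes follow the cut position and always conserve length", {
  toy <- transcript_model("t", "+", 11, 90, utr5 = 10, utr3 = 10)
  expect_equal(unname(predict_fragments(toy, 40)), c(50, 50))
  set.seed(3)
  for (rep in 1:20) {
    utr5 <- sample(0:50, 1); utr3 <- sample(0:50, 1)
    cds <- sample(10:500, 1)
    m <- transcript_model("m", "-", 1000 + cds, 1001, utr5 = utr5, utr3 = utr3)
    cut <- sample(cds - 1, 1)
    fr <- predict_fragments(m, cut)
    expect_equal(sum(fr), m$tx_length)
  }
  expect_error(predict_fragments(toy, 80), class = "pprcleave_input_error")
  expect_error(predict_fragments(toy, 0), class = "pprcleave_input_error")
})

test_that("probe placement is reported in transcript frame on both strands", {
  # reverse-strand gene: transcript 5' is the high genome coordinate
  m <- transcript_model("g", "-", 900, 501, utr5 = 50, utr3 = 50)
  site <- c(700, 716)
  expect_identical(probe_side(m, c(800, 780), site), "upstream_5prime")
  expect_identical(probe_side(m, c(600, 580), site), "downstream_3prime")
  expect_identical(probe_side(m, c(720, 710), site), "overlapping")
  f <- transcript_model("g", "+", 501, 900, utr5 = 50, utr3 = 50)
  expect_identical(probe_side(f, c(580, 600), site), "upstream_5prime")
  expect_identical(probe_side(f, c(780, 800), site), "downstream_3prime")
  expect_error(probe_side(m, c(2000, 2010), site),
               class = "pprcleave_input_error")
})
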