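test_that("classify_pair looks up stored classes and defaults to neutral", {
  code <- toy_code()
  expect_identical(classify_pair(c("T", "D"), "G", code), "perfect")
  expect_identical(classify_pair("TD", "A", code), "partial")
  expect_identical(classify_pair("TD", "C", code), "mismatch")
  # U/T interchangeable on input
  expect_identical(classify_pair("ND", "T", code), "perfect")
  # unknown residue pair is the non-committal class
  expect_identical(classify_pair(c("X", "X"), "A", code), "neutral")
  expect_identical(classify_pair("QQ", "G", code), "neutral")
  expect_error(classify_pair("TD", "Z", code), class = "pprcleave_input_error")
})

test_that("code tables validate their entries", {
  expect_error(ppr_code(list(TD = c(A = "perfect"))),
               class = "pprcleave_input_error")
  expect_error(ppr_code(list(TD = c(A = "good", C = "bad", G = "x", U = "y"))),
               class = "pprcleave_input_error")
  expect_error(ppr_code(list(c(A = "perfect"))),
               class = "pprcleave_input_error")
})

test_that("predict_binding conserves positions and counts", {
  code <- toy_code()
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(4:20, 1)
    prot <- random_toy_scaffold(n, include_unknown = TRUE)
    target <- random_rna(n)
    bp <- predict_binding(prot, target, code)
    expect_equal(nrow(bp$per_position), n)
    expect_equal(sum(bp$counts), n)
    expect_identical(bp$per_position$class, brute_classes(prot, target, code))
  }
  # homogeneous table: every pairing perfect
  allg <- ppr_code(list(TD = c(A = "perfect", C = "perfect", G = "perfect",
                               U = "perfect")))
  prot <- ppr_protein("p", data.frame(index = 1:16, res1 = "T", res2 = "D"))
  bp <- predict_binding(prot, random_rna(16), allg)
  expect_equal(unname(bp$counts["perfect"]), 16)
  expect_equal(bp$score, 32)
})

test_that("predict_binding rejects length mismatches, naming both lengths", {
  prot <- ppr_protein("p", data.frame(index = 1:16, res1 = "T", res2 = "D"))
  err <- expect_error(predict_binding(prot, random_rna(15), toy_code()),
                      class = "pprcleave_input_error")
  expect_match(conditionMessage(err), "15")
  expect_match(conditionMessage(err), "16")
})

test_that("predict_binding is position-local", {
  code <- toy_code()
  set.seed(7)
  prot <- random_toy_scaffold(12)
  target <- strsplit(random_rna(12), "")[[1]]
  base_cls <- predict_binding(prot, paste(target, collapse = ""), code)
  for (i in c(1, 6, 12)) {
    for (b in setdiff(c("A", "C", "G", "U"), target[i])) {
      mut <- target
      mut[i] <- b
      cls <- predict_binding(prot, paste(mut, collapse = ""), code)
      expect_identical(cls$per_position$class[-i],
                       base_cls$per_position$class[-i])
    }
  }
})

test_that("redesign fixes mismatches, is local, minimal and idempotent", {
  code <- toy_code()
  # fixed point: already perfect everywhere
  prot <- ppr_protein("p", data.frame(
    index = 1:4, res1 = c("T", "T", "N", "N"), res2 = c("D", "N", "D", "S")))
  target <- "GAUC"
  rd <- redesign(prot, target, code)
  expect_equal(nrow(rd$changes), 0)
  expect_identical(rd$protein$motifs, prot$motifs)
  expect_identical(rd$predicted_post$per_position,
                   predict_binding(prot, target, code)$per_position)

  # single mismatched motif -> exactly one change at that index
  rd1 <- redesign(prot, "GGUC", code)  # position 2: TN vs G = partial, not fixed
  expect_equal(nrow(rd1$changes), 0)
  rd2 <- redesign(prot, "GCUC", code)  # position 2: TN vs C = mismatch
  expect_equal(rd2$changes$index, 2L)
  expect_equal(unname(rd2$predicted_post$counts["mismatch"]), 0)

  # idempotence: redesigning the redesigned protein changes nothing
  rd3 <- redesign(rd2$protein, "GCUC", code)
  expect_equal(nrow(rd3$changes), 0)
  rds <- redesign(prot, "GCUC", code, strict = TRUE)
  expect_equal(nrow(redesign(rds$protein, "GCUC", code, strict = TRUE)$changes), 0)
})

test_that("redesign errors when no perfect pair exists for a base", {
  code <- ppr_code(list(
    TD = c(A = "partial", C = "mismatch", G = "perfect", U = "mismatch")))
  prot <- ppr_protein("p", data.frame(index = 1:2, res1 = "T", res2 = "D"))
  expect_error(redesign(prot, "GC", code),
               class = "pprcleave_design_infeasible")
})

test_that("strict redesign change-count equals brute-force non-perfect count", {
  code <- toy_code()
  set.seed(11)
  prot <- random_toy_scaffold(6, include_unknown = TRUE)
  bases <- c("A", "C", "G", "U")
  grid <- expand.grid(bases, bases, bases, bases, bases, bases,
                      stringsAsFactors = FALSE)
  # spot-check the full enumeration cheaply here; the acceptance suite runs
  # the complete 4^6 sweep
  for (i in sample(nrow(grid), 200)) {
    target <- paste(unlist(grid[i, ]), collapse = "")
    expected <- sum(brute_classes(prot, target, code) != "perfect")
    rd <- redesign(prot, target, code, strict = TRUE)
    expect_equal(nrow(rd$changes), expected)
    expect_true(all(rd$predicted_post$per_position$class[rd$changes$index] ==
                      "perfect"))
  }
})

test_that("motif tables round-trip through TSV and validate", {
  sc <- read_motif_table(system.file("extdata", "synthetic_scaffold_motifs.tsv",
                                     package = "pprcleave"))
  expect_s3_class(sc, "ppr_protein")
  expect_length(sc, 16)
  # the shipped synthetic scaffold is perfect for its documented target
  bp <- predict_binding(sc, "GAAUCCGUAUGGCAUC", default_ppr_code())
  expect_equal(unname(bp$counts["perfect"]), 16)
  expect_error(ppr_protein("x", data.frame(index = c(1, 3), res1 = "T",
                                           res2 = "D")),
               class = "pprcleave_input_error")
  expect_error(ppr_protein("x", data.frame(index = 1, res1 = "Z", res2 = "D")),
               class = "pprcleave_input_error")
})
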