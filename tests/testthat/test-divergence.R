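test_that("global affine alignment reproduces known scores", {
  ali <- global_align_affine("AAW", "AW")
  expect_equal(ali$score, 7)                      # 4 + 11 - 8
  expect_equal(nchar(ali$aligned_a), nchar(ali$aligned_b))
  expect_identical(gsub("-", "", ali$aligned_b), "AW")
  ident <- global_align_affine("MKWVD", "MKWVD")
  expect_false(grepl("-", ident$aligned_a))
  expect_equal(ident$score, sum(diag(blosum62[c("M", "K", "W", "V", "D"),
                                              c("M", "K", "W", "V", "D")])))
  gap1 <- global_align_affine("A", "")
  expect_equal(gap1$score, -8)
  expect_error(global_align_affine("AJ7", "AW"), "invalid residue")
})

test_that("alignment scores equal the brute-force enumeration optimum", {
  set.seed(42)
  alphabet <- c("A", "C", "D", "E")
  for (i in 1:25) {
    a <- paste(sample(alphabet, sample(1:6, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alphabet, sample(1:6, 1), replace = TRUE), collapse = "")
    got <- global_align_affine(a, b)$score
    want <- brute_force_align_score(a, b, blosum62)
    expect_equal(got, want, info = paste(a, b))
  }
})

test_that("column scores implement the affine gap-run convention", {
  ali <- hv_alignment("MKAAAW", "MK---W")
  cs <- column_scores(ali)
  expect_equal(cs$score, c(blosum62["M", "M"], blosum62["K", "K"], -8, -1, -1,
                           blosum62["W", "W"]))
  expect_identical(cs$gap_state, c("none", "none", "open", "extend", "extend", "none"))
  ## consistency identity: total alignment score is the sum of column scores
  set.seed(1)
  for (i in 1:10) {
    a <- paste(sample(rownames(blosum62)[1:20], 8, replace = TRUE), collapse = "")
    b <- paste(sample(rownames(blosum62)[1:20], 6, replace = TRUE), collapse = "")
    ali2 <- global_align_affine(a, b)
    expect_equal(sum(column_scores(ali2)$score), ali2$score)
  }
  expect_error(hv_alignment("A-W", "A-W"), "gaps in both rows")
  ## random columns equal independent table lookup
  set.seed(2)
  aa <- sample(rownames(blosum62)[1:20], 10, replace = TRUE)
  bb <- sample(rownames(blosum62)[1:20], 10, replace = TRUE)
  cs3 <- column_scores(hv_alignment(paste(aa, collapse = ""), paste(bb, collapse = "")))
  expect_equal(cs3$score, blosum62[cbind(aa, bb)], ignore_attr = TRUE)
})

test_that("divergence scale normalizes, smooths, and stays in [0, 1]", {
  ## constant similarity: degenerate scale of zeros
  const <- hv_alignment(strrep("A", 20), strrep("A", 20))
  expect_identical(as.numeric(divergence_scale(column_scores(const))), rep(0, 20))
  ## window 1 is identity smoothing: impulse stays a single-residue peak
  aa <- strrep("A", 11)
  bb <- paste0(strrep("A", 5), "W", strrep("A", 5))
  cs <- column_scores(hv_alignment(aa, bb))
  raw <- divergence_scale(cs, window = 1)
  expect_equal(as.integer(which(raw == 1)), 6L)
  expect_equal(sum(raw > 0), 1)
  ## window 5 spreads the impulse over a five-residue plateau of maxima
  sm <- divergence_scale(cs, window = 5)
  expect_equal(as.integer(which(sm == max(sm))), 4:8)
  expect_equal(sum(sm > 1e-12), 5)
  d <- mean(cs$score) - cs$score
  hand <- sapply(1:11, function(i) {
    h <- min(2, i - 1, 11 - i)
    mean(d[(i - h):(i + h)])
  })
  hand <- (hand - min(hand)) / diff(range(hand))
  expect_equal(as.numeric(sm), hand)
  expect_error(divergence_scale(cs, window = 4), "odd")
})

test_that("divergence scale properties hold on random alignments", {
  set.seed(9)
  for (i in 1:10) {
    aa <- sample(rownames(blosum62)[1:20], 30, replace = TRUE)
    bb <- aa
    flip <- sample(30, 8)
    bb[flip] <- sample(rownames(blosum62)[1:20], 8, replace = TRUE)
    cs <- column_scores(hv_alignment(paste(aa, collapse = ""), paste(bb, collapse = "")))
    sc <- divergence_scale(cs, window = 5)
    raw <- divergence_scale(cs, window = 1)
    if (length(unique(cs$score)) > 1) {
      expect_equal(min(sc), 0)
      expect_equal(max(sc), 1)
    }
    ## smoothing is a contraction of the unsmoothed deviation profile
    d <- mean(cs$score) - cs$score
    sm_d <- divergence_scale(cs, window = 5, smooth_first = FALSE)
    expect_gte(min(sm_d), min(raw) - 1e-12)
    expect_lte(max(sm_d), max(raw) + 1e-12)
  }
})

test_that("gap-in-reference columns fold into the flanking residue", {
  ## reference row a has 4 residues; the b-row insertion penalties attach to
  ## the preceding reference residue
  ali <- hv_alignment("AC--DE", "ACWWDE")
  cs <- column_scores(ali)
  sc <- divergence_scale(cs, reference = "a", window = 1)
  expect_length(sc, 4)
  w2 <- blosum62["C", "C"] - 8 - 1       # residue 2 absorbs the gap run
  w_exp <- c(blosum62["A", "A"], w2, blosum62["D", "D"], blosum62["E", "E"])
  d <- mean(w_exp) - w_exp
  expect_equal(as.numeric(sc), (d - min(d)) / diff(range(d)))
})

test_that("percent identity and substitution counts follow their conventions", {
  expect_equal(percent_identity(global_align_affine("MKWVD", "MKWVD")), 100)
  expect_equal(percent_identity(hv_alignment("AAAA", "AATT")), 50)
  ## symmetry
  a <- "MKWVDAAE"; b <- "MKYVDAE"
  expect_equal(percent_identity(global_align_affine(a, b)),
               percent_identity(global_align_affine(b, a)))
  expect_identical(as.integer(count_substitutions(a, b)),
                   as.integer(count_substitutions(b, a)))
  ## denominators
  ali <- global_align_affine("AAW", "AW")
  expect_equal(percent_identity(ali, "alignment"), 100 * 2 / 3)
  expect_equal(percent_identity(ali, "shorter"), 100)
  expect_equal(percent_identity(ali, "gapless"), 100)
  ## substitution counting
  expect_equal(as.integer(count_substitutions("MKWVD", "MKWVD")), 0L)
  expect_equal(as.integer(count_substitutions("MKWVD", "MKYVD")), 1L)
  one_gap <- count_substitutions("MKWVD", "MKWD")
  expect_identical(attr(one_gap, "gaps"), 1L)
})

test_that("divergence scales map onto PDB B-factors and round-trip", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(hvgating:::.synthetic_pdb_lines(), pdb)
  scale <- seq(0, 1, length.out = 10)
  out <- tempfile(fileext = ".pdb")
  res <- map_scale_to_structure(scale, pdb, chain = "A", out_file = out)
  expect_identical(as.integer(attr(res, "matched")), 1:10)
  b <- read_bfactors(out, chain = "A")
  expect_equal(unname(b), round(100 * scale, 2))
  expect_error(map_scale_to_structure(scale, pdb, chain = "B", out_file = out),
               "absent")
  expect_error(map_scale_to_structure(scale, pdb, chain = "A",
                                      numbering_offset = 500, out_file = out),
               "no residues matched")
})
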