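cfg <- default_motif_config()

test_that("the packaged config carries the text-anchored motif variants", {
  rnbsd <- cfg$motifs$RNBS_D_RNL
  expect_equal(paste(rnbsd$pattern, collapse = ""), "CFLDLGxFP")
  expect_equal(rnbsd$discriminant, c(1L, 4L, 6L))
  qhd <- cfg$motifs$MHD_RNL
  expect_equal(paste(qhd$pattern, collapse = ""), "QHD")
  expect_equal(qhd$discriminant, 1:3)
  expect_equal(paste(cfg$motifs$MHD_CNL2$pattern, collapse = ""), "VHD")
  # CNL2 RNBS-D: conserved cysteine in position 6 after the D in 4
  cnl2 <- cfg$motifs$RNBS_D_CNL2
  expect_equal(cnl2$pattern[4], "D")
  expect_equal(cnl2$pattern[6], "C")
  expect_true(all(c(4L, 6L) %in% cnl2$discriminant))
})

test_that("illegal motif definitions are rejected", {
  expect_error(motif_def("bad", "Q?"), "illegal|length")
  expect_error(motif_def("bad", "Q?LLL"), "illegal")
  expect_error(motif_def("bad", "QHDLL", discriminant = 9), "range")
  expect_error(motif_def("bad", "xhDLL", discriminant = 1), "exact")
  expect_error(motif_def("bad", "QHDLL", subfamily = "RNL"), "discriminant")
})

test_that("scan_motif finds the RNL RNBS-D and honours discriminants", {
  rec <- protein_records("t1", "AACFLDLGAFPKK")
  h <- scan_motif(rec, cfg$motifs$RNBS_D_RNL, max_mismatch = 0)
  expect_equal(h$start, 3L)
  # discriminant violation is never tolerated, whatever the budget
  rec2 <- protein_records("t2", "AACFLDLAAFPKK") # G6 -> A
  for (mm in 0:5) {
    expect_equal(nrow(scan_motif(rec2, cfg$motifs$RNBS_D_RNL,
                                 max_mismatch = mm)), 0L)
  }
  # X matches nothing, even at an 'any' position
  rec3 <- protein_records("t3", "AACFLDLGXFPKK")
  expect_equal(scan_motif(rec3, cfg$motifs$RNBS_D_RNL,
                          max_mismatch = 0)$start, integer(0))
  expect_equal(scan_motif(rec3, cfg$motifs$RNBS_D_RNL,
                          max_mismatch = 1)$start, 3L)
})

test_that("scan_motif equals the exhaustive oracle on random instances", {
  set.seed(42)
  hyd <- cfg$hydrophobic
  for (i in 1:300) {
    seq <- rand_seq(60, c(AA20, "X"))
    syms <- sample(c(AA20, "h", "x"), 6, replace = TRUE,
                   prob = c(rep(1, 20), 6, 6))
    exact_pos <- which(syms %in% AA20)
    disc <- if (length(exact_pos) > 0) {
      exact_pos[sample.int(length(exact_pos),
                           sample(0:min(2, length(exact_pos)), 1))]
    } else integer()
    mm_budget <- sample(0:2, 1)
    m <- motif_def("rand", paste(syms, collapse = ""), disc)
    got <- scan_motif(protein_records("q", seq), m, max_mismatch = mm_budget,
                      hydrophobic = hyd)
    want <- oracle_scan(seq, paste(syms, collapse = ""), disc, hyd, mm_budget)
    expect_equal(got$start, want$start)
    expect_equal(got$mismatches, want$mismatches)
  }
})

test_that("scan_motif is deterministic and monotone in the mismatch budget", {
  set.seed(9)
  seq <- rand_seq(80)
  rec <- protein_records("q", seq)
  m <- cfg$motifs$RNBS_A_CNL
  h1 <- scan_motif(rec, m, max_mismatch = 1)
  expect_identical(h1, scan_motif(rec, m, max_mismatch = 1))
  for (i in 1:20) {
    seqr <- protein_records("q", rand_seq(120))
    h_lo <- scan_motif(seqr, m, max_mismatch = 1)
    h_hi <- scan_motif(seqr, m, max_mismatch = 3)
    expect_true(all(h_lo$start %in% h_hi$start))
  }
})

test_that("locate_nbarc recovers planted signatures and fails cleanly", {
  sp <- synth_proteome(c(CNL = 3, RNL = 3), mutation_rate = 0, seed = 5)
  full <- sp$truth$seq_id[sp$truth$form == "nb_lrr"]
  for (id in full) {
    rec <- sp$records[sp$records$id == id, ]
    sig <- locate_nbarc(rec, cfg)
    want <- sp$truth$category[sp$truth$seq_id == id]
    expect_false(is.null(sig))
    expect_equal(sig$mhd_call, want)
    expect_equal(sig$rnbs_d_call, want)
    expect_lte(sig$anchor_start, sig$anchor_end)
  }
  blank <- protein_records("blank", strrep("A", 50))
  expect_null(locate_nbarc(blank, cfg))
})

test_that("an RNL whose QHD is corrupted loses its RNL MHD call", {
  sp <- synth_proteome(c(RNL = 6), mutation_rate = 0, seed = 5,
                       corrupt_discriminants = "MHD_RNL")
  full <- sp$truth$seq_id[sp$truth$form == "nb_lrr"]
  for (id in full) {
    sig <- locate_nbarc(sp$records[sp$records$id == id, ], cfg)
    if (!is.null(sig)) expect_true(sig$mhd_call != "RNL")
  }
})
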