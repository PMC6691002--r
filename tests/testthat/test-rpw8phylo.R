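test_that("extract_rpw8 applies the strict full-length rule", {
  rec <- protein_records(c("s1", "s2", "s3"),
                         c(rand_seq(200), rand_seq(200), rand_seq(200)))
  hits <- domain_hits(c("s1", "s2", "s3"), rep("RPW8", 3),
                      c(10, 10, 10), c(129, 89, 110)) # 120, 80 and 101 aa
  got <- extract_rpw8(rec, hits, min_length = 100)
  expect_setequal(got$id, c("s1", "s3"))
  expect_equal(got$length[got$id == "s1"], 120L)
  # exactly 100 residues is not "more than 100"
  h100 <- domain_hits("s1", "RPW8", 1, 100)
  expect_equal(nrow(extract_rpw8(rec, h100)), 0L)
})

test_that("planted RPW8 domains are all recovered", {
  sp <- synth_proteome(c(RNL = 12), mutation_rate = 0, seed = 13)
  n_rpw8 <- sum(sp$hits$domain == "RPW8")
  got <- extract_rpw8(sp$records, sp$hits)
  expect_equal(nrow(got), n_rpw8)
  expect_true(all(got$length > 100))
})

test_that("pairwise distances form a proper distance matrix", {
  s <- rand_seq(40, setdiff(AA20, "W"))
  rec <- protein_records(c("a", "b", "c"),
                         c(s, s, strrep("W", 40)))
  d <- pairwise_distances(rec)
  expect_equal(unname(d["a", "b"]), 0)
  expect_equal(unname(d["a", "c"]), 1) # disjoint alphabets
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  set.seed(3)
  rp <- synth_rpw8_set(n_parents = 5, n_members = 20, seed = 3)
  d2 <- pairwise_distances(rp)
  expect_equal(d2, t(d2))
  expect_true(all(d2 >= 0))
})

test_that("neighbor joining matches the 3-leaf closed form", {
  dm <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(dm)
  # (d_AB + d_AC - d_BC) / 2 = 1, etc.
  pat <- cophenetic(tr)[rownames(dm), colnames(dm)]
  expect_equal(pat, dm, tolerance = 1e-12)
  br <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(br[c("A", "B", "C")]), c(1, 1, 3))
  expect_error(nj_tree(dm[1:2, 1:2]), "at least 3")
})

test_that("neighbor joining exactly recovers additive matrices", {
  set.seed(41)
  for (i in 1:40) {
    tr <- ape::rtree(sample(4:8, 1))
    dm <- cophenetic(tr)
    rec <- nj_tree(dm)
    expect_lt(max(abs(cophenetic(rec)[rownames(dm), colnames(dm)] - dm)), 1e-9)
    expect_true(all(rec$edge.length >= 0))
  }
})

test_that("label order does not change the reconstructed tree", {
  set.seed(4)
  tr <- ape::rtree(7)
  dm <- cophenetic(tr)
  perm <- sample(nrow(dm))
  t1 <- nj_tree(dm)
  t2 <- nj_tree(dm[perm, perm])
  expect_equal(cophenetic(t2)[rownames(dm), colnames(dm)],
               cophenetic(t1)[rownames(dm), colnames(dm)],
               tolerance = 1e-9)
})

test_that("negative NJ branches are clamped on non-additive input", {
  set.seed(12)
  n <- 6
  m <- matrix(runif(n * n, 0.2, 1), n, n)
  dm <- (m + t(m)) / 2
  diag(dm) <- 0
  dimnames(dm) <- list(letters[1:n], letters[1:n])
  tr <- nj_tree(dm)
  expect_true(all(tr$edge.length >= 0))
  expect_setequal(tr$tip.label, letters[1:n])
})

test_that("group assignment recovers anchor-derived queries", {
  anchors <- load_rpw8_anchors()
  q <- mutate_records(anchors$records, n_copies = 2, divergence_max = 0.15,
                      seed = 77)
  truth <- anchors$groups[attr(q, "truth")$source]
  for (mode in c("patristic", "nearest_reference")) {
    g <- assign_groups(q, anchors, mode = mode)
    expect_equal(g$group, unname(truth))
    expect_true(all(g$margin > 0))
  }
})

test_that("a query identical to ADR1 lands in group 2 with margin", {
  anchors <- load_rpw8_anchors()
  adr1 <- anchors$records[startsWith(anchors$records$id, "ADR1"), ]
  q <- protein_records("query_adr1", adr1$seq)
  g <- assign_groups(q, anchors, mode = "nearest_reference")
  expect_equal(g$group, "2")
  expect_gt(g$margin, 0)
})

test_that("a query equidistant from two groups is left unassigned", {
  anchors <- load_rpw8_anchors()
  # plant the same sequence as an anchor of group 1 and group 3
  s <- rand_seq(120)
  rec <- protein_records(c("Conifer_G1a", "Conifer_G1b", "ADR1",
                           "Conifer_G3a", "twin_g3", "NRG1", "RPW8.1",
                           "RPW8.2"),
                         c(s, rand_seq(120), rand_seq(120), rand_seq(125),
                           s, rand_seq(130), rand_seq(130), rand_seq(130)),
                         species = "anchor")
  an <- list(records = rec,
             groups = setNames(c("1", "1", "2", "3", "3", "4", "4", "4"),
                               rec$id))
  q <- protein_records("q", s)
  g <- assign_groups(q, an, mode = "nearest_reference")
  expect_equal(g$group, "unassigned")
})

test_that("a missing anchor group is an error", {
  anchors <- load_rpw8_anchors()
  sub <- anchors
  keep <- anchors$groups != "3"
  sub$records <- anchors$records[keep, ]
  sub$groups <- anchors$groups[keep]
  q <- protein_records("q", rand_seq(110))
  expect_error(assign_groups(q, sub), "group")
})

test_that("representative clustering at 0.60 never moves an anchor's group", {
  anchors <- load_rpw8_anchors()
  q <- mutate_records(anchors$records, n_copies = 3, divergence_max = 0.12,
                      seed = 55)
  reps <- greedy_cluster(q, 0.60)
  rep_ids <- vapply(reps, `[[`, "", "representative")
  rep_rec <- q[match(rep_ids, q$id), ]
  class(rep_rec) <- class(q)
  g <- assign_groups(rep_rec, anchors, mode = "nearest_reference")
  truth <- anchors$groups[attr(q, "truth")$source[match(rep_ids, q$id)]]
  expect_equal(g$group, unname(truth))
})
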