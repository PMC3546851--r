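test_that("dyad discovery finds a planted inverted repeat and nothing less", {
  # CTGT = revcomp(ACAG): exactly one clean inverted repeat
  set.seed(1)
  mid <- "GAGTCAGT"
  s <- bioseq(paste0("CTGT", mid, "ACAG"))
  hits <- dyad_motif_discovery(s, dyad_len = 4, spacer = 8, max_mismatch = 0,
                               orientation = "INVERTED")
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$left_start, 1L)
  expect_identical(hits$right_start, 13L)
  expect_identical(hits$mismatches, 0L)
  expect_error(dyad_motif_discovery(s, 3, 1, 8), ">= 3")
  expect_error(dyad_motif_discovery(s, 4, 0, 1, 2), ">= 0")
})

test_that("dyad discovery equals the brute-force double loop", {
  for (seed in 0:9) {
    txt <- random_dna(200, seed = 7000 + seed)
    got <- dyad_motif_discovery(bioseq(txt), dyad_len = 4, d_tol = 1,
                                spacer = 8, s_tol = 1, max_mismatch = 2,
                                orientation = "BOTH")
    want <- oracle_dyad_repeats(txt, 3:5, 7:9, 2, c("DIRECT", "INVERTED"))
    key <- function(d) sort(paste(d$left_start, d$dyad_len, d$spacer,
                                  d$orientation, d$mismatches))
    expect_identical(key(got), key(want))
  }
})

test_that("relaxing max_mismatch only adds dyad hits", {
  txt <- random_dna(300, seed = 8)
  k <- function(d) paste(d$left_start, d$dyad_len, d$spacer, d$orientation)
  h0 <- dyad_motif_discovery(bioseq(txt), 4, 1, 8, 1, 0)
  h2 <- dyad_motif_discovery(bioseq(txt), 4, 1, 8, 1, 2)
  expect_true(all(k(h0) %in% k(h2)))
})

planted_case <- function(seed) {
  generate_planted(n_sequences = 10, length = 100, motif = "TTGACAAT",
                   seed = seed)
}

test_that("gibbs sampling is seed-deterministic and recovers planted sites", {
  pl <- planted_case(123)
  r1 <- gibbs_sample(pl$sequences, 8, iterations = 5, seed = 42)
  r2 <- gibbs_sample(pl$sequences, 8, iterations = 5, seed = 42)
  expect_identical(r1$sites, r2$sites)
  expect_identical(r1$information_content, r2$information_content)
  full <- gibbs_sample(pl$sequences, 8, iterations = 20, seed = 7)
  expect_gte(sum(full$sites$start == pl$truth$position), 9)
  expect_error(gibbs_sample(pl$sequences, 200, 5), "width")
})

test_that("single-sequence gibbs degenerates to one sampled window", {
  s <- seq_collection(bioseq("ACGTACGTAC", id = "only"))
  r <- gibbs_sample(s, 4, iterations = 3, seed = 1)
  expect_identical(nrow(r$sites), 1L)
  expect_identical(r$psfm$n_sites, 1L)
  # a single site is perfectly conserved
  expect_equal(r$information_content, 8)
})

test_that("greedy search is deterministic, monotone in restarts, and exact on twins", {
  pl <- planted_case(321)
  g1 <- greedy_search(pl$sequences, 8, iterations = 10, seed = 5)
  g2 <- greedy_search(pl$sequences, 8, iterations = 10, seed = 5)
  expect_identical(g1$sites, g2$sites)
  expect_gte(sum(g1$sites$start == pl$truth$position), 9)
  # two identical sequences align perfectly: IC = 2w bits
  twin <- seq_collection(bioseq("ACGTACGTTGCA", id = "a"),
                         bioseq("ACGTACGTTGCA", id = "b"))
  tw <- greedy_search(twin, 6, iterations = 3, seed = 1)
  expect_equal(tw$information_content, 12)
  # best-of-restarts is monotone in the number of restarts for one seed stream
  for (seed in 1:5) {
    pl2 <- planted_case(400 + seed)
    ic1 <- greedy_search(pl2$sequences, 8, iterations = 1, seed = seed)
    ic5 <- greedy_search(pl2$sequences, 8, iterations = 5, seed = seed)
    expect_gte(ic5$information_content, ic1$information_content - 1e-12)
    gb1 <- gibbs_sample(pl2$sequences, 8, iterations = 1, inner_steps = 50,
                        seed = seed)
    gb3 <- gibbs_sample(pl2$sequences, 8, iterations = 3, inner_steps = 50,
                        seed = seed)
    expect_gte(gb3$information_content, gb1$information_content - 1e-12)
  }
})

test_that("discovery handles protein collections", {
  pl <- generate_planted(8, 60, "WDAGKVHE", seed = 9)
  expect_identical(pl$sequences[[1]]$alphabet, "PROTEIN")
  res <- greedy_search(pl$sequences, 8, iterations = 20, seed = 3)
  expect_gte(sum(res$sites$start == pl$truth$position), 7)
  expect_equal(res$psfm$alphabet, "PROTEIN")
  # protein logo scale maximum is log2(20)
  logo <- render_consensus_logo(res$psfm)
  expect_equal(logo$max_bits, log2(20))
})

test_that("both-strand discovery recovers motifs planted on mixed strands", {
  pl <- generate_planted(8, 80, "TTGACAAT", strand = "both", seed = 31)
  res <- greedy_search(pl$sequences, 8, iterations = 50, seed = 11,
                       both_strands = TRUE)
  # a motif and its reverse complement are equivalent discoveries: accept the
  # planted spans with strands matching either all as-planted or all flipped
  expect_gte(sum(res$sites$start == pl$truth$position), 7)
  same <- res$sites$strand == pl$truth$strand
  expect_true(mean(same) >= 7 / 8 || mean(!same) >= 7 / 8)
})
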