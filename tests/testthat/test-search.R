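test_that("substring search is IUPAC-aware and exhaustive", {
  hit <- substring_search(bioseq("ACTGTA"), "CTGW", max_mismatch = 0)
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$start, 2L)
  expect_identical(hit$end, 5L)
  expect_identical(hit$mismatches, 0L)

  hits <- substring_search(bioseq("AAATAAA"), "AAAA", max_mismatch = 1)
  expect_identical(hits$start, 1:4)
  expect_true(all(hits$mismatches <= 1))

  expect_error(substring_search(bioseq("ACGT"), "AA", matrix = blosum62()),
               "protein")
})

test_that("matrix-scored protein search sums substitution entries", {
  m <- blosum62()
  hits <- substring_search(bioseq("MKMR", alphabet = "PROTEIN"), "MK",
                           matrix = m, min_matrix_score = 5)
  # window scores: MK=5+5=10, KM=-1-1.. hand summed from the matrix
  hand <- c(m["M", "M"] + m["K", "K"], m["K", "M"] + m["M", "K"],
            m["M", "M"] + m["R", "K"])
  expect_identical(hits$score, hand[hand >= 5])
  expect_identical(hits$start[1], 1L)
})

test_that("substring search equals the brute-force oracle on random inputs", {
  for (seed in 0:9) {
    txt <- random_dna(500, seed = 3000 + seed)
    set.seed(seed)
    pat <- paste(sample(c("A", "C", "G", "T", "R", "N"), 6, TRUE), collapse = "")
    mm <- sample(0:2, 1)
    got <- substring_search(bioseq(txt), pat, max_mismatch = mm)
    want <- oracle_substring_hits(txt, pat, mm)
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
    } else {
      expect_identical(got$start, as.integer(want[, "start"]))
      expect_identical(got$mismatches, as.integer(want[, "mm"]))
    }
  }
})

test_that("hit sets are monotone in max_mismatch and symmetric across strands", {
  txt <- random_dna(400, seed = 50)
  s <- bioseq(txt, id = "g")
  pat <- "CTGTAG"
  h0 <- substring_search(s, pat, max_mismatch = 0, strands = "BOTH")
  h2 <- substring_search(s, pat, max_mismatch = 2, strands = "BOTH")
  key <- function(h) paste(h$start, h$strand)
  expect_true(all(key(h0) %in% key(h2)))
  # strand symmetry: hits on the reverse complement mirror the originals
  rc <- reverse_complement(s)
  h_rc <- substring_search(rc, pat, max_mismatch = 2, strands = "BOTH")
  L <- nchar(txt)
  reflected <- paste(L - h_rc$end + 1, ifelse(h_rc$strand == "+", "-", "+"))
  expect_setequal(key(h2), reflected)
})

test_that("gapped search matches its oracle and the planted dyad", {
  set.seed(60)
  flank1 <- random_dna(20, 61)
  flank2 <- random_dna(20, 62)
  spacer <- "GGGGGGGG"
  s <- bioseq(paste0(flank1, "CTGT", spacer, "ACAG", flank2))
  hits <- gapped_search(s, "CTGW", "WCAG", max_mismatch = 0,
                        spacer_min = 6, spacer_max = 10)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$left_start, 21L)
  expect_identical(hits$spacer, 8L)
  expect_identical(hits$score, 0)
  expect_identical(hits$right_start, hits$left_end + hits$spacer + 1L)

  for (seed in 0:9) {
    txt <- random_dna(300, seed = 4000 + seed)
    got <- gapped_search(bioseq(txt), "CTGW", "WCAG", max_mismatch = 2,
                         spacer_min = 6, spacer_max = 10)
    want <- oracle_gapped_hits(txt, "CTGW", "WCAG", 2, 6, 10)
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
    } else {
      ord <- order(want[, "left_start"], want[, "spacer"])
      expect_identical(got$left_start, as.integer(want[ord, "left_start"]))
      expect_identical(got$spacer, as.integer(want[ord, "spacer"]))
      expect_identical(got$score, as.numeric(want[ord, "mm"]))
    }
    expect_true(all(got$right_start == got$left_end + got$spacer + 1))
  }
})

test_that("a fixed spacer reduces gapped search to a concatenated pattern", {
  txt <- random_dna(600, seed = 71)
  k <- 5
  g <- gapped_search(bioseq(txt), "CTGT", "ACAG", max_mismatch = 1,
                     spacer_min = k, spacer_max = k)
  ss <- substring_search(bioseq(txt), paste0("CTGT", strrep("N", k), "ACAG"),
                         max_mismatch = 1)
  expect_identical(g$left_start, ss$start)
  expect_identical(g$score, ss$score)
})

test_that("Ri scoring: conserved consensus scores 2w, uniform columns 0", {
  cons <- psfm_from_consensus("TTGACA")
  expect_identical(score_site_ri(cons, "TTGACA", "MUTUAL_INFO_RI"), 12)
  expect_identical(score_site_ri(psfm_from_consensus("N"), "A",
                                 "MUTUAL_INFO_RI"), 0)
  # zero frequency yields -Inf, not an error
  expect_identical(score_site_ri(cons, "AACAGT", "MUTUAL_INFO_RI"), -Inf)
  expect_error(score_site_ri(cons, "TTGAC"), "width")
})

test_that("probability-weighted mean Ri equals the total information content", {
  # exhaustive enumeration over all 4^w windows at small w
  set.seed(80)
  sites <- seq_collection(lapply(1:6, function(i)
    bioseq(paste(sample(c("A", "C", "G", "T"), 4, TRUE), collapse = ""),
           id = paste0("s", i))))
  p <- psfm_from_sites(sites, pseudocount = 1)
  wins <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), p$width))
  total <- 0
  for (r in seq_len(nrow(wins))) {
    win <- paste(unlist(wins[r, ]), collapse = "")
    prob <- prod(p$matrix[cbind(match(unlist(wins[r, ]), p$letters),
                                seq_len(p$width))])
    total <- total + prob * score_site_ri(p, win, "REL_ENTROPY_RI")
  }
  expect_equal(total, information_content(p, "REL_ENTROPY")$total,
               tolerance = 1e-9)
})

test_that("site scans agree with brute-force window scoring", {
  p <- psfm_from_consensus("TTGACAWT", pseudocount = 1)
  for (seed in 0:9) {
    txt <- random_dna(500, seed = 5000 + seed)
    got <- site_search(bioseq(txt), p, threshold_bits = 4)
    want <- oracle_site_hits(txt, p$matrix, p$letters, 4)
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
    } else {
      expect_identical(got$start, as.integer(want[, "start"]))
      expect_equal(got$score, unname(want[, "score"]), tolerance = 1e-9)
    }
  }
  # consensus window of a conserved PSFM is found with maximal score
  cons <- psfm_from_consensus("TTGACA")
  hit <- site_search(bioseq(paste0(random_dna(30, 1), "TTGACA",
                                   random_dna(30, 2))), cons, 0)
  expect_identical(hit$start[which.max(hit$score)], 31L)
  expect_equal(max(hit$score), 12)
  expect_warning(site_search(bioseq("ACGTACGT"), cons, threshold_bits = 99),
                 "maximum")
})

test_that("palindromic PSFMs hit both strands at the same positions", {
  p <- psfm_from_consensus("ACGCGT", pseudocount = 0.5)   # revcomp-symmetric
  txt <- random_dna(400, seed = 91)
  hits <- site_search(bioseq(txt), p, threshold_bits = 3, strands = "BOTH")
  expect_setequal(hits$start[hits$strand == "+"], hits$start[hits$strand == "-"])
})

test_that("dyad pattern search finds planted repeats and matches brute force", {
  half <- "CTGT"
  s <- bioseq(paste0(random_dna(25, 95), "CTGT", random_dna(8, 96), "ACAG",
                     random_dna(25, 97)))
  hits <- dyad_pattern_search(s, half, spacer_min = 6, spacer_max = 10,
                              orientation = "INVERTED", threshold_bits = 8)
  top <- hits[which.max(hits$score), ]
  expect_identical(top$left_start, 26L)
  expect_identical(top$spacer, 8L)
  expect_equal(top$left_score, top$right_score)
  expect_equal(top$score, 2 * top$left_score)
  expect_identical(top$right_start, top$left_end + top$spacer + 1L)

  p <- psfm_from_consensus(half, pseudocount = 1)
  tabp <- p$matrix
  for (seed in 0:9) {
    txt <- random_dna(300, seed = 6000 + seed)
    for (ori in c("DIRECT", "INVERTED")) {
      got <- dyad_pattern_search(bioseq(txt), p, spacer_min = 5, spacer_max = 9,
                                 orientation = ori, threshold_bits = 6)
      # oracle: score left window + (rev-complemented) right window
      L <- nchar(txt); w <- 4
      want <- list()
      for (i in seq_len(L)) {
        for (sp in 5:9) {
          j <- i + w + sp
          if (j + w - 1 > L) next
          lsc <- oracle_ri(tabp, p$letters, substr(txt, i, i + w - 1))
          rwin <- substr(txt, j, j + w - 1)
          if (ori == "INVERTED") rwin <- oracle_revcomp(rwin)
          rsc <- oracle_ri(tabp, p$letters, rwin)
          if (lsc + rsc >= 6) {
            want[[length(want) + 1]] <- c(i, sp, lsc + rsc)
          }
        }
      }
      if (!length(want)) {
        expect_identical(nrow(got), 0L)
      } else {
        wm <- do.call(rbind, want)
        ord <- order(wm[, 1], wm[, 2])
        expect_identical(got$left_start, as.integer(wm[ord, 1]))
        expect_equal(got$score, unname(wm[ord, 3]), tolerance = 1e-9)
      }
    }
  }
})

test_that("orientation is honoured: DIRECT does not report inverted plantings", {
  half <- "CCGTA"   # asymmetric half-site
  s <- bioseq(paste0(strrep("T", 20), half, strrep("G", 7),
                     oracle_revcomp(half), strrep("T", 20)))
  inv <- dyad_pattern_search(s, half, 7, 7, "INVERTED", threshold_bits = 13)
  dir <- dyad_pattern_search(s, half, 7, 7, "DIRECT", threshold_bits = 13)
  expect_identical(inv$left_start, 21L)
  expect_identical(nrow(dir), 0L)
})

test_that("hits export to TSV, BED and annotated FASTA", {
  s <- bioseq("ACTGTACTGT", id = "g")
  hits <- substring_search(s, "CTGT")
  tsv <- hits_tsv(hits)
  expect_match(tsv, "^sequence_id\tstart\tend")
  expect_match(tsv, "g\t2\t5")
  bed <- hits_bed(hits)
  expect_match(bed, "^g\t1\t5\thit1")
  fa <- annotate_hits_fasta(s, hits)
  expect_match(fa, "aCTGTaCTGT", fixed = TRUE)
  expect_match(fa, ">g")
})
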