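test_that("frame-dependent translation follows the standard code", {
  expect_identical(seq_text(translate_frame(bioseq("ATGAAATAA"), 1)), "MK*")
  expect_identical(seq_text(translate_frame(bioseq("AATGAAATAA"), 2)), "MK*")
  # ambiguity resolved when all expansions agree, X otherwise
  expect_identical(seq_text(translate_frame(bioseq("GCN", alphabet = "NUCLEIC"))), "A")
  expect_identical(seq_text(translate_frame(bioseq("ATN", alphabet = "NUCLEIC"))), "X")
  # trailing partial codon dropped
  expect_identical(seq_text(translate_frame(bioseq("ATGAA"), 1)), "M")
  expect_error(translate_frame(bioseq("MKLWPERS")), "PROTEIN")
})

test_that("NCBI-style code text parses and matches the built-in standard code", {
  txt <- paste(
    "  AAs  = FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
    "Starts = ---M---------------M---------------M----------------------------",
    "Base1  = TTTTTTTTTTTTTTTTCCCCCCCCCCCCCCCCAAAAAAAAAAAAAAAAGGGGGGGGGGGGGGGG",
    "Base2  = TTTTCCCCAAAAGGGGTTTTCCCCAAAAGGGGTTTTCCCCAAAAGGGGTTTTCCCCAAAAGGGG",
    "Base3  = TCAGTCAGTCAGTCAGTCAGTCAGTCAGTCAGTCAGTCAGTCAGTCAGTCAGTCAGTCAGTCAG",
    sep = "\n")
  gc <- parse_genetic_code(txt)
  std <- standard_genetic_code()
  expect_identical(gc$codon_to_aa, std$codon_to_aa)
  expect_true("ATG" %in% gc$start_codons)
})

test_that("translation maps align residues under codon middle bases", {
  map <- translation_map(bioseq("ATGAAA", id = "t"), frames = 1, line_width = 60)
  lines <- strsplit(map, "\n")[[1]]
  dna_line <- grep("^\\s*1 ", lines, value = TRUE)
  aa_line <- grep("^\\s*\\+1 ", lines, value = TRUE)
  expect_identical(substring(dna_line, 11), "ATGAAA")
  # M under the T (position 2), K under the middle A (position 5)
  expect_identical(substr(aa_line, 12, 12), "M")
  expect_identical(substr(aa_line, 15, 15), "K")
  # frame line lengths: floor((L - f + 1) / 3) residues
  map3 <- translation_map(bioseq("ATGAAATAG"), frames = 1:3)
  got <- strsplit(map3, "\n")[[1]]
  n_res <- vapply(grep("^\\s*\\+[123] ", got, value = TRUE), function(l)
    sum(strsplit(substring(l, 11), "")[[1]] != " "), 0L)
  expect_identical(unname(n_res), c(3L, 2L, 2L))
  expect_error(translation_map(bioseq("ATGAAA"), frames = integer()), "frame")
})

test_that("a translation map can be stripped back to its DNA", {
  set.seed(5)
  dna <- paste(sample(c("A", "C", "G", "T"), 145, TRUE), collapse = "")
  map <- translation_map(bioseq(dna), frames = c(1, 2, 3, -1, -2, -3),
                         line_width = 60)
  lines <- strsplit(map, "\n")[[1]]
  dna_lines <- grep("^\\s*[0-9]+ ", lines, value = TRUE)
  expect_identical(paste(substring(dna_lines, 11), collapse = ""), dna)
})

test_that("uniform reverse translation emits minimal IUPAC covers", {
  expect_identical(seq_text(reverse_translate_uniform(bioseq("M", alphabet = "PROTEIN"))), "ATG")
  expect_identical(seq_text(reverse_translate_uniform(bioseq("K", alphabet = "PROTEIN"))), "AAR")
  # leucine has no exact single-codon cover; minimal cover is YTN
  l <- reverse_translate_uniform(bioseq("L", alphabet = "PROTEIN"))
  expect_identical(seq_text(l), "YTN")
  expect_false(attr(l, "exact"))
  expect_error(reverse_translate_uniform(bioseq("M-K", alphabet = "PROTEIN")), "'-'")
})

test_that("emitted covers are supersets and minimal among all IUPAC codons", {
  # brute force over all 15^3 IUPAC codons for a few residue classes
  code <- standard_genetic_code()
  iub <- names(seqsuite:::IUB_EXPANSION)
  all_iub_codons <- expand.grid(iub, iub, iub, stringsAsFactors = FALSE)
  expand_codon <- function(cod) {
    parts <- lapply(strsplit(cod, "")[[1]], function(ch) ORACLE_IUB[[ch]])
    apply(expand.grid(parts, stringsAsFactors = FALSE), 1, paste, collapse = "")
  }
  for (aa in c("L", "R", "S", "A", "K", "M", "W")) {
    target <- names(code$codon_to_aa)[code$codon_to_aa == aa]
    emitted <- seq_text(reverse_translate_uniform(
      bioseq(aa, alphabet = "PROTEIN")))
    em_exp <- expand_codon(emitted)
    expect_true(all(target %in% em_exp))          # cover
    # no IUPAC codon covering the set expands to fewer codons
    sizes <- apply(all_iub_codons, 1, function(row) {
      cod <- paste(row, collapse = "")
      ex <- expand_codon(cod)
      if (all(target %in% ex)) length(ex) else NA_integer_
    })
    expect_identical(length(em_exp), as.integer(min(sizes, na.rm = TRUE)))
  }
})

test_that("codon-usage reverse translation inverts translation exactly", {
  usage <- parse_codon_usage_gcg(synthetic_usage_text())
  expect_identical(
    seq_text(reverse_translate_usage(
      bioseq("K", alphabet = "PROTEIN"),
      parse_codon_usage_gcg("Lys AAA 75 37.5 0.75\nLys AAG 25 12.5 0.25"),
      "MOST_FREQUENT")),
    "AAA")
  set.seed(8)
  for (k in 1:5) {
    prot <- bioseq(random_protein(60, seed = 100 + k), alphabet = "PROTEIN")
    for (mode in c("MOST_FREQUENT", "SAMPLE")) {
      nt <- reverse_translate_usage(prot, usage, mode, seed = k)
      expect_identical(seq_text(translate_frame(nt, 1)), seq_text(prot))
    }
    # seeded sampling is reproducible
    expect_identical(
      seq_text(reverse_translate_usage(prot, usage, "SAMPLE", seed = k)),
      seq_text(reverse_translate_usage(prot, usage, "SAMPLE", seed = k)))
  }
})

test_that("ORF detection matches a six-frame brute-force scan", {
  expect_error(find_orfs(bioseq("ATGAAATAA"), min_length_nt = 3), "at least 6")
  one <- find_orfs(bioseq("ATGAAATAA"), min_length_nt = 6)
  expect_identical(nrow(one), 1L)
  expect_identical(one$start, 1L)
  expect_identical(one$end, 9L)
  expect_identical(one$protein, "MK")
  # no start codon anywhere -> empty
  expect_identical(nrow(find_orfs(bioseq("CCCCCCCCCCCC"), min_length_nt = 6)), 0L)

  # brute-force oracle: walk all six frames explicitly
  oracle_orfs <- function(txt, min_len) {
    L <- nchar(txt)
    out <- list()
    for (strand in c("+", "-")) {
      t2 <- if (strand == "+") txt else oracle_revcomp(txt)
      for (off in 0:2) {
        pos <- seq(off + 1, L - 2, by = 3)
        cods <- substring(t2, pos, pos + 2)
        aas <- vapply(cods, function(cd)
          seqsuite:::translate_codon(cd, standard_genetic_code()$codon_to_aa), "")
        last_stop <- 0
        for (k in seq_along(cods)) {
          if (aas[k] != "*") next
          for (st in seq_len(k - 1)) {
            if (st <= last_stop || cods[st] != "ATG") next
            len <- 3 * (k - st + 1)
            if (len < min_len) next
            s <- pos[st]; e <- pos[k] + 2
            if (strand == "-") { tmp <- s; s <- L - e + 1; e <- L - tmp + 1 }
            out[[length(out) + 1]] <- c(s, e)
          }
          last_stop <- k
        }
      }
    }
    m <- do.call(rbind, out)
    if (is.null(m)) matrix(numeric(0), 0, 2) else m[order(m[, 1], m[, 2]), , drop = FALSE]
  }
  for (seed in 1:5) {
    txt <- random_dna(400, seed = 900 + seed)
    got <- find_orfs(bioseq(txt), min_length_nt = 30)
    want <- oracle_orfs(txt, 30)
    gm <- as.matrix(got[order(got$start, got$end), c("start", "end")])
    dimnames(gm) <- NULL
    expect_equal(gm, unname(want))
    # OrfHit invariants
    expect_true(all(got$length_nt == got$end - got$start + 1))
    expect_true(all(got$length_nt %% 3 == 0))
    expect_true(all(nchar(got$protein) == got$length_nt / 3 - 1))
  }
})

test_that("forward hits mirror reverse-strand hits of the reverse complement", {
  txt <- random_dna(300, seed = 77)
  s <- bioseq(txt, id = "g")
  rc <- reverse_complement(s)
  fwd <- find_orfs(s, min_length_nt = 30)
  rev_ <- find_orfs(rc, min_length_nt = 30)
  L <- nchar(txt)
  plus <- fwd[fwd$frame > 0, c("start", "end")]
  minus_reflected <- data.frame(start = L - rev_$end[rev_$frame < 0] + 1,
                                end = L - rev_$start[rev_$frame < 0] + 1)
  o1 <- plus[order(plus$start, plus$end), ]
  o2 <- minus_reflected[order(minus_reflected$start, minus_reflected$end), ]
  expect_equal(unname(as.matrix(o1)), unname(as.matrix(o2)))
})

test_that("usage-aware ORF ranking sorts by mean log2 codon fraction", {
  usage <- parse_codon_usage_gcg(synthetic_usage_text())
  g <- generate_random_genome(500, seed = 4,
                              orf = list(list(start = 31, length_nt = 60),
                                         list(start = 301, length_nt = 90)))
  hits <- find_orfs(g$sequence, min_length_nt = 30, usage = usage)
  expect_true(all(diff(hits$usage_score) <= 1e-12))
  expect_true(all(is.finite(hits$usage_score)))
})
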