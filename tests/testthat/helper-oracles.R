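# Independent brute-force oracles used to validate the search and alignment
# implementations, plus small fixture builders. The oracles are written as
# plain loops/recursions from first principles and share no code with the
# package internals they check.

ORACLE_IUB <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_chars_match <- function(a, b) {
  length(intersect(ORACLE_IUB[[a]], ORACLE_IUB[[b]])) > 0
}

oracle_mismatches <- function(word, pattern) {
  wc <- strsplit(word, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  sum(!mapply(oracle_chars_match, wc, pc))
}

oracle_revcomp <- function(txt) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", txt)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

# every window of txt with <= max_mismatch mismatches against pattern
oracle_substring_hits <- function(txt, pattern, max_mismatch) {
  m <- nchar(pattern)
  hits <- list()
  for (i in seq_len(nchar(txt) - m + 1)) {
    word <- substr(txt, i, i + m - 1)
    mm <- oracle_mismatches(word, pattern)
    if (mm <= max_mismatch) hits[[length(hits) + 1]] <- c(start = i, mm = mm)
  }
  do.call(rbind, hits)
}

# all gapped placements: left at i, right at i + nchar(left) + spacer
oracle_gapped_hits <- function(txt, left, right, max_mismatch,
                               spacer_min, spacer_max) {
  nl <- nchar(left); nr <- nchar(right); L <- nchar(txt)
  hits <- list()
  for (i in seq_len(L)) {
    for (sp in spacer_min:spacer_max) {
      j <- i + nl + sp
      if (j + nr - 1 > L) next
      mm <- oracle_mismatches(substr(txt, i, i + nl - 1), left) +
        oracle_mismatches(substr(txt, j, j + nr - 1), right)
      if (mm <= max_mismatch) {
        hits[[length(hits) + 1]] <- c(left_start = i, spacer = sp, mm = mm)
      }
    }
  }
  do.call(rbind, hits)
}

# Ri score of one window against a frequency matrix (mutual-information form)
oracle_ri <- function(fmat, letters, window) {
  wc <- strsplit(window, "")[[1]]
  total <- 0
  for (j in seq_along(wc)) {
    total <- total + log2(length(letters)) + log2(fmat[match(wc[j], letters), j])
  }
  unname(total)
}

oracle_site_hits <- function(txt, fmat, letters, threshold) {
  w <- ncol(fmat)
  hits <- list()
  for (i in seq_len(nchar(txt) - w + 1)) {
    sc <- oracle_ri(fmat, letters, substr(txt, i, i + w - 1))
    if (sc >= threshold) hits[[length(hits) + 1]] <- c(start = i, score = sc)
  }
  do.call(rbind, hits)
}

# exhaustive dyad repeat scan (direct and/or inverted)
oracle_dyad_repeats <- function(txt, len_range, spacer_range, max_mismatch,
                                orientations) {
  L <- nchar(txt)
  hits <- list()
  for (len in len_range) {
    for (sp in spacer_range) {
      for (i in seq_len(max(0, L - 2 * len - sp + 1))) {
        left <- substr(txt, i, i + len - 1)
        right <- substr(txt, i + len + sp, i + 2 * len + sp - 1)
        for (ori in orientations) {
          target <- if (ori == "DIRECT") right else oracle_revcomp(right)
          mm <- oracle_mismatches(left, target)
          if (mm <= max_mismatch) {
            hits[[length(hits) + 1]] <-
              data.frame(left_start = i, dyad_len = len, spacer = sp,
                         orientation = ori, mismatches = mm)
          }
        }
      }
    }
  }
  if (length(hits)) do.call(rbind, hits) else NULL
}

# optimal global alignment score by memoized recursion over the three moves
oracle_global_score <- function(a, b, score_fun, gap) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  memo <- matrix(NA_real_, n + 1, m + 1)
  rec <- function(i, j) {
    if (!is.na(memo[i + 1, j + 1])) return(memo[i + 1, j + 1])
    v <- if (i == 0 && j == 0) {
      0
    } else {
      cand <- numeric(0)
      if (i > 0 && j > 0) cand <- c(cand, rec(i - 1, j - 1) + score_fun(ac[i], bc[j]))
      if (i > 0) cand <- c(cand, rec(i - 1, j) + gap)
      if (j > 0) cand <- c(cand, rec(i, j - 1) + gap)
      max(cand)
    }
    memo[i + 1, j + 1] <<- v
    v
  }
  rec(n, m)
}

# optimal local alignment score: best suffix-anchored score at every cell
oracle_local_score <- function(a, b, score_fun, gap) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  H <- matrix(0, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      H[i + 1, j + 1] <- max(0,
                             H[i, j] + score_fun(ac[i], bc[j]),
                             H[i, j + 1] + gap,
                             H[i + 1, j] + gap)
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein <- function(n, seed) {
  set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# a small complete GCG-style codon usage text (synthetic organism)
synthetic_usage_text <- function() {
  code <- standard_genetic_code()
  aa1_to_3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
                Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
                L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
                S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
                `*` = "End")
  set.seed(42)
  counts <- sample(10:500, 64, replace = TRUE)
  lines <- c("AmAcid  Codon     Number    /1000     Fraction")
  for (k in seq_along(CODONS_TCAG)) {
    cod <- CODONS_TCAG[k]
    aa <- code$codon_to_aa[[cod]]
    fam <- which(code$codon_to_aa == aa)
    frac <- counts[k] / sum(counts[fam])
    lines <- c(lines, sprintf("%-7s %-9s %-10.2f %-9.2f %.4f",
                              aa1_to_3[[aa]], cod, counts[k],
                              1000 * counts[k] / sum(counts), frac))
  }
  paste(lines, collapse = "\n")
}
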