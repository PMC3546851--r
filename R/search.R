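# Pattern matching: two IUPAC characters match when their expansions
# intersect. MATCH_OK is a 16x16 lookup over canonical nucleotide letters.
MATCH_OK <- local({
  ltr <- names(IUB_EXPANSION)
  m <- matrix(FALSE, length(ltr), length(ltr), dimnames = list(ltr, ltr))
  for (a in ltr) for (b in ltr) {
    m[a, b] <- length(intersect(IUB_EXPANSION[[a]], IUB_EXPANSION[[b]])) > 0
  }
  m
})

# mismatch count of `pattern` at every start position of `txt` (canonical
# residue strings); IUPAC-aware for nucleic alphabets
mismatch_vector <- function(txt, pattern, nucleic = TRUE) {
  L <- nchar(txt); m <- nchar(pattern)
  if (m > L) return(integer(0))
  sc <- chars(txt); pc <- chars(pattern)
  nw <- L - m + 1L
  mm <- integer(nw)
  for (j in seq_len(m)) {
    sj <- sc[j:(j + nw - 1L)]
    mm <- mm + if (nucleic) !MATCH_OK[cbind(sj, pc[j])] else (sj != pc[j])
  }
  mm
}

empty_hits <- function() {
  data.frame(sequence_id = character(), start = integer(), end = integer(),
             strand = character(), matched = character(),
             mismatches = integer(), score = numeric(),
             stringsAsFactors = FALSE)
}

#' Substring search with mismatches or a substitution matrix
#'
#' Exhaustively reports every window of each sequence that matches `pattern`.
#' For nucleic sequences matching is IUPAC-aware (a degenerate letter matches
#' any base whose expansion intersects its own, at zero mismatch cost) and a
#' window is a hit when its mismatch count is at most `max_mismatch`. For
#' protein sequences a substitution matrix may be supplied instead, in which
#' case a window is a hit when its summed matrix score reaches
#' `min_matrix_score`.
#'
#' @param coll a [bioseq] or [seq_collection] to search.
#' @param pattern the query string (IUPAC codes allowed for nucleic searches).
#' @param max_mismatch maximum mismatches (ignored when `matrix` is given).
#' @param matrix optional `subst_matrix` for protein scoring.
#' @param min_matrix_score score threshold used with `matrix`.
#' @param strands `"FORWARD"` or `"BOTH"` (nucleic only); minus-strand hits
#'   are reported with forward coordinates, strand `-`, and `matched` as read
#'   on the minus strand.
#' @return data frame of class `search_hits` with columns `sequence_id`,
#'   `start`, `end`, `strand`, `matched`, `mismatches`, `score` (mismatch
#'   count, or matrix score), ordered by sequence then start.
#' @examples
#' substring_search(bioseq("ACTGTA"), "CTGW")   # W matches T
#' @export
substring_search <- function(coll, pattern, max_mismatch = 0, matrix = NULL,
                             min_matrix_score = NULL,
                             strands = c("FORWARD", "BOTH")) {
  strands <- match.arg(strands)
  coll <- as_collection(coll)
  rows <- list()
  for (s in coll) {
    nucleic <- s$alphabet == "NUCLEIC"
    if (nucleic && !is.null(matrix)) {
      stop2("substitution matrices apply to protein searches only")
    }
    pat <- clean_residue_text(pattern)
    if (nucleic) {
      pat <- gsub("U", "T", pat, fixed = TRUE)
      bad <- setdiff(chars(pat), names(IUB_EXPANSION))
      if (length(bad)) stop2("invalid nucleotide pattern character '", bad[1], "'")
    } else {
      bad <- setdiff(chars(pat), AMINO_ACIDS)
      if (length(bad)) {
        stop2("pattern character '", bad[1],
              "' is not a standard amino acid (IUPAC nucleotide codes are not",
              " valid in protein patterns)")
      }
    }
    m <- nchar(pat)
    if (m > nchar(s$residues)) {
      stop2("pattern longer than sequence '", s$id, "'")
    }
    scan_one <- function(query, strand) {
      if (!is.null(matrix)) {
        sc <- chars(s$residues); qc <- chars(query)
        nw <- nchar(s$residues) - m + 1L
        score <- numeric(nw); mm <- integer(nw)
        for (j in seq_len(m)) {
          sj <- sc[j:(j + nw - 1L)]
          score <- score + matrix[cbind(sj, qc[j])]
          mm <- mm + (sj != qc[j])
        }
        keep <- which(score >= (min_matrix_score %||% -Inf))
        mmk <- mm[keep]; sck <- score[keep]
      } else {
        mmv <- mismatch_vector(s$residues, query, nucleic)
        keep <- which(mmv <= max_mismatch)
        mmk <- mmv[keep]; sck <- as.numeric(mmk)
      }
      if (!length(keep)) return(NULL)
      matched <- substring(s$residues, keep, keep + m - 1L)
      if (strand == "-") matched <- vapply(matched, revcomp_string, "")
      data.frame(sequence_id = s$id, start = keep, end = keep + m - 1L,
                 strand = strand, matched = unname(matched),
                 mismatches = mmk, score = sck, stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- scan_one(pat, "+")
    if (strands == "BOTH" && nucleic) {
      rows[[length(rows) + 1L]] <- scan_one(revcomp_string(pat), "-")
    }
  }
  out <- do.call(rbind, c(rows, list(empty_hits())))
  out <- out[order(match(out$sequence_id, vapply(coll, function(s) s$id, "")),
                   out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("search_hits", "data.frame")
  out
}

empty_dyad_hits <- function() {
  data.frame(sequence_id = character(), left_start = integer(),
             left_end = integer(), right_start = integer(),
             right_end = integer(), spacer = integer(), strand = character(),
             left_score = numeric(), right_score = numeric(),
             score = numeric(), stringsAsFactors = FALSE)
}

#' Gapped (dyad substring) search with a variable spacer
#'
#' Finds placements of two substring patterns separated by a gap in
#' `[spacer_min, spacer_max]` where the summed mismatch count of the two
#' halves is at most `max_mismatch`. The overall score is the sum of the dyad
#' mismatch scores. On the minus strand the pattern pair is matched on the
#' reverse complement and reported with forward coordinates (halves ordered by
#' forward position, so `right_start = left_end + spacer + 1` always holds).
#'
#' @param coll a [bioseq] or [seq_collection] (NUCLEIC).
#' @param left,right the two half patterns (IUPAC codes allowed).
#' @param max_mismatch maximum combined mismatches.
#' @param spacer_min,spacer_max inclusive spacer range (>= 0).
#' @param strands `"FORWARD"` or `"BOTH"`.
#' @return data frame of class `dyad_hits` with per-half coordinates, scores
#'   and the combined `score`.
#' @export
gapped_search <- function(coll, left, right, max_mismatch = 0,
                          spacer_min = 0, spacer_max = 0,
                          strands = c("FORWARD", "BOTH")) {
  strands <- match.arg(strands)
  if (spacer_min < 0) stop2("spacer_min must be >= 0")
  if (spacer_min > spacer_max) stop2("spacer_min must be <= spacer_max")
  if (!nzchar(left) || !nzchar(right)) stop2("both patterns must be non-empty")
  coll <- as_collection(coll)
  clean_pat <- function(p) {
    p <- gsub("U", "T", clean_residue_text(p), fixed = TRUE)
    bad <- setdiff(chars(p), names(IUB_EXPANSION))
    if (length(bad)) stop2("invalid nucleotide pattern character '", bad[1], "'")
    p
  }
  lp <- clean_pat(left); rp <- clean_pat(right)
  rows <- list()
  for (s in coll) {
    if (s$alphabet != "NUCLEIC") stop2("gapped search requires NUCLEIC sequences")
    L <- nchar(s$residues)
    scan_one <- function(txt, strand) {
      mml <- mismatch_vector(txt, lp, TRUE)
      mmr <- mismatch_vector(txt, rp, TRUE)
      nl <- nchar(lp); nr <- nchar(rp)
      for (sp in spacer_min:spacer_max) {
        i_max <- L - nl - sp - nr + 1L
        if (i_max < 1L) next
        i <- seq_len(i_max)
        j <- i + nl + sp
        tot <- mml[i] + mmr[j]
        keep <- which(tot <= max_mismatch)
        if (!length(keep)) next
        if (strand == "+") {
          df <- data.frame(sequence_id = s$id, left_start = keep,
                           left_end = keep + nl - 1L,
                           right_start = j[keep], right_end = j[keep] + nr - 1L,
                           spacer = sp, strand = strand,
                           left_score = as.numeric(mml[keep]),
                           right_score = as.numeric(mmr[j[keep]]),
                           score = as.numeric(tot[keep]),
                           stringsAsFactors = FALSE)
        } else {
          # reflect revcomp coordinates; forward-leftmost half is the
          # reverse-complemented `right` pattern
          re <- j[keep] + nr - 1L
          df <- data.frame(sequence_id = s$id,
                           left_start = L - re + 1L,
                           left_end = L - j[keep] + 1L,
                           right_start = L - (keep + nl - 1L) + 1L,
                           right_end = L - keep + 1L,
                           spacer = sp, strand = strand,
                           left_score = as.numeric(mmr[j[keep]]),
                           right_score = as.numeric(mml[keep]),
                           score = as.numeric(tot[keep]),
                           stringsAsFactors = FALSE)
        }
        rows[[length(rows) + 1L]] <<- df
      }
    }
    scan_one(s$residues, "+")
    if (strands == "BOTH") scan_one(revcomp_string(s$residues), "-")
  }
  out <- do.call(rbind, c(rows, list(empty_dyad_hits())))
  out <- out[order(match(out$sequence_id, vapply(coll, function(s) s$id, "")),
                   out$left_start, out$spacer, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dyad_hits", "data.frame")
  out
}

# per-position score contribution table for every IUPAC letter: an ambiguous
# subject character scores the background-weighted mean of f(., j) over its
# expansion (and of p(.) for the relative-entropy denominator)
ri_contrib_table <- function(psfm, method) {
  f <- psfm$matrix; p <- psfm$background
  if (psfm$alphabet == "NUCLEIC") {
    ltr <- names(IUB_EXPANSION)
    fe <- matrix(NA_real_, length(ltr), psfm$width, dimnames = list(ltr, NULL))
    pe <- stats::setNames(numeric(length(ltr)), ltr)
    for (ch in ltr) {
      ex <- IUB_EXPANSION[[ch]]
      wgt <- p[ex] / sum(p[ex])
      fe[ch, ] <- as.numeric(wgt %*% f[ex, , drop = FALSE])
      pe[ch] <- sum(wgt * p[ex])
    }
  } else {
    ltr <- psfm$letters
    fe <- f
    pe <- p
  }
  if (method == "MUTUAL_INFO_RI") {
    log2(length(psfm$letters)) + log2(fe)
  } else {
    log2(fe / pe)
  }
}

#' Individual information (Ri) score of one window
#'
#' Scores a candidate site against a PSFM in bits. `MUTUAL_INFO_RI` computes
#' `sum_j (log2 |A| + log2 f(s_j, j))`; `REL_ENTROPY_RI` computes
#' `sum_j log2(f(s_j, j) / p(s_j))`. A residue with zero frequency (possible
#' when the PSFM was built without pseudocounts) yields `-Inf`, not an error.
#' Ambiguous subject characters (e.g. `N`) score the background-weighted mean
#' frequency of their expansion.
#'
#' @param psfm a [psfm].
#' @param window residue text of length `psfm$width`.
#' @param method `"MUTUAL_INFO_RI"` or `"REL_ENTROPY_RI"`.
#' @return score in bits (possibly `-Inf`).
#' @export
score_site_ri <- function(psfm, window,
                          method = c("MUTUAL_INFO_RI", "REL_ENTROPY_RI")) {
  method <- match.arg(method)
  win <- clean_residue_text(window)
  if (psfm$alphabet == "NUCLEIC") win <- gsub("U", "T", win, fixed = TRUE)
  if (nchar(win) != psfm$width) {
    stop2("window length ", nchar(win), " != PSFM width ", psfm$width)
  }
  tab <- ri_contrib_table(psfm, method)
  ri <- match(chars(win), rownames(tab))
  if (anyNA(ri)) {
    stop2("window contains residues outside the PSFM alphabet")
  }
  sum(tab[cbind(ri, seq_len(psfm$width))])
}

#' PSFM site scan
#'
#' Scores every window of every sequence against a PSFM (see
#' [score_site_ri()]) and reports the windows at or above `threshold_bits`.
#' Reverse-strand windows are scored on their reverse complement and reported
#' with forward coordinates and strand `-`.
#'
#' @param coll a [bioseq] or [seq_collection].
#' @param psfm a [psfm].
#' @param threshold_bits minimum reported score; a threshold above the PSFM's
#'   maximum possible score (`width * log2 |A|`) triggers a warning and an
#'   empty result.
#' @param method see [score_site_ri()].
#' @param strands `"FORWARD"` or `"BOTH"`.
#' @return a `search_hits` data frame (`score` in bits), sorted by position.
#' @export
site_search <- function(coll, psfm, threshold_bits = 0,
                        method = c("MUTUAL_INFO_RI", "REL_ENTROPY_RI"),
                        strands = c("FORWARD", "BOTH")) {
  method <- match.arg(method)
  strands <- match.arg(strands)
  coll <- as_collection(coll)
  w <- psfm$width
  if (threshold_bits > w * log2(length(psfm$letters))) {
    warning("threshold exceeds the PSFM's maximum possible score; no hits")
    return(structure(empty_hits(), class = c("search_hits", "data.frame")))
  }
  tab <- ri_contrib_table(psfm, method)
  rows <- list()
  for (s in coll) {
    if ((psfm$alphabet == "NUCLEIC") != (s$alphabet == "NUCLEIC")) {
      stop2("PSFM and sequence '", s$id, "' have different alphabets")
    }
    if (w > nchar(s$residues)) stop2("PSFM wider than sequence '", s$id, "'")
    scan_one <- function(txt, strand) {
      sc <- window_scores(txt, tab, w)
      keep <- which(sc >= threshold_bits)
      if (!length(keep)) return(NULL)
      if (strand == "+") {
        st <- keep
        matched <- substring(txt, keep, keep + w - 1L)
      } else {
        L <- nchar(txt)
        st <- L - (keep + w - 1L) + 1L
        matched <- substring(txt, keep, keep + w - 1L)
      }
      data.frame(sequence_id = s$id, start = st, end = st + w - 1L,
                 strand = strand, matched = matched, mismatches = NA_integer_,
                 score = sc[keep], stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- scan_one(s$residues, "+")
    if (strands == "BOTH" && s$alphabet == "NUCLEIC") {
      rows[[length(rows) + 1L]] <- scan_one(revcomp_string(s$residues), "-")
    }
  }
  out <- do.call(rbind, c(rows, list(empty_hits())))
  out <- out[order(match(out$sequence_id, vapply(coll, function(s) s$id, "")),
                   out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("search_hits", "data.frame")
  out
}

# sum of per-position contributions for every window of txt
window_scores <- function(txt, tab, w) {
  ri <- match(chars(txt), rownames(tab))
  if (anyNA(ri)) {
    stop2("sequence contains residues outside the PSFM alphabet")
  }
  nw <- nchar(txt) - w + 1L
  if (nw < 1L) return(numeric(0))
  sc <- numeric(nw)
  for (j in seq_len(w)) {
    sc <- sc + tab[cbind(ri[j:(j + nw - 1L)], j)]
  }
  sc
}

#' Dyad pattern search (PSFM half-sites with a variable spacer)
#'
#' Searches for two occurrences of a half-site model separated by a spacer in
#' `[spacer_min, spacer_max]`, as a direct repeat or an inverted repeat (the
#' right half scored on the reverse complement of its window). The overall
#' score is the sum of the two half-site Ri scores; only placements whose sum
#' reaches `threshold_bits` (and whose halves each reach `per_half_min`, by
#' default unbounded) are reported.
#'
#' @param coll a [bioseq] or [seq_collection] (NUCLEIC).
#' @param half_site a [psfm] or an IUPAC consensus string (converted with
#'   [psfm_from_consensus()], with pseudocount 1 so scores stay finite).
#' @param spacer_min,spacer_max inclusive spacer range.
#' @param orientation `"INVERTED"` or `"DIRECT"`.
#' @param threshold_bits minimum combined score.
#' @param method see [score_site_ri()].
#' @param per_half_min optional per-half score floor (default `-Inf`: only the
#'   combined threshold filters).
#' @return a `dyad_hits` data frame with per-half scores in bits.
#' @export
dyad_pattern_search <- function(coll, half_site, spacer_min = 0, spacer_max = 0,
                                orientation = c("INVERTED", "DIRECT"),
                                threshold_bits = 0,
                                method = c("MUTUAL_INFO_RI", "REL_ENTROPY_RI"),
                                per_half_min = -Inf) {
  orientation <- match.arg(orientation)
  method <- match.arg(method)
  if (spacer_min < 0) stop2("spacer_min must be >= 0")
  if (spacer_min > spacer_max) stop2("spacer_min must be <= spacer_max")
  if (is.character(half_site)) {
    half_site <- psfm_from_consensus(half_site, pseudocount = 1)
  }
  stopifnot(inherits(half_site, "psfm"))
  w <- half_site$width
  if (threshold_bits > 2 * w * log2(length(half_site$letters))) {
    warning("threshold exceeds the maximum possible dyad score; no hits")
    return(structure(empty_dyad_hits(), class = c("dyad_hits", "data.frame")))
  }
  tab <- ri_contrib_table(half_site, method)
  coll <- as_collection(coll)
  rows <- list()
  for (s in coll) {
    if (s$alphabet != "NUCLEIC") stop2("dyad pattern search requires NUCLEIC sequences")
    L <- nchar(s$residues)
    fwd <- window_scores(s$residues, tab, w)
    right_vec <- if (orientation == "DIRECT") fwd else {
      rc <- window_scores(revcomp_string(s$residues), tab, w)
      rev(rc)   # rc[k] scores the window ending at forward position L-k+1
    }
    for (sp in spacer_min:spacer_max) {
      i_max <- L - 2L * w - sp + 1L
      if (i_max < 1L) next
      i <- seq_len(i_max)
      j <- i + w + sp
      tot <- fwd[i] + right_vec[j]
      keep <- which(tot >= threshold_bits & fwd[i] >= per_half_min &
                      right_vec[j] >= per_half_min)
      if (!length(keep)) next
      rows[[length(rows) + 1L]] <- data.frame(
        sequence_id = s$id, left_start = keep, left_end = keep + w - 1L,
        right_start = j[keep], right_end = j[keep] + w - 1L, spacer = sp,
        strand = "+", left_score = fwd[keep], right_score = right_vec[j[keep]],
        score = tot[keep], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(empty_dyad_hits())))
  out <- out[order(match(out$sequence_id, vapply(coll, function(s) s$id, "")),
                   out$left_start, out$spacer), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dyad_hits", "data.frame")
  out
}

#' Export hits as TSV, BED or annotated FASTA
#'
#' `hits_tsv()` renders any hits data frame as tab-separated text with a
#' header row. `hits_bed()` converts `search_hits` to BED6 (0-based
#' half-open; scores clamped to 0-1000). `annotate_hits_fasta()` writes the
#' searched sequences in FASTA with hit spans upper-case and everything else
#' lower-case.
#'
#' @param hits a hits data frame.
#' @return character scalar of formatted text.
#' @export
hits_tsv <- function(hits) {
  df <- as.data.frame(hits)
  con <- textConnection("out", "w", local = TRUE)
  utils::write.table(format(df, digits = 6, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  paste0(paste(out, collapse = "\n"), "\n")
}

#' @rdname hits_tsv
#' @export
hits_bed <- function(hits) {
  if (!nrow(hits)) return("")
  sc <- hits$score
  rng <- range(sc[is.finite(sc)], 0)
  scaled <- if (diff(rng) > 0) {
    as.integer(round(1000 * (pmax(sc, rng[1]) - rng[1]) / diff(rng)))
  } else rep(0L, nrow(hits))
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   hits$sequence_id, hits$start - 1L, hits$end,
                   paste0("hit", seq_len(nrow(hits))), scaled, hits$strand)
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' @rdname hits_tsv
#' @param coll the searched collection.
#' @export
annotate_hits_fasta <- function(coll, hits) {
  coll <- as_collection(coll)
  out <- character()
  for (s in coll) {
    cs <- chars(tolower(seq_text(s)))
    sel <- hits[hits$sequence_id == s$id, , drop = FALSE]
    for (k in seq_len(nrow(sel))) {
      span <- sel$start[k]:sel$end[k]
      cs[span] <- toupper(cs[span])
    }
    out <- c(out, paste0(">", s$id,
                         if (nzchar(s$desc)) paste0(" ", s$desc) else ""),
             wrap_text(collapse(cs), 60))
  }
  paste0(paste(out, collapse = "\n"), "\n")
}
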