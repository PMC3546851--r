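#' Genetic code models
#'
#' `standard_genetic_code()` returns the standard code (translation table 1,
#' with `ATG` as the default start codon). `genetic_code()` builds a code from
#' its components, and `parse_genetic_code()` reads the NCBI translation-table
#' text layout (`AAs = ...`, `Starts = ...`, `Base1/2/3 = ...` lines).
#'
#' @param codon_to_aa named character vector mapping all 64 DNA codons to
#'   amino-acid letters, with `*` for stops.
#' @param start_codons codons treated as translation starts.
#' @param table_id label for the code.
#' @param usage optional `codon_usage` table attached to the code.
#' @return object of class `genetic_code`.
#' @export
genetic_code <- function(codon_to_aa, start_codons = "ATG", table_id = "custom",
                         usage = NULL) {
  if (length(codon_to_aa) != 64 || !setequal(names(codon_to_aa), CODONS_TCAG)) {
    stop2("codon_to_aa must map exactly the 64 DNA codons")
  }
  if (!all(start_codons %in% CODONS_TCAG)) stop2("invalid start codon")
  structure(list(table_id = table_id,
                 codon_to_aa = codon_to_aa[CODONS_TCAG],
                 start_codons = start_codons, usage = usage),
            class = "genetic_code")
}

#' @rdname genetic_code
#' @export
standard_genetic_code <- function(start_codons = "ATG") {
  genetic_code(stats::setNames(chars(STANDARD_CODE_AAS), CODONS_TCAG),
               start_codons = start_codons, table_id = "1")
}

#' @rdname genetic_code
#' @param stream text in NCBI translation-table layout.
#' @export
parse_genetic_code <- function(stream, table_id = "custom") {
  lines <- if (length(stream) == 1) strsplit(stream, "\r?\n")[[1]] else stream
  grab <- function(key) {
    ln <- grep(paste0("^\\s*", key, "\\s*="), lines, value = TRUE)
    if (!length(ln)) stop2("missing '", key, "' line")
    gsub("\\s", "", sub(".*=", "", ln[1]))
  }
  aas <- toupper(grab("AAs"))
  starts <- toupper(grab("Starts"))
  b1 <- toupper(gsub("U", "T", grab("Base1")))
  b2 <- toupper(gsub("U", "T", grab("Base2")))
  b3 <- toupper(gsub("U", "T", grab("Base3")))
  if (nchar(aas) != 64) stop2("AAs line must list 64 letters")
  codons <- paste0(chars(b1), chars(b2), chars(b3))
  map <- stats::setNames(chars(aas), codons)
  start_set <- codons[chars(starts) == "M"]
  genetic_code(map, start_codons = start_set, table_id = table_id)
}

# Translate one canonical-DNA codon, resolving IUPAC ambiguity: if every
# expansion of the codon encodes the same amino acid, return it; otherwise X.
translate_codon <- function(codon, map) {
  aa <- map[codon]
  if (!is.na(aa)) return(unname(aa))
  parts <- lapply(chars(codon), function(ch) {
    ex <- IUB_EXPANSION[[ch]]
    if (is.null(ex)) stop2("invalid nucleotide '", ch, "' in codon ", codon)
    ex
  })
  grid <- expand.grid(parts, stringsAsFactors = FALSE)
  aas <- unique(map[apply(grid, 1, collapse)])
  if (length(aas) == 1) unname(aas) else "X"
}

translate_string <- function(txt, code) {
  n_codons <- nchar(txt) %/% 3L
  if (n_codons == 0) return("")
  starts <- 3L * seq_len(n_codons) - 2L
  codons <- substring(txt, starts, starts + 2L)
  aa <- code$codon_to_aa[codons]
  miss <- is.na(aa)
  if (any(miss)) {
    aa[miss] <- vapply(codons[miss], translate_codon, "", map = code$codon_to_aa)
  }
  collapse(unname(aa))
}

#' Frame-dependent translation
#'
#' Translates a nucleic sequence starting at position `frame` (1, 2 or 3);
#' the trailing partial codon is dropped and stops are rendered `*`. Codons
#' containing IUPAC ambiguity codes translate to the unique amino acid when
#' all expansions agree, and to `X` otherwise.
#'
#' @param seq a NUCLEIC [bioseq] (or a `seq_collection`, translated serially).
#' @param frame 1, 2 or 3.
#' @param code a [genetic_code]; defaults to the standard code.
#' @return a PROTEIN `bioseq` (or collection).
#' @examples
#' seq_text(translate_frame(bioseq("ATGAAATAA")))   # "MK*"
#' @export
translate_frame <- function(seq, frame = 1, code = standard_genetic_code()) {
  if (!frame %in% 1:3) stop2("frame must be 1, 2 or 3")
  map_serial(seq, function(s) {
    if (s$alphabet != "NUCLEIC") stop2("cannot translate a PROTEIN sequence")
    txt <- substr(s$residues, frame, nchar(s$residues))
    if (nchar(txt) < 3) stop2("sequence too short to translate in frame ", frame)
    bioseq(translate_string(txt, code), id = s$id,
           desc = paste0("translation frame +", frame), alphabet = "PROTEIN")
  })
}

#' Translation map
#'
#' Renders a nucleic sequence with its translation in any subset of the six
#' reading frames as a plain-text block: a position ruler, the DNA line, and
#' one amino-acid line per frame with each letter aligned under the middle
#' base of its codon. Negative frames are translated on the reverse complement
#' and therefore read right-to-left under the forward sequence.
#'
#' @param seq a NUCLEIC [bioseq].
#' @param frames integer subset of `c(1, 2, 3, -1, -2, -3)`.
#' @param code a [genetic_code].
#' @param line_width residues per block line.
#' @return character scalar (multi-line text).
#' @export
translation_map <- function(seq, frames = c(1, 2, 3),
                            code = standard_genetic_code(), line_width = 60) {
  stopifnot(inherits(seq, "bioseq"))
  if (seq$alphabet != "NUCLEIC") stop2("translation map requires a NUCLEIC sequence")
  if (!length(frames)) stop2("at least one frame must be requested")
  if (!all(frames %in% c(1:3, -(1:3)))) stop2("frames must be in {+-1,+-2,+-3}")
  L <- nchar(seq$residues)
  dna <- chars(seq_text(seq))
  rows <- list()
  for (f in frames) {
    row <- rep(" ", L)
    if (f > 0) {
      prot <- chars(translate_string(substr(seq$residues, f, L), code))
      if (length(prot)) {
        mid <- f + 3L * (seq_along(prot) - 1L) + 1L   # middle base of codon
        row[mid] <- prot
      }
    } else {
      rc <- revcomp_string(seq$residues)
      prot <- chars(translate_string(substr(rc, -f, L), code))
      if (length(prot)) {
        mid_rc <- -f + 3L * (seq_along(prot) - 1L) + 1L
        row[L - mid_rc + 1L] <- prot                   # reflect to forward coords
      }
    }
    rows[[sprintf("%+d", f)]] <- row
  }
  out <- character()
  for (st in seq(1L, L, by = line_width)) {
    en <- min(st + line_width - 1L, L)
    ruler_pos <- if (en >= st + 9L) seq(st + 9L, en, by = 10L) else integer()
    ruler <- rep(" ", en - st + 1L)
    for (p in ruler_pos) {
      lab <- as.character(p)
      ruler[(p - st + 2L - nchar(lab)):(p - st + 1L)] <- chars(lab)
    }
    out <- c(out,
             paste0("    ruler ", collapse(ruler)),
             sprintf("%9d %s", st, collapse(dna[st:en])))
    for (nm in names(rows)) {
      out <- c(out, sprintf("%9s %s", nm, collapse(rows[[nm]][st:en])))
    }
    out <- c(out, "")
  }
  paste0(collapse(paste0(out, "\n")))
}

# minimal single-IUPAC-codon cover of an amino acid's codon set: per position,
# the IUPAC letter for the union of bases seen at that position
iub_cover_codon <- function(codons) {
  vapply(1:3, function(j) {
    bases <- sort(unique(substr(codons, j, j)))
    IUB_FROM_BASES[[paste(bases, collapse = "")]]
  }, "") |> collapse()
}

codons_for_aa <- function(aa, code) {
  names(code$codon_to_aa)[code$codon_to_aa == aa]
}

#' Reverse translation assuming uniform codon usage
#'
#' Each amino acid is rendered as the minimal single IUPAC-degenerate codon
#' covering all of its codons. For leucine, arginine and serine no exact
#' single-codon cover exists, so the emitted codon overgenerates; the
#' `exact` attribute reports per-residue whether the cover is exact.
#'
#' @param prot a PROTEIN [bioseq].
#' @param code a [genetic_code].
#' @return a NUCLEIC `bioseq` of length `3 * nchar(prot)` with an `exact`
#'   logical attribute (one flag per input residue).
#' @examples
#' seq_text(reverse_translate_uniform(bioseq("MK", alphabet = "PROTEIN")))
#' @export
reverse_translate_uniform <- function(prot, code = standard_genetic_code()) {
  stopifnot(inherits(prot, "bioseq"))
  if (prot$alphabet != "PROTEIN") stop2("reverse translation needs a PROTEIN sequence")
  res <- chars(prot$residues)
  out <- character(length(res))
  exact <- logical(length(res))
  for (i in seq_along(res)) {
    cods <- codons_for_aa(res[i], code)
    if (!length(cods)) stop2("residue '", res[i], "' has no codon")
    cover <- iub_cover_codon(cods)
    n_exp <- prod(vapply(chars(cover), function(ch)
      length(IUB_EXPANSION[[ch]]), 0))
    out[i] <- cover
    exact[i] <- n_exp == length(cods)
  }
  s <- bioseq(collapse(out), id = prot$id, desc = "uniform reverse translation",
              alphabet = "NUCLEIC")
  attr(s, "exact") <- exact
  s
}

#' Reverse translation following a codon usage table
#'
#' `MOST_FREQUENT` deterministically picks the highest-fraction codon for each
#' residue (ties broken alphabetically); `SAMPLE` draws each codon from the
#' usage fractions under the given seed. In both modes
#' `translate_frame(result, 1)` returns the input protein exactly.
#'
#' @param prot a PROTEIN [bioseq].
#' @param usage a `codon_usage` table (see [parse_codon_usage_gcg()]).
#' @param mode `"MOST_FREQUENT"` or `"SAMPLE"`.
#' @param seed RNG seed for `SAMPLE` mode.
#' @param code a [genetic_code].
#' @return a NUCLEIC `bioseq`.
#' @export
reverse_translate_usage <- function(prot, usage,
                                    mode = c("MOST_FREQUENT", "SAMPLE"),
                                    seed = 0, code = standard_genetic_code()) {
  stopifnot(inherits(prot, "bioseq"), inherits(usage, "codon_usage"))
  if (prot$alphabet != "PROTEIN") stop2("reverse translation needs a PROTEIN sequence")
  mode <- match.arg(mode)
  res <- chars(prot$residues)
  pick_one <- function(aa) {
    cods <- codons_for_aa(aa, code)
    if (!length(cods)) stop2("residue '", aa, "' has no codon")
    rows <- usage[usage$codon %in% cods, , drop = FALSE]
    fr <- rows$fraction
    if (all(fr <= 0)) stop2("amino acid '", aa, "' has all-zero codon usage")
    if (mode == "MOST_FREQUENT") {
      rows$codon[order(-fr, rows$codon)][1]
    } else {
      sample(rows$codon, 1L, prob = fr)
    }
  }
  out <- if (mode == "SAMPLE") {
    with_seed(seed, vapply(res, pick_one, ""))
  } else {
    vapply(res, pick_one, "")
  }
  bioseq(collapse(out), id = prot$id,
         desc = paste0("codon-usage reverse translation (", mode, ")"),
         alphabet = "NUCLEIC")
}

#' Open reading frame detection
#'
#' Scans three (forward) or six (both-strand) reading frames for ORFs: a start
#' codon followed in frame by the nearest stop codon with no internal stop.
#' The reported span includes the stop codon, so `length_nt` is divisible by
#' 3, and coordinates are 1-based inclusive on the forward strand. Nested
#' starts sharing a stop are all reported. When a codon usage table is given,
#' each ORF also gets `usage_score`, the mean over its codons of
#' `log2(fraction)` (fractions floored at 1e-4), and hits are sorted by that
#' score, then length; otherwise by length, then position.
#'
#' @param seq a NUCLEIC [bioseq].
#' @param code a [genetic_code]; its `start_codons` define ORF starts.
#' @param min_length_nt minimum ORF length in nucleotides (must be >= 6).
#' @param strands `"BOTH"` or `"FORWARD"`.
#' @param usage optional `codon_usage` table.
#' @return a data frame of class `orf_hits` with columns `sequence_id`,
#'   `frame`, `start`, `end`, `length_nt`, `protein`, `usage_score`.
#' @export
find_orfs <- function(seq, code = standard_genetic_code(), min_length_nt = 30,
                      strands = c("BOTH", "FORWARD"), usage = NULL) {
  stopifnot(inherits(seq, "bioseq"))
  if (seq$alphabet != "NUCLEIC") stop2("ORF search requires a NUCLEIC sequence")
  strands <- match.arg(strands)
  if (min_length_nt < 6) stop2("min_length_nt must be at least 6")
  L <- nchar(seq$residues)
  hits <- list()
  scan_strand <- function(txt, strand) {
    for (off in 0:2) {
      n_codons <- (nchar(txt) - off) %/% 3L
      if (n_codons < 2) next
      starts_nt <- off + 3L * seq_len(n_codons) - 2L
      codons <- substring(txt, starts_nt, starts_nt + 2L)
      aa <- vapply(codons, function(cd) {
        v <- code$codon_to_aa[cd]
        if (is.na(v)) translate_codon(cd, code$codon_to_aa) else unname(v)
      }, "")
      is_stop <- aa == "*"
      is_start <- codons %in% code$start_codons
      last_stop <- 0L
      for (k in seq_len(n_codons)) {
        if (!is_stop[k]) next
        cand <- which(is_start & seq_len(n_codons) > last_stop &
                        seq_len(n_codons) < k)
        for (st in cand) {
          len <- 3L * (k - st + 1L)
          if (len < min_length_nt) next
          s_pos <- starts_nt[st]; e_pos <- starts_nt[k] + 2L
          if (strand == "+") {
            fstart <- s_pos; fend <- e_pos; frame <- ((s_pos - 1L) %% 3L) + 1L
          } else {
            fstart <- L - e_pos + 1L; fend <- L - s_pos + 1L
            frame <- -(((s_pos - 1L) %% 3L) + 1L)
          }
          prot <- collapse(aa[st:(k - 1L)])
          uscore <- NA_real_
          if (!is.null(usage)) {
            fr <- usage$fraction[match(codons[st:k], usage$codon)]
            uscore <- mean(log2(pmax(fr, 1e-4)))
          }
          hits[[length(hits) + 1L]] <<- data.frame(
            sequence_id = seq$id, frame = frame, start = fstart, end = fend,
            length_nt = len, protein = prot, usage_score = uscore,
            stringsAsFactors = FALSE)
        }
        last_stop <- k
      }
    }
  }
  scan_strand(seq$residues, "+")
  if (strands == "BOTH") scan_strand(revcomp_string(seq$residues), "-")
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(sequence_id = character(), frame = integer(), start = integer(),
               end = integer(), length_nt = integer(), protein = character(),
               usage_score = numeric(), stringsAsFactors = FALSE)
  ord <- if (!is.null(usage) && nrow(out)) {
    order(-out$usage_score, -out$length_nt, out$start)
  } else {
    order(-out$length_nt, out$start)
  }
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("orf_hits", "data.frame")
  out
}
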