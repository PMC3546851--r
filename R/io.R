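#' Parse sequence text in FASTA, GenBank flat file or raw format
#'
#' @param stream character scalar (or vector of lines) holding the records.
#' @param format one of `"FASTA"`, `"GENBANK"`, `"RAW"`, `"AUTO"`. `AUTO`
#'   sniffs the format from the first non-blank line: `>` means FASTA, a
#'   `LOCUS` keyword means GenBank, anything else is treated as raw text.
#' @param nucleic_threshold passed to [bioseq()] for alphabet detection.
#' @return a [seq_collection].
#' @details FASTA headers are split at the first whitespace into identifier
#'   and description. GenBank records use the LOCUS name as identifier, the
#'   DEFINITION line as description and the ORIGIN block as residues; a record
#'   without an ORIGIN block is an error. Raw input yields a single record
#'   with a generated identifier after stripping whitespace, digits and
#'   `\\ / |`.
#' @examples
#' parse_sequences(">s1 test\nACGT\n", "FASTA")
#' @export
parse_sequences <- function(stream, format = c("AUTO", "FASTA", "GENBANK", "RAW"),
                            nucleic_threshold = 0.85) {
  format <- match.arg(toupper(format[1]), c("AUTO", "FASTA", "GENBANK", "RAW"))
  lines <- if (length(stream) == 1) strsplit(stream, "\r?\n")[[1]] else stream
  if (!length(lines) || !any(nzchar(trimws(lines)))) stop2("empty input stream")
  if (format == "AUTO") {
    first <- trimws(lines[nzchar(trimws(lines))][1])
    format <- if (startsWith(first, ">")) "FASTA"
              else if (grepl("^LOCUS\\b", first)) "GENBANK"
              else "RAW"
  }
  switch(format,
         FASTA   = parse_fasta(lines, nucleic_threshold),
         GENBANK = parse_genbank(lines, nucleic_threshold),
         RAW     = parse_raw(lines, nucleic_threshold))
}

parse_fasta <- function(lines, nucleic_threshold) {
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop2("no FASTA header ('>') found")
  bounds <- c(hdr, length(lines) + 1L)
  seqs <- vector("list", length(hdr))
  for (k in seq_along(hdr)) {
    header <- sub("^>", "", lines[hdr[k]])
    id <- sub("\\s.*$", "", header)
    desc <- if (grepl("\\s", header)) trimws(sub("^\\S+\\s+", "", header)) else ""
    body <- collapse(lines[seq(hdr[k] + 1L, length.out = bounds[k + 1L] - hdr[k] - 1L)])
    if (!nzchar(clean_residue_text(body))) {
      stop2("FASTA record '", id, "' has an empty body")
    }
    seqs[[k]] <- bioseq(body, id = id, desc = desc,
                        nucleic_threshold = nucleic_threshold)
  }
  seq_collection(seqs)
}

parse_genbank <- function(lines, nucleic_threshold) {
  loci <- grep("^LOCUS\\b", lines)
  if (!length(loci)) stop2("no LOCUS line found in GenBank input")
  bounds <- c(loci, length(lines) + 1L)
  seqs <- vector("list", length(loci))
  for (k in seq_along(loci)) {
    block <- lines[seq(loci[k], bounds[k + 1L] - 1L)]
    toks <- strsplit(trimws(block[1]), "\\s+")[[1]]
    id <- if (length(toks) >= 2) toks[2] else "genbank_record"
    defn <- grep("^DEFINITION", block, value = TRUE)
    desc <- if (length(defn)) trimws(sub("^DEFINITION\\s*", "", defn[1])) else ""
    ori <- grep("^ORIGIN", block)
    if (!length(ori)) stop2("GenBank record '", id, "' has no ORIGIN block")
    end <- grep("^//", block)
    end <- if (length(end)) end[1] else length(block) + 1L
    body <- collapse(block[seq(ori[1] + 1L, length.out = max(0L, end - ori[1] - 1L))])
    if (!nzchar(clean_residue_text(body))) {
      stop2("GenBank record '", id, "' has an empty ORIGIN block")
    }
    seqs[[k]] <- bioseq(body, id = id, desc = desc,
                        nucleic_threshold = nucleic_threshold)
  }
  seq_collection(seqs)
}

parse_raw <- function(lines, nucleic_threshold) {
  seq_collection(list(bioseq(collapse(lines), id = "raw_1",
                             nucleic_threshold = nucleic_threshold)))
}

#' Write sequences as FASTA, GenBank or raw text
#'
#' The writers round-trip with [parse_sequences()]: identifiers and residues
#' are reproduced exactly (for RAW, which carries no identifiers, only the
#' residues of a single-sequence collection round-trip).
#'
#' @param coll a [seq_collection] or single [bioseq].
#' @param format `"FASTA"`, `"GENBANK"` or `"RAW"`.
#' @param line_width wrap width for FASTA bodies (GenBank always uses the
#'   canonical 60-residue lines in 10-residue groups).
#' @return character scalar ending in a newline.
#' @export
write_sequences <- function(coll, format = c("FASTA", "GENBANK", "RAW"),
                            line_width = 60) {
  format <- match.arg(toupper(format[1]), c("FASTA", "GENBANK", "RAW"))
  coll <- as_collection(coll)
  out <- switch(format,
    FASTA = unlist(lapply(coll, function(s) {
      header <- paste0(">", s$id, if (nzchar(s$desc)) paste0(" ", s$desc) else "")
      c(header, wrap_text(seq_text(s), line_width))
    })),
    GENBANK = unlist(lapply(coll, write_genbank_record)),
    RAW = vapply(coll, seq_text, "")
  )
  paste0(collapse(paste0(out, "\n")))
}

wrap_text <- function(txt, width) {
  n <- nchar(txt)
  if (n == 0) return(character())
  starts <- seq(1L, n, by = width)
  substring(txt, starts, pmin(starts + width - 1L, n))
}

write_genbank_record <- function(s) {
  txt <- tolower(seq_text(s))
  n <- nchar(txt)
  unit <- if (s$alphabet == "NUCLEIC") "bp" else "aa"
  mol <- if (s$alphabet == "PROTEIN") "PRT" else if (s$is_rna) "RNA" else "DNA"
  head <- c(
    sprintf("LOCUS       %-16s %d %s    %s     linear", s$id, n, unit, mol),
    if (nzchar(s$desc)) sprintf("DEFINITION  %s", s$desc),
    "ORIGIN"
  )
  starts <- seq(1L, n, by = 60L)
  body <- vapply(starts, function(st) {
    seg <- substr(txt, st, min(st + 59L, n))
    groups <- wrap_text(seg, 10L)
    sprintf("%9d %s", st, paste(groups, collapse = " "))
  }, "")
  c(head, body, "//")
}

#' Read sequences from a file
#'
#' Convenience wrapper around [parse_sequences()].
#'
#' @param path file path ("-" reads standard input).
#' @inheritParams parse_sequences
#' @return a [seq_collection].
#' @export
read_sequences <- function(path, format = "AUTO", nucleic_threshold = 0.85) {
  lines <- if (identical(path, "-")) readLines(file("stdin")) else readLines(path)
  parse_sequences(lines, format, nucleic_threshold)
}

#' Parse a GCG Wisconsin Package codon usage table
#'
#' Accepts the tabular format distributed by the Codon Usage Database: rows of
#' `AmAcid Codon Number /1000 Fraction` (3-letter amino acid, 3-letter codon,
#' three numerics). Header or title lines are tolerated. Codons written with
#' `U` are stored as DNA. Missing codons are filled in with count 0 and the
#' standard-code amino acid; per-amino-acid fractions are renormalized from
#' the stated fractions whenever they do not already sum to 1.
#'
#' @param stream character scalar or vector of lines, or a file path when
#'   `is_path = TRUE`.
#' @param is_path treat `stream` as a file path.
#' @return object of class `codon_usage`: a data frame with columns `codon`,
#'   `aa`, `count`, `per_thousand`, `fraction` (64 rows) and an `organism`
#'   attribute.
#' @export
parse_codon_usage_gcg <- function(stream, is_path = FALSE) {
  lines <- if (is_path) readLines(stream)
           else if (length(stream) == 1) strsplit(stream, "\r?\n")[[1]]
           else stream
  pat <- "^\\s*([A-Za-z*]{3})\\s+([A-Za-z]{3})\\s+([-0-9.eE+]+)\\s+([-0-9.eE+]+)\\s+([-0-9.eE+]+)\\s*$"
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!grepl(pat, ln)) next
    m <- regmatches(ln, regexec(pat, ln))[[1]]
    aa3 <- toupper(m[2])
    codon <- toupper(gsub("U", "T", m[3]))
    if (!grepl("^[ACGT]{3}$", codon)) {
      stop2(sprintf("line %d: '%s' is not a valid codon", i, m[3]))
    }
    aa1 <- AA_THREE_TO_ONE[aa3]
    if (is.na(aa1)) stop2(sprintf("line %d: unknown amino acid '%s'", i, m[2]))
    rows[[length(rows) + 1L]] <- data.frame(
      codon = codon, aa = unname(aa1),
      count = as.numeric(m[4]), per_thousand = as.numeric(m[5]),
      fraction = as.numeric(m[6]), stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop2("no codon usage rows recognised")
  tab <- do.call(rbind, rows)
  if (anyDuplicated(tab$codon)) {
    stop2("duplicate codon '", tab$codon[duplicated(tab$codon)][1],
          "' in usage table")
  }
  code <- standard_genetic_code()
  missing <- setdiff(CODONS_TCAG, tab$codon)
  if (length(missing)) {
    tab <- rbind(tab, data.frame(codon = missing,
                                 aa = unname(code$codon_to_aa[missing]),
                                 count = 0, per_thousand = 0, fraction = 0,
                                 stringsAsFactors = FALSE))
  }
  tab <- tab[match(CODONS_TCAG, tab$codon), , drop = FALSE]
  rownames(tab) <- NULL
  # renormalize fractions within each amino acid
  for (aa in unique(tab$aa)) {
    sel <- tab$aa == aa
    tot <- sum(tab$fraction[sel])
    if (abs(tot - 1) > 1e-6) {
      ctot <- sum(tab$count[sel])
      tab$fraction[sel] <-
        if (tot > 0) tab$fraction[sel] / tot
        else if (ctot > 0) tab$count[sel] / ctot
        else 1 / sum(sel)
    }
  }
  structure(tab, class = c("codon_usage", "data.frame"), organism = NA_character_)
}

#' Parse an NCBI-format substitution matrix
#'
#' Reads the plain-text matrix layout used by NCBI tools (comment lines start
#' with `#`, a header row of residue letters, then one row of scores per
#' residue). A copy of BLOSUM62 ships with the package; see [blosum62()].
#'
#' @param stream character scalar/vector, or a file path with `is_path = TRUE`.
#' @param is_path treat `stream` as a path.
#' @return object of class `subst_matrix`: a symmetric numeric matrix with
#'   residue dimnames.
#' @export
parse_substitution_matrix <- function(stream, is_path = FALSE) {
  lines <- if (is_path) readLines(stream)
           else if (length(stream) == 1) strsplit(stream, "\r?\n")[[1]]
           else stream
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2) stop2("substitution matrix input too short")
  letters <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- length(letters)
  m <- matrix(NA_real_, n, n, dimnames = list(letters, letters))
  for (ln in lines[-1]) {
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(toks) != n + 1) {
      stop2("malformed matrix row: '", ln, "'")
    }
    m[toks[1], ] <- as.numeric(toks[-1])
  }
  if (anyNA(m)) stop2("substitution matrix is missing rows")
  if (!isSymmetric(unname(m))) stop2("substitution matrix is not symmetric")
  structure(m, class = c("subst_matrix", class(m)))
}

#' The BLOSUM62 substitution matrix
#'
#' Loads the packaged copy of the standard BLOSUM62 matrix (half-bit units).
#'
#' @return a `subst_matrix`.
#' @export
blosum62 <- function() {
  parse_substitution_matrix(
    system.file("extdata", "BLOSUM62.txt", package = "seqsuite",
                mustWork = TRUE), is_path = TRUE)
}
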