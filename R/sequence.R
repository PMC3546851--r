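#' Biological sequence objects
#'
#' `bioseq()` constructs a typed biological sequence. Residues are upper-cased
#' and cleaned of whitespace, digits and the characters `\ / |` (frequent in
#' pasted GenBank ORIGIN blocks). The alphabet is either declared or detected
#' with [detect_alphabet()]. RNA input (containing `U`) is stored internally
#' with `T` so that every downstream algorithm has a single code path; the
#' `is_rna` flag restores `U` on output (see [seq_text()]).
#'
#' @param residues character scalar of residue letters (may be mixed case,
#'   may contain whitespace/digits which are stripped).
#' @param id sequence identifier.
#' @param desc free-text description.
#' @param alphabet `"NUCLEIC"`, `"PROTEIN"`, or `NULL` to auto-detect.
#' @param nucleic_threshold fraction of `A/C/G/T/U` characters at or above
#'   which a sequence is classified as nucleic (default 0.85).
#' @return an object of class `bioseq` with fields `id`, `desc`, `residues`
#'   (canonical upper-case, `T` for `U`), `alphabet` and `is_rna`.
#' @examples
#' s <- bioseq("acg tacgt", id = "demo")
#' seq_text(s)
#' @export
bioseq <- function(residues, id = "seq", desc = "", alphabet = NULL,
                   nucleic_threshold = 0.85) {
  txt <- clean_residue_text(residues)
  if (!nzchar(txt)) stop2("empty sequence for '", id, "'")
  if (is.null(alphabet)) {
    alphabet <- detect_alphabet(txt, nucleic_threshold)
  } else {
    alphabet <- match.arg(alphabet, c("NUCLEIC", "PROTEIN"))
    validate_alphabet(txt, alphabet)
  }
  is_rna <- FALSE
  if (alphabet == "NUCLEIC") {
    # RNA only when U appears without T; the rare mixed T/U input is
    # normalised to DNA (restoring U per position would be ill-defined)
    is_rna <- grepl("U", txt, fixed = TRUE) && !grepl("T", txt, fixed = TRUE)
    txt <- gsub("U", "T", txt, fixed = TRUE)
  }
  structure(list(id = as.character(id), desc = as.character(desc),
                 residues = txt, alphabet = alphabet, is_rna = is_rna),
            class = "bioseq")
}

#' @export
print.bioseq <- function(x, ...) {
  n <- nchar(x$residues)
  shown <- if (n > 60) paste0(substr(seq_text(x), 1, 57), "...") else seq_text(x)
  cat(sprintf("<bioseq %s> %s, %d residues%s\n  %s\n", x$id, x$alphabet, n,
              if (x$is_rna) " (RNA)" else "", shown))
  invisible(x)
}

#' Display text of a sequence
#'
#' Returns the residues as the user supplied them: `U` is restored for RNA
#' sequences. All internal computation uses the canonical `$residues` slot.
#'
#' @param x a `bioseq`.
#' @return character scalar.
#' @export
seq_text <- function(x) {
  stopifnot(inherits(x, "bioseq"))
  if (x$is_rna) gsub("T", "U", x$residues, fixed = TRUE) else x$residues
}

#' Detect whether residue text is nucleic or protein
#'
#' A sequence is classified `NUCLEIC` when the fraction of its characters in
#' `{A, C, G, T, U}` (case-insensitive) reaches `nucleic_threshold`, and
#' `PROTEIN` otherwise. Characters outside both the IUPAC nucleotide alphabet
#' and the amino-acid alphabet (20 letters plus `X * -`) are an error.
#'
#' @param text residue text (whitespace/digits are stripped first).
#' @param nucleic_threshold fraction in (0, 1]; default 0.85 tolerates
#'   ambiguity codes and sequencing Ns while still rejecting proteins.
#' @return `"NUCLEIC"` or `"PROTEIN"`.
#' @examples
#' detect_alphabet("ACGTACGT")          # NUCLEIC
#' detect_alphabet("MKLWPERS")          # PROTEIN
#' @export
detect_alphabet <- function(text, nucleic_threshold = 0.85) {
  if (!(nucleic_threshold > 0 && nucleic_threshold <= 1)) {
    stop2("nucleic_threshold must be in (0, 1]")
  }
  txt <- clean_residue_text(text)
  if (!nzchar(txt)) stop2("empty sequence text")
  cs <- chars(txt)
  known <- union(NUCLEIC_LETTERS, PROTEIN_LETTERS)
  bad <- which(!(cs %in% known))
  if (length(bad)) {
    stop2(sprintf("character '%s' at position %d is neither a nucleotide nor an amino-acid code",
                  cs[bad[1]], bad[1]))
  }
  frac <- mean(cs %in% c("A", "C", "G", "T", "U"))
  if (frac >= nucleic_threshold) "NUCLEIC" else "PROTEIN"
}

validate_alphabet <- function(txt, alphabet) {
  cs <- chars(txt)
  ok <- if (alphabet == "NUCLEIC") NUCLEIC_LETTERS else PROTEIN_LETTERS
  bad <- which(!(cs %in% ok))
  if (length(bad)) {
    stop2(sprintf("character '%s' at position %d is not a valid %s residue",
                  cs[bad[1]], bad[1], alphabet))
  }
  invisible(TRUE)
}

#' Sequence collections
#'
#' An ordered list of [bioseq] objects. Serial operations (complement,
#' translation, ...) applied to a collection are defined as the per-member
#' operation applied in order, preserving order.
#'
#' @param ... `bioseq` objects, or a single list of them.
#' @return an object of class `seq_collection`.
#' @export
seq_collection <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && is.list(xs[[1]]) && !inherits(xs[[1]], "bioseq")) {
    xs <- xs[[1]]
  }
  ok <- vapply(xs, inherits, TRUE, what = "bioseq")
  if (!all(ok)) stop2("all members of a seq_collection must be bioseq objects")
  structure(unname(xs), class = "seq_collection")
}

#' @export
print.seq_collection <- function(x, ...) {
  cat(sprintf("<seq_collection of %d sequence(s)>\n", length(x)))
  for (s in x) print(s)
  invisible(x)
}

#' @export
`[.seq_collection` <- function(x, i) {
  structure(unclass(x)[i], class = "seq_collection")
}

as_collection <- function(x) {
  if (inherits(x, "seq_collection")) x
  else if (inherits(x, "bioseq")) seq_collection(list(x))
  else stop2("expected a bioseq or seq_collection")
}

# apply a bioseq -> bioseq function serially; single sequences stay single
map_serial <- function(x, f) {
  if (inherits(x, "bioseq")) return(f(x))
  seq_collection(lapply(as_collection(x), f))
}

complement_string <- function(txt, is_rna = FALSE) {
  out <- collapse(unname(IUB_COMPLEMENT[chars(txt)]))
  if (is_rna) gsub("T", "U", out, fixed = TRUE) else out
}

#' Complement, reverse and reverse-complement
#'
#' IUPAC-aware nucleotide complement (`A<->T/U`, `C<->G`, `R<->Y`, `K<->M`,
#' `B<->V`, `D<->H`; `S W N` are self-complementary). Applying `complement()`
#' or `reverse_complement()` twice returns the original sequence. All three
#' accept a single `bioseq` or a `seq_collection` (applied serially in order).
#'
#' @param x a NUCLEIC `bioseq` or `seq_collection`.
#' @return object of the same shape as `x`.
#' @examples
#' seq_text(complement(bioseq("ACGT")))          # "TGCA"
#' seq_text(reverse_complement(bioseq("AAC")))   # "GTT"
#' @export
complement <- function(x) {
  map_serial(x, function(s) {
    if (s$alphabet != "NUCLEIC") {
      stop2("complement is only defined for NUCLEIC sequences (got PROTEIN for '",
            s$id, "')")
    }
    s$residues <- collapse(unname(IUB_COMPLEMENT[chars(s$residues)]))
    s
  })
}

#' @rdname complement
#' @export
reverse_sequence <- function(x) {
  map_serial(x, function(s) {
    s$residues <- collapse(rev(chars(s$residues)))
    s
  })
}

#' @rdname complement
#' @export
reverse_complement <- function(x) reverse_sequence(complement(x))

# plain-string reverse complement on canonical DNA text (internal fast path)
revcomp_string <- function(txt) {
  collapse(rev(unname(IUB_COMPLEMENT[chars(txt)])))
}

#' Remove duplicates and sort a collection
#'
#' Stable sort of a collection by identifier or by residue string, with
#' duplicates (equal key) reduced to their first occurrence.
#'
#' @param coll a `seq_collection`.
#' @param key `"IDENTIFIER"` or `"RESIDUES"`.
#' @param sort sort the survivors by key (default `TRUE`); with `FALSE` only
#'   deduplication is performed and input order is kept.
#' @return a `seq_collection`.
#' @export
dedupe_and_sort <- function(coll, key = c("IDENTIFIER", "RESIDUES"),
                            sort = TRUE) {
  key <- match.arg(key)
  coll <- as_collection(coll)
  ks <- vapply(coll, function(s)
    if (key == "IDENTIFIER") s$id else s$residues, "")
  keep <- !duplicated(ks)
  coll <- coll[keep]
  ks <- ks[keep]
  if (sort) coll <- coll[order(ks, method = "radix")]
  coll
}
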