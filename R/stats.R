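#' n-gram counts
#'
#' Counts every overlapping window of `n` residues. Counts sum to
#' `length - n + 1`; only observed words are reported.
#'
#' @param seq a [bioseq].
#' @param n word length (must not exceed the sequence length).
#' @return named integer vector (words in alphabetical order).
#' @examples
#' ngram_counts(bioseq("ACGA"), 2)
#' @export
ngram_counts <- function(seq, n) {
  stopifnot(inherits(seq, "bioseq"))
  L <- nchar(seq$residues)
  if (n < 1 || n > L) stop2("n must be between 1 and the sequence length (", L, ")")
  starts <- seq_len(L - n + 1L)
  words <- substring(seq$residues, starts, starts + n - 1L)
  tab <- table(words)
  stats::setNames(as.integer(tab), names(tab))
}

#' Windowed %GC profile
#'
#' Percentage of G/C bases in sliding windows. The ambiguity code `S` (G or C)
#' counts as GC; all other ambiguity codes count 0.
#'
#' @param seq a NUCLEIC [bioseq].
#' @param window window size (<= sequence length).
#' @param step step between window starts (>= 1).
#' @return data frame of class `window_profile` with columns `start` (1-based
#'   window start) and `value` (percentage in `[0, 100]`); `window` and `step`
#'   attributes record the parameters.
#' @examples
#' gc_profile(bioseq("GGCCAT"), window = 2, step = 2)
#' @export
gc_profile <- function(seq, window, step = 1) {
  stopifnot(inherits(seq, "bioseq"))
  if (seq$alphabet != "NUCLEIC") stop2("%GC is only defined for NUCLEIC sequences")
  L <- nchar(seq$residues)
  if (window < 1 || window > L) stop2("window must be between 1 and the sequence length")
  if (step < 1) stop2("step must be >= 1")
  is_gc <- chars(seq$residues) %in% c("G", "C", "S")
  cum <- c(0L, cumsum(is_gc))
  starts <- seq(1L, L - window + 1L, by = step)
  vals <- 100 * (cum[starts + window] - cum[starts]) / window
  structure(data.frame(start = starts, value = vals),
            class = c("window_profile", "data.frame"),
            window = window, step = step)
}

#' GRAVY score (grand average of hydropathy)
#'
#' Mean Kyte-Doolittle hydropathy over the 20 standard residues; `X`, `*` and
#' `-` are excluded from both numerator and denominator.
#'
#' @param prot a PROTEIN [bioseq].
#' @return numeric scalar in `[-4.5, 4.5]`.
#' @export
gravy <- function(prot) {
  stopifnot(inherits(prot, "bioseq"))
  if (prot$alphabet != "PROTEIN") stop2("GRAVY is only defined for PROTEIN sequences")
  h <- KYTE_DOOLITTLE[chars(prot$residues)]
  h <- h[!is.na(h)]
  if (!length(h)) stop2("no standard amino-acid residues in '", prot$id, "'")
  mean(h)
}

#' Amino-acid composition
#'
#' Percentage of each of the 20 standard residues among the standard residues
#' of the sequence.
#'
#' @param prot a PROTEIN [bioseq].
#' @return named numeric vector (20 entries, sums to 100).
#' @export
aa_composition <- function(prot) {
  stopifnot(inherits(prot, "bioseq"))
  if (prot$alphabet != "PROTEIN") stop2("composition is only defined for PROTEIN sequences")
  cs <- chars(prot$residues)
  cs <- cs[cs %in% AMINO_ACIDS]
  if (!length(cs)) stop2("no standard amino-acid residues in '", prot$id, "'")
  counts <- table(factor(cs, levels = AMINO_ACIDS))
  stats::setNames(100 * as.numeric(counts) / length(cs), AMINO_ACIDS)
}
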