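# Deterministic synthetic-data generators. These define the test surface:
# planted-motif collections for discovery benchmarks and random genomes with
# known ORFs or dyads for the search tools. All generators are pure functions
# of their arguments (seed included).

sample_background <- function(n, dist) {
  collapse(sample(names(dist), n, replace = TRUE, prob = dist))
}

#' Generate sequences with one planted motif instance each
#'
#' Background residues are drawn i.i.d. from `background`; exactly one motif
#' instance is inserted per sequence (overwriting the background), either the
#' literal `motif` string or a sample from a [psfm]. The returned truth table
#' records the planted position and strand of every instance, for recovery
#' scoring.
#'
#' @param n_sequences number of sequences.
#' @param length length of each sequence.
#' @param motif motif string (DNA or protein) or a `psfm` to sample sites from.
#' @param positions optional explicit 1-based start positions (recycled);
#'   `NULL` draws them uniformly.
#' @param strand `"forward"` plants all instances on the given strand;
#'   `"both"` reverse-complements each instance with probability 1/2 (DNA
#'   only).
#' @param background named residue distribution; `NULL` = uniform over the
#'   unambiguous alphabet of the motif.
#' @param seed RNG seed.
#' @param id_prefix identifier prefix for the generated sequences.
#' @return list with `sequences` (a [seq_collection]) and `truth` (data frame
#'   `sequence_id`, `position`, `strand`, `site`).
#' @export
generate_planted <- function(n_sequences, length, motif, positions = NULL,
                             strand = c("forward", "both"), background = NULL,
                             seed = 0, id_prefix = "seq") {
  strand <- match.arg(strand)
  from_psfm <- inherits(motif, "psfm")
  w <- if (from_psfm) motif$width else nchar(motif)
  if (length < w) stop2("sequence length must be >= motif width")
  letters <- if (from_psfm) {
    motif$letters
  } else {
    txt <- clean_residue_text(motif)
    if (all(chars(txt) %in% DNA_BASES)) DNA_BASES else AMINO_ACIDS
  }
  nucleic <- identical(letters, DNA_BASES)
  if (strand == "both" && !nucleic) stop2("strand = 'both' requires a DNA motif")
  bg <- check_background(background, letters)
  if (!is.null(positions)) {
    positions <- rep_len(as.integer(positions), n_sequences)
    if (any(positions < 1 | positions > length - w + 1)) {
      stop2("planted positions leave no room for the motif")
    }
  }
  with_seed(seed, {
    pos <- positions %||% sample.int(length - w + 1L, n_sequences, replace = TRUE)
    strands <- if (strand == "both") {
      sample(c("+", "-"), n_sequences, replace = TRUE)
    } else rep("+", n_sequences)
    seqs <- vector("list", n_sequences)
    sites <- character(n_sequences)
    for (i in seq_len(n_sequences)) {
      bgtxt <- chars(sample_background(length, bg))
      site <- if (from_psfm) {
        collapse(vapply(seq_len(w), function(j)
          sample(letters, 1L, prob = motif$matrix[, j]), ""))
      } else clean_residue_text(motif)
      inserted <- if (strands[i] == "-") revcomp_string(site) else site
      bgtxt[pos[i]:(pos[i] + w - 1L)] <- chars(inserted)
      seqs[[i]] <- bioseq(collapse(bgtxt), id = paste0(id_prefix, i),
                          alphabet = if (nucleic) "NUCLEIC" else "PROTEIN")
      sites[i] <- site
    }
    list(sequences = seq_collection(seqs),
         truth = data.frame(sequence_id = paste0(id_prefix, seq_len(n_sequences)),
                            position = pos, strand = strands, site = sites,
                            stringsAsFactors = FALSE))
  })
}

#' Generate a random genome-like sequence with optional planted features
#'
#' Draws bases i.i.d. with the requested GC fraction (split evenly between G
#' and C, and between A and T). ORFs (`ATG`, random stop-free codons, `TAA`)
#' and dyads (half-site + spacer + direct/inverted half-site) can be planted
#' at recorded positions; every planted feature is returned in the truth
#' table.
#'
#' @param length sequence length.
#' @param gc_fraction target GC content in `[0, 1]`.
#' @param seed RNG seed.
#' @param orf optional list or list-of-lists with fields `start` and
#'   `length_nt` (divisible by 3, >= 9).
#' @param dyad optional list or list-of-lists with fields `start`, `half`
#'   (half-site string), `spacer` and `inverted` (logical, default TRUE).
#' @param id identifier of the generated sequence.
#' @return list with `sequence` (a [bioseq]) and `truth` (data frame
#'   `feature`, `start`, `end`, `detail`).
#' @export
generate_random_genome <- function(length, gc_fraction = 0.5, seed = 0,
                                   orf = NULL, dyad = NULL, id = "genome") {
  if (gc_fraction < 0 || gc_fraction > 1) stop2("gc_fraction must be in [0, 1]")
  bg <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
          G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  as_list_of_lists <- function(x) {
    if (is.null(x)) list() else if (!is.null(names(x))) list(x) else x
  }
  orfs <- as_list_of_lists(orf)
  dyads <- as_list_of_lists(dyad)
  with_seed(seed, {
    cs <- chars(sample_background(length, bg))
    truth <- list()
    # codons free of stops and of ATG (so the planted ORF is the whole hit)
    safe_codons <- setdiff(CODONS_TCAG,
                           c("TAA", "TAG", "TGA", "ATG"))
    for (o in orfs) {
      len <- o$length_nt
      if (len %% 3 != 0 || len < 9) stop2("planted ORF length must be >= 9 and divisible by 3")
      if (o$start < 1 || o$start + len - 1 > length) stop2("planted ORF out of range")
      body <- collapse(sample(safe_codons, len / 3 - 2, replace = TRUE))
      ins <- paste0("ATG", body, "TAA")
      cs[o$start:(o$start + len - 1L)] <- chars(ins)
      truth[[length(truth) + 1L]] <- data.frame(
        feature = "orf", start = o$start, end = o$start + len - 1L,
        detail = ins, stringsAsFactors = FALSE)
    }
    for (d in dyads) {
      half <- clean_residue_text(d$half)
      inverted <- d$inverted %||% TRUE
      other <- if (inverted) revcomp_string(half) else half
      spacer_txt <- sample_background(d$spacer, bg)
      ins <- paste0(half, spacer_txt, other)
      if (d$start < 1 || d$start + nchar(ins) - 1 > length) {
        stop2("planted dyad out of range")
      }
      cs[d$start:(d$start + nchar(ins) - 1L)] <- chars(ins)
      truth[[length(truth) + 1L]] <- data.frame(
        feature = if (inverted) "inverted_dyad" else "direct_dyad",
        start = d$start, end = d$start + nchar(ins) - 1L,
        detail = ins, stringsAsFactors = FALSE)
    }
    truth_df <- if (length(truth)) do.call(rbind, truth) else
      data.frame(feature = character(), start = integer(), end = integer(),
                 detail = character(), stringsAsFactors = FALSE)
    list(sequence = bioseq(collapse(cs), id = id, alphabet = "NUCLEIC"),
         truth = truth_df)
  })
}
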