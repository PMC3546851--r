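#' Position-specific frequency matrices
#'
#' A PSFM stores, for each motif position, a probability distribution over the
#' residue alphabet together with the background distribution it is scored
#' against. `psfm_from_sites()` estimates it from an aligned collection of
#' equal-length sites with optional pseudocounts:
#' `f(b, j) = (count(b, j) + alpha * p(b)) / (n + alpha)`.
#' `psfm_from_consensus()` builds one from an IUPAC consensus string, putting
#' uniform mass on each position's expansion.
#'
#' @param sites a [seq_collection] of equal-length, same-alphabet sequences.
#' @param pseudocount total pseudocount `alpha`, distributed by the background.
#' @param background named probability vector over the alphabet letters;
#'   `NULL` means uniform.
#' @return object of class `psfm` with fields `matrix` (letters x width),
#'   `letters`, `alphabet`, `width`, `background`, `pseudocount`, `n_sites`.
#' @examples
#' sites <- seq_collection(bioseq("ACGT", "a"), bioseq("ACGT", "b"))
#' psfm_from_sites(sites, pseudocount = 0)
#' @export
psfm_from_sites <- function(sites, pseudocount = 0, background = NULL) {
  sites <- as_collection(sites)
  if (!length(sites)) stop2("no sites given")
  lens <- vapply(sites, function(s) nchar(s$residues), 0L)
  if (length(unique(lens)) != 1) {
    bad <- vapply(sites[lens != lens[1]], function(s) s$id, "")
    stop2("sites have unequal lengths (offenders: ",
          paste(bad, collapse = ", "), ")")
  }
  alph <- unique(vapply(sites, function(s) s$alphabet, ""))
  if (length(alph) != 1) stop2("sites mix NUCLEIC and PROTEIN alphabets")
  letters <- if (alph == "NUCLEIC") DNA_BASES else AMINO_ACIDS
  w <- lens[1]
  n <- length(sites)
  bg <- check_background(background, letters)
  counts <- matrix(0, length(letters), w, dimnames = list(letters, NULL))
  for (s in sites) {
    cs <- chars(s$residues)
    if (!all(cs %in% letters)) {
      stop2("site '", s$id, "' contains residues outside the unambiguous alphabet")
    }
    counts[cbind(match(cs, letters), seq_len(w))] <-
      counts[cbind(match(cs, letters), seq_len(w))] + 1
  }
  f <- (counts + pseudocount * bg) / (n + pseudocount)
  new_psfm(f, letters, alph, bg, pseudocount, n)
}

check_background <- function(background, letters) {
  if (is.null(background)) {
    return(stats::setNames(rep(1 / length(letters), length(letters)), letters))
  }
  if (is.null(names(background)) || !setequal(names(background), letters)) {
    stop2("background must be named with exactly the alphabet letters")
  }
  bg <- background[letters]
  if (abs(sum(bg) - 1) > 1e-6 || any(bg < 0)) {
    stop2("background must be a probability distribution")
  }
  bg
}

new_psfm <- function(f, letters, alphabet, bg, pseudocount, n_sites) {
  stopifnot(all(abs(colSums(f) - 1) < 1e-9))
  structure(list(matrix = f, letters = letters, alphabet = alphabet,
                 width = ncol(f), background = bg,
                 pseudocount = pseudocount, n_sites = n_sites),
            class = "psfm")
}

#' @rdname psfm_from_sites
#' @param consensus IUPAC consensus string (NUCLEIC alphabet).
#' @export
psfm_from_consensus <- function(consensus, pseudocount = 0, background = NULL) {
  txt <- clean_residue_text(consensus)
  txt <- gsub("U", "T", txt, fixed = TRUE)
  cs <- chars(txt)
  bad <- which(!(cs %in% names(IUB_EXPANSION)))
  if (length(bad)) {
    stop2(sprintf("invalid IUPAC character '%s' at position %d", cs[bad[1]], bad[1]))
  }
  bg <- check_background(background, DNA_BASES)
  f <- vapply(cs, function(ch) {
    col <- stats::setNames(rep(0, 4), DNA_BASES)
    ex <- IUB_EXPANSION[[ch]]
    col[ex] <- 1 / length(ex)
    col
  }, numeric(4))
  f <- (f + pseudocount * bg) / (1 + pseudocount)
  dimnames(f) <- list(DNA_BASES, NULL)
  new_psfm(f, DNA_BASES, "NUCLEIC", bg, pseudocount, 0L)
}

#' @export
print.psfm <- function(x, digits = 3, ...) {
  cat(sprintf("<psfm %s, width %d, %d site(s), pseudocount %g>\n",
              x$alphabet, x$width, x$n_sites, x$pseudocount))
  print(round(x$matrix, digits))
  invisible(x)
}

#' Per-position information content of a PSFM
#'
#' `MUTUAL_INFO` measures conservation as `log2 |A| - H(j)` where `H(j)` is
#' the Shannon entropy of column `j` (with `0 log 0 = 0`); the maximum is 2
#' bits for DNA and `log2 20` for protein. `REL_ENTROPY` is the
#' Kullback-Leibler divergence from the background,
#' `sum_b f(b,j) log2(f(b,j)/p(b))`. The two coincide for a uniform
#' background.
#'
#' @param psfm a [psfm].
#' @param method `"MUTUAL_INFO"` or `"REL_ENTROPY"`.
#' @return list with `per_position` (bits, length `width`) and `total`.
#' @examples
#' p <- psfm_from_consensus("ACGT")
#' information_content(p)$total   # 8 bits: four fully conserved DNA columns
#' @export
information_content <- function(psfm, method = c("MUTUAL_INFO", "REL_ENTROPY")) {
  method <- match.arg(method)
  f <- psfm$matrix
  if (method == "MUTUAL_INFO") {
    h <- apply(f, 2, function(col) {
      nz <- col > 0
      -sum(col[nz] * log2(col[nz]))
    })
    per <- log2(length(psfm$letters)) - h
  } else {
    p <- psfm$background
    if (any(p == 0 & rowSums(f > 0) > 0)) {
      stop2("relative entropy undefined: zero background for an observed residue")
    }
    per <- apply(f, 2, function(col) {
      nz <- col > 0
      sum(col[nz] * log2(col[nz] / p[nz]))
    })
  }
  list(per_position = unname(per), total = sum(per))
}

#' Text consensus logo
#'
#' Renders a motif as its consensus string plus a fixed-row text grid in which
#' the consensus letter of each position is placed at the row proportional to
#' that position's information content, with a vertical-bar y-axis whose
#' maximum (2 bits for DNA, `log2 20` for protein) is printed at the top.
#' This conveys positional conservation in plain text, the role sequence
#' logos play graphically.
#'
#' @param psfm a [psfm].
#' @param method information measure, see [information_content()].
#' @param rows number of grid rows (>= 2).
#' @return object of class `consensus_logo` with fields `consensus`,
#'   `heights` (bits per position), `max_bits` and `rendering` (character
#'   vector of lines: grid, axis, consensus).
#' @export
render_consensus_logo <- function(psfm, method = c("MUTUAL_INFO", "REL_ENTROPY"),
                                  rows = 10) {
  method <- match.arg(method)
  if (rows < 2) stop2("rows must be >= 2")
  ic <- information_content(psfm, method)$per_position
  max_bits <- log2(length(psfm$letters))
  cons <- consensus_string(psfm)
  lvl <- pmin(pmax(round(ic / max_bits * rows), 1L), rows)
  grid <- matrix(" ", rows, psfm$width)
  grid[cbind(rows - lvl + 1L, seq_len(psfm$width))] <- chars(cons)
  scale_lab <- as.character(round(max_bits, 2))
  pad <- nchar(scale_lab)
  lines <- vapply(seq_len(rows), function(r) {
    lab <- if (r == 1) scale_lab else strrep(" ", pad)
    paste0(lab, "|", collapse(grid[r, ]))
  }, "")
  lines <- c(lines, paste0(strrep(" ", pad), "+", strrep("-", psfm$width)),
             paste0(strrep(" ", pad), " ", cons))
  structure(list(consensus = cons, heights = ic, max_bits = max_bits,
                 rendering = lines),
            class = "consensus_logo")
}

#' @export
print.consensus_logo <- function(x, ...) {
  cat(paste(x$rendering, collapse = "\n"), "\n")
  invisible(x)
}

# argmax residue per column, ties broken by alphabet order
consensus_string <- function(psfm) {
  collapse(psfm$letters[apply(psfm$matrix, 2, which.max)])
}
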