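# Pairwise alignment by dynamic programming with a linear (per-gap-character)
# gap penalty. The DP is filled row-wise; within a row the left-moving chain
# H[i,j] = max_k (V[k] + gap*(j-k)) is resolved with a running cummax, which
# keeps the fill vectorised. Traceback pointers are recovered from the score
# matrix itself with the fixed tie order DIAG > UP > LEFT.

pair_score_matrix <- function(a, b, scoring) {
  ac <- chars(a); bc <- chars(b)
  if (inherits(scoring, "subst_matrix") || is.matrix(scoring)) {
    miss <- setdiff(c(ac, bc), rownames(scoring))
    if (length(miss)) {
      stop2("residue '", miss[1], "' is not covered by the substitution matrix")
    }
    outer(ac, bc, function(x, y) scoring[cbind(x, y)])
  } else {
    match_s <- scoring[["match"]]
    mismatch_s <- scoring[["mismatch"]]
    outer(ac, bc, function(x, y) ifelse(x == y, match_s, mismatch_s))
  }
}

fill_dp <- function(S, gap, local) {
  n <- nrow(S); m <- ncol(S)
  H <- matrix(0, n + 1L, m + 1L)
  if (!local) {
    H[1, ] <- gap * (0:m)
    H[, 1] <- gap * (0:n)
  }
  ks <- seq_len(m + 1L)
  for (i in 2:(n + 1L)) {
    diag_up <- pmax(H[i - 1L, 1:m] + S[i - 1L, ], H[i - 1L, 2:(m + 1L)] + gap)
    V <- c(H[i, 1L], diag_up)
    H[i, ] <- gap * ks + cummax(V - gap * ks)
    if (local) H[i, ] <- pmax(H[i, ], 0)
  }
  H
}

traceback <- function(H, S, gap, a, b, local, start_cell = NULL) {
  i <- if (local) start_cell[1] else nrow(H)
  j <- if (local) start_cell[2] else ncol(H)
  end_a <- i - 1L; end_b <- j - 1L
  ac <- chars(a); bc <- chars(b)
  ra <- character(); rb <- character()
  repeat {
    if (local && H[i, j] == 0) break
    if (!local && i == 1L && j == 1L) break
    if (i > 1L && j > 1L &&
        abs(H[i, j] - (H[i - 1L, j - 1L] + S[i - 1L, j - 1L])) < 1e-9) {
      ra <- c(ac[i - 1L], ra); rb <- c(bc[j - 1L], rb)
      i <- i - 1L; j <- j - 1L
    } else if (i > 1L && abs(H[i, j] - (H[i - 1L, j] + gap)) < 1e-9) {
      ra <- c(ac[i - 1L], ra); rb <- c("-", rb)
      i <- i - 1L
    } else if (j > 1L && abs(H[i, j] - (H[i, j - 1L] + gap)) < 1e-9) {
      ra <- c("-", ra); rb <- c(bc[j - 1L], rb)
      j <- j - 1L
    } else {
      stop2("traceback failed (inconsistent DP matrix)")   # should not happen
    }
  }
  list(aligned_a = collapse(ra), aligned_b = collapse(rb),
       start_a = i, start_b = j, end_a = end_a, end_b = end_b)
}

new_alignment <- function(tb, score, mode, a, b, scoring, gap) {
  la <- chars(tb$aligned_a); lb <- chars(tb$aligned_b)
  ident <- if (length(la)) mean(la == lb & la != "-") else NA_real_
  structure(list(aligned_a = tb$aligned_a, aligned_b = tb$aligned_b,
                 score = score, mode = mode,
                 start_a = tb$start_a, start_b = tb$start_b,
                 end_a = tb$end_a, end_b = tb$end_b,
                 identity_fraction = ident,
                 id_a = a$id, id_b = b$id, scoring = scoring, gap = gap),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, width = 60, ...) {
  cat(sprintf("<%s alignment: %s vs %s, score %g, identity %.1f%%>\n",
              x$mode, x$id_a, x$id_b, x$score, 100 * x$identity_fraction))
  la <- chars(x$aligned_a); lb <- chars(x$aligned_b)
  if (!length(la)) {
    cat("(empty alignment)\n")
    return(invisible(x))
  }
  mid <- ifelse(la == lb & la != "-", "|", " ")
  for (st in seq(1, length(la), by = width)) {
    en <- min(st + width - 1L, length(la))
    cat(collapse(la[st:en]), "\n", collapse(mid[st:en]), "\n",
        collapse(lb[st:en]), "\n\n", sep = "")
  }
  invisible(x)
}

prep_align_pair <- function(a, b) {
  if (!inherits(a, "bioseq")) a <- bioseq(a, id = "a")
  if (!inherits(b, "bioseq")) b <- bioseq(b, id = "b")
  if (a$alphabet != b$alphabet) {
    stop2("cannot align a ", a$alphabet, " sequence with a ", b$alphabet, " one")
  }
  list(a = a, b = b)
}

resolve_scoring <- function(scoring, match, mismatch) {
  if (!is.null(scoring)) scoring else list(match = match, mismatch = mismatch)
}

#' Global pairwise alignment (Needleman-Wunsch)
#'
#' Optimal global alignment under a substitution matrix or match/mismatch
#' scores and a linear gap penalty (`gap` per gap character). Traceback ties
#' are broken in the fixed order diagonal > up > left, so results are
#' deterministic.
#'
#' @param a,b [bioseq] objects (or residue strings) of the same alphabet.
#' @param scoring optional `subst_matrix` (e.g. [blosum62()]); when `NULL`,
#'   `match`/`mismatch` scores are used.
#' @param match,mismatch scores used when no matrix is given.
#' @param gap penalty per gap character (negative).
#' @return object of class `alignment_result`: `aligned_a`/`aligned_b` (gapped
#'   texts), `score`, 1-based `start_*`/`end_*` spans and `identity_fraction`.
#' @examples
#' needleman_wunsch(bioseq("GATTACA"), bioseq("GCATGCT"))
#' @export
needleman_wunsch <- function(a, b, scoring = NULL, match = 1, mismatch = -1,
                             gap = -2) {
  p <- prep_align_pair(a, b)
  sc <- resolve_scoring(scoring, match, mismatch)
  S <- pair_score_matrix(p$a$residues, p$b$residues, sc)
  H <- fill_dp(S, gap, local = FALSE)
  tb <- traceback(H, S, gap, p$a$residues, p$b$residues, local = FALSE)
  tb$start_a <- 1L; tb$start_b <- 1L
  new_alignment(tb, H[nrow(H), ncol(H)], "global", p$a, p$b, sc, gap)
}

#' Local pairwise alignment (Smith-Waterman)
#'
#' Optimal local alignment; the score is always >= 0 and the empty alignment
#' (score 0) is allowed when no positively scoring segment pair exists.
#'
#' @inheritParams needleman_wunsch
#' @return an `alignment_result`; for an empty alignment the aligned texts are
#'   empty and the span fields are `NA`.
#' @export
smith_waterman <- function(a, b, scoring = NULL, match = 1, mismatch = -1,
                           gap = -2) {
  p <- prep_align_pair(a, b)
  sc <- resolve_scoring(scoring, match, mismatch)
  S <- pair_score_matrix(p$a$residues, p$b$residues, sc)
  H <- fill_dp(S, gap, local = TRUE)
  best <- max(H)
  if (best <= 0) {
    tb <- list(aligned_a = "", aligned_b = "", start_a = NA_integer_,
               start_b = NA_integer_, end_a = NA_integer_, end_b = NA_integer_)
    return(new_alignment(tb, 0, "local", p$a, p$b, sc, gap))
  }
  cell <- which(H == best, arr.ind = TRUE)[1, ]   # first by column-major order
  tb <- traceback(H, S, gap, p$a$residues, p$b$residues, local = TRUE,
                  start_cell = cell)
  new_alignment(tb, best, "local", p$a, p$b, sc, gap)
}

#' Recompute an alignment's score from its aligned texts
#'
#' Sums substitution and gap contributions over the aligned columns; used to
#' verify that a reported score is consistent with its traceback.
#'
#' @param aln an `alignment_result`.
#' @return numeric score.
#' @export
alignment_score_from_traceback <- function(aln) {
  la <- chars(aln$aligned_a); lb <- chars(aln$aligned_b)
  if (!length(la)) return(0)
  sc <- aln$scoring
  total <- 0
  for (k in seq_along(la)) {
    total <- total + if (la[k] == "-" || lb[k] == "-") {
      aln$gap
    } else if (inherits(sc, "subst_matrix") || is.matrix(sc)) {
      sc[la[k], lb[k]]
    } else if (la[k] == lb[k]) sc$match else sc$mismatch
  }
  total
}
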