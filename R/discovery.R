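# Motif discovery: Gibbs site sampling and greedy search over a collection of
# unaligned sequences, one site per sequence, plus string-based dyad (direct /
# inverted repeat) discovery on a single sequence.

# integer residue indices for a canonical residue string (unambiguous letters
# only; discovery models have no column for ambiguity codes)
seq_to_idx <- function(txt, letters) {
  idx <- match(chars(txt), letters)
  if (anyNA(idx)) {
    stop2("sequence contains ambiguity codes; motif discovery needs unambiguous residues")
  }
  idx
}

# candidate windows of width w as an (n_windows x w) integer matrix, plus the
# 1-based forward start and strand of each row
candidate_windows <- function(idx, w, letters, both_strands = FALSE) {
  L <- length(idx)
  nw <- L - w + 1L
  wm <- vapply(seq_len(w), function(j) idx[j:(j + nw - 1L)], integer(nw))
  if (nw == 1L) wm <- matrix(wm, 1L, w)
  starts <- seq_len(nw)
  strands <- rep("+", nw)
  if (both_strands) {
    comp_idx <- match(IUB_COMPLEMENT[letters], letters)   # DNA only
    ridx <- rev(comp_idx[idx])
    rm_ <- vapply(seq_len(w), function(j) ridx[j:(j + nw - 1L)], integer(nw))
    if (nw == 1L) rm_ <- matrix(rm_, 1L, w)
    wm <- rbind(wm, rm_)
    starts <- c(starts, as.integer(L - w + 2L - seq_len(nw)))
    strands <- c(strands, rep("-", nw))
  }
  list(windows = wm, start = starts, strand = strands)
}

onehot_counts <- function(window_row, n_letters, w) {
  m <- matrix(0, n_letters, w)
  m[cbind(window_row, seq_len(w))] <- 1
  m
}

# total information content (bits) of a count matrix holding n sites
ic_from_counts <- function(counts, n, method, bg) {
  f <- counts / n
  if (method == "MUTUAL_INFO") {
    lf <- f * log2(f)
    lf[counts == 0] <- 0
    log2(nrow(counts)) * ncol(counts) + sum(lf)
  } else {
    lf <- f * log2(f / bg)
    lf[counts == 0] <- 0
    sum(lf)
  }
}

finish_motif <- function(coll, w, pos, strand, method, iterations) {
  site_seqs <- lapply(seq_along(coll), function(i) {
    s <- coll[[i]]
    win <- substr(s$residues, pos[i], pos[i] + w - 1L)
    if (strand[i] == "-") win <- revcomp_string(win)
    bioseq(win, id = s$id, alphabet = s$alphabet)
  })
  p <- psfm_from_sites(seq_collection(site_seqs), pseudocount = 0)
  ic <- information_content(p, method)
  structure(list(
    psfm = p,
    sites = data.frame(sequence_id = vapply(coll, function(s) s$id, ""),
                       start = pos, strand = strand, stringsAsFactors = FALSE),
    site_sequences = seq_collection(site_seqs),
    information_content = ic$total,
    method = method, width = w, iterations_run = iterations),
    class = "motif_result")
}

#' @export
print.motif_result <- function(x, ...) {
  cat(sprintf("<motif_result width %d, %.3f bits (%s), %d iteration(s)>\n",
              x$width, x$information_content, x$method, x$iterations_run))
  cat("consensus:", consensus_string(x$psfm), "\n")
  invisible(x)
}

check_discovery_input <- function(coll, w, iterations) {
  coll <- as_collection(coll)
  if (!length(coll)) stop2("empty collection")
  if (iterations < 1) stop2("iterations must be >= 1")
  lens <- vapply(coll, function(s) nchar(s$residues), 0L)
  if (w > min(lens)) {
    stop2("motif width ", w, " exceeds the shortest sequence (", min(lens), ")")
  }
  alph <- unique(vapply(coll, function(s) s$alphabet, ""))
  if (length(alph) != 1) stop2("collection mixes alphabets")
  coll
}

#' Motif discovery by Gibbs site sampling
#'
#' Assumes one motif instance per sequence. Each restart initialises the site
#' positions at random, then repeatedly holds out one sequence (round-robin),
#' builds a pseudocount-smoothed PSFM from the remaining sites and resamples
#' the held-out sequence's site with probability proportional to
#' `prod_j f(s_j, j) / p(s_j)`. The reported motif is the site configuration
#' with the largest information content seen across all restarts and steps.
#'
#' @param coll a [seq_collection] of DNA or protein sequences.
#' @param w motif width (at most the shortest sequence length).
#' @param iterations number of random restarts.
#' @param inner_steps sampling steps per restart (default `100 * n` sequences).
#' @param seed RNG seed; fixed seed gives an identical result.
#' @param method information measure used to rank configurations
#'   (`"MUTUAL_INFO"` or `"REL_ENTROPY"`).
#' @param pseudocount smoothing added (background-distributed) to the hold-out
#'   PSFM; default 1.
#' @param background named background distribution (`NULL` = uniform).
#' @param both_strands also consider reverse-complement windows (DNA only);
#'   default searches the given strand only.
#' @return object of class `motif_result`: the final `psfm` (built without
#'   pseudocounts from the chosen sites), the per-sequence `sites` (start,
#'   strand), `information_content` in bits and `iterations_run`.
#' @export
gibbs_sample <- function(coll, w, iterations = 20, inner_steps = NULL,
                         seed = 0, method = c("MUTUAL_INFO", "REL_ENTROPY"),
                         pseudocount = 1, background = NULL,
                         both_strands = FALSE) {
  method <- match.arg(method)
  coll <- check_discovery_input(coll, w, iterations)
  n <- length(coll)
  inner_steps <- inner_steps %||% (100L * n)
  letters <- if (coll[[1]]$alphabet == "NUCLEIC") DNA_BASES else AMINO_ACIDS
  nl <- length(letters)
  bg <- check_background(background, letters)
  cand <- lapply(coll, function(s)
    candidate_windows(seq_to_idx(s$residues, letters), w, letters, both_strands))
  ncand <- vapply(cand, function(x) nrow(x$windows), 0L)
  best <- list(ic = -Inf, rowsel = NULL)
  with_seed(seed, {
    for (r in seq_len(iterations)) {
      rowsel <- vapply(ncand, function(k) sample.int(k, 1L), 0L)
      counts <- Reduce(`+`, lapply(seq_len(n), function(i)
        onehot_counts(cand[[i]]$windows[rowsel[i], ], nl, w)))
      ic <- ic_from_counts(counts, n, method, bg)
      if (ic > best$ic) best <- list(ic = ic, rowsel = rowsel)
      if (n == 1L) next   # degenerate: the initial sample is the motif
      for (t in seq_len(inner_steps)) {
        h <- ((t - 1L) %% n) + 1L
        cm <- counts - onehot_counts(cand[[h]]$windows[rowsel[h], ], nl, w)
        f <- (cm + pseudocount * bg) / (n - 1L + pseudocount)
        lw <- log(f) - log(bg)
        wts <- exp(.rowSums(lw[cbind(as.vector(cand[[h]]$windows),
                                     rep(seq_len(w), each = ncand[h]))],
                            ncand[h], w))
        rowsel[h] <- sample.int(ncand[h], 1L, prob = wts)
        counts <- cm + onehot_counts(cand[[h]]$windows[rowsel[h], ], nl, w)
        ic <- ic_from_counts(counts, n, method, bg)
        if (ic > best$ic) best <- list(ic = ic, rowsel = rowsel)
        # phase-shift move after every full round-robin pass: sliding all
        # sites one position left/right escapes the shifted local optima
        # plain site samplers are prone to
        if (t %% n == 0L) {
          for (delta in c(-1L, 1L)) {
            shifted <- shift_rowsel(rowsel, delta, cand, ncand)
            if (is.null(shifted)) next
            cs <- Reduce(`+`, lapply(seq_len(n), function(i)
              onehot_counts(cand[[i]]$windows[shifted[i], ], nl, w)))
            ics <- ic_from_counts(cs, n, method, bg)
            if (ics > ic) {
              rowsel <- shifted
              counts <- cs
              ic <- ics
              if (ic > best$ic) best <- list(ic = ic, rowsel = rowsel)
            }
          }
        }
      }
    }
  })
  pos <- vapply(seq_len(n), function(i) cand[[i]]$start[best$rowsel[i]], 0L)
  str <- vapply(seq_len(n), function(i) cand[[i]]$strand[best$rowsel[i]], "")
  finish_motif(coll, w, pos, str, method, iterations)
}

# shift every site's forward start by delta, staying on its strand; NULL when
# any site would fall off its sequence
shift_rowsel <- function(rowsel, delta, cand, ncand) {
  out <- integer(length(rowsel))
  for (i in seq_along(rowsel)) {
    n_fwd <- sum(cand[[i]]$strand == "+")
    r <- rowsel[i]
    nr <- if (r <= n_fwd) r + delta else r - delta   # minus-strand rows run backwards
    on_fwd <- r <= n_fwd
    if (on_fwd && (nr < 1L || nr > n_fwd)) return(NULL)
    if (!on_fwd && (nr <= n_fwd || nr > ncand[i])) return(NULL)
    out[i] <- nr
  }
  out
}

# column-wise IC lookup: entry [b, j] is the total IC if a site with letter b
# at column j is added to `counts` (n_new sites after addition)
ic_addition_table <- function(counts, n_new, method, bg) {
  nl <- nrow(counts); w <- ncol(counts)
  tab <- matrix(0, nl, w)
  for (j in seq_len(w)) {
    col <- counts[, j]
    for (b in seq_len(nl)) {
      cb <- col
      cb[b] <- cb[b] + 1
      f <- cb / n_new
      nz <- cb > 0
      tab[b, j] <- if (method == "MUTUAL_INFO") {
        log2(nl) + sum(f[nz] * log2(f[nz]))
      } else {
        sum(f[nz] * log2(f[nz] / bg[nz]))
      }
    }
  }
  tab
}

# best candidate row by summed column IC contributions; ties -> first row
best_candidate <- function(windows, tab) {
  nw <- nrow(windows); w <- ncol(windows)
  sc <- .rowSums(tab[cbind(as.vector(windows), rep(seq_len(w), each = nw))],
                 nw, w)
  which.max(sc)
}

#' Motif discovery by greedy search
#'
#' Each restart shuffles the sequence order, seeds the alignment with a random
#' window from the first sequence, then adds, for each subsequent sequence,
#' the window that maximises the information content of the growing alignment.
#' Refinement passes then re-choose each sequence's site with the others held
#' fixed until no site changes (at most 10 passes). The motif with the
#' largest information content across restarts is reported.
#'
#' @inheritParams gibbs_sample
#' @param iterations number of restarts (each with a fresh random order and
#'   seed window).
#' @return a `motif_result`; see [gibbs_sample()].
#' @export
greedy_search <- function(coll, w, iterations = 100, seed = 0,
                          method = c("MUTUAL_INFO", "REL_ENTROPY"),
                          background = NULL, both_strands = FALSE,
                          max_refine_passes = 10) {
  method <- match.arg(method)
  coll <- check_discovery_input(coll, w, iterations)
  n <- length(coll)
  letters <- if (coll[[1]]$alphabet == "NUCLEIC") DNA_BASES else AMINO_ACIDS
  nl <- length(letters)
  bg <- check_background(background, letters)
  cand <- lapply(coll, function(s)
    candidate_windows(seq_to_idx(s$residues, letters), w, letters, both_strands))
  ncand <- vapply(cand, function(x) nrow(x$windows), 0L)
  best <- list(ic = -Inf, rowsel = NULL)
  with_seed(seed, {
    for (r in seq_len(iterations)) {
      ord <- sample.int(n)
      rowsel <- integer(n)
      first <- ord[1]
      rowsel[first] <- sample.int(nrow(cand[[first]]$windows), 1L)
      counts <- onehot_counts(cand[[first]]$windows[rowsel[first], ], nl, w)
      n_cur <- 1L
      for (i in ord[-1]) {
        tab <- ic_addition_table(counts, n_cur + 1L, method, bg)
        rowsel[i] <- best_candidate(cand[[i]]$windows, tab)
        counts <- counts + onehot_counts(cand[[i]]$windows[rowsel[i], ], nl, w)
        n_cur <- n_cur + 1L
      }
      if (n > 1L) {
        for (pass in seq_len(max_refine_passes)) {
          changed <- FALSE
          for (i in ord) {
            cm <- counts - onehot_counts(cand[[i]]$windows[rowsel[i], ], nl, w)
            tab <- ic_addition_table(cm, n, method, bg)
            k <- best_candidate(cand[[i]]$windows, tab)
            if (k != rowsel[i]) {
              changed <- TRUE
              rowsel[i] <- k
            }
            counts <- cm + onehot_counts(cand[[i]]$windows[k, ], nl, w)
          }
          if (!changed) break
        }
        # phase-shift hill climb: slide the whole alignment while IC improves
        # (refinement alone cannot escape a uniformly shifted optimum)
        ic_cur <- ic_from_counts(counts, n, method, bg)
        repeat {
          improved <- FALSE
          for (delta in c(-1L, 1L)) {
            shifted <- shift_rowsel(rowsel, delta, cand, ncand)
            if (is.null(shifted)) next
            cs <- Reduce(`+`, lapply(seq_len(n), function(i)
              onehot_counts(cand[[i]]$windows[shifted[i], ], nl, w)))
            ics <- ic_from_counts(cs, n, method, bg)
            if (ics > ic_cur + 1e-12) {
              rowsel <- shifted
              counts <- cs
              ic_cur <- ics
              improved <- TRUE
              break
            }
          }
          if (!improved) break
        }
      }
      ic <- ic_from_counts(counts, n, method, bg)
      if (ic > best$ic) best <- list(ic = ic, rowsel = rowsel)
    }
  })
  pos <- vapply(seq_len(n), function(i) cand[[i]]$start[best$rowsel[i]], 0L)
  str <- vapply(seq_len(n), function(i) cand[[i]]$strand[best$rowsel[i]], "")
  finish_motif(coll, w, pos, str, method, iterations)
}

#' Dyad (direct / inverted repeat) motif discovery
#'
#' Exhaustively reports every pair of equal-length words of length
#' `dyad_len +- d_tol` separated by a spacer of `spacer +- s_tol` that match
#' each other -- the second word taken as-is (`DIRECT`) or reverse-complemented
#' (`INVERTED`) -- with at most `max_mismatch` mismatches (IUPAC-aware). The
#' reported score is the mismatch count.
#'
#' @param seq a NUCLEIC [bioseq].
#' @param dyad_len half-site length; `dyad_len - d_tol` must be >= 3.
#' @param d_tol half-site length tolerance.
#' @param spacer spacer length; `spacer - s_tol` must be >= 0.
#' @param s_tol spacer tolerance.
#' @param max_mismatch maximum mismatches between the two half-sites.
#' @param orientation `"BOTH"`, `"DIRECT"` or `"INVERTED"`.
#' @return data frame of class `dyad_discovery_hits`, sorted by position then
#'   score, with per-half coordinates, `dyad_len`, `spacer`, `orientation` and
#'   `score` (= mismatches).
#' @export
dyad_motif_discovery <- function(seq, dyad_len, d_tol = 0, spacer, s_tol = 0,
                                 max_mismatch = 0,
                                 orientation = c("BOTH", "DIRECT", "INVERTED")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(seq, "bioseq"))
  if (seq$alphabet != "NUCLEIC") stop2("dyad discovery requires a NUCLEIC sequence")
  if (dyad_len - d_tol < 3) stop2("dyad_len - d_tol must be >= 3")
  if (spacer - s_tol < 0) stop2("spacer - s_tol must be >= 0")
  sc <- chars(seq$residues)
  comp <- unname(IUB_COMPLEMENT[sc])
  L <- length(sc)
  oris <- if (orientation == "BOTH") c("DIRECT", "INVERTED") else orientation
  rows <- list()
  for (len in (dyad_len - d_tol):(dyad_len + d_tol)) {
    for (sp in (spacer - s_tol):(spacer + s_tol)) {
      i_max <- L - 2L * len - sp + 1L
      if (i_max < 1L) next
      i <- seq_len(i_max)
      for (ori in oris) {
        mm <- integer(i_max)
        for (j in seq_len(len)) {
          left_ch <- sc[i + j - 1L]
          right_ch <- if (ori == "DIRECT") {
            sc[i + len + sp + j - 1L]
          } else {
            comp[i + 2L * len + sp - j]   # reverse complement of the right word
          }
          mm <- mm + !MATCH_OK[cbind(left_ch, right_ch)]
        }
        keep <- which(mm <= max_mismatch)
        if (!length(keep)) next
        rows[[length(rows) + 1L]] <- data.frame(
          sequence_id = seq$id, left_start = keep, left_end = keep + len - 1L,
          right_start = keep + len + sp, right_end = keep + 2L * len + sp - 1L,
          dyad_len = len, spacer = sp, orientation = ori,
          mismatches = mm[keep], score = as.numeric(mm[keep]),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, c(rows, list(data.frame(
    sequence_id = character(), left_start = integer(), left_end = integer(),
    right_start = integer(), right_end = integer(), dyad_len = integer(),
    spacer = integer(), orientation = character(), mismatches = integer(),
    score = numeric(), stringsAsFactors = FALSE))))
  out <- out[order(out$left_start, out$score, out$dyad_len, out$spacer,
                   out$orientation), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dyad_discovery_hits", "data.frame")
  out
}
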