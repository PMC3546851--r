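# internal helpers

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

collapse <- function(x) paste(x, collapse = "")

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded operations never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

stop2 <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# strip whitespace, digits and the \ / | characters that commonly survive a
# paste from GenBank ORIGIN blocks or numbered alignments
clean_residue_text <- function(text) {
  toupper(gsub("[[:space:][:digit:]\\\\/|]", "", text))
}
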