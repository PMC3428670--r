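`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded helpers do not
#' perturb an enclosing simulation. A `NULL` seed leaves the RNG untouched.
#'
#' @param seed integer seed or `NULL`
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else suppressWarnings(rm(".Random.seed", envir = genv))
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a per-stage seed from a master seed
#'
#' Fans one master seed out into deterministic, label-keyed streams so each
#' pipeline stage gets an independent but reproducible seed.
#'
#' @param master integer master seed
#' @param label character stage label
#' @return an integer seed in `[0, 2^31 - 2]`
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(label))
  v <- utf8ToInt(label)
  h <- sum(v * ((seq_along(v) - 1) %% 7 + 1))
  as.integer((abs(as.double(master)) * 48271 + h * 1009 + 1) %% 2147483647)
}

#' Reverse-complement nucleotide strings
#'
#' @param x character vector of A/C/G/T/N strings
#' @return character vector of reverse complements
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m))
}
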