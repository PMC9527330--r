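#' @keywords internal
"_PACKAGE"

STIMULI <- c("DA10", "LA3", "LA30Hz")
EYES <- c("L", "R")

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state on exit so that seeded helpers do not
#' perturb the global stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

## seed for a named sub-stream, kept below 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 7919L + as.integer(offset)) %% 214748329L
}

#' Round half-up to a number of decimals
#'
#' Base `round()` rounds half to even; cohort percentages are presented with
#' conventional half-up rounding instead.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## stratified fold assignment at the patient level; returns integer folds
stratified_folds <- function(labels, k) {
  n <- length(labels)
  fold <- integer(n)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) {
      stopf("class '%s' has %d members; cannot stratify into %d folds",
            cl, length(idx), k)
    }
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

## rbind a list of one-row data frames; empty list gives a 0-row frame
rbind_rows <- function(rows) {
  if (!length(rows)) return(data.frame())
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

vlog <- function(verbose, fmt, ...) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
}
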