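# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not disturb the
#' caller's RNG stream. A `NULL` seed leaves the stream untouched.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Derive a child seed from a base seed, kept inside the 32-bit integer range.
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647L)
}

stop_argument <- function(...) stop(..., call. = FALSE)

stop_integrity <- function(...) {
  stop(structure(class = c("foodcue_integrity_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

# seconds -> sample index (1-based, sample 1 is t = 0); half-open windows are
# handled by the callers via n = round(width * fs) samples from this start.
sample_at <- function(t, fs) as.integer(round(t * fs)) + 1L

# union / intersection bookkeeping for time spans given as 2-column matrices
merge_spans <- function(spans) {
  if (is.null(spans) || nrow(spans) == 0) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  spans <- spans[order(spans[, 1]), , drop = FALSE]
  out <- spans[1, , drop = FALSE]
  if (nrow(spans) > 1) {
    for (i in 2:nrow(spans)) {
      if (spans[i, 1] <= out[nrow(out), 2]) {
        out[nrow(out), 2] <- max(out[nrow(out), 2], spans[i, 2])
      } else {
        out <- rbind(out, spans[i, , drop = FALSE])
      }
    }
  }
  colnames(out) <- c("start", "end")
  out
}

span_intersection_length <- function(a, b) {
  if (is.null(a) || is.null(b) || nrow(a) == 0 || nrow(b) == 0) return(0)
  total <- 0
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a[i, 1], b[, 1])
    hi <- pmin(a[i, 2], b[, 2])
    total <- total + sum(pmax(hi - lo, 0))
  }
  total
}

span_total_length <- function(a) {
  if (is.null(a) || nrow(a) == 0) return(0)
  sum(a[, 2] - a[, 1])
}
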