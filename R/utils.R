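# Internal helpers: condition constructors and stable log-space reductions.

parse_error <- function(msg, line = NA_integer_) {
  if (!is.na(line)) msg <- sprintf("%s (line %d)", msg, line)
  stop(errorCondition(msg, line = line,
                      class = c("dgepair_parse_error", "dgepair_error", "error")))
}

domain_error <- function(msg) {
  stop(errorCondition(msg, class = c("dgepair_domain_error", "dgepair_error", "error")))
}

stage_error <- function(stage, msg) {
  stop(errorCondition(sprintf("[stage %s] %s", stage, msg), stage = stage,
                      class = c("dgepair_stage_error", "dgepair_error", "error")))
}

# log(sum(exp(lx))) without overflow; -Inf-safe.
log_sum_exp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

# Scalar positive-integer check (counts, totals, sizes).
is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == trunc(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
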