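`%||%` <- function(a, b) if (is.null(a)) b else a

# stop/warning without the call, with sprintf-style formatting
t_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
t_warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# competition ranking in decreasing order: ties share the best (minimum) rank
rank_decreasing_min <- function(x) rank(-x, ties.method = "min")
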