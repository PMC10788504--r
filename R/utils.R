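# Internal helpers shared across modules.

# Condition / outcome label vocabulary. Labels are matched case-insensitively
# so cohorts written by other tools ("MI", "Rest", "HIT") import cleanly.
.conditions <- c("mi", "rest")
.outcomes <- c("hit", "miss")

norm_labels <- function(x, allowed, what) {
  x <- tolower(as.character(x))
  bad <- setdiff(unique(x[!is.na(x)]), allowed)
  if (length(bad) > 0) {
    abort(
      sprintf(
        "Unknown %s label(s): %s. Allowed: %s.",
        what, paste(sQuote(bad), collapse = ", "),
        paste(sQuote(allowed), collapse = ", ")
      ),
      class = "avalanchr_label_error"
    )
  }
  x
}

# Seed handling: every stochastic entry point takes `seed`; NULL means
# "continue the caller's RNG stream".
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1)
    set.seed(as.integer(seed))
  }
  expr
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1].", name))
  }
  x
}

# Flatten a square matrix in row-major order (the documented ATM feature
# layout); inverse of matrix(x, byrow = TRUE).
flatten_rowmajor <- function(m) as.vector(t(m))

default_region_names <- function(n) sprintf("R%02d", seq_len(n))
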