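# Small in-code fixtures shared across test files.

# Cohort/reference rows carrying pre-computed scale scores, bypassing the
# item-level scoring stage (which has its own tests).
scored_tbl <- function(id, gender, age, hscl = NULL, css = NULL,
                       group = NULL, cutoff = 1.85) {
  out <- tibble::tibble(id = id, gender = gender, age = as.integer(age))
  if (!is.null(group)) out$group <- group
  if (!is.null(hscl)) {
    out$hscl10_score <- hscl
    out$hscl10_case <- hscl >= cutoff
  }
  if (!is.null(css)) out$css4_score <- css
  out
}

# Item columns where every item equals `value` (so the score equals value).
flat_items <- function(def, n, value) {
  m <- matrix(as.integer(value), n, def$n_items)
  colnames(m) <- item_columns(def)
  tibble::as_tibble(m)
}

# A fast, small synthetic configuration for pipeline-level tests.
small_config <- function(seed = 1, ...) {
  synthetic_config(n_reference = 800L, n_cohort = 120L, seed = seed, ...)
}

score_both <- function(data) {
  score_responses(score_responses(data, hscl10()), css4())
}
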