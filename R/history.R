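# Choice histories are written chronologically as strings over {A, B}:
# "AAB" means the first two deciders chose A and the most recent chose B.
# Internally A = +1 and B = -1, so that a choice acts as a sign inside
# the social-likelihood factor.

parse_history <- function(history) {
  if (length(history) == 0L) return(integer(0))
  if (length(history) == 1L && is.character(history)) {
    ch <- strsplit(history, "")[[1]]
  } else {
    ch <- as.character(history)
  }
  if (length(ch) == 0L) return(integer(0))
  ch <- toupper(ch)
  if (!all(ch %in% c("A", "B")))
    stop("choice history must consist of letters 'A' and 'B' only", call. = FALSE)
  ifelse(ch == "A", 1L, -1L)
}

history_string <- function(signs) {
  if (length(signs) == 0L) return("")
  paste(ifelse(signs > 0, "A", "B"), collapse = "")
}

#' Mirror a choice history
#'
#' Swaps A and B throughout.  The model is symmetric under this relabeling:
#' critical values negate and conditional choice probabilities reflect
#' around 1/2.
#'
#' @param history A history string such as `"AAB"` (chronological order,
#'   most recent last) or a character vector of `"A"`/`"B"`.
#' @return The mirrored history as a string.
#' @examples
#' mirror_history("AAB") # "BBA"
#' @export
mirror_history <- function(history) {
  history_string(-parse_history(history))
}

# all non-empty histories of length 1..max_len, lexicographic within length
all_histories <- function(max_len) {
  unlist(lapply(seq_len(max_len), function(m) {
    g <- expand.grid(rep(list(c("A", "B")), m), stringsAsFactors = FALSE)
    # expand.grid varies the first column fastest; flip for chronological lex order
    apply(g[, rev(seq_len(m)), drop = FALSE], 1L, paste, collapse = "")
  }))
}
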