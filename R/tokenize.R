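#' Tokenize short social-media messages
#'
#' Normalizes raw message text into bag-of-words tokens: lowercases, removes
#' URLs and @-mentions, strips the `#` from hashtags (keeping the word),
#' splits on runs of non-alphanumeric characters, and drops tokens shorter
#' than 2 characters.
#'
#' @param text Character vector of raw messages (may be empty strings).
#' @return A list with one character vector of tokens per input message.
#' @examples
#' tokenize("Get your colonoscopy!")
#' tokenize("#Paptest saves lives http://t.co/x @user")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text))
  x <- tolower(text)
  x <- gsub("https?://\\S+|www\\.\\S+", " ", x)
  x <- gsub("@\\w+", " ", x)
  x <- gsub("#", "", x, fixed = TRUE)
  parts <- strsplit(x, "[^a-z0-9]+")
  lapply(parts, function(tok) tok[nchar(tok) >= 2L])
}
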