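#' Token codec: fixed-length DNA words as base-4 integers
#'
#' Tokens are DNA words of fixed length `n` over `{A,C,G,T}`. The codec maps
#' each token bijectively to an integer code in `[0, 4^n)` using A=0, C=1,
#' G=2, T=3 as big-endian base-4 digits, so code 0 is `AA...A` and code
#' `4^n - 1` is `TT...T`. These codes index the rows of the token-existence
#' bitvector index.
#'
#' @param token_size Token length `n` (>= 1). Sizes above 15 are rejected to
#'   keep `4^n` exactly representable.
#' @return An object of class `token_codec` with fields `token_size` and
#'   `n_tokens` (= `4^n`).
#' @examples
#' codec <- token_codec(5)
#' encode_token("ACGTA", codec)
#' @export
token_codec <- function(token_size) {
  token_size <- as.integer(token_size)
  if (is.na(token_size) || token_size < 1L) stop("token_size must be an integer >= 1")
  if (token_size > 15L) stop("token_size above 15 is not supported")
  structure(
    list(token_size = token_size, n_tokens = 4^token_size),
    class = "token_codec"
  )
}

#' @export
print.token_codec <- function(x, ...) {
  cat("<token_codec> n = ", x$token_size, " (", x$n_tokens,
      " possible tokens; A=0, C=1, G=2, T=3, big-endian)\n", sep = "")
  invisible(x)
}

BASE_CODES <- c(A = 0, C = 1, G = 2, T = 3)

#' Encode / decode tokens
#'
#' `encode_token()` maps one or more tokens to their integer codes;
#' `decode_token()` inverts it. Both are vectorized. Tokens containing any
#' character outside ACGT are ambiguous: `encode_token()` errors on them
#' unless `ambiguous_na = TRUE`, in which case they encode to `NA` (the
#' policy used when scanning reads and references).
#'
#' @param token Character vector of DNA words, each exactly `n` long.
#' @param codec A [token_codec()].
#' @param ambiguous_na If `TRUE`, tokens with non-ACGT characters give `NA`
#'   instead of an error.
#' @return `encode_token()`: numeric vector of codes in `[0, 4^n)`;
#'   `decode_token()`: character vector of tokens.
#' @examples
#' codec <- token_codec(5)
#' encode_token(c("AAAAA", "TTTTT"), codec)  # 0 and 1023
#' decode_token(108, codec)                  # "ACGTA"
#' @export
encode_token <- function(token, codec, ambiguous_na = FALSE) {
  stopifnot(inherits(codec, "token_codec"))
  n <- codec$token_size
  if (any(nchar(token) != n)) {
    stop("all tokens must have length ", n, " (the codec's token size)")
  }
  chars <- strsplit(toupper(token), "", fixed = TRUE)
  codes <- vapply(chars, function(ch) {
    d <- BASE_CODES[ch]
    if (anyNA(d)) return(NA_real_)
    sum(d * 4^((n - 1):0))
  }, numeric(1))
  if (!ambiguous_na && anyNA(codes)) {
    stop("token contains a non-ACGT character; ",
         "use ambiguous_na = TRUE to encode such tokens as NA")
  }
  codes
}

#' @rdname encode_token
#' @export
decode_token <- function(code, codec) {
  stopifnot(inherits(codec, "token_codec"))
  n <- codec$token_size
  code <- as.numeric(code)
  if (anyNA(code) || any(code < 0 | code >= codec$n_tokens)) {
    stop("token code out of range [0, 4^n)")
  }
  bases <- c("A", "C", "G", "T")
  vapply(code, function(k) {
    digits <- integer(n)
    for (i in n:1) {
      digits[i] <- k %% 4
      k <- k %/% 4
    }
    paste(bases[digits + 1L], collapse = "")
  }, character(1))
}

# Rolling token codes for every position of a sequence string.
# Returns a numeric vector of length max(0, nchar(seq) - n + 1); positions
# whose window touches a non-ACGT character are NA. Vectorized: one pass of
# n shifted digit vectors, so scanning a megabase reference is cheap.
scan_token_codes <- function(seq, codec) {
  n <- codec$token_size
  len <- nchar(seq)
  if (len < n) return(numeric(0))
  digits <- unname(BASE_CODES[strsplit(seq, "", fixed = TRUE)[[1]]])
  npos <- len - n + 1L
  codes <- numeric(npos)
  ok <- rep(TRUE, npos)
  for (j in seq_len(n)) {
    d <- digits[j:(j + npos - 1L)]
    ok <- ok & !is.na(d)
    d[is.na(d)] <- 0
    codes <- codes + d * 4^(n - j)
  }
  codes[!ok] <- NA_real_
  codes
}
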