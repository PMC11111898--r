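#' Strip lexical stress digits from ARPAbet labels
#'
#' CMU-dictionary pronunciations mark vowel stress with a trailing digit
#' (e.g. `AA1`, `IH0`). Phoneme-level scoring ignores stress, so digits are
#' removed while order and repetitions are preserved.
#'
#' @param raw character vector of ARPAbet labels, optionally with a trailing
#'   stress digit 0-2.
#' @return Character vector of stress-stripped symbols, all members of
#'   [ARPABET], same length as the input.
#' @examples
#' strip_stress(c("P", "AA1", "L", "IH0", "SH"))
#' @export
strip_stress <- function(raw) {
  if (length(raw) < 1L) stop("phoneme sequence must have length >= 1")
  out <- sub("[0-2]$", "", toupper(raw))
  bad <- !(out %in% ARPABET)
  if (any(bad)) {
    stop("unknown ARPAbet symbol(s): ", paste(unique(raw[bad]), collapse = ", "))
  }
  out
}

#' Load a pronouncing lexicon in CMU dictionary format
#'
#' Parses plain-text lines of the form `WORD  PH1 PH2 ...`. Alternate
#' pronunciations carry a `(n)` suffix on the word (`ECHOS(2)`) and are merged
#' under the base word; lines starting with `;;;` are comments. Stress digits
#' are stripped at load time and lookup is case-insensitive (keys are stored
#' lowercase).
#'
#' @param path path to a CMU-format dictionary file.
#' @return An object of class `avsin_lexicon`: a list with `entries` (named
#'   list mapping lowercase word to a list of character-vector pronunciation
#'   variants) and `n_skipped` (count of malformed lines).
#' @export
load_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "latin1")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, ";;;")]
  entries <- list()
  n_skipped <- 0L
  for (line in lines) {
    parts <- strsplit(trimws(line), "[ \t]+")[[1]]
    if (length(parts) < 2L) {
      n_skipped <- n_skipped + 1L
      next
    }
    word <- tolower(sub("\\([0-9]+\\)$", "", parts[1L]))
    phones <- tryCatch(strip_stress(parts[-1L]), error = function(e) NULL)
    if (is.null(phones)) {
      n_skipped <- n_skipped + 1L
      next
    }
    entries[[word]] <- c(entries[[word]], list(phones))
  }
  if (n_skipped > 0L) {
    warning(n_skipped, " malformed lexicon line(s) skipped in ", path)
  }
  structure(list(entries = entries, n_skipped = n_skipped),
            class = "avsin_lexicon")
}

#' @export
print.avsin_lexicon <- function(x, ...) {
  n_var <- sum(lengths(x$entries))
  cat("CMU-format pronouncing lexicon:", length(x$entries), "words,",
      n_var, "pronunciation variants\n")
  invisible(x)
}

#' Write a lexicon back to CMU dictionary format
#'
#' Inverse of [load_lexicon()] (modulo stress digits, which are already
#' stripped): words are uppercased and alternate variants get `(n)` suffixes.
#'
#' @param lexicon an `avsin_lexicon`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  words <- sort(names(lexicon$entries))
  lines <- unlist(lapply(words, function(w) {
    vars <- lexicon$entries[[w]]
    vapply(seq_along(vars), function(i) {
      key <- if (i == 1L) toupper(w) else sprintf("%s(%d)", toupper(w), i)
      paste0(key, "  ", paste(vars[[i]], collapse = " "))
    }, character(1))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Normalize a typed response
#'
#' Lowercases, trims, drops characters outside letters/apostrophe/hyphen/space,
#' treats hyphens as spaces, and collapses repeated whitespace. This is the
#' fixed normalization applied before any lookup or comparison; typed
#' crowd-sourced responses are noisy and the rule must be deterministic.
#'
#' @param text character vector of raw responses.
#' @return Character vector of normalized responses (possibly empty strings).
#' @export
normalize_response <- function(text) {
  x <- tolower(text)
  x <- gsub("-", " ", x, fixed = TRUE)
  x <- gsub("[^a-z' ]", "", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

# deterministic letter-to-phoneme fallback for out-of-vocabulary tokens:
# common digraphs first, then single letters, each mapped to its most frequent
# ARPAbet correspondence. Crude by design -- it only has to be reproducible,
# never accurate.
OOV_DIGRAPHS <- list(
  th = "TH", sh = "SH", ch = "CH", ph = "F", wh = "W", ck = "K",
  ng = "NG", qu = c("K", "W"), ee = "IY", oo = "UW", ea = "IY",
  ai = "EY", ay = "EY", oi = "OY", oy = "OY", ou = "AW", ow = "AW",
  er = "ER", gh = "G"
)
OOV_LETTERS <- c(
  a = "AE", b = "B", c = "K", d = "D", e = "EH", f = "F", g = "G",
  h = "HH", i = "IH", j = "JH", k = "K", l = "L", m = "M", n = "N",
  o = "AA", p = "P", q = "K", r = "R", s = "S", t = "T", u = "AH",
  v = "V", w = "W", y = "Y", z = "Z"
)

oov_phonemize <- function(token) {
  token <- gsub("'", "", token)
  chars <- strsplit(token, "")[[1]]
  out <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    if (i < length(chars)) {
      pair <- paste0(chars[i], chars[i + 1L])
      if (!is.null(OOV_DIGRAPHS[[pair]])) {
        out <- c(out, OOV_DIGRAPHS[[pair]])
        i <- i + 2L
        next
      }
    }
    ch <- chars[i]
    if (ch == "x") {
      out <- c(out, "K", "S")
    } else if (!is.na(OOV_LETTERS[ch])) {
      out <- c(out, unname(OOV_LETTERS[ch]))
    }
    i <- i + 1L
  }
  if (length(out) == 0L) out <- "AH"
  out
}

#' Phonemize free text against a lexicon
#'
#' Normalizes the text, splits it on whitespace, looks each token up in the
#' lexicon, and for multi-word text concatenates the cross-product of token
#' pronunciation variants in token order. Tokens absent from the lexicon are
#' phonemized with a deterministic letter-to-phoneme fallback and flagged.
#'
#' @param text a single free-text response.
#' @param lexicon an `avsin_lexicon`.
#' @param max_variants cap on the number of concatenated variant combinations
#'   retained for multi-word responses (cross-products can explode; 16
#'   combinations is far beyond any realistic response).
#' @return List with `variants` (list of phoneme character vectors) and `oov`
#'   (logical: TRUE if any token used the fallback).
#' @export
phonemize <- function(text, lexicon, max_variants = 16L) {
  norm <- normalize_response(text)
  if (!nzchar(norm)) stop("empty response after normalization")
  tokens <- strsplit(norm, " ", fixed = TRUE)[[1]]
  oov <- FALSE
  per_token <- lapply(tokens, function(tok) {
    vars <- lexicon$entries[[tok]]
    if (is.null(vars)) {
      oov <<- TRUE
      vars <- list(oov_phonemize(tok))
    }
    vars
  })
  variants <- list(character(0))
  for (tv in per_token) {
    variants <- unlist(lapply(variants, function(head) {
      lapply(tv, function(v) c(head, v))
    }), recursive = FALSE)
    if (length(variants) > max_variants) variants <- variants[seq_len(max_variants)]
  }
  list(variants = variants, oov = oov)
}

#' Are two words homophones?
#'
#' TRUE iff any stress-stripped pronunciation variant of `a` is identical
#' (same symbols, same order) to any variant of `b`. Out-of-vocabulary words
#' are never homophones of anything (a warning is emitted, not an error).
#'
#' @param a,b single words.
#' @param lexicon an `avsin_lexicon`.
#' @return Logical scalar.
#' @examples
#' \dontrun{are_homophones("wore", "war", lex)  # TRUE}
#' @export
are_homophones <- function(a, b, lexicon) {
  ka <- normalize_response(a)
  kb <- normalize_response(b)
  va <- lexicon$entries[[ka]]
  vb <- lexicon$entries[[kb]]
  if (is.null(va) || is.null(vb)) {
    warning("out-of-vocabulary word in homophone check: ",
            if (is.null(va)) ka else kb)
    return(FALSE)
  }
  for (x in va) for (y in vb) {
    if (length(x) == length(y) && all(x == y)) return(TRUE)
  }
  FALSE
}
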