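#' The canonical stress-stripped ARPAbet phoneme set
#'
#' The 39 ARPAbet symbols used by the CMU pronouncing dictionary once lexical
#' stress digits are removed from vowels. All phoneme sequences handled by this
#' package are drawn from this set.
#'
#' @format Character vector of length 39.
#' @export
ARPABET <- c(
  "AA", "AE", "AH", "AO", "AW", "AY", "B", "CH", "D", "DH",
  "EH", "ER", "EY", "F", "G", "HH", "IH", "IY", "JH", "K",
  "L", "M", "N", "NG", "OW", "OY", "P", "R", "S", "SH",
  "T", "TH", "UH", "UW", "V", "W", "Y", "Z", "ZH"
)

# vowels carry stress digits in CMU format
ARPABET_VOWELS <- c("AA", "AE", "AH", "AO", "AW", "AY", "EH", "ER", "EY",
                    "IH", "IY", "OW", "OY", "UH", "UW")

#' Multiset phoneme counts over the canonical alphabet
#'
#' Tabulates how many times each of the 39 ARPAbet symbols occurs in a
#' phoneme sequence. Used throughout scoring and simulation so that multiset
#' operations reduce to arithmetic on fixed-length count vectors.
#'
#' @param symbols character vector of stress-stripped ARPAbet symbols.
#' @return Named integer vector of length 39 (names = `ARPABET`).
#' @keywords internal
phoneme_counts <- function(symbols) {
  idx <- match(symbols, ARPABET)
  if (anyNA(idx)) {
    stop("unknown ARPAbet symbol(s): ",
         paste(unique(symbols[is.na(idx)]), collapse = ", "))
  }
  counts <- tabulate(idx, nbins = length(ARPABET))
  names(counts) <- ARPABET
  counts
}
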