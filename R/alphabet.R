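#' The 21-symbol analysis alphabet
#'
#' The analysis treats the alignment gap as a special amino-acid type with
#' index 0, followed by the 20 standard amino acids with indices 1 to 20.
#' All frequency, mutation and correlation computations run over these
#' M = 21 types.
#'
#' @return A list with components `symbols` (character vector of length 21,
#'   gap `"-"` first, then the 20 one-letter amino-acid codes in alphabetical
#'   order) and `index` (named integer vector mapping each symbol to its
#'   type index 0..20).
#' @examples
#' ab <- cmca_alphabet()
#' ab$symbols[1]      # "-"
#' ab$index[["A"]]    # 1
#' @export
cmca_alphabet <- function() {
  symbols <- c("-", "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  index <- seq_along(symbols) - 1L
  names(index) <- symbols
  list(symbols = symbols, index = index)
}

# Residue codes with no place in the 21-type model; normalized to gap on input.
.ambiguous_codes <- c("X", "B", "Z", "U", "O", "J", "*")
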