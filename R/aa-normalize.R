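# HGVS p. protein-change normalization: three-letter residue codes to the
# one-letter nomenclature used as the reference join key.

# IUPAC three-letter -> one-letter amino acid code, plus Ter -> * for stops.
.AA3_TO_1 <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
  Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
  Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
  Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V",
  Ter = "*", Sec = "U", Xaa = "X"
)

#' Normalize a protein-change string to one-letter HGVS form
#'
#' Converts three-letter residue codes in an HGVS p. protein change to the
#' one-letter code used by COSMIC-style references (e.g. `"p.Gly12Asp"` to
#' `"p.G12D"`). Stop codons (`Ter`) become `*`; frameshift (`fs`, `fs*N`),
#' `del`, `ins`, `dup`, `ext` and synonymous (`=`) tokens are preserved, as is
#' a leading `"p."` prefix. Strings already in one-letter form pass through
#' unchanged, so the function is idempotent. Strings that cannot be
#' interpreted as a protein change yield `""` with a warning; callers treat
#' such rows as non-joinable rather than dropping them.
#'
#' @param aa_raw Character vector of protein-change strings (three-letter
#'   codes as emitted by snpEff-style annotators, or one-letter form).
#' @return Character vector of the same length: the normalized one-letter
#'   form, or `""` where the input was unrecognizable.
#' @examples
#' normalize_aa_change("p.Gly12Asp")   # "p.G12D"
#' normalize_aa_change("p.V600E")      # unchanged
#' normalize_aa_change("p.Ter494Ter")  # "p.*494*"
#' normalize_aa_change("p.Glu23fs")    # "p.E23fs"
#' @export
normalize_aa_change <- function(aa_raw) {
  vapply(as.character(aa_raw), normalize_aa_one, character(1), USE.NAMES = FALSE)
}

normalize_aa_one <- function(x) {
  if (is.na(x)) return("")
  x <- trimws(x)
  if (x == "" || x == "." || x == "-") return("")

  has_prefix <- grepl("^p\\.", x)
  body <- sub("^p\\.", "", x)

  # Replace every three-letter residue token. Tokens are capitalized
  # (e.g. "Gly"), so lowercase HGVS keywords (del/ins/dup/fs/ext) survive.
  for (code in names(.AA3_TO_1)) {
    body <- gsub(code, .AA3_TO_1[[code]], body, fixed = TRUE)
  }

  if (!is_valid_aa_one_letter(body)) {
    warning("unparseable protein change: ", sQuote(x), call. = FALSE)
    return("")
  }
  paste0(if (has_prefix) "p." else "", body)
}

# A normalized body must start <residue><position> and contain only one-letter
# residues, digits, stop (*), synonymous (=), range (_), ? and the lowercase
# HGVS keywords del / ins / dup / fs / ext.
is_valid_aa_one_letter <- function(body) {
  if (!grepl("^[A-Z*][0-9]+", body)) return(FALSE)
  residue <- gsub("del|ins|dup|fs|ext", "", body)
  grepl("^[A-Z*0-9_=*?]+$", residue)
}
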