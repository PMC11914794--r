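# protein-level HGVS parsing: only enough of the grammar to classify the
# variant classes the pipeline must distinguish (missense vs everything else)

AA3_TO_1 <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q", Glu = "E",
  Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K", Met = "M", Phe = "F",
  Pro = "P", Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V"
)
AA1_TO_3 <- stats::setNames(names(AA3_TO_1), AA3_TO_1)

aa_token_to_1 <- function(tok) {
  if (tok %in% names(AA3_TO_1)) return(unname(AA3_TO_1[tok]))
  if (tok %in% AA_STANDARD) return(tok)
  NA_character_
}

#' Parse a protein-level HGVS annotation
#'
#' Classifies `p.` annotations into the classes the pipeline distinguishes:
#' single-residue missense substitutions (the only class peptides are designed
#' for), nonsense (`Ter`/`*`), frameshift (`fs`), synonymous (`=`), other
#' in-frame events (`del`/`ins`/`dup`), or unparseable. One- and three-letter
#' residue codes are both accepted.
#'
#' @param hgvs Character vector of `p.` annotations, e.g. `"p.Ala123Thr"` or
#'   `"p.A123T"`.
#' @return A tibble with columns `hgvs_protein`, `class` (one of `missense`,
#'   `nonsense`, `frameshift`, `synonymous`, `other`, `unparseable`), and for
#'   missense rows `pos`, `wt_residue`, `mut_residue` (NA otherwise).
#' @export
parse_hgvs_protein <- function(hgvs) {
  one <- function(h) {
    if (is.na(h) || !grepl("^p\\.", h)) {
      return(list(class = "unparseable", pos = NA_integer_,
                  wt = NA_character_, mut = NA_character_))
    }
    body <- sub("^p\\.", "", h)
    body <- gsub("^\\(|\\)$", "", body)
    if (grepl("fs", body)) return(list(class = "frameshift", pos = NA_integer_,
                                       wt = NA_character_, mut = NA_character_))
    if (grepl("del|ins|dup", body)) {
      return(list(class = "other", pos = NA_integer_,
                  wt = NA_character_, mut = NA_character_))
    }
    m <- regmatches(body, regexec(
      "^([A-Z][a-z]{2}|[A-Z])([0-9]+)([A-Z][a-z]{2}|[A-Z*=]|Ter|=)$", body))[[1]]
    if (length(m) == 0) {
      return(list(class = "unparseable", pos = NA_integer_,
                  wt = NA_character_, mut = NA_character_))
    }
    wt <- aa_token_to_1(m[2])
    pos <- as.integer(m[3])
    if (is.na(wt)) {
      return(list(class = "unparseable", pos = NA_integer_,
                  wt = NA_character_, mut = NA_character_))
    }
    if (m[4] %in% c("Ter", "*")) {
      return(list(class = "nonsense", pos = pos, wt = wt, mut = NA_character_))
    }
    if (m[4] == "=") {
      return(list(class = "synonymous", pos = pos, wt = wt, mut = wt))
    }
    mut <- aa_token_to_1(m[4])
    if (is.na(mut)) {
      return(list(class = "unparseable", pos = NA_integer_,
                  wt = NA_character_, mut = NA_character_))
    }
    if (mut == wt) {
      return(list(class = "synonymous", pos = pos, wt = wt, mut = mut))
    }
    list(class = "missense", pos = pos, wt = wt, mut = mut)
  }
  parsed <- map(hgvs, one)
  tibble(
    hgvs_protein = hgvs,
    class = map_chr(parsed, "class"),
    pos = vapply(parsed, function(p) as.integer(p$pos), integer(1)),
    wt_residue = map_chr(parsed, "wt"),
    mut_residue = map_chr(parsed, "mut")
  )
}
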