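## Standard atomic weights (amu), IUPAC 2021 abridged values.
## Keys are upper-case element symbols as found in PDB columns 77-78.
.atomic_masses <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998, "NA" = 22.990, MG = 24.305, P = 30.974, S = 32.06,
  CL = 35.45, K = 39.098, CA = 40.078, MN = 54.938, FE = 55.845,
  CO = 58.933, NI = 58.693, CU = 63.546, ZN = 65.38, SE = 78.971,
  BR = 79.904, I = 126.904
)

#' Look up standard atomic weights
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of masses in amu.
#' @examples
#' element_mass(c("C", "N", "Zn"))
#' @export
element_mass <- function(element) {
  key <- toupper(trimws(element))
  m <- .atomic_masses[key]
  if (anyNA(m)) {
    bad <- unique(key[is.na(m)])
    stop("no mass entry for element(s): ", paste(bad, collapse = ", "))
  }
  unname(m)
}

## Infer the element symbol from a PDB atom name when columns 77-78 are blank.
## `raw_name` is the untrimmed 4-character name field: a name starting in
## column 13 (first char non-blank) can carry a two-letter element (FE, ZN...);
## names starting in column 14 are one-letter elements. Leading digits
## (hydrogen naming like "1HB ") are stripped first.
.infer_element <- function(raw_name) {
  two_letter <- c("FE", "ZN", "MG", "NA", "CL", "BR", "SE", "MN",
                  "CU", "NI", "CO")
  vapply(raw_name, function(nm) {
    stripped <- gsub("[0-9' ]", "", toupper(nm))
    if (!nzchar(stripped)) stop("cannot infer element from atom name '", nm, "'")
    first_char <- substr(nm, 1L, 1L)
    if (first_char != " " && nchar(stripped) >= 2L &&
        substr(stripped, 1L, 2L) %in% two_letter) {
      return(substr(stripped, 1L, 2L))
    }
    substr(stripped, 1L, 1L)
  }, character(1), USE.NAMES = FALSE)
}
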