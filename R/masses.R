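# Standard atomic masses (u) for the elements that occur in protein/water
# systems; sufficient for residue centre-of-mass computations.
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, NA_ = 22.990, CL = 35.45, K = 39.098, FE = 55.845,
  CU = 63.546, MG = 24.305, ZN = 65.38, CA = 40.078
)

#' Guess the element from a PDB-style atom name
#'
#' Leading digits are stripped (e.g. "1HG1" -> H); two-letter elements are
#' only assumed for names that cannot be a protein atom (FE, CU, ZN, MG,
#' CL, NA, K as full names).
#'
#' @param atom_name character vector of atom names
#' @return character vector of element symbols
#' @export
guess_element <- function(atom_name) {
  nm <- toupper(gsub("^[0-9]+", "", trimws(atom_name)))
  two <- c("FE", "CU", "ZN", "MG", "CL")
  el <- substr(nm, 1, 1)
  el[nm %in% two] <- nm[nm %in% two]
  el[nm == "NA"] <- "NA_"
  el
}

#' Standard atomic mass of an element symbol
#' @param element character vector of element symbols
#' @return numeric vector of masses (u); unknown elements get 12.011 with a warning
#' @export
atomic_mass <- function(element) {
  m <- .element_masses[element]
  if (anyNA(m)) {
    warning("unknown element(s): ",
            paste(unique(element[is.na(m)]), collapse = ", "),
            "; using carbon mass")
    m[is.na(m)] <- 12.011
  }
  unname(m)
}
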