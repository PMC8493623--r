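#' Element data used throughout pixkit
#'
#' Atomic masses (u), single-bond covalent radii (Angstrom), Bondi-style van
#' der Waals radii (Angstrom) and atomic numbers for the elements that occur
#' in ordinary molecular crystals. The tables are deliberately small: exotic
#' elements raise an error rather than silently getting a default radius.
#'
#' @name element-data
#' @keywords internal
NULL

.pixkit_elements <- local({
  # symbol, Z, mass, covalent radius, vdW radius
  tab <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
symbol  z   mass       rcov  rvdw
H       1   1.008      0.31  1.20
B       5   10.81      0.84  1.92
C       6   12.011     0.76  1.70
N       7   14.007     0.71  1.55
O       8   15.999     0.66  1.52
F       9   18.998     0.57  1.47
Na      11  22.990     1.66  2.27
Si      14  28.085     1.11  2.10
P       15  30.974     1.07  1.80
S       16  32.06      1.05  1.80
Cl      17  35.45      1.02  1.75
K       19  39.098     2.03  2.75
Ca      20  40.078     1.76  2.31
Cr      24  51.996     1.39  2.00
Fe      26  55.845     1.32  2.00
Cu      29  63.546     1.32  1.40
Zn      30  65.38      1.22  1.39
Br      35  79.904     1.20  1.85
I       53  126.904    1.39  1.98
")
  rownames(tab) <- tab$symbol
  tab
})

.element_lookup <- function(element, column) {
  element <- normalize_element(element)
  bad <- !(element %in% rownames(.pixkit_elements))
  if (any(bad)) {
    stop("unrecognized element symbol(s): ",
         paste(unique(element[bad]), collapse = ", "), call. = FALSE)
  }
  .pixkit_elements[element, column]
}

#' Normalize an element symbol
#'
#' Strips charge/label decorations ("C1", "O2-", "N(1)") down to a bare
#' capitalized element symbol.
#'
#' @param x character vector of element symbols or decorated labels.
#' @return character vector of bare symbols, e.g. `"Cl"`.
#' @export
normalize_element <- function(x) {
  sym <- sub("^([A-Za-z]{1,2}).*$", "\\1", x)
  sym <- paste0(toupper(substr(sym, 1, 1)), tolower(substr(sym, 2, 2)))
  # single-letter symbols followed by a letter that is not part of the symbol
  # (e.g. "CA" meaning the calcium label of a C atom in small-molecule CIFs is
  # ambiguous; we resolve by preferring a two-letter match, else one letter)
  known <- rownames(.pixkit_elements)
  fix <- !(sym %in% known) & nchar(sym) == 2
  sym[fix] <- substr(sym[fix], 1, 1)
  sym
}

#' @rdname element-data
#' @param element character vector of element symbols.
#' @return numeric vector.
#' @export
atomic_mass <- function(element) .element_lookup(element, "mass")

#' @rdname element-data
#' @export
covalent_radius <- function(element) .element_lookup(element, "rcov")

#' @rdname element-data
#' @export
vdw_radius <- function(element) .element_lookup(element, "rvdw")

#' @rdname element-data
#' @export
atomic_number <- function(element) .element_lookup(element, "z")
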