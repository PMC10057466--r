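# Atomic property table used as descriptor weighting schemes: relative
# atomic mass (m), van der Waals volume (v, A^3 from Bondi radii), Sanderson
# electronegativity (e) and atomic polarizability (p, A^3). These are the
# standard weighting values used by autocorrelation / 3D-MoRSE descriptor
# calculators; each scheme is applied carbon-scaled (value / value of C).

ATOM_PROPERTIES <- tibble::tribble(
  ~element, ~m,      ~v,    ~e,    ~p,
  "H",       1.008,  7.24, 2.592, 0.667,
  "B",      10.811, 17.88, 2.275, 3.030,
  "C",      12.011, 20.58, 2.746, 1.760,
  "N",      14.007, 15.60, 3.194, 1.100,
  "O",      15.999, 14.71, 3.654, 0.802,
  "F",      18.998, 13.31, 4.000, 0.557,
  "Si",     28.086, 38.79, 2.138, 5.380,
  "P",      30.974, 24.43, 2.515, 3.630,
  "S",      32.060, 24.43, 2.957, 2.900,
  "Cl",     35.453, 22.45, 3.475, 2.180,
  "Br",     79.904, 26.52, 3.219, 3.050,
  "I",     126.904, 32.52, 2.778, 5.350
)

#' Atomic weights for a descriptor weighting scheme
#'
#' Returns per-atom weights for the elements given: unit weights (`"u"`) or
#' one of the tabulated atomic properties, carbon-scaled so that carbon has
#' weight 1 — mass (`"m"`), van der Waals volume (`"v"`), Sanderson
#' electronegativity (`"e"`) or polarizability (`"p"`).
#'
#' @param elements Character vector of element symbols.
#' @param scheme One of `"u"`, `"m"`, `"v"`, `"e"`, `"p"`.
#' @return Numeric vector of weights, same length as `elements`.
#' @export
atom_weights <- function(elements, scheme = c("u", "m", "v", "e", "p")) {
  scheme <- match.arg(scheme)
  if (scheme == "u") return(rep(1, length(elements)))
  idx <- match(elements, ATOM_PROPERTIES$element)
  if (anyNA(idx)) {
    abort(paste0("no tabulated atomic properties for: ",
                 paste(unique(elements[is.na(idx)]), collapse = ", ")))
  }
  vals <- ATOM_PROPERTIES[[scheme]][idx]
  vals / ATOM_PROPERTIES[[scheme]][ATOM_PROPERTIES$element == "C"]
}
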