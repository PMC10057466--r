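# Seeded, deterministic 3D embedding. Conformers come from RDKit's ETKDG
# distance-geometry embedding (seeded, hence exactly reproducible) followed
# by MMFF94 force-field minimization (UFF fallback), driven through the
# system `python`. Graphs and all 2D work stay on the OpenBabel/ChemmineR
# path; only geometry generation uses this backend.

# Run fn() under a fixed RNG seed without disturbing the global stream.
with_local_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  fn()
}

python_path <- function() {
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) abort("python (with RDKit) not found on PATH")
  unname(p)
}

EMBED_SCRIPT <- '
import sys
from rdkit import Chem
from rdkit.Chem import AllChem

smiles, seed, out = sys.argv[1], int(sys.argv[2]), sys.argv[3]
mol = Chem.MolFromSmiles(smiles)
if mol is None:
    sys.stderr.write("PARSE_ERROR\\n"); sys.exit(2)
mol = Chem.AddHs(mol)
params = AllChem.ETKDGv3()
params.randomSeed = seed
ok = AllChem.EmbedMolecule(mol, params)
tries = 0
while ok != 0 and tries < 5:
    tries += 1
    params.randomSeed = seed + 7919 * tries
    params.useRandomCoords = tries >= 3
    ok = AllChem.EmbedMolecule(mol, params)
if ok != 0:
    sys.stderr.write("EMBED_ERROR\\n"); sys.exit(3)
ff = "MMFF94"
try:
    if AllChem.MMFFOptimizeMolecule(mol, maxIters=2000) < 0:
        raise ValueError
except Exception:
    ff = "UFF"
    AllChem.UFFOptimizeMolecule(mol, maxIters=2000)
w = Chem.SDWriter(out)
w.write(mol)
w.close()
print(ff)
'

#' Embed a seeded 3D conformer for a SMILES string
#'
#' Generates hydrogen-complete 3D coordinates by seeded ETKDG
#' distance-geometry embedding refined with a deterministic MMFF94
#' force-field minimization (UFF where MMFF94 lacks parameters). The same
#' seed always reproduces identical coordinates; different seeds give
#' different (relaxed) conformers. Geometry-based descriptors
#' ([morse_descriptor()]) consume the result; it stands in for the
#' quantum-chemically optimized geometries a full study would use.
#'
#' @param smiles A single SMILES string.
#' @param seed Integer embedding seed.
#' @return An object of class `conformer`: list with `atoms` (tibble:
#'   `element`, `x`, `y`, `z` in Angstroms, hydrogens included), `bonds`,
#'   and fields `seed` and `forcefield`.
#' @export
embed_conformer <- function(smiles, seed = 7L) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  fout <- tempfile(fileext = ".sdf")
  on.exit(unlink(fout), add = TRUE)
  res <- suppressWarnings(system2(
    python_path(), c("-c", shQuote(EMBED_SCRIPT), shQuote(smiles),
                     as.integer(seed), shQuote(fout)),
    stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0) {
    if (any(grepl("PARSE_ERROR", res))) {
      abort(paste0("could not parse structure string: ", smiles))
    }
    if (any(grepl("EMBED_ERROR", res))) {
      abort(paste0("3D embedding failed after retries for: ", smiles))
    }
    abort(paste0("conformer backend failed: ", paste(res, collapse = "\n")))
  }
  ff <- utils::tail(res, 1)
  out <- parse_sdf_mol(readLines(fout, warn = FALSE))
  xyz <- as.matrix(out$atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) abort("embedding produced non-finite coordinates")
  structure(
    list(atoms = out$atoms %>% select("idx", "element", "x", "y", "z"),
         bonds = out$bonds, seed = as.integer(seed), forcefield = ff),
    class = "conformer"
  )
}

#' @export
print.conformer <- function(x, ...) {
  cat("<conformer> ", nrow(x$atoms), " atoms (H included), seed ", x$seed,
      ", ", x$forcefield, "\n", sep = "")
  invisible(x)
}

# Interatomic distance matrix of a conformer (Angstroms).
conformer_distances <- function(conf) {
  as.matrix(stats::dist(as.matrix(conf$atoms[, c("x", "y", "z")])))
}

#' Bond lengths of a conformer
#'
#' @param conf A `conformer` object.
#' @return Tibble with one row per bond: atom indices, elements and the
#'   bond length in Angstroms.
#' @export
conformer_bond_lengths <- function(conf) {
  xyz <- as.matrix(conf$atoms[, c("x", "y", "z")])
  conf$bonds %>%
    mutate(
      elem_a = conf$atoms$element[.data$a],
      elem_b = conf$atoms$element[.data$b],
      length = sqrt(rowSums((xyz[.data$a, , drop = FALSE] -
                               xyz[.data$b, , drop = FALSE])^2))
    )
}
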