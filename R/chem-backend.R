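# OpenBabel-backed structure handling. All SMILES/SDF conversion goes through
# the obabel CLI; V2000 blocks are parsed with ChemmineR. Formal charges are
# taken from "M  CHG" property lines (they override the legacy atom-block
# charge column).

obabel_path <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) abort("obabel not found on PATH; OpenBabel is required.")
  unname(p)
}

run_obabel <- function(args) {
  out <- suppressWarnings(system2(obabel_path(), args,
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    abort(paste0("obabel failed: ", paste(out, collapse = "\n")))
  }
  invisible(out)
}

# Light SMILES well-formedness screen. OpenBabel silently repairs truncated
# strings (e.g. "C(" parses as methane), so unbalanced parentheses, dangling
# bonds and unpaired ring closures are rejected up front.
check_smiles_syntax <- function(smiles) {
  bad <- function() abort(paste0("could not parse structure string: ", smiles))
  if (!nzchar(smiles) || grepl("\\s", smiles)) bad()
  chars <- strsplit(smiles, "")[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0) || depth[length(depth)] != 0) bad()
  if (grepl("[-=#:/\\\\(]$", smiles)) bad()
  # ring-closure labels: digits outside bracket atoms, plus %nn pairs
  no_brackets <- gsub("\\[[^]]*\\]", "A", smiles)
  if (grepl("\\[|\\]", no_brackets)) bad()
  pct <- regmatches(no_brackets, gregexpr("%[0-9]{2}", no_brackets))[[1]]
  rest <- gsub("%[0-9]{2}", "", no_brackets)
  digits <- regmatches(rest, gregexpr("[0-9]", rest))[[1]]
  counts <- table(c(pct, digits))
  if (length(counts) && any(counts %% 2 != 0)) bad()
  invisible(smiles)
}

# Convert a single SMILES to SDF text. `extra` are additional obabel args
# (e.g. "-h" for explicit hydrogens, "--gen3d fastest" for 3D building).
smiles_to_sdf <- function(smiles, extra = character(), name = "mol") {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  check_smiles_syntax(smiles)
  fin <- tempfile(fileext = ".smi")
  fout <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste0(smiles, "\t", name), fin)
  log <- run_obabel(c(shQuote(fin), "-osdf", "-O", shQuote(fout), extra))
  txt <- if (file.exists(fout)) readLines(fout, warn = FALSE) else character()
  if (!length(txt) || !any(grepl("V2000", txt, fixed = TRUE))) {
    abort(paste0("could not parse structure string: ", smiles))
  }
  txt
}

# Formal charges from "M  CHG" lines, as a named (by atom index) integer map.
sdf_charges <- function(sdf_lines, n_atoms) {
  charges <- integer(n_atoms)
  for (ln in grep("^M  CHG", sdf_lines, value = TRUE)) {
    flds <- as.integer(strsplit(trimws(sub("^M  CHG\\s+\\d+", "", ln)),
                                "\\s+")[[1]])
    idx <- flds[seq(1, length(flds), by = 2)]
    val <- flds[seq(2, length(flds), by = 2)]
    charges[idx] <- val
  }
  charges
}

# Parse SDF text (one molecule, explicit hydrogens expected) into atom and
# bond tables covering all atoms including hydrogens.
parse_sdf_mol <- function(sdf_lines) {
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(sdf_lines, tmp)
  sdf <- ChemmineR::read.SDFset(tmp)[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  element <- sub("_\\d+$", "", rownames(ab))
  atoms <- tibble(
    idx = seq_len(nrow(ab)),
    element = element,
    x = unname(ab[, 1]), y = unname(ab[, 2]), z = unname(ab[, 3]),
    charge = sdf_charges(sdf_lines, nrow(ab))
  )
  bonds <- tibble(
    a = as.integer(bb[, 1]),
    b = as.integer(bb[, 2]),
    order = as.integer(bb[, 3])
  )
  list(atoms = atoms, bonds = bonds)
}

# Breadth-first all-pairs shortest-path matrix (bond counts) on an adjacency
# list; unreachable pairs keep Inf.
bfs_distances <- function(adj, n) {
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
      }
    }
    d[s, ] <- dist
  }
  d
}

adjacency_list <- function(n, a, b) {
  adj <- vector("list", n)
  for (k in seq_along(a)) {
    adj[[a[k]]] <- c(adj[[a[k]]], b[k])
    adj[[b[k]]] <- c(adj[[b[k]]], a[k])
  }
  adj
}

#' Build a hydrogen-depleted molecular graph from a SMILES string
#'
#' Parses the structure with OpenBabel, records attached-hydrogen counts on
#' the heavy atoms, and computes the all-pairs topological distance matrix
#' (shortest paths in bond counts) by breadth-first search. Topological
#' descriptors ([moran_autocorrelation()], [cats2d()],
#' [atom_pair_presence()]) operate on this graph.
#'
#' @param smiles A single SMILES string. Multi-fragment inputs (salts,
#'   mixtures) are rejected: shortest-path semantics require a connected
#'   graph, so strip counter-ions first.
#' @return An object of class `mol_graph`: a list with
#'   `atoms` (tibble: `idx`, `element`, `charge`, `n_h` attached hydrogens),
#'   `bonds` (tibble: `a`, `b`, `order`), and `dist` (integer matrix of
#'   topological distances between heavy atoms).
#' @examples
#' \dontrun{
#' g <- build_graph("Oc1ccccc1")  # phenol: 7 heavy atoms
#' max(g$dist[g$atoms$element == "O", ])
#' }
#' @export
build_graph <- function(smiles) {
  mol <- parse_sdf_mol(smiles_to_sdf(smiles, extra = "-h"))
  atoms <- mol$atoms
  bonds <- mol$bonds
  is_h <- atoms$element == "H"
  heavy <- which(!is_h)
  if (length(heavy) == 0L) abort("structure has no heavy atoms")
  # attached-H counts
  n_h <- integer(nrow(atoms))
  for (k in seq_len(nrow(bonds))) {
    a <- bonds$a[k]; b <- bonds$b[k]
    if (is_h[a]) n_h[b] <- n_h[b] + 1L
    if (is_h[b]) n_h[a] <- n_h[a] + 1L
  }
  remap <- match(seq_len(nrow(atoms)), heavy)
  hb <- bonds %>% filter(!is_h[.data$a], !is_h[.data$b]) %>%
    mutate(a = remap[.data$a], b = remap[.data$b])
  n <- length(heavy)
  d <- bfs_distances(adjacency_list(n, hb$a, hb$b), n)
  if (any(is.infinite(d))) {
    abort("disconnected (multi-fragment) structure; strip salts/fragments first")
  }
  structure(
    list(
      atoms = tibble(
        idx = seq_len(n),
        element = atoms$element[heavy],
        charge = atoms$charge[heavy],
        n_h = n_h[heavy]
      ),
      bonds = hb %>% select("a", "b", "order"),
      dist = matrix(as.integer(d), n, n)
    ),
    class = "mol_graph"
  )
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", nrow(x$atoms), " heavy atoms, ",
      nrow(x$bonds), " bonds, diameter ", max(x$dist), "\n", sep = "")
  invisible(x)
}
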