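# Descriptor families of the degradation-mechanism model: Moran
# autocorrelations (MATS) and binary 2D atom pairs (B0k) on the H-depleted
# graph, CATS2D pharmacophore-pair counts on the same graph, and 3D-MoRSE
# scattering sums on the hydrogen-complete conformer.

PPP_TYPES <- c("D", "A", "P", "N", "L")

is_halogen <- function(el) el %in% c("F", "Cl", "Br", "I")

# Does atom i participate in any double/triple bond?
has_multiple_bond <- function(graph) {
  out <- logical(nrow(graph$atoms))
  multi <- graph$bonds[graph$bonds$order > 1L, , drop = FALSE]
  out[c(multi$a, multi$b)] <- TRUE
  out
}

neighbors_of <- function(graph) {
  adjacency_list(nrow(graph$atoms), graph$bonds$a, graph$bonds$b)
}

# Terminal oxygens double-bonded to atom i
dbl_o_count <- function(graph, i) {
  bb <- graph$bonds
  hit <- (bb$a == i & graph$atoms$element[bb$b] == "O" & bb$order == 2L) |
    (bb$b == i & graph$atoms$element[bb$a] == "O" & bb$order == 2L)
  sum(hit)
}

# Single-bonded hydroxyl oxygen neighbours of atom i
oh_count <- function(graph, i) {
  bb <- graph$bonds
  o_at <- function(j) graph$atoms$element[j] == "O" & graph$atoms$n_h[j] >= 1L
  hit <- (bb$a == i & o_at(bb$b) & bb$order == 1L) |
    (bb$b == i & o_at(bb$a) & bb$order == 1L)
  sum(hit)
}

#' Assign pharmacophore point types to graph atoms
#'
#' Types every heavy atom with a subset of the five CATS pharmacophore
#' classes: hydrogen-bond donor (D: O or N bearing at least one hydrogen),
#' hydrogen-bond acceptor (A: any oxygen, plus nitrogens without attached
#' hydrogen that are not nitro nitrogens), positively charged (P: formal
#' positive charge, or a basic amine nitrogen — all bonds single and no
#' neighbour engaged in a multiple bond, which excludes amides, anilines and
#' heteroaromatic N), negatively charged (N: formal negative charge, or the
#' central atom of an acidic group — carboxylic carbon, sulfonic sulfur,
#' phosphonic phosphorus), and lipophilic (L: carbon or sulfur surrounded
#' only by carbon, sulfur or halogen). Typing the acid's *central* atom as N
#' puts the donor-negative pair of a carboxyl group at topological distance
#' 1.
#'
#' @param graph A [build_graph()] result.
#' @return A tibble with `idx`, `element`, and logical columns `D`, `A`,
#'   `P`, `N`, `L`.
#' @export
assign_ppp_types <- function(graph) {
  at <- graph$atoms
  n <- nrow(at)
  adj <- neighbors_of(graph)
  multi <- has_multiple_bond(graph)

  nitro_n <- map_lgl(seq_len(n), function(i) {
    at$element[i] == "N" && dbl_o_count(graph, i) >= 1L
  })
  acid_central <- map_lgl(seq_len(n), function(i) {
    (at$element[i] == "C" && dbl_o_count(graph, i) >= 1L &&
       oh_count(graph, i) >= 1L) ||
      (at$element[i] == "S" && dbl_o_count(graph, i) >= 2L &&
         oh_count(graph, i) >= 1L) ||
      (at$element[i] == "P" && dbl_o_count(graph, i) >= 1L &&
         oh_count(graph, i) >= 1L)
  })
  basic_amine <- map_lgl(seq_len(n), function(i) {
    at$element[i] == "N" && at$charge[i] == 0L && !multi[i] &&
      !nitro_n[i] && length(adj[[i]]) > 0L && !any(multi[adj[[i]]])
  })
  lipo <- map_lgl(seq_len(n), function(i) {
    at$element[i] %in% c("C", "S") &&
      all(at$element[adj[[i]]] %in% c("C", "S") |
            is_halogen(at$element[adj[[i]]]))
  })

  tibble(
    idx = at$idx,
    element = at$element,
    D = at$element %in% c("O", "N") & at$n_h >= 1L,
    A = at$element == "O" | (at$element == "N" & at$n_h == 0L & !nitro_n),
    P = at$charge > 0L | basic_amine,
    N = at$charge < 0L | acid_central,
    L = lipo
  )
}

#' CATS2D pharmacophore-pair count
#'
#' Counts atom pairs whose pharmacophore types match the requested pair and
#' whose topological distance equals the lag. Pairs are de-duplicated
#' (unordered); at lag 0 each atom pairs with itself, so e.g. the DD count
#' at lag 0 is the number of donor atoms. Counts are raw (not
#' occurrence-scaled).
#'
#' @param graph A [build_graph()] result.
#' @param lag Topological distance, 0-9.
#' @param pair Two pharmacophore type letters, e.g. `"DN"` or `c("D","N")`.
#' @param types Optional precomputed [assign_ppp_types()] table.
#' @return Integer count.
#' @export
cats2d <- function(graph, lag, pair, types = NULL) {
  if (length(lag) != 1L || lag < 0 || lag > 9) abort("lag must be in 0-9")
  pair <- toupper(unlist(strsplit(paste(pair, collapse = ""), "")))
  if (length(pair) != 2L || !all(pair %in% PPP_TYPES)) {
    abort("pair must be two of D, A, P, N, L")
  }
  if (is.null(types)) types <- assign_ppp_types(graph)
  m1 <- types[[pair[1]]]
  m2 <- types[[pair[2]]]
  d <- graph$dist
  match_mat <- outer(m1, m2, `&`) | outer(m2, m1, `&`)
  cnt <- sum(upper.tri(d) & d == lag & match_mat)
  if (lag == 0L) cnt <- cnt + sum(m1 & m2)   # self-pairs
  as.integer(cnt)
}

#' Binary 2D atom-pair descriptor B0k[X-Y]
#'
#' Presence (1) or absence (0) of at least one pair of atoms with the given
#' elements at exactly the given topological distance; symmetric in the two
#' elements.
#'
#' @param graph A [build_graph()] result.
#' @param elem_a,elem_b Element symbols.
#' @param k Topological distance, 1-10.
#' @return 0 or 1.
#' @export
atom_pair_presence <- function(graph, elem_a, elem_b, k) {
  if (length(k) != 1L || k < 1 || k > 10) abort("k must be in 1-10")
  ia <- which(graph$atoms$element == elem_a)
  ib <- which(graph$atoms$element == elem_b)
  if (!length(ia) || !length(ib)) return(0L)
  d <- graph$dist[ia, ib, drop = FALSE]
  as.integer(any(d == k))
}

#' Moran autocorrelation of an atomic property (MATSkw)
#'
#' Spatial autocorrelation of carbon-scaled atomic weights over atom pairs
#' at a fixed topological distance:
#' `MATS_k = [sum_{d(i,j)=k} (w_i - wbar)(w_j - wbar) / Delta_k] /
#'           [sum_i (w_i - wbar)^2 / A]`
#' with `Delta_k` the ordered-pair count and `A` the number of heavy atoms.
#' Returns 0 when no pair exists at the lag or the weights have zero
#' variance; the statistic is invariant to any affine rescaling of the
#' weights, so the carbon-scaling convention does not affect it.
#'
#' @param graph A [build_graph()] result.
#' @param lag Topological distance, 1-8.
#' @param scheme Weighting scheme passed to [atom_weights()]; `"v"` is van
#'   der Waals volume.
#' @param weights Optional explicit per-atom weights overriding `scheme`.
#' @return Numeric value.
#' @export
moran_autocorrelation <- function(graph, lag, scheme = "v", weights = NULL) {
  if (length(lag) != 1L || lag < 1) abort("lag must be a positive integer")
  w <- if (is.null(weights)) atom_weights(graph$atoms$element, scheme) else weights
  A <- nrow(graph$atoms)
  if (A < 2L) return(0)
  wc <- w - mean(w)
  denom <- sum(wc^2) / A
  if (denom <= .Machine$double.eps * max(1, mean(w)^2)) return(0)
  sel <- graph$dist == lag
  delta <- sum(sel)          # ordered pairs (matrix is symmetric, diag 0)
  if (delta == 0L) return(0)
  num <- sum(outer(wc, wc)[sel]) / delta
  num / denom
}

#' 3D-MoRSE descriptor (Mor t)
#'
#' Electron-diffraction-style scattering sum over all atom pairs of the
#' hydrogen-complete conformer:
#' `Mor_t = sum_{i<j} w_i w_j sin(s r_ij) / (s r_ij)` with scattering
#' parameter `s = t - 1` (1/Angstrom); at `s = 0` the sinc term is 1, so
#' Mor1 is the sum of weight products.
#'
#' @param conf An [embed_conformer()] result.
#' @param signal Signal number t, 1-32.
#' @param scheme Weighting scheme (`"u"` unweighted, or `"m"`, `"v"`,
#'   `"e"`, `"p"` carbon-scaled).
#' @return Numeric value.
#' @export
morse_descriptor <- function(conf, signal, scheme = "u") {
  if (length(signal) != 1L || signal < 1 || signal > 32) {
    abort("signal must be in 1-32")
  }
  n <- nrow(conf$atoms)
  if (n < 2L) return(0)
  w <- atom_weights(conf$atoms$element, scheme)
  r <- conformer_distances(conf)
  iu <- which(upper.tri(r))
  rij <- r[iu]
  if (any(rij <= 0)) abort("coincident atoms in conformer")
  s <- signal - 1
  sc <- if (s == 0) rep(1, length(rij)) else sin(s * rij) / (s * rij)
  ww <- outer(w, w)[iu]
  sum(ww * sc)
}
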