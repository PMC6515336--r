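# The 85-descriptor feature block.
#
# The descriptor set is a named, versioned surrogate for the proprietary
# Marvin set: 30 physicochemical descriptors (mass, lipophilicity,
# polarizability, refractivity, H-bonding, polar surface area, elemental
# composition, drug-likeness and functional-group counts) and 55 topological
# descriptors computed from the hydrogen-suppressed molecular graph
# (connectivity, distance, shape and ring-system indices). Molecular
# polarizability is estimated from molar refractivity via the Lorentz-Lorenz
# proportionality (alpha ~ 0.3925 * MR).

DESCRIPTOR_SET_VERSION <- "diliqsar-85-v1"

PHYSCHEM_NAMES <- c(
  "molecular_weight", "clogp", "molar_refractivity", "polarizability",
  "tpsa", "hbond_donors", "hbond_acceptors", "hbond_acceptors_lipinski",
  "n_carbon", "n_nitrogen", "n_oxygen", "n_sulfur", "n_phosphorus",
  "n_fluorine", "n_chlorine", "n_bromine", "n_iodine", "n_halogen",
  "n_heteroatoms", "heteroatom_fraction", "n_hydrogen", "heavy_atom_count",
  "mean_atomic_mass", "lipinski_violations", "hbond_total",
  "n_amine_primary", "n_amine_secondary", "n_amine_tertiary",
  "n_hydroxyl", "n_carboxylic_acid")

TOPOLOGICAL_NAMES <- c(
  "n_bonds", "ring_count", "n_aromatic_atoms", "aromatic_atom_fraction",
  "n_aromatic_rings", "n_ring_atoms", "n_ring_bonds", "n_rotatable_bonds",
  "fraction_rotatable", "n_terminal_atoms", "n_branch_atoms", "max_degree",
  "mean_degree", "graph_density", "wiener_index", "mean_distance",
  "graph_diameter", "graph_radius", "mean_eccentricity",
  "eccentric_connectivity", "harary_index", "wiener_polarity",
  "zagreb_m1", "zagreb_m2", "randic_chi1", "chi0", "chi2", "balaban_j",
  "kappa1", "kappa2", "kappa3", "platt_number", "n_paths_len2",
  "n_paths_len3", "n_triangles", "girth", "chi0_valence", "chi1_valence",
  "mean_bond_order", "n_double_bonds", "n_triple_bonds", "n_single_bonds",
  "unsaturation_index", "fraction_csp3", "n_sp3_carbons", "n_sp2_carbons",
  "n_sp_carbons", "hyper_wiener", "petitjean_index", "mean_wiener",
  "log_wiener", "n_pairs_dist4", "n_pairs_dist5", "n_pairs_dist6",
  "n_pairs_dist7")

#' Names and classes of the default descriptor set
#'
#' @return data.frame with columns `name` and `class`
#'   (`physicochemical`/`topological`); exactly 85 rows (30 + 55).
#' @export
descriptor_metadata <- function() {
  data.frame(
    name = c(PHYSCHEM_NAMES, TOPOLOGICAL_NAMES),
    class = c(rep("physicochemical", length(PHYSCHEM_NAMES)),
              rep("topological", length(TOPOLOGICAL_NAMES))),
    stringsAsFactors = FALSE
  )
}

# element data for valence-corrected connectivity indices (Kier-Hall deltas)
ELEMENT_Z <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15,
               S = 16, Cl = 17, Se = 34, Br = 35, I = 53)
ELEMENT_ZV <- c(H = 1, B = 3, C = 4, N = 5, O = 6, F = 7, Si = 4, P = 5,
                S = 6, Cl = 7, Se = 6, Br = 7, I = 7)
ELEMENT_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3,
                     S = 2, Cl = 1, Se = 2, Br = 1, I = 1)

# atoms of a SMILES string with aromaticity flags, in token order
smiles_atoms <- function(s) {
  el <- character(0); arom <- logical(0)
  chars <- strsplit(s, "")[[1]]
  i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      content <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      sym <- bracket_element(content)
      if (!identical(sym, "H")) {
        el <- c(el, sym)
        body <- sub("^[0-9]*", "", content)
        arom <- c(arom, grepl("^[a-z]", body))
      }
      i <- j + 1L
    } else if (i < n && paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      el <- c(el, paste0(ch, chars[i + 1L])); arom <- c(arom, FALSE); i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      el <- c(el, ch); arom <- c(arom, FALSE); i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      el <- c(el, toupper(ch)); arom <- c(arom, TRUE); i <- i + 1L
    } else i <- i + 1L
  }
  data.frame(element = el, aromatic = arom, stringsAsFactors = FALSE)
}

# hydrogen-suppressed molecular graph of one standardized SMILES
mol_graph <- function(smiles) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  fallback <- tryCatch({
    ChemmineR::atomblock(sdf[[1]]); FALSE
  }, error = function(e) TRUE)
  if (fallback) {
    # single-atom molecules produce a bond-free SDF that ChemmineR's
    # accessors reject; fall back to the SMILES token parse
    atoms <- smiles_atoms(smiles)
    return(list(sdf = NULL, n = nrow(atoms), elements = atoms$element,
                edges = matrix(integer(0), 0, 2), orders = numeric(0)))
  }
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  elements <- sub("_.*$", "", rownames(ab))
  nb <- nrow(ab)
  bb <- ChemmineR::bondblock(mol)
  if (is.null(dim(bb)) || nrow(bb) == 0) {
    edges <- matrix(integer(0), 0, 2)
    orders <- numeric(0)
  } else {
    edges <- cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
    orders <- as.numeric(bb[, 3])
  }
  list(sdf = sdf, n = nb, elements = elements, edges = edges, orders = orders)
}

descriptor_row_one <- function(smiles) {
  props <- mol_props(smiles)
  if (is.na(props$cansmi[1])) return(NULL)
  # all graph work happens on the stereo-free canonical form, so descriptor
  # values are invariant to how the input SMILES was written
  can <- props$cansmiNS[1]
  g <- mol_graph(can)
  atoms <- smiles_atoms(can)

  el <- g$elements
  n_heavy <- g$n
  counts <- table(factor(el, levels = names(ELEMENT_Z)))
  formula <- props$formula[1]
  nH <- formula_count(formula, "H")
  n_hal <- sum(counts[c("F", "Cl", "Br", "I")])
  n_het <- n_heavy - counts[["C"]]
  lip <- sum(props$MW[1] > 500, props$logP[1] > 5, props$HBD[1] > 5,
             props$HBA1[1] > 10)
  grp <- functional_groups(g$sdf)

  phys <- c(
    molecular_weight = props$MW[1],
    clogp = props$logP[1],
    molar_refractivity = props$MR[1],
    polarizability = 0.3925 * props$MR[1],
    tpsa = props$TPSA[1],
    hbond_donors = props$HBD[1],
    hbond_acceptors = props$HBA1[1],
    hbond_acceptors_lipinski = props$HBA2[1],
    n_carbon = counts[["C"]],
    n_nitrogen = counts[["N"]],
    n_oxygen = counts[["O"]],
    n_sulfur = counts[["S"]],
    n_phosphorus = counts[["P"]],
    n_fluorine = counts[["F"]],
    n_chlorine = counts[["Cl"]],
    n_bromine = counts[["Br"]],
    n_iodine = counts[["I"]],
    n_halogen = n_hal,
    n_heteroatoms = n_het,
    heteroatom_fraction = if (n_heavy > 0) n_het / n_heavy else 0,
    n_hydrogen = nH,
    heavy_atom_count = n_heavy,
    mean_atomic_mass = props$MW[1] / max(1, n_heavy + nH),
    lipinski_violations = lip,
    hbond_total = props$HBD[1] + props$HBA1[1],
    n_amine_primary = grp[["RNH2"]],
    n_amine_secondary = grp[["R2NH"]],
    n_amine_tertiary = grp[["R3N"]],
    n_hydroxyl = grp[["ROH"]],
    n_carboxylic_acid = grp[["RCOOH"]]
  )
  topo <- topological_descriptors(g, atoms, nH)
  row <- c(phys, topo)
  stopifnot(identical(names(row), c(PHYSCHEM_NAMES, TOPOLOGICAL_NAMES)))
  row
}

formula_count <- function(formula, element) {
  m <- regmatches(formula,
                  regexpr(paste0(element, "(?![a-z])[0-9]*"), formula, perl = TRUE))
  if (!length(m)) return(0)
  d <- sub(paste0("^", element), "", m)
  if (nzchar(d)) as.numeric(d) else 1
}

functional_groups <- function(sdf) {
  want <- c("RNH2", "R2NH", "R3N", "ROH", "RCOOH")
  if (is.null(sdf)) return(stats::setNames(rep(0, length(want)), want))
  grp <- tryCatch(
    suppressWarnings(ChemmineR::groups(sdf, groups = "fctgroup", type = "countMA")),
    error = function(e) NULL)
  out <- stats::setNames(rep(0, length(want)), want)
  if (!is.null(grp)) {
    grp <- as.matrix(grp)
    for (w in intersect(want, colnames(grp))) out[w] <- grp[1, w]
  }
  out
}

topological_descriptors <- function(g, atoms, nH) {
  n <- g$n; m <- nrow(g$edges)
  deg <- rep(0L, n)
  if (m) for (k in seq_len(m)) {
    deg[g$edges[k, 1]] <- deg[g$edges[k, 1]] + 1L
    deg[g$edges[k, 2]] <- deg[g$edges[k, 2]] + 1L
  }
  ig <- igraph::make_empty_graph(n, directed = FALSE)
  if (m) ig <- igraph::add_edges(ig, t(g$edges))
  D <- igraph::distances(ig)
  finite_pairs <- is.finite(D) & upper.tri(D)
  dvals <- D[finite_pairs]
  comps <- igraph::components(ig)$no
  ring_count <- m - n + comps

  # aromatic atoms / rings from the canonical SMILES and its subgraph
  arom_idx <- which(atoms$aromatic)
  n_arom <- length(arom_idx)
  n_arom_rings <- aromatic_ring_count(atoms, g)

  bridges_e <- if (m) igraph::bridges(ig) else integer(0)
  is_bridge <- rep(FALSE, m)
  if (length(bridges_e)) is_bridge[as.integer(bridges_e)] <- TRUE
  ring_bonds <- sum(!is_bridge)
  ring_atoms <- if (m) length(unique(as.vector(g$edges[!is_bridge, , drop = FALSE]))) else 0
  rot <- if (m) sum(is_bridge & g$orders == 1 &
                      deg[g$edges[, 1]] > 1 & deg[g$edges[, 2]] > 1) else 0

  ecc <- if (n > 1 && all(is.finite(D))) apply(D, 1, max) else rep(0, n)
  wiener <- sum(dvals)
  npairs <- max(1, n * (n - 1) / 2)
  harary <- sum(1 / dvals[dvals > 0])
  zg1 <- sum(deg^2)
  zg2 <- if (m) sum(deg[g$edges[, 1]] * deg[g$edges[, 2]]) else 0
  chi1 <- if (m) sum(1 / sqrt(deg[g$edges[, 1]] * deg[g$edges[, 2]])) else 0
  chi0 <- sum(1 / sqrt(pmax(deg, 1)))
  # paths of length 2 through each middle vertex, with branch deltas for chi2
  p2 <- sum(choose(deg, 2))
  chi2 <- 0
  adj <- igraph::as_adj_list(ig)
  for (v in seq_len(n)) {
    nb <- as.integer(adj[[v]])
    if (length(nb) >= 2) {
      prs <- utils::combn(nb, 2)
      chi2 <- chi2 + sum(1 / sqrt(deg[prs[1, ]] * deg[v] * deg[prs[2, ]]))
    }
  }
  tri <- sum(igraph::count_triangles(ig)) / 3
  p3 <- if (m) sum((deg[g$edges[, 1]] - 1) * (deg[g$edges[, 2]] - 1)) - 3 * tri else 0
  girth_v <- suppressWarnings(igraph::girth(ig)$girth)
  if (!is.finite(girth_v)) girth_v <- 0

  balaban <- 0
  if (m && all(is.finite(D)) && n > 1) {
    srow <- rowSums(D)
    mu <- ring_count
    balaban <- m / (mu + 1) *
      sum(1 / sqrt(srow[g$edges[, 1]] * srow[g$edges[, 2]]))
  }
  kappa1 <- if (m > 0) n * (n - 1)^2 / m^2 else 0
  kappa2 <- if (p2 > 0) (n - 1) * (n - 2)^2 / p2^2 else 0
  kappa3 <- if (p3 > 0 && n >= 4) (n - 1) * (n - 3)^2 / p3^2 else 0
  platt <- if (m) sum(deg[g$edges[, 1]] + deg[g$edges[, 2]] - 2) else 0

  # valence deltas (Kier-Hall); implicit H from standard valences
  hv <- implicit_h(g, deg)
  zv <- ELEMENT_ZV[g$elements]; z <- ELEMENT_Z[g$elements]
  denom <- pmax(z - zv - 1, 1)
  dv <- pmax((zv - hv) / denom, 0.25)
  chi0v <- sum(1 / sqrt(dv))
  chi1v <- if (m) sum(1 / sqrt(dv[g$edges[, 1]] * dv[g$edges[, 2]])) else 0

  ords <- g$orders
  n_double <- sum(ords == 2); n_triple <- sum(ords == 3)
  n_single <- sum(ords == 1)
  dbe <- unsaturation(g, nH)
  carbons <- which(g$elements == "C")
  csp3 <- csp2 <- csp <- 0
  if (length(carbons) && m) {
    for (ci in carbons) {
      o <- ords[g$edges[, 1] == ci | g$edges[, 2] == ci]
      arom_here <- ci <= nrow(atoms) && atoms$aromatic[ci]
      if (any(o == 3) || sum(o == 2) >= 2) csp <- csp + 1
      else if (any(o >= 2) || arom_here) csp2 <- csp2 + 1
      else csp3 <- csp3 + 1
    }
  } else csp3 <- length(carbons)
  hyperw <- 0.5 * sum(dvals + dvals^2)
  diam <- if (length(dvals)) max(dvals) else 0
  radius <- if (n > 1 && all(is.finite(D))) min(ecc[ecc > 0]) else 0
  petitjean <- if (radius > 0) (diam - radius) / radius else 0

  c(
    n_bonds = m,
    ring_count = ring_count,
    n_aromatic_atoms = n_arom,
    aromatic_atom_fraction = if (n > 0) n_arom / n else 0,
    n_aromatic_rings = n_arom_rings,
    n_ring_atoms = ring_atoms,
    n_ring_bonds = ring_bonds,
    n_rotatable_bonds = rot,
    fraction_rotatable = if (m > 0) rot / m else 0,
    n_terminal_atoms = sum(deg == 1),
    n_branch_atoms = sum(deg >= 3),
    max_degree = if (n) max(deg) else 0,
    mean_degree = mean(deg),
    graph_density = if (n > 1) 2 * m / (n * (n - 1)) else 0,
    wiener_index = wiener,
    mean_distance = if (length(dvals)) mean(dvals) else 0,
    graph_diameter = diam,
    graph_radius = radius,
    mean_eccentricity = mean(ecc),
    eccentric_connectivity = sum(deg * ecc),
    harary_index = harary,
    wiener_polarity = sum(dvals == 3),
    zagreb_m1 = zg1,
    zagreb_m2 = zg2,
    randic_chi1 = chi1,
    chi0 = chi0,
    chi2 = chi2,
    balaban_j = balaban,
    kappa1 = kappa1,
    kappa2 = kappa2,
    kappa3 = kappa3,
    platt_number = platt,
    n_paths_len2 = p2,
    n_paths_len3 = max(p3, 0),
    n_triangles = tri,
    girth = girth_v,
    chi0_valence = chi0v,
    chi1_valence = chi1v,
    mean_bond_order = if (m) mean(ords) else 0,
    n_double_bonds = n_double,
    n_triple_bonds = n_triple,
    n_single_bonds = n_single,
    unsaturation_index = dbe,
    fraction_csp3 = if (length(carbons)) csp3 / length(carbons) else 0,
    n_sp3_carbons = csp3,
    n_sp2_carbons = csp2,
    n_sp_carbons = csp,
    hyper_wiener = hyperw,
    petitjean_index = petitjean,
    mean_wiener = wiener / npairs,
    log_wiener = log1p(wiener),
    n_pairs_dist4 = sum(dvals == 4),
    n_pairs_dist5 = sum(dvals == 5),
    n_pairs_dist6 = sum(dvals == 6),
    n_pairs_dist7 = sum(dvals == 7)
  )
}

implicit_h <- function(g, deg) {
  if (!g$n) return(numeric(0))
  bond_sum <- rep(0, g$n)
  if (nrow(g$edges)) for (k in seq_len(nrow(g$edges))) {
    bond_sum[g$edges[k, 1]] <- bond_sum[g$edges[k, 1]] + g$orders[k]
    bond_sum[g$edges[k, 2]] <- bond_sum[g$edges[k, 2]] + g$orders[k]
  }
  val <- ELEMENT_VALENCE[g$elements]
  val[is.na(val)] <- deg[is.na(val)]
  pmax(val - bond_sum, 0)
}

unsaturation <- function(g, nH) {
  counts <- table(factor(g$elements, levels = names(ELEMENT_Z)))
  x_like <- sum(counts[c("F", "Cl", "Br", "I")])
  counts[["C"]] + counts[["Si"]] - (nH + x_like) / 2 +
    (counts[["N"]] + counts[["P"]]) / 2 + 1
}

# aromatic SSSR-equivalent count: cyclomatic number of the subgraph induced
# by aromatic atoms of the canonical SMILES (atom order matches the SDF that
# Open Babel writes from the same canonical SMILES)
aromatic_ring_count <- function(atoms, g) {
  if (!any(atoms$aromatic)) return(0)
  # rebuild the graph from the canonical SMILES so indices line up
  can <- g
  if (nrow(atoms) != g$n) return(0)
  arom <- which(atoms$aromatic)
  keep <- can$edges[, 1] %in% arom & can$edges[, 2] %in% arom
  sub_edges <- can$edges[keep, , drop = FALSE]
  if (!nrow(sub_edges)) return(0)
  ig <- igraph::make_empty_graph(can$n, directed = FALSE)
  ig <- igraph::add_edges(ig, t(sub_edges))
  used <- unique(as.vector(sub_edges))
  nrow(sub_edges) - length(used) + igraph::components(
    igraph::induced_subgraph(ig, used))$no
}

#' Compute the default 85-descriptor block
#'
#' @param x compound record data.frame (active rows are used) or a character
#'   vector of standardized SMILES. Computing on an already-standardized
#'   molecule is a no-op on the values (standardization invariance).
#' @return numeric matrix, one row per compound (rownames = compound ids),
#'   85 named columns. Molecules whose descriptor row contains a non-finite
#'   value are dropped from the matrix and reported via the `"failed_ids"`
#'   attribute and a message.
#' @export
compute_descriptors <- function(x) {
  if (is.data.frame(x)) {
    x <- active_records(x)
    smiles <- x$smiles
    ids <- x$compound_id
  } else {
    smiles <- as.character(x)
    ids <- if (!is.null(names(x))) names(x) else paste0("mol", seq_along(x))
  }
  meta <- descriptor_metadata()
  out <- matrix(NA_real_, length(smiles), nrow(meta),
                dimnames = list(ids, meta$name))
  for (i in seq_along(smiles)) {
    row <- tryCatch(descriptor_row_one(smiles[i]), error = function(e) NULL)
    if (!is.null(row)) out[i, ] <- row
  }
  ok <- apply(out, 1, function(r) all(is.finite(r)))
  if (!all(ok)) {
    message("descriptor computation failed for: ",
            paste(ids[!ok], collapse = ", "))
  }
  res <- out[ok, , drop = FALSE]
  attr(res, "failed_ids") <- ids[!ok]
  attr(res, "descriptor_set") <- DESCRIPTOR_SET_VERSION
  res
}

#' Hashed linear-path (FP2) fingerprints
#'
#' Open Babel FP2 fingerprints: all linear fragments up to 7 bonds, hashed
#' into 1021 of 1024 bits. For `nbits < 1024` the native fingerprint is
#' folded by bitwise OR. A molecule with no eligible paths (e.g. methane)
#' yields the all-zero fingerprint.
#'
#' @param x compound record data.frame (active rows) or character vector of
#'   SMILES.
#' @param nbits fingerprint length; 1024 (native) by default, smaller values
#'   must divide 1024.
#' @return binary integer matrix, one row per molecule.
#' @export
compute_fingerprint <- function(x, nbits = 1024) {
  if (is.data.frame(x)) {
    x <- active_records(x)
    smiles <- stats::setNames(x$smiles, x$compound_id)
  } else {
    smiles <- as.character(x)
    names(smiles) <- if (!is.null(names(x))) names(x) else paste0("mol", seq_along(x))
  }
  stopifnot(nbits >= 1, 1024 %% nbits == 0)
  mat <- matrix(0L, length(smiles), 1024)
  for (i in seq_along(smiles)) {
    # per molecule: a degenerate structure (no eligible path, e.g. methane)
    # keeps the documented all-zero fingerprint instead of failing the batch
    row <- tryCatch({
      sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles[i]))
      as.integer(ChemmineR::fingerprintOB(sdf, "FP2")@fpma[1, ])
    }, error = function(e) rep(0L, 1024))
    mat[i, ] <- row
  }
  rownames(mat) <- names(smiles)
  if (nbits < 1024) {
    folds <- 1024 / nbits
    folded <- matrix(0L, nrow(mat), nbits, dimnames = list(rownames(mat), NULL))
    for (f in seq_len(folds)) {
      blk <- mat[, ((f - 1) * nbits + 1):(f * nbits), drop = FALSE]
      folded <- pmax(folded, blk)
    }
    mat <- folded
  }
  mat
}

#' Tanimoto similarity of two bit fingerprints
#'
#' `|a AND b| / |a OR b|`; two all-zero fingerprints are defined as
#' identical (similarity 1), so degenerate molecules compare as equal.
#'
#' @param a,b binary vectors of equal length.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint length mismatch: ",
                                   length(a), " vs ", length(b))
  a <- as.logical(a); b <- as.logical(b)
  un <- sum(a | b)
  if (un == 0) return(1.0)
  sum(a & b) / un
}

#' Chemical diversity and chemical-space summary of a dataset
#'
#' Mean pairwise FP2 Tanimoto similarity over all unordered pairs, its
#' histogram, and the molecular-weight / ClogP ranges spanning the dataset's
#' chemical space.
#'
#' @param records compound record data.frame with >= 2 active compounds.
#' @param breaks histogram breaks on `[0, 1]`.
#' @return list with `mean_tanimoto`, `histogram` (object of class
#'   `histogram`), `n_pairs`, `mw_range`, `clogp_range`.
#' @export
diversity_summary <- function(records, breaks = seq(0, 1, by = 0.1)) {
  act <- active_records(records)
  if (nrow(act) < 2) stop("diversity_summary() needs at least 2 active compounds")
  fps <- compute_fingerprint(act)
  n <- nrow(fps)
  sims <- numeric(n * (n - 1) / 2)
  k <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    k <- k + 1L
    sims[k] <- tanimoto(fps[i, ], fps[j, ])
  }
  props <- mol_props(act$smiles)
  list(
    mean_tanimoto = mean(sims),
    histogram = graphics::hist(sims, breaks = breaks, plot = FALSE),
    n_pairs = length(sims),
    mw_range = range(props$MW, na.rm = TRUE),
    clogp_range = range(props$logP, na.rm = TRUE)
  )
}
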