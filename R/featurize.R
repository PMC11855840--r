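# Molecular graph construction: SMILES -> featurized graph.
#
# Parsing and structure perception go through Open Babel (ChemmineOB) via
# ChemmineR; the SDF export is kekulized, so atom aromaticity is taken from
# the SMILES notation itself (lowercase organic-subset / bracket atoms),
# ring membership from smallest-ring perception, and implicit hydrogens,
# hybridization and conjugation from standard valence rules.
#
# Feature layout (row conventions; every one-hot block carries a trailing
# "other" slot for out-of-vocabulary categories):
#   atoms (133): atomic number 1..100 (+other) | heavy degree 0..5 (+other) |
#     formal charge -1,-2,+1,+2,0 (+other) | chirality none,CW,CCW,other (+other) |
#     implicit H 0..4 (+other) | hybridization SP,SP2,SP3,SP3D,SP3D2 (+other) |
#     aromatic flag | atomic mass / 100
#   bonds (14): null-bond flag | single,double,triple,aromatic | conjugated |
#     in-ring | stereo none,any,Z,E,cis,trans (+other)

.ELEM <- c("H","He","Li","Be","B","C","N","O","F","Ne","Na","Mg","Al","Si","P",
  "S","Cl","Ar","K","Ca","Sc","Ti","V","Cr","Mn","Fe","Co","Ni","Cu","Zn","Ga",
  "Ge","As","Se","Br","Kr","Rb","Sr","Y","Zr","Nb","Mo","Tc","Ru","Rh","Pd",
  "Ag","Cd","In","Sn","Sb","Te","I","Xe","Cs","Ba","La","Ce","Pr","Nd","Pm",
  "Sm","Eu","Gd","Tb","Dy","Ho","Er","Tm","Yb","Lu","Hf","Ta","W","Re","Os",
  "Ir","Pt","Au","Hg","Tl","Pb","Bi","Po","At","Rn","Fr","Ra","Ac","Th","Pa",
  "U","Np","Pu","Am","Cm","Bk","Cf","Es","Fm")

.MASS <- c(1.008,4.003,6.94,9.012,10.81,12.011,14.007,15.999,18.998,20.180,
  22.990,24.305,26.982,28.085,30.974,32.06,35.45,39.948,39.098,40.078,44.956,
  47.867,50.942,51.996,54.938,55.845,58.933,58.693,63.546,65.38,69.723,72.630,
  74.922,78.971,79.904,83.798,85.468,87.62,88.906,91.224,92.906,95.95,98,
  101.07,102.906,106.42,107.868,112.414,114.818,118.710,121.760,127.60,
  126.904,131.293,132.905,137.327,138.905,140.116,140.908,144.242,145,150.36,
  151.964,157.25,158.925,162.500,164.930,167.259,168.934,173.045,174.967,
  178.49,180.948,183.84,186.207,190.23,192.217,195.084,196.967,200.592,
  204.38,207.2,208.980,209,210,222,223,226,227,232.038,231.036,238.029,237,
  244,243,247,247,251,252,257)

# default valences for implicit-H assignment (charge-adjusted)
.VALENCE <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
              Cl = 1, Br = 1, I = 1)

ATOM_FDIM <- 133L
BOND_FDIM <- 14L

.onehot <- function(value, choices) {
  v <- numeric(length(choices) + 1L)
  i <- match(value, choices)
  v[if (is.na(i)) length(v) else i] <- 1
  v
}

# Lexical scan of a SMILES string: atom symbols in order with an aromatic
# flag from lowercase notation. Used only for aromaticity; structure comes
# from Open Babel.
scan_smiles_atoms <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  syms <- character(0); arom <- logical(0)
  i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unmatched '[' in SMILES: ", smiles)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(body, regexpr("[A-Za-z][a-z]?", body))[1]
      # inside brackets a trailing lowercase may be explicit H ([CH3]) rather
      # than a two-letter element; accept two letters only for real elements
      if (!(m %in% .ELEM) && !(toupper(substr(m, 1, 1)) %in% .ELEM && nchar(m) == 1L))
        m <- substr(m, 1, 1)
      if (nchar(m) == 2L && !(m %in% .ELEM)) m <- substr(m, 1, 1)
      if (nchar(m) == 2L && substr(m, 2, 2) == "H" && substr(m, 1, 1) %in% .ELEM)
        m <- substr(m, 1, 1)  # e.g. [CH], [NH]
      is_arom <- m %in% c("b", "c", "n", "o", "p", "s", "se", "as")
      syms <- c(syms, if (is_arom) paste0(toupper(substr(m, 1, 1)), substr(m, 2, 10)) else m)
      arom <- c(arom, is_arom)
      i <- j + 1L
    } else if (i < n && paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      syms <- c(syms, paste0(ch, chars[i + 1L])); arom <- c(arom, FALSE)
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      syms <- c(syms, ch); arom <- c(arom, FALSE); i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      syms <- c(syms, toupper(ch)); arom <- c(arom, TRUE); i <- i + 1L
    } else {
      i <- i + 1L  # bonds, branches, ring closures, digits
    }
  }
  list(symbols = syms, aromatic = arom)
}

.parse_sdf <- function(smiles) {
  nm <- "m"
  smi <- smiles; names(smi) <- nm
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smi)),
                  error = function(e) NULL)
  if (is.null(sdf)) stop("cannot parse SMILES string: '", smiles, "'")
  sdf[[1]]
}

#' Build a featurized molecular graph from a SMILES string
#'
#' Parses a SMILES string and returns the atom feature matrix
#' (`n_atoms` x 133), the bond feature matrix (`n_bonds` x 14, one row per
#' undirected bond) and a directed edge list (two directed edges per bond)
#' ready for message passing. Hydrogens are implicit; atoms appear in SMILES
#' order.
#'
#' @param smiles a single SMILES string
#' @return an object of class `mol_graph` with elements `atom_features`,
#'   `bond_features`, `edges` (2*n_bonds x 2 integer matrix, columns
#'   source/target), `edge_bond` (undirected bond index of each directed
#'   edge), `n_atoms`, `n_bonds`, `smiles`
#' @examples
#' g <- build_mol_graph("CCO")
#' dim(g$atom_features)  # 3 x 133
#' @export
build_mol_graph <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  scan0 <- scan_smiles_atoms(smiles)
  if (length(scan0$symbols) == 0L) stop("SMILES '", smiles, "' yields an empty molecule")
  if (length(scan0$symbols) == 1L) return(.single_atom_graph(smiles, scan0))
  sdfobj <- .parse_sdf(smiles)
  ab <- ChemmineR::atomblock(sdfobj)
  if (is.null(ab) || nrow(ab) == 0L) stop("SMILES '", smiles, "' yields an empty molecule")
  bb <- ChemmineR::bondblock(sdfobj)
  n_atoms <- nrow(ab)
  n_bonds <- if (is.null(bb)) 0L else nrow(bb)

  sym <- sub("_.*$", "", rownames(ab))
  col_or_zero <- function(nm) if (nm %in% colnames(ab)) ab[, nm] else rep(0L, n_atoms)
  charge_code <- col_or_zero("C6")
  charge <- c(0, 3, 2, 1, 0, -1, -2, -3)[charge_code + 1L]
  parity <- col_or_zero("C7")

  scan <- scan_smiles_atoms(smiles)
  aromatic <- if (length(scan$symbols) == n_atoms) scan$aromatic else rep(FALSE, n_atoms)

  src <- if (n_bonds) as.integer(bb[, "C1"]) else integer(0)
  dst <- if (n_bonds) as.integer(bb[, "C2"]) else integer(0)
  order <- if (n_bonds) as.integer(bb[, "C3"]) else integer(0)
  wedge <- if (n_bonds) as.integer(bb[, "C4"]) else integer(0)

  # per-atom bond bookkeeping
  deg <- tabulate(c(src, dst), nbins = n_atoms)
  bondsum <- numeric(n_atoms)
  has_multi <- logical(n_atoms)   # any double/triple bond on the atom
  n_double <- integer(n_atoms)
  has_triple <- logical(n_atoms)
  for (b in seq_len(n_bonds)) {
    o <- order[b]
    bondsum[src[b]] <- bondsum[src[b]] + o
    bondsum[dst[b]] <- bondsum[dst[b]] + o
    if (o >= 2L) { has_multi[src[b]] <- TRUE; has_multi[dst[b]] <- TRUE }
    if (o == 2L) { n_double[src[b]] <- n_double[src[b]] + 1L
                   n_double[dst[b]] <- n_double[dst[b]] + 1L }
    if (o == 3L) { has_triple[src[b]] <- TRUE; has_triple[dst[b]] <- TRUE }
  }

  base_val <- .VALENCE[sym]
  base_val[is.na(base_val)] <- 0
  eff_val <- base_val + charge
  n_h <- pmax(0, round(eff_val - bondsum))
  n_h[!(sym %in% names(.VALENCE))] <- 0

  hyb <- ifelse(aromatic, "SP2",
         ifelse(has_triple | n_double >= 2L, "SP",
         ifelse(has_multi, "SP2", "SP3")))

  # ring bonds from smallest-ring perception
  in_ring <- rep(FALSE, n_bonds)
  if (n_bonds > 0L) {
    rg <- tryCatch(
      suppressWarnings(ChemmineR::rings(sdfobj, type = "all", arom = FALSE, inner = TRUE)),
      error = function(e) NULL)
    ring_list <- if (is.list(rg) && !is.null(rg$RINGS)) rg$RINGS else rg
    if (length(ring_list)) {
      key <- function(a, b) paste(pmin(a, b), pmax(a, b))
      bkey <- key(src, dst)
      ringkeys <- unlist(lapply(ring_list, function(r) {
        ix <- as.integer(sub("^.*_", "", r))
        key(ix, c(ix[-1L], ix[1L]))
      }))
      in_ring <- bkey %in% ringkeys
    }
  }

  arom_bond <- aromatic[src] & aromatic[dst] & in_ring
  pi_cap <- has_multi | aromatic | sym %in% c("N", "O", "S")
  conj <- (pi_cap[src] & pi_cap[dst]) & (arom_bond | order >= 2L |
            ((has_multi | aromatic)[src] & (has_multi | aromatic)[dst]))

  chir <- ifelse(parity == 1L, "CW", ifelse(parity == 2L, "CCW",
          ifelse(parity == 3L, "OTHER", "NONE")))

  atom_features <- t(vapply(seq_len(n_atoms), function(i) {
    z <- match(sym[i], .ELEM)
    c(.onehot(if (is.na(z)) -1L else z, 1:100),
      .onehot(deg[i], 0:5),
      .onehot(charge[i], c(-1, -2, 1, 2, 0)),
      .onehot(chir[i], c("NONE", "CW", "CCW", "OTHER")),
      .onehot(n_h[i], 0:4),
      .onehot(hyb[i], c("SP", "SP2", "SP3", "SP3D", "SP3D2")),
      as.numeric(aromatic[i]),
      if (is.na(z)) 0 else .MASS[z] / 100)
  }, numeric(ATOM_FDIM)))
  if (n_atoms == 1L) atom_features <- matrix(atom_features, 1L, ATOM_FDIM)

  bond_features <- matrix(0, n_bonds, BOND_FDIM)
  for (b in seq_len(n_bonds)) {
    btype <- if (arom_bond[b]) "aromatic" else c("single", "double", "triple")[order[b]]
    stereo <- if (wedge[b] != 0L) "ANY" else "NONE"
    bond_features[b, ] <- c(0,
      .onehot(btype, c("single", "double", "triple", "aromatic"))[1:4],
      as.numeric(conj[b]),
      as.numeric(in_ring[b]),
      .onehot(stereo, c("NONE", "ANY", "Z", "E", "CIS", "TRANS")))
  }

  edges <- cbind(source = c(src, dst), target = c(dst, src))
  if (n_bonds == 0L) edges <- matrix(integer(0), 0L, 2L,
                                     dimnames = list(NULL, c("source", "target")))
  structure(list(atom_features = atom_features,
                 bond_features = bond_features,
                 edges = edges,
                 edge_bond = c(seq_len(n_bonds), seq_len(n_bonds)),
                 n_atoms = n_atoms, n_bonds = n_bonds,
                 smiles = smiles),
            class = "mol_graph")
}

# Single heavy-atom molecules cannot round-trip through an SDF block;
# build the (bond-free) graph directly from the lexical scan.
.single_atom_graph <- function(smiles, scan) {
  .parse_sdf(smiles)  # still validate parseability through Open Babel
  sym <- scan$symbols[1]
  z <- match(sym, .ELEM)
  charge <- 0L
  if (grepl("^\\[", smiles)) {
    body <- sub("^\\[(.*)\\]$", "\\1", smiles)
    pm <- regmatches(body, regexpr("[+-]+[0-9]*$", body))
    if (length(pm) && nzchar(pm)) {
      mag <- as.integer(sub("^[+-]", "", pm))
      if (is.na(mag)) mag <- nchar(pm)
      charge <- if (substr(pm, 1, 1) == "-") -mag else mag
    }
  }
  base <- .VALENCE[sym]; if (is.na(base)) base <- 0
  n_h <- max(0L, base + charge)
  af <- matrix(c(.onehot(if (is.na(z)) -1L else z, 1:100),
                 .onehot(0L, 0:5),
                 .onehot(charge, c(-1, -2, 1, 2, 0)),
                 .onehot("NONE", c("NONE", "CW", "CCW", "OTHER")),
                 .onehot(n_h, 0:4),
                 .onehot("SP3", c("SP", "SP2", "SP3", "SP3D", "SP3D2")),
                 0,
                 if (is.na(z)) 0 else .MASS[z] / 100), 1L, ATOM_FDIM)
  structure(list(atom_features = af,
                 bond_features = matrix(0, 0L, BOND_FDIM),
                 edges = matrix(integer(0), 0L, 2L,
                                dimnames = list(NULL, c("source", "target"))),
                 edge_bond = integer(0), n_atoms = 1L, n_bonds = 0L,
                 smiles = smiles),
            class = "mol_graph")
}

#' Build molecular graphs for a vector of SMILES
#'
#' @param smiles character vector
#' @return list of `mol_graph`
#' @export
build_mol_graphs <- function(smiles) lapply(smiles, build_mol_graph)

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("mol_graph: %d atoms x %d features, %d bonds x %d features (%s)\n",
              x$n_atoms, ncol(x$atom_features), x$n_bonds, ncol(x$bond_features),
              x$smiles))
  invisible(x)
}
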