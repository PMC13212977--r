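#' Default atom/bond feature scheme
#'
#' Declarative description of the drug graph featurization: ordered blocks of
#' one-hot vocabularies, flags and scalar slots. The default sums to exactly
#' 85 atom features (element one-hot with an "unknown" slot, heavy-atom
#' degree, formal charge, hybridization, chirality, implicit hydrogen count,
#' ring membership, aromaticity, atomic mass scaled by 1/100) and 10 bond
#' features (bond type one-hot single/double/triple/aromatic, conjugation
#' flag, ring flag, stereo one-hot). Alternative widths are allowed but
#' flagged when a scheme is constructed.
#'
#' @return A `feature_scheme` with elements `atom_blocks`, `bond_blocks`,
#'   `atom_dim`, `bond_dim`.
#' @export
default_feature_scheme <- function() {
  elements <- c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P", "B", "Si",
                "Se", "As", "H", "Li", "Na", "K", "Rb", "Cs", "Mg", "Ca",
                "Sr", "Ba", "Fe", "Zn", "Cu", "Mn", "Co", "Ni", "Pt", "Au",
                "Hg", "Sn", "Pb", "Al", "Cr", "V", "Ti", "Gd", "Sb", "Bi",
                "Ag", "Pd", "Mo", "W", "Ru", "Rh", "Ir", "Os", "Re", "Tc",
                "Cd", "Ga")
  feature_scheme(
    atom_blocks = list(
      list(name = "element", type = "onehot",
           vocab = c(elements, "unknown")),
      list(name = "degree", type = "onehot", vocab = as.character(0:6)),
      list(name = "formal_charge", type = "onehot",
           vocab = c("-2", "-1", "0", "1", "2", "other")),
      list(name = "hybridization", type = "onehot",
           vocab = c("s", "sp", "sp2", "sp3", "sp3d", "sp3d2", "other")),
      list(name = "chirality", type = "onehot",
           vocab = c("none", "cw", "ccw")),
      list(name = "num_h", type = "onehot", vocab = as.character(0:4)),
      list(name = "in_ring", type = "flag"),
      list(name = "aromatic", type = "flag"),
      list(name = "mass_scaled", type = "scalar")),
    bond_blocks = list(
      list(name = "bond_type", type = "onehot",
           vocab = c("single", "double", "triple", "aromatic")),
      list(name = "conjugated", type = "flag"),
      list(name = "in_ring", type = "flag"),
      list(name = "stereo", type = "onehot",
           vocab = c("none", "wedge", "hash", "other"))))
}

#' Construct a feature scheme
#'
#' @param atom_blocks,bond_blocks Lists of blocks, each a list with `name`,
#'   `type` (`"onehot"`, `"flag"`, `"scalar"`) and, for one-hots, `vocab`.
#' @return A `feature_scheme`; widths other than (85, 10) trigger a warning
#'   flag but are permitted.
#' @export
feature_scheme <- function(atom_blocks, bond_blocks) {
  dim_of <- function(blocks) sum(vapply(blocks, function(b)
    if (b$type == "onehot") length(b$vocab) else 1L, integer(1)))
  a <- dim_of(atom_blocks); b <- dim_of(bond_blocks)
  if (a != 85L || b != 10L)
    warning("non-standard feature widths (", a, ", ", b,
            "); the reference scheme uses (85, 10)")
  structure(list(atom_blocks = atom_blocks, bond_blocks = bond_blocks,
                 atom_dim = a, bond_dim = b),
            class = "feature_scheme")
}

scheme_hash <- function(scheme) {
  digestable <- rawToChar(serialize(list(scheme$atom_blocks,
                                         scheme$bond_blocks),
                                    NULL, ascii = TRUE))
  as.character(sum(utf8ToInt(digestable) * seq_along(utf8ToInt(digestable))) %% 2^31)
}

block_encode <- function(blocks, values) {
  out <- numeric(0)
  for (b in blocks) {
    v <- values[[b$name]]
    out <- c(out, switch(b$type,
      onehot = {
        hot <- numeric(length(b$vocab))
        i <- match(as.character(v), b$vocab)
        if (is.na(i)) i <- match("unknown", b$vocab)
        if (is.na(i)) i <- match("other", b$vocab)
        if (!is.na(i)) hot[i] <- 1
        hot
      },
      flag = as.numeric(isTRUE(v) || (is.numeric(v) && v != 0)),
      scalar = as.numeric(v)))
  }
  out
}

# atomic masses for the mass_scaled slot
.atomic_mass <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998, Na = 22.99, Mg = 24.305, Al = 26.982, Si = 28.085, P = 30.974,
  S = 32.06, Cl = 35.45, K = 39.098, Ca = 40.078, Ti = 47.867, V = 50.942,
  Cr = 51.996, Mn = 54.938, Fe = 55.845, Co = 58.933, Ni = 58.693,
  Cu = 63.546, Zn = 65.38, Ga = 69.723, As = 74.922, Se = 78.971,
  Br = 79.904, Rb = 85.468, Sr = 87.62, Mo = 95.95, Tc = 98, Ru = 101.07,
  Rh = 102.906, Pd = 106.42, Ag = 107.868, Cd = 112.414, Sn = 118.71,
  Sb = 121.76, I = 126.904, Cs = 132.905, Ba = 137.327, Gd = 157.25,
  W = 183.84, Re = 186.207, Os = 190.23, Ir = 192.217, Pt = 195.084,
  Au = 196.967, Hg = 200.592, Pb = 207.2, Bi = 208.98, Li = 6.94)

# V2000 old-style charge codes (atom block field 6)
.v2000_charge <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1,
                   `6` = -2, `7` = -3)

parse_molblock <- function(sdf) {
  txt <- tryCatch(ChemmineR::sdf2str(sdf), error = function(e) NULL)
  if (is.null(txt)) {
    # bondless molecules (single heavy atom): fall back to the atom block
    ab <- ChemmineR::atomblock(sdf)
    element <- sub("_.*$", "", rownames(ab))
    return(list(element = element, charge = rep(0, length(element)),
                bonds = data.frame(a1 = integer(0), a2 = integer(0),
                                   order = integer(0), stereo = integer(0))))
  }
  counts <- txt[4]
  n_atoms <- as.integer(substr(counts, 1, 3))
  n_bonds <- as.integer(substr(counts, 4, 6))
  atom_lines <- txt[5:(4 + n_atoms)]
  element <- trimws(substr(atom_lines, 32, 34))
  charge_code <- as.integer(trimws(substr(atom_lines, 37, 39)))
  charge <- unname(.v2000_charge[as.character(charge_code)])
  charge[is.na(charge)] <- 0
  # M CHG property lines override the old-style codes
  chg_lines <- grep("^M  CHG", txt, value = TRUE)
  for (ln in chg_lines) {
    f <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "[[:space:]]+")[[1]])
    k <- f[1]
    for (i in seq_len(k)) {
      charge[f[2 * i]] <- f[2 * i + 1]
    }
  }
  if (n_bonds > 0) {
    bond_lines <- txt[(5 + n_atoms):(4 + n_atoms + n_bonds)]
    bonds <- data.frame(
      a1 = as.integer(substr(bond_lines, 1, 3)),
      a2 = as.integer(substr(bond_lines, 4, 6)),
      order = as.integer(substr(bond_lines, 7, 9)),
      stereo = as.integer(substr(bond_lines, 10, 12)))
    bonds$stereo[is.na(bonds$stereo)] <- 0L
  } else {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0),
                        order = integer(0), stereo = integer(0))
  }
  list(element = element, charge = charge, bonds = bonds)
}

# heavy-atom chirality annotations read off the SMILES bracket atoms, in
# input atom order (OpenBabel preserves SMILES atom order; the 2D MOL block
# itself carries no stereo parity)
smiles_chirality <- function(smiles) {
  tokens <- gregexpr(
    "\\[[^]]*\\]|Cl|Br|b|c|n|o|s|p|B|C|N|O|S|P|F|I|\\*",
    smiles)[[1]]
  if (tokens[1] == -1) return(character(0))
  len <- attr(tokens, "match.length")
  out <- character(0)
  for (i in seq_along(tokens)) {
    tok <- substr(smiles, tokens[i], tokens[i] + len[i] - 1)
    if (startsWith(tok, "[")) {
      # skip explicit-hydrogen-only bracket atoms like [H] or [2H]
      if (grepl("^\\[[0-9]*H[^a-z]*\\]$", tok)) next
      out <- c(out, if (grepl("@@", tok)) "cw"
               else if (grepl("@", tok)) "ccw" else "none")
    } else out <- c(out, "none")
  }
  out
}

#' Featurize a SMILES string into an atom-bond graph
#'
#' Parses the molecule (implicit hydrogens, salts/fragments kept as
#' disconnected components) and builds the numeric graph consumed by the
#' drug encoder: per-atom feature rows, a directed edge index in which each
#' chemical bond appears as two directed edges, and per-directed-edge bond
#' feature rows.
#'
#' @param smiles A single SMILES string.
#' @param scheme A `feature_scheme` (default [default_feature_scheme()]).
#' @return A `drug_graph`: list with `atom_features` (n_atoms x atom_dim),
#'   `bond_index` (n_directed_edges x 2, 1-based), `bond_features`
#'   (n_directed_edges x bond_dim), `smiles`.
#' @export
featurize_drug <- function(smiles, scheme = default_feature_scheme()) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  sdfset <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) stop("unparseable SMILES '", smiles, "': ",
                             conditionMessage(e), call. = FALSE))
  mol <- parse_molblock(sdfset[[1]])
  n_atoms <- length(mol$element)
  if (n_atoms < 1) stop("unparseable SMILES '", smiles, "': no atoms")

  # ring/aromaticity perception
  ring_atoms <- integer(0); arom_atoms <- integer(0)
  arom_bond <- rep(FALSE, nrow(mol$bonds))
  ring_bond <- rep(FALSE, nrow(mol$bonds))
  if (nrow(mol$bonds) > 0) {
    rr <- tryCatch(suppressWarnings(
      ChemmineR::rings(sdfset[[1]], type = "all", arom = TRUE)),
      error = function(e) list(RINGS = list(), AROMATIC = logical(0)))
    ring_list <- lapply(rr$RINGS, function(r)
      as.integer(sub("^.*_", "", r)))
    arom_flags <- vapply(seq_along(ring_list), function(k)
      isTRUE(as.logical(rr$AROMATIC[k])), logical(1))
    for (k in seq_along(ring_list)) {
      ring_atoms <- union(ring_atoms, ring_list[[k]])
      if (arom_flags[k]) arom_atoms <- union(arom_atoms, ring_list[[k]])
    }
    if (length(ring_list)) {
      in_same_ring <- function(a, b, rings) any(vapply(rings, function(r)
        a %in% r && b %in% r, logical(1)))
      arom_rings <- ring_list[arom_flags]
      for (e in seq_len(nrow(mol$bonds))) {
        a <- mol$bonds$a1[e]; b <- mol$bonds$a2[e]
        ring_bond[e] <- in_same_ring(a, b, ring_list)
        arom_bond[e] <- length(arom_rings) > 0 &&
          in_same_ring(a, b, arom_rings)
      }
    }
  }

  # per-atom bond-order bookkeeping for degree/hybridization/H counts
  degree <- integer(n_atoms); n_double <- integer(n_atoms)
  n_triple <- integer(n_atoms); order_sum <- numeric(n_atoms)
  if (nrow(mol$bonds) > 0) {
    for (e in seq_len(nrow(mol$bonds))) {
      for (a in c(mol$bonds$a1[e], mol$bonds$a2[e])) {
        degree[a] <- degree[a] + 1L
        order_sum[a] <- order_sum[a] +
          if (arom_bond[e]) 1.5 else mol$bonds$order[e]
        if (mol$bonds$order[e] == 2 && !arom_bond[e])
          n_double[a] <- n_double[a] + 1L
        if (mol$bonds$order[e] == 3) n_triple[a] <- n_triple[a] + 1L
      }
    }
  }
  hybrid <- vapply(seq_len(n_atoms), function(a) {
    el <- mol$element[a]
    if (!el %in% c("C", "N", "O", "S", "P", "B", "Si", "Se", "As")) return("other")
    if (n_triple[a] > 0 || n_double[a] >= 2) "sp"
    else if (n_double[a] == 1 || a %in% arom_atoms) "sp2"
    else if (degree[a] == 0 && el %in% c("O", "S")) "sp3"
    else "sp3"
  }, character(1))
  valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1,
               I = 1, B = 3, Si = 4, Se = 2, As = 3)
  num_h <- vapply(seq_len(n_atoms), function(a) {
    v <- valence[mol$element[a]]
    if (is.na(v)) return(0L)
    h <- round(v + mol$charge[a] * (if (mol$element[a] %in% c("N", "O", "S", "P")) 1 else -1) -
               ceiling(order_sum[a]))
    max(0L, min(4L, as.integer(h)))
  }, integer(1))

  chir <- tryCatch(smiles_chirality(smiles), error = function(e) character(0))
  if (length(chir) != n_atoms) chir <- rep("none", n_atoms)

  atom_features <- t(vapply(seq_len(n_atoms), function(a) {
    mass <- .atomic_mass[mol$element[a]]
    if (is.na(mass)) mass <- 0
    block_encode(scheme$atom_blocks, list(
      element = mol$element[a], degree = degree[a],
      formal_charge = mol$charge[a], hybridization = hybrid[a],
      chirality = chir[a], num_h = num_h[a],
      in_ring = a %in% ring_atoms, aromatic = a %in% arom_atoms,
      mass_scaled = mass / 100))
  }, numeric(scheme$atom_dim)))

  nb <- nrow(mol$bonds)
  bond_index <- matrix(integer(0), 0, 2)
  bond_features <- matrix(numeric(0), 0, scheme$bond_dim)
  if (nb > 0) {
    rows <- lapply(seq_len(nb), function(e) {
      a <- mol$bonds$a1[e]; b <- mol$bonds$a2[e]
      btype <- if (arom_bond[e]) "aromatic"
               else c("single", "double", "triple")[min(mol$bonds$order[e], 3)]
      conj <- arom_bond[e] ||
        (hybrid[a] %in% c("sp", "sp2") && hybrid[b] %in% c("sp", "sp2"))
      stereo <- switch(as.character(mol$bonds$stereo[e]),
                       `0` = "none", `1` = "wedge", `6` = "hash", "other")
      feat <- block_encode(scheme$bond_blocks, list(
        bond_type = btype, conjugated = conj, in_ring = ring_bond[e],
        stereo = stereo))
      list(idx = rbind(c(a, b), c(b, a)), feat = rbind(feat, feat))
    })
    bond_index <- do.call(rbind, lapply(rows, `[[`, "idx"))
    bond_features <- do.call(rbind, lapply(rows, `[[`, "feat"))
  }
  structure(list(atom_features = atom_features, bond_index = bond_index,
                 bond_features = bond_features, smiles = smiles),
            class = "drug_graph")
}

#' @export
print.drug_graph <- function(x, ...) {
  cat("drug_graph:", nrow(x$atom_features), "atoms,",
      nrow(x$bond_index) / 2, "bonds (", x$smiles, ")\n")
  invisible(x)
}

#' Featurize a table of drug records
#'
#' Runs [featurize_drug()] over a drug table, collecting failures instead of
#' aborting. Results are keyed by `drug_id` in the input order.
#'
#' @param records Data frame with columns `drug_id`, `smiles` (and optional
#'   `cid`).
#' @param scheme A `feature_scheme`.
#' @param cache Optional RDS path; graphs are cached keyed by
#'   (smiles, scheme hash) and reused across calls.
#' @return List with `graphs` (named list of `drug_graph`s) and `failures`
#'   (data frame `drug_id`, `smiles`, `error`). Errors if every record fails.
#' @export
featurize_table <- function(records, scheme = default_feature_scheme(),
                            cache = NULL) {
  stopifnot(all(c("drug_id", "smiles") %in% names(records)))
  if (nrow(records) == 0L) stop("empty drug table")
  if (anyDuplicated(records$drug_id))
    stop("duplicate drug_id in drug table: ",
         paste(unique(records$drug_id[duplicated(records$drug_id)]),
               collapse = ", "))
  stash <- if (!is.null(cache) && file.exists(cache)) readRDS(cache) else list()
  hash <- scheme_hash(scheme)
  graphs <- list(); fails <- list()
  for (i in seq_len(nrow(records))) {
    id <- as.character(records$drug_id[i]); smi <- records$smiles[i]
    key <- paste0(hash, "|", smi)
    g <- stash[[key]]
    if (is.null(g))
      g <- tryCatch(featurize_drug(smi, scheme), error = function(e) e)
    if (inherits(g, "error")) {
      fails[[length(fails) + 1L]] <- data.frame(
        drug_id = id, smiles = smi, error = conditionMessage(g),
        stringsAsFactors = FALSE)
    } else {
      graphs[[id]] <- g
      stash[[key]] <- g
    }
  }
  if (length(graphs) == 0L) stop("all drug records failed featurization")
  if (!is.null(cache)) saveRDS(stash, cache)
  failures <- if (length(fails)) do.call(rbind, fails) else
    data.frame(drug_id = character(0), smiles = character(0),
               error = character(0))
  list(graphs = graphs, failures = failures)
}

#' Circular (Morgan-style) fingerprint of a molecule
#'
#' Delegates to OpenBabel's extended-connectivity fingerprints (radius 1, 2,
#' 3 map to ECFP2, ECFP4, ECFP6) and folds the native 4096-bit vector down
#' to the requested length with bitwise OR.
#'
#' @param smiles A single valid SMILES string.
#' @param bits Fingerprint length: 128, 256, 512 or 1024.
#' @param radius Circular radius: 1, 2 or 3.
#' @return Integer 0/1 vector of length `bits`.
#' @export
morgan_fingerprint <- function(smiles, bits = 256, radius = 2) {
  stopifnot(bits %in% c(128L, 256L, 512L, 1024L), radius %in% 1:3)
  mols <- tryCatch(
    suppressWarnings(ChemmineOB::forEachMol("SMILES", smiles, identity)),
    error = function(e) stop("invalid SMILES '", smiles, "'", call. = FALSE))
  fp_name <- c("ECFP2", "ECFP4", "ECFP6")[radius]
  raw <- ChemmineOB::fingerprint_OB(mols, fp_name)
  raw <- as.numeric(raw)
  if (sum(raw) == 0 && nchar(gsub("[A-Za-z0-9@+\\-\\[\\]()=#/\\\\%.*]", "",
                                  smiles)) > 0)
    stop("invalid SMILES '", smiles, "'")
  folded <- matrix(raw, nrow = bits)
  as.integer(rowSums(folded) > 0)
}

#' Read a drug table (drug_id, optional cid, smiles)
#'
#' @param path CSV or TSV file (separator sniffed from the header).
#' @return Data frame with character `drug_id`, `smiles` (and `cid` if
#'   present).
#' @export
read_drug_table <- function(path) {
  first <- readLines(con <- gzfile(path), n = 1L); close(con)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("drug_id", "smiles") %in% names(df)))
  df$drug_id <- as.character(df$drug_id)
  df
}
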