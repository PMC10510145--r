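# SMILES -> featurized undirected molecular graph.
#
# Parsing and perception are delegated to OpenBabel (via ChemmineOB) and
# ChemmineR.  Input SMILES are first canonicalized so that any two spellings
# of the same molecule produce bit-identical graphs; aromaticity is perceived
# from ring analysis rather than trusted to the (kekulized) bond orders the
# SDF carries.

ELEMENTS <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "other")
DEGREES <- c(0L, 1L, 2L, 3L, 4L, 5L)          # last slot = 5 or more
CHARGES <- c(-2L, -1L, 0L, 1L, 2L)            # plus trailing "other"
NUM_HS <- c(0L, 1L, 2L, 3L, 4L)               # last slot = 4 or more
HYBRIDIZATIONS <- c("sp", "sp2", "sp3", "other")
BOND_ORDERS <- c("single", "double", "triple", "aromatic")

# default valences used for the implicit-hydrogen count
.default_valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3,
                      F = 1, Cl = 1, Br = 1, I = 1, B = 3)

#' Atom feature vector width
#' @return Integer, the number of columns of `atom_features`.
#' @export
atom_feature_dim <- function() {
  length(ELEMENTS) + length(DEGREES) + length(CHARGES) + 1L +
    length(NUM_HS) + length(HYBRIDIZATIONS) + 1L
}

#' Bond feature vector width
#' @return Integer, the number of columns of `bond_features`.
#' @export
bond_feature_dim <- function() length(BOND_ORDERS) + 2L

one_hot <- function(idx, n) {
  v <- numeric(n)
  v[idx] <- 1
  v
}

# SDF atom-block charge codes: 1..3 are +3..+1, 5..7 are -1..-3.
.sdf_charge <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                 `5` = -1L, `6` = -2L, `7` = -3L)

#' Featurize one atom
#'
#' Builds the binary descriptor row for a single atom: one-hot blocks for
#' element identity, heavy-atom degree, formal charge, implicit hydrogen
#' count and hybridization, plus a single aromaticity bit.  Elements outside
#' the supported set fall into a reserved "other" slot.
#'
#' @param element Element symbol, e.g. `"C"`.
#' @param degree Number of heavy-atom neighbours.
#' @param charge Formal charge.
#' @param n_h Implicit hydrogen count.
#' @param hybridization One of `"sp"`, `"sp2"`, `"sp3"`, `"other"`.
#' @param aromatic Logical aromaticity flag.
#' @return Numeric 0/1 vector of length [atom_feature_dim()].
#' @export
featurize_atom <- function(element, degree, charge, n_h, hybridization,
                           aromatic) {
  e_idx <- match(element, ELEMENTS, nomatch = length(ELEMENTS))
  d_idx <- min(degree, 5L) + 1L
  c_idx <- match(charge, CHARGES)
  c_vec <- if (is.na(c_idx)) c(numeric(length(CHARGES)), 1) else
    c(one_hot(c_idx, length(CHARGES)), 0)
  h_idx <- min(n_h, 4L) + 1L
  y_idx <- match(hybridization, HYBRIDIZATIONS,
                 nomatch = length(HYBRIDIZATIONS))
  c(one_hot(e_idx, length(ELEMENTS)),
    one_hot(d_idx, length(DEGREES)),
    c_vec,
    one_hot(h_idx, length(NUM_HS)),
    one_hot(y_idx, length(HYBRIDIZATIONS)),
    as.numeric(aromatic))
}

#' Featurize one bond
#'
#' One-hot block for the bond order (`single`, `double`, `triple`,
#' `aromatic`) plus conjugation and ring-membership bits.
#'
#' @param order One of `"single"`, `"double"`, `"triple"`, `"aromatic"`.
#' @param conjugated Logical.
#' @param in_ring Logical.
#' @return Numeric 0/1 vector of length [bond_feature_dim()].
#' @export
featurize_bond <- function(order, conjugated, in_ring) {
  o_idx <- match(order, BOND_ORDERS)
  if (is.na(o_idx)) {
    rlang::abort(paste0("unknown bond order '", order, "'"),
                 class = "dtakit_error_input")
  }
  c(one_hot(o_idx, length(BOND_ORDERS)),
    as.numeric(conjugated), as.numeric(in_ring))
}

canonical_smiles <- function(smiles) {
  out <- suppressWarnings(
    utils::capture.output(
      res <- ChemmineOB::convertFormat("SMI", "CAN", source = smiles),
      type = "message"
    )
  )
  res <- sub("[\t\n ].*$", "", res)
  res
}

# Minimal reader for a single-atom SMILES (canonical form), e.g. "C", "O",
# "[NH4+]".  ChemmineR's SDF reader misparses the degenerate 1-atom/0-bond
# molfile, so this case is handled directly.
parse_single_atom <- function(can) {
  element <- can
  charge <- 0L
  n_h_explicit <- NA_integer_
  if (grepl("^\\[.*\\]$", can)) {
    body <- sub("^\\[(.*)\\]$", "\\1", can)
    m <- regmatches(body, regexec(
      "^([0-9]*)([A-Z][a-z]?|[a-z])(H[0-9]*)?([+-][0-9]*|[+]+|[-]+)?$", body))[[1]]
    if (length(m) == 0L) return(NULL)
    element <- m[3]
    if (nzchar(m[4])) {
      n_h_explicit <- if (m[4] == "H") 1L else as.integer(sub("H", "", m[4]))
    } else n_h_explicit <- 0L
    if (nzchar(m[5])) {
      s <- m[5]
      charge <- if (s %in% c("+", "-")) ifelse(s == "+", 1L, -1L)
      else if (grepl("^[+-][0-9]+$", s)) as.integer(s)
      else (nchar(s)) * ifelse(substr(s, 1, 1) == "+", 1L, -1L)
    }
  }
  list(element = element, charge = charge, n_h = n_h_explicit)
}

# Scan the atom tokens of a canonical SMILES in order, recording element and
# aromaticity (lowercase = aromatic).  OpenBabel's SDF conversion preserves
# this atom order, so flags line up with the atom block by position.  This is
# a token scan only -- connectivity still comes from the toolkit.
smiles_atom_flags <- function(can) {
  pat <- "\\[[^]]+\\]|Br|Cl|[BCNOPSFIbcnops]"
  toks <- regmatches(can, gregexpr(pat, can))[[1]]
  el <- character(length(toks))
  arom <- logical(length(toks))
  for (k in seq_along(toks)) {
    t <- toks[k]
    if (startsWith(t, "[")) {
      s <- sub("^\\[[0-9]*", "", t)
      m <- regmatches(s, regexec("([A-Za-z][a-z]?)", s))[[1]][2]
      arom[k] <- grepl("^[a-z]", m)
      el[k] <- paste0(toupper(substr(m, 1, 1)), tolower(substring(m, 2)))
    } else {
      arom[k] <- grepl("^[a-z]", t)
      el[k] <- if (arom[k]) toupper(t) else t
    }
  }
  list(element = el, aromatic = arom)
}

implicit_h_count <- function(element, valence_used, charge) {
  dv <- .default_valence[element]
  if (is.na(dv)) return(0L)
  # common organic-subset adjustment: N/P/O/S gain capacity with positive
  # charge and lose it with negative charge; C loses either way
  adj <- if (element %in% c("N", "P", "O", "S")) charge
  else if (element == "C") -abs(charge) else 0L
  max(0L, as.integer(dv + adj - valence_used))
}

#' Parse a SMILES string into a featurized molecular graph
#'
#' Canonicalizes the SMILES through OpenBabel, perceives the heavy-atom graph
#' (hydrogens stay implicit), detects ring membership and aromaticity, and
#' builds the three adjacency maps the message-passing encoder consumes:
#' atom-to-atom neighbours, atom-to-incident-bonds, and bond-to-neighbour-bonds
#' (bonds sharing exactly one endpoint, never the bond itself).  Bonds are
#' stored once, undirected.
#'
#' @param smiles A single non-empty SMILES string.
#' @return An object of class `molecular_graph`: a list with `n_atoms`,
#'   `n_bonds`, `atom_features` (n_atoms x [atom_feature_dim()]),
#'   `bond_features` (n_bonds x [bond_feature_dim()]), `atom_neighbors`,
#'   `incident_bonds`, `bond_neighbors` (lists of integer vectors),
#'   `endpoints` (n_bonds x 2 matrix), `elements`, `n_aromatic_rings`, and
#'   the canonical SMILES.
#' @examples
#' g <- smiles_to_graph("C1CC1")
#' g$n_atoms  # 3
#' g$n_bonds  # 3
#' @export
smiles_to_graph <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    rlang::abort("`smiles` must be a single non-empty string",
                 class = "dtakit_error_input")
  }
  can <- canonical_smiles(smiles)
  if (!nzchar(can)) {
    rlang::abort(paste0("invalid SMILES: '", smiles, "'"),
                 class = "dtakit_error_parse")
  }

  # degenerate single-atom molecule (ChemmineR cannot read 0-bond molfiles)
  if (grepl("^(\\[[^]]+\\]|Br|Cl|[BCNOPSFI])$", can)) {
    pa <- parse_single_atom(can)
    if (!is.null(pa)) {
      n_h <- if (is.na(pa$n_h)) {
        implicit_h_count(pa$element, 0L, pa$charge)
      } else pa$n_h
      g <- list(
        n_atoms = 1L, n_bonds = 0L,
        atom_features = matrix(
          featurize_atom(pa$element, 0L, pa$charge, n_h, "sp3", FALSE), 1L),
        bond_features = matrix(numeric(0), 0L, bond_feature_dim()),
        atom_neighbors = list(integer(0)),
        incident_bonds = list(integer(0)),
        bond_neighbors = list(),
        endpoints = matrix(integer(0), 0L, 2L),
        elements = pa$element,
        n_aromatic_rings = 0L,
        smiles = can
      )
      class(g) <- "molecular_graph"
      return(g)
    }
  }

  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(can)),
    error = function(e) {
      rlang::abort(paste0("invalid SMILES: '", smiles, "'"),
                   class = "dtakit_error_parse", parent = e)
    }
  )
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  bb <- ChemmineR::bondblock(mol)
  n_atoms <- nrow(ab)
  elements <- sub("_.*$", "", rownames(ab))
  charges <- vapply(as.character(ab[, 5L]), function(code) {
    v <- .sdf_charge[code]
    if (is.na(v)) 0L else v
  }, integer(1), USE.NAMES = FALSE)

  n_bonds <- if (is.null(bb) || nrow(bb) == 0L) 0L else nrow(bb)
  endpoints <- if (n_bonds > 0L) {
    cbind(as.integer(bb[, 1L]), as.integer(bb[, 2L]))
  } else matrix(integer(0), 0L, 2L)
  kek_order <- if (n_bonds > 0L) as.integer(bb[, 3L]) else integer(0)

  # Aromatic flags come from the canonical SMILES (lowercase atoms); ring
  # membership from ChemmineR ring perception.  A bond is aromatic when it is
  # a ring bond between two aromatic atoms; aromatic rings are counted at
  # chemically sensible sizes (3-7) so fused-ring envelopes are not counted.
  flags <- smiles_atom_flags(can)
  aromatic_atoms <- if (length(flags$aromatic) == n_atoms) flags$aromatic
  else rep(FALSE, n_atoms)
  ring_bond <- rep(FALSE, n_bonds)
  n_aromatic_rings <- 0L
  if (n_bonds >= 3L) {  # rings need at least three bonds
    rr <- tryCatch(ChemmineR::rings(mol, type = "all", arom = FALSE),
                   error = function(e) NULL)
    if (!is.null(rr) && length(rr) > 0L) {
      bond_key <- paste(pmin(endpoints[, 1L], endpoints[, 2L]),
                        pmax(endpoints[, 1L], endpoints[, 2L]))
      for (k in seq_along(rr)) {
        idx <- as.integer(sub("^.*_", "", rr[[k]]))
        cyc <- cbind(idx, c(idx[-1L], idx[1L]))
        keys <- paste(pmin(cyc[, 1L], cyc[, 2L]), pmax(cyc[, 1L], cyc[, 2L]))
        ring_bond[bond_key %in% keys] <- TRUE
        if (length(idx) <= 7L && all(aromatic_atoms[idx])) {
          n_aromatic_rings <- n_aromatic_rings + 1L
        }
      }
    }
  }
  aromatic_bond <- rep(FALSE, n_bonds)
  if (n_bonds > 0L) {
    aromatic_bond <- ring_bond & aromatic_atoms[endpoints[, 1L]] &
      aromatic_atoms[endpoints[, 2L]]
  }

  atom_neighbors <- vector("list", n_atoms)
  incident_bonds <- vector("list", n_atoms)
  for (v in seq_len(n_atoms)) {
    atom_neighbors[[v]] <- integer(0)
    incident_bonds[[v]] <- integer(0)
  }
  if (n_bonds > 0L) {
    for (b in seq_len(n_bonds)) {
      u <- endpoints[b, 1L]; v <- endpoints[b, 2L]
      atom_neighbors[[u]] <- c(atom_neighbors[[u]], v)
      atom_neighbors[[v]] <- c(atom_neighbors[[v]], u)
      incident_bonds[[u]] <- c(incident_bonds[[u]], b)
      incident_bonds[[v]] <- c(incident_bonds[[v]], b)
    }
  }
  bond_neighbors <- vector("list", n_bonds)
  for (b in seq_len(n_bonds)) {
    u <- endpoints[b, 1L]; v <- endpoints[b, 2L]
    bond_neighbors[[b]] <- setdiff(
      union(incident_bonds[[u]], incident_bonds[[v]]), b)
  }

  # per-atom valence used by heavy-atom bonds (kekulized orders are exact)
  valence_used <- numeric(n_atoms)
  if (n_bonds > 0L) {
    for (b in seq_len(n_bonds)) {
      o <- kek_order[b]
      valence_used[endpoints[b, 1L]] <- valence_used[endpoints[b, 1L]] + o
      valence_used[endpoints[b, 2L]] <- valence_used[endpoints[b, 2L]] + o
    }
  }

  hybrid <- vapply(seq_len(n_atoms), function(v) {
    bs <- incident_bonds[[v]]
    if (aromatic_atoms[v]) return("sp2")
    orders <- kek_order[bs]
    if (any(orders == 3L) || sum(orders == 2L) >= 2L) return("sp")
    if (any(orders == 2L)) return("sp2")
    "sp3"
  }, character(1))

  atom_features <- t(vapply(seq_len(n_atoms), function(v) {
    n_h <- implicit_h_count(elements[v], valence_used[v], charges[v])
    featurize_atom(elements[v], length(atom_neighbors[[v]]), charges[v],
                   n_h, hybrid[v], aromatic_atoms[v])
  }, numeric(atom_feature_dim())))

  bond_features <- if (n_bonds > 0L) {
    t(vapply(seq_len(n_bonds), function(b) {
      order <- if (aromatic_bond[b]) "aromatic" else
        c("single", "double", "triple")[kek_order[b]]
      u <- endpoints[b, 1L]; v <- endpoints[b, 2L]
      conj <- aromatic_bond[b] ||
        (hybrid[u] %in% c("sp", "sp2") && hybrid[v] %in% c("sp", "sp2"))
      featurize_bond(order, conj, ring_bond[b])
    }, numeric(bond_feature_dim())))
  } else matrix(numeric(0), 0L, bond_feature_dim())

  g <- list(
    n_atoms = n_atoms, n_bonds = n_bonds,
    atom_features = atom_features, bond_features = bond_features,
    atom_neighbors = atom_neighbors, incident_bonds = incident_bonds,
    bond_neighbors = bond_neighbors, endpoints = endpoints,
    elements = elements, n_aromatic_rings = n_aromatic_rings,
    smiles = can
  )
  class(g) <- "molecular_graph"
  g
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("<molecular_graph> ", x$smiles, ": ", x$n_atoms, " atoms, ",
      x$n_bonds, " bonds\n", sep = "")
  invisible(x)
}

#' Read SMILES strings from a text file (one per line)
#'
#' Blank lines are skipped.  Unparseable lines are reported together at the
#' end; parsing continues past them.
#'
#' @param path Path to a text file with one SMILES per line.
#' @return A tibble with columns `smiles` (input), `graph` (list of
#'   [smiles_to_graph()] results) and `ok` (logical).
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  res <- purrr::map(lines, function(s) {
    tryCatch(list(graph = smiles_to_graph(s), ok = TRUE),
             error = function(e) list(graph = NULL, ok = FALSE))
  })
  tibble::tibble(
    smiles = lines,
    graph = purrr::map(res, "graph"),
    ok = purrr::map_lgl(res, "ok")
  )
}
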