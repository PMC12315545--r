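# Monomer library handling and peptide assembly by amide condensation.
#
# Monomer SMILES carry their attachment chemistry as dummy atoms with atom-map
# numbers: [*:1] marks the amine-side attachment (bonded to the backbone N),
# [*:2] the carboxyl-side attachment (bonded to the carbonyl C). Capping
# monomers carry a single dummy. On assembly the carboxyl C of residue i is
# bonded to the amine N of residue i+1 (condensation; the hydroxyl is lost),
# the N-terminal dummy is dropped and the C-terminal dummy becomes a hydroxyl
# oxygen.

#' Load a monomer library from TSV
#'
#' The TSV must have a header with columns `code`, `smiles`, `is_canonical`
#' and `side_chain_atoms` (semicolon-separated 0-based within-monomer heavy
#' atom indices, dummies excluded; may be empty). Every SMILES is parsed and
#' its attachment points validated at load time.
#'
#' @param path path to the TSV file.
#' @param provenance free-text provenance note.
#' @return a `monomer_library` object (named list of monomers plus metadata).
#' @export
load_monomer_library <- function(path, provenance = path) {
  if (!file.exists(path)) stop(sprintf("monomer library file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("monomer TSV is empty")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  need <- c("code", "smiles", "is_canonical", "side_chain_atoms")
  if (!all(need %in% header)) {
    stop(sprintf("monomer TSV header must contain: %s", paste(need, collapse = ", ")))
  }
  idx <- match(need, header)
  monomers <- list()
  for (ln in seq_along(lines)[-1]) {
    fields <- strsplit(lines[[ln]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < max(idx[1:3])) {
      stop(sprintf("malformed monomer TSV row at line %d", ln))
    }
    code <- trimws(fields[[idx[1]]])
    smi <- trimws(fields[[idx[2]]])
    canon <- tolower(trimws(fields[[idx[3]]]))
    side_raw <- if (length(fields) >= idx[4]) trimws(fields[[idx[4]]]) else ""
    if (!nzchar(code)) stop(sprintf("empty monomer code at line %d", ln))
    if (!canon %in% c("true", "false")) {
      stop(sprintf("is_canonical must be true/false at line %d", ln))
    }
    if (!is.null(monomers[[code]])) {
      stop(sprintf("duplicate monomer code '%s' at line %d", code, ln))
    }
    mon <- tryCatch(
      .pt_build_monomer(code, smi, canon == "true", side_raw),
      error = function(e) stop(sprintf(
        "invalid monomer '%s' (line %d): %s", code, ln, conditionMessage(e)
      ), call. = FALSE)
    )
    monomers[[code]] <- mon
  }
  structure(
    list(monomers = monomers, provenance = provenance),
    class = "monomer_library"
  )
}

.pt_build_monomer <- function(code, smiles, is_canonical, side_raw) {
  g <- pt_parse_smiles(smiles)
  dummies <- which(g$atoms$element == "*")
  amine_d <- dummies[g$atoms$map[dummies] == 1L]
  carboxyl_d <- dummies[g$atoms$map[dummies] == 2L]
  if (length(dummies) != length(amine_d) + length(carboxyl_d)) {
    stop("dummy atoms must carry map number 1 (amine side) or 2 (carboxyl side)")
  }
  capping <- length(dummies) == 1L
  if (!capping && (length(amine_d) != 1L || length(carboxyl_d) != 1L)) {
    stop("non-capping monomers need exactly one amine and one carboxyl attachment")
  }
  adj <- .pt_adjacency(g)
  att <- function(d) {
    if (length(d) == 0L) return(NA_integer_)
    nb <- adj[[d]]
    if (length(nb) != 1L) stop("attachment dummy must have exactly one neighbour")
    nb
  }
  side <- integer(0)
  if (nzchar(side_raw)) {
    side <- as.integer(strsplit(side_raw, ";", fixed = TRUE)[[1]])
    if (anyNA(side)) stop("side_chain_atoms must be ';'-separated integers")
  }
  n_heavy <- sum(g$atoms$element != "*")
  if (length(side) > 0L && any(side < 0L | side >= n_heavy)) {
    stop("side_chain_atoms index out of range")
  }
  structure(
    list(
      code = code, smiles = smiles, is_canonical = is_canonical,
      graph = g,
      amine_dummy = if (length(amine_d)) amine_d else NA_integer_,
      carboxyl_dummy = if (length(carboxyl_d)) carboxyl_d else NA_integer_,
      amine_attach = att(amine_d),
      carboxyl_attach = att(carboxyl_d),
      capping = capping,
      side_chain_atoms = side  # 0-based, heavy atoms only
    ),
    class = "pep_monomer"
  )
}

#' Built-in monomer libraries
#'
#' `builtin_monomer_library()` returns the 20 canonical amino acids, optionally
#' extended with a small set of non-canonical monomers (D-alanine,
#' D-phenylalanine, Aib, sarcosine, N-methyl-phenylalanine, norleucine,
#' norvaline, homoserine, ornithine) and acetyl/amide caps.
#'
#' @param include_noncanonical also load the non-canonical set.
#' @return a `monomer_library`.
#' @export
builtin_monomer_library <- function(include_noncanonical = TRUE) {
  lib <- load_monomer_library(
    system.file("extdata", "monomers_canonical.tsv", package = "peptigraph"),
    provenance = "built-in canonical set"
  )
  if (include_noncanonical) {
    nc <- load_monomer_library(
      system.file("extdata", "monomers_noncanonical.tsv", package = "peptigraph"),
      provenance = "built-in non-canonical set"
    )
    for (code in names(nc$monomers)) {
      if (!is.null(lib$monomers[[code]])) stop(sprintf("duplicate monomer code '%s'", code))
      lib$monomers[[code]] <- nc$monomers[[code]]
    }
    lib$provenance <- "built-in canonical + non-canonical sets"
  }
  lib
}

#' @export
print.monomer_library <- function(x, ...) {
  cat(sprintf(
    "<monomer_library> %d monomers (%d canonical) — %s\n",
    length(x$monomers),
    sum(vapply(x$monomers, function(m) m$is_canonical, logical(1))),
    x$provenance
  ))
  invisible(x)
}

#' Tokenize a peptide sequence string
#'
#' Single uppercase letters are canonical one-letter codes; bracketed
#' substrings (`"[Aib]"`) are literal multi-character monomer codes.
#'
#' @param seq_string e.g. `"GA[Aib]F"`.
#' @return character vector of monomer codes.
#' @export
tokenize_sequence <- function(seq_string) {
  stopifnot(is.character(seq_string), length(seq_string) == 1L)
  s <- trimws(seq_string)
  out <- character(0)
  i <- 1L; n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(s, i, n), fixed = TRUE)
      if (j < 0L) stop("unclosed '[' in sequence string")
      out <- c(out, substr(s, i + 1L, i + j - 2L))
      i <- i + j
    } else if (grepl("^[A-Za-z]$", ch)) {
      out <- c(out, ch)
      i <- i + 1L
    } else {
      stop(sprintf("unexpected character '%s' in sequence string", ch))
    }
  }
  if (length(out) == 0L) stop("empty sequence string")
  out
}

#' Build a peptide molecule from a monomer sequence
#'
#' Monomers are joined N-to-C by amide condensation: the carboxyl carbon of
#' residue i is bonded to the amine nitrogen of residue i+1 and the hydroxyl
#' is lost. The C-terminal attachment becomes a hydroxyl (linear peptides) or
#' is bonded head-to-tail to the N-terminus (`cyclic = TRUE`).
#'
#' @param seq character vector of monomer codes (or a single sequence string,
#'   which is tokenized).
#' @param lib a `monomer_library`.
#' @param cyclic build a head-to-tail macrocycle.
#' @return a `pep_mol` with `residue_of_atom` populated.
#' @export
sequence_to_molecule <- function(seq, lib, cyclic = FALSE) {
  stopifnot(inherits(lib, "monomer_library"))
  if (is.character(seq) && length(seq) == 1L && !seq %in% names(lib$monomers)) {
    seq <- tokenize_sequence(seq)
  }
  if (length(seq) < 1L) stop("sequence must contain at least one monomer")
  unknown <- setdiff(seq, names(lib$monomers))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown monomer code(s): %s", paste(unique(unknown), collapse = ", ")))
  }
  mons <- lapply(seq, function(code) lib$monomers[[code]])
  nres <- length(mons)
  for (r in seq_len(nres)) {
    m <- mons[[r]]
    if (m$capping) {
      if (is.na(m$carboxyl_dummy) && r != nres) {
        stop(sprintf("C-capping monomer '%s' must be last in the sequence", m$code))
      }
      if (is.na(m$amine_dummy) && r != 1L) {
        stop(sprintf("N-capping monomer '%s' must be first in the sequence", m$code))
      }
      if (cyclic) stop("capping monomers cannot be used in a cyclic peptide")
    }
  }

  element <- character(0); aromatic <- logical(0); charge <- integer(0)
  h_explicit <- integer(0); chirality <- character(0); amap <- integer(0)
  chiral_ref <- list(); bond_a <- integer(0); bond_b <- integer(0)
  bond_order <- character(0); residue <- integer(0)

  glob <- vector("list", nres)    # local atom id -> global id (NA for dummies)
  amine_g <- carboxyl_g <- rep(NA_integer_, nres)
  dummy_sub <- vector("list", nres) # local dummy id -> global substitute (or NA)

  for (r in seq_len(nres)) {
    g <- mons[[r]]$graph
    nl <- n_atoms(g)
    keep <- g$atoms$element != "*"
    map_local <- rep(NA_integer_, nl)
    map_local[keep] <- length(element) + seq_len(sum(keep))
    glob[[r]] <- map_local
    element <- c(element, g$atoms$element[keep])
    aromatic <- c(aromatic, g$atoms$aromatic[keep])
    charge <- c(charge, g$atoms$charge[keep])
    # re-derive implicit H for organic-subset atoms whose bonding changes
    hx <- g$atoms$n_h[keep]
    brack <- .pt_was_bracket(g)[keep]
    h_explicit <- c(h_explicit, ifelse(brack, hx, NA_integer_))
    chirality <- c(chirality, g$atoms$chirality[keep])
    amap <- c(amap, rep(0L, sum(keep)))
    residue <- c(residue, rep(r, sum(keep)))
    for (k in seq_len(nrow(g$bonds))) {
      a <- g$bonds$a[k]; bb <- g$bonds$b[k]
      if (keep[a] && keep[bb]) {
        bond_a <- c(bond_a, map_local[a]); bond_b <- c(bond_b, map_local[bb])
        bond_order <- c(bond_order, g$bonds$order[k])
      }
    }
    chiral_ref <- c(chiral_ref, lapply(which(keep), function(a) {
      ref <- g$chiral_ref[[a]]
      # translate now where possible; dummy neighbours resolved later
      vapply(ref, function(x) {
        if (x <= 0L) x else if (keep[x]) map_local[x] else -(r * 1000L + x)
      }, integer(1))
    }))
    if (!is.na(mons[[r]]$amine_attach)) amine_g[r] <- map_local[mons[[r]]$amine_attach]
    if (!is.na(mons[[r]]$carboxyl_attach)) carboxyl_g[r] <- map_local[mons[[r]]$carboxyl_attach]
  }

  sub_of <- function(r, local_dummy) -(r * 1000L + local_dummy) # placeholder key

  resolve_map <- new.env(hash = TRUE)
  set_sub <- function(r, local_dummy, global_id) {
    assign(as.character(sub_of(r, local_dummy)), global_id, envir = resolve_map)
  }

  # inter-residue amide bonds
  for (r in seq_len(nres - 1L)) {
    ci <- carboxyl_g[r]; nj <- amine_g[r + 1L]
    if (is.na(ci)) stop(sprintf("monomer '%s' has no carboxyl attachment", mons[[r]]$code))
    if (is.na(nj)) stop(sprintf("monomer '%s' has no amine attachment", mons[[r + 1L]]$code))
    bond_a <- c(bond_a, ci); bond_b <- c(bond_b, nj)
    bond_order <- c(bond_order, "single")
    set_sub(r, mons[[r]]$carboxyl_dummy, nj)
    set_sub(r + 1L, mons[[r + 1L]]$amine_dummy, ci)
  }

  if (cyclic) {
    if (nres < 2L) stop("cyclic peptides need at least two residues")
    ci <- carboxyl_g[nres]; nj <- amine_g[1L]
    bond_a <- c(bond_a, ci); bond_b <- c(bond_b, nj)
    bond_order <- c(bond_order, "single")
    set_sub(nres, mons[[nres]]$carboxyl_dummy, nj)
    set_sub(1L, mons[[1L]]$amine_dummy, ci)
  } else {
    # C-terminal hydroxyl replaces the carboxyl dummy
    if (!is.na(carboxyl_g[nres])) {
      o_id <- length(element) + 1L
      element <- c(element, "O"); aromatic <- c(aromatic, FALSE)
      charge <- c(charge, 0L); h_explicit <- c(h_explicit, NA_integer_)
      chirality <- c(chirality, "none"); amap <- c(amap, 0L)
      residue <- c(residue, nres)
      chiral_ref <- c(chiral_ref, list(integer(0)))
      bond_a <- c(bond_a, carboxyl_g[nres]); bond_b <- c(bond_b, o_id)
      bond_order <- c(bond_order, "single")
      set_sub(nres, mons[[nres]]$carboxyl_dummy, o_id)
    }
    # N-terminal amine dummy simply disappears (implicit H refill)
  }

  # resolve dummy placeholders inside chirality reference lists
  chiral_ref <- lapply(seq_along(chiral_ref), function(i) {
    ref <- chiral_ref[[i]]
    bad <- FALSE
    out <- vapply(ref, function(x) {
      if (x >= 0L) return(x)
      key <- as.character(x)
      if (exists(key, envir = resolve_map, inherits = FALSE)) {
        get(key, envir = resolve_map)
      } else { bad <<- TRUE; NA_integer_ }
    }, integer(1))
    if (bad) integer(0) else out
  })
  chirality[chirality != "none" &
    vapply(chiral_ref, length, integer(1)) == 0L] <- "none"

  pep_mol_from_parts(
    element = element, aromatic = aromatic, charge = charge,
    h_explicit = h_explicit, chirality = chirality, map = amap,
    chiral_ref = chiral_ref, bond_a = bond_a, bond_b = bond_b,
    bond_order = bond_order, source = "sequence",
    residue_of_atom = residue
  )
}

# which atoms of a parsed monomer graph came from bracket tokens (explicit H)
.pt_was_bracket <- function(g) {
  g$atoms$charge != 0L | g$atoms$chirality != "none" |
    (g$atoms$aromatic & g$atoms$element %in% c("N", "O", "S", "P") & g$atoms$n_h > 0L) |
    !(g$atoms$element %in% .pt_organic_subset)
}

#' Construct a peptide molecule from SMILES
#'
#' Validates the string with the package reader, canonicalizes it with
#' OpenBabel (which also perceives aromaticity), and parses the canonical
#' form into the package's graph representation.
#'
#' @param smiles a single SMILES string.
#' @return a `pep_mol` with `source = "smiles"`.
#' @export
pep_mol <- function(smiles) {
  pt_parse_smiles(smiles) # strict validation; errors on malformed input
  canon <- .pt_ob_canonical_batch(smiles)
  pt_parse_smiles(canon, source = "smiles")
}

#' Read peptide structures from a file
#'
#' @param path input file.
#' @param format `"smiles_lines"` (one SMILES per line, optional id after
#'   whitespace), `"fasta"`, or `"sequence_lines"` (one monomer-code sequence
#'   per line, bracketed tokens allowed).
#' @param lib a `monomer_library`; required for the sequence-based formats.
#' @return a named list of `pep_mol` (names are record identifiers; line
#'   numbers where the format carries none). Empty files give an empty list.
#' @export
read_structures <- function(path, format = c("smiles_lines", "fasta", "sequence_lines"),
                            lib = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (format == "fasta") {
    heads <- grep("^>", lines)
    if (length(heads) == 0L) {
      if (all(!nzchar(trimws(lines)))) return(list())
      stop("FASTA file contains no '>' records")
    }
    ids <- sub("^>\\s*", "", lines[heads])
    ids <- vapply(strsplit(ids, "\\s+"), `[[`, character(1), 1L)
    starts <- heads + 1L
    ends <- c(heads[-1] - 1L, length(lines))
    seqs <- vapply(seq_along(heads), function(i) {
      if (ends[i] < starts[i]) return("")
      paste(trimws(lines[starts[i]:ends[i]]), collapse = "")
    }, character(1))
    recs <- seqs
  } else {
    keepl <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
    recs <- trimws(lines[keepl])
    ids <- as.character(keepl)
    if (format == "smiles_lines") {
      parts <- strsplit(recs, "[ \t]+")
      has_id <- vapply(parts, length, integer(1)) >= 2L
      ids[has_id] <- vapply(parts[has_id], `[[`, character(1), 2L)
      recs <- vapply(parts, `[[`, character(1), 1L)
    }
  }
  if (length(recs) == 0L) return(list())
  if (format %in% c("fasta", "sequence_lines") && is.null(lib)) {
    stop("a monomer library must be supplied for sequence-based formats")
  }
  out <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    out[[i]] <- tryCatch(
      if (format == "smiles_lines") pep_mol(recs[[i]])
      else sequence_to_molecule(tokenize_sequence(recs[[i]]), lib),
      error = function(e) stop(sprintf(
        "record %d ('%s') could not be parsed: %s", i, ids[[i]], conditionMessage(e)
      ), call. = FALSE)
    )
  }
  names(out) <- ids
  out
}

#' Write molecules as canonical SMILES lines
#'
#' @param mols list of `pep_mol`.
#' @param path output file; each line is `<canonical smiles>\t<id>`.
#' @export
write_structures <- function(mols, path) {
  keys <- .pt_canonical_keys(mols)
  ids <- names(mols)
  if (is.null(ids)) ids <- as.character(seq_along(mols))
  writeLines(paste(keys, ids, sep = "\t"), path)
  invisible(path)
}
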