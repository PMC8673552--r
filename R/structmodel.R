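# Structure data model and file I/O.
#
# A structure is held as a flat atom table plus an entity list. The atom table
# is the substrate of every score in the package; entities carry the polymer
# typing used by chain mapping and target selection.

AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")
AA1 <- stats::setNames(names(AA3), AA3)
NUC3 <- c(A = "A", C = "C", G = "G", U = "U",
          DA = "A", DC = "C", DG = "G", DT = "T")
WATER_COMPS <- c("HOH", "WAT", "DOD", "H2O")

AMINO_ALPHABET   <- sort(unname(AA3))
DNA_ALPHABET     <- c("A", "C", "G", "T")
RNA_ALPHABET     <- c("A", "C", "G", "U")

#' Create an entity record
#'
#' An entity is a unique polymer sequence (or nonpolymer chemical); multiple
#' chains of a structure may instantiate the same entity. Sequences are stored
#' as token vectors: canonical residues as one-letter codes, noncanonical
#' residues as \code{"(COMP)"} bracketed PDB component identifiers.
#'
#' @param id entity identifier (character).
#' @param polymer_type one of \code{"protein"}, \code{"peptide"}, \code{"dna"},
#'   \code{"rna"}, \code{"nonpolymer"}.
#' @param seq character vector of sequence tokens (empty for nonpolymer).
#' @return An object of class \code{cam_entity}.
#' @export
cam_entity <- function(id, polymer_type, seq = character()) {
  polymer_type <- match.arg(polymer_type,
                            c("protein", "peptide", "dna", "rna", "nonpolymer"))
  structure(list(id = as.character(id), polymer_type = polymer_type,
                 seq = as.character(seq)),
            class = "cam_entity")
}

#' Create a structure object
#'
#' @param atoms data.frame with columns \code{chain}, \code{resnum},
#'   \code{icode}, \code{comp_id}, \code{kind}, \code{atom}, \code{element},
#'   \code{x}, \code{y}, \code{z}, \code{occ}, \code{hetero},
#'   \code{entity_id}.
#' @param entities list of \code{\link{cam_entity}} objects.
#' @param id structure identifier.
#' @param assembly_label label distinguishing multiple reference biological
#'   assemblies of one target.
#' @return An object of class \code{camstruct}.
#' @export
cam_structure <- function(atoms, entities = list(), id = "struct",
                          assembly_label = "1") {
  stopifnot(is.data.frame(atoms))
  need <- c("chain", "resnum", "icode", "comp_id", "kind", "atom", "element",
            "x", "y", "z", "occ", "hetero", "entity_id")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty structure")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  if (any(!nzchar(atoms$element))) stop("atoms with empty element symbol")
  key <- paste(atoms$chain, atoms$resnum, atoms$icode, atoms$atom, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate atom name within a residue after alt-loc resolution")
  ent_ids <- vapply(entities, function(e) e$id, "")
  names(entities) <- ent_ids
  bad <- setdiff(unique(atoms$entity_id), c(ent_ids, NA_character_))
  if (length(bad)) stop("chain entity ids without entity record: ",
                        paste(bad, collapse = ", "))
  rownames(atoms) <- NULL
  structure(list(id = id, assembly_label = assembly_label,
                 atoms = atoms, entities = entities),
            class = "camstruct")
}

#' @export
print.camstruct <- function(x, ...) {
  ch <- cam_chains(x)
  cat(sprintf("<camstruct> %s (assembly %s): %d chains, %d residues, %d atoms\n",
              x$id, x$assembly_label, length(ch),
              nrow(residue_table(x)), nrow(x$atoms)))
  for (cc in ch) {
    e <- x$entities[[chain_entity(x, cc)]]
    cat(sprintf("  chain %s  entity %s (%s), %d residues\n", cc,
                if (is.null(e)) "?" else e$id,
                if (is.null(e)) "?" else e$polymer_type,
                nrow(residue_table(x, cc))))
  }
  invisible(x)
}

#' Chain identifiers of a structure
#' @param s a \code{camstruct}.
#' @return character vector in file order.
#' @export
cam_chains <- function(s) unique(s$atoms$chain)

#' Entity id of a chain
#' @param s a \code{camstruct}.
#' @param chain chain identifier.
#' @export
chain_entity <- function(s, chain) {
  e <- s$atoms$entity_id[s$atoms$chain == chain]
  if (!length(e)) stop("no such chain: ", chain)
  e[1]
}

res_key <- function(chain, resnum, icode) paste(chain, resnum, icode, sep = "|")

#' Residue table of a structure
#'
#' One row per residue in atom-table order, with its chain, author number,
#' insertion code, component id and kind.
#' @param s a \code{camstruct}.
#' @param chain optional chain filter.
#' @export
residue_table <- function(s, chain = NULL) {
  a <- s$atoms
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  k <- res_key(a$chain, a$resnum, a$icode)
  keep <- !duplicated(k)
  out <- a[keep, c("chain", "resnum", "icode", "comp_id", "kind"), drop = FALSE]
  out$key <- k[keep]
  rownames(out) <- NULL
  out
}

residue_token <- function(comp_id, kind) {
  ifelse(kind == "amino" & comp_id %in% names(AA3), unname(AA3[comp_id]),
  ifelse(kind == "nucleotide" & comp_id %in% names(NUC3), unname(NUC3[comp_id]),
         paste0("(", comp_id, ")")))
}

# ---------------------------------------------------------------------------
# Residue kind / entity inference

classify_residue_kind <- function(comp_id, atom_names, hetero) {
  if (comp_id %in% names(AA3)) return("amino")
  if (comp_id %in% names(NUC3)) return("nucleotide")
  if (all(c("N", "CA", "C") %in% atom_names)) return("amino")
  if ("C1'" %in% atom_names || "P" %in% atom_names) return("nucleotide")
  if (hetero) return("ligand")
  "other"
}

infer_entities <- function(atoms) {
  # Group chains with identical polymer token sequences (PDB has no entity
  # records); nonpolymer chains keyed by their component sequence.
  chains <- unique(atoms$chain)
  sigs <- character(length(chains))
  seqs <- vector("list", length(chains))
  types <- character(length(chains))
  for (i in seq_along(chains)) {
    a <- atoms[atoms$chain == chains[i], , drop = FALSE]
    k <- res_key(a$chain, a$resnum, a$icode)
    first <- !duplicated(k)
    kind <- a$kind[first]; comp <- a$comp_id[first]
    pol <- kind %in% c("amino", "nucleotide")
    if (any(pol)) {
      toks <- residue_token(comp[pol], kind[pol])
      seqs[[i]] <- toks
      types[i] <- infer_polymer_type(kind[pol], comp[pol], toks)
      sigs[i] <- paste(types[i], paste(toks, collapse = ""), sep = ":")
    } else {
      seqs[[i]] <- character()
      types[i] <- "nonpolymer"
      sigs[i] <- paste("np", paste(comp, collapse = ","), sep = ":")
    }
  }
  uniq <- !duplicated(sigs)
  ent_of_sig <- stats::setNames(as.character(seq_len(sum(uniq))), sigs[uniq])
  entities <- lapply(which(uniq), function(i)
    cam_entity(ent_of_sig[[sigs[i]]], types[i], seqs[[i]]))
  atoms$entity_id <- unname(ent_of_sig[sigs[match(atoms$chain, chains)]])
  list(atoms = atoms, entities = entities)
}

infer_polymer_type <- function(kinds, comps, toks) {
  if (all(kinds == "amino")) {
    if (length(toks) >= 30) "protein" else "peptide"
  } else if (any(comps %in% c("DA", "DC", "DG", "DT"))) "dna"
  else "rna"
}

# ---------------------------------------------------------------------------
# Reading

#' Read a structure from PDB or mmCIF
#'
#' Alternate locations are resolved to the highest-occupancy conformer
#' (first-in-file on ties), waters and hydrogens are dropped, and entities are
#' taken from mmCIF entity records or, for PDB, inferred by grouping chains
#' with identical sequences.
#'
#' @param path file path.
#' @param format \code{"pdb"}, \code{"mmcif"} or \code{"auto"} (by extension,
#'   falling back to content sniffing).
#' @param id structure identifier; defaults to the file base name.
#' @param assembly_label assembly label stored on the structure.
#' @return A \code{\link{cam_structure}} object.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           id = NULL, assembly_label = "1") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif"
      else if (ext %in% c("pdb", "ent")) "pdb"
      else {
        first <- readLines(path, n = 1L, warn = FALSE)
        if (length(first) && startsWith(trimws(first), "data_")) "mmcif" else "pdb"
      }
  }
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  if (format == "pdb") read_pdb_file(path, id, assembly_label)
  else read_mmcif_file(path, id, assembly_label)
}

strip_atoms <- function(at) {
  # waters, hydrogens, then alt-loc resolution (max occupancy, first on tie)
  at <- at[!(at$comp_id %in% WATER_COMPS), , drop = FALSE]
  at <- at[!(toupper(at$element) %in% c("H", "D")), , drop = FALSE]
  if (!nrow(at)) return(at)
  key <- paste(at$chain, at$resnum, at$icode, at$atom, sep = "|")
  ord <- order(key, -at$occ, seq_len(nrow(at)), method = "radix")
  at <- at[ord, , drop = FALSE]
  key <- key[ord]
  at <- at[!duplicated(key), , drop = FALSE]
  at <- at[order(at$serial), , drop = FALSE]
  at$serial <- NULL
  at$altloc <- NULL
  rownames(at) <- NULL
  at
}

element_from_name <- function(name) {
  two <- c("FE", "ZN", "MG", "MN", "CU", "SE", "CL", "BR", "NA", "CO", "NI")
  nm <- gsub("[0-9']", "", toupper(name))
  ifelse(nm %in% two & nchar(name) > 2, nm, substr(nm, 1, 1))
}

read_pdb_file <- function(path, id, assembly_label) {
  ln <- readLines(path, warn = FALSE)
  sel <- grepl("^(ATOM  |HETATM)", ln)
  if (!any(sel)) stop("PDB parse failure: no ATOM/HETATM records in ", path)
  ln <- ln[sel]
  fx <- function(a, b) trimws(substr(ln, a, b))
  x <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
  if (anyNA(x) || anyNA(y) || anyNA(z))
    stop("PDB parse failure: bad coordinate field at line ",
         which(is.na(x) | is.na(y) | is.na(z))[1])
  occ <- suppressWarnings(as.numeric(substr(ln, 55, 60)))
  occ[is.na(occ)] <- 1
  el <- fx(77, 78)
  nm <- fx(13, 16)
  el[!nzchar(el)] <- element_from_name(nm[!nzchar(el)])
  at <- data.frame(serial = seq_along(ln),
                   chain = fx(22, 22), resnum = as.integer(fx(23, 26)),
                   icode = fx(27, 27), comp_id = fx(18, 20),
                   atom = nm, altloc = fx(17, 17), element = el,
                   x = x, y = y, z = z, occ = occ,
                   hetero = startsWith(ln, "HETATM"),
                   stringsAsFactors = FALSE)
  finish_structure(at, entities = NULL, id, assembly_label)
}

finish_structure <- function(at, entities, id, assembly_label) {
  at <- strip_atoms(at)
  if (!nrow(at)) stop("empty structure after filtering: ", id)
  # residue kinds
  k <- res_key(at$chain, at$resnum, at$icode)
  at$kind <- NA_character_
  for (kk in unique(k)) {
    idx <- which(k == kk)
    at$kind[idx] <- classify_residue_kind(at$comp_id[idx[1]], at$atom[idx],
                                          any(at$hetero[idx]))
  }
  if (is.null(entities)) {
    inf <- infer_entities(at)
    at <- inf$atoms; entities <- inf$entities
  }
  cam_structure(at, entities, id = id, assembly_label = assembly_label)
}

# -- minimal CIF tokenizer -------------------------------------------------

cif_tokens <- function(lines) {
  toks <- list(); n <- 0L
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (startsWith(ln, ";")) {              # multi-line text field
      buf <- substring(ln, 2)
      i <- i + 1L
      while (i <= length(lines) && !startsWith(lines[i], ";")) {
        buf <- paste0(buf, lines[i]); i <- i + 1L
      }
      n <- n + 1L; toks[[n]] <- buf
      i <- i + 1L
      next
    }
    ln <- sub("^\\s+", "", ln)
    while (nzchar(ln)) {
      if (startsWith(ln, "#")) break
      ch <- substr(ln, 1, 1)
      if (ch %in% c("'", '"')) {
        close <- regexpr(paste0(ch, "(\\s|$)"), substring(ln, 2))
        if (close < 0) stop("CIF parse failure: unterminated quote: ", ln)
        n <- n + 1L; toks[[n]] <- substr(ln, 2, close)
        ln <- sub("^\\s+", "", substring(ln, close + 2))
      } else {
        sp <- regexpr("\\s", ln)
        if (sp < 0) { n <- n + 1L; toks[[n]] <- ln; ln <- "" }
        else {
          n <- n + 1L; toks[[n]] <- substr(ln, 1, sp - 1)
          ln <- sub("^\\s+", "", substring(ln, sp + 1))
        }
      }
    }
    i <- i + 1L
  }
  unlist(toks, use.names = FALSE)
}

# Parse CIF tokens into a list of category data.frames (loops) and single
# key-value items.
cif_parse <- function(path) {
  toks <- cif_tokens(readLines(path, warn = FALSE))
  cats <- list(); items <- list()
  i <- 1L; N <- length(toks)
  while (i <= N) {
    t <- toks[i]
    if (startsWith(t, "data_")) { i <- i + 1L; next }
    if (identical(t, "loop_")) {
      i <- i + 1L
      tags <- character()
      while (i <= N && startsWith(toks[i], "_")) { tags <- c(tags, toks[i]); i <- i + 1L }
      if (!length(tags)) stop("CIF parse failure: loop_ without tags")
      vals <- list(); v <- 0L
      while (i <= N && !startsWith(toks[i], "_") &&
             !identical(toks[i], "loop_") && !startsWith(toks[i], "data_")) {
        v <- v + 1L; vals[[v]] <- toks[i]; i <- i + 1L
      }
      vals <- unlist(vals, use.names = FALSE)
      if (length(vals) %% length(tags) != 0L)
        stop("CIF parse failure: ragged loop for category ",
             sub("\\..*", "", tags[1]))
      m <- matrix(vals, ncol = length(tags), byrow = TRUE)
      df <- as.data.frame(m, stringsAsFactors = FALSE)
      names(df) <- tags
      cat_name <- sub("\\..*", "", tags[1])
      cats[[cat_name]] <- if (is.null(cats[[cat_name]])) df else rbind(cats[[cat_name]], df)
    } else if (startsWith(t, "_")) {
      if (i + 1L > N) stop("CIF parse failure: item without value: ", t)
      items[[t]] <- toks[i + 1L]
      i <- i + 2L
    } else i <- i + 1L
  }
  # fold single items into one-row categories as well
  for (nm in names(items)) {
    cat_name <- sub("\\..*", "", nm)
    if (is.null(cats[[cat_name]])) cats[[cat_name]] <- data.frame(row.names = 1)
    cats[[cat_name]][[nm]] <- items[[nm]]
  }
  cats
}

cif_col <- function(df, cat, field, default = NULL) {
  nm <- paste0(cat, ".", field)
  if (!is.null(df[[nm]])) df[[nm]] else default
}

read_mmcif_file <- function(path, id, assembly_label) {
  cats <- cif_parse(path)
  as_ <- cats[["_atom_site"]]
  if (is.null(as_)) stop("mmCIF parse failure: no _atom_site category in ", path)
  n <- nrow(as_)
  pick <- function(field, alt = NULL, default = NULL) {
    v <- cif_col(as_, "_atom_site", field)
    if (is.null(v) && !is.null(alt)) v <- cif_col(as_, "_atom_site", alt)
    if (is.null(v)) { if (is.null(default)) NULL else rep(default, n) } else v
  }
  chain <- pick("auth_asym_id", "label_asym_id")
  if (is.null(chain)) stop("mmCIF parse failure: no asym_id in _atom_site")
  resnum <- pick("auth_seq_id", "label_seq_id")
  icode <- pick("pdbx_PDB_ins_code", default = "")
  icode[icode %in% c("?", ".")] <- ""
  altloc <- pick("label_alt_id", default = "")
  altloc[altloc %in% c("?", ".")] <- ""
  occ <- suppressWarnings(as.numeric(pick("occupancy", default = "1")))
  occ[is.na(occ)] <- 1
  at <- data.frame(serial = seq_len(n), chain = chain,
                   resnum = as.integer(resnum), icode = icode,
                   comp_id = pick("label_comp_id", "auth_comp_id"),
                   atom = pick("label_atom_id", "auth_atom_id"),
                   altloc = altloc,
                   element = toupper(pick("type_symbol", default = "")),
                   x = as.numeric(pick("Cartn_x")),
                   y = as.numeric(pick("Cartn_y")),
                   z = as.numeric(pick("Cartn_z")),
                   occ = occ,
                   hetero = pick("group_PDB", default = "ATOM") == "HETATM",
                   stringsAsFactors = FALSE)
  if (!nzchar(at$element[1])) at$element <- element_from_name(at$atom)
  ent_id <- pick("label_entity_id")

  entities <- NULL
  ep <- cats[["_entity_poly"]]
  if (!is.null(ep) && !is.null(ent_id)) {
    type_map <- function(tp, nseq) switch(tp,
      "polypeptide(L)" = if (nseq >= 30) "protein" else "peptide",
      "polydeoxyribonucleotide" = "dna",
      "polyribonucleotide" = "rna", "nonpolymer")
    ids <- cif_col(ep, "_entity_poly", "entity_id")
    tps <- cif_col(ep, "_entity_poly", "type")
    sqs <- cif_col(ep, "_entity_poly", "pdbx_seq_one_letter_code")
    entities <- lapply(seq_along(ids), function(j) {
      toks <- tokenize_seq(gsub("\\s", "", sqs[j]))
      cam_entity(ids[j], type_map(tps[j], length(toks)), toks)
    })
    # nonpolymer entities present in atoms but not entity_poly
    extra <- setdiff(unique(ent_id), ids)
    entities <- c(entities, lapply(extra, function(e)
      cam_entity(e, "nonpolymer", character())))
    at$entity_id <- ent_id
    return(finish_structure(at, entities, id, assembly_label))
  }
  finish_structure(at, NULL, id, assembly_label)
}

# ---------------------------------------------------------------------------
# Writing

#' Write a structure to PDB or mmCIF
#'
#' Round-trips through \code{\link{read_structure}} preserve chain ids,
#' residue numbering and coordinates to 0.001 A (the PDB fixed-width
#' contract).
#'
#' @param s a \code{camstruct}.
#' @param path output path.
#' @param format \code{"pdb"} or \code{"mmcif"}.
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(s, path, format = c("pdb", "mmcif")) {
  format <- match.arg(format)
  if (nrow(s$atoms) == 0L) stop("refusing to write empty structure")
  if (format == "pdb") write_pdb_file(s, path) else write_mmcif_file(s, path)
  invisible(path)
}

write_pdb_file <- function(s, path) {
  a <- s$atoms
  if (any(nchar(a$chain) > 1L))
    stop("chain id too long for the PDB dialect (one character); use format = \"mmcif\"")
  if (any(nchar(a$comp_id) > 3L))
    stop("component id too long for the PDB dialect; use format = \"mmcif\"")
  fmt_name <- ifelse(nchar(a$atom) < 4L, paste0(" ", sprintf("%-3s", a$atom)),
                     a$atom)
  rec <- ifelse(a$hetero, "HETATM", "ATOM  ")
  lines <- sprintf("%s%5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, seq_len(nrow(a)), fmt_name, a$comp_id, a$chain,
                   a$resnum, ifelse(nzchar(a$icode), a$icode, " "),
                   a$x, a$y, a$z, a$occ, 0, a$element)
  out <- character()
  for (ch in cam_chains(s)) {
    out <- c(out, lines[a$chain == ch], "TER")
  }
  writeLines(c(out, "END"), path)
}

cif_quote <- function(x) {
  need <- grepl("[ '\"()]", x) | !nzchar(x)
  ifelse(need, paste0("'", x, "'"), x)
}

write_mmcif_file <- function(s, path) {
  a <- s$atoms
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w(paste0("data_", gsub("\\s", "_", s$id)))
  w(paste0("_entry.id ", cif_quote(s$id)))
  ents <- s$entities
  if (length(ents)) {
    w("loop_", "_entity.id", "_entity.type")
    for (e in ents)
      w(paste(e$id, if (e$polymer_type == "nonpolymer") "non-polymer" else "polymer"))
    poly <- Filter(function(e) e$polymer_type != "nonpolymer", ents)
    if (length(poly)) {
      w("loop_", "_entity_poly.entity_id", "_entity_poly.type",
        "_entity_poly.pdbx_seq_one_letter_code")
      tp <- c(protein = "polypeptide(L)", peptide = "polypeptide(L)",
              dna = "polydeoxyribonucleotide", rna = "polyribonucleotide")
      for (e in poly)
        w(paste(e$id, cif_quote(tp[[e$polymer_type]]),
                cif_quote(paste(e$seq, collapse = ""))))
    }
  }
  w("loop_", "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.auth_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.auth_asym_id",
    "_atom_site.occupancy", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z")
  w(sprintf("%s %d %s %s . %s %s %s %d %s %s %.2f %.3f %.3f %.3f",
            ifelse(a$hetero, "HETATM", "ATOM"), seq_len(nrow(a)), a$element,
            cif_quote(a$atom), a$comp_id, a$chain,
            ifelse(is.na(a$entity_id), ".", a$entity_id), a$resnum,
            ifelse(nzchar(a$icode), a$icode, "?"), a$chain, a$occ,
            a$x, a$y, a$z))
}

# ---------------------------------------------------------------------------
# FASTA with bracketed noncanonical residues

#' Tokenize an extended-FASTA sequence string
#'
#' Noncanonical residues appear as PDB component identifiers enclosed in round
#' brackets; \code{"AC(MLZ)G"} yields the four tokens
#' \code{A, C, (MLZ), G}.
#'
#' @param s sequence string.
#' @return character vector of tokens.
#' @export
tokenize_seq <- function(s) {
  chars <- strsplit(s, "")[[1]]
  toks <- character(); i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      close <- which(chars == ")" & seq_along(chars) > i)
      if (!length(close)) stop("unbalanced bracket at offset ", i - 1L)
      j <- close[1]
      if (j == i + 1L) stop("empty component id at offset ", i - 1L)
      toks <- c(toks, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch == ")") {
      stop("unbalanced bracket at offset ", i - 1L)
    } else {
      toks <- c(toks, ch)
      i <- i + 1L
    }
  }
  toks
}

#' Render sequence tokens back to a string
#' @param tokens character vector of tokens as from \code{\link{tokenize_seq}}.
#' @export
detokenize_seq <- function(tokens) paste(tokens, collapse = "")

#' Read entities from extended FASTA
#'
#' Headers carry the entity id and a \code{type=} tag, e.g.
#' \code{>e1 type=protein}.
#'
#' @param path FASTA file path.
#' @return list of \code{\link{cam_entity}} objects.
#' @export
read_fasta_ext <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(trimws(ln))]
  hd <- grep("^>", ln)
  if (!length(hd)) stop("FASTA parse failure: no header lines in ", path)
  ends <- c(hd[-1] - 1L, length(ln))
  lapply(seq_along(hd), function(i) {
    header <- sub("^>", "", ln[hd[i]])
    fields <- strsplit(trimws(header), "\\s+")[[1]]
    id <- fields[1]
    tp <- sub("^type=", "", grep("^type=", fields, value = TRUE))
    if (!length(tp)) tp <- "protein"
    if (hd[i] + 1L > ends[i]) stop("empty sequence for entity ", id)
    seq <- gsub("\\s", "", paste(ln[seq(hd[i] + 1L, ends[i])], collapse = ""))
    if (!nzchar(seq)) stop("empty sequence for entity ", id)
    cam_entity(id, tp, tokenize_seq(seq))
  })
}

#' Write entities to extended FASTA
#' @param entities list of \code{\link{cam_entity}}.
#' @param path output path.
#' @export
write_fasta_ext <- function(entities, path) {
  out <- unlist(lapply(entities, function(e)
    c(sprintf(">%s type=%s", e$id, e$polymer_type), detokenize_seq(e$seq))))
  writeLines(out, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Residue alignment

#' Needleman-Wunsch global alignment of token sequences
#'
#' Linear gap penalty; ties in the dynamic program are resolved preferring the
#' diagonal move, then the vertical one, giving a deterministic traceback.
#'
#' @param a,b character vectors of residue tokens.
#' @param match,mismatch,gap alignment scores (defaults +1 / -1 / -2).
#' @return integer matrix with columns \code{a}, \code{b}: indices of aligned
#'   pairs.
#' @export
nw_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  n <- length(a); m <- length(b)
  S <- matrix(0, n + 1L, m + 1L)
  S[, 1] <- gap * (0:n); S[1, ] <- gap * (0:m)
  P <- matrix(0L, n + 1L, m + 1L)        # 1 diag, 2 up, 3 left
  P[, 1] <- 2L; P[1, ] <- 3L; P[1, 1] <- 0L
  for (i in seq_len(n)) {
    sub <- ifelse(a[i] == b, match, mismatch)
    for (j in seq_len(m)) {
      d <- S[i, j] + sub[j]; u <- S[i, j + 1L] + gap; l <- S[i + 1L, j] + gap
      best <- max(d, u, l)
      S[i + 1L, j + 1L] <- best
      P[i + 1L, j + 1L] <- if (d == best) 1L else if (u == best) 2L else 3L
    }
  }
  ai <- integer(); bi <- integer()
  i <- n + 1L; j <- m + 1L
  while (i > 1L || j > 1L) {
    mv <- P[i, j]
    if (mv == 1L) { ai <- c(i - 1L, ai); bi <- c(j - 1L, bi); i <- i - 1L; j <- j - 1L }
    else if (mv == 2L) i <- i - 1L
    else j <- j - 1L
  }
  cbind(a = ai, b = bi)
}

#' Align residues of a model chain to a reference chain
#'
#' If every reference residue's (number, insertion code, component) triple has
#' an exact, monotone match in the model the author-numbering correspondence
#' is used directly; otherwise a global sequence alignment on residue tokens
#' decides the pairing (noncanonical tokens compare by component id).
#'
#' @param model,ref \code{camstruct} objects.
#' @param model_chain,ref_chain chain identifiers.
#' @return Object of class \code{residue_alignment}: list with \code{pairs}
#'   (integer matrix, columns \code{model}, \code{ref}, row indices into each
#'   chain's \code{\link{residue_table}}), \code{method}
#'   (\code{"by_number"} or \code{"by_sequence"}), the two chain ids, and the
#'   residue tables themselves.
#' @export
align_residues <- function(model, ref, model_chain = cam_chains(model)[1],
                           ref_chain = cam_chains(ref)[1]) {
  mt <- residue_table(model, model_chain)
  rt <- residue_table(ref, ref_chain)
  if (!nrow(mt) || !nrow(rt)) stop("empty chain")
  mtrip <- paste(mt$resnum, mt$icode, mt$comp_id, sep = "|")
  rtrip <- paste(rt$resnum, rt$icode, rt$comp_id, sep = "|")
  pos <- match(rtrip, mtrip)
  if (!anyNA(pos) && !is.unsorted(pos, strictly = TRUE)) {
    pairs <- cbind(model = pos, ref = seq_len(nrow(rt)))
    method <- "by_number"
  } else {
    mtok <- residue_token(mt$comp_id, mt$kind)
    rtok <- residue_token(rt$comp_id, rt$kind)
    al <- nw_align(mtok, rtok)
    pairs <- cbind(model = al[, "a"], ref = al[, "b"])
    method <- "by_sequence"
  }
  if (!nrow(pairs)) stop("no correspondence between chains ",
                         model_chain, " and ", ref_chain)
  structure(list(pairs = pairs, method = method,
                 model_chain = model_chain, ref_chain = ref_chain,
                 model_residues = mt, ref_residues = rt),
            class = "residue_alignment")
}

#' @export
print.residue_alignment <- function(x, ...) {
  cat(sprintf("<residue_alignment> %s -> %s: %d pairs (%s)\n",
              x$model_chain, x$ref_chain, nrow(x$pairs), x$method))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Kabsch superposition

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' \code{xs} onto \code{ys}; reflections are excluded by sign correction of
#' the smallest singular direction.
#'
#' @param xs,ys numeric N x 3 coordinate matrices, N >= 3.
#' @return list with \code{rotation} (3 x 3, det +1), \code{translation}
#'   (length-3) such that \code{xs \%*\% rotation + translation} best fits
#'   \code{ys}, and \code{rmsd} in Angstrom.
#' @export
superpose_kabsch <- function(xs, ys) {
  xs <- as.matrix(xs); ys <- as.matrix(ys)
  if (nrow(xs) != nrow(ys) || ncol(xs) != 3L || ncol(ys) != 3L)
    stop("coordinate matrices must be N x 3 with matching N")
  if (nrow(xs) < 3L) stop("at least 3 points are required")
  cx <- colMeans(xs); cy <- colMeans(ys)
  xc <- sweep(xs, 2, cx); yc <- sweep(ys, 2, cy)
  H <- crossprod(xc, yc)
  sv <- svd(H)
  s <- sign(det(sv$u %*% t(sv$v)))
  if (s == 0) s <- 1
  R <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
  tr <- cy - drop(cx %*% R)
  fitted <- sweep(xc %*% R, 2, cy, "+")
  rmsd <- sqrt(mean(rowSums((fitted - ys)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd)
}
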