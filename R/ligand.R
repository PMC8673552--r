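# Ligand-pose evaluation: molecular-graph automorphisms, symmetry-corrected
# RMSD after (optional) binding-site superposition, and superposition-free
# distance RMSD. Chemically equivalent atoms (e.g. the two carboxylate
# oxygens) are interchangeable in a pose, so naive index-matched RMSD
# overestimates the error; minimizing over graph automorphisms corrects this.

#' Ligand graph
#'
#' Molecular graph of one ligand with index-aligned reference and model
#' coordinates. Hydrogens are expected to be absent; aromatic bonds should be
#' normalized to order 1.5 (see \code{\link{read_bond_table}}).
#'
#' @param elements character vector of element symbols (one per atom).
#' @param bonds data.frame with columns \code{i}, \code{j} (1-based atom
#'   indices) and \code{order}.
#' @param coords_ref,coords_model N x 3 coordinate matrices, Angstrom.
#' @return Object of class \code{ligand_graph}.
#' @export
ligand_graph <- function(elements, bonds, coords_ref,
                         coords_model = coords_ref) {
  n <- length(elements)
  coords_ref <- as.matrix(coords_ref); coords_model <- as.matrix(coords_model)
  stopifnot(n >= 1, ncol(coords_ref) == 3, ncol(coords_model) == 3,
            nrow(coords_ref) == n, nrow(coords_model) == n,
            all(c("i", "j", "order") %in% names(bonds)))
  if (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n |
          bonds$i == bonds$j))
    stop("invalid bond endpoints")
  # connectivity check
  if (n > 1L) {
    adj <- vector("list", n)
    for (k in seq_len(nrow(bonds))) {
      adj[[bonds$i[k]]] <- c(adj[[bonds$i[k]]], bonds$j[k])
      adj[[bonds$j[k]]] <- c(adj[[bonds$j[k]]], bonds$i[k])
    }
    seen <- logical(n); queue <- 1L; seen[1] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    if (!all(seen)) stop("ligand graph is not connected")
  }
  structure(list(elements = toupper(elements),
                 bonds = bonds[, c("i", "j", "order")],
                 coords_ref = coords_ref, coords_model = coords_model),
            class = "ligand_graph")
}

#' Read a ligand bond table
#'
#' TSV with columns \code{i}, \code{j}, \code{order}; order \code{"ar"} (or
#' \code{"aromatic"}) is normalized to 1.5.
#'
#' @param path file path.
#' @export
read_bond_table <- function(path) {
  b <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("i", "j", "order") %in% names(b)))
    stop("bond table must have columns i, j, order")
  ord <- as.character(b$order)
  ord[ord %in% c("ar", "aromatic")] <- "1.5"
  b$order <- as.numeric(ord)
  if (anyNA(b$order)) stop("unparseable bond order in ", path)
  b
}

bond_order_matrix <- function(g) {
  n <- length(g$elements)
  B <- matrix(0, n, n)
  for (k in seq_len(nrow(g$bonds))) {
    B[g$bonds$i[k], g$bonds$j[k]] <- g$bonds$order[k]
    B[g$bonds$j[k], g$bonds$i[k]] <- g$bonds$order[k]
  }
  B
}

#' Enumerate graph automorphisms of a ligand
#'
#' All permutations of atom indices preserving element labels and the bond
#' multiset with orders, found by iterative invariant refinement (element,
#' degree, sorted incident bond orders, then neighborhood colors) followed by
#' backtracking. The identity is always included and comes first; ordering is
#' deterministic.
#'
#' @param g \code{\link{ligand_graph}}.
#' @param cap maximum number of automorphisms (error beyond; default 100000).
#' @return integer matrix, one automorphism per row.
#' @export
automorphisms <- function(g, cap = 1e5) {
  n <- length(g$elements)
  if (n > 200L) stop("ligand too large (> 200 atoms)")
  B <- bond_order_matrix(g)
  col <- paste(g$elements, rowSums(B > 0),
               vapply(seq_len(n), function(i)
                 paste(sort(B[i, B[i, ] > 0]), collapse = ","), ""))
  repeat {
    nb <- vapply(seq_len(n), function(i) {
      js <- which(B[i, ] > 0)
      paste(sort(paste(B[i, js], col[js])), collapse = ";")
    }, "")
    new_col <- paste(col, nb)
    new_col <- match(new_col, unique(new_col))
    if (length(unique(new_col)) == length(unique(col)) &&
        all(tapply(new_col, col, function(v) length(unique(v))) == 1))
      break
    col <- as.character(new_col)
  }
  perms <- list()
  used <- logical(n)
  sigma <- integer(n)
  bt <- function(i) {
    if (i > n) {
      if (length(perms) >= cap)
        stop("automorphism count exceeds cap (", cap, "); raise `cap`")
      perms[[length(perms) + 1L]] <<- sigma
      return()
    }
    for (c_ in which(col == col[i] & !used)) {
      ok <- TRUE
      for (j in seq_len(i - 1L)) {
        if (B[i, j] != B[c_, sigma[j]]) { ok <- FALSE; break }
      }
      if (ok) {
        sigma[i] <<- c_; used[c_] <<- TRUE
        bt(i + 1L)
        used[c_] <<- FALSE
      }
    }
  }
  bt(1L)
  do.call(rbind, perms)
}

#' Symmetry-corrected ligand RMSD
#'
#' RMSD between model and reference ligand poses minimized over the ligand's
#' graph automorphisms. With \code{frame = "pocket_superpose"} the model is
#' first rigidly superposed onto the reference using mapped binding-site
#' atom pairs (typically backbone atoms of the pocket residues).
#'
#' @param g \code{\link{ligand_graph}}.
#' @param frame \code{"presuperposed"} (coordinates already share a frame) or
#'   \code{"pocket_superpose"}.
#' @param pocket for \code{pocket_superpose}: list with \code{model} and
#'   \code{ref}, matched M x 3 coordinate matrices (M >= 3).
#' @param cap automorphism cap.
#' @return list with \code{rmsd}, \code{best_perm} (atom index permutation),
#'   and \code{naive_rmsd} (identity permutation).
#' @export
symcorr_rmsd <- function(g, frame = c("presuperposed", "pocket_superpose"),
                         pocket = NULL, cap = 1e5) {
  frame <- match.arg(frame)
  xm <- g$coords_model; xr <- g$coords_ref
  if (frame == "pocket_superpose") {
    if (is.null(pocket) || nrow(as.matrix(pocket$model)) < 3L)
      stop("pocket_superpose requires >= 3 pocket atom pairs")
    fit <- superpose_kabsch(as.matrix(pocket$model), as.matrix(pocket$ref))
    xm <- sweep(xm %*% fit$rotation, 2, fit$translation, "+")
  }
  perms <- automorphisms(g, cap = cap)
  rmsds <- apply(perms, 1L, function(p)
    sqrt(mean(rowSums((xm[p, , drop = FALSE] - xr)^2))))
  k <- which.min(rmsds)
  list(rmsd = rmsds[k], best_perm = perms[k, ],
       naive_rmsd = sqrt(mean(rowSums((xm - xr)^2))))
}

#' Symmetry-corrected distance RMSD (dRMSD)
#'
#' Superposition-free pose score: the RMS deviation of all intramolecular
#' pairwise distances between model and reference, minimized over graph
#' automorphisms. Invariant to any rigid transform (proper or improper) of
#' either coordinate set.
#'
#' @param g \code{\link{ligand_graph}}.
#' @param cap automorphism cap.
#' @return dRMSD in Angstrom.
#' @export
drmsd <- function(g, cap = 1e5) {
  n <- length(g$elements)
  if (n < 2L) stop("dRMSD requires at least 2 atoms")
  Dm <- as.matrix(stats::dist(g$coords_model))
  Dr <- as.matrix(stats::dist(g$coords_ref))
  ut <- upper.tri(Dr)
  perms <- automorphisms(g, cap = cap)
  vals <- apply(perms, 1L, function(p)
    sqrt(mean((Dm[p, p][ut] - Dr[ut])^2)))
  min(vals)
}

#' Build a ligand graph from reference and model structures
#'
#' Extracts one ligand residue from both structures, matching atoms by name,
#' and attaches a bond table.
#'
#' @param ref,model \code{camstruct} objects.
#' @param ligand list with \code{chain}, \code{resnum}, optional
#'   \code{icode} identifying the ligand residue in both structures.
#' @param bonds bond data.frame (see \code{\link{read_bond_table}}) indexed
#'   on the reference atom order.
#' @export
ligand_graph_from_structures <- function(ref, model, ligand, bonds) {
  if (is.null(ligand$icode)) ligand$icode <- ""
  key <- res_key(ligand$chain, ligand$resnum, ligand$icode)
  pick <- function(s) {
    a <- s$atoms
    a[res_key(a$chain, a$resnum, a$icode) == key, , drop = FALSE]
  }
  ra <- pick(ref); ma <- pick(model)
  if (!nrow(ra)) stop("ligand residue not found in reference: ", key)
  if (!nrow(ma)) stop("ligand residue not found in model: ", key)
  idx <- match(ra$atom, ma$atom)
  if (anyNA(idx)) stop("model is missing ligand atoms: ",
                       paste(ra$atom[is.na(idx)], collapse = ", "))
  ma <- ma[idx, , drop = FALSE]
  if (!identical(ra$element, ma$element))
    stop("element mismatch between model and reference ligand atoms")
  ligand_graph(ra$element, bonds,
               as.matrix(ra[, c("x", "y", "z")]),
               as.matrix(ma[, c("x", "y", "z")]))
}
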