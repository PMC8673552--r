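# Superposition-free local Distance Difference Test.
#
# Contacts are defined from the reference structure only: all unordered
# heavy-atom pairs within the inclusion radius (same-residue pairs excluded by
# default). A contact is preserved at tolerance t when both atoms exist in the
# model (same residue via the alignment, same atom name) and the model
# distance deviates from the reference distance by less than t. Extra model
# atoms without a reference counterpart can therefore never change the score,
# while missing model atoms count against it.

#' lDDT parameters
#'
#' @param inclusion_radius contact inclusion radius in Angstrom.
#' @param thresholds strictly increasing distance tolerances in Angstrom.
#' @param exclude_same_residue drop atom pairs within one residue.
#' @return list of class \code{lddt_params}.
#' @export
lddt_params <- function(inclusion_radius = 15, thresholds = c(0.5, 1, 2, 4),
                        exclude_same_residue = TRUE) {
  stopifnot(length(thresholds) >= 1, all(thresholds > 0),
            !is.unsorted(thresholds, strictly = TRUE),
            inclusion_radius > max(thresholds))
  structure(list(inclusion_radius = inclusion_radius, thresholds = thresholds,
                 exclude_same_residue = exclude_same_residue),
            class = "lddt_params")
}

# All heavy-atom pairs of `atoms` within `radius`; canonical unordered storage
# ordered by (chain, residue, atom) lexicographic sort keys.
atom_pair_contacts <- function(atoms, radius, exclude_same_residue = TRUE) {
  n <- nrow(atoms)
  empty <- data.frame(chain_a = character(), resnum_a = integer(),
                      icode_a = character(), atom_a = character(),
                      chain_b = character(), resnum_b = integer(),
                      icode_b = character(), atom_b = character(),
                      d = numeric(), stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  dm <- as.matrix(stats::dist(xyz))
  rk <- res_key(atoms$chain, atoms$resnum, atoms$icode)
  ok <- upper.tri(dm) & dm <= radius
  if (exclude_same_residue) ok <- ok & outer(rk, rk, "!=")
  idx <- which(ok, arr.ind = TRUE)
  if (!nrow(idx)) return(empty)
  i <- idx[, 1]; j <- idx[, 2]
  sk <- sprintf("%s|%09d|%s|%s", atoms$chain, atoms$resnum + 5e8,
                atoms$icode, atoms$atom)
  swap <- sk[j] < sk[i]
  a <- ifelse(swap, j, i); b <- ifelse(swap, i, j)
  out <- data.frame(chain_a = atoms$chain[a], resnum_a = atoms$resnum[a],
                    icode_a = atoms$icode[a], atom_a = atoms$atom[a],
                    chain_b = atoms$chain[b], resnum_b = atoms$resnum[b],
                    icode_b = atoms$icode[b], atom_b = atoms$atom[b],
                    d = dm[cbind(i, j)], stringsAsFactors = FALSE)
  out[order(sk[a], sk[b]), , drop = FALSE]
}

#' Reference atom contacts for lDDT
#'
#' @param ref reference \code{camstruct}.
#' @param params \code{\link{lddt_params}}.
#' @param chain_subset chains to consider (default all); when the subset spans
#'   several chains, inter-chain contacts are included.
#' @return data.frame of unordered atom pairs with reference distances.
#' @export
reference_contacts <- function(ref, params = lddt_params(),
                               chain_subset = NULL) {
  atoms <- ref$atoms
  if (!is.null(chain_subset))
    atoms <- atoms[atoms$chain %in% chain_subset, , drop = FALSE]
  atom_pair_contacts(atoms, params$inclusion_radius,
                     params$exclude_same_residue)
}

# Map from reference residue key to model residue key, built from a list of
# residue_alignment objects.
ref_to_model_residues <- function(alignments) {
  out <- character(); nm <- character()
  for (al in alignments) {
    mres <- al$model_residues[al$pairs[, "model"], , drop = FALSE]
    rres <- al$ref_residues[al$pairs[, "ref"], , drop = FALSE]
    nm <- c(nm, rres$key)
    out <- c(out, mres$key)
  }
  stats::setNames(out, nm)
}

default_alignments <- function(model, ref, chain_map = NULL) {
  mc <- cam_chains(model); rc <- cam_chains(ref)
  if (is.null(chain_map)) {
    if (length(mc) == 1L && length(rc) == 1L) chain_map <- stats::setNames(rc, mc)
    else {
      shared <- intersect(mc, rc)
      if (!length(shared)) stop("no shared chain ids; supply alignments or chain_map")
      chain_map <- stats::setNames(shared, shared)
    }
  }
  lapply(names(chain_map), function(m)
    align_residues(model, ref, m, chain_map[[m]]))
}

# Core scoring engine shared by lddt(), lddt_bs() and oligo_lddt().
# `extra_totals` inflates the per-threshold denominator by contacts that can
# never be preserved (extra-chain penalty).
lddt_engine <- function(contacts, model, alignments, params,
                        extra_totals = 0L) {
  nthr <- length(params$thresholds)
  total <- nrow(contacts) + extra_totals
  if (total == 0L) stop("lDDT undefined: no contacts")
  r2m <- ref_to_model_residues(alignments)
  matoms <- model$atoms
  mkey <- paste(res_key(matoms$chain, matoms$resnum, matoms$icode),
                matoms$atom, sep = "|")
  mxyz <- as.matrix(matoms[, c("x", "y", "z")])
  rka <- res_key(contacts$chain_a, contacts$resnum_a, contacts$icode_a)
  rkb <- res_key(contacts$chain_b, contacts$resnum_b, contacts$icode_b)
  ma <- match(paste(r2m[rka], contacts$atom_a, sep = "|"), mkey)
  mb <- match(paste(r2m[rkb], contacts$atom_b, sep = "|"), mkey)
  present <- !is.na(ma) & !is.na(mb)
  dev <- rep(Inf, nrow(contacts))
  if (any(present)) {
    dm <- sqrt(rowSums((mxyz[ma[present], , drop = FALSE] -
                        mxyz[mb[present], , drop = FALSE])^2))
    dev[present] <- abs(dm - contacts$d[present])
  }
  pres_mat <- outer(dev, params$thresholds, "<")     # contacts x thresholds
  n_pres <- colSums(pres_mat)
  global <- mean(n_pres / total)

  # per-residue: contacts touching the residue, reference side
  keys2 <- c(rka, rkb)
  idx2 <- rep(seq_len(nrow(contacts)), 2L)
  per_res <- NULL
  if (nrow(contacts)) {
    sp <- split(idx2, keys2)
    scr <- vapply(sp, function(ii)
      mean(colSums(pres_mat[ii, , drop = FALSE]) / length(ii)), 0)
    cnt <- vapply(sp, length, 0L)
    parts <- strsplit(names(sp), "|", fixed = TRUE)
    per_res <- data.frame(chain = vapply(parts, `[`, "", 1L),
                          resnum = as.integer(vapply(parts, `[`, "", 2L)),
                          icode = vapply(parts, function(p)
                            if (length(p) >= 3L) p[3] else "", ""),
                          score = unname(scr), n_contacts = unname(cnt),
                          stringsAsFactors = FALSE)
    per_res <- per_res[order(per_res$chain, per_res$resnum, per_res$icode), ,
                       drop = FALSE]
    rownames(per_res) <- NULL
  }
  structure(list(global_score = global,
                 per_residue = per_res,
                 n_contacts = total,
                 per_threshold = data.frame(threshold = params$thresholds,
                                            preserved = n_pres,
                                            total = total),
                 params = params),
            class = "lddt_result")
}

#' @export
print.lddt_result <- function(x, ...) {
  cat(sprintf("<lddt_result> global %.4f over %d contacts x %d thresholds\n",
              x$global_score, x$n_contacts, nrow(x$per_threshold)))
  invisible(x)
}

#' Local Distance Difference Test
#'
#' @param model model \code{camstruct}.
#' @param ref reference \code{camstruct}.
#' @param alignments list of \code{\link{align_residues}} results covering the
#'   chains to score; by default chains are paired by shared id (or the single
#'   chain of each structure).
#' @param params \code{\link{lddt_params}}.
#' @param chain_map optional named character vector (model chain -> reference
#'   chain) used to build default alignments.
#' @return Object of class \code{lddt_result}: global score, per-residue
#'   scores (reference residues with at least one contact), contact counts
#'   per threshold.
#' @export
lddt <- function(model, ref, alignments = NULL, params = lddt_params(),
                 chain_map = NULL) {
  if (is.null(alignments)) alignments <- default_alignments(model, ref, chain_map)
  ref_chains <- vapply(alignments, function(a) a$ref_chain, "")
  contacts <- reference_contacts(ref, params, chain_subset = ref_chains)
  lddt_engine(contacts, model, alignments, params)
}

#' Binding-site restricted lDDT (lDDT-BS)
#'
#' Measures model accuracy in the region of a ligand binding site: the
#' reference polymer residues with any heavy atom within \code{bs_radius} of
#' any ligand heavy atom define the site, and the lDDT contact set is
#' restricted to contacts touching at least one site residue. The ligand's
#' own atoms are excluded from the contact set.
#'
#' @inheritParams lddt
#' @param ligand reference ligand residue: list with \code{chain},
#'   \code{resnum} and optional \code{icode}.
#' @param bs_radius binding-site radius in Angstrom (default 4.0).
#' @return \code{lddt_result} restricted to the binding site.
#' @export
lddt_bs <- function(model, ref, ligand, alignments = NULL,
                    params = lddt_params(), bs_radius = 4.0,
                    chain_map = NULL) {
  if (is.null(ligand$icode)) ligand$icode <- ""
  lig_key <- res_key(ligand$chain, ligand$resnum, ligand$icode)
  ra <- ref$atoms
  rk <- res_key(ra$chain, ra$resnum, ra$icode)
  lig_idx <- which(rk == lig_key)
  if (!length(lig_idx)) stop("ligand residue not found in reference: ", lig_key)
  lig_xyz <- as.matrix(ra[lig_idx, c("x", "y", "z")])
  pol <- which(ra$kind %in% c("amino", "nucleotide"))
  if (!length(pol)) stop("reference has no polymer residues")
  pxyz <- as.matrix(ra[pol, c("x", "y", "z")])
  dmin <- apply(pxyz, 1L, function(p)
    sqrt(min(colSums((t(lig_xyz) - p)^2))))
  bs_keys <- unique(rk[pol][dmin <= bs_radius])
  if (!length(bs_keys)) stop("empty binding site: no polymer residue within ",
                             bs_radius, " A of the ligand")
  if (is.null(alignments)) alignments <- default_alignments(model, ref, chain_map)
  ref_chains <- vapply(alignments, function(a) a$ref_chain, "")
  contacts <- reference_contacts(ref, params, chain_subset = ref_chains)
  cka <- res_key(contacts$chain_a, contacts$resnum_a, contacts$icode_a)
  ckb <- res_key(contacts$chain_b, contacts$resnum_b, contacts$icode_b)
  keep <- (cka %in% bs_keys | ckb %in% bs_keys) &
          cka != lig_key & ckb != lig_key
  res <- lddt_engine(contacts[keep, , drop = FALSE], model, alignments, params)
  res$binding_site <- bs_keys
  res
}
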