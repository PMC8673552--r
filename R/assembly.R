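# Complex-level evaluation: interface contacts, QS-score, entity-consistent
# chain mapping search, oligo-lDDT and best-score selection over assemblies.

#' QS-score parameters
#'
#' @param contact_cutoff interface contact cutoff between representative
#'   atoms, Angstrom.
#' @param full_weight_cutoff distance up to which a contact carries full
#'   weight; the weight decays linearly to zero at \code{contact_cutoff}.
#' @export
qs_params <- function(contact_cutoff = 12, full_weight_cutoff = 5) {
  stopifnot(full_weight_cutoff > 0, contact_cutoff > full_weight_cutoff)
  structure(list(contact_cutoff = contact_cutoff,
                 full_weight_cutoff = full_weight_cutoff),
            class = "qs_params")
}

#' Interface contact weight
#'
#' Piecewise-linear weight: 1 up to the full-weight cutoff, decaying linearly
#' to 0 at the contact cutoff.
#'
#' @param d distance(s) in Angstrom, non-negative.
#' @param params \code{\link{qs_params}}.
#' @export
contact_weight <- function(d, params = qs_params()) {
  if (any(d < 0)) stop("negative distance")
  lo <- params$full_weight_cutoff; hi <- params$contact_cutoff
  pmin(1, pmax(0, (hi - d) / (hi - lo)))
}

# Representative atom per polymer residue: Cb for amino acids (Ca for Gly),
# C1' for nucleotides; fallback Ca, then first heavy atom.
rep_atom_table <- function(s, chains = NULL) {
  a <- s$atoms
  if (!is.null(chains)) a <- a[a$chain %in% chains, , drop = FALSE]
  a <- a[a$kind %in% c("amino", "nucleotide"), , drop = FALSE]
  if (!nrow(a)) return(data.frame(chain = character(), resnum = integer(),
                                  icode = character(), key = character(),
                                  x = numeric(), y = numeric(), z = numeric(),
                                  stringsAsFactors = FALSE))
  k <- res_key(a$chain, a$resnum, a$icode)
  rows <- vapply(split(seq_len(nrow(a)), factor(k, levels = unique(k))),
    function(ii) {
      sub <- a[ii, , drop = FALSE]
      want <- if (sub$kind[1] == "nucleotide") "C1'"
        else if (sub$comp_id[1] == "GLY") "CA" else "CB"
      w <- which(sub$atom == want)
      if (!length(w)) w <- which(sub$atom == "CA")
      if (!length(w)) w <- 1L
      ii[w[1]]
    }, 0L)
  out <- a[rows, c("chain", "resnum", "icode", "x", "y", "z"), drop = FALSE]
  out$key <- res_key(out$chain, out$resnum, out$icode)
  rownames(out) <- NULL
  out
}

#' Inter-chain residue contacts
#'
#' All residue pairs from different chains whose representative atoms lie
#' within the contact cutoff.
#'
#' @param s a \code{camstruct}.
#' @param params \code{\link{qs_params}}.
#' @param chains optional chain subset.
#' @return data.frame with chain/residue keys of both partners and the
#'   distance; empty for single-chain structures.
#' @export
interface_contacts <- function(s, params = qs_params(), chains = NULL) {
  rt <- rep_atom_table(s, chains)
  empty <- data.frame(chain_a = character(), key_a = character(),
                      chain_b = character(), key_b = character(),
                      d = numeric(), stringsAsFactors = FALSE)
  if (nrow(rt) < 2L) return(empty)
  dm <- as.matrix(stats::dist(rt[, c("x", "y", "z")]))
  ok <- upper.tri(dm) & dm <= params$contact_cutoff &
        outer(rt$chain, rt$chain, "!=")
  idx <- which(ok, arr.ind = TRUE)
  if (!nrow(idx)) return(empty)
  i <- idx[, 1]; j <- idx[, 2]
  sk <- sprintf("%s|%09d|%s", rt$chain, rt$resnum + 5e8, rt$icode)
  swap <- sk[j] < sk[i]
  a <- ifelse(swap, j, i); b <- ifelse(swap, i, j)
  out <- data.frame(chain_a = rt$chain[a], key_a = rt$key[a],
                    chain_b = rt$chain[b], key_b = rt$key[b],
                    d = dm[cbind(i, j)], stringsAsFactors = FALSE)
  out <- out[order(sk[a], sk[b]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chain mapping between model and reference
#'
#' An injective, entity-consistent assignment of model chains to reference
#' chains.
#'
#' @param pairs named character vector: names are model chains, values the
#'   reference chains they map to.
#' @param model,ref the two structures (used to record unmapped chains).
#' @export
chain_mapping <- function(pairs, model, ref) {
  pairs <- unlist(pairs)
  if (anyDuplicated(pairs) || anyDuplicated(names(pairs)))
    stop("chain mapping must be injective in both directions")
  structure(list(pairs = pairs,
                 unmapped_model = setdiff(cam_chains(model), names(pairs)),
                 unmapped_ref = setdiff(cam_chains(ref), pairs)),
            class = "chain_mapping")
}

#' @export
print.chain_mapping <- function(x, ...) {
  cat("<chain_mapping> ",
      paste(names(x$pairs), x$pairs, sep = "->", collapse = ", "), "\n")
  if (length(x$unmapped_model))
    cat("  unmapped model: ", paste(x$unmapped_model, collapse = ", "), "\n")
  if (length(x$unmapped_ref))
    cat("  unmapped ref:   ", paste(x$unmapped_ref, collapse = ", "), "\n")
  invisible(x)
}

# Sequence identity (matches / shorter length) between two token vectors.
seq_identity <- function(a, b) {
  if (!length(a) || !length(b)) return(0)
  al <- nw_align(a, b)
  if (!nrow(al)) return(0)
  sum(a[al[, "a"]] == b[al[, "b"]]) / min(length(a), length(b))
}

entity_class <- function(pt) if (pt %in% c("protein", "peptide")) "amino" else pt

# model chain x ref chain compatibility matrix (entity-consistent:
# same polymer class, >= identity_min sequence identity over the shorter).
chain_compatibility <- function(model, ref, identity_min = 0.95) {
  mc <- cam_chains(model); rc <- cam_chains(ref)
  me <- lapply(mc, function(ch) model$entities[[chain_entity(model, ch)]])
  re <- lapply(rc, function(ch) ref$entities[[chain_entity(ref, ch)]])
  cmp <- matrix(FALSE, length(mc), length(rc), dimnames = list(mc, rc))
  memo <- new.env(parent = emptyenv())
  for (i in seq_along(mc)) for (j in seq_along(rc)) {
    em <- me[[i]]; er <- re[[j]]
    if (is.null(em) || is.null(er)) next
    if (em$polymer_type == "nonpolymer" || er$polymer_type == "nonpolymer") next
    if (entity_class(em$polymer_type) != entity_class(er$polymer_type)) next
    k <- paste(em$id, er$id, sep = "&")
    if (is.null(memo[[k]])) memo[[k]] <- seq_identity(em$seq, er$seq) >= identity_min
    cmp[i, j] <- memo[[k]]
  }
  cmp
}

#' Enumerate entity-consistent chain mappings
#'
#' All maximal injective mappings of model chains onto compatible reference
#' chains when their number stays at or below \code{cap}; beyond that a
#' deterministic greedy search returns a single candidate (seeded with the
#' chain-pair assignment whose translated interface maximizes QS, extended by
#' the chain pair maximizing incremental global QS; lexicographic
#' tie-breaks).
#'
#' @param model,ref \code{camstruct} objects.
#' @param cap maximum number of exhaustive mappings (default 720).
#' @param identity_min entity compatibility threshold (sequence identity over
#'   the shorter sequence).
#' @param params \code{\link{qs_params}} used by the greedy search.
#' @return list of \code{\link{chain_mapping}}; attribute \code{method} is
#'   \code{"exhaustive"} or \code{"greedy"}.
#' @export
enumerate_mappings <- function(model, ref, cap = 720, identity_min = 0.95,
                               params = qs_params()) {
  cmp <- chain_compatibility(model, ref, identity_min)
  if (!any(cmp)) stop("no mapping possible: no entity-compatible chain pair")
  mc <- rownames(cmp); rc <- colnames(cmp)
  # analytic estimate: product over model entity groups of P(n_ref, n_model)
  sig <- apply(cmp, 1L, paste, collapse = "")
  est <- 1
  for (s in unique(sig[rowSums(cmp) > 0])) {
    nm <- sum(sig == s)
    nr <- sum(cmp[which(sig == s)[1], ])
    lo <- min(nm, nr); hi <- max(nm, nr)
    est <- est * prod(seq(hi, hi - lo + 1))
  }
  if (est > cap) return(greedy_mapping(model, ref, cmp, params))

  results <- list()
  used <- rep(FALSE, length(rc))
  assign_next <- function(i, pairs) {
    if (i > length(mc)) {
      # maximality: no unmapped model chain may have an unused compatible ref
      for (k in seq_along(mc))
        if (!(mc[k] %in% names(pairs)) && any(cmp[k, ] & !used)) return()
      results[[length(results) + 1L]] <<- pairs
      return()
    }
    opts <- which(cmp[i, ] & !used)
    for (j in opts) {
      used[j] <<- TRUE
      assign_next(i + 1L, c(pairs, stats::setNames(rc[j], mc[i])))
      used[j] <<- FALSE
    }
    assign_next(i + 1L, pairs)          # leave unmapped (pruned by maximality)
  }
  assign_next(1L, stats::setNames(character(), character()))
  if (length(results) > cap) return(greedy_mapping(model, ref, cmp, params))
  maps <- lapply(results, chain_mapping, model = model, ref = ref)
  attr(maps, "method") <- "exhaustive"
  maps
}

greedy_mapping <- function(model, ref, cmp, params) {
  mc <- rownames(cmp); rc <- colnames(cmp)
  mcon <- interface_contacts(model, params)
  rcon <- interface_contacts(ref, params)
  acache <- new.env(parent = emptyenv())
  score_of <- function(pairs) {
    mp <- chain_mapping(pairs, model, ref)
    res <- try(qs_score(model, ref, mp, params,
                        .model_contacts = mcon, .ref_contacts = rcon,
                        .align_cache = acache), silent = TRUE)
    if (inherits(res, "try-error")) -Inf else res$global
  }
  # seed: two-pair assignment maximizing QS; fall back to first compatible pair
  best <- NULL; best_s <- -Inf
  cand <- which(cmp, arr.ind = TRUE)
  if (length(mc) >= 2L && length(rc) >= 2L) {
    for (p in seq_len(nrow(cand))) for (q in seq_len(nrow(cand))) {
      if (cand[p, 1] >= cand[q, 1] || cand[p, 2] == cand[q, 2]) next
      pairs <- stats::setNames(rc[c(cand[p, 2], cand[q, 2])],
                               mc[c(cand[p, 1], cand[q, 1])])
      s <- score_of(pairs)
      if (s > best_s) { best_s <- s; best <- pairs }
    }
  }
  if (is.null(best)) {
    p <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE][1, , drop = FALSE]
    best <- stats::setNames(rc[p[2]], mc[p[1]])
  }
  repeat {
    ext <- NULL; ext_s <- -Inf
    for (i in seq_along(mc)) {
      if (mc[i] %in% names(best)) next
      for (j in seq_along(rc)) {
        if (!cmp[i, j] || rc[j] %in% best) next
        s <- score_of(c(best, stats::setNames(rc[j], mc[i])))
        if (s > ext_s) { ext_s <- s; ext <- c(i, j) }
      }
    }
    if (is.null(ext)) break
    best <- c(best, stats::setNames(rc[ext[2]], mc[ext[1]]))
  }
  maps <- list(chain_mapping(best, model, ref))
  attr(maps, "method") <- "greedy"
  maps
}

mapping_alignments <- function(model, ref, mapping, cache = NULL) {
  lapply(names(mapping$pairs), function(m) {
    r <- mapping$pairs[[m]]
    key <- paste(m, r, sep = "&")
    if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
    al <- align_residues(model, ref, m, r)
    if (!is.null(cache)) cache[[key]] <- al
    al
  })
}

#' QS-score: conservation of weighted interface contacts
#'
#' Model contacts are translated into reference residue space via the chain
#' mapping and per-chain residue alignments. Contacts present on both sides
#' contribute min(w_model, w_ref) to the numerator and max(w_model, w_ref) to
#' the denominator; one-sided contacts (including all contacts touching
#' unmapped chains) contribute their weight to the denominator only.
#'
#' @param model,ref \code{camstruct} objects.
#' @param mapping \code{\link{chain_mapping}}.
#' @param params \code{\link{qs_params}}.
#' @param alignments optional list of residue alignments per mapped pair.
#' @param .model_contacts,.ref_contacts,.align_cache internal caches.
#' @return list of class \code{qs_result}: \code{global} in [0,1] and
#'   \code{per_interface} ratios per reference-space chain pair.
#' @export
qs_score <- function(model, ref, mapping, params = qs_params(),
                     alignments = NULL,
                     .model_contacts = NULL, .ref_contacts = NULL,
                     .align_cache = NULL) {
  if (is.null(alignments))
    alignments <- mapping_alignments(model, ref, mapping, .align_cache)
  mcon <- if (is.null(.model_contacts)) interface_contacts(model, params)
          else .model_contacts
  rcon <- if (is.null(.ref_contacts)) interface_contacts(ref, params)
          else .ref_contacts
  # model residue key -> ref residue key for mapped chains
  m2r <- character(); nm <- character()
  for (al in alignments) {
    mres <- al$model_residues[al$pairs[, "model"], , drop = FALSE]
    rres <- al$ref_residues[al$pairs[, "ref"], , drop = FALSE]
    nm <- c(nm, mres$key); m2r <- c(m2r, rres$key)
  }
  m2r <- stats::setNames(m2r, nm)
  trans <- function(keys) {
    out <- unname(m2r[keys])
    ifelse(is.na(out), paste0("M:", keys), paste0("R:", out))
  }
  canon_pair <- function(a, b) {
    swap <- b < a
    paste(ifelse(swap, b, a), ifelse(swap, a, b), sep = "&&")
  }
  mkeys <- if (nrow(mcon)) canon_pair(trans(mcon$key_a), trans(mcon$key_b))
           else character(0)
  rkeys <- if (nrow(rcon)) canon_pair(paste0("R:", rcon$key_a),
                                      paste0("R:", rcon$key_b))
           else character(0)
  wm <- stats::setNames(contact_weight(mcon$d, params), mkeys)
  wr <- stats::setNames(contact_weight(rcon$d, params), rkeys)
  all_keys <- union(mkeys, rkeys)
  if (!length(all_keys)) stop("QS-score undefined: no interface contacts")
  wmv <- wm[all_keys]; wrv <- wr[all_keys]
  wmv[is.na(wmv)] <- NA; wrv[is.na(wrv)] <- NA
  shared <- !is.na(wmv) & !is.na(wrv)
  num <- sum(pmin(wmv[shared], wrv[shared]))
  den <- sum(pmax(wmv[shared], wrv[shared])) +
         sum(wmv[!shared & !is.na(wmv)]) + sum(wrv[!shared & !is.na(wrv)])
  if (den == 0) stop("QS-score undefined: zero total weight")

  # interface label in ref-space chain terms (model chains of unmapped or
  # untranslated endpoints keep a model-space label)
  chain_of <- function(k) sub("\\|.*", "", sub("^[MR]:", "", k))
  iface_label <- function(keys) {
    parts <- strsplit(keys, "&&", fixed = TRUE)
    side <- function(k) {
      ch <- chain_of(k)
      if (startsWith(k, "M:")) {
        mapped <- mapping$pairs[ch]
        if (!is.na(mapped)) unname(mapped) else paste0("model.", ch)
      } else ch
    }
    vapply(parts, function(p) {
      a <- side(p[1]); b <- side(p[2])
      paste(sort(c(a, b)), collapse = ":")
    }, "")
  }
  lab <- iface_label(all_keys)
  per_iface <- vapply(split(seq_along(all_keys), lab), function(ii) {
    sh <- shared[ii]
    nn <- sum(pmin(wmv[ii][sh], wrv[ii][sh]))
    dd <- sum(pmax(wmv[ii][sh], wrv[ii][sh])) +
          sum(wmv[ii][!sh & !is.na(wmv[ii])]) +
          sum(wrv[ii][!sh & !is.na(wrv[ii])])
    if (dd == 0) NA_real_ else nn / dd
  }, 0)
  structure(list(global = num / den, per_interface = per_iface,
                 numerator = num, denominator = den),
            class = "qs_result")
}

#' @export
print.qs_result <- function(x, ...) {
  cat(sprintf("<qs_result> global %.4f (%d interfaces)\n", x$global,
              length(x$per_interface)))
  invisible(x)
}

#' Oligomeric lDDT
#'
#' lDDT over the whole complex: the contact universe is every reference
#' contact (intra- and inter-chain), scored against the model through the
#' chain mapping, plus the contacts of unmapped (extra) model chains, which
#' enter the denominator at every threshold and are never preserved. Missing
#' chains are penalized automatically because their reference contacts cannot
#' be preserved.
#'
#' @inheritParams qs_score
#' @param params \code{\link{lddt_params}}.
#' @param extra_chain_mode \code{"full"} counts intra- and inter-chain
#'   contacts of unmapped model chains; \code{"inter"} counts only their
#'   inter-chain contacts.
#' @param .ref_contacts,.model_contacts internal caches of
#'   \code{\link{reference_contacts}} on all chains of each structure.
#' @return \code{lddt_result} over the complex contact universe.
#' @export
oligo_lddt <- function(model, ref, mapping, params = lddt_params(),
                       alignments = NULL,
                       extra_chain_mode = c("full", "inter"),
                       .ref_contacts = NULL, .model_contacts = NULL,
                       .align_cache = NULL) {
  extra_chain_mode <- match.arg(extra_chain_mode)
  if (is.null(alignments))
    alignments <- mapping_alignments(model, ref, mapping, .align_cache)
  rcon <- if (is.null(.ref_contacts)) reference_contacts(ref, params)
          else .ref_contacts
  extra <- 0L
  if (length(mapping$unmapped_model)) {
    mcon <- if (is.null(.model_contacts)) reference_contacts(model, params)
            else .model_contacts
    touch <- mcon$chain_a %in% mapping$unmapped_model |
             mcon$chain_b %in% mapping$unmapped_model
    if (extra_chain_mode == "inter")
      touch <- touch & mcon$chain_a != mcon$chain_b
    extra <- sum(touch)
  }
  lddt_engine(rcon, model, alignments, params, extra_totals = extra)
}

#' Best-score selection across assemblies and chain mappings
#'
#' Computes the requested scores for every combination of reference assembly
#' and candidate chain mapping and keeps, independently for each score, the
#' most favorable value together with its winning assembly and mapping.
#'
#' @param model model \code{camstruct}.
#' @param ref_assemblies a \code{camstruct} or list of them (alternative
#'   biological assemblies of one target).
#' @param scores subset of \code{c("qs", "oligo_lddt")}.
#' @param qs_par \code{\link{qs_params}}.
#' @param lddt_par \code{\link{lddt_params}}.
#' @param cap mapping enumeration cap (see \code{\link{enumerate_mappings}}).
#' @param identity_min entity compatibility threshold.
#' @return Object of class \code{complex_score_report} with elements
#'   \code{qs_score}, \code{oligo_lddt}, \code{winning} (per score: assembly
#'   label and mapping), \code{per_interface_qs}, \code{per_chain_lddt} and
#'   \code{n_candidates}.
#' @export
best_score <- function(model, ref_assemblies, scores = c("qs", "oligo_lddt"),
                       qs_par = qs_params(), lddt_par = lddt_params(),
                       cap = 720, identity_min = 0.95) {
  scores <- match.arg(scores, c("qs", "oligo_lddt"), several.ok = TRUE)
  if (inherits(ref_assemblies, "camstruct")) ref_assemblies <- list(ref_assemblies)
  stopifnot(length(ref_assemblies) >= 1)
  best <- list(qs = NULL, oligo_lddt = NULL)
  win <- list(qs = NULL, oligo_lddt = NULL)
  detail <- list(qs = NULL, oligo_lddt = NULL)
  n_cand <- 0L
  errs <- character()
  for (ref in ref_assemblies) {
    maps <- try(enumerate_mappings(model, ref, cap = cap,
                                   identity_min = identity_min,
                                   params = qs_par), silent = TRUE)
    if (inherits(maps, "try-error")) { errs <- c(errs, attr(maps, "condition")$message); next }
    acache <- new.env(parent = emptyenv())
    micon <- interface_contacts(model, qs_par)
    ricon <- interface_contacts(ref, qs_par)
    mlcon <- reference_contacts(model, lddt_par)
    rlcon <- reference_contacts(ref, lddt_par)
    for (mp in maps) {
      n_cand <- n_cand + 1L
      if ("qs" %in% scores) {
        r <- try(qs_score(model, ref, mp, qs_par,
                          .model_contacts = micon, .ref_contacts = ricon,
                          .align_cache = acache), silent = TRUE)
        if (!inherits(r, "try-error") &&
            (is.null(best$qs) || r$global > best$qs)) {
          best$qs <- r$global
          win$qs <- list(assembly = ref$assembly_label, mapping = mp)
          detail$qs <- r$per_interface
        }
      }
      if ("oligo_lddt" %in% scores) {
        r <- try(oligo_lddt(model, ref, mp, lddt_par,
                            .ref_contacts = rlcon, .model_contacts = mlcon,
                            .align_cache = acache), silent = TRUE)
        if (!inherits(r, "try-error") &&
            (is.null(best$oligo_lddt) || r$global_score > best$oligo_lddt)) {
          best$oligo_lddt <- r$global_score
          win$oligo_lddt <- list(assembly = ref$assembly_label, mapping = mp)
          detail$oligo_lddt <- r
        }
      }
    }
  }
  if (n_cand == 0L)
    stop("no mapping possible for any assembly: ", paste(errs, collapse = "; "))
  per_chain <- NULL
  if (!is.null(win$oligo_lddt)) {
    mp <- win$oligo_lddt$mapping
    ref <- ref_assemblies[[match(win$oligo_lddt$assembly,
      vapply(ref_assemblies, function(r) r$assembly_label, ""))]]
    per_chain <- vapply(names(mp$pairs), function(m) {
      r <- try(lddt(model, ref,
                    alignments = list(align_residues(model, ref, m, mp$pairs[[m]])),
                    params = lddt_par), silent = TRUE)
      if (inherits(r, "try-error")) NA_real_ else r$global_score
    }, 0)
  }
  structure(list(qs_score = best$qs, oligo_lddt = best$oligo_lddt,
                 winning = win, per_interface_qs = detail$qs,
                 per_chain_lddt = per_chain,
                 oligo_result = detail$oligo_lddt,
                 n_candidates = n_cand),
            class = "complex_score_report")
}

#' @export
print.complex_score_report <- function(x, ...) {
  cat("<complex_score_report>\n")
  if (!is.null(x$qs_score))
    cat(sprintf("  QS-score:   %.4f (assembly %s)\n", x$qs_score,
                x$winning$qs$assembly))
  if (!is.null(x$oligo_lddt))
    cat(sprintf("  oligo-lDDT: %.4f (assembly %s)\n", x$oligo_lddt,
                x$winning$oligo_lddt$assembly))
  cat(sprintf("  candidates evaluated: %d\n", x$n_candidates))
  invisible(x)
}
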