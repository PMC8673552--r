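# Prerelease target processing: entity filtering and typing, greedy
# sequence-identity clustering, aggregation of per-entity homology hits into
# full-complex templates, and target novelty categorization.

#' Target selection parameters
#'
#' Thresholds for hit filtering and sequence clustering. Boundaries are
#' inclusive ("at least"): a BLAST hit at exactly 85% identity and 70%
#' coverage passes.
#'
#' @param blast_identity_min,blast_coverage_min BLAST pass thresholds (%).
#' @param hh_probability_min,hh_coverage_min HHblits pass thresholds (%).
#' @param cluster_identity protein clustering identity threshold (fraction).
#' @param protein_min_len minimum amino-acid length for the "protein" class;
#'   shorter amino-acid sequences are "peptides".
#' @export
selection_params <- function(blast_identity_min = 85, blast_coverage_min = 70,
                             hh_probability_min = 70, hh_coverage_min = 70,
                             cluster_identity = 0.99, protein_min_len = 30) {
  stopifnot(cluster_identity > 0, cluster_identity <= 1, protein_min_len >= 1)
  structure(list(blast_identity_min = blast_identity_min,
                 blast_coverage_min = blast_coverage_min,
                 hh_probability_min = hh_probability_min,
                 hh_coverage_min = hh_coverage_min,
                 cluster_identity = cluster_identity,
                 peptide_exact_identity = 1.0,
                 protein_min_len = protein_min_len),
            class = "selection_params")
}

#' Target novelty categories
#'
#' The categories assigned by \code{\link{categorize_target}}: a close-homolog
#' full-complex template makes a target NOT_INTERESTING; the remaining
#' multi-entity targets split by remote-template availability, and
#' single-entity targets map to the monomer analogues.
#' @export
TARGET_CATEGORIES <- c("NOT_INTERESTING", "NOVEL_COMPLEX",
                       "REMOTE_COMPLEX_TEMPLATE", "NO_TEMPLATE_ENTITY",
                       "NOVEL_MONOMER", "MONOMER_WITH_REMOTE_TEMPLATE",
                       "TEMPLATE_ONLY_IN_OTHER_COMPLEX")

token_alphabet_types <- function(tokens) {
  # polymer types whose alphabet is consistent with the whole token vector;
  # bracketed noncanonical tokens are treated as consistent with any type
  canon <- tokens[!startsWith(tokens, "(")]
  types <- character()
  if (all(canon %in% AMINO_ALPHABET)) types <- c(types, "amino")
  if (all(canon %in% DNA_ALPHABET)) types <- c(types, "dna")
  if (all(canon %in% RNA_ALPHABET)) types <- c(types, "rna")
  types
}

#' Classify the polymer type of a sequence
#'
#' Amino-acid sequences of \code{protein_min_len} (default 30) residues or
#' longer are "protein", shorter ones "peptide"; nucleic sequences are typed
#' by alphabet or declared type.
#'
#' @param tokens sequence token vector (see \code{\link{tokenize_seq}}).
#' @param declared optional declared type used to disambiguate.
#' @param params \code{\link{selection_params}}.
#' @return one of \code{"protein"}, \code{"peptide"}, \code{"dna"},
#'   \code{"rna"}.
#' @export
classify_entity_type <- function(tokens, declared = NULL,
                                 params = selection_params()) {
  if (!length(tokens)) stop("empty sequence")
  types <- token_alphabet_types(tokens)
  if (!is.null(declared)) {
    cls <- if (declared %in% c("protein", "peptide")) "amino" else declared
    if (!(cls %in% types))
      stop("declared type ", declared, " inconsistent with sequence alphabet")
    types <- cls
  }
  if (!length(types)) stop("sequence alphabet fits no polymer type")
  t1 <- types[1]
  if (t1 == "amino") {
    if (length(tokens) >= params$protein_min_len) "protein" else "peptide"
  } else t1
}

#' Filter entities for target selection
#'
#' Discards entities whose sequence contains unknown-residue tokens (X for
#' amino acids, N for nucleic acids) or whose polymer type cannot be assigned
#' unambiguously from the alphabet and declared type.
#'
#' @param entities list of \code{\link{cam_entity}}.
#' @return list with \code{kept} (entities) and \code{discarded}
#'   (data.frame of entity id and reason).
#' @export
filter_entities <- function(entities) {
  kept <- list()
  disc_id <- character(); disc_reason <- character()
  for (e in entities) {
    nuc <- e$polymer_type %in% c("dna", "rna")
    unknown <- if (nuc) "N" else "X"
    if (any(e$seq == unknown)) {
      disc_id <- c(disc_id, e$id); disc_reason <- c(disc_reason, "unknown_residue")
      next
    }
    types <- token_alphabet_types(e$seq)
    cls <- if (e$polymer_type %in% c("protein", "peptide")) "amino" else e$polymer_type
    if (!(cls %in% types)) {
      disc_id <- c(disc_id, e$id); disc_reason <- c(disc_reason, "ambiguous_type")
      next
    }
    kept[[length(kept) + 1L]] <- e
  }
  list(kept = kept,
       discarded = data.frame(id = disc_id, reason = disc_reason,
                              stringsAsFactors = FALSE))
}

#' Greedy sequence-identity clustering
#'
#' CD-HIT style: sequences are sorted by descending length (ties
#' lexicographic by id) and each joins the first cluster whose representative
#' (the founding, longest member) shares at least the identity threshold —
#' identical aligned positions divided by the length of the shorter sequence.
#' Peptide and nucleic classes cluster on exact string identity.
#'
#' @param entities list of \code{\link{cam_entity}} of one polymer class.
#' @param params \code{\link{selection_params}}.
#' @return data.frame with \code{id}, \code{cluster}, \code{representative}.
#' @export
cluster_sequences <- function(entities, params = selection_params()) {
  if (!length(entities)) return(data.frame(id = character(),
                                           cluster = integer(),
                                           representative = logical()))
  types <- vapply(entities, function(e) e$polymer_type, "")
  if (length(unique(types)) > 1L) stop("entities of one polymer class required")
  exact <- types[1] != "protein"
  lens <- vapply(entities, function(e) length(e$seq), 0L)
  ids <- vapply(entities, function(e) e$id, "")
  ord <- order(-lens, ids, method = "radix")
  reps <- list(); rep_ids <- integer()
  assign <- integer(length(entities))
  for (k in ord) {
    e <- entities[[k]]
    placed <- FALSE
    for (ci in seq_along(reps)) {
      r <- reps[[ci]]
      same <- if (exact) identical(e$seq, r$seq)
              else seq_identity(e$seq, r$seq) >= params$cluster_identity
      if (same) { assign[k] <- ci; placed <- TRUE; break }
    }
    if (!placed) {
      reps[[length(reps) + 1L]] <- e
      assign[k] <- length(reps)
      rep_ids <- c(rep_ids, k)
    }
  }
  data.frame(id = ids, cluster = assign,
             representative = seq_along(entities) %in% rep_ids,
             stringsAsFactors = FALSE)
}

#' Does a homology hit pass the selection thresholds?
#'
#' BLAST hits pass at identity >= 85% and coverage >= 70%; HHblits hits at
#' probability >= 70% and coverage >= 70%; lookup hits require 100% identity.
#' All boundaries inclusive.
#'
#' @param hits data.frame with columns \code{query_entity},
#'   \code{template_structure}, \code{template_chain}, \code{identity},
#'   \code{coverage}, \code{probability}, \code{source}; optionally
#'   \code{release_date}.
#' @param params \code{\link{selection_params}}.
#' @param before optional date string: drop hits whose \code{release_date} is
#'   on or after it (retrospective filtering).
#' @return logical vector, one flag per hit row.
#' @export
pass_hit <- function(hits, params = selection_params(), before = NULL) {
  src <- hits$source
  if (any(!src %in% c("blast", "hhblits", "lookup")))
    stop("unknown hit source: ",
         paste(unique(setdiff(src, c("blast", "hhblits", "lookup"))), collapse = ", "))
  need_id <- src %in% c("blast", "lookup")
  if (any(need_id & is.na(hits$identity)))
    stop("missing identity field for blast/lookup hit")
  if (any(src == "hhblits" & is.na(hits$probability)))
    stop("missing probability field for hhblits hit")
  ok <- rep(FALSE, nrow(hits))
  b <- src == "blast"
  ok[b] <- hits$identity[b] >= params$blast_identity_min &
           hits$coverage[b] >= params$blast_coverage_min
  h <- src == "hhblits"
  ok[h] <- hits$probability[h] >= params$hh_probability_min &
           hits$coverage[h] >= params$hh_coverage_min
  l <- src == "lookup"
  ok[l] <- hits$identity[l] == 100
  if (!is.null(before) && "release_date" %in% names(hits))
    ok <- ok & (is.na(hits$release_date) | hits$release_date < before)
  ok
}

# Maximum bipartite matching by augmenting paths. adj: list over left
# vertices of integer vectors of right neighbors. Returns match_right
# (for each right vertex, its left partner or 0).
bipartite_matching <- function(adj, n_right) {
  match_right <- integer(n_right)
  for (v in seq_along(adj)) {
    visited <- rep(FALSE, n_right)
    augment <- function(v) {
      for (u in adj[[v]]) {
        if (!visited[u]) {
          visited[u] <<- TRUE
          if (match_right[u] == 0L || augment(match_right[u])) {
            match_right[u] <<- v
            return(TRUE)
          }
        }
      }
      FALSE
    }
    augment(v)
  }
  match_right
}

#' Aggregate per-entity hits into full-complex templates
#'
#' A template structure is accepted when a perfect matching exists in the
#' bipartite graph of target chains and template polymer chains (an edge
#' wherever a passing hit links the target chain's entity to the template
#' chain): every target chain must be uniquely mapped and the template must
#' not contain any extra polymer chain.
#'
#' @param target list with \code{chains}: data.frame of \code{chain},
#'   \code{entity} for the target's polymer chains.
#' @param hits data.frame of passing hits (see \code{\link{pass_hit}}).
#' @param compositions data.frame with \code{template_structure},
#'   \code{chain}, \code{polymer_type} describing each candidate template.
#' @return list of complex templates, each a list with
#'   \code{template_structure}, \code{chain_assignment} (named character:
#'   target chain -> template chain) and \code{source}.
#' @export
aggregate_complex_templates <- function(target, hits, compositions) {
  out <- list()
  if (!nrow(hits)) return(out)
  for (src in sort(unique(hits$source))) {
    hs <- hits[hits$source == src, , drop = FALSE]
    for (ts in sort(unique(hs$template_structure))) {
      tchains <- sort(compositions$chain[
        compositions$template_structure == ts &
        compositions$polymer_type != "nonpolymer"])
      ntc <- nrow(target$chains)
      if (length(tchains) != ntc || !ntc) next
      adj <- lapply(seq_len(ntc), function(i) {
        ent <- target$chains$entity[i]
        linked <- hs$template_chain[hs$query_entity == ent &
                                    hs$template_structure == ts]
        which(tchains %in% linked)
      })
      mr <- bipartite_matching(adj, length(tchains))
      if (all(mr > 0L) && length(unique(mr)) == ntc) {
        assignment <- stats::setNames(tchains, target$chains$chain[mr])
        assignment <- assignment[order(names(assignment))]
        out[[length(out) + 1L]] <- list(template_structure = ts,
                                        chain_assignment = assignment,
                                        source = src)
      }
    }
  }
  out
}

#' Categorize a target by template availability
#'
#' A target with a close-homolog (BLAST or lookup) full-complex template is
#' NOT_INTERESTING. Otherwise, multi-entity targets are
#' REMOTE_COMPLEX_TEMPLATE when an HHblits full-complex template exists,
#' NOVEL_COMPLEX when every entity has at least one passing hit but no
#' full-complex template exists, and NO_TEMPLATE_ENTITY when at least one
#' entity has no passing hit at all. Single-entity targets map to the
#' monomer analogues, with TEMPLATE_ONLY_IN_OTHER_COMPLEX when all of the
#' entity's hits occur in templates that contain additional polymer chains.
#'
#' @param target list with \code{chains} (data.frame \code{chain},
#'   \code{entity}) and \code{entities} (character vector of entity ids).
#' @param hits data.frame of hits (filtered by \code{\link{pass_hit}}
#'   internally).
#' @param compositions template composition table (see
#'   \code{\link{aggregate_complex_templates}}).
#' @param params \code{\link{selection_params}}.
#' @return list with \code{category} and supporting detail (templates found
#'   per tier).
#' @export
categorize_target <- function(target, hits, compositions,
                              params = selection_params()) {
  ents <- unique(target$entities)
  if (nrow(hits) && any(!hits$query_entity %in% ents))
    stop("hits reference unknown entities: ",
         paste(setdiff(unique(hits$query_entity), ents), collapse = ", "))
  ok <- if (nrow(hits)) pass_hit(hits, params) else logical(0)
  hp <- hits[ok, , drop = FALSE]
  close_tier <- hp[hp$source %in% c("blast", "lookup"), , drop = FALSE]
  hh_tier <- hp[hp$source == "hhblits", , drop = FALSE]
  blast_tpl <- aggregate_complex_templates(target, close_tier, compositions)
  hh_tpl <- aggregate_complex_templates(target, hh_tier, compositions)
  has_hit <- vapply(ents, function(e) any(hp$query_entity == e), TRUE)

  multi <- length(ents) > 1L || nrow(target$chains) > 1L
  category <- if (length(blast_tpl)) "NOT_INTERESTING"
  else if (multi) {
    if (length(hh_tpl)) "REMOTE_COMPLEX_TEMPLATE"
    else if (all(has_hit)) "NOVEL_COMPLEX"
    else "NO_TEMPLATE_ENTITY"
  } else {
    if (length(hh_tpl)) "MONOMER_WITH_REMOTE_TEMPLATE"
    else if (all(has_hit)) "TEMPLATE_ONLY_IN_OTHER_COMPLEX"
    else "NOVEL_MONOMER"
  }
  list(category = category, blast_templates = blast_tpl,
       hh_templates = hh_tpl, entities_with_hits = has_hit)
}
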