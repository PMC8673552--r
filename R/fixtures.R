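# Deterministic synthetic-fixture generators: parametric helical chains,
# symmetric oligomers, perturbed models, ligands with known automorphism
# groups, homology-hit tables per novelty category, and QE sample sets.
# Every generator is a pure function of its arguments and seed.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

HELIX_RISE <- 1.5      # A per residue
HELIX_TWIST <- 100     # degrees per residue
HELIX_RADIUS <- 2.3    # A

#' Generate a parametric helical chain
#'
#' An idealized alpha-helical trace: Calpha atoms at 1.5 A rise and 100
#' degrees twist per residue on a 2.3 A radius, with N, C, O and Cbeta placed
#' at fixed ideal offsets in the local helix frame. The sequence is drawn
#' uniformly from the 19 non-glycine amino acids (every residue carries a
#' Cbeta).
#'
#' @param n_res number of residues (>= 3).
#' @param seed RNG seed (sequence only; geometry is deterministic).
#' @param chain_id chain identifier.
#' @return single-chain \code{camstruct}.
#' @export
make_chain <- function(n_res, seed = 1, chain_id = "A") {
  if (n_res < 3) stop("n_res must be at least 3")
  aa3 <- setdiff(names(AA3), "GLY")
  seq3 <- with_seed(seed, sample(aa3, n_res, replace = TRUE))
  rows <- vector("list", n_res)
  for (i in seq_len(n_res)) {
    th <- (i - 1) * HELIX_TWIST * pi / 180
    ca <- c(HELIX_RADIUS * cos(th), HELIX_RADIUS * sin(th),
            HELIX_RISE * (i - 1))
    tv <- c(-HELIX_RADIUS * sin(th), HELIX_RADIUS * cos(th), 0) *
          (HELIX_TWIST * pi / 180) + c(0, 0, HELIX_RISE)
    tv <- tv / sqrt(sum(tv^2))
    nv <- c(-cos(th), -sin(th), 0)
    bv <- c(tv[2] * nv[3] - tv[3] * nv[2],
            tv[3] * nv[1] - tv[1] * nv[3],
            tv[1] * nv[2] - tv[2] * nv[1])
    pos <- rbind(N  = ca - 1.2 * tv + 0.5 * nv,
                 CA = ca,
                 C  = ca + 1.2 * tv + 0.5 * nv,
                 O  = ca + 1.2 * tv + 0.5 * nv + 1.2 * bv,
                 CB = ca - 1.6 * nv + 0.4 * bv)
    rows[[i]] <- data.frame(chain = chain_id, resnum = i, icode = "",
                            comp_id = seq3[i], kind = "amino",
                            atom = rownames(pos),
                            element = c("N", "C", "C", "O", "C"),
                            x = pos[, 1], y = pos[, 2], z = pos[, 3],
                            occ = 1, hetero = FALSE, entity_id = "1",
                            stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  ptype <- if (n_res >= 30) "protein" else "peptide"
  cam_structure(atoms,
                list(cam_entity("1", ptype, unname(AA3[seq3]))),
                id = sprintf("helix%d", n_res))
}

rotate_z <- function(xyz, angle) {
  R <- matrix(c(cos(angle), sin(angle), 0,
                -sin(angle), cos(angle), 0,
                0, 0, 1), 3, 3)
  xyz %*% R
}

#' Assemble copies of a chain into an oligomer
#'
#' Cyclic arrangement: each copy is translated to \code{spacing} Angstrom
#' from an external z axis and rotated by 360/copies degrees per copy,
#' guaranteeing inter-chain contacts between neighbors at small spacings.
#' Chains are labeled A, B, C, ... and share one entity.
#'
#' @param chain single-chain \code{camstruct} (e.g. \code{\link{make_chain}}).
#' @param copies number of copies (1 to 26).
#' @param arrangement \code{"cyclic"} or \code{"linear"}.
#' @param spacing radial (cyclic) or translational (linear) spacing, A.
#' @return \code{camstruct} with \code{copies} chains.
#' @export
make_oligomer <- function(chain, copies, arrangement = c("cyclic", "linear"),
                          spacing = 8) {
  arrangement <- match.arg(arrangement)
  stopifnot(copies >= 1, copies <= 26)
  base <- chain$atoms
  if (length(unique(base$chain)) != 1L) stop("chain must have a single chain")
  out <- vector("list", copies)
  for (k in seq_len(copies)) {
    a <- base
    xyz <- as.matrix(a[, c("x", "y", "z")])
    if (arrangement == "cyclic") {
      xyz[, 1] <- xyz[, 1] + spacing
      xyz <- rotate_z(xyz, 2 * pi * (k - 1) / copies)
    } else {
      xyz[, 1] <- xyz[, 1] + spacing * (k - 1)
    }
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    a$chain <- LETTERS[k]
    out[[k]] <- a
  }
  atoms <- do.call(rbind, out)
  rownames(atoms) <- NULL
  cam_structure(atoms, chain$entities,
                id = sprintf("%s_x%d", chain$id, copies))
}

#' Perturb a structure into a model of controllable quality
#'
#' @param s \code{camstruct}.
#' @param sigma Gaussian noise level in Angstrom (jitter mode).
#' @param seed RNG seed.
#' @param mode \code{"jitter"} (iid Gaussian coordinate noise),
#'   \code{"rigid_shift_chain"} (translate one chain rigidly),
#'   \code{"delete_chain"}, or \code{"add_chain"} (duplicate the first chain
#'   under a new label).
#' @param chain chain to shift/delete (default: last chain).
#' @param shift translation vector for rigid_shift_chain/add_chain.
#' @return perturbed \code{camstruct}.
#' @export
perturb <- function(s, sigma = 0.5, seed = 1,
                    mode = c("jitter", "rigid_shift_chain", "delete_chain",
                             "add_chain"),
                    chain = NULL, shift = c(5, 0, 0)) {
  mode <- match.arg(mode)
  a <- s$atoms
  if (is.null(chain)) chain <- utils::tail(cam_chains(s), 1)
  if (mode == "jitter") {
    if (sigma > 0) {
      noise <- with_seed(seed, matrix(stats::rnorm(3 * nrow(a), 0, sigma),
                                      ncol = 3))
      a$x <- a$x + noise[, 1]; a$y <- a$y + noise[, 2]; a$z <- a$z + noise[, 3]
    }
  } else if (mode == "rigid_shift_chain") {
    sel <- a$chain == chain
    if (!any(sel)) stop("no such chain: ", chain)
    a$x[sel] <- a$x[sel] + shift[1]
    a$y[sel] <- a$y[sel] + shift[2]
    a$z[sel] <- a$z[sel] + shift[3]
  } else if (mode == "delete_chain") {
    a <- a[a$chain != chain, , drop = FALSE]
    if (!nrow(a)) stop("delete_chain would empty the structure")
  } else if (mode == "add_chain") {
    first <- a[a$chain == cam_chains(s)[1], , drop = FALSE]
    newc <- setdiff(LETTERS, unique(a$chain))[1]
    if (is.na(newc)) stop("no free chain label")
    first$chain <- newc
    first$x <- first$x + shift[1]
    first$y <- first$y + shift[2]
    first$z <- first$z + shift[3]
    a <- rbind(a, first)
  }
  rownames(a) <- NULL
  cam_structure(a, s$entities, id = paste0(s$id, "_", mode),
                assembly_label = s$assembly_label)
}

#' Generate a ligand with a known automorphism group
#'
#' \describe{
#'   \item{linear}{O-C-O, 2 automorphisms (identity + end swap).}
#'   \item{ring6}{six-membered carbon ring, uniform bond order: 12
#'     (dihedral group).}
#'   \item{tetrahedral}{central carbon with four identical substituents:
#'     24 (all substituent permutations).}
#'   \item{asymmetric}{N-C-C-O chain: identity only.}
#' }
#' Model coordinates start equal to reference coordinates.
#'
#' @param kind ligand kind.
#' @param seed kept for generator-interface uniformity; geometries are fixed
#'   ideal shapes.
#' @return \code{\link{ligand_graph}}.
#' @export
make_ligand <- function(kind = c("linear", "ring6", "tetrahedral",
                                 "asymmetric"), seed = 1) {
  kind <- match.arg(kind)
  if (kind == "linear") {
    el <- c("O", "C", "O")
    xyz <- rbind(c(-1.16, 0, 0), c(0, 0, 0), c(1.16, 0, 0))
    bonds <- data.frame(i = c(1, 2), j = c(2, 3), order = c(2, 2))
  } else if (kind == "ring6") {
    el <- rep("C", 6)
    th <- (0:5) * pi / 3
    xyz <- cbind(1.39 * cos(th), 1.39 * sin(th), 0)
    bonds <- data.frame(i = 1:6, j = c(2:6, 1), order = 1)
  } else if (kind == "tetrahedral") {
    el <- c("C", rep("CL", 4))
    v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
    xyz <- rbind(c(0, 0, 0), 1.77 * v)
    bonds <- data.frame(i = rep(1, 4), j = 2:5, order = 1)
  } else {
    el <- c("N", "C", "C", "O")
    xyz <- rbind(c(0, 0, 0), c(1.47, 0, 0), c(2.1, 1.3, 0), c(3.3, 1.4, 0.4))
    bonds <- data.frame(i = c(1, 2, 3), j = c(2, 3, 4), order = c(1, 1, 1))
  }
  ligand_graph(el, bonds, xyz)
}

#' Generate a synthetic quality-estimation sample set
#'
#' True lDDT drawn from Beta(2,2); the confidence score mixes the truth with
#' uniform noise under weight \code{rho} and is clipped to [0,1]. Regenerates
#' with an incremented seed (bounded retries) until both classes are present
#' at the lDDT threshold.
#'
#' @param n_models number of samples (>= 10).
#' @param rho correlation control in [0,1]: 1 = confidence equals truth,
#'   0 = pure noise.
#' @param seed RNG seed.
#' @param lddt_threshold class boundary used for the both-classes check.
#' @return data.frame with \code{target_id}, \code{model_id}, \code{server},
#'   \code{predicted}, \code{true_lddt}.
#' @export
make_qe_set <- function(n_models, rho, seed = 1, lddt_threshold = 0.6) {
  stopifnot(n_models >= 10, rho >= 0, rho <= 1)
  for (trial in 0:49) {
    df <- with_seed(seed + trial, {
      true <- stats::rbeta(n_models, 2, 2)
      pred <- pmin(1, pmax(0, rho * true + (1 - rho) * stats::runif(n_models)))
      data.frame(target_id = "t1",
                 model_id = sprintf("m%04d", seq_len(n_models)),
                 server = sprintf("s%d", (seq_len(n_models) - 1L) %% 4L + 1L),
                 predicted = pred, true_lddt = true,
                 stringsAsFactors = FALSE)
    })
    pos <- df$true_lddt >= lddt_threshold
    if (any(pos) && !all(pos)) return(df)
  }
  stop("could not generate both classes in 50 attempts")
}

#' Generate a target, hit table and template compositions for a category
#'
#' Closed-loop generator: the returned bundle is constructed so that
#' \code{\link{categorize_target}} assigns the requested category. Decoy
#' hits below the pass thresholds are added at random.
#'
#' @param scenario one of the values in \code{TARGET_CATEGORIES}.
#' @param seed RNG seed (decoy decoration and threshold margins).
#' @return list with \code{target} (chains + entities), \code{hits},
#'   \code{compositions} and \code{scenario}.
#' @export
make_hit_table <- function(scenario = TARGET_CATEGORIES, seed = 1) {
  scenario <- match.arg(scenario)
  with_seed(seed, {
    hit <- function(ent, ts, tc, source,
                    identity = NA, coverage = NA, probability = NA)
      data.frame(query_entity = ent, template_structure = ts,
                 template_chain = tc, identity = identity,
                 coverage = coverage, probability = probability,
                 source = source, stringsAsFactors = FALSE)
    pass_blast <- function(ent, ts, tc)
      hit(ent, ts, tc, "blast", identity = stats::runif(1, 85, 100),
          coverage = stats::runif(1, 70, 100))
    pass_hh <- function(ent, ts, tc)
      hit(ent, ts, tc, "hhblits", coverage = stats::runif(1, 70, 100),
          probability = stats::runif(1, 70, 100))
    fail_hit <- function(ent, ts, tc)
      if (stats::runif(1) < 0.5)
        hit(ent, ts, tc, "blast", identity = stats::runif(1, 10, 84.9),
            coverage = stats::runif(1, 10, 100))
      else
        hit(ent, ts, tc, "hhblits", coverage = stats::runif(1, 10, 69.9),
            probability = stats::runif(1, 10, 100))
    comp <- function(ts, chains)
      data.frame(template_structure = ts, chain = chains,
                 polymer_type = "protein", stringsAsFactors = FALSE)

    monomer <- scenario %in% c("NOVEL_MONOMER", "MONOMER_WITH_REMOTE_TEMPLATE",
                               "TEMPLATE_ONLY_IN_OTHER_COMPLEX")
    if (monomer) {
      target <- list(chains = data.frame(chain = "A", entity = "E1",
                                         stringsAsFactors = FALSE),
                     entities = "E1")
    } else {
      target <- list(chains = data.frame(chain = c("A", "B"),
                                         entity = c("E1", "E2"),
                                         stringsAsFactors = FALSE),
                     entities = c("E1", "E2"))
    }
    hits <- list(); comps <- list()
    if (scenario == "NOT_INTERESTING") {
      hits <- list(pass_blast("E1", "T1", "a"), pass_blast("E2", "T1", "b"))
      comps <- list(comp("T1", c("a", "b")))
    } else if (scenario == "REMOTE_COMPLEX_TEMPLATE") {
      hits <- list(pass_hh("E1", "T1", "a"), pass_hh("E2", "T1", "b"))
      comps <- list(comp("T1", c("a", "b")))
    } else if (scenario == "NOVEL_COMPLEX") {
      hits <- list(pass_hh("E1", "T1", "a"), pass_hh("E2", "T2", "b"))
      comps <- list(comp("T1", "a"), comp("T2", "b"))
    } else if (scenario == "NO_TEMPLATE_ENTITY") {
      hits <- list(pass_hh("E1", "T1", "a"), fail_hit("E2", "T2", "b"))
      comps <- list(comp("T1", "a"), comp("T2", "b"))
    } else if (scenario == "NOVEL_MONOMER") {
      hits <- list(fail_hit("E1", "T1", "a"))
      comps <- list(comp("T1", "a"))
    } else if (scenario == "MONOMER_WITH_REMOTE_TEMPLATE") {
      hits <- list(pass_hh("E1", "T1", "a"))
      comps <- list(comp("T1", "a"))
    } else {                       # TEMPLATE_ONLY_IN_OTHER_COMPLEX
      hits <- list(pass_hh("E1", "T1", "a"))
      comps <- list(comp("T1", c("a", "b")))
    }
    # random decoys that never pass
    n_decoy <- sample(0:3, 1)
    for (d in seq_len(n_decoy))
      hits[[length(hits) + 1L]] <- fail_hit(sample(target$entities, 1),
                                            sprintf("D%d", d), "x")
    hits <- do.call(rbind, hits)
    comps_extra <- lapply(seq_len(n_decoy), function(d) comp(sprintf("D%d", d), "x"))
    comps <- do.call(rbind, c(comps, comps_extra))
    list(target = target, hits = hits, compositions = comps,
         scenario = scenario)
  })
}
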