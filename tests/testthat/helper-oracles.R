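# Independent brute-force oracles used to verify the package implementations
# on small inputs, plus fixture builders shared across test files. Oracles
# deliberately share no code with the implementations they check.

# Brute-force lDDT: double loop over all reference atom pairs; residue
# correspondence by identical (chain, resnum, icode, atom name).
oracle_lddt <- function(model, ref, radius = 15,
                        thresholds = c(0.5, 1, 2, 4),
                        extra_model_contacts = 0L) {
  ra <- ref$atoms; ma <- model$atoms
  mk <- paste(ma$chain, ma$resnum, ma$icode, ma$atom)
  preserved <- rep(0L, length(thresholds))
  total <- 0L
  n <- nrow(ra)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    same_res <- ra$chain[i] == ra$chain[j] && ra$resnum[i] == ra$resnum[j] &&
                ra$icode[i] == ra$icode[j]
    if (same_res) next
    dr <- sqrt(sum((ra[i, c("x", "y", "z")] - ra[j, c("x", "y", "z")])^2))
    if (dr > radius) next
    total <- total + 1L
    mi <- match(paste(ra$chain[i], ra$resnum[i], ra$icode[i], ra$atom[i]), mk)
    mj <- match(paste(ra$chain[j], ra$resnum[j], ra$icode[j], ra$atom[j]), mk)
    if (is.na(mi) || is.na(mj)) next
    dm <- sqrt(sum((ma[mi, c("x", "y", "z")] - ma[mj, c("x", "y", "z")])^2))
    dev <- abs(dm - dr)
    for (t in seq_along(thresholds))
      if (dev < thresholds[t]) preserved[t] <- preserved[t] + 1L
  }
  if (total + extra_model_contacts == 0L) return(NA_real_)
  mean(preserved / (total + extra_model_contacts))
}

# All permutations of 1..n (n <= 8), in lexicographic order.
oracle_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- oracle_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# Brute-force automorphisms: filter all n! permutations on element labels and
# the full bond-order matrix.
oracle_autos <- function(elements, bonds, n = length(elements)) {
  B <- matrix(0, n, n)
  for (k in seq_len(nrow(bonds))) {
    B[bonds$i[k], bonds$j[k]] <- bonds$order[k]
    B[bonds$j[k], bonds$i[k]] <- bonds$order[k]
  }
  perms <- oracle_perms(n)
  keep <- apply(perms, 1L, function(p)
    all(elements[p] == elements) && all(B[p, p] == B))
  perms[keep, , drop = FALSE]
}

# Tie-corrected Mann-Whitney AUC via midranks.
oracle_mw_auc <- function(predicted, positive) {
  r <- rank(predicted)
  n_pos <- sum(positive); n_neg <- sum(!positive)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Independent recursive Needleman-Wunsch (memoized) returning the optimal
# global alignment score for match +1 / mismatch -1 / gap -2.
oracle_nw_score <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  f <- function(i, j) {
    if (i == 0L) return(-2 * j)
    if (j == 0L) return(-2 * i)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- max(f(i - 1L, j - 1L) + if (a[i] == b[j]) 1 else -1,
             f(i - 1L, j) - 2, f(i, j - 1L) - 2)
    memo[[key]] <- v
    v
  }
  f(length(a), length(b))
}

# Brute-force minimum RMSD over proper rotations (grid + local refinement).
oracle_min_rmsd <- function(xs, ys) {
  xc <- sweep(xs, 2, colMeans(xs)); yc <- sweep(ys, 2, colMeans(ys))
  rot <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) sqrt(mean(rowSums((xc %*% rot(ang) - yc)^2)))
  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  best <- Inf; best_ang <- c(0, 0, 0)
  for (a1 in grid) for (a2 in grid) for (a3 in grid) {
    v <- obj(c(a1, a2, a3))
    if (v < best) { best <- v; best_ang <- c(a1, a2, a3) }
  }
  stats::optim(best_ang, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 5000))$value
}

# Random proper rotation matrix.
random_rotation <- function() {
  M <- matrix(stats::rnorm(9), 3)
  qr_ <- qr(M)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Random small single-chain structure (<= max_atoms heavy atoms) for oracle
# equivalence tests; residues of 1-3 atoms with arbitrary names.
random_small_structure <- function(seed, max_atoms = 30) {
  set.seed(seed)
  n_res <- sample(3:8, 1)
  rows <- list()
  for (r in seq_len(n_res)) {
    n_at <- sample(1:3, 1)
    center <- runif(3, 0, 12)
    for (k in seq_len(n_at)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chain = "A", resnum = r, icode = "", comp_id = "ALA", kind = "amino",
        atom = paste0("X", k), element = "C",
        x = center[1] + rnorm(1), y = center[2] + rnorm(1),
        z = center[3] + rnorm(1), occ = 1, hetero = FALSE, entity_id = "1",
        stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, rows)[seq_len(min(max_atoms, length(rows))), ,
                                drop = FALSE]
  cam_structure(atoms, list(cam_entity("1", "peptide",
                                       rep("A", length(unique(atoms$resnum))))),
                id = paste0("rand", seed))
}

# Three 1-atom residues with prescribed pairwise distances d12, d23, d13
# (must satisfy the triangle inequality).
three_atom_structure <- function(d12, d23, d13, id = "toy3") {
  x3 <- (d13^2 - d23^2 + d12^2) / (2 * d12)
  y3 <- sqrt(max(0, d13^2 - x3^2))
  atoms <- data.frame(
    chain = "A", resnum = 1:3, icode = "", comp_id = "GLY", kind = "amino",
    atom = "CA", element = "C",
    x = c(0, d12, x3), y = c(0, 0, y3), z = 0,
    occ = 1, hetero = FALSE, entity_id = "1", stringsAsFactors = FALSE)
  cam_structure(atoms, list(cam_entity("1", "peptide", rep("G", 3))), id = id)
}

# Dimer of 1-atom residues at controlled inter-chain distances: residue k of
# chain A sits at (0, 40k, 0) and its partner in chain B at (d_k, 40k, 0),
# so only intended pairs fall within the QS contact cutoff.
station_dimer <- function(dists, id = "stations") {
  n <- length(dists)
  mk <- function(chain, xs) data.frame(
    chain = chain, resnum = seq_len(n), icode = "", comp_id = "ALA",
    kind = "amino", atom = "CA", element = "C",
    x = xs, y = 40 * seq_len(n), z = 0, occ = 1, hetero = FALSE,
    entity_id = "1", stringsAsFactors = FALSE)
  atoms <- rbind(mk("A", rep(0, n)), mk("B", dists))
  cam_structure(atoms, list(cam_entity("1", "peptide", rep("A", n))), id = id)
}

# Relabel the chains of a structure according to a named map old -> new.
relabel_chains <- function(s, map) {
  a <- s$atoms
  a$chain <- unname(map[a$chain])
  a <- a[order(match(a$chain, sort(unique(a$chain)))), , drop = FALSE]
  rownames(a) <- NULL
  cam_structure(a, s$entities, id = s$id, assembly_label = s$assembly_label)
}
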