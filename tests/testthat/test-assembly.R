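# QS-score, chain mapping enumeration, oligo-lDDT and best-score selection.

test_that("contact weight follows the piecewise-linear form", {
  expect_equal(contact_weight(3.0), 1.0)
  expect_equal(contact_weight(12.0), 0.0)
  expect_equal(contact_weight(8.5), (12 - 8.5) / 7)
  expect_equal(contact_weight(c(0, 5, 13)), c(1, 1, 0))
  expect_error(contact_weight(-1), "negative")
})

test_that("interface contacts match a brute-force cross-chain loop", {
  dimer <- make_oligomer(make_chain(10, seed = 3), 2)
  con <- interface_contacts(dimer)
  rt <- rep_atom_table(dimer)
  cnt <- 0L
  for (i in 1:(nrow(rt) - 1)) for (j in (i + 1):nrow(rt)) {
    if (rt$chain[i] == rt$chain[j]) next
    d <- sqrt(sum((rt[i, c("x", "y", "z")] - rt[j, c("x", "y", "z")])^2))
    if (d <= 12) cnt <- cnt + 1L
  }
  expect_equal(nrow(con), cnt)
  expect_gt(cnt, 0L)
  # two far-apart chains: no contacts; 6 A apart: one contact
  far <- station_dimer(40)
  expect_equal(nrow(interface_contacts(far)), 0L)
  near <- station_dimer(6)
  con2 <- interface_contacts(near)
  expect_equal(nrow(con2), 1L)
  expect_equal(con2$d, 6)
})

test_that("representative atoms follow the Cb/Ca/C1' rule", {
  helix <- make_chain(5, seed = 1)
  rt <- rep_atom_table(helix)
  cb <- helix$atoms[helix$atoms$atom == "CB", ]
  expect_equal(rt$x, cb$x)
  gly <- helix
  gly$atoms <- gly$atoms[!(gly$atoms$resnum == 2 & gly$atoms$atom == "CB"), ]
  gly$atoms$comp_id[gly$atoms$resnum == 2] <- "GLY"
  gly <- cam_structure(gly$atoms, gly$entities, "gly")
  rt2 <- rep_atom_table(gly)
  ca2 <- gly$atoms[gly$atoms$resnum == 2 & gly$atoms$atom == "CA", ]
  expect_equal(rt2$x[2], ca2$x)
})

test_that("QS-score: identity, hand-enumerated toy, and model/ref symmetry", {
  dimer <- make_oligomer(make_chain(12, seed = 5), 2)
  idmap <- chain_mapping(c(A = "A", B = "B"), dimer, dimer)
  expect_equal(qs_score(dimer, dimer, idmap)$global, 1.0)

  # shared contacts min {1, 0.5, 1}, max {1, 1, 1}; one model-only (w 0.5),
  # one ref-only (w 1): 2.5 / 4.5
  ref <- station_dimer(c(4, 4, 4, 4, 20), id = "ref")
  mod <- station_dimer(c(4.5, 8.5, 3, 20, 8.5), id = "mod")
  qs <- qs_score(mod, ref, chain_mapping(c(A = "A", B = "B"), mod, ref))
  expect_equal(qs$global, 2.5 / 4.5)

  # symmetry under swapping model and reference
  qs_rev <- qs_score(ref, mod, chain_mapping(c(A = "A", B = "B"), ref, mod))
  expect_equal(qs_rev$global, qs$global)

  trimer <- make_oligomer(make_chain(12, seed = 5), 3)
  noisy <- perturb(trimer, sigma = 0.4, seed = 2)
  mp <- chain_mapping(c(A = "A", B = "B", C = "C"), noisy, trimer)
  expect_equal(qs_score(noisy, trimer, mp)$global,
               qs_score(trimer, noisy, mp)$global, tolerance = 1e-12)
})

test_that("a fully missing interface halves the QS of an otherwise perfect model", {
  # reference: chain A contacts B and C in two equal-weight interfaces;
  # model reproduces A-B exactly but moves C away
  # chain A spans two stations 40 A apart; B binds at station 1, C at
  # station 2, so A-B and A-C are the only interfaces (equal weight 1)
  mk3 <- function(cx) {
    row <- function(chain, resnum, x, y)
      data.frame(chain = chain, resnum = resnum, icode = "", comp_id = "ALA",
                 kind = "amino", atom = "CA", element = "C", x = x, y = y,
                 z = 0, occ = 1, hetero = FALSE, entity_id = "1")
    atoms <- rbind(row("A", 1, 0, 0), row("A", 2, 0, 40),
                   row("B", 1, 4, 0), row("C", 1, cx, 40))
    cam_structure(atoms, list(cam_entity("1", "peptide", "A")), "t")
  }
  ref <- mk3(4); mod <- mk3(400)
  mp <- chain_mapping(c(A = "A", B = "B", C = "C"), mod, ref)
  expect_equal(qs_score(mod, ref, mp)$global, 0.5)
})

test_that("mapping enumeration counts match analytic factorial products", {
  trimer <- make_oligomer(make_chain(10, seed = 1), 3)
  m3 <- enumerate_mappings(trimer, trimer)
  expect_equal(length(m3), 6L)
  expect_equal(attr(m3, "method"), "exhaustive")

  dimer <- make_oligomer(make_chain(10, seed = 1), 2)
  m1 <- enumerate_mappings(dimer, dimer)
  expect_equal(length(m1), 2L)

  # hetero-dimer: exactly one mapping
  a <- make_chain(10, seed = 1)
  b <- make_chain(10, seed = 50, chain_id = "B")
  ba <- b$atoms; ba$x <- ba$x + 9; ba$entity_id <- "2"
  het <- cam_structure(rbind(a$atoms, ba),
                       c(a$entities, list(cam_entity("2", "peptide",
                           unname(AA3[ba$comp_id[ba$atom == "CA"]])))),
                       "het")
  expect_equal(length(enumerate_mappings(het, het)), 1L)

  # A2B vs A2B: 2! * 1! = 2
  a2 <- a$atoms; a2$chain <- "C"; a2$x <- a2$x - 9
  a2b <- cam_structure(rbind(a$atoms, ba, a2), het$entities, "a2b")
  maps <- enumerate_mappings(a2b, a2b)
  expect_equal(length(maps), 2L)
  # brute-force oracle: all injective chain bijections that are
  # entity-consistent
  ents <- c(A = "1", B = "2", C = "1")
  perms <- oracle_perms(3)
  ok <- apply(perms, 1, function(p)
    all(ents == ents[p]))
  expect_equal(sum(ok), 2L)

  # homo-tetramer: 4! = 24
  tet <- make_oligomer(make_chain(10, seed = 1), 4)
  expect_equal(length(enumerate_mappings(tet, tet)), 24L)
  # incompatible entities: no mapping
  expect_error(enumerate_mappings(a, cam_structure(ba,
    list(cam_entity("2", "peptide", unname(AA3[ba$comp_id[ba$atom == "CA"]]))),
    "b")), "no mapping possible")
})

test_that("the greedy fallback engages beyond the cap and recovers identity", {
  tet <- make_oligomer(make_chain(10, seed = 2), 4)
  maps <- enumerate_mappings(tet, tet, cap = 10)
  expect_equal(attr(maps, "method"), "greedy")
  expect_equal(length(maps), 1L)
  mp <- maps[[1]]$pairs
  # a greedy mapping of a C4-symmetric self-comparison must be one of the
  # four rotations; verify it scores 1
  expect_equal(qs_score(tet, tet, maps[[1]])$global, 1.0)
  expect_equal(length(mp), 4L)
})

test_that("oligo-lDDT reduces to lDDT for one mapped pair and penalizes extras", {
  dimer <- make_oligomer(make_chain(12, seed = 7), 2)
  mono <- perturb(dimer, mode = "delete_chain", chain = "B")
  noisy <- perturb(mono, sigma = 0.6, seed = 3)

  # single mapped pair, no unmapped chains on either side
  mp1 <- chain_mapping(c(A = "A"), noisy, mono)
  expect_equal(oligo_lddt(noisy, mono, mp1)$global_score,
               lddt(noisy, mono, chain_map = c(A = "A"))$global_score)

  # identity on the full dimer
  mp2 <- chain_mapping(c(A = "A", B = "B"), dimer, dimer)
  expect_equal(oligo_lddt(dimer, dimer, mp2)$global_score, 1.0)

  # extra contacting model chain strictly decreases the score
  extra <- perturb(dimer, mode = "add_chain", shift = c(0, 9, 0))
  mp3 <- chain_mapping(c(A = "A", B = "B"), extra, dimer)
  expect_lt(oligo_lddt(extra, dimer, mp3)$global_score, 1.0)
  # ... but not when the extra chain has no contacts counted
  lonely <- perturb(dimer, mode = "add_chain", shift = c(500, 0, 0))
  mp4 <- chain_mapping(c(A = "A", B = "B"), lonely, dimer)
  expect_lt(oligo_lddt(lonely, dimer, mp4)$global_score, 1.0)  # intra counted
  expect_equal(oligo_lddt(lonely, dimer, mp4,
                          extra_chain_mode = "inter")$global_score, 1.0)

  # missing chain: perfect dimer model of a trimer reference vs oracle
  trimer <- make_oligomer(make_chain(12, seed = 7), 3)
  dimer_model <- perturb(trimer, mode = "delete_chain", chain = "C")
  mp5 <- chain_mapping(c(A = "A", B = "B"), dimer_model, trimer)
  got <- oligo_lddt(dimer_model, trimer, mp5)$global_score
  expect_equal(got, oracle_lddt(dimer_model, trimer))
  expect_lt(got, 1.0)
})

test_that("best_score equals explicit enumeration over assemblies and mappings", {
  chain <- make_chain(12, seed = 9)
  assemblies <- lapply(2:4, function(k) {
    s <- make_oligomer(chain, k)
    s$assembly_label <- as.character(k)
    s
  })
  model <- perturb(make_oligomer(chain, 3), sigma = 0.5, seed = 11)

  rep_ <- best_score(model, assemblies)

  # explicit enumeration oracle
  best_qs <- -Inf; best_ol <- -Inf
  for (ref in assemblies) {
    for (mp in enumerate_mappings(model, ref)) {
      q <- try(qs_score(model, ref, mp)$global, silent = TRUE)
      o <- try(oligo_lddt(model, ref, mp)$global_score, silent = TRUE)
      if (!inherits(q, "try-error")) best_qs <- max(best_qs, q)
      if (!inherits(o, "try-error")) best_ol <- max(best_ol, o)
    }
  }
  expect_equal(rep_$qs_score, best_qs)
  expect_equal(rep_$oligo_lddt, best_ol)
  expect_equal(rep_$winning$oligo_lddt$assembly, "3")
  expect_equal(rep_$winning$qs$assembly, "3")

  # model matching one assembly exactly wins with score 1
  exact <- make_oligomer(chain, 4)
  rep2 <- best_score(exact, assemblies)
  expect_equal(rep2$oligo_lddt, 1.0)
  expect_equal(rep2$winning$oligo_lddt$assembly, "4")

  # single-chain model vs multi-copy reference: one mapping per ref chain,
  # best one kept
  mono <- perturb(make_oligomer(chain, 1), sigma = 0.3, seed = 13)
  rep3 <- best_score(mono, assemblies[[1]], scores = "oligo_lddt")
  expect_equal(rep3$n_candidates, 2L)
})

test_that("noisy cyclic tetramer mapping lands in the planted symmetry class", {
  ref <- make_oligomer(make_chain(12, seed = 15), 4)
  rot <- c(A = "B", B = "C", C = "D", D = "A")   # C4 rotation generator
  cyc <- list(c(A = "A", B = "B", C = "C", D = "D"), rot,
              stats::setNames(rot[rot], names(rot)),
              stats::setNames(rot[rot[rot]], names(rot)))
  hits <- 0L
  n_rep <- 30L
  for (r in seq_len(n_rep)) {
    set.seed(1000 + r)
    planted <- sample(c("A", "B", "C", "D"))
    names(planted) <- c("A", "B", "C", "D")      # ref chain -> model label
    model <- relabel_chains(perturb(ref, sigma = 0.2, seed = r), planted)
    win <- best_score(model, ref, scores = "qs")$winning$qs$mapping$pairs
    # expected model->ref map is the inverse of `planted`, up to C4 rotation
    inv <- stats::setNames(names(planted), planted)
    ok <- any(vapply(cyc, function(cc)
      identical(unname(cc[inv[names(win)]]), unname(win)), TRUE))
    hits <- hits + ok
  }
  expect_gte(hits, ceiling(0.95 * n_rep))
})
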