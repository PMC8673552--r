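test_that("PDB fixture round-trips and formats agree", {
  s <- make_chain(12, seed = 7)
  tp <- withr::local_tempfile(fileext = ".pdb")
  tc <- withr::local_tempfile(fileext = ".cif")
  write_structure(s, tp, "pdb")
  write_structure(s, tc, "mmcif")
  sp <- read_structure(tp)
  sc <- read_structure(tc)
  expect_equal(nrow(sp$atoms), nrow(s$atoms))
  expect_equal(cam_chains(sp), cam_chains(s))
  expect_equal(sp$atoms$resnum, s$atoms$resnum)
  expect_lt(max(abs(sp$atoms$x - s$atoms$x)), 1e-3)
  expect_lt(max(abs(sp$atoms$z - s$atoms$z)), 1e-3)
  # mmCIF read equals PDB read
  expect_equal(sc$atoms$chain, sp$atoms$chain)
  expect_equal(sc$atoms$atom, sp$atoms$atom)
  expect_equal(sc$atoms$x, sp$atoms$x)
  expect_equal(sc$atoms$y, sp$atoms$y)
  expect_equal(sc$atoms$z, sp$atoms$z)
})

test_that("PDB writer agrees with an independent reader", {
  skip_if_not_installed("bio3d")
  s <- make_chain(10, seed = 3)
  tp <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, tp, "pdb")
  b <- bio3d::read.pdb(tp)
  expect_equal(nrow(b$atom), nrow(s$atoms))
  expect_equal(b$atom$x, round(s$atoms$x, 3))
  expect_equal(b$atom$resno, s$atoms$resnum)
  expect_equal(unique(b$atom$chain), "A")
})

test_that("minimal hand-written PDB parses with stated filtering rules", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.460   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA AGLY A   2       3.000   1.000   0.000  0.60  0.00           C",
    "ATOM      4  CA BGLY A   2       9.000   9.000   0.000  0.40  0.00           C",
    "ATOM      5  CA  SER A   3       5.000   2.000   0.000  1.00  0.00           C",
    "ATOM      6  H   SER A   3       5.500   2.000   0.000  1.00  0.00           H",
    "HETATM    7  O   HOH A   9       8.000   8.000   8.000  1.00  0.00           O")
  tp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, tp)
  s <- read_structure(tp)
  expect_equal(length(cam_chains(s)), 1L)
  expect_equal(nrow(residue_table(s)), 3L)           # waters dropped
  expect_false(any(s$atoms$element == "H"))          # hydrogens dropped
  # alt-loc: highest occupancy (A, occ 0.6) wins
  alt <- s$atoms[s$atoms$resnum == 2, ]
  expect_equal(nrow(alt), 1L)
  expect_equal(alt$x, 3.0)
})

test_that("PDB dialect limits are enforced and mmCIF accepts them", {
  s <- make_chain(5)
  s$atoms$chain <- "AB"
  s2 <- cam_structure(s$atoms, s$entities, id = "wide")
  expect_error(write_structure(s2, tempfile(), "pdb"), "mmcif|mmCIF")
  tc <- withr::local_tempfile(fileext = ".cif")
  expect_silent(write_structure(s2, tc, "mmcif"))
  back <- read_structure(tc)
  expect_equal(cam_chains(back), "AB")
})

test_that("entity inference groups identical chains", {
  dimer <- make_oligomer(make_chain(8, seed = 1), 2)
  other <- make_chain(8, seed = 99, chain_id = "C")
  oa <- other$atoms
  oa$x <- oa$x + 30
  atoms <- rbind(dimer$atoms, oa)      # A,B share a sequence; C differs
  mixed <- cam_structure(atoms, dimer$entities, id = "mixed")
  tp <- withr::local_tempfile(fileext = ".pdb")
  write_structure(mixed, tp, "pdb")    # PDB carries no entity records
  s <- read_structure(tp)
  expect_equal(chain_entity(s, "A"), chain_entity(s, "B"))
  expect_false(chain_entity(s, "C") == chain_entity(s, "A"))
})

test_that("extended FASTA grammar tokenizes and round-trips", {
  expect_equal(tokenize_seq("AC(MLZ)G"), c("A", "C", "(MLZ)", "G"))
  expect_error(tokenize_seq("AC(MLZG"), "offset 2")
  expect_error(tokenize_seq("ACM)G"), "unbalanced")
  set.seed(42)
  for (i in 1:20) {
    toks <- c(sample(LETTERS[1:20], 5, replace = TRUE),
              sprintf("(%s)", paste0(sample(LETTERS, 3), collapse = "")))
    toks <- sample(toks)
    expect_equal(tokenize_seq(detokenize_seq(toks)), toks)
  }
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">e1 type=protein", "AC(MLZ)G"), tf)
  ents <- read_fasta_ext(tf)
  expect_equal(ents[[1]]$id, "e1")
  expect_equal(ents[[1]]$seq, c("A", "C", "(MLZ)", "G"))
  writeLines(c(">e2 type=protein", ""), tf)
  expect_error(read_fasta_ext(tf), "empty sequence")
})

test_that("residue alignment prefers author numbering, falls back to sequence", {
  ref <- make_chain(10, seed = 5)
  al <- align_residues(ref, ref)
  expect_equal(al$method, "by_number")
  expect_equal(nrow(al$pairs), 10L)
  # model missing residues 5-7
  mod <- ref
  mod$atoms <- mod$atoms[!(mod$atoms$resnum %in% 5:7), ]
  mod <- cam_structure(mod$atoms, mod$entities, "gap")
  expect_equal(nrow(align_residues(mod, ref)$pairs), 7L)
  # renumbered +100, identical sequence: full-length via sequence alignment
  ren <- ref
  ren$atoms$resnum <- ren$atoms$resnum + 100L
  ren <- cam_structure(ren$atoms, ren$entities, "ren")
  al2 <- align_residues(ren, ref)
  expect_equal(al2$method, "by_sequence")
  expect_equal(nrow(al2$pairs), 10L)
})

test_that("alignment scores match an exhaustive NW oracle and are symmetric", {
  set.seed(11)
  for (i in 1:10) {
    a <- sample(c("A", "C", "G", "W"), sample(4:8, 1), replace = TRUE)
    b <- sample(c("A", "C", "G", "W"), sample(4:8, 1), replace = TRUE)
    al <- nw_align(a, b)
    sc <- sum(ifelse(a[al[, "a"]] == b[al[, "b"]], 1, -1)) -
          2 * (length(a) - nrow(al)) - 2 * (length(b) - nrow(al))
    expect_equal(sc, oracle_nw_score(a, b))
    expect_equal(nrow(nw_align(b, a)), nrow(al))
  }
})

test_that("Kabsch superposition recovers exact and noisy transforms", {
  set.seed(21)
  xs <- matrix(rnorm(15), ncol = 3)
  id <- superpose_kabsch(xs, xs)
  expect_equal(id$rmsd, 0, tolerance = 1e-10)
  expect_equal(id$rotation, diag(3), tolerance = 1e-8)
  R <- random_rotation(); tr <- c(3, -2, 5)
  ys <- sweep(xs %*% R, 2, tr, "+")
  fit <- superpose_kabsch(xs, ys)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
  # 4-point jittered toy vs grid/numeric minimization oracle
  x4 <- matrix(c(0, 0, 0, 1.5, 0, 0, 0, 1.5, 0, 0.4, 0.4, 1.2),
               ncol = 3, byrow = TRUE)
  y4 <- x4 + matrix(c(0.05, -0.1, 0.08, 0.02, 0.1, -0.06,
                      -0.04, 0.03, 0.1, 0.06, -0.08, 0.02),
                    ncol = 3, byrow = TRUE)
  expect_equal(superpose_kabsch(x4, y4)$rmsd, oracle_min_rmsd(x4, y4),
               tolerance = 1e-3)
  expect_error(superpose_kabsch(xs[1:2, ], xs[1:2, ]), "3 points")
  # invariance under a shared rigid transform
  R2 <- random_rotation()
  expect_equal(superpose_kabsch(x4 %*% R2, y4 %*% R2)$rmsd,
               superpose_kabsch(x4, y4)$rmsd, tolerance = 1e-9)
})
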