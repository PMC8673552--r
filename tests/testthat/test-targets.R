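# Entity filtering/typing, clustering, hit thresholds, template aggregation
# and novelty categorization.

test_that("entity type classification honors the 30-residue boundary", {
  aa30 <- rep("L", 30); aa29 <- rep("L", 29)
  expect_equal(classify_entity_type(aa30), "protein")
  expect_equal(classify_entity_type(aa29), "peptide")
  expect_equal(classify_entity_type(strsplit("ACGU", "")[[1]]), "rna")
  expect_error(classify_entity_type(character()), "empty")
})

test_that("entity filtering discards unknown residues and ambiguous types", {
  e_ok <- cam_entity("e1", "dna", strsplit("ACGT", "")[[1]])
  e_x <- cam_entity("e2", "protein", c(rep("L", 20), "X"))
  e_amb <- cam_entity("e3", "protein", strsplit("ACGU", "")[[1]])
  e_prot <- cam_entity("e4", "protein", strsplit("MKVLAWHE", "")[[1]])
  flt <- filter_entities(list(e_ok, e_x, e_amb, e_prot))
  kept <- vapply(flt$kept, function(e) e$id, "")
  expect_setequal(kept, c("e1", "e4"))
  expect_equal(flt$discarded$reason[flt$discarded$id == "e2"],
               "unknown_residue")
  expect_equal(flt$discarded$reason[flt$discarded$id == "e3"],
               "ambiguous_type")
  # nucleic unknown token is N
  e_n <- cam_entity("e5", "rna", c("A", "C", "N"))
  expect_equal(filter_entities(list(e_n))$discarded$reason, "unknown_residue")
})

test_that("greedy clustering follows the identity-over-shorter rule", {
  mk <- function(id, seq, type = "protein")
    cam_entity(id, type, strsplit(seq, "")[[1]])
  base <- paste(rep(c("M", "K", "V", "L", "A"), 20), collapse = "")  # 100-mer
  twosub <- base
  substr(twosub, 3, 3) <- "W"; substr(twosub, 50, 50) <- "W"         # 98%
  cl <- cluster_sequences(list(mk("a", base), mk("b", base),
                               mk("c", twosub)))
  expect_equal(cl$cluster[cl$id == "a"], cl$cluster[cl$id == "b"])
  expect_false(cl$cluster[cl$id == "c"] == cl$cluster[cl$id == "a"])
  # at a 0.98 threshold the two-substitution copy joins
  cl2 <- cluster_sequences(list(mk("a", base), mk("c", twosub)),
                           selection_params(cluster_identity = 0.98))
  expect_equal(length(unique(cl2$cluster)), 1L)
  # representative is the founding (longest) member
  expect_true(cl$representative[cl$id == "a"])

  # peptides need exact identity
  pep <- cluster_sequences(list(mk("p1", "AAAA", "peptide"),
                                mk("p2", "AAAB", "peptide")))
  expect_equal(length(unique(pep$cluster)), 2L)
  # re-clustering representatives is idempotent
  reps <- list(mk("a", base), mk("c", twosub))
  cl3 <- cluster_sequences(reps)
  expect_true(all(cl3$representative))
})

test_that("hit thresholds are inclusive at the stated boundaries", {
  h <- data.frame(query_entity = "E1", template_structure = "T",
                  template_chain = "a",
                  identity = c(85, 84.9, NA, NA, 100, 99.9),
                  coverage = c(70, 90, 70, 69.9, 100, 100),
                  probability = c(NA, NA, 70, 70, NA, NA),
                  source = c("blast", "blast", "hhblits", "hhblits",
                             "lookup", "lookup"),
                  stringsAsFactors = FALSE)
  expect_equal(pass_hit(h), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  bad <- h[1, ]; bad$identity <- NA
  expect_error(pass_hit(bad), "identity")
  # raising any threshold never increases the number of passing hits
  set.seed(3)
  rnd <- data.frame(query_entity = "E1", template_structure = "T",
                    template_chain = "a",
                    identity = runif(200, 0, 100),
                    coverage = runif(200, 0, 100),
                    probability = runif(200, 0, 100),
                    source = sample(c("blast", "hhblits"), 200, TRUE),
                    stringsAsFactors = FALSE)
  base_n <- sum(pass_hit(rnd))
  for (arg in c("blast_identity_min", "blast_coverage_min",
                "hh_probability_min", "hh_coverage_min")) {
    p <- selection_params()
    p[[arg]] <- p[[arg]] + 10
    expect_lte(sum(pass_hit(rnd, p)), base_n)
  }
})

test_that("complex-template aggregation requires a perfect chain matching", {
  target <- list(chains = data.frame(chain = c("A", "B", "C"),
                                     entity = c("E1", "E1", "E2"),
                                     stringsAsFactors = FALSE),
                 entities = c("E1", "E2"))
  hit <- function(ent, ts, tc)
    data.frame(query_entity = ent, template_structure = ts,
               template_chain = tc, identity = 95, coverage = 90,
               probability = NA, source = "blast", stringsAsFactors = FALSE)
  comps <- data.frame(template_structure = c("T1", "T1", "T1",
                                             "T2", "T2",
                                             "T3", "T3", "T3", "T3"),
                      chain = c("a1", "a2", "b", "a1", "b",
                                "a1", "a2", "b", "c"),
                      polymer_type = "protein", stringsAsFactors = FALSE)
  hits <- rbind(hit("E1", "T1", "a1"), hit("E1", "T1", "a2"),
                hit("E2", "T1", "b"),
                hit("E1", "T2", "a1"), hit("E2", "T2", "b"),
                hit("E1", "T3", "a1"), hit("E1", "T3", "a2"),
                hit("E2", "T3", "b"))
  out <- aggregate_complex_templates(target, hits, comps)
  # T1 matches; T2 lacks one A-chain; T3 has an extra polymer chain c
  expect_equal(length(out), 1L)
  expect_equal(out[[1]]$template_structure, "T1")
  expect_setequal(names(out[[1]]$chain_assignment), c("A", "B", "C"))
  expect_equal(unname(out[[1]]$chain_assignment[c("A", "B")][order(
    out[[1]]$chain_assignment[c("A", "B")])]), c("a1", "a2"))

  # brute-force bijection oracle on the 3-chain target
  linked <- function(tch, tpl_ch)
    any(hits$template_structure == "T1" & hits$template_chain == tpl_ch &
        hits$query_entity == target$chains$entity[target$chains$chain == tch])
  tpl_chains <- c("a1", "a2", "b")
  found <- FALSE
  for (p in asplit(oracle_perms(3), 1))
    found <- found || all(mapply(linked, target$chains$chain, tpl_chains[p]))
  expect_true(found)
})

test_that("every generated scenario is categorized as constructed", {
  for (sc in TARGET_CATEGORIES) {
    b <- make_hit_table(sc, seed = 42)
    got <- categorize_target(b$target, b$hits, b$compositions)
    expect_equal(got$category, sc, info = sc)
  }
  # unknown entity in hits is an error
  b <- make_hit_table("NOT_INTERESTING", 1)
  bad <- b$hits; bad$query_entity[1] <- "EZZZ"
  expect_error(categorize_target(b$target, bad, b$compositions), "unknown")
})

test_that("categories partition randomized hit tables", {
  set.seed(99)
  n <- 300L
  for (k in seq_len(n)) {
    sc <- sample(TARGET_CATEGORIES, 1)
    b <- make_hit_table(sc, seed = k)
    got <- categorize_target(b$target, b$hits, b$compositions)$category
    expect_equal(got, sc, info = paste(sc, k))
    expect_true(got %in% TARGET_CATEGORIES)
  }
})
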