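test_that("residue templates enforce the declared formal charge", {
  tpl <- toy_templates()
  expect_equal(sum(tpl$cysteine$atoms$charge), 0, tolerance = 1e-9)
  expect_equal(sum(tpl$cystine$atoms$charge), 0, tolerance = 1e-9)
  bad <- tpl$cysteine$atoms
  bad$charge[1] <- bad$charge[1] + 0.5
  expect_error(residue_template("CYS", bad, formal_charge = 0),
               "formal charge")
})

test_that("the hybrid residue adds exactly the dummy atom and two virtual sites", {
  tpl <- toy_templates()
  hyb <- build_hybrid_residue(tpl$cystine, tpl$cysteine)
  expect_equal(nrow(hyb$atoms), nrow(tpl$cysteine$atoms) + 2L)
  expect_setequal(hyb$atoms$name[hyb$atoms$kind != "real"],
                  c("HUD", "VC", "VS"))
  vs <- hyb$atoms[hyb$atoms$kind == "vsite", ]
  expect_setequal(vs$anchor, c("CB", "SG"))
})

test_that("end-state projections reproduce the templates field-for-field", {
  tpl <- toy_templates()
  hyb <- build_hybrid_residue(tpl$cystine, tpl$cysteine)
  pA <- project_state(hyb, "A")
  pB <- project_state(hyb, "B")
  expect_equal(pA$atoms, tpl$cystine$atoms)
  expect_equal(pA$bonds, tpl$cystine$bonds)
  expect_equal(pA$angles, tpl$cystine$angles)
  expect_equal(pA$dihedrals, tpl$cystine$dihedrals)
  expect_equal(pB$atoms, tpl$cysteine$atoms)
  expect_equal(pB$bonds, tpl$cysteine$bonds)
  expect_equal(pB$angles, tpl$cysteine$angles)
  expect_equal(pB$dihedrals, tpl$cysteine$dihedrals)
  # B-state charge sum equals the cysteine total charge
  expect_lt(abs(sum(pB$atoms$charge) - tpl$cysteine$formal_charge), 1e-6)
})

test_that("template mismatches yield a structured error listing differences", {
  tpl <- toy_templates()
  odd <- tpl$cystine
  odd$atoms$name[odd$atoms$name == "CB"] <- "CG"
  odd$bonds[] <- lapply(odd$bonds, function(x) ifelse(x == "CB", "CG", x))
  odd$angles[] <- lapply(odd$angles, function(x) ifelse(x == "CB", "CG", x))
  odd$dihedrals[] <- lapply(odd$dihedrals, function(x) ifelse(x == "CB", "CG", x))
  expect_error(build_hybrid_residue(odd, tpl$cysteine), "CG")
})

test_that("cross terms carry the S1-S2 bond, both CB-S-S angles, A-state only", {
  tpl <- toy_templates()
  hyb <- build_hybrid_residue(tpl$cystine, tpl$cysteine)
  ct <- pair_cross_terms(hyb, hyb)
  expect_equal(nrow(ct$bond), 1L)
  expect_equal(nrow(ct$angles), 2L)
  expect_equal(ct$state, "A")
  expect_equal(sort(c(ct$bond$ai, ct$bond$aj)), c("1:SG", "2:SG"))
  expect_error(pair_cross_terms(hyb, tpl$cysteine), "CYD")
})

test_that("cross dihedrals match brute-force 4-atom path enumeration", {
  tpl <- toy_templates()
  hyb <- build_hybrid_residue(tpl$cystine, tpl$cysteine)
  ct <- pair_cross_terms(hyb, hyb)
  # assemble the qualified A-state bond graph of the pair
  qual <- function(df, i) data.frame(ai = paste0(i, ":", df$ai),
                                     aj = paste0(i, ":", df$aj),
                                     stringsAsFactors = FALSE)
  edges <- rbind(qual(hyb$bonded_A$bonds, 1), qual(hyb$bonded_A$bonds, 2),
                 data.frame(ai = "1:SG", aj = "2:SG"))
  paths <- brute_dihedral_paths(edges, "1:SG", "2:SG")
  got <- lapply(seq_len(nrow(ct$dihedrals)), function(k) {
    unlist(ct$dihedrals[k, ], use.names = FALSE)
  })
  key <- function(p) paste(p, collapse = "-")
  expect_setequal(vapply(got, key, character(1)),
                  vapply(paths, key, character(1)))
})

test_that("perturbed topology writer/reader round trip is the identity", {
  tpl <- toy_templates()
  hyb <- build_hybrid_residue(tpl$cystine, tpl$cysteine)
  ct <- pair_cross_terms(hyb, hyb)
  f <- withr::local_tempfile(fileext = ".itp")
  write_perturbed_topology(list(hyb, hyb), list(ct), f)
  back <- read_perturbed_topology(f)
  expect_length(back$residues, 2L)
  expect_equal(back$residues[[1]], hyb)
  expect_equal(back$residues[[2]], hyb)
  expect_equal(back$cross[[1]], ct)
  # B-only terms (thiol bond via HUD) are flagged B, absent from state A
  txt <- readLines(f)
  expect_true(any(grepl("^SG HUD B$", txt)))
  expect_true(any(grepl("^CB SG AB$", txt)))
})

test_that("the emitted topology is stable against the golden fixture", {
  tpl <- toy_templates()
  hyb <- build_hybrid_residue(tpl$cystine, tpl$cysteine)
  ct <- pair_cross_terms(hyb, hyb)
  f <- withr::local_tempfile(fileext = ".itp")
  write_perturbed_topology(list(hyb, hyb), list(ct), f)
  expect_identical(readLines(f), readLines(test_path("golden_cyd_pair.itp")))
})

test_that("state-equivalence validation passes correct hybrids and counts injected faults", {
  tpl <- toy_templates()
  hyb <- build_hybrid_residue(tpl$cystine, tpl$cysteine)
  rep <- validate_state_equivalence(hyb, tpl$cystine, tpl$cysteine)
  expect_true(all(rep$pass))

  # single fault: HUD given charge in state A
  bad1 <- hyb
  bad1$atoms$chargeA[bad1$atoms$name == "HUD"] <- 0.1
  r1 <- validate_state_equivalence(bad1, tpl$cystine, tpl$cysteine)
  expect_false(r1$pass[r1$check == "dummy_neutral_in_A"])
  expect_equal(sum(!r1$pass), 1L)

  # three independent faults touch three distinct checks
  bad3 <- hyb
  bad3$atoms$chargeA[bad3$atoms$name == "HUD"] <- 0.1
  bad3$atoms$typeB[bad3$atoms$name == "CA"] <- "CT9"
  bad3$atoms$chargeB[bad3$atoms$name == "VC"] <- 0.05
  r3 <- validate_state_equivalence(bad3, tpl$cystine, tpl$cysteine)
  expect_equal(sum(!r3$pass), 3L)
})

test_that("template files read back into equal structures", {
  fx <- toy_fixtures()
  tpl <- read_residue_template(fx$cysteine)
  expect_equal(tpl$name, "CYS")
  expect_equal(nrow(tpl$atoms), 6L)
  expect_equal(nrow(tpl$bonds), 5L)
  expect_error(read_residue_template(tempfile()), "not found")
})
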