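# Generators: manifest fidelity, determinism, defect injection.

test_that("the toy manifest exactly describes the emitted model", {
  toy <- make_toy_diazotroph()
  s <- summarize_model(toy$model)
  expect_equal(s$n_reactions, toy$manifest$n_reactions)
  expect_equal(s$n_metabolites, toy$manifest$n_metabolites)
  expect_equal(s$n_genes, toy$manifest$n_genes)
  expect_setequal(names(toy$model$compartments), toy$manifest$compartments)
  expect_equal(toy$model$objective, toy$manifest$objective)
  # every declared carbon source grows, every decoy does not
  res <- run_screen(toy$model,
                    lapply(c(toy$manifest$carbon_sources,
                             toy$manifest$decoy_sources),
                           function(s) screen_condition(s, "carbon")))
  grew <- stats::setNames(res$grew, res$source)
  expect_true(all(grew[toy$manifest$carbon_sources]))
  expect_false(any(grew[toy$manifest$decoy_sources]))
  # nitrogen sources support growth on pyruvate
  resn <- run_screen(toy$model,
                     lapply(toy$manifest$nitrogen_sources,
                            function(s) screen_condition(s, "nitrogen")))
  expect_true(all(resn$grew))
})

test_that("generators are byte-identical under a fixed seed", {
  d1 <- tempfile(); d2 <- tempfile()
  t1 <- make_toy_diazotroph(seed = 7); t2 <- make_toy_diazotroph(seed = 7)
  f1 <- file.path(tempdir(), "t1.json"); f2 <- file.path(tempdir(), "t2.json")
  write_model(t1$model, f1); write_model(t2$model, f2)
  expect_identical(readLines(f1), readLines(f2))
  p1 <- make_plate(t1, 12, 8, "carbon", seed = 3, dir = d1)
  p2 <- make_plate(t1, 12, 8, "carbon", seed = 3, dir = d2)
  expect_identical(readLines(p1$plate_path), readLines(p2$plate_path))
  expect_identical(readLines(p1$calls_path), readLines(p2$calls_path))
  pr1 <- make_proteome(c(G = 1), 5, 50, seed = 2)
  pr2 <- make_proteome(c(G = 1), 5, 50, seed = 2)
  expect_identical(pr1$sequences, pr2$sequences)
  h1 <- make_homology_table(seed = 4); h2 <- make_homology_table(seed = 4)
  expect_identical(h1$hits, h2$hits)
  # a different seed reshuffles the plate
  p3 <- make_plate(t1, 12, 8, "carbon", seed = 4)
  expect_false(identical(p1$plate$source_metabolite_id,
                         p3$plate$source_metabolite_id))
  unlink(c(f1, f2, d1, d2), recursive = TRUE)
})

test_that("each injected defect trips exactly its intended check", {
  clean <- make_toy_diazotroph()
  clean_bal <- element_balance(clean$model)
  clean_de <- classify_dead_ends(clean$model)$metabolite
  for (d in c("unbalanced", "atp_cycle", "orphan_met")) {
    td <- make_toy_diazotroph(defects = d)
    expect_equal(td$manifest$defects$defect, d)
    bal <- element_balance(td$model)
    unbal <- bal$table$reaction_id[!bal$table$balanced]
    atp <- energy_cycle_check(td$model, "atp")
    nadh <- energy_cycle_check(td$model, "nadh")
    nadph <- energy_cycle_check(td$model, "nadph")
    new_dead <- setdiff(classify_dead_ends(td$model)$metabolite, clean_de)
    if (d == "unbalanced") {
      expect_equal(unbal, td$manifest$defects$reaction)
      expect_true(atp$pass && nadh$pass && nadph$pass)
      expect_length(new_dead, 0)
    } else if (d == "atp_cycle") {
      expect_length(unbal, 0)
      expect_false(atp$pass)
      expect_true(td$manifest$defects$reaction %in% atp$cycle_reactions)
      expect_true(nadh$pass && nadph$pass)
      expect_length(new_dead, 0)
    } else {
      expect_length(unbal, 0)
      expect_true(atp$pass && nadh$pass && nadph$pass)
      expect_equal(new_dead, "orphan__X_c")
    }
  }
  # the clean model passes the whole panel
  expect_true(all(clean_bal$table$balanced))
  expect_true(qc_suite(clean$model)$pass)
  expect_error(make_toy_diazotroph(defects = "nope"), "unknown defects")
})

test_that("plates honour their grower counts at the extremes", {
  toy <- make_toy_diazotroph()
  all_neg <- make_plate(toy, 5, 0, "carbon", seed = 1)
  expect_equal(sum(all_neg$calls$grew), 0)
  all_pos <- make_plate(toy, 5, 5, "carbon", seed = 1)
  expect_equal(sum(all_pos$calls$grew), 5)
  res <- run_screen(toy$model,
                    lapply(all_pos$plate$source_metabolite_id,
                           function(s) screen_condition(s, "carbon")))
  expect_true(all(res$grew))
  expect_error(make_plate(toy, 30, 20, "carbon"), "connectable")
})

test_that("proteome and homology generators match their sidecars", {
  pr <- make_proteome(c(G = 1), n_proteins = 3, mean_length = 40, seed = 1,
                      path = tempfile(fileext = ".faa"))
  expect_true(all(grepl("^G+$", pr$sequences)))
  # FASTA read back through the standard parser
  f <- aa_frequencies(pr$path)
  expect_equal(unname(f["G"]), 1)
  # uniform composition recovered within sampling error at 1e4 residues
  comp <- stats::setNames(rep(1 / 20, 20), names(aa_residue_masses))
  pru <- make_proteome(comp, n_proteins = 50, mean_length = 200, seed = 9)
  n_res <- sum(nchar(pru$sequences))
  se <- sqrt((1 / 20) * (19 / 20) / n_res)
  expect_true(all(abs(pru$realized_composition - 1 / 20) < 4 * se))
  # homology sidecar equals the filter output, order-invariantly
  tab <- make_homology_table(n_hits = 32, seed = 6,
                             path = tempfile(fileext = ".tsv"))
  hits <- read_homology_hits(tab$path)
  expect_setequal(filter_hits(hits)$qseqid, tab$expected_accepted)
  shuffled <- hits[rev(seq_len(nrow(hits))), ]
  expect_setequal(filter_hits(shuffled)$qseqid, tab$expected_accepted)
  # the exact-boundary row is present and accepted
  boundary <- hits[hits$pident == 40 & hits$evalue == 1e-4 & hits$qcovs == 85, ]
  expect_equal(nrow(boundary), 1)
  expect_true(boundary$qseqid %in% tab$expected_accepted)
  unlink(c(pr$path, tab$path))
})
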