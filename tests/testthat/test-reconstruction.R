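# Curation: hit filtering, GPR remapping, exogenous pruning, dead ends,
# gap-filling.

test_that("hit filtering applies all three thresholds inclusively", {
  h <- data.frame(qseqid = sprintf("q%d", 1:5), sseqid = sprintf("s%d", 1:5),
                  pident = c(45.0, 40.0, 39.9, 60, 60),
                  evalue = c(1e-10, 1e-4, 1e-10, 1e-2, 1e-10),
                  qcovs = c(90, 85, 99, 99, 84), stringsAsFactors = FALSE)
  acc <- filter_hits(h)
  expect_setequal(acc$qseqid, c("q1", "q2"))  # boundary row q2 accepted
  # each criterion alone rejects
  expect_false("q3" %in% acc$qseqid)  # identity fails
  expect_false("q4" %in% acc$qseqid)  # e-value fails
  expect_false("q5" %in% acc$qseqid)  # coverage fails
})

test_that("filtering is monotone in every threshold", {
  tab <- make_homology_table(n_hits = 40, seed = 11)
  base <- nrow(filter_hits(tab$hits))
  expect_gte(nrow(filter_hits(tab$hits, min_identity = 30)), base)
  expect_gte(nrow(filter_hits(tab$hits, max_evalue = 1e-2)), base)
  expect_gte(nrow(filter_hits(tab$hits, min_coverage = 70)), base)
  # and tightening never grows the set
  expect_lte(nrow(filter_hits(tab$hits, min_identity = 60)), base)
})

test_that("best-hit selection is deterministic under the tie rules", {
  h <- data.frame(qseqid = "t1", sseqid = c("gB", "gA", "gC"),
                  pident = c(80, 80, 90), evalue = c(1e-20, 1e-20, 1e-10),
                  qcovs = 95, stringsAsFactors = FALSE)
  # lowest e-value first; among gA/gB ties on identity, lexicographic
  expect_equal(unname(best_hit_mapping(h)), "gA")
})

test_that("GPR remapping renames, simplifies and flags exogenous-only", {
  mapping <- c(tA = "gA", tB = "gB")
  # full complex mapped
  r1 <- remap_gpr(parse_gpr("tA and tB"), mapping)
  expect_true(gpr_equal(r1$gpr, parse_gpr("gA and gB")))
  # OR drops the unmapped leaf
  r2 <- remap_gpr(parse_gpr("tA or tX"), mapping)
  expect_true(gpr_equal(r2$gpr, gpr_gene("gA")))
  # strict policy never asserts a complex with a missing subunit:
  # exhaustive truth table over mapped subsets of a two-gene AND
  for (mapped in list(character(), "tA", "tB", c("tA", "tB"))) {
    mp <- mapping[mapped]
    res <- remap_gpr(parse_gpr("tA and tB"), mp, policy = "strict")
    if (length(mapped) < 2) {
      expect_null(res$gpr)
      expect_true(res$exogenous_only)
    } else {
      expect_false(res$exogenous_only)
    }
  }
  # permissive keeps the mapped subunit
  rp <- remap_gpr(parse_gpr("tA and tB"), mapping["tA"], "permissive")
  expect_true(gpr_equal(rp$gpr, gpr_gene("gA")))
  # empty input stays empty and is not flagged
  r0 <- remap_gpr(NULL, mapping)
  expect_null(r0$gpr); expect_false(r0$exogenous_only)
})

test_that("pruning removes only flux-dead exogenous reactions", {
  t3 <- toy3_model()
  mets <- rbind(t3$metabolites,
                data.frame(id = "X_c", name = "X", formula = "C", charge = 0,
                           compartment = "c", stringsAsFactors = FALSE))
  m <- metabolic_model(
    "prune", mets,
    c(t3$reactions,
      list(reaction("DEADX", c(A_c = -1, X_c = 1), lb = 0,
                    exogenous_only = TRUE),
           reaction("NATORPH", c(X_c = -1, A_c = 1), lb = 0,
                    provenance = "orphan"))),
    objective = "BIO", compartments = t3$compartments)
  cond <- medium_spec(EX_A = c(-10, 1000))
  before <- fba(m, medium = cond)$objective_value
  res <- prune_exogenous(m, list(cond))
  # DEADX and NATORPH form a futile A<->X loop, so neither is blocked;
  # nothing is removed and optima are intact
  expect_length(res$removed, 0)
  # break the loop: now DEADX is exogenous-only AND blocked -> removed;
  # the native orphan (also blocked) is conserved
  m2 <- remove_reactions(m, "NATORPH")
  m2 <- add_reaction(m2, reaction("NATDEAD", c(A_c = -1, X_c = 1), lb = 0,
                                  provenance = "orphan"))
  res2 <- prune_exogenous(m2, list(cond))
  expect_equal(res2$removed, "DEADX")
  expect_true("NATDEAD" %in% names(res2$model$reactions))
  expect_equal(fba(res2$model, medium = cond)$objective_value, before,
               tolerance = 1e-6)
  # an exogenous-only reaction carrying flux under any condition is kept
  m3 <- m2
  m3$reactions$R1$exogenous_only <- TRUE   # R1 carries all growth flux
  res3 <- prune_exogenous(m3, list(cond))
  expect_false("R1" %in% res3$removed)
})

test_that("dead-end classes match a brute-force incidence scan", {
  set.seed(42)
  for (k in 1:50) {
    n_m <- sample(4:10, 1); n_r <- sample(3:8, 1)
    ids <- sprintf("m%02d_c", seq_len(n_m))
    mets <- data.frame(id = ids, name = ids, formula = "C", charge = 0,
                       compartment = "c", stringsAsFactors = FALSE)
    rxns <- lapply(seq_len(n_r), function(j) {
      k_m <- sample(2:min(4, n_m), 1)
      who <- sample(ids, k_m)
      sto <- stats::setNames(sample(c(-2, -1, 1, 2), k_m, replace = TRUE), who)
      if (all(sto > 0)) sto[1] <- -sto[1]
      rev <- runif(1) < 0.4
      reaction(sprintf("r%02d", j), sto, lb = if (rev) -1000 else 0)
    })
    m <- metabolic_model("rand", mets, rxns,
                         compartments = c(c = "cytoplasm"), validate = FALSE)
    got <- classify_dead_ends(m)
    # oracle: raw incidence scan with reversibility expansion
    for (met in ids) {
      prod <- FALSE; cons <- FALSE; n_in <- 0
      for (r in rxns) if (met %in% names(r$stoich)) {
        n_in <- n_in + 1
        s <- r$stoich[[met]]
        if (s > 0 || r$lb < 0) prod <- TRUE
        if (s < 0 || r$lb < 0) cons <- TRUE
      }
      expected <- if (n_in == 0) "disconnected"
        else if (prod && !cons) "produced-only"
        else if (cons && !prod) "consumed-only" else NA
      hit <- got$class[got$metabolite == met]
      if (is.na(expected)) expect_length(hit, 0)
      else expect_equal(hit, expected, label = paste(k, met))
    }
  }
})

test_that("single-reversible-reaction metabolites are flagged, not dead", {
  mets <- data.frame(id = c("A_c", "X_c"), name = "m", formula = "C",
                     charge = 0, compartment = "c", stringsAsFactors = FALSE)
  m <- metabolic_model("sr", mets,
                       list(reaction("RREV", c(A_c = -1, X_c = 1),
                                     lb = -1000),
                            reaction("EX_A_pseudo", c(A_c = -1), lb = -10)),
                       compartments = c(c = "cytoplasm"))
  de <- classify_dead_ends(m)
  expect_false("X_c" %in% de$metabolite)
  expect_true("X_c" %in% attr(de, "single_reaction"))
  # declared but unused metabolite is disconnected
  mets2 <- rbind(mets, data.frame(id = "Z_c", name = "m", formula = "C",
                                  charge = 0, compartment = "c",
                                  stringsAsFactors = FALSE))
  m2 <- metabolic_model("sr2", mets2, m$reactions,
                        compartments = c(c = "cytoplasm"))
  de2 <- classify_dead_ends(m2)
  expect_equal(de2$class[de2$metabolite == "Z_c"], "disconnected")
})

test_that("gap-filling returns the brute-force minimal set", {
  t3 <- toy3_model()
  broken <- remove_reactions(t3, "R1")
  pool_mets <- rbind(t3$metabolites,
                     data.frame(id = "Q_c", name = "Q", formula = "C",
                                charge = 0, compartment = "c",
                                stringsAsFactors = FALSE))
  pool <- metabolic_model(
    "pool", pool_mets,
    list(reaction("FIX_R1", c(A_c = -1, B_c = 1), lb = 0),
         reaction("IRRELEVANT", c(A_c = -1, Q_c = 1), lb = 0),
         # a two-step alternative, strictly larger than the one-step fix
         reaction("ALT1", c(A_c = -1, Q_c = 1), lb = 0),
         reaction("ALT2", c(Q_c = -1, B_c = 1), lb = 0)),
    compartments = t3$compartments, validate = FALSE)
  sol <- gapfill(broken, pool, target = "BIO")
  expect_equal(sol$status, "filled")
  expect_equal(sol$added, "FIX_R1")
  expect_gt(sol$objective, 0.001)
  # brute-force oracle: smallest subset (lexicographic among equal size)
  subsets <- unlist(lapply(1:4, function(k)
    utils::combn(sort(names(pool$reactions)), k, simplify = FALSE)),
    recursive = FALSE)
  works <- function(sel) {
    m <- broken
    for (rid in sel) {
      r <- pool$reactions[[rid]]
      nm <- pool$metabolites[pool$metabolites$id %in%
        setdiff(names(r$stoich), m$metabolites$id), , drop = FALSE]
      m <- add_reaction(m, r, new_metabolites = nm)
    }
    f <- fba(m, "BIO")
    f$status == "optimal" && f$objective_value > 0.001
  }
  first <- Filter(works, subsets)[[1]]
  expect_equal(sol$added, first)
  # minimality by deletion: dropping any chosen reaction kills growth
  for (rid in sol$added) expect_false(works(setdiff(sol$added, rid)))
  # already-growing model needs nothing
  sol0 <- gapfill(t3, pool, target = "BIO")
  expect_equal(sol0$status, "already-growing")
  expect_length(sol0$added, 0)
  # interchangeable candidates resolve lexicographically
  pool2 <- metabolic_model(
    "pool2", t3$metabolites,
    list(reaction("R1b", c(A_c = -1, B_c = 1), lb = 0),
         reaction("R1a", c(A_c = -1, B_c = 1), lb = 0)),
    compartments = t3$compartments, validate = FALSE)
  expect_equal(gapfill(broken, pool2, target = "BIO")$added, "R1a")
  # unfillable pools say so and point at the dead ends
  pool3 <- metabolic_model(
    "pool3", pool_mets,
    list(reaction("NOPE", c(A_c = -1, Q_c = 1), lb = 0)),
    compartments = t3$compartments, validate = FALSE)
  sol3 <- gapfill(broken, pool3, target = "BIO")
  expect_equal(sol3$status, "unfillable")
  expect_true("B_c" %in% sol3$dead_ends$metabolite)
})
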