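test_that("the elimination table reproduces the published inference chain", {
  # full evidence isolates the dimer-of-protomers architecture
  full <- consistent_models(stoich_evidence("multiple", "multiple", "dimer"))
  expect_identical(full$model, "D")

  # no multiplicity anywhere leaves only the minimal complex
  minimal <- consistent_models(stoich_evidence("single", "single", "monomer"))
  expect_identical(minimal$model, "A")

  # multiple micropeptides but single-copy partners leave the two
  # multi-micropeptide monomer models
  expect_identical(
    consistent_models(stoich_evidence("multiple", "single", "monomer"))$model,
    c("B", "C")
  )

  # individual elimination sentences
  expect_false("A" %in% consistent_models(stoich_evidence(plm_multiplicity = "multiple"))$model)
  expect_identical(
    consistent_models(stoich_evidence(beta_multiplicity = "multiple"))$model,
    c("D", "E")
  )
  expect_identical(
    consistent_models(stoich_evidence(alpha_assembly = "dimer"))$model,
    "D"
  )
  expect_identical(
    consistent_models(stoich_evidence(alpha_assembly = "higher_order"))$model,
    "E"
  )
})

test_that("no evidence keeps all models; contradictions give an empty set", {
  all_m <- consistent_models(stoich_evidence())
  expect_identical(all_m$model, c("A", "B", "C", "D", "E"))

  none <- consistent_models(stoich_evidence("unknown", "multiple", "monomer"))
  expect_identical(nrow(none), 0L)
  expect_no_error(print(none))
})

test_that("adding evidence never enlarges the consistent set", {
  plm_vals <- c("single", "multiple", "unknown")
  beta_vals <- c("single", "multiple", "unknown")
  alpha_vals <- c("monomer", "dimer", "higher_order", "unknown")
  for (p in plm_vals) {
    for (b in beta_vals) {
      for (a in alpha_vals) {
        base <- consistent_models(stoich_evidence(p, b, a))$model
        # specialize each unknown field in turn
        if (p == "unknown") {
          for (p2 in setdiff(plm_vals, "unknown")) {
            refined <- consistent_models(stoich_evidence(p2, b, a))$model
            expect_true(all(refined %in% base))
          }
        }
        if (b == "unknown") {
          for (b2 in setdiff(beta_vals, "unknown")) {
            refined <- consistent_models(stoich_evidence(p, b2, a))$model
            expect_true(all(refined %in% base))
          }
        }
        if (a == "unknown") {
          for (a2 in setdiff(alpha_vals, "unknown")) {
            refined <- consistent_models(stoich_evidence(p, b, a2))$model
            expect_true(all(refined %in% base))
          }
        }
      }
    }
  }
})

test_that("the pipeline recovers the generating architecture end to end", {
  cfg_d <- pipeline_config("model_d",
    seed = 7, n_cells = 300L,
    n_decay_records = 4L, photons_per_decay = 1e5
  )
  rep_d <- suppressWarnings(run_pipeline(cfg_d))
  expect_identical(rep_d$consistent_models, "D")
  expect_identical(rep_d$evidence$alpha_assembly, "dimer")
  expect_equal(rep_d$decay$shared_lifetimes[2:3], c(1.8, 0.8), tolerance = 0.15)

  cfg_a <- pipeline_config("model_a",
    seed = 8, n_cells = 300L,
    n_decay_records = 4L, photons_per_decay = 1e5
  )
  rep_a <- suppressWarnings(run_pipeline(cfg_a))
  expect_identical(rep_a$consistent_models, "A")
  expect_identical(rep_a$evidence$alpha_assembly, "monomer")
})

test_that("pipeline recovery is reliable across seeded replicates", {
  hits <- vapply(seq_len(10), function(i) {
    cfg <- pipeline_config("model_d",
      seed = 100 + i, n_cells = 300L,
      n_decay_records = 3L, photons_per_decay = 5e4
    )
    rep <- suppressWarnings(run_pipeline(cfg))
    identical(rep$consistent_models, "D")
  }, NA)
  expect_gte(mean(hits), 0.9)
})

test_that("identical configurations give byte-identical reports", {
  cfg <- pipeline_config("model_d",
    seed = 3, n_cells = 120L,
    n_decay_records = 2L, photons_per_decay = 5e4
  )
  r1 <- suppressWarnings(run_pipeline(cfg))
  r2 <- suppressWarnings(run_pipeline(cfg))
  p1 <- tempfile(fileext = ".json")
  p2 <- tempfile(fileext = ".json")
  write_pipeline_report(r1, p1)
  write_pipeline_report(r2, p2)
  expect_identical(readLines(p1), readLines(p2))

  # stage logging is available without perturbing the report
  lf <- tempfile(fileext = ".log")
  r3 <- suppressWarnings(run_pipeline(cfg, log_file = lf))
  expect_true(any(grepl("model_elimination", readLines(lf))))
  p3 <- tempfile(fileext = ".json")
  write_pipeline_report(r3, p3)
  expect_identical(readLines(p1), readLines(p3))
})
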