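build_fixture_inputs <- function(dir, name = "planted") {
  sim <- sim_fixture(name)
  write_cohort(sim$cohort, dir)
  sim
}

test_that("run_build produces a complete, round-trippable, deterministic artifact set", {
  dir <- withr::local_tempdir()
  sim <- build_fixture_inputs(dir)
  out1 <- file.path(dir, "out1"); out2 <- file.path(dir, "out2")
  res <- run_build(file.path(dir, "measurements.csv"),
                   file.path(dir, "outcomes.csv"),
                   treatments = file.path(dir, "treatments.csv"),
                   rules = sim$rules, out_dir = out1)
  for (f in c("map.json", "map.dot", "nodes.csv", "bifurcations.csv",
              "evaluation.csv", "assignments.csv", "config.json", "map.pdf"))
    expect_true(file.exists(file.path(out1, f)), label = f)

  # JSON round-trip reconstructs an equal map
  back <- read_map(file.path(out1, "map.json"))
  expect_identical(map_nodes_df(back), map_nodes_df(res$map))
  expect_identical(back$root$split_feature, res$map$root$split_feature)
  expect_identical(back$slice_counts, res$map$slice_counts)
  expect_identical(lapply(back$nodes, `[[`, "members"),
                   lapply(res$map$nodes, `[[`, "members"))

  # identical inputs give byte-identical canonical output
  run_build(file.path(dir, "measurements.csv"), file.path(dir, "outcomes.csv"),
            treatments = file.path(dir, "treatments.csv"),
            rules = sim$rules, out_dir = out2)
  expect_identical(unname(tools::md5sum(file.path(out1, "map.json"))),
                   unname(tools::md5sum(file.path(out2, "map.json"))))

  # a changed configuration changes the embedded hash
  res_alt <- run_build(file.path(dir, "measurements.csv"),
                       file.path(dir, "outcomes.csv"), rules = sim$rules,
                       epv = 20)
  expect_false(identical(res$config_hash, res_alt$config_hash))
})

test_that("comparator stage labels are evaluated and compared per slice", {
  dir <- withr::local_tempdir()
  sim <- build_fixture_inputs(dir)
  # a deliberately shuffled comparator: should not beat the map
  set.seed(1)
  ids <- sim$cohort$outcomes$patient_id
  stages <- do.call(rbind, lapply(1:3, function(ts)
    data.frame(patient_id = ids, slice = ts, system = "shuffled",
               stage = sample(1:4, length(ids), replace = TRUE))))
  res <- run_build(file.path(dir, "measurements.csv"),
                   file.path(dir, "outcomes.csv"), stages = stages,
                   rules = sim$rules)
  ev <- res$evaluation
  sh <- ev[ev$system == "shuffled", ]
  expect_gt(nrow(sh), 0)
  expect_true(all(sh$verdict %in% c("map_superior", "no_difference")))
  mp <- ev[ev$system == "survival_path" & ev$slice == 1, ]
  expect_gt(mp$c_index, 0.5)
})

test_that("assignment from serialized artifacts is self-consistent and guarded", {
  dir <- withr::local_tempdir()
  sim <- build_fixture_inputs(dir)
  out <- file.path(dir, "out")
  res <- run_build(file.path(dir, "measurements.csv"),
                   file.path(dir, "outcomes.csv"), rules = sim$rules,
                   out_dir = out)
  traj <- run_assign(file.path(out, "map.json"),
                     file.path(dir, "measurements.csv"),
                     file.path(dir, "outcomes.csv"), rules = sim$rules,
                     out_csv = file.path(dir, "traj.csv"))
  expect_true(file.exists(file.path(dir, "traj.csv")))
  expect_identical(traj[traj$status == "complete", ],
                   res$assignments[res$assignments$status == "complete", ])

  # empty patient set: empty report, no error
  empty_m <- file.path(dir, "empty_m.csv"); empty_o <- file.path(dir, "empty_o.csv")
  write.csv(sim$cohort$measurements[0, ], empty_m, row.names = FALSE)
  write.csv(sim$cohort$outcomes[0, ], empty_o, row.names = FALSE)
  tr0 <- run_assign(file.path(out, "map.json"), empty_m, empty_o,
                    rules = sim$rules)
  expect_identical(nrow(tr0), 0L)

  # an incompatible rule set is a named mismatch error
  expect_error(run_assign(file.path(out, "map.json"),
                          file.path(dir, "measurements.csv"),
                          file.path(dir, "outcomes.csv"),
                          rules = binary_rules(paste0("f", 1:8))),
               "rule-set mismatch")
})

test_that("the map plot draws one polyline per path with a defined median", {
  dir <- withr::local_tempdir()
  sim <- build_fixture_inputs(dir)
  res <- run_build(file.path(dir, "measurements.csv"),
                   file.path(dir, "outcomes.csv"), rules = sim$rules)
  pdf(NULL)
  on.exit(dev.off())
  drawn <- plot(res$map)
  df <- map_nodes_df(res$map)
  expect_setequal(unique(drawn$p),
                  unique(df$p[!df$excluded & !is.na(df$median_os)]))
})

test_that("the command-line shell runs the simulate and build subcommands", {
  cli <- system.file("cli", "survmap", package = "survmap")
  skip_if(cli == "", "CLI script not installed")
  rscript <- file.path(R.home("bin"), "Rscript")
  dir <- withr::local_tempdir()
  sim_dir <- file.path(dir, "cohort"); out_dir <- file.path(dir, "out")
  s1 <- system2(rscript, c(cli, "simulate", "--n", "80", "--seed", "4",
                           "--out", sim_dir), stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(sim_dir, "measurements.csv")))
  s2 <- system2(rscript, c(cli, "build",
                           "--measurements", file.path(sim_dir, "measurements.csv"),
                           "--outcomes", file.path(sim_dir, "outcomes.csv"),
                           "--rules", "binary", "--out", out_dir),
                stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(out_dir, "map.json")))
  # schema violations exit non-zero
  bad <- file.path(dir, "bad.csv")
  writeLines("patient_id,oops\n1,2", bad)
  st <- system2(rscript, c(cli, "build", "--measurements", bad,
                           "--outcomes", bad, "--out", file.path(dir, "x")),
                stdout = FALSE, stderr = FALSE)
  expect_identical(st, 1L)
})
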