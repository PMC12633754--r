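# Build a complete synthetic study on disk for the orchestration tests.
make_study_dir <- function(root = tempfile("study")) {
  dir.create(root)
  systems <- list(
    luteolin = list(dH = -25.241, dS = -6.585, ic50 = 18.22e-6,
                    cd = ref_cd$luteolin),
    hyperoside = list(dH = -27.511, dS = -4.108, ic50 = 31.01e-6,
                      cd = ref_cd$hyperoside))
  ligands <- lapply(names(systems), function(nm) {
    sys <- systems[[nm]]
    dose <- gen_dose_response(sys$ic50, hill = 1,
                              concs = c(5, 10, 20, 30, 45, 60, 80) * 1e-6,
                              noise = noise_model(0))
    dose_file <- file.path(root, paste0(nm, "_dose.csv"))
    utils::write.csv(dose, dose_file, row.names = FALSE)
    sims <- gen_titration(binding_truth(dH = sys$dH, dS = sys$dS),
                          noise = noise_model(0), mode = "exact")
    tfiles <- vapply(seq_along(sims), function(i) {
      f <- file.path(root, sprintf("%s_t%d.csv", nm, i))
      write_titration(sims[[i]], f)
      f
    }, "")
    pair <- gen_fret_pair()
    donor_file <- file.path(root, paste0(nm, "_em.csv"))
    acceptor_file <- file.path(root, paste0(nm, "_abs.csv"))
    write_spectrum(pair$donor, donor_file)
    write_spectrum(pair$acceptor, acceptor_file)
    list(label = nm, dose_file = dose_file,
         titration_files = as.list(tfiles),
         fret = list(donor_file = donor_file,
                     acceptor_file = acceptor_file, f0 = 1000, f = 912),
         cd = list(free = as.list(ref_cd$free), complexed = as.list(sys$cd)))
  })
  list(root = root, config = list(seed = 1, ligands = ligands))
}

test_that("run_study produces complete, deterministic per-ligand reports", {
  st <- make_study_dir()
  cfg <- st$config
  cfg$output_dir <- file.path(st$root, "out1")
  rep1 <- run_study(cfg)
  expect_s3_class(rep1, "study_report")
  expect_length(rep1$failures, 0)
  expect_named(rep1$ligands, c("luteolin", "hyperoside"))

  lut <- rep1$ligands$luteolin
  expect_equal(lut$ic50$ic50_M, 18.22e-6, tolerance = 1e-3)
  expect_equal(lut$classification$verdict, "static")
  expect_equal(lut$thermodynamics$force_class, "hbond_vdw")
  expect_equal(lut$thermodynamics$dH_kJ_per_mol, -25.241, tolerance = 1e-3)
  expect_equal(lut$cd$random_coil_increase_pct, 5.53)

  # potency and coil rankings agree with the per-ligand numbers
  expect_equal(rep1$summary$potency_rank[rep1$summary$label == "luteolin"], 1L)
  expect_equal(rep1$summary$coil_rank[rep1$summary$label == "luteolin"], 1L)

  # byte-identical re-run
  cfg$output_dir <- file.path(st$root, "out2")
  run_study(cfg)
  for (f in list.files(file.path(st$root, "out1")))
    expect_identical(readLines(file.path(st$root, "out1", f)),
                     readLines(file.path(st$root, "out2", f)),
                     label = f)
})

test_that("a missing file yields a partial report with a failure manifest", {
  st <- make_study_dir()
  cfg <- st$config
  cfg$ligands[[1]]$dose_file <- file.path(st$root, "nonexistent.csv")
  rep <- suppressWarnings(suppressMessages(run_study(cfg)))
  expect_length(rep$failures, 1)
  expect_equal(rep$failures[[1]]$stage, "ic50")
  expect_equal(rep$failures[[1]]$ligand, "luteolin")
  # the other stages of the same ligand still ran
  expect_equal(rep$ligands$luteolin$classification$verdict, "static")
  expect_true(is.na(rep$summary$ic50_M[rep$summary$label == "luteolin"]))
})

test_that("a quenching-only configuration reports only those sections", {
  st <- make_study_dir()
  lig <- st$config$ligands[[1]]
  cfg <- list(ligands = list(list(label = lig$label,
                                  titration_files = lig$titration_files)))
  rep <- run_study(cfg)
  expect_length(rep$failures, 0)
  r <- rep$ligands[[1]]
  expect_null(r$ic50)
  expect_null(r$fret)
  expect_null(r$cd)
  expect_length(r$quenching, 3)
  expect_length(r$binding, 3)
  expect_false(is.null(r$thermodynamics))
})

test_that("YAML configurations load equivalently to lists", {
  st <- make_study_dir()
  lig <- st$config$ligands[[2]]
  cfg <- list(seed = 1,
              ligands = list(list(label = lig$label,
                                  dose_file = lig$dose_file)))
  yml <- file.path(st$root, "study.yaml")
  yaml::write_yaml(cfg, yml)
  rep_file <- run_study(yml)
  rep_list <- run_study(cfg)
  expect_equal(rep_file$ligands, rep_list$ligands)
})

test_that("rendered markdown mirrors the report content", {
  st <- make_study_dir()
  rep <- run_study(st$config)
  md <- render_report(rep)
  expect_match(md, "## luteolin")
  expect_match(md, "## hyperoside")
  expect_match(md, "Quenching mode: \\*\\*static\\*\\*")
  expect_match(md, "T \\(K\\) \\| Ksv \\(L/mol\\)")
  expect_match(md, "force: \\*\\*hbond_vdw\\*\\*")
  expect_match(md, "random-coil increase")

  # empty report renders header only
  empty <- render_report(structure(list(ligands = list(), summary = NULL,
                                        failures = list()),
                                   class = "study_report"))
  expect_match(empty, "^# Binding study report")

  # failures render as a manifest
  cfg <- st$config
  cfg$ligands[[1]]$dose_file <- "missing.csv"
  md2 <- render_report(suppressWarnings(suppressMessages(run_study(cfg))))
  expect_match(md2, "Failure manifest")
  expect_match(md2, "luteolin / ic50")
})
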