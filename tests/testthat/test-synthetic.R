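test_that("generated investment datasets are reproducible byte-for-byte", {
  d1 <- file.path(tempdir(), "synthA"); d2 <- file.path(tempdir(), "synthB")
  generate_investment_dataset(n = 25, seed = 9, dir = d1)
  generate_investment_dataset(n = 25, seed = 9, dir = d2)
  for (f in c("annotations.tsv", "class_map.tsv", "truth.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # a different seed changes the data
  d3 <- file.path(tempdir(), "synthC")
  generate_investment_dataset(n = 25, seed = 10, dir = d3)
  expect_false(identical(readLines(file.path(d1, "annotations.tsv")),
                         readLines(file.path(d3, "annotations.tsv"))))
})

test_that("generated tables pass the loader and reproduce investments", {
  d <- file.path(tempdir(), "synthRT")
  g <- generate_investment_dataset(n = 30, seed = 3, dir = d)
  ann <- load_annotations(file.path(d, "annotations.tsv"),
                          file.path(d, "class_map.tsv"))
  iv <- investment_table(ann)
  m <- match(iv$genome_id, g$pairs$genome_id)
  expect_equal(iv$I_PCD, g$pairs$I_PCD[m], tolerance = 1e-12)
  expect_equal(iv$I_Imm, g$pairs$I_Imm[m], tolerance = 1e-12)
  expect_true(all(iv$I_PCD + iv$I_Imm <= 1))
})

test_that("planted pairs respect the unit-interval feasibility constraint", {
  g <- generate_investment_dataset(n = 400, gamma = 1.5, seed = 8,
                                   imm_meanlog = log(0.05))
  expect_true(all(g$pairs$I_PCD + g$pairs$I_Imm < 1))
  expect_error(generate_investment_dataset(beta = 50,
                                           imm_meanlog = log(0.5)),
               "infeasible")
})

test_that("loader rejects malformed annotation tables", {
  d <- tempdir()
  cm <- file.path(d, "cm.tsv")
  writeLines("system_name\tclass\nsysA\tPCD", cm)
  bad1 <- file.path(d, "bad1.tsv")
  writeLines(c("genome_id\tgenome_length\tsystem_name\tspan_nt",
               "g1\t1000\tsysA\t200", "g1\t2000\tsysA\t100"), bad1)
  expect_error(load_annotations(bad1, cm), "conflicting genome_length")
  bad2 <- file.path(d, "bad2.tsv")
  writeLines(c("genome_id\tgenome_length\tsystem_name\tspan_nt",
               "g1\t1000\tsysA\t2000"), bad2)
  expect_error(load_annotations(bad2, cm), "exceeds genome length")
  bad3 <- file.path(d, "bad3.tsv")
  writeLines(c("genome_id\tgenome_length\tsystem_name\tspan_nt",
               "g1\t1000\tmystery\t10"), bad3)
  expect_error(load_annotations(bad3, cm), "missing from the class map")
})

test_that("genomes without defense hits load as empty records", {
  d <- tempdir()
  cm <- file.path(d, "cm0.tsv")
  writeLines(c("system_name\tclass", "sysA\tPCD"), cm)
  ann <- file.path(d, "ann0.tsv")
  writeLines(c("genome_id\tgenome_length\tsystem_name\tspan_nt",
               "g1\t1000\t\t", "g2\t2000\t\t", "g3\t1500\t\t"), ann)
  res <- load_annotations(ann, cm)
  expect_equal(length(res$records), 3)
  expect_true(all(vapply(res$records,
                         function(r) nrow(r$hits) == 0, logical(1))))
  iv <- investment_table(res)
  expect_equal(iv$I_PCD, rep(0, 3))
  expect_equal(iv$I_Imm, rep(0, 3))
})

test_that("overlapping same-class annotations are counted once", {
  d <- tempdir()
  cm <- file.path(d, "cm2.tsv")
  writeLines(c("system_name\tclass", "sysA\tPCD", "sysB\tImmunity"), cm)
  ann <- file.path(d, "ann2.tsv")
  writeLines(c("genome_id\tgenome_length\tsystem_name\tstart\tend",
               "g1\t100000\tsysA\t1001\t2000",
               "g1\t100000\tsysA\t1001\t2000",   # exact duplicate interval
               "g1\t100000\tsysB\t5001\t6000"), ann)
  res <- load_annotations(ann, cm)
  iv <- compute_investment(res$records[["g1"]], res$class_map)
  expect_equal(iv$I_PCD, 1000 / 100000)
  expect_equal(iv$I_Imm, 1000 / 100000)
})

test_that("abundance generator output passes the classifier pipeline", {
  g <- generate_abundance_dataset(n_species = 30, n_samples = 105, seed = 2)
  expect_true(all(c("sample_id", "species_id", "rank") %in% names(g$ranks)))
  # ranks within a sample form a permutation of 1..S_present
  by_sample <- split(g$ranks$rank, g$ranks$sample_id)
  for (rk in by_sample[1:5]) expect_equal(sort(rk), seq_along(rk))
  # rare species appear in fewer than min_samples samples
  lab <- unlist(g$truth$labels)
  cnt <- table(g$ranks$species_id)
  rare <- names(lab)[lab == "rare"]
  if (length(rare)) expect_true(all(cnt[rare] < 100))
  expect_error(generate_abundance_dataset(frac_high = 1.2), "frac_high")
})

test_that("null-effect abundance data keep the false-positive rate in check", {
  set.seed(70)
  pv <- numeric(30)
  for (i in seq_along(pv)) {
    g <- generate_abundance_dataset(n_species = 40, n_samples = 105,
                                    investment_effect = 1,
                                    dispersion = 0.05,
                                    frac_intermediate = 0, frac_rare = 0,
                                    seed = 7000 + i)
    cl <- classify_abundance(g$ranks, choose_threshold(
      g$ranks, g$investments$species_id, 100)$T_a, 100)
    pv[i] <- compare_investment(cl, g$investments, "PCD")$p_value
  }
  # binomial(30, 0.05) upper tail: 6+ rejections would be anomalous
  expect_lte(sum(pv < 0.05), 5)
})

test_that("random gene profiles have the requested size and reproduce", {
  gl <- data.frame(species_id = sprintf("s%02d", 1:15),
                   genome_length = exp(rnorm(15, log(4e6), 0.3)))
  r1 <- generate_random_gene_profiles(12, gl, seed = 5)
  r2 <- generate_random_gene_profiles(12, gl, seed = 5)
  expect_identical(r1, r2)
  expect_equal(length(unique(r1$system)), 12)
  expect_equal(nrow(r1), 12 * 15)
  expect_true(all(r1$content_nt > 0))
})
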