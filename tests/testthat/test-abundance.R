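make_ranks <- function(mat) {
  # mat: species x samples of oriented ranks -> raw-convention table
  S <- nrow(mat)
  do.call(rbind, lapply(seq_len(ncol(mat)), function(s)
    data.frame(sample_id = paste0("S", s),
               species_id = rownames(mat),
               rank = S + 1 - mat[, s])))
}

test_that("quartile rule classifies high, low and intermediate species", {
  or <- rbind(topsp = rep(10, 8), upsp = c(9, 9, 9, 9, 9, 8, 8, 8),
              strad = c(2, 3, 9, 10, 2, 9, 3, 10),
              lowsp = c(1, 2, 1, 2, 1, 2, 1, 2))
  or <- or + 0
  rownames(or) <- c("topsp", "upsp", "strad", "lowsp")
  tab <- make_ranks(or)
  cl <- classify_abundance(tab, T_a = 5, min_samples = 2)
  got <- setNames(cl$species$class, cl$species$species_id)
  expect_equal(got[["topsp"]], "high")
  expect_equal(got[["upsp"]], "high")
  expect_equal(got[["strad"]], "intermediate")
  expect_equal(got[["lowsp"]], "low")
})

test_that("species below the sample filter are excluded", {
  tab <- data.frame(sample_id = rep(paste0("S", 1:10), each = 2),
                    species_id = rep(c("common", "common2"), 10),
                    rank = rep(c(1, 2), 10))
  tab <- rbind(tab, data.frame(sample_id = "S1", species_id = "rare",
                               rank = 3))
  cl <- classify_abundance(tab, T_a = 1, min_samples = 5)
  expect_false("rare" %in% cl$species$species_id)
  expect_true(all(c("common", "common2") %in% cl$species$species_id))
})

test_that("zero-dispersion synthetic cohorts are recovered exactly", {
  g <- generate_abundance_dataset(n_species = 40, n_samples = 110,
                                  frac_high = 0.5, dispersion = 0,
                                  frac_intermediate = 0, frac_rare = 0,
                                  seed = 17)
  th <- choose_threshold(g$ranks, g$investments$species_id,
                         min_samples = 100)
  cl <- classify_abundance(g$ranks, th$T_a, min_samples = 100)
  lab <- unlist(g$truth$labels)
  got <- setNames(cl$species$class, cl$species$species_id)
  expect_equal(unname(got[names(lab)]), unname(lab))
  expect_equal(cl$n_intermediate, 0)
})

test_that("chosen threshold attains the brute-force maximum", {
  set.seed(23)
  g <- generate_abundance_dataset(n_species = 30, n_samples = 105,
                                  dispersion = 0.5, seed = 23)
  genomes <- sample(g$investments$species_id, 20)
  th <- choose_threshold(g$ranks, genomes, min_samples = 100)
  tab <- orient_ranks(g$ranks)
  brute <- sapply(sort(unique(round(tab$oriented_rank))), function(Ta) {
    sp <- classify_abundance(tab, Ta, 100)$species
    min(sum(sp$class == "high" & sp$species_id %in% genomes),
        sum(sp$class == "low" & sp$species_id %in% genomes))
  })
  expect_equal(th$objective, max(brute))
  # availability restricted to one group -> error
  cl <- classify_abundance(tab, th$T_a, 100)
  hi_only <- cl$species$species_id[cl$species$class == "high"]
  expect_error(choose_threshold(g$ranks, hi_only[1], min_samples = 100),
               "nonempty")
})

test_that("Mann-Whitney agrees with brute-force pair counting", {
  brute_U <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  mk_classes <- function(x, y) {
    structure(list(species = data.frame(
      species_id = c(paste0("h", seq_along(x)), paste0("l", seq_along(y))),
      class = rep(c("high", "low"), c(length(x), length(y)))),
      T_a = 0), class = "abundance_classes")
  }
  set.seed(31)
  for (rep in 1:20) {
    nx <- sample(2:8, 1); ny <- sample(2:8, 1)
    x <- sample(1:20, nx, replace = TRUE) / 20
    y <- sample(1:20, ny, replace = TRUE) / 20
    cl <- mk_classes(x, y)
    inv <- data.frame(species_id = cl$species$species_id,
                      I_PCD = c(x, y), I_Imm = 0.01)
    got <- compare_investment(cl, inv, "PCD")
    expect_equal(unname(got$U), brute_U(x, y))
  }
  # {1,2,3} vs {4,5,6}: no pair has the first group larger
  cl <- mk_classes(1:3, 4:6)
  inv <- data.frame(species_id = cl$species$species_id,
                    I_PCD = c(1:3, 4:6) / 10, I_Imm = 0.01)
  got <- compare_investment(cl, inv, "PCD")
  expect_equal(unname(got$U), 0)
  # identical tiny tie-free-rank groups: exact p = 1
  cl2 <- mk_classes(c(0.1, 0.3), c(0.2, 0.4))
  inv2 <- data.frame(species_id = cl2$species$species_id,
                     I_PCD = c(0.1, 0.3, 0.2, 0.4), I_Imm = 0.01)
  expect_gt(compare_investment(cl2, inv2, "PCD")$p_value, 0.6)
  expect_error(compare_investment(mk_classes(1, 1:3), inv, "PCD"),
               "at least 2")
})

test_that("planted investment shift is detected with adequate power", {
  set.seed(40)
  hits <- 0
  for (i in 1:40) {
    g <- generate_abundance_dataset(n_species = 50, n_samples = 105,
                                    frac_high = 0.5, investment_effect = 2,
                                    dispersion = 0.05,
                                    frac_intermediate = 0, frac_rare = 0,
                                    seed = 400 + i)
    cl <- classify_abundance(g$ranks, choose_threshold(
      g$ranks, g$investments$species_id, 100)$T_a, 100)
    p <- compare_investment(cl, g$investments, "PCD")$p_value
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits / 40, 0.8)
})

test_that("deviation analysis: proportional investment gives a null result", {
  set.seed(50)
  n <- 40
  ids <- sprintf("sp%02d", 1:n)
  len <- rlnorm(n, log(4e6), 0.3)
  cl <- structure(list(species = data.frame(
    species_id = ids, class = rep(c("high", "low"), each = n / 2)),
    T_a = 0), class = "abundance_classes")
  sysc <- data.frame(species_id = ids, system = "propsys",
                     content_nt = 0.002 * len)   # exactly proportional
  gl <- data.frame(species_id = ids, genome_length = len)
  dev <- genome_size_deviation(cl, sysc, gl)
  expect_lt(max(abs(c(dev$signed_logp_low, dev$signed_logp_high))), 1.35)
})

test_that("deviation analysis is invariant to species relabeling", {
  set.seed(51)
  n <- 30
  ids <- sprintf("sp%02d", 1:n)
  len <- rlnorm(n, log(4e6), 0.3)
  content <- 0.002 * len + rnorm(n, 0, 2000)
  cls <- rep(c("high", "low"), c(12, 18))
  mk <- function(ids) {
    cl <- structure(list(species = data.frame(species_id = ids, class = cls),
                         T_a = 0), class = "abundance_classes")
    genome_size_deviation(cl,
                          data.frame(species_id = ids, system = "s",
                                     content_nt = content),
                          data.frame(species_id = ids, genome_length = len))
  }
  d1 <- mk(ids)
  d2 <- mk(paste0("renamed_", ids))
  expect_equal(d1$signed_logp_low, d2$signed_logp_low)
  expect_equal(d1$signed_logp_high, d2$signed_logp_high)
})

test_that("genome-size confound: raw bias but planted low-high quadrant", {
  g <- generate_abundance_dataset(n_species = 60, n_samples = 110,
                                  investment_effect = 1, confound = TRUE,
                                  dispersion = 0.05, frac_intermediate = 0,
                                  frac_rare = 0, seed = 60)
  cl <- classify_abundance(g$ranks, choose_threshold(
    g$ranks, g$investments$species_id, 100)$T_a, 100)
  sysc <- data.frame(species_id = g$investments$species_id, system = "PCD",
                     content_nt = g$investments$pcd_content_nt)
  rnd <- generate_random_gene_profiles(8, g$investments, seed = 60)
  dev <- genome_size_deviation(cl, rbind(sysc, rnd), g$investments)
  pcd <- dev[dev$system == "PCD", ]
  expect_equal(pcd$quadrant, "low-high")  # over in high, under in low
  # random profiles stay near-null
  rnd_dev <- dev[dev$system != "PCD", ]
  expect_lt(median(abs(c(rnd_dev$signed_logp_low,
                         rnd_dev$signed_logp_high))), 1.35)
})
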