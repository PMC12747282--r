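#' Generate a synthetic defense-investment dataset
#'
#' Draws per-genome immunity investments from a lognormal prior, plants the
#' power-law relation \code{I_PCD = beta * I_Imm^alpha * exp(eps)} with
#' \code{eps ~ Normal(0, gamma^2)}, draws genome lengths from a lognormal
#' size law, and materializes the investments as annotation spans split
#' across named systems, together with a class map and a truth record.
#' Pairs violating \code{I_PCD + I_Imm <= 1} (or unit-exceeding single
#' investments) are redrawn. With \code{gamma = 0} a downstream fit recovers
#' \code{(alpha, beta)} exactly; spans are therefore written as real-valued
#' \code{span_nt}.
#'
#' @param alpha,beta,gamma Planted power-law exponent, scale, and lognormal
#'   noise sd (log scale).
#' @param n Number of genomes (>= 3).
#' @param seed Random seed.
#' @param imm_meanlog,imm_sdlog Lognormal prior of \code{I_Imm}
#'   (median 1\% of the genome, log-sd 1 by default).
#' @param size_meanlog,size_sdlog Lognormal genome-size law (median 4 Mb,
#'   log-sd 0.3 by default).
#' @param dir Optional output directory; when given, writes
#'   \code{annotations.tsv}, \code{class_map.tsv} and \code{truth.json}.
#' @return List with \code{annotations} (data frame), \code{class_map}
#'   (data frame), \code{pairs} (planted investments) and \code{truth}.
#' @export
generate_investment_dataset <- function(alpha = 0.554, beta = 0.15,
                                        gamma = 1, n = 5000, seed = 1,
                                        imm_meanlog = log(0.01),
                                        imm_sdlog = 1,
                                        size_meanlog = log(4e6),
                                        size_sdlog = 0.3, dir = NULL) {
  stopifnot(gamma >= 0, n >= 3)
  if (beta <= 0) stop("beta must be positive")
  # feasibility: at the prior median the planted relation must fit a genome
  if (beta * exp(imm_meanlog)^alpha + exp(imm_meanlog) >= 1)
    stop("infeasible fractions: beta too large for the immunity prior")
  set.seed(seed)
  I_Imm <- numeric(n); I_PCD <- numeric(n)
  todo <- seq_len(n)
  for (tries in 1:100) {
    m <- length(todo)
    if (!m) break
    ii <- rlnorm(m, imm_meanlog, imm_sdlog)
    ip <- beta * ii^alpha * exp(rnorm(m, 0, gamma))
    ok <- ii + ip < 1 & ii < 1 & ip < 1
    I_Imm[todo[ok]] <- ii[ok]; I_PCD[todo[ok]] <- ip[ok]
    todo <- todo[!ok]
  }
  if (length(todo)) stop("could not draw feasible investment pairs")
  genome_length <- rlnorm(n, size_meanlog, size_sdlog)
  ids <- sprintf("G%05d", seq_len(n))

  systems <- data.frame(
    system_name = c("TA_mod1", "abi_like", "cbass_like",
                    "RM_like", "crispr_like", "brex_like",
                    "orphan_sys1", "orphan_sys2"),
    class = c("PCD", "PCD", "PCD", "Immunity", "Immunity", "Immunity",
              "Undefined", "Undefined"))
  split_spans <- function(total_nt, names) {
    w <- runif(length(names)); w <- w / sum(w)
    data.frame(system_name = names, span_nt = total_nt * w)
  }
  ann <- vector("list", n)
  for (i in seq_len(n)) {
    pcd <- split_spans(I_PCD[i] * genome_length[i],
                       systems$system_name[systems$class == "PCD"])
    imm <- split_spans(I_Imm[i] * genome_length[i],
                       systems$system_name[systems$class == "Immunity"])
    und <- data.frame(system_name = "orphan_sys1",
                      span_nt = runif(1, 0, 1e-4) * genome_length[i])
    h <- rbind(pcd, imm, und)
    ann[[i]] <- data.frame(genome_id = ids[i],
                           genome_length = genome_length[i], h)
  }
  annotations <- do.call(rbind, ann)
  pairs <- data.frame(genome_id = ids, genome_length = genome_length,
                      I_PCD = I_PCD, I_Imm = I_Imm)
  truth <- list(kind = "investment", alpha = alpha, beta = beta,
                gamma = gamma, n = n, seed = seed,
                imm_meanlog = imm_meanlog, imm_sdlog = imm_sdlog,
                size_meanlog = size_meanlog, size_sdlog = size_sdlog)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write.table(annotations, file.path(dir, "annotations.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(systems, file.path(dir, "class_map.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(annotations = annotations, class_map = systems, pairs = pairs,
       truth = truth)
}

#' Generate a synthetic rank-abundance dataset
#'
#' Emulates per-sample species rank abundances with two planted groups:
#' high-abundant species (latent abundance scores concentrated at the top)
#' and low-abundant species, plus optional high-variance intermediate
#' species. Within each sample, species are ranked by latent score plus
#' noise (rank 1 = most abundant). Planted PCD investments are multiplied
#' by \code{investment_effect} in the high group; with
#' \code{confound = TRUE} the high group also receives systematically
#' larger genomes and every genome's PCD content gains a genome-size
#' proportional component plus a group offset, so that the raw comparison
#' is biased while the deviation-from-genome-size analysis recovers the
#' planted group signal.
#'
#' @param n_species Number of species.
#' @param n_samples Number of samples (>= 100 recommended, to exercise the
#'   minimum-sample filter realistically).
#' @param frac_high Fraction of species planted as high-abundant, in (0,1).
#' @param investment_effect Multiplicative PCD-investment effect in the
#'   high group (1 = null).
#' @param dispersion Sd of the per-sample score noise (0 = deterministic
#'   ranks; planted labels then recovered exactly).
#' @param frac_intermediate Fraction of species planted as high-variance
#'   (intermediate) species.
#' @param frac_rare Fraction of species appearing in fewer than
#'   \code{min_samples} samples (filter fodder).
#' @param min_samples Presence threshold the rare species are planted below.
#' @param confound Add the genome-size confound (larger genomes in the high
#'   group).
#' @param seed Random seed.
#' @param dir Optional output directory (writes \code{ranks.tsv},
#'   \code{investments.tsv}, \code{truth.json}).
#' @return List with \code{ranks}, \code{investments} (species_id,
#'   genome_length, I_PCD, I_Imm, pcd_content_nt), \code{truth} (including
#'   planted labels).
#' @export
generate_abundance_dataset <- function(n_species = 60, n_samples = 120,
                                       frac_high = 0.4,
                                       investment_effect = 2,
                                       dispersion = 0.1,
                                       frac_intermediate = 0.1,
                                       frac_rare = 0.05,
                                       min_samples = 100,
                                       confound = FALSE, seed = 1,
                                       dir = NULL) {
  if (frac_high <= 0 || frac_high >= 1)
    stop("frac_high must lie strictly between 0 and 1")
  set.seed(seed)
  n_int <- round(frac_intermediate * n_species)
  n_rare <- round(frac_rare * n_species)
  n_core <- n_species - n_int - n_rare
  n_high <- round(frac_high * n_core)
  n_low <- n_core - n_high
  label <- c(rep("high", n_high), rep("low", n_low),
             rep("intermediate", n_int), rep("rare", n_rare))
  ids <- sprintf("sp%03d", seq_len(n_species))
  # latent abundance scores: high group on top, intermediates high-variance
  base <- c(seq(2, 3, length.out = n_high),
            seq(0, 1, length.out = n_low),
            rep(1.5, n_int), seq(0.2, 0.8, length.out = n_rare))
  ranks <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    present <- rep(TRUE, n_species)
    if (n_rare > 0)   # rare species present in < min_samples samples
      present[label == "rare"] <-
        s <= sample.int(max(min_samples - 1, 1), n_rare, replace = TRUE)
    score <- base + rnorm(n_species, 0, dispersion) +
      (label == "intermediate") * rnorm(n_species, 0, 1.5)
    idx <- which(present)
    rk <- rank(-score[idx], ties.method = "first")  # 1 = most abundant
    ranks[[s]] <- data.frame(sample_id = sprintf("S%04d", s),
                             species_id = ids[idx], rank = rk)
  }
  ranks <- do.call(rbind, ranks)

  genome_length <- rlnorm(n_species, log(4e6), 0.3)
  if (confound)
    genome_length[label == "high"] <-
      genome_length[label == "high"] * 1.6
  I_Imm <- rlnorm(n_species, log(0.01), 0.5)
  I_PCD <- rlnorm(n_species, log(0.005), 0.5)
  I_PCD[label == "high"] <- I_PCD[label == "high"] * investment_effect
  pcd_content <- I_PCD * genome_length
  if (confound) {
    # content = baseline + size-proportional part + group offset
    pcd_content <- 0.004 * genome_length +
      ifelse(label == "high", 8e3, -8e3) +
      rnorm(n_species, 0, 2e3)
    pcd_content <- pmax(pcd_content, 100)
    I_PCD <- pcd_content / genome_length
  }
  investments <- data.frame(species_id = ids, genome_length = genome_length,
                            I_PCD = I_PCD, I_Imm = I_Imm,
                            pcd_content_nt = pcd_content)
  truth <- list(kind = "abundance", n_species = n_species,
                n_samples = n_samples, frac_high = frac_high,
                investment_effect = investment_effect,
                dispersion = dispersion, confound = confound, seed = seed,
                labels = setNames(as.list(label), ids))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write.table(ranks, file.path(dir, "ranks.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(investments, file.path(dir, "investments.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(ranks = ranks, investments = investments, truth = truth)
}

#' Generate random gene profiles (null systems)
#'
#' Per-genome random gene content proportional to genome length with
#' multiplicative noise: a null family of systems whose investment is fully
#' explained by genome size, used as the negative control in the
#' deviation-from-genome-size analysis.
#'
#' @param n_profiles Number of random profiles (default 159).
#' @param genome_lengths Data frame with species_id and genome_length.
#' @param mean_fraction Mean content as a fraction of genome length.
#' @param noise_sdlog Multiplicative (lognormal) noise sd.
#' @param seed Random seed.
#' @return Data frame with columns species_id, system, content_nt.
#' @export
generate_random_gene_profiles <- function(n_profiles = 159, genome_lengths,
                                          mean_fraction = 2e-3,
                                          noise_sdlog = 0.2, seed = 1) {
  if (NROW(genome_lengths) == 0) stop("genome_lengths must be nonempty")
  set.seed(seed)
  out <- vector("list", n_profiles)
  for (j in seq_len(n_profiles)) {
    out[[j]] <- data.frame(
      species_id = genome_lengths$species_id,
      system = sprintf("random_%03d", j),
      content_nt = mean_fraction * genome_lengths$genome_length *
        rlnorm(nrow(genome_lengths), 0, noise_sdlog))
  }
  do.call(rbind, out)
}
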