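#' Orient a rank-abundance table
#'
#' Input tables follow the common convention rank 1 = most abundant. For the
#' quartile classification rule it is convenient to work with oriented ranks
#' where larger = more abundant; this flips ranks within each sample
#' (oriented = S_sample + 1 - rank, with S_sample the number of species
#' ranked in that sample).
#'
#' @param table Data frame with columns sample_id, species_id, rank.
#' @param orient \code{"flip"} (default; convert to larger-is-more-abundant)
#'   or \code{"keep"} (ranks already oriented).
#' @return The table with an \code{oriented_rank} column.
#' @export
orient_ranks <- function(table, orient = c("flip", "keep")) {
  orient <- match.arg(orient)
  need <- c("sample_id", "species_id", "rank")
  if (!all(need %in% names(table)))
    stop("rank table must have columns: ", paste(need, collapse = ", "))
  if (orient == "keep") {
    table$oriented_rank <- table$rank
    return(table)
  }
  smax <- tapply(table$rank, table$sample_id, max)
  table$oriented_rank <- as.numeric(smax[as.character(table$sample_id)]) +
    1 - table$rank
  table
}

#' Classify species by consistent abundance
#'
#' A species is high-abundant if the 1st quartile of its oriented rank
#' distribution across samples exceeds the threshold \code{T_a}, and
#' low-abundant if the 3rd quartile falls below \code{T_a}; species with
#' highly variable abundance (quartiles straddling the threshold) are
#' intermediate and discarded from group comparisons. Species observed in
#' fewer than \code{min_samples} samples are excluded beforehand. Quartiles
#' use linear interpolation (type 7).
#'
#' @param table Rank table (will be oriented via \code{\link{orient_ranks}}
#'   unless it already has an \code{oriented_rank} column).
#' @param T_a Integer rank threshold (oriented scale).
#' @param min_samples Minimum number of samples a species must appear in.
#' @param orient Passed to \code{\link{orient_ranks}}.
#' @return An \code{"abundance_classes"} object: data frame \code{species}
#'   (species_id, n_samples, q1, q3, class), \code{T_a}, group sizes.
#' @export
classify_abundance <- function(table, T_a, min_samples = 100,
                               orient = c("flip", "keep")) {
  if (!"oriented_rank" %in% names(table))
    table <- orient_ranks(table, match.arg(orient))
  cnt <- table(table$species_id)
  keep <- names(cnt)[cnt >= min_samples]
  tab <- table[table$species_id %in% keep, , drop = FALSE]
  if (nrow(tab) == 0) stop("no species retained at min_samples = ",
                           min_samples)
  sp <- split(tab$oriented_rank, tab$species_id)
  q1 <- vapply(sp, quantile, numeric(1), probs = 0.25, type = 7, names = FALSE)
  q3 <- vapply(sp, quantile, numeric(1), probs = 0.75, type = 7, names = FALSE)
  cls <- ifelse(q1 > T_a, "high", ifelse(q3 < T_a, "low", "intermediate"))
  species <- data.frame(species_id = names(sp),
                        n_samples = as.integer(lengths(sp)),
                        q1 = q1, q3 = q3, class = cls,
                        row.names = NULL)
  structure(list(species = species, T_a = T_a,
                 n_high = sum(cls == "high"), n_low = sum(cls == "low"),
                 n_intermediate = sum(cls == "intermediate")),
            class = "abundance_classes")
}

#' @exportS3Method base::print
print.abundance_classes <- function(x, ...) {
  cat(sprintf("Abundance classification at T_a = %g: %d high, %d low, %d intermediate\n",
              x$T_a, x$n_high, x$n_low, x$n_intermediate))
  invisible(x)
}

#' Choose the abundance threshold
#'
#' Scans all candidate integer thresholds and picks the one maximizing the
#' size of the smaller of the two groups (high, low) restricted to species
#' with available genomes; ties go to the smallest threshold.
#'
#' @param table Rank table (as in \code{\link{classify_abundance}}).
#' @param genomes Character vector of species ids with available genomes.
#' @param min_samples Minimum sample count per species.
#' @param orient Passed to \code{\link{orient_ranks}}.
#' @return List with \code{T_a}, the achieved \code{objective}
#'   (min group size), and the per-candidate search table.
#' @export
choose_threshold <- function(table, genomes, min_samples = 100,
                             orient = c("flip", "keep")) {
  if (!"oriented_rank" %in% names(table))
    table <- orient_ranks(table, match.arg(orient))
  ranks <- sort(unique(round(table$oriented_rank)))
  # midpoints included: with strict inequalities on both quartile rules an
  # attained integer threshold always strands the species sitting on it
  cand <- sort(unique(c(ranks, ranks - 0.5)))
  obj <- vapply(cand, function(Ta) {
    cl <- classify_abundance(table, Ta, min_samples)
    sp <- cl$species
    min(sum(sp$class == "high" & sp$species_id %in% genomes),
        sum(sp$class == "low" & sp$species_id %in% genomes))
  }, numeric(1))
  if (max(obj) == 0)
    stop("no threshold yields nonempty high and low groups with genomes")
  T_a <- cand[which.max(obj)]   # which.max takes the first (smallest) tie
  list(T_a = T_a, objective = max(obj),
       search = data.frame(T_a = cand, objective = obj))
}

#' Compare defense investment between abundance groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of the chosen investment
#' between high- and low-abundant species, with tie correction (exact
#' distribution on small tie-free samples).
#'
#' @param classes An \code{"abundance_classes"} object.
#' @param investments Data frame with columns species_id and the investment
#'   columns \code{I_PCD}, \code{I_Imm} (e.g. \code{\link{investment_table}}
#'   output with genome_id matching species_id).
#' @param which \code{"PCD"} or \code{"Immunity"}.
#' @return List with \code{U} (Mann-Whitney statistic for the high group),
#'   \code{p_value}, group sizes and medians.
#' @export
compare_investment <- function(classes, investments,
                               which = c("PCD", "Immunity")) {
  which <- match.arg(which)
  col <- if (which == "PCD") "I_PCD" else "I_Imm"
  if (!"species_id" %in% names(investments)) {
    if ("genome_id" %in% names(investments))
      investments$species_id <- investments$genome_id
    else stop("investments need a species_id (or genome_id) column")
  }
  sp <- classes$species
  hi_ids <- sp$species_id[sp$class == "high"]
  lo_ids <- sp$species_id[sp$class == "low"]
  x <- investments[[col]][match(hi_ids, investments$species_id)]
  y <- investments[[col]][match(lo_ids, investments$species_id)]
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("both abundance groups need at least 2 species with investments ",
         "(high: ", length(x), ", low: ", length(y), ")")
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided",
                                     exact = NULL, correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       n_high = length(x), n_low = length(y),
       median_high = median(x), median_low = median(y))
}

#' Deviation of investment from the genome-size expectation
#'
#' For each gene system, per-genome nucleotide content is regressed on
#' genome length across all high- and low-abundant species jointly (the
#' genome-size expectation); within each abundance group the residuals are
#' tested against zero (two-sided Wilcoxon signed-rank). Results are
#' reported as signed log p-values (-log10 p when the group's median
#' residual is positive, +log10 p when negative) and a quadrant label
#' \code{"<low-group direction>-<high-group direction>"} with
#' \code{high} = overinvested, \code{low} = underinvested. A system
#' overinvested only in high-abundant species therefore falls in quadrant
#' \code{"low-high"}.
#'
#' @param classes An \code{"abundance_classes"} object.
#' @param system_content Data frame with columns species_id, system,
#'   content_nt (nucleotides attributed to the system in that genome).
#' @param genome_lengths Data frame with columns species_id, genome_length.
#' @return Data frame with one row per system: signed log p and direction
#'   per group, and the quadrant label. Systems absent from all genomes are
#'   flagged and excluded.
#' @export
genome_size_deviation <- function(classes, system_content, genome_lengths) {
  sp <- classes$species
  grp <- setNames(sp$class, sp$species_id)
  ids <- sp$species_id[sp$class %in% c("high", "low")]
  gl <- setNames(genome_lengths$genome_length, genome_lengths$species_id)
  if (!all(ids %in% names(gl)))
    stop("genome length missing for: ",
         paste(head(setdiff(ids, names(gl))), collapse = ", "))
  out <- list(); skipped <- character(0)
  for (sys in unique(system_content$system)) {
    d <- system_content[system_content$system == sys &
                          system_content$species_id %in% ids, , drop = FALSE]
    # species without a row for this system have zero content
    content <- setNames(rep(0, length(ids)), ids)
    content[d$species_id] <- d$content_nt
    if (all(content == 0)) { skipped <- c(skipped, sys); next }
    len <- gl[ids]
    fitres <- content - stats::fitted(lm(content ~ len))
    res <- list()
    for (g in c("low", "high")) {
      rg <- fitres[grp[ids] == g]
      if (length(rg) < 2 || all(rg == 0)) {
        res[[g]] <- list(dir = "none", slp = 0)
        next
      }
      pv <- suppressWarnings(wilcox.test(rg, mu = 0,
                                         alternative = "two.sided")$p.value)
      pos <- median(rg) > 0
      res[[g]] <- list(dir = if (pos) "high" else "low",
                       slp = if (pos) -log10(pv) else log10(pv))
    }
    out[[sys]] <- data.frame(
      system = sys,
      signed_logp_low = res$low$slp, signed_logp_high = res$high$slp,
      dir_low = res$low$dir, dir_high = res$high$dir,
      quadrant = paste(res$low$dir, res$high$dir, sep = "-"))
  }
  result <- do.call(rbind, out)
  rownames(result) <- NULL
  attr(result, "skipped") <- skipped
  result
}
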