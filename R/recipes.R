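#' Read a run configuration
#'
#' YAML configuration with one section per module
#' (\code{chemostat}, \code{strategy}, \code{landscape}, \code{metapop},
#' \code{powerlaw}, \code{abundance}, \code{control}); unknown keys are an
#' error. Values override the package defaults; the resolved configuration
#' (with provenance default/user) is attached.
#'
#' @param path YAML file path.
#' @return Named list of sections with attribute \code{"resolved"}.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("chemostat", "strategy", "landscape", "metapop", "powerlaw",
             "abundance", "control", "seed")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) stop("unknown config section(s): ",
                          paste(extra, collapse = ", "))
  cfg
}

resolve_params <- function(cfg) {
  ch <- do.call(chemostat_params, cfg$chemostat %||% list())
  ctl <- do.call(sim_control, cfg$control %||% list())
  list(chemostat = ch, control = ctl)
}

#' Run a packaged analysis recipe
#'
#' End-to-end module chains at desk scale, each writing CSV/JSON outputs and
#' a resolved-config snapshot when \code{out_dir} is given:
#' \describe{
#'   \item{viral_pressure_sweep}{optimal strategy vs viral pressure \code{psi0}.}
#'   \item{capacity_sweep}{optimal strategy vs inverse carrying capacity
#'     (sweeping \code{C}).}
#'   \item{antagonism_sweep}{optimal strategy vs replication rate \code{F}
#'     at low and high MOI.}
#'   \item{fixation_demo}{landscape optimum, altruist-cheater competition
#'     and seeded metapopulation runs.}
#'   \item{powerlaw_demo}{synthetic investment dataset, ML power-law fit
#'     and BIC model comparison, recovery verdict.}
#'   \item{abundance_demo}{synthetic rank abundances, threshold choice,
#'     group comparison and genome-size-deviation quadrants.}
#' }
#'
#' @param name Recipe name.
#' @param config Optional configuration list (see \code{\link{read_config}}).
#' @param out_dir Optional output directory.
#' @param seeds Integer seeds for stochastic recipes.
#' @param verbose Print stage progress.
#' @return Recipe-specific result list (invisibly when writing files).
#' @export
run_recipe <- function(name = c("viral_pressure_sweep", "capacity_sweep",
                                "antagonism_sweep", "fixation_demo",
                                "powerlaw_demo", "abundance_demo"),
                       config = NULL, out_dir = NULL, seeds = 1:5,
                       verbose = interactive()) {
  name <- match.arg(name)
  rp <- resolve_params(config %||% list())
  p <- rp$chemostat; ctl <- rp$control
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(what, expr) {
    say("[%s] %s", name, what)
    tryCatch(expr, error = function(e)
      stop("recipe ", name, " failed at stage '", what, "': ",
           conditionMessage(e), call. = FALSE))
  }
  out <- switch(name,
    viral_pressure_sweep = stage("sweep psi0", {
      vals <- (config$landscape$values %||% (p$psi0 * c(1 / 3, 1, 3)))
      list(sweep = sweep_parameter(p, "psi0", vals, control = ctl))
    }),
    capacity_sweep = stage("sweep C", {
      vals <- (config$landscape$values %||% (p$C * c(1 / 3, 1, 3)))
      list(sweep = sweep_parameter(p, "C", vals, control = ctl))
    }),
    antagonism_sweep = {
      lo <- stage("sweep F at low MOI", {
        plo <- p; plo$psi0 <- 0.01 / plo$C
        sweep_parameter(plo, "F", p$F * c(0.5, 1, 2), control = ctl)
      })
      hi <- stage("sweep F at high MOI", {
        phi <- p; phi$psi0 <- 100 / phi$C
        sweep_parameter(phi, "F", p$F * c(0.5, 1, 2), control = ctl)
      })
      list(low_moi = lo, high_moi = hi)
    },
    fixation_demo = {
      ls <- stage("landscape scan", scan_landscape(
        p, a_grid = seq(0, 1, length.out = 11),
        rE_grid = seq(0, 1, length.out = 11), control = ctl))
      op <- stage("refine optimum", refine_optimum(p, ls, control = ctl))
      comp <- stage("competition", run_competition(
        p, defense_strategy(op$a_opt, op$r_opt),
        defense_strategy(0, op$r_opt), control = ctl))
      mp <- metapop_params(p, defense_strategy(op$a_opt, op$r_opt))
      runs <- lapply(seeds, function(s) stage(
        paste("metapopulation seed", s),
        simulate_metapopulation(mp, seed = s, control = ctl)))
      list(optimum = op, competition = classify_outcome(comp),
           fixation = vapply(runs, function(r) r$outcome, character(1)),
           runs = runs)
    },
    powerlaw_demo = stage("power-law recovery", {
      g <- generate_investment_dataset(
        alpha = config$powerlaw$alpha %||% 0.554,
        gamma = config$powerlaw$gamma %||% 1,
        n = config$powerlaw$n %||% 5000, seed = seeds[1])
      fit <- fit_power_law(g$pairs)
      cmp <- compare_models(g$pairs)
      se <- fit$gamma / (sqrt(fit$n_obs) * sd(log(g$pairs$I_Imm)))
      list(truth = g$truth, fit = fit, comparison = cmp,
           recovered = abs(fit$alpha - g$truth$alpha) < 3 * se)
    }),
    abundance_demo = stage("abundance pipeline", {
      g <- generate_abundance_dataset(confound = TRUE, seed = seeds[1])
      th <- choose_threshold(g$ranks, g$investments$species_id)
      cl <- classify_abundance(g$ranks, th$T_a)
      mw <- compare_investment(cl, g$investments, "PCD")
      sysc <- data.frame(species_id = g$investments$species_id,
                         system = "PCD",
                         content_nt = g$investments$pcd_content_nt)
      rnd <- generate_random_gene_profiles(10, g$investments,
                                           seed = seeds[1])
      dev <- genome_size_deviation(cl, rbind(sysc, rnd), g$investments)
      list(threshold = th$T_a, classes = cl, mann_whitney = mw,
           deviation = dev)
    }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    snap <- list(recipe = name, chemostat = unclass(p),
                 control = unclass(ctl), seeds = seeds,
                 user_config = config)
    jsonlite::write_json(snap, file.path(out_dir, "resolved_config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    for (nm in names(out)) {
      x <- out[[nm]]
      if (is.data.frame(x))
        write.table(x, file.path(out_dir, paste0(nm, ".csv")), sep = ",",
                    quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(
      summarize_recipe(out), file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE)
    return(invisible(out))
  }
  out
}

summarize_recipe <- function(out) {
  lapply(out, function(x) {
    if (is.data.frame(x)) x
    else if (inherits(x, "power_law_fit")) unclass(x)
    else if (is.atomic(x)) x
    else if (is.list(x) && !is.null(x$outcome)) x$outcome
    else NULL
  })
}

#' Write an equilibrium trajectory/state to CSV
#'
#' Long-format export (p, q, n) of an equilibrium state plus its burst-size
#' distribution, for downstream plotting.
#'
#' @param eq A \code{\link{run_to_equilibrium}} result.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_equilibrium <- function(eq, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- eq$state$n
  long <- data.frame(p = rep(as.integer(rownames(n)), ncol(n)),
                     q = rep(eq$state$qgrid, each = nrow(n)),
                     n = as.vector(n))
  long <- long[long$n > 0, ]
  f1 <- file.path(dir, "state.csv")
  write.table(long, f1, sep = ",", quote = FALSE, row.names = FALSE)
  f2 <- file.path(dir, "burst.csv")
  write.table(burst_size_distribution(eq), f2, sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(c(f1, f2))
}
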