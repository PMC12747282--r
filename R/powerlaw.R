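#' Load defense-system annotation tables
#'
#' Reads a per-genome defense-system annotation table and the system-to-class
#' map. The annotation TSV has columns \code{genome_id}, \code{genome_length}
#' and either \code{span_nt} (total nucleotides of the system's genes) or
#' 1-based inclusive \code{start}/\code{end} coordinates, plus
#' \code{system_name}. The class map TSV has columns \code{system_name} and
#' \code{class} (one of \code{PCD}, \code{Immunity}, \code{Undefined}).
#' System names present in the annotations but missing from the map are an
#' error (unknown systems must be classified, not silently dropped).
#'
#' @param path Annotation TSV path.
#' @param class_map_path Class map TSV path.
#' @return List with \code{records} (list of per-genome records: genome_id,
#'   genome_length, hits data frame) and \code{class_map} (named character
#'   vector).
#' @export
load_annotations <- function(path, class_map_path) {
  ann <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  cm <- read.delim(class_map_path, stringsAsFactors = FALSE)
  need <- c("genome_id", "genome_length", "system_name")
  if (!all(need %in% names(ann)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  if (!all(c("system_name", "class") %in% names(cm)))
    stop("class map must have columns system_name, class")
  bad_class <- setdiff(unique(cm$class), c("PCD", "Immunity", "Undefined"))
  if (length(bad_class))
    stop("unknown class label(s): ", paste(bad_class, collapse = ", "))
  class_map <- setNames(cm$class, cm$system_name)

  has_span <- "span_nt" %in% names(ann)
  has_coord <- all(c("start", "end") %in% names(ann))
  if (!has_span && !has_coord)
    stop("annotation table needs either span_nt or start/end columns")
  keep <- !is.na(ann$system_name) & ann$system_name != ""
  sys_names <- unique(ann$system_name[keep])
  unknown <- setdiff(sys_names, names(class_map))
  if (length(unknown))
    stop("system name(s) missing from the class map: ",
         paste(unknown, collapse = ", "))

  ids <- unique(ann$genome_id)
  len_by_id <- tapply(ann$genome_length, ann$genome_id,
                      function(x) unique(x[!is.na(x)]))
  multi <- names(len_by_id)[vapply(len_by_id, length, 1L) != 1L]
  if (length(multi))
    stop("genome(s) with missing or conflicting genome_length: ",
         paste(multi, collapse = ", "))
  records <- lapply(ids, function(id) {
    rows <- ann[ann$genome_id == id & keep, , drop = FALSE]
    gl <- as.numeric(len_by_id[[id]])
    if (!is.finite(gl) || gl <= 0)
      stop("genome ", id, ": genome_length must be positive (line ",
           which(ann$genome_id == id)[1], ")")
    hits <- if (nrow(rows) == 0) {
      data.frame(system_name = character(0), start = numeric(0),
                 end = numeric(0), span_nt = numeric(0))
    } else if (has_coord && (!has_span || any(is.na(rows$span_nt)))) {
      if (any(rows$end < rows$start))
        stop("genome ", id, ": end < start (line ",
             which(ann$genome_id == id & ann$end < ann$start)[1], ")")
      data.frame(system_name = rows$system_name, start = rows$start,
                 end = rows$end, span_nt = rows$end - rows$start + 1)
    } else {
      data.frame(system_name = rows$system_name, start = NA_real_,
                 end = NA_real_, span_nt = rows$span_nt)
    }
    if (any(hits$span_nt < 0))
      stop("genome ", id, ": negative span (line ",
           which(ann$genome_id == id)[1], ")")
    if (any(hits$span_nt > gl))
      stop("genome ", id, ": system span exceeds genome length")
    list(genome_id = id, genome_length = gl, hits = hits)
  })
  names(records) <- ids
  list(records = records, class_map = class_map)
}

#' Genomic investment in PCD and immunity
#'
#' The investment in a defense class is the fraction of the genome length
#' (in nucleotides) occupied by that class's systems: overlapping annotated
#' intervals of the same class are merged (interval union) before summing;
#' systems mapped to \code{Undefined} are excluded from both classes.
#'
#' @param record A genome record from \code{\link{load_annotations}}.
#' @param class_map Named character vector system_name -> class.
#' @return List with \code{I_PCD} and \code{I_Imm}, both in [0, 1] with
#'   \code{I_PCD + I_Imm <= 1}.
#' @export
compute_investment <- function(record, class_map) {
  hits <- record$hits
  if (nrow(hits) == 0) return(list(I_PCD = 0, I_Imm = 0))
  cls <- class_map[hits$system_name]
  if (anyNA(cls))
    stop("unclassified system(s): ",
         paste(unique(hits$system_name[is.na(cls)]), collapse = ", "))
  span_of <- function(idx) {
    if (!length(idx)) return(0)
    h <- hits[idx, , drop = FALSE]
    coord <- is.finite(h$start) & is.finite(h$end)
    tot <- sum(h$span_nt[!coord])
    if (any(coord)) {
      ir <- IRanges::reduce(IRanges::IRanges(start = h$start[coord],
                                             end = h$end[coord]))
      tot <- tot + sum(IRanges::width(ir))
    }
    tot
  }
  I_PCD <- span_of(which(cls == "PCD")) / record$genome_length
  I_Imm <- span_of(which(cls == "Immunity")) / record$genome_length
  if (I_PCD + I_Imm > 1)
    stop("genome ", record$genome_id,
         ": defense spans exceed the genome length")
  list(I_PCD = I_PCD, I_Imm = I_Imm)
}

#' Table of per-genome investments
#'
#' @param annotations Result of \code{\link{load_annotations}}.
#' @return Data frame with columns genome_id, genome_length, I_PCD, I_Imm.
#' @export
investment_table <- function(annotations) {
  rows <- lapply(annotations$records, function(rec) {
    iv <- compute_investment(rec, annotations$class_map)
    data.frame(genome_id = rec$genome_id,
               genome_length = rec$genome_length,
               I_PCD = iv$I_PCD, I_Imm = iv$I_Imm)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Maximum-likelihood power-law fit of PCD vs immunity investment
#'
#' Fits \code{I_PCD = beta * I_Imm^alpha} with lognormal noise: on natural
#' logs, \code{ln I_PCD = ln beta + alpha ln I_Imm + eps},
#' \code{eps ~ Normal(0, gamma^2)}. With \code{alpha} free the ML solution
#' is ordinary least squares on the logs with \code{gamma^2} the mean
#' squared residual (3 parameters); with \code{alpha} fixed the intercept is
#' the residual mean (2 parameters). Genomes with zero investment in either
#' class are excluded (their count is reported); the exponent \code{alpha}
#' measures how fast PCD investment grows relative to immunity investment as
#' total defense investment (a proxy for viral pressure) increases.
#'
#' @param pairs Data frame with columns \code{I_PCD} and \code{I_Imm}.
#' @param alpha_fixed Optional fixed exponent (e.g. 1 for proportional
#'   investment, 0 for constant PCD investment).
#' @return A \code{"power_law_fit"}: alpha, beta, gamma, loglik, n_params,
#'   BIC (\code{n_params*log(n) - 2*loglik}), n_obs, n_dropped.
#' @export
fit_power_law <- function(pairs, alpha_fixed = NULL) {
  ok <- is.finite(pairs$I_PCD) & is.finite(pairs$I_Imm) &
    pairs$I_PCD > 0 & pairs$I_Imm > 0
  n_dropped <- sum(!ok)
  d <- pairs[ok, , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 genomes with nonzero investment ",
                        "in both classes")
  y <- log(d$I_PCD); x <- log(d$I_Imm)
  n <- length(y)
  if (is.null(alpha_fixed)) {
    if (var(x) == 0)
      stop("all immunity investments identical: alpha is not identifiable")
    alpha <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    lbeta <- mean(y) - alpha * mean(x)
    k <- 3L
  } else {
    alpha <- alpha_fixed
    lbeta <- mean(y - alpha * x)
    k <- 2L
  }
  res <- y - (lbeta + alpha * x)
  gamma <- sqrt(mean(res^2))
  loglik <- if (gamma < 1e-12) Inf else sum(dnorm(res, 0, gamma, log = TRUE))
  structure(list(alpha = alpha, beta = exp(lbeta), gamma = gamma,
                 loglik = loglik, n_params = k,
                 BIC = k * log(n) - 2 * loglik, n_obs = n,
                 n_dropped = n_dropped,
                 alpha_fixed = !is.null(alpha_fixed)),
            class = "power_law_fit")
}

#' @exportS3Method base::print
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "Power-law fit: I_PCD = %.4g * I_Imm^%.4g  (gamma = %.4g)%s\n",
    x$beta, x$alpha, x$gamma, if (x$alpha_fixed) "  [alpha fixed]" else ""))
  cat(sprintf("  n = %d (%d zero-investment genomes dropped), ", x$n_obs,
              x$n_dropped))
  cat(sprintf("loglik = %.4g, BIC = %.4g\n", x$loglik, x$BIC))
  invisible(x)
}

#' Compare the free power law against naive fixed-exponent models
#'
#' Fits the free-exponent model and the two naive alternatives:
#' \code{alpha = 1} (investment in PCD proportional to immunity, independent
#' of total defense investment) and \code{alpha = 0} (constant PCD
#' investment). Reports each BIC relative to the free model; the preferred
#' model minimizes BIC.
#'
#' @param pairs Data frame with columns \code{I_PCD}, \code{I_Imm}.
#' @return Data frame with rows \code{free}, \code{alpha=1}, \code{alpha=0}
#'   and columns alpha, beta, gamma, loglik, BIC, dBIC; attribute
#'   \code{preferred}.
#' @export
compare_models <- function(pairs) {
  fits <- list(free = fit_power_law(pairs),
               `alpha=1` = fit_power_law(pairs, alpha_fixed = 1),
               `alpha=0` = fit_power_law(pairs, alpha_fixed = 0))
  out <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(model = nm, alpha = f$alpha, beta = f$beta, gamma = f$gamma,
               loglik = f$loglik, BIC = f$BIC)
  }))
  out$dBIC <- out$BIC - out$BIC[out$model == "free"]
  attr(out, "preferred") <- out$model[which.min(out$BIC)]
  out
}
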