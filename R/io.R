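# Readers and writers for the package's plain-text formats.
#
# Landscape TSV: header `genotype<TAB>lambda_max<TAB>functional`; genotype
# is a "+"-joined list of mutation labels with the literal "ancestor" for
# the empty set; lambda_max is blank or "NF" on nonfunctional rows. All
# files are UTF-8 and the Unicode minus (U+2212) is normalised to "-" on
# read.

norm_minus <- function(x) gsub("−", "-", x)

#' Read a genotype-phenotype landscape from TSV
#'
#' @param path path to a tab-separated file with columns `genotype`,
#'   `lambda_max`, `functional`.
#' @param sites optional site labels fixing the site order; default the
#'   order of first appearance in the file.
#' @return a [landscape()].
#' @export
parse_landscape <- function(path, sites = NULL) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", fileEncoding = "UTF-8",
                           blank.lines.skip = FALSE)
  need <- c("genotype", "lambda_max", "functional")
  if (!all(need %in% names(raw)))
    stop("landscape file must have columns: ", paste(need, collapse = ", "))
  if (nrow(raw) == 0L) stop("missing ancestor: file has no rows")
  gty <- trimws(norm_minus(raw$genotype))
  lam_raw <- trimws(norm_minus(raw$lambda_max))
  fun_raw <- tolower(trimws(raw$functional))
  fun <- fun_raw %in% c("true", "t", "1", "yes")
  bad_fun <- !fun_raw %in% c("true", "t", "1", "yes", "false", "f", "0", "no")
  if (any(bad_fun))
    stop("unparseable functional flag on line(s) ",
         paste(which(bad_fun) + 1L, collapse = ", "))
  lam <- suppressWarnings(as.numeric(lam_raw))
  blank <- lam_raw == "" | toupper(lam_raw) == "NF"
  bad_lam <- fun & (blank | is.na(lam))
  if (any(bad_lam))
    stop("functional row with missing/non-numeric lambda_max on line(s) ",
         paste(which(bad_lam) + 1L, collapse = ", "))
  if (is.null(sites)) {
    toks <- unlist(strsplit(gty[gty != "ancestor"], "+", fixed = TRUE))
    sites <- unique(toks)
  }
  L <- length(sites)
  masks <- vapply(gty, genotype_mask, integer(1L), sites = sites,
                  USE.NAMES = FALSE)
  if (anyDuplicated(masks)) {
    dup <- which(duplicated(masks) | duplicated(masks, fromLast = TRUE))
    stop("duplicate genotype rows on line(s) ",
         paste(dup + 1L, collapse = ", "))
  }
  if (!0L %in% masks) stop("missing ancestor row")
  n <- 2L^L
  lambda <- rep(NA_real_, n)
  functional <- rep(NA, n)
  lambda[masks + 1L] <- ifelse(fun, lam, NA_real_)
  functional[masks + 1L] <- fun
  landscape(sites, lambda[1L], lambda = lambda, functional = functional)
}

#' Write a landscape to TSV
#'
#' Inverse of [parse_landscape()]: one row per present genotype in
#' size-then-mask order, nonfunctional rows written with `NF`.
#' Imputed lambdas are not written — only measured phenotypes round-trip.
#'
#' @param ls a [landscape()].
#' @param path output path.
#' @param digits decimal places for lambda (default 1; the assay convention
#'   reports whole nm, formatting is a choice).
#' @return `path`, invisibly.
#' @export
write_landscape <- function(ls, path, digits = 1L) {
  df <- as.data.frame(ls)
  measured <- df$source %in% "measured"
  lam <- ifelse(df$functional & measured, round(df$lambda_max, digits), NA)
  out <- data.frame(
    genotype = df$genotype,
    lambda_max = ifelse(is.na(lam), "NF", format(lam, trim = TRUE)),
    functional = ifelse(df$functional, "true", "false"),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write an effect table to TSV
#'
#' Columns `subset`, `order`, `theta`, `se`, `p`, `imputed` (SE/p columns
#' included when present).
#'
#' @param effects an `effect_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_effect_table <- function(effects, path) {
  cols <- intersect(c("subset", "order", "theta", "se", "p", "imputed"),
                    names(effects))
  utils::write.table(as.data.frame(effects)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a taxa-by-sites character matrix from CSV
#'
#' Rows are taxa (first column holds the taxon name), remaining columns are
#' site labels with single-letter amino-acid states.
#'
#' @param path path to the CSV.
#' @return character matrix with taxon rownames.
#' @export
parse_characters <- function(path) {
  df <- utils::read.csv(path, header = TRUE, colClasses = "character",
                        fileEncoding = "UTF-8", check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  if (any(nchar(m) != 1L))
    stop("character states must be single letters")
  m
}

#' Run the full analysis pipeline and write a report bundle
#'
#' Decomposes the landscape (with imputation, standard errors and
#' significance), enumerates and summarises all trajectories, and — when a
#' tree and character matrix are supplied — infers the substitution order
#' and the constrained trajectory set. Writes `effects.tsv`,
#' `trajectories.tsv`, `summary.json` and (if ordering ran)
#' `constrained_paths.tsv` under `out_dir`. The summary embeds the full
#' configuration, so identical configurations give byte-identical output.
#'
#' @param ls a complete [landscape()] (or a path to a landscape TSV).
#' @param out_dir output directory (created if needed); `NULL` skips file
#'   output.
#' @param tree optional `ape::phylo` for substitution ordering.
#' @param characters optional character matrix matching the tree's tips.
#' @param focal_tip focal lineage tip label (required with `tree`).
#' @param step_threshold_nm per-step classification threshold (default 25,
#'   strict).
#' @param split_threshold_nm variance-split threshold (default 30, strict).
#' @param theta_cutoff_nm report interactions with `|theta|` at or above
#'   this cutoff (default 5).
#' @param population_variance use the n denominator for step variances.
#' @param seed echoed into the report for provenance (no randomness is
#'   used by the pipeline itself).
#' @return list with `effects`, `landscape` (imputed), `trajectories`,
#'   `summary` (the JSON-ready list) and, when ordering ran, `placement`,
#'   `partial_orders` and `constrained`.
#' @export
run_pipeline <- function(ls, out_dir = NULL, tree = NULL, characters = NULL,
                         focal_tip = NULL, step_threshold_nm = 25,
                         split_threshold_nm = 30, theta_cutoff_nm = 5,
                         population_variance = FALSE, seed = NULL) {
  if (is.character(ls)) ls <- parse_landscape(ls)
  stopifnot(inherits(ls, "landscape"))
  if (step_threshold_nm <= 0 || split_threshold_nm <= 0 ||
      theta_cutoff_nm < 0)
    stop("thresholds must be positive")

  fit <- decompose(ls)
  system <- build_design_system(fit$landscape)
  se <- standard_errors(system)
  effects <- significance(fit$effects, se = se)

  trj <- enumerate_trajectories(ls)
  summ <- count_accessible(ls)
  cls <- classify_by_step(trj, step_threshold_nm, strict = TRUE)
  vsplit <- path_variance_distribution(trj, split_threshold_nm,
                                       population = population_variance)

  big <- effects[effects$order >= 2L & abs(effects$theta) >= theta_cutoff_nm, ]
  report <- list(
    config = list(
      sites = ls$sites, lambda_anc = ls$lambda_anc,
      step_threshold_nm = step_threshold_nm,
      split_threshold_nm = split_threshold_nm,
      theta_cutoff_nm = theta_cutoff_nm,
      variance_denominator = if (population_variance) "n" else "n-1",
      seed = seed
    ),
    landscape = list(
      n_genotypes = 2L^ls$L,
      n_nonfunctional = sum(!ls$functional),
      n_imputed = sum(fit$landscape$source == "imputed")
    ),
    trajectories = list(
      total = summ$total, accessible = summ$accessible,
      terminated = summ$terminated,
      fraction_accessible = summ$fraction_accessible,
      per_first_mutation = as.list(summ$per_first_mutation),
      step_class = list(threshold_nm = step_threshold_nm,
                        within = cls$n_within,
                        exceeding = cls$n_exceeding),
      variance_split = list(
        threshold_nm = split_threshold_nm,
        n_with_large = length(vsplit$with_large),
        n_without_large = length(vsplit$without_large),
        mean_var_with_large = if (length(vsplit$with_large))
          mean(vsplit$with_large) else NA,
        mean_var_without_large = if (length(vsplit$without_large))
          mean(vsplit$without_large) else NA)
    ),
    large_interactions = list(
      cutoff_nm = theta_cutoff_nm,
      n = nrow(big),
      n_interaction_terms = sum(effects$order >= 2L),
      subsets = big$subset, theta = big$theta
    ),
    versions = list(
      package = as.character(utils::packageVersion("lambdascape")),
      r = paste(R.version$major, R.version$minor, sep = ".")
    )
  )

  out <- list(effects = effects, landscape = fit$landscape,
              trajectories = trj, summary = report)

  if (!is.null(tree)) {
    if (is.null(characters) || is.null(focal_tip))
      stop("ordering stage needs both `characters` and `focal_tip`")
    placement <- place_substitutions(tree, characters, focal_tip,
                                     sites = ls$sites)
    pos <- partial_orders(placement)
    report$ordering <- list(
      n_partial_orders = length(pos),
      groups = lapply(pos[[1L]], identity),
      n_constrained = linear_extensions(pos[[1L]])$count
    )
    constrained <- constrained_paths(ls, pos[[1L]], effects = effects)
    out$placement <- placement
    out$partial_orders <- pos
    out$constrained <- constrained
    out$summary <- report
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_effect_table(effects, file.path(out_dir, "effects.tsv"))
    utils::write.table(as.data.frame(trj),
                       file.path(out_dir, "trajectories.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    jsonlite::write_json(report, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null", na = "null")
    if (!is.null(out$constrained))
      utils::write.table(as.data.frame(out$constrained),
                         file.path(out_dir, "constrained_paths.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         fileEncoding = "UTF-8")
  }
  invisible(out)
}
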