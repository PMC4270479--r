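# Exhaustive enumeration and counting of mutational orderings.
#
# A trajectory is an ordering of all L mutations; it is accessible when
# every intermediate genotype AND the endpoint are functional, and is
# terminated at the first nonfunctional genotype otherwise. Phenotype
# profiles along a path use measured lambdas only — an imputed lambda
# belongs to a genotype evolution cannot pass through.

# all permutations of v, rows in lexicographic order when v is sorted
permutations <- function(v) {
  n <- length(v)
  if (n == 0L) return(matrix(v, 1L, 0L))
  if (n == 1L) return(matrix(v, 1L, 1L))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- permutations(v[-i])
    out[[i]] <- cbind(v[i], rest, deparse.level = 0L)
  }
  do.call(rbind, out)
}

# prefix genotype masks for a matrix of site-index orderings; distinct
# bits make bitwise-or a plain cumulative sum
prefix_masks <- function(P) {
  bitvals <- 2L^(0:(max(P) - 1L))
  res <- apply(P, 1L, function(r) cumsum(bitvals[r]))
  if (is.null(dim(res))) matrix(res, ncol = 1L) else t(res)
}

#' Enumerate all mutational trajectories over a landscape
#'
#' Generates every ordering of the L mutations (lexicographic in site
#' label order), walks each through the landscape, and records per-step
#' phenotype profiles. A trajectory stops at the first nonfunctional
#' genotype; its profile covers only the functional prefix.
#'
#' @param ls a complete [landscape()].
#' @param orderings optional integer matrix of site-index orderings (one
#'   row per path); defaults to all `L!` permutations. Used by
#'   [constrained_paths()].
#' @return An object of class `"trajectory_set"`: a list with
#'   \describe{
#'     \item{perm}{integer matrix of orderings (site indices).}
#'     \item{masks}{matrix of prefix genotype masks.}
#'     \item{lambda}{matrix of the lambda profile, `L + 1` columns starting
#'       at the ancestor; `NA` from the first nonfunctional genotype on.}
#'     \item{delta}{matrix of per-step lambda shifts (`L` columns).}
#'     \item{status}{`"complete"` or `"terminated"` per path.}
#'     \item{terminated_at}{step index of the first nonfunctional genotype
#'       (`NA` for complete paths).}
#'     \item{max_abs_delta, step_variance}{per-path summaries over the
#'       full profile (`NA` for terminated paths); the variance uses the
#'       n-1 denominator.}
#'   }
#' @examples
#' trj <- enumerate_trajectories(human_m_fixture())
#' table(trj$status)
#' @export
enumerate_trajectories <- function(ls, orderings = NULL) {
  stopifnot(inherits(ls, "landscape"))
  assert_complete(ls)
  L <- ls$L
  if (is.null(orderings)) {
    if (L > 10L)
      stop("brute-force enumeration refused for L > 10 (", L,
           " sites = ", format(factorial(L), big.mark = ","),
           " paths); use count_accessible() for counts")
    P <- permutations(seq_len(L))
  } else {
    P <- orderings
    stopifnot(ncol(P) == L)
  }
  masks <- prefix_masks(P)
  lambda_meas <- ls$lambda
  lambda_meas[ls$source %in% "imputed"] <- NA_real_
  fun <- matrix(ls$functional[masks + 1L], nrow(P), L)
  lam <- cbind(ls$lambda_anc,
               matrix(lambda_meas[masks + 1L], nrow(P), L),
               deparse.level = 0L)
  # first nonfunctional step per path (NA when all functional)
  term_at <- apply(fun, 1L, function(f) {
    w <- which(!f)
    if (length(w)) w[1L] else NA_integer_
  })
  # blank the profile from the first nonfunctional genotype on
  for (i in which(!is.na(term_at)))
    lam[i, (term_at[i] + 1L):(L + 1L)] <- NA_real_
  delta <- lam[, -1L, drop = FALSE] - lam[, -(L + 1L), drop = FALSE]
  complete <- is.na(term_at)
  max_abs <- ifelse(complete, apply(abs(delta), 1L, max), NA_real_)
  stepvar <- ifelse(complete & L >= 2L, apply(delta, 1L, stats::var),
                    NA_real_)
  structure(
    list(sites = ls$sites, perm = P, masks = masks, lambda = lam,
         delta = delta,
         status = ifelse(complete, "complete", "terminated"),
         terminated_at = term_at, max_abs_delta = max_abs,
         step_variance = stepvar),
    class = "trajectory_set"
  )
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("trajectory_set: %d paths over %d sites (%d complete, %d terminated)\n",
              nrow(x$perm), length(x$sites), sum(x$status == "complete"),
              sum(x$status == "terminated")))
  invisible(x)
}

#' @export
as.data.frame.trajectory_set <- function(x, ...) {
  fmt_profile <- function(i) {
    v <- x$lambda[i, !is.na(x$lambda[i, ])]
    paste(v, collapse = ";")
  }
  data.frame(
    ordering = apply(x$perm, 1L, function(r) paste(x$sites[r], collapse = ",")),
    status = x$status,
    terminated_at = x$terminated_at,
    lambda_profile = vapply(seq_len(nrow(x$perm)), fmt_profile, character(1L)),
    max_abs_delta = x$max_abs_delta,
    step_variance = x$step_variance,
    stringsAsFactors = FALSE
  )
}

#' Count accessible trajectories by dynamic programming on the lattice
#'
#' Counts orderings of all L mutations whose every intermediate genotype
#' and endpoint are functional, without enumerating permutations: the
#' number of accessible routes into each functional genotype is the sum of
#' the routes into its functional immediate predecessors (O(2^L * L)).
#' Also tracks counts by first mutation.
#'
#' @param ls a complete [landscape()].
#' @return An object of class `"trajectory_summary"`: list with `total`
#'   (`L!`), `accessible`, `terminated`, `fraction_accessible`, and
#'   `per_first_mutation` (named vector of accessible counts by initial
#'   mutation).
#' @examples
#' count_accessible(human_m_fixture())
#' @export
count_accessible <- function(ls) {
  stopifnot(inherits(ls, "landscape"))
  assert_complete(ls)
  L <- ls$L
  n <- 2L^L
  ways <- numeric(n)
  byfirst <- matrix(0, n, L)
  ways[1L] <- 1
  for (m in lattice_order(L)[-1L]) {
    if (!ls$functional[m + 1L]) next
    for (j in mask_sites(m)) {
      prev <- m - bit_mask(j)
      if (prev == 0L) {
        ways[m + 1L] <- ways[m + 1L] + 1
        byfirst[m + 1L, j] <- byfirst[m + 1L, j] + 1
      } else if (ls$functional[prev + 1L]) {
        ways[m + 1L] <- ways[m + 1L] + ways[prev + 1L]
        byfirst[m + 1L, ] <- byfirst[m + 1L, ] + byfirst[prev + 1L, ]
      }
    }
  }
  full <- n - 1L
  accessible <- ways[full + 1L]
  total <- factorial(L)
  per_first <- byfirst[full + 1L, ]
  names(per_first) <- ls$sites
  structure(
    list(total = total, accessible = accessible,
         terminated = total - accessible,
         fraction_accessible = accessible / total,
         per_first_mutation = per_first),
    class = "trajectory_summary"
  )
}

#' @export
print.trajectory_summary <- function(x, ...) {
  cat(sprintf("trajectories: %s total, %s accessible (%.2f%%), %s terminated\n",
              format(x$total, big.mark = ","),
              format(x$accessible, big.mark = ","),
              100 * x$fraction_accessible,
              format(x$terminated, big.mark = ",")))
  cat("accessible by first mutation:\n")
  print(x$per_first_mutation)
  invisible(x)
}

#' Partition accessible paths by their largest per-step shift
#'
#' Splits the complete (accessible) trajectories by whether the absolute
#' lambda shift at every step stays below a threshold. The default, 25 nm
#' with a strict inequality, separates gradual spectral tuning from paths
#' containing at least one large jump.
#'
#' @param trj a [enumerate_trajectories()] result.
#' @param threshold_nm positive threshold in nm (default 25).
#' @param strict logical; `TRUE` (default) compares `max |delta| <
#'   threshold`, `FALSE` uses `<=`.
#' @return list with `n_accessible`, `n_within` (all steps under the
#'   threshold), `n_exceeding`, `fraction_within`, and the row indices
#'   `within` / `exceeding` into `trj`.
#' @export
classify_by_step <- function(trj, threshold_nm = 25, strict = TRUE) {
  stopifnot(inherits(trj, "trajectory_set"))
  if (!is.numeric(threshold_nm) || threshold_nm <= 0)
    stop("threshold must be positive")
  acc <- which(trj$status == "complete")
  pass <- if (strict) trj$max_abs_delta[acc] < threshold_nm
          else trj$max_abs_delta[acc] <= threshold_nm
  list(
    n_accessible = length(acc),
    n_within = sum(pass),
    n_exceeding = sum(!pass),
    fraction_within = if (length(acc)) mean(pass) else NA_real_,
    within = acc[pass],
    exceeding = acc[!pass]
  )
}

#' Distribution of per-path step variances, split by large steps
#'
#' For every complete path, the variance of its L per-step lambda shifts;
#' the paths are split by whether any single step exceeds
#' `split_threshold_nm` (strict, signed). Gradual trajectories fall in the
#' low-variance group.
#'
#' @param trj a [enumerate_trajectories()] result.
#' @param split_threshold_nm split point in nm (default 30).
#' @param population logical; `FALSE` (default) uses the n-1 sample
#'   variance, `TRUE` divides by n.
#' @return list with numeric vectors `with_large` and `without_large`
#'   (variances of the two groups, named by path row index) and the
#'   denominator used.
#' @export
path_variance_distribution <- function(trj, split_threshold_nm = 30,
                                       population = FALSE) {
  stopifnot(inherits(trj, "trajectory_set"))
  acc <- which(trj$status == "complete")
  L <- ncol(trj$delta)
  v <- trj$step_variance[acc]
  if (population) v <- v * (L - 1) / L
  names(v) <- acc
  large <- apply(trj$delta[acc, , drop = FALSE] > split_threshold_nm, 1L, any)
  list(with_large = v[large], without_large = v[!large],
       denominator = if (population) "n" else "n-1")
}

#' Trajectories consistent with a branch-wise partial order
#'
#' Enumerates the complete orderings compatible with ordered groups of
#' mutations (mutations within a group occurred on the same branch, in
#' unknown internal order; groups occurred strictly in sequence), and
#' attaches each path's observed lambda profile plus the profile predicted
#' from epistatic interactions alone (effect terms of order >= 2 only).
#'
#' @param ls a complete [landscape()].
#' @param partial_order list of character vectors of mutation labels,
#'   root-most group first; groups must be disjoint and cover all sites.
#' @param effects optional `effect_table` (computed via [decompose()] if
#'   missing) used for the epistasis-only prediction.
#' @return a `"trajectory_set"` (see [enumerate_trajectories()]) with an
#'   extra matrix element `lambda_epistasis`: the min-order-2 predicted
#'   profile for each path.
#' @examples
#' fx <- s1_like_fixture()
#' cp <- constrained_paths(fx$landscape, fx$partial_order)
#' nrow(cp$perm)   # 8
#' @export
constrained_paths <- function(ls, partial_order, effects = NULL) {
  stopifnot(inherits(ls, "landscape"))
  flat <- unlist(partial_order)
  if (anyDuplicated(flat))
    stop("partial order groups must be disjoint")
  if (!setequal(flat, ls$sites) || length(flat) != ls$L)
    stop("partial order must cover exactly the landscape's sites")
  group_idx <- lapply(partial_order, function(g) match(g, ls$sites))
  # cartesian concatenation of within-group permutations, groups in order
  P <- matrix(integer(0), 1L, 0L)
  for (gi in group_idx) {
    gp <- permutations(gi)
    P <- do.call(rbind, lapply(seq_len(nrow(P)), function(i)
      cbind(matrix(P[i, ], nrow(gp), ncol(P), byrow = TRUE), gp,
            deparse.level = 0L)))
  }
  trj <- enumerate_trajectories(ls, orderings = P)
  if (is.null(effects)) effects <- decompose(ls)$effects
  epi <- t(apply(trj$masks, 1L, function(ms)
    c(attr(effects, "lambda_anc"),
      vapply(ms, function(m) reconstruct(effects, m, min_order = 2L),
             numeric(1L)))))
  trj$lambda_epistasis <- epi
  trj
}
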