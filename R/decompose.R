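#' Factorial decomposition of a phenotype landscape into effect terms
#'
#' Expresses every genotype's lambda-max as the ancestral lambda plus the
#' sum of effect terms theta over all non-empty subsets of its mutations:
#' \deqn{\lambda(g) = \lambda_{anc} + \sum_{\emptyset \ne T \subseteq g} \theta_T.}
#' Order-1 terms are main effects of single mutations; order >= 2 terms are
#' epistatic interactions. With all \eqn{2^L} genotypes observed this is a
#' square triangular linear system (one equation per genotype) solved
#' exactly by forward substitution in subset-size order.
#'
#' Nonfunctional genotypes carry no phenotype, so their highest-order term
#' cannot be estimated; processing subsets in increasing size, such a
#' genotype's own theta is set to exactly 0, the genotype is flagged
#' imputed, and its lambda is reconstructed from the already-estimated
#' lower-order terms. Because imputation proceeds bottom-up it cascades
#' naturally through nested nonfunctional genotypes.
#'
#' @param ls a complete [landscape()]: every genotype listed, possibly
#'   nonfunctional; the ancestor functional.
#' @return A list with components:
#'   \describe{
#'     \item{effects}{an `effect_table` data frame: one row per non-empty
#'       subset (columns `subset`, `mask`, `order`, `theta`, `imputed`),
#'       sorted by order then mask, with attributes `sites` and
#'       `lambda_anc`.}
#'     \item{landscape}{the input landscape with imputed lambdas filled in
#'       (`source = "imputed"`).}
#'   }
#' @examples
#' hm <- human_m_fixture()
#' fit <- decompose(hm)
#' subset(fit$effects, order == 1)
#' @seealso [mobius_decompose()] for the closed-form inversion,
#'   [reconstruct()], [standard_errors()], [significance()].
#' @export
decompose <- function(ls) {
  stopifnot(inherits(ls, "landscape"))
  assert_complete(ls)
  n <- 2L^ls$L
  theta <- numeric(n)          # theta[mask+1]; position 1 (empty set) stays 0
  lambda <- ls$lambda
  source <- ls$source
  imputed <- logical(n)
  for (m in lattice_order(ls$L)[-1L]) {
    subs <- submasks(m)
    subs <- subs[subs != m & subs != 0L]
    psum <- if (length(subs)) sum(theta[subs + 1L]) else 0
    if (ls$functional[m + 1L]) {
      theta[m + 1L] <- lambda[m + 1L] - ls$lambda_anc - psum
    } else {
      theta[m + 1L] <- 0
      imputed[m + 1L] <- TRUE
      lambda[m + 1L] <- ls$lambda_anc + psum
      source[m + 1L] <- "imputed"
    }
  }
  out_ls <- ls
  out_ls$lambda <- lambda
  out_ls$source <- source
  list(
    effects = new_effect_table(theta, imputed, ls$sites, ls$lambda_anc),
    landscape = out_ls
  )
}

# effect-table constructor shared by the decomposition routines
new_effect_table <- function(theta, imputed, sites, lambda_anc,
                             masks = NULL, se = NULL, p = NULL) {
  L <- length(sites)
  if (is.null(masks)) masks <- lattice_order(L)[-1L]
  df <- data.frame(
    subset = mask_label(masks, sites),
    mask = masks,
    order = popcount(masks),
    theta = theta[masks + 1L],
    imputed = imputed[masks + 1L],
    stringsAsFactors = FALSE
  )
  if (!is.null(se)) df$se <- se[masks + 1L]
  if (!is.null(p)) df$p <- p[masks + 1L]
  attr(df, "sites") <- sites
  attr(df, "lambda_anc") <- lambda_anc
  class(df) <- c("effect_table", "data.frame")
  df
}

# theta for one subset, by mask; 0 for the empty set
effect_theta <- function(effects, mask) {
  if (mask == 0L) return(0)
  i <- match(mask, effects$mask)
  if (is.na(i)) stop("effect table has no entry for mask ", mask)
  effects$theta[i]
}

#' Moebius inversion of a landscape (independent route to the effects)
#'
#' Computes every effect term directly by inclusion-exclusion on the
#' subset lattice,
#' \deqn{\theta_S = \sum_{T \subseteq S} (-1)^{|S|-|T|} \lambda(T),}
#' with \eqn{\lambda(\emptyset) = \lambda_{anc}}. Requires every lambda to
#' be present (run [decompose()] first if the landscape has nonfunctional
#' genotypes, and pass its imputed landscape). Exists as an algebraically
#' independent cross-check of the forward-substitution solve; the two must
#' agree exactly.
#'
#' @param ls a complete [landscape()] with all lambdas present.
#' @return An `effect_table` as in [decompose()] (no `imputed` information:
#'   the column is all `FALSE`).
#' @export
mobius_decompose <- function(ls) {
  stopifnot(inherits(ls, "landscape"))
  assert_complete(ls)
  if (anyNA(ls$lambda))
    stop("mobius_decompose needs every lambda present; impute first via decompose()")
  n <- 2L^ls$L
  theta <- numeric(n)
  sz <- popcount(0:(n - 1L))
  for (m in seq_len(n - 1L)) {          # m is the mask here (skip empty set)
    subs <- submasks(m)
    sign <- (-1)^(sz[m + 1L] - sz[subs + 1L])
    theta[m + 1L] <- sum(sign * ls$lambda[subs + 1L])
  }
  new_effect_table(theta, logical(n), ls$sites, ls$lambda_anc)
}

#' Reconstruct a genotype's phenotype from effect terms
#'
#' Sums the ancestral lambda and the theta of every non-empty subset of the
#' genotype with order at least `min_order`. `min_order = 1` reproduces the
#' observed (or imputed) lambda exactly; `min_order = 2` gives the
#' prediction from epistatic interactions alone, with all main effects
#' suppressed.
#'
#' @param effects an `effect_table` from [decompose()] or
#'   [mobius_decompose()].
#' @param g genotype (mask, label vector, or "+"-joined string).
#' @param min_order smallest subset order to include (default 1).
#' @return predicted lambda-max in nm.
#' @examples
#' fit <- decompose(human_m_fixture())
#' reconstruct(fit$effects, c("S180A", "Y277F"))   # 545
#' @export
reconstruct <- function(effects, g, min_order = 1L) {
  sites <- attr(effects, "sites")
  m <- genotype_mask(g, sites)
  if (m == 0L) return(attr(effects, "lambda_anc"))
  subs <- submasks(m)
  subs <- subs[subs != 0L & popcount(subs) >= min_order]
  th <- if (length(subs)) {
    idx <- match(subs, effects$mask)
    if (anyNA(idx))
      stop("effect table incomplete for genotype ", mask_label(m, sites))
    sum(effects$theta[idx])
  } else 0
  attr(effects, "lambda_anc") + th
}

#' The subset-incidence linear system behind the decomposition
#'
#' Builds the coefficient matrix C (rows = genotypes, columns = effect
#' terms, entries 1 where the column's subset is contained in the row's
#' genotype), the observation vector Y of lambda-max values in the same
#' ordering, and the observation variance-covariance V (identity by
#' default: unit variance, zero covariance). Under subset-size-then-mask
#' ordering C is unit lower-triangular, so `solve(C, Y)` is an exact
#' forward substitution.
#'
#' @param ls a complete [landscape()] with all lambdas present (use the
#'   imputed landscape from [decompose()] when there are nonfunctional
#'   genotypes).
#' @param V observation variance-covariance matrix (`2^L` square); default
#'   identity.
#' @return list with `C`, `Y`, `V`, `masks` (row/column genotype masks, in
#'   order), and `sites`.
#' @export
build_design_system <- function(ls, V = NULL) {
  stopifnot(inherits(ls, "landscape"))
  assert_complete(ls)
  if (anyNA(ls$lambda)) {
    miss <- which(is.na(ls$lambda)) - 1L
    stop("missing phenotypes for genotypes: ",
         paste(mask_label(miss, ls$sites), collapse = ", "),
         "; impute first via decompose()")
  }
  if (ls$L > 12L)
    stop("dense design system limited to L <= 12")
  masks <- lattice_order(ls$L)
  n <- length(masks)
  C <- matrix(0L, n, n, dimnames = list(mask_label(masks, ls$sites),
                                        mask_label(masks, ls$sites)))
  for (i in seq_len(n)) {
    subs <- submasks(masks[i])
    C[i, match(subs, masks)] <- 1L
  }
  if (is.null(V)) V <- diag(n)
  stopifnot(nrow(V) == n, ncol(V) == n)
  list(C = C, Y = ls$lambda[masks + 1L], V = V, masks = masks,
       sites = ls$sites)
}

#' Standard errors of the effect estimates
#'
#' The effects are linear in the observations, X = C^-1 Y, so their
#' covariance is C^-1 V (C^-1)'. With V = I (each lambda measured with unit
#' variance, independently) the standard error of theta_S has the closed
#' form \eqn{2^{|S|/2}}: the estimate is a signed sum over the \eqn{2^{|S|}}
#' subsets of S with coefficients +/-1.
#'
#' @param system a design system from [build_design_system()].
#' @return named numeric vector of standard errors, one per genotype/subset
#'   in the system's ordering (the empty set's entry is the SE of the
#'   ancestral lambda itself, 1 under V = I).
#' @export
standard_errors <- function(system) {
  ev <- eigen(system$V, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8))
    stop("V must be positive semidefinite")
  Cinv <- tryCatch(solve(system$C),
                   error = function(e) stop("singular coefficient matrix"))
  se <- sqrt(pmax(diag(Cinv %*% system$V %*% t(Cinv)), 0))
  names(se) <- colnames(system$C)
  se
}

#' Two-sided significance of effect terms
#'
#' z-tests each theta against 0 using its standard error (normal
#' reference), flagging p < 0.05 with one star and p < 0.01 with two. No
#' multiple-testing correction by default; `adjust = "BH"` applies
#' Benjamini-Hochberg across all terms.
#'
#' @param effects an `effect_table`.
#' @param se standard errors: either a vector aligned with
#'   `effects$subset` names (as from [standard_errors()]) or a single
#'   number; default the V = I closed form `2^(order/2)`.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return the effect table with columns `se`, `p`, `stars` added.
#' @export
significance <- function(effects, se = NULL, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is.null(se)) {
    se <- 2^(effects$order / 2)
  } else if (!is.null(names(se))) {
    se <- unname(se[effects$subset])
    if (anyNA(se)) stop("se vector does not cover every subset")
  } else if (length(se) == 1L) {
    se <- rep(se, nrow(effects))
  }
  stopifnot(length(se) == nrow(effects), all(se >= 0))
  z <- ifelse(se > 0, effects$theta / se, NA_real_)
  p <- 2 * stats::pnorm(-abs(z))
  zero_se <- se == 0
  if (any(zero_se)) {
    nonzero_theta <- zero_se & effects$theta != 0
    if (any(nonzero_theta))
      warning("zero SE with nonzero theta: p set to 0 for ",
              paste(effects$subset[nonzero_theta], collapse = ", "))
    p[zero_se] <- ifelse(effects$theta[zero_se] == 0, 1, 0)
  }
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  effects$se <- se
  effects$p <- p
  effects$stars <- ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
  effects
}

#' Decomposition restricted to structurally stable (functional) genotypes
#'
#' Runs the same size-ordered forward substitution using only functional
#' genotypes: terms whose subsets are nonfunctional (or absent) are skipped
#' — they contribute zero, exactly as the full analysis forces their theta
#' to zero by imputation. Returns theta only for the estimable subsets;
#' every returned value equals the corresponding term of the full imputed
#' decomposition exactly.
#'
#' Unlike [decompose()], tolerates landscapes where nonfunctional genotypes
#' are simply absent (unlisted genotypes are treated as inestimable).
#'
#' @param ls a [landscape()]; the ancestor must be functional.
#' @return an `effect_table` covering only the functional subsets.
#' @export
decompose_stable_only <- function(ls) {
  stopifnot(inherits(ls, "landscape"))
  n <- 2L^ls$L
  ok <- ls$functional %in% TRUE        # NA (absent) counts as not estimable
  theta <- numeric(n)
  for (m in lattice_order(ls$L)[-1L]) {
    if (!ok[m + 1L]) next
    subs <- submasks(m)
    subs <- subs[subs != m & subs != 0L]
    subs <- subs[ok[subs + 1L]]
    psum <- if (length(subs)) sum(theta[subs + 1L]) else 0
    theta[m + 1L] <- ls$lambda[m + 1L] - ls$lambda_anc - psum
  }
  masks <- lattice_order(ls$L)[-1L]
  masks <- masks[ok[masks + 1L]]
  new_effect_table(theta, logical(n), ls$sites, ls$lambda_anc, masks = masks)
}
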