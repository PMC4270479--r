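#' Construct a phenotype landscape on the mutational hypercube
#'
#' A landscape holds the phenotype (lambda-max, in nm) of genotypes drawn
#' from the \eqn{2^L} subsets of L named mutations, anchored at a functional
#' ancestor. Genotypes may be nonfunctional (no measurable absorbance peak),
#' in which case their lambda is unknown until imputed by [decompose()].
#'
#' @param sites ordered character vector of the L unique mutation labels,
#'   e.g. `c("F46T", "F49L", ...)`. `1 <= L <= 20`.
#' @param lambda_anc ancestral phenotype in nm; the lambda of the empty
#'   genotype.
#' @param lambda numeric vector of length `2^L` giving lambda-max by
#'   genotype bitmask (index `mask + 1`); `NA` where unmeasured. If omitted,
#'   only the ancestor is set.
#' @param functional logical vector of length `2^L`; `NA` marks genotypes
#'   absent from the data (allowed only for incomplete landscapes).
#' @param source character vector, `"measured"` or `"imputed"`, parallel to
#'   `lambda`.
#' @return An object of class `"landscape"`: a list with elements `sites`,
#'   `L`, `lambda_anc`, `lambda`, `functional`, `source`, `complete`.
#' @examples
#' ls <- landscape(c("a", "b"), 100, lambda = c(100, 101, 103, 110),
#'                 functional = rep(TRUE, 4))
#' ls
#' @export
landscape <- function(sites, lambda_anc, lambda = NULL, functional = NULL,
                      source = NULL) {
  sites <- as.character(sites)
  L <- length(sites)
  if (L < 1L || L > 20L)
    stop("need between 1 and 20 sites (the 2^L lattice must be materializable)")
  if (anyDuplicated(sites) || any(!nzchar(sites)))
    stop("site labels must be unique and non-empty")
  n <- 2L^L
  if (is.null(lambda)) {
    lambda <- rep(NA_real_, n)
    lambda[1L] <- lambda_anc
  }
  if (is.null(functional)) functional <- !is.na(lambda)
  if (is.null(source)) {
    source <- rep(NA_character_, n)
    source[!is.na(lambda)] <- "measured"
  }
  stopifnot(length(lambda) == n, length(functional) == n, length(source) == n)
  lambda <- as.numeric(lambda)
  functional <- as.logical(functional)
  if (is.na(functional[1L]) || !functional[1L] || is.na(lambda[1L]))
    stop("ancestor must be present and functional with a measured lambda")
  if (!isTRUE(all.equal(lambda[1L], as.numeric(lambda_anc))))
    stop("ancestor lambda must equal lambda_anc")
  bad <- which(functional %in% TRUE & is.na(lambda) & is.na(source))
  if (length(bad))
    stop("functional genotypes without lambda: ",
         paste(mask_label(bad - 1L, sites), collapse = ", "))
  structure(
    list(sites = sites, L = L, lambda_anc = as.numeric(lambda_anc),
         lambda = lambda, functional = functional, source = source,
         complete = !anyNA(functional)),
    class = "landscape"
  )
}

#' @export
print.landscape <- function(x, ...) {
  nf <- sum(!x$functional, na.rm = TRUE)
  imp <- sum(x$source == "imputed", na.rm = TRUE)
  cat(sprintf(
    "landscape: %d sites (%s), lambda_anc = %g nm\n", x$L,
    paste(x$sites, collapse = ", "), x$lambda_anc))
  cat(sprintf("  %d/%d genotypes present, %d nonfunctional, %d imputed\n",
              sum(!is.na(x$functional)), 2L^x$L, nf, imp))
  invisible(x)
}

#' @export
as.data.frame.landscape <- function(x, ...) {
  masks <- lattice_order(x$L)
  present <- !is.na(x$functional[masks + 1L])
  masks <- masks[present]
  data.frame(
    genotype = mask_label(masks, x$sites),
    order = popcount(masks),
    lambda_max = x$lambda[masks + 1L],
    functional = x$functional[masks + 1L],
    source = x$source[masks + 1L],
    stringsAsFactors = FALSE
  )
}

#' Look up the phenotype of a genotype
#'
#' @param ls a [landscape()].
#' @param g genotype (mask, label vector, or "+"-joined string).
#' @return lambda-max in nm (`NA` if unmeasured).
#' @export
landscape_lambda <- function(ls, g) {
  ls$lambda[genotype_mask(g, ls$sites) + 1L]
}

#' Is a genotype functional?
#' @inheritParams landscape_lambda
#' @export
landscape_functional <- function(ls, g) {
  ls$functional[genotype_mask(g, ls$sites) + 1L]
}

# internal: stop unless every genotype is listed (possibly nonfunctional)
assert_complete <- function(ls) {
  if (!ls$complete) {
    missing <- which(is.na(ls$functional)) - 1L
    stop("missing phenotypes for genotypes: ",
         paste(utils::head(mask_label(missing, ls$sites), 10L),
               collapse = ", "),
         if (length(missing) > 10L) sprintf(" (and %d more)",
                                            length(missing) - 10L))
  }
  invisible(ls)
}
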